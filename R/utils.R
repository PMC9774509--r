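# Internal helpers: seeded evaluation, numeric clamps, structured logging.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomness in the package flows
# through this so that a seed fully determines every artifact.
with_seed_ <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite number.", class = "koi_argument_error")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed < 2^31 from a parent seed and stream labels.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.numeric(p) %% 2147483647) %% 2147483647
  as.integer(s %% 2147483562) + 1L
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_koi <- function(msg, class) rlang::abort(msg, class = c(class, "koi_error"))

#' Emit a timestamped log line
#'
#' Writes a level-tagged, timestamped line to `stderr` and, when `file` is
#' set, appends the same line to that log file.
#'
#' @param msg Message text.
#' @param level One of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param file Optional path of a log file to append to.
#' @return `msg`, invisibly.
#' @export
koi_log <- function(msg, level = "INFO", file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, msg)
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
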