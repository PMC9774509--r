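MANIFEST_COLS <- c("path", "class_id", "class_name", "split", "provenance",
                   "transform_json", "seed")
SPLIT_LEVELS <- c("train", "val", "test", "unassigned")

#' Validate a dataset manifest
#'
#' A manifest is a tibble with one row per image and columns `path`,
#' `class_id`, `class_name`, `split` (train/val/test/unassigned),
#' `provenance` (original/augmented), `transform_json` and `seed`. Paths must
#' be unique and class ids non-negative.
#'
#' @param m Candidate manifest.
#' @return `m`, invisibly, or an error describing the violation.
#' @export
validate_manifest <- function(m) {
  if (!is.data.frame(m)) stop_koi("Manifest must be a data frame.", "koi_schema_error")
  missing <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing)) {
    stop_koi(paste0("Manifest is missing column(s): ",
                    paste(missing, collapse = ", ")), "koi_schema_error")
  }
  if (nrow(m)) {
    if (anyDuplicated(m$path)) {
      stop_koi("Manifest contains duplicate paths.", "koi_schema_error")
    }
    bad <- setdiff(unique(m$split), SPLIT_LEVELS)
    if (length(bad)) {
      stop_koi(paste0("Unknown split token(s): ", paste(bad, collapse = ", ")),
               "koi_parse_error")
    }
    if (any(!m$provenance %in% c("original", "augmented"))) {
      stop_koi("`provenance` must be 'original' or 'augmented'.", "koi_parse_error")
    }
    if (any(m$class_id < 0)) stop_koi("Negative class_id.", "koi_schema_error")
  }
  invisible(m)
}

#' Read / write manifest CSVs
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a validated manifest tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing)) {
    stop_koi(paste0("Manifest is missing column(s): ",
                    paste(missing, collapse = ", ")), "koi_schema_error")
  }
  m$class_id <- as.integer(m$class_id)
  m$seed <- as.integer(m$seed)
  m$transform_json[is.na(m$transform_json)] <- ""
  validate_manifest(m)
  m
}

#' @param m A manifest tibble.
#' @rdname read_manifest
#' @export
write_manifest <- function(m, path) {
  validate_manifest(m)
  readr::write_csv(m, path)
  invisible(path)
}

#' Per-class, per-split sample counts
#'
#' @param m A manifest.
#' @return Tibble with one row per class and one count column per split.
#' @export
manifest_counts <- function(m) {
  validate_manifest(m)
  m |>
    dplyr::count(.data$class_id, .data$class_name, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n", values_fill = 0L) |>
    dplyr::arrange(.data$class_id)
}

#' Stratified train/val/test split
#'
#' Assigns every manifest row to train, val or test, per class, using
#' largest-remainder rounding of the requested ratios (ties broken in the
#' fixed order train, val, test) and a seeded shuffle within each class, so
#' the same seed always yields the same assignment. The defaults (0.70, 0.20,
#' 0.10) mirror the proportions of the original study's 1027/294/143 split of
#' its 1464-image dataset.
#'
#' @param m A manifest.
#' @param ratios Length-3 non-negative vector `(train, val, test)` summing
#'   to 1.
#' @param seed Integer seed.
#' @return The manifest with its `split` column filled in.
#' @examples
#' \dontrun{
#' manifest |> stratified_split(c(0.7, 0.2, 0.1), seed = 1) |> manifest_counts()
#' }
#' @export
stratified_split <- function(m, ratios = c(0.70, 0.20, 0.10), seed = 1L) {
  validate_manifest(m)
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop_koi("`ratios` must be 3 non-negative numbers summing to 1.",
             "koi_argument_error")
  }
  cls_sizes <- table(m$class_id)
  if (any(cls_sizes < 3)) {
    stop_koi("Every class needs at least 3 samples to stratify.",
             "koi_stratification_error")
  }
  m$split <- NA_character_
  with_seed_(derive_seed(seed, 101L), {
    for (cid in sort(unique(m$class_id))) {
      idx <- which(m$class_id == cid)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      quota <- n * ratios
      base <- floor(quota)
      rem <- quota - base
      leftover <- n - sum(base)
      if (leftover > 0) {
        # largest remainder; ties resolved in train < val < test order
        ord <- order(-rem, seq_along(rem))
        base[ord[seq_len(leftover)]] <- base[ord[seq_len(leftover)]] + 1L
      }
      lab <- rep(c("train", "val", "test"), times = base)
      m$split[idx] <- lab
    }
  })
  validate_manifest(m)
  m
}
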