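#' Architecture width configuration
#'
#' Channel and layer widths of the residual AlexNet-style network: an
#' AlexNet-derived stem whose local response normalization is replaced by
#' batch normalization, eight identity-skip residual blocks at constant
#' width, and a two-layer fully-connected head. The published account of the
#' architecture pins its structural counts (71 layers, 78 connections, eight
#' skip connections, roughly 10.9 M parameters) but not its channel widths;
#' the defaults here (64/192/192/768 at 227 x 227 input) are the package's
#' reconstruction that lands on those counts. The `"desk"` preset is a
#' reduced configuration (16/32/32/128 at 64 x 64, stride-2 stem) sized for
#' CPU-scale runs on the synthetic dataset.
#'
#' @param preset `"default"` (full-scale) or `"desk"` (reduced).
#' @param ... Named overrides of individual fields.
#' @return A list of class `koi_width_config` with fields `conv1_channels`,
#'   `conv1_stride`, `conv2_channels`, `residual_channels`,
#'   `n_residual_blocks`, `fc6_width`, `input_size`, `n_classes`,
#'   `dropout_rate`.
#' @examples
#' width_config()
#' width_config("desk", n_residual_blocks = 4)
#' @export
width_config <- function(preset = c("default", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- list(conv1_channels = 64L, conv1_stride = 4L, conv2_channels = 192L,
              residual_channels = 192L, n_residual_blocks = 8L,
              fc6_width = 768L, input_size = 227L, n_classes = 13L,
              dropout_rate = 0.5)
  if (preset == "desk") {
    cfg[c("conv1_channels", "conv1_stride", "conv2_channels",
          "residual_channels", "fc6_width", "input_size")] <-
      list(16L, 2L, 32L, 32L, 128L, 64L)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop_koi(paste0("Unknown width_config field(s): ", paste(bad, collapse = ", ")),
             "koi_config_error")
  }
  cfg[names(over)] <- over
  num <- setdiff(names(cfg), "dropout_rate")
  if (any(vapply(cfg[num], function(x) !is_count(x) || x < 1, TRUE)) &&
      cfg$n_residual_blocks != 0) {
    stop_koi("All width_config sizes must be positive integers.", "koi_config_error")
  }
  if (cfg$n_residual_blocks < 0) stop_koi("Negative block count.", "koi_config_error")
  if (cfg$residual_channels != cfg$conv2_channels) {
    stop_koi("Identity-skip design requires residual_channels == conv2_channels.",
             "koi_config_error")
  }
  structure(cfg, class = "koi_width_config")
}

node_row <- function(id, kind, ...) {
  tibble::tibble(id = as.integer(id), kind = kind, hyper = list(list(...)))
}

#' Build the residual network graph
#'
#' Constructs the layer DAG: a 9-node stem (input; 11x11 conv; batchnorm;
#' relu; 3x3/2 maxpool; 5x5 conv; batchnorm; relu; maxpool), then
#' `n_residual_blocks` identity-skip residual blocks of 7 nodes each
#' (conv-bn-relu-conv-bn-addition-relu, with the block input short-cut into
#' the addition), then a 6-node head (maxpool; fc; relu; dropout; fc to
#' `n_classes`; softmax). With the default eight blocks this yields 71 layer
#' nodes and 78 directed connections, eight of them skip connections.
#'
#' @param cfg A [width_config()].
#' @return A validated `koi_network`: list with `nodes` (tibble `id`, `kind`,
#'   `hyper`), `edges` (tibble `from`, `to`), `cfg` and inferred `shapes`.
#' @examples
#' net <- build_network(width_config())
#' nrow(net$nodes); nrow(net$edges)
#' @export
build_network <- function(cfg = width_config()) {
  stopifnot(inherits(cfg, "koi_width_config"))
  nodes <- list()
  add_node <- function(kind, ...) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- node_row(id, kind, ...)
    id
  }
  # stem
  add_node("input")
  add_node("conv", kh = 11L, kw = 11L, stride = cfg$conv1_stride, pad = 0L,
           cin = 3L, cout = cfg$conv1_channels)
  add_node("batchnorm", channels = cfg$conv1_channels)
  add_node("relu")
  add_node("maxpool", win = 3L, stride = 2L)
  add_node("conv", kh = 5L, kw = 5L, stride = 1L, pad = 2L,
           cin = cfg$conv1_channels, cout = cfg$conv2_channels)
  add_node("batchnorm", channels = cfg$conv2_channels)
  add_node("relu")
  last <- add_node("maxpool", win = 3L, stride = 2L)

  edges_from <- seq_len(last - 1L)
  edges_to <- seq_len(last - 1L) + 1L
  skip_edges <- NULL
  ch <- cfg$residual_channels
  for (b in seq_len(cfg$n_residual_blocks)) {
    entry <- last
    add_node("conv", kh = 3L, kw = 3L, stride = 1L, pad = 1L, cin = ch, cout = ch)
    add_node("batchnorm", channels = ch)
    add_node("relu")
    add_node("conv", kh = 3L, kw = 3L, stride = 1L, pad = 1L, cin = ch, cout = ch)
    add_node("batchnorm", channels = ch)
    add_id <- add_node("addition")
    last <- add_node("relu")
    new_ids <- (entry + 1L):last
    edges_from <- c(edges_from, entry, new_ids[-length(new_ids)], entry)
    edges_to <- c(edges_to, new_ids, add_id)
    skip_edges <- c(skip_edges, add_id)
  }
  # head
  p_id <- add_node("maxpool", win = 3L, stride = 2L)
  fc6_id <- add_node("fc", win = NA_integer_, wout = cfg$fc6_width)
  r_id <- add_node("relu")
  d_id <- add_node("dropout", rate = cfg$dropout_rate)
  fc7_id <- add_node("fc", win = cfg$fc6_width, wout = cfg$n_classes)
  s_id <- add_node("softmax")
  edges_from <- c(edges_from, last, p_id, fc6_id, r_id, d_id, fc7_id)
  edges_to <- c(edges_to, p_id, fc6_id, r_id, d_id, fc7_id, s_id)

  g <- structure(list(
    nodes = dplyr::bind_rows(nodes),
    edges = tibble::tibble(from = as.integer(edges_from), to = as.integer(edges_to)),
    cfg = cfg
  ), class = "koi_network")
  g <- validate_network(g)
  g$shapes <- infer_shapes(g)
  # fc6 fan-in is only known once shapes are inferred
  sh <- g$shapes[[p_id]]
  g$nodes$hyper[[fc6_id]]$win <- as.integer(prod(sh))
  g
}

incoming <- function(g, id) g$edges$from[g$edges$to == id]

#' Validate a network graph
#'
#' Checks acyclicity, the single-source/single-sink property, and the
#' in-degree rules (addition nodes merge exactly two branches; every other
#' non-input node has one predecessor). Stores a topological order on the
#' graph.
#'
#' @param g A `koi_network`.
#' @return `g`, with attribute `validated = TRUE` and `topo` order attached.
#' @export
validate_network <- function(g) {
  n <- nrow(g$nodes)
  indeg <- tabulate(g$edges$to, n)
  outdeg <- tabulate(g$edges$from, n)
  if (sum(indeg == 0) != 1 || g$nodes$kind[indeg == 0] != "input") {
    stop_koi("Graph must have exactly one input node with in-degree 0.",
             "koi_validation_error")
  }
  if (sum(outdeg == 0) != 1) {
    stop_koi("Graph must have exactly one sink.", "koi_validation_error")
  }
  need2 <- g$nodes$kind == "addition"
  if (any(indeg[need2] != 2) || any(indeg[!need2 & g$nodes$kind != "input"] != 1)) {
    stop_koi("Addition nodes need in-degree 2; all other non-input nodes 1.",
             "koi_validation_error")
  }
  # Kahn's algorithm; leftover nodes indicate a cycle
  deg <- indeg
  queue <- which(deg == 0)
  topo <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (w in g$edges$to[g$edges$from == v]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0) queue <- c(queue, w)
    }
  }
  if (length(topo) != n) stop_koi("Graph has a cycle.", "koi_validation_error")
  attr(g, "validated") <- TRUE
  attr(g, "topo") <- topo
  g
}

#' Count skip connections
#'
#' For this single-source, single-sink series-parallel layer graph the number
#' of shortcut merges equals `|edges| - (|nodes| - 1)`: a pure chain
#' contributes zero and every residual block exactly one.
#'
#' @param g A validated `koi_network`.
#' @return Integer skip-connection count.
#' @export
count_skip_connections <- function(g) {
  if (!isTRUE(attr(g, "validated"))) {
    stop_koi("Graph must be validated first (see validate_network()).",
             "koi_validation_error")
  }
  nrow(g$edges) - (nrow(g$nodes) - 1L)
}

params_for_node <- function(kind, h) {
  switch(kind,
    conv = h$kh * h$kw * h$cin * h$cout + h$cout,
    fc = h$win * h$wout + h$wout,
    batchnorm = 2 * h$channels,  # learned scale + shift
    0
  )
}

#' Count learnable parameters
#'
#' Sums weights and biases over all nodes: `kh*kw*cin*cout + cout` per
#' convolution, `win*wout + wout` per fully-connected layer, and the two
#' learned per-channel terms of each batch normalization. Running batchnorm
#' statistics are not counted.
#'
#' @param g A `koi_network`.
#' @return Total parameter count (numeric).
#' @examples
#' count_parameters(build_network(width_config())) / 1e6
#' @export
count_parameters <- function(g) {
  sum(vapply(seq_len(nrow(g$nodes)),
             function(i) params_for_node(g$nodes$kind[i], g$nodes$hyper[[i]]),
             numeric(1)))
}

# Walk the graph propagating (h, w, c) shapes from the input node.
infer_shapes <- function(g, input_size = g$cfg$input_size) {
  topo <- attr(g, "topo")
  shapes <- vector("list", nrow(g$nodes))
  for (id in topo) {
    kind <- g$nodes$kind[id]
    h <- g$nodes$hyper[[id]]
    ins <- lapply(incoming(g, id), function(p) shapes[[p]])
    shapes[[id]] <- switch(kind,
      input = c(input_size, input_size, 3L),
      conv = {
        s <- ins[[1]]
        oh <- (s[1] + 2 * h$pad - h$kh) %/% h$stride + 1L
        ow <- (s[2] + 2 * h$pad - h$kw) %/% h$stride + 1L
        if (oh < 1 || ow < 1) stop_koi("Convolution output collapsed to < 1 px.",
                                       "koi_config_error")
        c(oh, ow, h$cout)
      },
      maxpool = {
        s <- ins[[1]]
        oh <- (s[1] - h$win) %/% h$stride + 1L
        ow <- (s[2] - h$win) %/% h$stride + 1L
        if (oh < 1 || ow < 1) stop_koi("Pooling output collapsed to < 1 px.",
                                       "koi_config_error")
        c(oh, ow, s[3])
      },
      addition = {
        if (!identical(ins[[1]], ins[[2]])) {
          stop_koi("Addition branches have mismatched shapes.", "koi_validation_error")
        }
        ins[[1]]
      },
      fc = c(1L, 1L, h$wout),
      ins[[1]]  # relu, batchnorm, dropout, softmax preserve shape
    )
  }
  shapes
}

#' Summarise a network's structure
#'
#' @param g A `koi_network`.
#' @return Tibble with `n_nodes`, `n_edges`, `n_skip_connections`,
#'   `n_parameters`, `n_classes`, `input_size`.
#' @export
inspect_network <- function(g) {
  tibble::tibble(
    n_nodes = nrow(g$nodes),
    n_edges = nrow(g$edges),
    n_skip_connections = count_skip_connections(g),
    n_parameters = count_parameters(g),
    n_classes = g$cfg$n_classes,
    input_size = g$cfg$input_size
  )
}

#' @export
print.koi_network <- function(x, ...) {
  cat(sprintf("<koi_network> %d nodes, %d edges, %d skip connections, %.2fM parameters\n",
              nrow(x$nodes), nrow(x$edges), count_skip_connections(x),
              count_parameters(x) / 1e6))
  invisible(x)
}
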