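#' Gradient-weighted class activation map
#'
#' Standard Grad-CAM: the gradient of the target class logit with respect to
#' a convolutional tap layer's activations is spatially averaged into one
#' weight per channel; the rectified, weighted channel sum is bilinearly
#' upsampled to the input resolution and min-max normalised to `[0,1]`. The
#' highlighted region is the evidence the network uses for that class — on
#' the synthetic varieties it should settle on the recipe's discriminative
#' cue (e.g. the head disc of the Tancho-like class) as training succeeds.
#'
#' @param fit A `koi_cnn_fit` (or a list with `graph` and `weights`).
#' @param image `(H, W, 3)` array in `[0,1]` (resized to the network input
#'   size if needed).
#' @param target_class Class id in `[0, n_classes)`.
#' @param tap Node id of a conv node or a relu fed (possibly through
#'   batchnorm/addition) by convolutions; defaults to the last residual
#'   block's post-addition relu.
#' @return Object of class `koi_cam`: `values` (input-resolution matrix in
#'   `[0,1]`), `raw` (tap-resolution rectified map), `target_class`, `tap`,
#'   and `all_zero` flag (map identically zero before normalisation).
#' @export
grad_cam <- function(fit, image, target_class, tap = NULL) {
  g <- fit$graph
  weights <- fit$weights
  lm <- landmark_nodes(g)
  if (is.null(tap)) tap <- lm$cam_tap
  if (!tap %in% g$nodes$id || !g$nodes$kind[tap] %in% c("conv", "relu")) {
    stop_koi("`tap` must be a conv or relu node.", "koi_layer_error")
  }
  k <- g$cfg$n_classes
  if (target_class < 0 || target_class >= k) {
    stop_koi("`target_class` out of range.", "koi_label_error")
  }
  S <- g$cfg$input_size
  if (!all(dim(image)[1:2] == S)) image <- resize_bilinear_cpp(image, S, S)
  x <- array(image, c(S, S, 3, 1))
  fw <- network_forward(g, weights, x, mode = "eval")
  dout <- array(0, c(1, 1, k, 1))
  dout[1, 1, target_class + 1, 1] <- 1
  bw <- network_backward(g, weights, fw, dout, from_node = lm$logits, tap = tap)
  A <- fw$acts[[tap]][, , , 1, drop = FALSE]
  dA <- bw$tap_grad[, , , 1, drop = FALSE]
  d <- dim(A)
  ch_w <- apply(dA, 3, mean)                      # global-average-pooled grads
  cam <- matrix(0, d[1], d[2])
  for (c1 in seq_len(d[3])) cam <- cam + ch_w[c1] * A[, , c1, 1]
  cam <- pmax(cam, 0)
  all_zero <- max(cam) == 0
  up <- resize_bilinear_cpp(array(cam, c(d[1], d[2], 1)), S, S)[, , 1]
  if (!all_zero) {
    up <- (up - min(up)) / (max(up) - min(up))
  } else {
    up <- matrix(0, S, S)
  }
  structure(list(values = up, raw = cam, target_class = target_class,
                 tap = tap, all_zero = all_zero),
            class = "koi_cam")
}

#' The nine introspection taps
#'
#' The layers whose activations and class activation maps are inspected
#' when studying what the network learns at each depth: the rectified first
#' convolution, then each residual block's output relu, shallow to deep.
#' The first tap has the finest spatial resolution and is the one to use
#' for localization checks against the renderer's masks; the block taps
#' show how attention evolves with depth but live on much coarser grids
#' (and, at small input sizes, gradients there are sparsified by the head
#' max-pooling, which makes their spatially-averaged channel weights
#' unreliable for pixel-level claims).
#'
#' @param g A `koi_network`.
#' @return Integer vector of node ids, length `n_residual_blocks + 1`.
#' @export
introspection_taps <- function(g) {
  first_relu <- which(g$nodes$kind == "relu")[1]
  adds <- which(g$nodes$kind == "addition")
  block_out <- vapply(adds, function(a) g$edges$to[g$edges$from == a],
                      integer(1))
  c(first_relu, block_out)
}

#' Does a class activation map peak inside a mask?
#'
#' @param cam A `koi_cam`.
#' @param mask Logical matrix (resized by nearest sampling if needed).
#' @return `TRUE` if the location of the map's maximum lies in the mask.
#' @export
cam_peak_in_mask <- function(cam, mask) {
  v <- cam$values
  S <- nrow(v)
  if (!all(dim(mask) == S)) {
    mask <- resize_bilinear_cpp(array(mask * 1, c(dim(mask), 1)), S, S)[, , 1] > 0.5
  }
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  isTRUE(mask[peak[1], peak[2]])
}

#' Per-layer activation montage
#'
#' For each requested layer, tiles every channel's activation map (each tile
#' min-max normalised independently) plus one extra "fusion" tile, the
#' pixelwise mean over channels taken before normalisation — the layer-wise
#' feature summaries used to inspect what the network extracts at each
#' depth.
#'
#' @param fit A `koi_cnn_fit`.
#' @param image `(H, W, 3)` input image.
#' @param layer_ids Node ids with spatial activations.
#' @return List of class `koi_montage`; per layer, a list with `tiles`
#'   (array `h x w x (channels+1)`, fusion last) and `montage` (one matrix
#'   with the tiles laid out on a near-square grid).
#' @export
activation_grid <- function(fit, image, layer_ids) {
  g <- fit$graph
  S <- g$cfg$input_size
  if (!all(dim(image)[1:2] == S)) image <- resize_bilinear_cpp(image, S, S)
  x <- array(image, c(S, S, 3, 1))
  fw <- network_forward(g, fit$weights, x, mode = "eval")
  out <- lapply(layer_ids, function(id) {
    if (!id %in% g$nodes$id) stop_koi("Unknown layer id.", "koi_layer_error")
    A <- fw$acts[[id]]
    d <- dim(A)
    norm01 <- function(m) {
      r <- range(m)
      if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
    }
    tiles <- array(0, c(d[1], d[2], d[3] + 1))
    fusion <- matrix(0, d[1], d[2])
    for (c1 in seq_len(d[3])) {
      fusion <- fusion + A[, , c1, 1]
      tiles[, , c1] <- norm01(A[, , c1, 1])
    }
    tiles[, , d[3] + 1] <- norm01(fusion / d[3])
    ncol_g <- ceiling(sqrt(d[3] + 1))
    nrow_g <- ceiling((d[3] + 1) / ncol_g)
    mont <- matrix(0, nrow_g * d[1], ncol_g * d[2])
    for (t1 in seq_len(d[3] + 1)) {
      r0 <- ((t1 - 1) %/% ncol_g) * d[1]
      c0 <- ((t1 - 1) %% ncol_g) * d[2]
      mont[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- tiles[, , t1]
    }
    list(layer = id, tiles = tiles, montage = mont)
  })
  structure(out, class = "koi_montage")
}
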