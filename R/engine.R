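# Forward/backward execution of a koi_network. Activations are (H, W, C, N)
# arrays throughout; fully-connected outputs use shape (1, 1, width, N) so
# every node handles one uniform tensor type.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Initialise network weights
#'
#' He-normal initialisation for convolution and fully-connected weights,
#' zero biases, unit-scale/zero-shift batch normalization with zero/unit
#' running statistics.
#'
#' @param g A `koi_network`.
#' @param seed Integer seed.
#' @return A list of per-node parameter lists, indexable by node id.
#' @export
init_weights <- function(g, seed = 1L) {
  with_seed_(derive_seed(seed, 7L), {
    lapply(seq_len(nrow(g$nodes)), function(id) {
      kind <- g$nodes$kind[id]
      h <- g$nodes$hyper[[id]]
      if (kind == "conv") {
        fan_in <- h$kh * h$kw * h$cin
        list(w = array(rnorm(h$kh * h$kw * h$cin * h$cout, 0, sqrt(2 / fan_in)),
                       c(h$kh, h$kw, h$cin, h$cout)),
             b = numeric(h$cout))
      } else if (kind == "fc") {
        list(w = matrix(rnorm(h$win * h$wout, 0, sqrt(2 / h$win)), h$win, h$wout),
             b = numeric(h$wout))
      } else if (kind == "batchnorm") {
        list(gamma = rep(1, h$channels), beta = numeric(h$channels),
             running_mean = numeric(h$channels), running_var = rep(1, h$channels))
      } else NULL
    })
  })
}

# per-channel statistics of a (H, W, C, N) tensor
channel_stats <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  list(mean = colMeans(m), var = colMeans(m^2) - colMeans(m)^2,
       n = nrow(m))
}

sweep3 <- function(x, v, op) sweep(x, 3, v, op)

#' Run a forward pass
#'
#' Executes the graph in topological order. In `"train"` mode batch
#' normalization uses batch statistics (and updates its running ones) and
#' dropout applies a seeded inverted-dropout mask; in `"eval"` mode both are
#' deterministic (running statistics, no dropout), so repeated calls on the
#' same input give identical outputs.
#'
#' @param g A `koi_network`.
#' @param weights From [init_weights()] (or a trained fit).
#' @param x Input batch, `(input_size, input_size, 3, N)` array.
#' @param mode `"eval"` or `"train"`.
#' @param dropout_seed Seed for the dropout mask in train mode.
#' @return List with `acts` (per-node activations), `cache` (solver
#'   by-products needed for the backward pass) and `weights` (running
#'   batchnorm statistics updated in train mode).
#' @export
network_forward <- function(g, weights, x, mode = c("eval", "train"),
                            dropout_seed = 0L) {
  mode <- match.arg(mode)
  topo <- attr(g, "topo")
  n_nodes <- nrow(g$nodes)
  acts <- vector("list", n_nodes)
  cache <- vector("list", n_nodes)
  for (id in topo) {
    kind <- g$nodes$kind[id]
    h <- g$nodes$hyper[[id]]
    ins <- incoming(g, id)
    acts[[id]] <- switch(kind,
      input = x,
      conv = conv2d_forward_cpp(acts[[ins]], weights[[id]]$w, weights[[id]]$b,
                                h$stride, h$pad),
      batchnorm = {
        a <- acts[[ins]]
        w <- weights[[id]]
        if (mode == "train") {
          st <- channel_stats(a)
          unb <- st$var * st$n / max(st$n - 1, 1)
          weights[[id]]$running_mean <- (1 - BN_MOMENTUM) * w$running_mean +
            BN_MOMENTUM * st$mean
          weights[[id]]$running_var <- (1 - BN_MOMENTUM) * w$running_var +
            BN_MOMENTUM * unb
          inv_sd <- 1 / sqrt(st$var + BN_EPS)
          xhat <- sweep3(sweep3(a, st$mean, "-"), inv_sd, "*")
          cache[[id]] <- list(xhat = xhat, inv_sd = inv_sd, n = st$n)
          sweep3(sweep3(xhat, w$gamma, "*"), w$beta, "+")
        } else {
          inv_sd <- 1 / sqrt(w$running_var + BN_EPS)
          sweep3(sweep3(sweep3(sweep3(a, w$running_mean, "-"), inv_sd, "*"),
                        w$gamma, "*"), w$beta, "+")
        }
      },
      relu = pmax(acts[[ins]], 0),
      maxpool = {
        r <- maxpool_forward_cpp(acts[[ins]], h$win, h$stride)
        cache[[id]] <- list(idx = r$idx, xdim = dim(acts[[ins]]))
        r$y
      },
      addition = acts[[ins[1]]] + acts[[ins[2]]],
      fc = {
        a <- acts[[ins]]
        d <- dim(a)
        X <- t(matrix(a, nrow = prod(d[1:3]), ncol = d[4]))
        Y <- X %*% weights[[id]]$w
        Y <- sweep(Y, 2, weights[[id]]$b, "+")
        cache[[id]] <- list(X = X, in_dim = d)
        array(t(Y), c(1L, 1L, ncol(Y), d[4]))
      },
      dropout = {
        a <- acts[[ins]]
        if (mode == "train" && h$rate > 0) {
          mask <- with_seed_(derive_seed(dropout_seed, id), {
            array((runif(length(a)) > h$rate) / (1 - h$rate), dim(a))
          })
          cache[[id]] <- list(mask = mask)
          a * mask
        } else a
      },
      softmax = {
        a <- acts[[ins]]
        d <- dim(a)
        Z <- matrix(a, nrow = d[3], ncol = d[4])
        Z <- sweep(Z, 2, apply(Z, 2, max), "-")
        E <- exp(Z)
        P <- sweep(E, 2, colSums(E), "/")
        array(P, d)
      }
    )
  }
  list(acts = acts, cache = cache, weights = weights)
}

#' Run a backward pass
#'
#' Back-propagates a gradient injected at `from_node` (by default the final
#' fully-connected layer, i.e. the class logits) through the graph,
#' returning per-node parameter gradients and, if requested, the gradient of
#' the objective with respect to a tap node's activation (used by Grad-CAM).
#'
#' @param g A `koi_network`.
#' @param weights Parameter list used in the forward pass.
#' @param fw Result of [network_forward()] (train-mode caches required for
#'   batchnorm/dropout gradients).
#' @param dout Gradient array matching the activation of `from_node`.
#' @param from_node Node id where `dout` is injected.
#' @param tap Optional node id whose activation gradient to return.
#' @return List with `grads` (per-node lists, e.g. `dw`, `db`, `dgamma`,
#'   `dbeta`) and `tap_grad`.
#' @export
network_backward <- function(g, weights, fw, dout, from_node = NULL, tap = NULL) {
  topo <- attr(g, "topo")
  if (is.null(from_node)) from_node <- landmark_nodes(g)$logits
  acts <- fw$acts
  cache <- fw$cache
  n_nodes <- nrow(g$nodes)
  dacts <- vector("list", n_nodes)
  grads <- vector("list", n_nodes)
  dacts[[from_node]] <- dout
  start <- match(from_node, topo)
  for (pos in seq(start, 1)) {
    id <- topo[pos]
    dy <- dacts[[id]]
    if (is.null(dy)) next
    kind <- g$nodes$kind[id]
    h <- g$nodes$hyper[[id]]
    ins <- incoming(g, id)
    push <- function(node, grad) {
      dacts[[node]] <<- if (is.null(dacts[[node]])) grad else dacts[[node]] + grad
    }
    switch(kind,
      input = NULL,
      conv = {
        r <- conv2d_backward_cpp(acts[[ins]], weights[[id]]$w, dy, h$stride, h$pad)
        grads[[id]] <- list(dw = r$dw, db = r$db)
        push(ins, r$dx)
      },
      batchnorm = {
        cc <- cache[[id]]
        w <- weights[[id]]
        d <- dim(dy)
        if (is.null(cc)) {
          # eval-mode forward: running statistics are constants, so the
          # normalization is an affine map per channel
          inv_sd <- 1 / sqrt(w$running_var + BN_EPS)
          xhat <- sweep3(sweep3(acts[[ins]], w$running_mean, "-"), inv_sd, "*")
          per_ch <- function(a) {
            m <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3])
            colSums(m)
          }
          grads[[id]] <- list(dgamma = per_ch(dy * xhat), dbeta = per_ch(dy))
          push(ins, sweep3(sweep3(dy, w$gamma, "*"), inv_sd, "*"))
          next
        }
        per_ch <- function(a) {
          m <- matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3])
          colSums(m)
        }
        dgamma <- per_ch(dy * cc$xhat)
        dbeta <- per_ch(dy)
        n_el <- cc$n
        dxhat <- sweep3(dy, w$gamma, "*")
        t1 <- per_ch(dxhat)
        t2 <- per_ch(dxhat * cc$xhat)
        dx <- sweep3(dxhat - sweep3(array(1, d), t1 / n_el, "*") -
                       sweep3(cc$xhat, t2 / n_el, "*"),
                     cc$inv_sd, "*")
        grads[[id]] <- list(dgamma = dgamma, dbeta = dbeta)
        push(ins, dx)
      },
      relu = push(ins, dy * (acts[[ins]] > 0)),
      maxpool = push(ins, maxpool_backward_cpp(dy, cache[[id]]$idx,
                                               cache[[id]]$xdim)),
      addition = { push(ins[1], dy); push(ins[2], dy) },
      fc = {
        cc <- cache[[id]]
        dY <- t(matrix(dy, nrow = dim(dy)[3], ncol = dim(dy)[4]))
        grads[[id]] <- list(dw = crossprod(cc$X, dY), db = colSums(dY))
        dX <- dY %*% t(weights[[id]]$w)
        push(ins, array(t(dX), cc$in_dim))
      },
      dropout = {
        cc <- cache[[id]]
        push(ins, if (is.null(cc)) dy else dy * cc$mask)
      },
      softmax = {
        d <- dim(dy)
        P <- matrix(acts[[id]], d[3], d[4])
        DY <- matrix(dy, d[3], d[4])
        dz <- P * sweep(DY, 2, colSums(DY * P), "-")
        push(ins, array(dz, d))
      }
    )
    if (!is.null(tap) && id == tap) break
  }
  list(grads = grads,
       tap_grad = if (!is.null(tap)) dacts[[tap]] else NULL)
}

# Landmark node ids: head fc layers, the feature tap (post-relu fc6), the
# softmax sink and the default Grad-CAM tap (last activation entering the
# head maxpool).
landmark_nodes <- function(g) {
  kinds <- g$nodes$kind
  fc_ids <- which(kinds == "fc")
  softmax_id <- which(kinds == "softmax")
  fc6 <- fc_ids[1]
  fc7 <- fc_ids[2]
  fc6_relu <- g$edges$to[g$edges$from == fc6]
  pools <- which(kinds == "maxpool")
  head_pool <- pools[length(pools)]
  list(fc6 = fc6, fc6_relu = fc6_relu, logits = fc7, softmax = softmax_id,
       head_pool = head_pool,
       cam_tap = incoming(g, head_pool))
}

#' Class scores for a batch of images
#'
#' Deterministic evaluation-mode forward pass; rows are softmax
#' probabilities summing to 1.
#'
#' @param g A `koi_network`.
#' @param weights Network parameters.
#' @param x `(H, W, 3, N)` input array at the network's input size.
#' @return `N x n_classes` score matrix.
#' @export
forward_scores <- function(g, weights, x) {
  if (!identical(dim(x)[1:2], rep(as.integer(g$cfg$input_size), 2)) &&
      !all(dim(x)[1:2] == g$cfg$input_size)) {
    stop_koi("Input images must match the network input size.", "koi_shape_error")
  }
  fw <- network_forward(g, weights, x, mode = "eval")
  p <- fw$acts[[landmark_nodes(g)$softmax]]
  t(matrix(p, dim(p)[3], dim(p)[4]))
}

#' Feature matrix at a tap node
#'
#' Truncates the evaluation-mode forward pass at `tap` (by default the
#' rectified first fully-connected layer, whose vectors feed the SVM head)
#' and returns one flattened feature row per sample.
#'
#' @param g,weights,x As in [forward_scores()].
#' @param tap Node id; must be an `fc` or `relu` node (default: post-relu
#'   first fc layer).
#' @return `N x width` feature matrix.
#' @export
extract_features <- function(g, weights, x, tap = NULL) {
  if (is.null(tap)) tap <- landmark_nodes(g)$fc6_relu
  if (!tap %in% g$nodes$id || !g$nodes$kind[tap] %in% c("fc", "relu")) {
    stop_koi("`tap` must be an fc or relu node id in the graph.",
             "koi_lookup_error")
  }
  fw <- network_forward(g, weights, x, mode = "eval")
  a <- fw$acts[[tap]]
  d <- dim(a)
  t(matrix(a, prod(d[1:3]), d[4]))
}
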