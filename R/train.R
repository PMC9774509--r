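#' Training configuration
#'
#' Plain stochastic gradient descent on the softmax cross-entropy of the
#' network's class scores. The full-scale defaults follow the original
#' study's protocol (learning rate 0.0001; batch sizes drawn from
#' {4, 8, 16, 32, 64}; epoch budgets from {25, 50, 75, 100}). The `"desk"`
#' preset pairs the reduced [width_config()] with a learning rate of 0.01
#' (stepped down tenfold for the final fifth of the epochs to settle the
#' oscillation a large step causes late in training) and 10 epochs, sized
#' for CPU runs on the synthetic dataset — a from-scratch batch-normalized
#' network at this scale needs the larger step to move in so few updates.
#'
#' @param preset `"default"` or `"desk"`.
#' @param ... Named overrides (`learning_rate`, `batch_size`, `epochs`,
#'   `momentum`, `lr_decay`, `lr_decay_at`, `seed`, `width`).
#' @return A list of class `koi_train_config`.
#' @export
train_config <- function(preset = c("default", "desk"), ...) {
  preset <- match.arg(preset)
  cfg <- list(learning_rate = 1e-4, batch_size = 8L, epochs = 25L,
              momentum = 0, lr_decay = 1, lr_decay_at = 0.8, seed = 42L,
              width = width_config())
  if (preset == "desk") {
    cfg$learning_rate <- 0.01
    cfg$lr_decay <- 0.1
    cfg$epochs <- 10L
    cfg$width <- width_config("desk")
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_koi(paste0("Unknown train_config field(s): ",
                                   paste(bad, collapse = ", ")), "koi_config_error")
  cfg[names(over)] <- over
  if (cfg$learning_rate <= 0) stop_koi("learning_rate must be > 0.",
                                       "koi_config_error")
  structure(cfg, class = "koi_train_config")
}

#' Load manifest images as an input batch array
#'
#' Reads the PNGs of a manifest (optionally one split), resizing each to the
#' network input size by bilinear interpolation.
#'
#' @param m A manifest.
#' @param input_size Target side length in pixels.
#' @param split Optional split filter.
#' @return List with `x` (`size x size x 3 x n` array) and `y` (class ids).
#' @export
load_image_batch <- function(m, input_size, split = NULL) {
  validate_manifest(m)
  if (!is.null(split)) m <- m[m$split == split, ]
  if (!nrow(m)) stop_koi("No rows in the requested split.", "koi_data_error")
  x <- array(0, c(input_size, input_size, 3, nrow(m)))
  for (i in seq_len(nrow(m))) {
    img <- png::readPNG(m$path[i])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3]
    if (!all(dim(img)[1:2] == input_size)) {
      img <- resize_bilinear_cpp(img, input_size, input_size)
    }
    x[, , , i] <- img
  }
  list(x = x, y = as.integer(m$class_id))
}

cross_entropy <- function(scores_logits, y_onehot) {
  # stable log-softmax
  z <- sweep(scores_logits, 1, apply(scores_logits, 1, max), "-")
  logp <- z - log(rowSums(exp(z)))
  -mean(rowSums(y_onehot * logp))
}

#' Train the residual network
#'
#' Minibatch stochastic gradient descent on softmax cross-entropy. Per
#' epoch, training loss/accuracy (averaged over batches) and validation
#' loss/accuracy are logged; the weights with the best validation accuracy
#' are retained as the checkpoint. A fixed seed reproduces the run exactly.
#'
#' @param manifest A split manifest with non-empty `train` and `val` splits.
#' @param cfg A [train_config()].
#' @param verbose Log per-epoch progress.
#' @return Object of class `koi_cnn_fit`: `graph`, `weights` (best
#'   checkpoint), `final_weights`, `traces` tibble (epoch, train_loss,
#'   train_acc, val_loss, val_acc), `best_epoch`, `cfg`.
#' @export
train_network <- function(manifest, cfg = train_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "koi_train_config"))
  g <- build_network(cfg$width)
  tr <- load_image_batch(manifest, cfg$width$input_size, "train")
  va <- load_image_batch(manifest, cfg$width$input_size, "val")
  k <- g$cfg$n_classes
  if (any(c(tr$y, va$y) >= k)) stop_koi("class_id outside the network's classes.",
                                        "koi_label_error")
  weights <- init_weights(g, cfg$seed)
  vel <- NULL
  n_tr <- length(tr$y)
  lognode <- landmark_nodes(g)$logits
  traces <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, weights = weights, epoch = 0L)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    # step decay: shrink the step for the final stretch of epochs
    lr <- cfg$learning_rate *
      if (ep > cfg$lr_decay_at * cfg$epochs) cfg$lr_decay else 1
    ord <- with_seed_(derive_seed(cfg$seed, 31L, ep), sample.int(n_tr))
    batch_losses <- c(); batch_correct <- 0L
    for (b0 in seq(1, n_tr, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n_tr)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[idx]
      step <- step + 1L
      fw <- network_forward(g, weights, xb, mode = "train",
                            dropout_seed = derive_seed(cfg$seed, 97L, step))
      weights <- fw$weights  # running batchnorm statistics
      logits <- t(matrix(fw$acts[[lognode]], k, length(idx)))
      onehot <- diag(k)[yb + 1, , drop = FALSE]
      batch_losses <- c(batch_losses, cross_entropy(logits, onehot))
      batch_correct <- batch_correct +
        sum(max.col(logits, ties.method = "first") - 1L == yb)
      # d(mean CE)/d(logits) = (softmax - onehot) / batch_n
      z <- sweep(logits, 1, apply(logits, 1, max), "-")
      p <- exp(z) / rowSums(exp(z))
      dlog <- (p - onehot) / length(idx)
      bw <- network_backward(g, weights, fw,
                             array(t(dlog), c(1, 1, k, length(idx))),
                             from_node = lognode)
      upd <- sgd_update(weights, bw$grads, lr, cfg$momentum, vel)
      weights <- upd$weights
      vel <- upd$vel
    }
    ev <- eval_on(g, weights, va$x, va$y, k)
    traces[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = mean(batch_losses),
      train_acc = batch_correct / n_tr,
      val_loss = ev$loss, val_acc = ev$acc
    )
    if (ev$acc > best$acc) best <- list(acc = ev$acc, weights = weights, epoch = ep)
    if (verbose) {
      koi_log(sprintf("epoch %d/%d train_loss=%.4f train_acc=%.3f val_acc=%.3f",
                      ep, cfg$epochs, mean(batch_losses),
                      batch_correct / n_tr, ev$acc))
    }
    if (!is.finite(mean(batch_losses))) {
      stop_koi(sprintf("Training diverged at epoch %d (non-finite loss).", ep),
               "koi_divergence_error")
    }
  }
  structure(list(graph = g, weights = best$weights, final_weights = weights,
                 traces = dplyr::bind_rows(traces), best_epoch = best$epoch,
                 cfg = cfg),
            class = "koi_cnn_fit")
}

# classical momentum: v <- mu v + g; w <- w - lr v (plain SGD when mu = 0)
sgd_update <- function(weights, grads, lr, mu = 0, vel = NULL) {
  if (is.null(vel)) vel <- vector("list", length(weights))
  for (id in seq_along(weights)) {
    if (is.null(grads[[id]])) next
    w <- weights[[id]]; gr <- grads[[id]]
    v <- vel[[id]]
    if (is.null(v)) v <- lapply(gr, function(x) x * 0)
    for (nm in names(gr)) v[[nm]] <- mu * v[[nm]] + gr[[nm]]
    if (!is.null(gr$dw)) { w$w <- w$w - lr * v$dw; w$b <- w$b - lr * v$db }
    if (!is.null(gr$dgamma)) {
      w$gamma <- w$gamma - lr * v$dgamma
      w$beta <- w$beta - lr * v$dbeta
    }
    vel[[id]] <- v
    weights[[id]] <- w
  }
  list(weights = weights, vel = vel)
}

eval_on <- function(g, weights, x, y, k, batch = 32L) {
  n <- dim(x)[4]
  losses <- numeric(0); correct <- 0L
  preds <- integer(n)
  lognode <- landmark_nodes(g)$logits
  for (b0 in seq(1, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1, n)
    fw <- network_forward(g, weights, x[, , , idx, drop = FALSE], mode = "eval")
    logits <- t(matrix(fw$acts[[lognode]], k, length(idx)))
    onehot <- diag(k)[y[idx] + 1, , drop = FALSE]
    losses <- c(losses, cross_entropy(logits, onehot) * length(idx))
    preds[idx] <- max.col(logits, ties.method = "first") - 1L
    correct <- correct + sum(preds[idx] == y[idx])
  }
  list(loss = sum(losses) / n, acc = correct / n, preds = preds)
}

#' Batch-size by epoch accuracy grid
#'
#' Runs an independent seeded train+evaluate for every (batch size, epochs)
#' combination and tabulates test accuracy, mirroring the original study's
#' hyperparameter sweep.
#'
#' @param manifest A split manifest.
#' @param batch_sizes,epoch_list Grid axes.
#' @param cfg Base [train_config()]; each cell overrides its batch size and
#'   epochs and derives its own seed.
#' @param verbose Log progress.
#' @return Tibble with `batch_size` rows and one column per epoch budget.
#' @export
run_grid <- function(manifest, batch_sizes = c(4, 8, 16, 32, 64),
                     epoch_list = c(25, 50, 75, 100),
                     cfg = train_config(), verbose = FALSE) {
  cells <- purrr::map_dfr(batch_sizes, function(bs) {
    accs <- purrr::map_dbl(epoch_list, function(ep) {
      ccfg <- cfg
      ccfg$batch_size <- as.integer(bs)
      ccfg$epochs <- as.integer(ep)
      ccfg$seed <- derive_seed(cfg$seed, bs, ep)
      fit <- train_network(manifest, ccfg, verbose = verbose)
      te <- load_image_batch(manifest, ccfg$width$input_size, "test")
      ev <- eval_on(fit$graph, fit$weights, te$x, te$y, fit$graph$cfg$n_classes)
      ev$acc
    })
    tibble::tibble(batch_size = as.integer(bs),
                   !!!setNames(as.list(accs), paste0("epochs_", epoch_list)))
  })
  cells
}

#' @export
print.koi_cnn_fit <- function(x, ...) {
  cat(sprintf("<koi_cnn_fit> %d epochs, best val accuracy %.3f (epoch %d)\n",
              nrow(x$traces), max(x$traces$val_acc), x$best_epoch))
  invisible(x)
}

#' @rdname train_network
#' @param x A `koi_cnn_fit`.
#' @method tidy koi_cnn_fit
#' @export
tidy.koi_cnn_fit <- function(x, ...) x$traces

#' @rdname train_network
#' @method glance koi_cnn_fit
#' @export
glance.koi_cnn_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$traces),
    best_epoch = x$best_epoch,
    best_val_acc = max(x$traces$val_acc),
    final_train_loss = x$traces$train_loss[nrow(x$traces)],
    n_parameters = count_parameters(x$graph)
  )
}
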