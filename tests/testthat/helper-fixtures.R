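# Shared fixtures: datasets are rendered once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function(n_per_class = 20, seed = 11) {
  key <- sprintf("ds_%d_%d", n_per_class, seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("koi_", key))
  m <- generate_dataset(n_per_class, render_config(seed = seed), dir)
  .fixture_env[[key]] <- m
  m
}

# A network config small enough for sub-second forward/backward passes.
tiny_width <- function(...) {
  width_config("desk", conv1_channels = 4L, conv2_channels = 6L,
               residual_channels = 6L, fc6_width = 12L, input_size = 48L,
               n_residual_blocks = 1L, ...)
}

random_image <- function(size = 48, seed = 1) {
  set.seed(seed)
  array(runif(size * size * 3), c(size, size, 3))
}

# Separable three-class Gaussian blobs for SVM tests.
gaussian_blobs <- function(n_per_class = 30, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 4, 0, 0, 4), ncol = 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:3, function(k) {
    cbind(rnorm(n_per_class, centers[k, 1], sd),
          rnorm(n_per_class, centers[k, 2], sd))
  }))
  list(X = X, y = rep(0:2, each = n_per_class))
}
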