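fit_stub <- function(cfg, seed = 4) {
  g <- build_network(cfg)
  list(graph = g, weights = init_weights(g, seed))
}

test_that("maps are rectified, normalized and reproducible", {
  fit <- fit_stub(tiny_width())
  img <- random_image(48, seed = 3)
  cam <- grad_cam(fit, img, target_class = 2)
  expect_true(all(cam$raw >= 0))
  expect_gte(min(cam$values), 0)
  expect_lte(max(cam$values), 1)
  expect_identical(dim(cam$values), c(48L, 48L))
  cam2 <- grad_cam(fit, img, target_class = 2)
  expect_identical(cam$values, cam2$values)
  expect_error(grad_cam(fit, img, 99), class = "koi_label_error")
  expect_error(grad_cam(fit, img, 0, tap = 1L), class = "koi_layer_error")
})

test_that("a single-channel tap reproduces the analytic map", {
  # with one channel, the map is relu(wbar * A); wbar is obtained
  # independently by finite differences of the logit in the tap activation
  cfg <- width_config("desk", conv1_channels = 3L, conv2_channels = 1L,
                      residual_channels = 1L, fc6_width = 8L,
                      input_size = 48L, n_residual_blocks = 1L,
                      n_classes = 4L, dropout_rate = 0)
  fit <- fit_stub(cfg, seed = 6)
  g <- fit$graph
  img <- random_image(48, seed = 9)
  lm <- koivision:::landmark_nodes(g)
  tap <- lm$cam_tap
  x <- array(img, c(48, 48, 3, 1))
  fw <- network_forward(g, fit$weights, x, mode = "eval")
  A <- fw$acts[[tap]][, , 1, 1]
  # finite-difference channel weight: perturb the whole channel uniformly
  logit_from_tap <- function(a_tap) {
    d <- dim(fw$acts[[tap]])
    h <- g$nodes$hyper[[lm$head_pool]]
    pooled <- koivision:::maxpool_forward_cpp(array(a_tap, d), h$win, h$stride)$y
    dp <- dim(pooled)
    f6 <- fit$weights[[lm$fc6]]
    v <- as.vector(pooled)
    z6 <- pmax(as.vector(v %*% f6$w) + f6$b, 0)
    f7 <- fit$weights[[lm$logits]]
    (z6 %*% f7$w + f7$b)[3]          # logit of class 2
  }
  eps <- 1e-4
  wbar_fd <- (logit_from_tap(fw$acts[[tap]] + eps) -
              logit_from_tap(fw$acts[[tap]] - eps)) / (2 * eps) / length(A)
  expected <- pmax(wbar_fd * A, 0)
  cam <- grad_cam(fit, img, target_class = 2)
  if (max(expected) > 0 && max(cam$raw) > 0) {
    expect_gt(stats::cor(as.vector(cam$raw), as.vector(expected)), 0.999)
  } else {
    expect_identical(max(cam$raw) == 0, max(expected) == 0)
  }
})

test_that("the normalized map is invariant to positive gradient scaling", {
  # scaling the target logit scales all channel weights by the same
  # positive constant, which min-max normalization removes
  cfg <- tiny_width(dropout_rate = 0)
  fit <- fit_stub(cfg, seed = 8)
  img <- random_image(48, seed = 2)
  cam1 <- grad_cam(fit, img, 1)
  scaled <- fit
  lm <- koivision:::landmark_nodes(fit$graph)
  scaled$weights[[lm$logits]]$w <- fit$weights[[lm$logits]]$w * 3
  scaled$weights[[lm$logits]]$b <- fit$weights[[lm$logits]]$b * 3
  cam2 <- grad_cam(scaled, img, 1)
  expect_equal(cam1$values, cam2$values, tolerance = 1e-8)
})

test_that("tap-layer gradients agree with central finite differences", {
  cfg <- tiny_width(dropout_rate = 0)
  fit <- fit_stub(cfg, seed = 10)
  g <- fit$graph
  lm <- koivision:::landmark_nodes(g)
  x <- array(random_image(48, seed = 4), c(48, 48, 3, 1))
  fw <- network_forward(g, fit$weights, x, mode = "eval")
  k <- g$cfg$n_classes
  dout <- array(0, c(1, 1, k, 1)); dout[1, 1, 2, 1] <- 1
  bw <- network_backward(g, fit$weights, fw, dout, from_node = lm$logits,
                         tap = lm$cam_tap)
  # continuation from the tap: head pool -> fc6 -> relu -> fc7 logit
  logit_from_tap <- function(a_tap) {
    h <- g$nodes$hyper[[lm$head_pool]]
    pooled <- koivision:::maxpool_forward_cpp(a_tap, h$win, h$stride)$y
    f6 <- fit$weights[[lm$fc6]]
    z6 <- pmax(as.vector(as.vector(pooled) %*% f6$w) + f6$b, 0)
    f7 <- fit$weights[[lm$logits]]
    (z6 %*% f7$w + f7$b)[2]
  }
  a0 <- fw$acts[[lm$cam_tap]]
  set.seed(5)
  probe <- sample(which(a0 > 1e-3), 5)  # away from pooling ties
  eps <- 1e-4
  for (i in probe) {
    ap <- a0; ap[i] <- ap[i] + eps
    am <- a0; am[i] <- am[i] - eps
    num <- (logit_from_tap(ap) - logit_from_tap(am)) / (2 * eps)
    ana <- bw$tap_grad[i]
    expect_lt(abs(num - ana) / max(abs(num), 1e-6), 1e-3)
  }
})

test_that("activation montages tile channels plus one fusion tile", {
  cfg <- tiny_width()
  fit <- fit_stub(cfg, seed = 12)
  img <- random_image(48, seed = 6)
  conv1 <- which(fit$graph$nodes$kind == "conv")[1]
  grid <- activation_grid(fit, img, conv1)
  tiles <- grid[[1]]$tiles
  expect_identical(dim(tiles)[3], cfg$conv1_channels + 1L)
  # fusion tile is the pre-normalization pixelwise channel mean
  x <- array(img, c(48, 48, 3, 1))
  fw <- network_forward(fit$graph, fit$weights, x, mode = "eval")
  A <- fw$acts[[conv1]]
  fusion <- apply(A[, , , 1], c(1, 2), mean)
  rng <- range(fusion)
  expect_equal(tiles[, , dim(tiles)[3]],
               (fusion - rng[1]) / (rng[2] - rng[1]), tolerance = 1e-12)
  # determinism
  grid2 <- activation_grid(fit, img, conv1)
  expect_identical(grid[[1]]$montage, grid2[[1]]$montage)
  expect_error(activation_grid(fit, img, 999L), class = "koi_layer_error")
})
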