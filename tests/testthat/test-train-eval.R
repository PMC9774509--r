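split_small_manifest <- function(n_per_class = 6, seed = 2) {
  m <- fixture_dataset(20)
  m <- m |>
    dplyr::group_by(class_id) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
  stratified_split(m, c(0.6, 0.2, 0.2), seed = seed)
}

test_that("perfect predictions give unit metrics", {
  r <- evaluate_predictions(rep(0:3, 5), rep(0:3, 5), 4)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$macro$precision, 1)
  expect_equal(r$macro$recall, 1)
  expect_equal(r$macro$f1, 1)
  expect_true(all(diag(r$confusion) == 5))
})

test_that("binary counts reproduce the metric formulas by substitution", {
  # TP=50 TN=40 FP=5 FN=5 for the positive class (class 1)
  truth <- c(rep(1, 55), rep(0, 45))
  pred <- c(rep(1, 50), rep(0, 5), rep(1, 5), rep(0, 40))
  r <- evaluate_predictions(truth, pred, 2)
  pos <- r$per_class[r$per_class$class_id == 1, ]
  expect_identical(c(pos$tp, pos$tn, pos$fp, pos$fn), c(50L, 40L, 5L, 5L))
  expect_equal(pos$accuracy, 0.90)
  expect_equal(pos$precision, 10 / 11)
  expect_equal(pos$recall, 10 / 11)
  expect_equal(pos$f1, 10 / 11)
})

test_that("three-class metrics match a brute-force per-class count oracle", {
  conf <- rbind(c(8L, 1L, 1L), c(0L, 9L, 1L), c(1L, 0L, 9L))
  truth <- rep(0:2, times = rowSums(conf))
  pred <- unlist(lapply(1:3, function(i) rep(0:2, times = conf[i, ])))
  r <- evaluate_predictions(truth, pred, 3)
  expect_identical(unname(r$confusion), conf)
  expect_equal(r$overall_accuracy, 26 / 30)
  # brute force: recount every one-vs-rest cell by enumeration
  brute <- t(vapply(0:2, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    tn <- sum(truth != cls & pred != cls)
    pr <- tp / (tp + fp); re <- tp / (tp + fn)
    c(pr = pr, re = re, f1 = 2 * pr * re / (pr + re))
  }, numeric(3)))
  expect_equal(r$macro$precision, mean(brute[, "pr"]))
  expect_equal(r$macro$recall, mean(brute[, "re"]))
  expect_equal(r$macro$f1, mean(brute[, "f1"]))
})

test_that("per-class count conservation and macro-F1 bounds hold", {
  set.seed(12)
  for (rep in 1:8) {
    n <- 60
    truth <- sample(0:4, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(0:4, n, replace = TRUE))
    r <- evaluate_predictions(truth, pred, 5)
    expect_true(all(r$per_class$tp + r$per_class$tn +
                      r$per_class$fp + r$per_class$fn == n))
    expect_gte(r$macro$f1, min(r$per_class$f1))
    expect_lte(r$macro$f1, max(r$per_class$f1))
    # overall accuracy = trace/total = support-weighted recall
    sup <- rowSums(r$confusion)
    expect_equal(r$overall_accuracy,
                 sum(r$per_class$recall * sup) / sum(sup))
    # purity: same inputs, same report
    expect_identical(r, evaluate_predictions(truth, pred, 5))
  }
})

test_that("zero-predicted classes are flagged with precision 0", {
  r <- evaluate_predictions(c(0, 0, 1, 1), c(0, 0, 0, 0), 2)
  expect_identical(r$flagged_classes, 1L)
  expect_equal(r$per_class$precision[2], 0)
  expect_error(evaluate_predictions(c(0, 5), c(0, 1), 2), class = "koi_label_error")
  expect_error(evaluate_predictions(0:1, 0L, 2), class = "koi_argument_error")
})

test_that("a tiny network overfits a small training subset", {
  m <- fixture_dataset(20)
  sub <- m |>
    dplyr::filter(class_id < 4) |>
    dplyr::group_by(class_id) |>
    dplyr::slice_head(n = 5) |>
    dplyr::ungroup()
  sub$split <- rep(c("train", "train", "train", "train", "val"), 4)
  cfg <- train_config("desk",
                      width = tiny_width(n_classes = 4L, dropout_rate = 0),
                      epochs = 40L, batch_size = 8L, seed = 3L)
  fit <- train_network(sub, cfg, verbose = FALSE)
  # 16 train samples, batch 8 -> 2 steps/epoch; 1.0 within 200 steps
  first_perfect <- which(fit$traces$train_acc == 1)[1]
  expect_false(is.na(first_perfect))
  expect_lte(first_perfect * 2, 200)
})

test_that("training descends and is reproducible", {
  sm <- split_small_manifest()
  cfg <- train_config("desk", width = tiny_width(), epochs = 3L, seed = 7L)
  fit1 <- train_network(sm, cfg, verbose = FALSE)
  expect_gt(fit1$traces$train_loss[1], fit1$traces$train_loss[3])
  fit2 <- train_network(sm, cfg, verbose = FALSE)
  expect_identical(fit1$traces, fit2$traces)
  expect_identical(dim(tidy(fit1)), dim(fit1$traces))
  expect_identical(glance(fit1)$epochs, 3L)
})

test_that("a 1x1 grid equals a direct train and evaluate call", {
  sm <- split_small_manifest()
  base <- train_config("desk", width = tiny_width(), epochs = 2L, seed = 5L)
  grid <- run_grid(sm, batch_sizes = 8, epoch_list = 2, cfg = base)
  expect_identical(dim(grid), c(1L, 2L))
  direct_cfg <- base
  direct_cfg$batch_size <- 8L
  direct_cfg$epochs <- 2L
  direct_cfg$seed <- koivision:::derive_seed(base$seed, 8, 2)
  fit <- train_network(sm, direct_cfg, verbose = FALSE)
  te <- load_image_batch(sm, direct_cfg$width$input_size, "test")
  ev <- koivision:::eval_on(fit$graph, fit$weights, te$x, te$y, 13)
  expect_equal(grid$epochs_2[1], ev$acc)
})

test_that("a reduced grid reports every requested cell", {
  sm <- split_small_manifest()
  base <- train_config("desk", width = tiny_width(), seed = 5L)
  grid <- run_grid(sm, batch_sizes = c(8, 64), epoch_list = 2, cfg = base)
  expect_identical(dim(grid), c(2L, 2L))
  expect_identical(grid$batch_size, c(8L, 64L))
  expect_true(all(is.finite(grid$epochs_2)))
})
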