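#' End-to-end hybrid pipeline
#'
#' The full hybrid classification procedure: train the residual network with
#' its softmax head, freeze it, extract rectified fully-connected features
#' for the train and test splits, fit the one-vs-one kernel SVM on the train
#' features, and evaluate both decision heads — softmax argmax and SVM — on
#' the test split. The SVM is fitted post hoc on frozen features; the two
#' heads therefore share the identical feature extractor and differ only in
#' the final decision rule.
#'
#' @param manifest A manifest with non-empty train, val and test splits.
#' @param cfg A [train_config()].
#' @param kernel A [kernel_spec()] for the SVM head.
#' @param C SVM box penalty.
#' @param augment_train Augment the training split before training (the
#'   method's own data-expansion step): each class's original training
#'   images are expanded by seeded random operator chains up to
#'   `augment_factor` times their count. Only the training split is
#'   touched; validation and test images stay pristine.
#' @param augment_factor Expansion factor (2 doubles each class).
#' @param verbose Log progress.
#' @return Object of class `koi_pipeline`: the `fit` (`koi_cnn_fit`), the
#'   fitted `svm`, and `report_svm` / `report_softmax` (`koi_eval`) on the
#'   test split, plus `test_predictions` (tibble with truth and both heads'
#'   predictions).
#' @export
pipeline_end_to_end <- function(manifest, cfg = train_config("desk"),
                                kernel = kernel_spec("rbf"), C = 1,
                                augment_train = TRUE, augment_factor = 2,
                                verbose = TRUE) {
  validate_manifest(manifest)
  for (s in c("train", "val", "test")) {
    if (!any(manifest$split == s)) {
      stop_koi(sprintf("Split '%s' is empty.", s), "koi_data_error")
    }
  }
  train_manifest <- manifest
  if (augment_train && augment_factor > 1) {
    if (verbose) koi_log("augmenting the training split")
    tr_rows <- manifest[manifest$split == "train", ]
    classes <- sort(unique(tr_rows$class_id))
    orig <- as.integer(table(factor(tr_rows$class_id, levels = classes)))
    plan <- plan_balance(orig, as.integer(round(orig * augment_factor)),
                         classes)
    aug <- execute_plan(tr_rows, plan, seed = cfg$seed)
    aug$split <- "train"
    train_manifest <- dplyr::bind_rows(manifest[manifest$split != "train", ],
                                       aug)
  }
  fit <- train_network(train_manifest, cfg, verbose = verbose)
  g <- fit$graph
  k <- g$cfg$n_classes
  tr <- load_image_batch(train_manifest, g$cfg$input_size, "train")
  te <- load_image_batch(manifest, g$cfg$input_size, "test")
  if (verbose) koi_log("extracting fully-connected features for the SVM head")
  ftr <- batched_features(g, fit$weights, tr$x)
  fte <- batched_features(g, fit$weights, te$x)
  svm <- fit_svm(ftr, tr$y, kernel = kernel, C = C)
  pred_svm <- predict(svm, fte)
  ev <- eval_on(g, fit$weights, te$x, te$y, k)
  structure(list(
    fit = fit, svm = svm,
    report_svm = evaluate_predictions(te$y, pred_svm, k),
    report_softmax = evaluate_predictions(te$y, ev$preds, k),
    test_predictions = tibble::tibble(truth = te$y, pred_svm = pred_svm,
                                      pred_softmax = ev$preds)
  ), class = "koi_pipeline")
}

batched_features <- function(g, weights, x, batch = 32L) {
  n <- dim(x)[4]
  out <- NULL
  for (b0 in seq(1, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1, n)
    f <- extract_features(g, weights, x[, , , idx, drop = FALSE])
    out <- rbind(out, f)
  }
  out
}

#' @export
print.koi_pipeline <- function(x, ...) {
  cat(sprintf("<koi_pipeline> test accuracy: SVM head %.4f | softmax head %.4f\n",
              x$report_svm$overall_accuracy, x$report_softmax$overall_accuracy))
  invisible(x)
}

#' @rdname pipeline_end_to_end
#' @param x A `koi_pipeline`.
#' @param ... Unused.
#' @method glance koi_pipeline
#' @export
glance.koi_pipeline <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$report_svm), head = "svm", .before = 1),
    dplyr::mutate(glance(x$report_softmax), head = "softmax", .before = 1)
  )
}
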