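#' Kernel specification
#'
#' The kernel \eqn{K(x_i, x_j) = \varphi(x_i) \cdot \varphi(x_j)} used by the
#' SVM head; the feature map \eqn{\varphi} is never materialised (kernel
#' trick). When `gamma` is `NULL` it is resolved at fit time as
#' `1 / (feature_width * overall feature variance)`.
#'
#' @param kind `"linear"`, `"rbf"` or `"polynomial"`.
#' @param gamma Positive kernel width parameter (rbf/polynomial).
#' @param degree Polynomial degree (>= 1).
#' @param coef0 Polynomial offset.
#' @return A list of class `koi_kernel`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial"), gamma = NULL,
                        degree = 3L, coef0 = 0) {
  kind <- match.arg(kind)
  if (!is.null(gamma) && gamma <= 0) {
    stop_koi("`gamma` must be positive.", "koi_argument_error")
  }
  if (degree < 1) stop_koi("`degree` must be >= 1.", "koi_argument_error")
  structure(list(kind = kind, gamma = gamma, degree = degree, coef0 = coef0),
            class = "koi_kernel")
}

resolve_gamma <- function(spec, X) {
  if (!is.null(spec$gamma) || spec$kind == "linear") return(spec)
  v <- stats::var(as.vector(X))
  spec$gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  spec
}

#' Kernel (Gram) matrix
#'
#' @param X `n x p` feature matrix (finite values).
#' @param spec A [kernel_spec()] with a concrete `gamma` where required.
#' @param Y Optional second matrix (defaults to `X`), giving the `n x m`
#'   cross-kernel.
#' @return Kernel matrix; symmetric with unit diagonal for the rbf kernel
#'   when `Y` is `X`.
#' @export
kernel_matrix <- function(X, spec = kernel_spec("linear"), Y = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_koi("Non-finite feature values.", "koi_numeric_error")
  sym <- is.null(Y)
  Y <- if (sym) X else as.matrix(Y)
  if (!all(is.finite(Y))) stop_koi("Non-finite feature values.", "koi_numeric_error")
  spec <- resolve_gamma(spec, X)
  G <- X %*% t(Y)
  K <- switch(spec$kind,
    linear = G,
    polynomial = (spec$gamma * G + spec$coef0)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      exp(-spec$gamma * pmax(d2, 0))
    }
  )
  if (sym) K <- (K + t(K)) / 2  # enforce exact symmetry
  if (sym && spec$kind == "rbf") diag(K) <- 1  # K(x,x) = exp(0) exactly
  K
}

#' Solve the SVM dual problem
#'
#' Maximises the dual objective
#' \deqn{W(\alpha) = \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j
#'   y_i y_j K(x_i, x_j)}
#' subject to \eqn{\sum_i \alpha_i y_i = 0} and the box constraint
#' \eqn{0 \le \alpha_i \le C}, by sequential minimal optimisation: repeated
#' analytic two-variable updates on the maximally KKT-violating pair, until
#' the maximal violation falls below `tol` or `max_iter` updates have run.
#'
#' @param K Symmetric positive-semidefinite kernel matrix.
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param C Positive box penalty.
#' @param tol Stopping threshold on the maximal KKT violation.
#' @param max_iter Cap on two-variable updates.
#' @param trace_objective Record the dual objective after every update
#'   (diagnostics; the sequence is non-decreasing).
#' @return A list of class `koi_dual`: `alpha`, `bias`, `bias_fallback`,
#'   `support_indices` (`alpha > 1e-8`), `margin_indices`
#'   (`0 < alpha < C`), `objective`, `iterations`, `converged`, plus the
#'   inputs (`y`, `C`) needed to evaluate decisions.
#' @export
solve_dual <- function(K, y, C, tol = 1e-4, max_iter = 10000L,
                       trace_objective = FALSE) {
  if (C <= 0) stop_koi("`C` must be positive.", "koi_argument_error")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2) {
    stop_koi("`y` must contain both -1 and +1.", "koi_degenerate_error")
  }
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  Q <- K * tcrossprod(y)
  alpha <- numeric(n)
  G <- rep(-1, n)           # gradient of 1/2 a'Qa - sum(a)
  obj_trace <- if (trace_objective) numeric(0) else NULL
  it <- 0L
  converged <- FALSE
  tau <- 1e-12
  repeat {
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    yg <- -y * G
    m_up <- if (any(up)) max(yg[up]) else -Inf
    m_lo <- if (any(lo)) min(yg[lo]) else Inf
    if (m_up - m_lo < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    # analytic two-variable solve with box clipping
    s <- y[i] * y[j]
    eta <- Q[i, i] + Q[j, j] - 2 * s * Q[i, j]
    if (eta <= 0) eta <- tau
    # prediction errors in terms of the gradient: E_t = f_t - y_t = y_t G_t
    Ei <- y[i] * G[i]; Ej <- y[j] * G[j]
    aj_old <- alpha[j]; ai_old <- alpha[i]
    aj <- aj_old + y[j] * (Ei - Ej) / eta
    if (s < 0) { L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old) }
    else { L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old) }
    aj <- min(max(aj, L), H)
    ai <- ai_old + s * (aj_old - aj)
    dai <- ai - ai_old; daj <- aj - aj_old
    if (abs(daj) < 1e-15 && abs(dai) < 1e-15) { converged <- TRUE; break }
    alpha[i] <- ai; alpha[j] <- aj
    G <- G + Q[, i] * dai + Q[, j] * daj
    it <- it + 1L
    if (trace_objective) obj_trace <- c(obj_trace, (sum(alpha) - sum(alpha * G)) / 2)
  }
  objective <- sum(alpha) - 0.5 * sum(alpha * (Q %*% alpha))
  sol <- structure(list(
    alpha = alpha, y = y, C = C,
    support_indices = which(alpha > 1e-8),
    margin_indices = which(alpha > 1e-7 * max(C, 1) &
                             alpha < C - 1e-7 * max(C, 1)),
    objective = objective, iterations = it, converged = converged,
    objective_trace = obj_trace, bias = NA_real_, bias_fallback = FALSE
  ), class = "koi_dual")
  b <- compute_bias(sol, K)
  sol$bias <- b$bias
  sol$bias_fallback <- b$fallback
  sol
}

#' Recover the bias term
#'
#' Each margin support vector \eqn{j} (with \eqn{0 < \alpha_j < C}) gives an
#' estimate \eqn{b^* = y_j - \sum_i \alpha_i^* y_i K(x_i, x_j)}; the returned
#' bias averages them. If no margin support vector exists (all multipliers
#' at a bound) the midpoint of the feasible bias interval is used and
#' flagged.
#'
#' @param sol A `koi_dual` solution.
#' @param K The training kernel matrix the solution was fitted on.
#' @return List with `bias`, `fallback` flag, and the vector `estimates`
#'   (one per margin support vector).
#' @export
compute_bias <- function(sol, K) {
  alpha <- sol$alpha; y <- sol$y; C <- sol$C
  f0 <- as.vector(K %*% (alpha * y))  # decision values without bias
  msv <- sol$margin_indices
  if (length(msv)) {
    est <- y[msv] - f0[msv]
    return(list(bias = mean(est), fallback = FALSE, estimates = est))
  }
  # all alphas at bounds: any b in [max over one side, min over other] is
  # KKT-consistent; take the midpoint
  G <- f0 * y - 1
  up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
  lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
  yg <- -y * G
  hi <- if (any(up)) max(yg[up]) else 0
  lw <- if (any(lo)) min(yg[lo]) else 0
  list(bias = (hi + lw) / 2, fallback = TRUE, estimates = numeric(0))
}

#' SVM decision values and predictions
#'
#' Evaluates the decision function
#' \eqn{f(x) = \mathrm{sign}[\sum_i \alpha_i^* y_i K(x_i, x) + b^*]};
#' `decision_values()` returns the signed argument, `predict` its sign (a
#' raw value of exactly zero is broken to `+1`).
#'
#' @param sol A fitted `koi_dual` carrying training features (as produced by
#'   [fit_binary_svm()]).
#' @param x_new Feature matrix of query points.
#' @return Numeric decision values / `+1`/`-1` predictions.
#' @export
decision_values <- function(sol, x_new) {
  if (is.null(sol$X)) stop_koi("Solution lacks stored training vectors.",
                               "koi_argument_error")
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != ncol(sol$X)) {
    stop_koi("Feature width mismatch with the training vectors.", "koi_shape_error")
  }
  Kx <- kernel_matrix(x_new, sol$kernel, sol$X)
  as.vector(Kx %*% (sol$alpha * sol$y)) + sol$bias
}

#' @rdname decision_values
#' @param ... Unused.
#' @export
predict.koi_dual <- function(object, x_new, ...) {
  f <- decision_values(object, x_new)
  ifelse(f >= 0, 1, -1)
}

#' Fit a binary kernel SVM
#'
#' Convenience wrapper: builds the kernel matrix, runs [solve_dual()] and
#' stores the training vectors so the fitted object can score new points.
#'
#' @param X `n x p` feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param kernel A [kernel_spec()].
#' @param C Box penalty (default 1).
#' @param ... Passed to [solve_dual()].
#' @return A `koi_dual` with `X` and resolved `kernel` attached.
#' @export
fit_binary_svm <- function(X, y, kernel = kernel_spec("rbf"), C = 1, ...) {
  X <- as.matrix(X)
  kernel <- resolve_gamma(kernel, X)
  K <- kernel_matrix(X, kernel)
  sol <- solve_dual(K, y, C, ...)
  sol$X <- X
  sol$kernel <- kernel
  sol
}

#' Fit a one-vs-one multiclass SVM on deep features
#'
#' Trains one binary machine per unordered class pair (78 machines for 13
#' classes), each on only its two classes' samples. Prediction is majority
#' voting; ties are broken by summed decision values, then by the lowest
#' class id.
#'
#' @param features `n x p` numeric feature matrix (e.g. rectified
#'   fully-connected-layer activations).
#' @param labels Integer class labels (>= 2 classes, each with >= 2 samples).
#' @param kernel A [kernel_spec()]; `gamma`, when unset, is resolved once on
#'   the full feature matrix.
#' @param C Box penalty.
#' @param ... Passed to [solve_dual()].
#' @return A list of class `koi_svm`: `machines` (per-pair `koi_dual`),
#'   `pairs`, `classes`, `kernel`, `C`.
#' @export
fit_svm <- function(features, labels, kernel = kernel_spec("rbf"), C = 1, ...) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_koi("Need at least two classes.",
                                    "koi_degenerate_error")
  if (any(table(labels) < 2)) {
    stop_koi("Every class needs at least 2 samples.", "koi_training_error")
  }
  kernel <- resolve_gamma(kernel, features)
  pairs <- utils::combn(classes, 2)
  machines <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    idx <- labels %in% c(a, b)
    ybin <- ifelse(labels[idx] == a, 1, -1)
    fit_binary_svm(features[idx, , drop = FALSE], ybin, kernel, C, ...)
  })
  structure(list(machines = machines, pairs = pairs, classes = classes,
                 kernel = kernel, C = C), class = "koi_svm")
}

#' @rdname fit_svm
#' @param object A fitted `koi_svm`.
#' @param x_new Feature matrix to classify.
#' @export
predict.koi_svm <- function(object, x_new, ...) {
  x_new <- as.matrix(x_new)
  n <- nrow(x_new)
  k <- length(object$classes)
  votes <- matrix(0L, n, k)
  scores <- matrix(0, n, k)
  for (m in seq_along(object$machines)) {
    a <- match(object$pairs[1, m], object$classes)
    b <- match(object$pairs[2, m], object$classes)
    f <- decision_values(object$machines[[m]], x_new)
    wa <- f >= 0
    votes[, a] <- votes[, a] + wa
    votes[, b] <- votes[, b] + !wa
    scores[, a] <- scores[, a] + f
    scores[, b] <- scores[, b] - f
  }
  vapply(seq_len(n), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) {
      best <- best[scores[i, best] == max(scores[i, best])]
    }
    object$classes[min(best)]
  }, integer(1))
}
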