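# The QP oracle (kernlab::ipop) and the reference SVM (e1071, libsvm) are
# used only to check the package's own solver.

# Compare a solution's dual objective with kernlab's interior-point QP
# solver. Both objectives are evaluated on the same lightly ridged matrix
# (the ridge keeps the QP well conditioned; with C = 1 its effect on the
# objective is ~1e-5 absolute, far below the comparison scale).
qp_oracle_gap <- function(K, y, C, alpha_mine, ridge = 1e-6) {
  n <- length(y)
  Q <- K * tcrossprod(y) + diag(ridge, n)
  fit <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 7)
  a <- kernlab::primal(fit)
  obj <- function(a) sum(a) - 0.5 * as.numeric(t(a) %*% Q %*% a)
  abs(obj(alpha_mine) - obj(a)) / max(abs(obj(a)), 1e-8)
}

random_binary_instance <- function(n, p = 2, seed = 1, separation = 2.5) {
  set.seed(seed)
  y <- sample(c(-1, 1), n, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(c(-1, 1), n, replace = TRUE)
  X <- matrix(rnorm(n * p), n, p) + separation * outer(y, rep(0.5, p))
  list(X = X, y = y)
}

test_that("kernel matrices have the defining algebraic properties", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  Krbf <- kernel_matrix(X, kernel_spec("rbf", gamma = 0.7))
  expect_true(all(diag(Krbf) == 1))
  expect_identical(Krbf, t(Krbf))
  # linear kernel of orthonormal rows is the identity
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(kernel_matrix(Q, kernel_spec("linear")), diag(5), tolerance = 1e-12)
  # positive semidefiniteness on random inputs
  for (s in 1:5) {
    set.seed(s)
    Xs <- matrix(rnorm(30 * 4), 30, 4)
    for (spec in list(kernel_spec("linear"), kernel_spec("rbf", gamma = 0.3))) {
      ev <- eigen(kernel_matrix(Xs, spec), symmetric = TRUE, only.values = TRUE)
      expect_gte(min(ev$values), -1e-8)
    }
  }
  expect_error(kernel_matrix(matrix(c(1, NA), 1)), class = "koi_numeric_error")
})

test_that("the symmetric two-point problem is solved exactly", {
  X <- matrix(c(-1, 1), 2, 1)
  sol <- fit_binary_svm(X, c(-1, 1), kernel_spec("linear"), C = 10)
  expect_equal(sol$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sol$bias, 0, tolerance = 1e-6)
  # effective normal vector w* = sum alpha_i y_i x_i = 1
  expect_equal(sum(sol$alpha * sol$y * X[, 1]), 1, tolerance = 1e-6)
  # far-side query and the boundary tie rule
  expect_identical(predict(sol, matrix(2)), 1)
  f0 <- decision_values(sol, matrix(0))
  expect_equal(f0, 0, tolerance = 1e-9)
  expect_identical(predict(sol, matrix(0)), 1)  # tie broken to +1
})

test_that("the shifted two-point problem recovers the analytic bias", {
  # x in {0, 2}: max margin hyperplane at x = 1 with w = 1, so b = -1
  sol <- fit_binary_svm(matrix(c(0, 2), 2, 1), c(-1, 1),
                        kernel_spec("linear"), C = 10)
  expect_equal(sol$bias, -1, tolerance = 1e-6)
  # analytic maximum-margin solution: alpha = (0.5, 0.5), objective 0.5
  expect_equal(sol$objective, 0.5, tolerance = 1e-6)
})

test_that("the rbf kernel solves XOR", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(-1, -1, 1, 1)
  sol <- fit_binary_svm(X, y, kernel_spec("rbf", gamma = 1), C = 10)
  expect_identical(predict(sol, X), y)
})

test_that("dual objectives match the QP oracle on random instances", {
  skip_if_not_installed("kernlab")
  worst <- 0
  for (s in 1:50) {
    inst <- random_binary_instance(n = sample(6:30, 1), seed = s)
    spec <- if (s %% 2) kernel_spec("linear") else kernel_spec("rbf", gamma = 0.5)
    C <- 1
    sol <- fit_binary_svm(inst$X, inst$y, spec, C)
    worst <- max(worst, qp_oracle_gap(kernel_matrix(inst$X, spec), inst$y, C,
                                      sol$alpha))
  }
  expect_lt(worst, 1e-4)
})

test_that("solutions satisfy feasibility and complementary slackness", {
  for (s in 1:10) {
    inst <- random_binary_instance(n = 24, seed = 100 + s, separation = 1.5)
    C <- 1
    sol <- fit_binary_svm(inst$X, inst$y, kernel_spec("rbf", gamma = 0.5), C)
    expect_true(all(sol$alpha >= -1e-6 & sol$alpha <= C + 1e-6))
    expect_lt(abs(sum(sol$alpha * sol$y)), 1e-6)
    f <- decision_values(sol, inst$X)
    m <- inst$y * f
    tol <- 1e-3
    expect_true(all(m[sol$alpha < 1e-7] >= 1 - tol))
    msv <- sol$margin_indices
    if (length(msv)) expect_true(all(abs(m[msv] - 1) <= tol))
    expect_true(all(m[sol$alpha > C - 1e-7] <= 1 + tol))
  }
})

test_that("the dual objective is non-decreasing across solver iterations", {
  inst <- random_binary_instance(n = 30, seed = 77, separation = 1)
  K <- kernel_matrix(inst$X, kernel_spec("rbf", gamma = 0.5))
  sol <- solve_dual(K, inst$y, C = 1, trace_objective = TRUE)
  tr <- sol$objective_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-10))
})

test_that("margin-SV bias estimates agree with their average", {
  for (s in 1:10) {
    inst <- random_binary_instance(n = 26, seed = 200 + s, separation = 2)
    sol <- fit_binary_svm(inst$X, inst$y, kernel_spec("linear"), C = 1,
                          tol = 1e-6)
    K <- kernel_matrix(inst$X, sol$kernel)
    b <- compute_bias(sol, K)
    if (length(b$estimates) > 1) {
      expect_lt(max(abs(b$estimates - b$bias)), 1e-3)
    }
    # margin support vectors evaluate to +/- 1
    msv <- sol$margin_indices
    if (length(msv)) {
      f <- decision_values(sol, inst$X[msv, , drop = FALSE])
      expect_true(all(abs(abs(f) - 1) < 1e-3))
    }
  }
})

test_that("predictions agree with the reference implementation", {
  skip_if_not_installed("e1071")
  agree <- total <- 0
  for (s in 1:10) {
    inst <- random_binary_instance(n = 30, seed = 300 + s, separation = 2)
    test_inst <- random_binary_instance(n = 40, seed = 400 + s, separation = 2)
    gamma <- 0.5
    sol <- fit_binary_svm(inst$X, inst$y, kernel_spec("rbf", gamma = gamma), C = 1)
    ref <- e1071::svm(inst$X, factor(inst$y), kernel = "radial", gamma = gamma,
                      cost = 1, scale = FALSE)
    mine <- predict(sol, test_inst$X)
    theirs <- as.numeric(as.character(predict(ref, test_inst$X)))
    agree <- agree + sum(mine == theirs)
    total <- total + length(mine)
  }
  expect_gte(agree / total, 0.98)
})

test_that("linear-kernel predictions are invariant to feature scaling with C rescaled", {
  inst <- random_binary_instance(n = 30, seed = 9, separation = 1.5)
  test_X <- random_binary_instance(n = 20, seed = 10, separation = 1.5)$X
  s <- 2
  sol1 <- fit_binary_svm(inst$X, inst$y, kernel_spec("linear"), C = 1)
  sol2 <- fit_binary_svm(inst$X * s, inst$y, kernel_spec("linear"), C = 1 / s^2)
  expect_identical(predict(sol1, test_X), predict(sol2, test_X * s))
})

test_that("one-vs-one multiclass voting separates Gaussian blobs", {
  blobs <- gaussian_blobs(30)
  model <- fit_svm(blobs$X, blobs$y, kernel_spec("rbf", gamma = 1), C = 1)
  expect_identical(length(model$machines), 3L)  # 3 classes -> 3 pairs
  expect_identical(predict(model, blobs$X), blobs$y)
  # held-out agreement with the reference implementation
  skip_if_not_installed("e1071")
  held <- gaussian_blobs(20, seed = 2)
  ref <- e1071::svm(blobs$X, factor(blobs$y), kernel = "radial", gamma = 1,
                    cost = 1, scale = FALSE)
  theirs <- as.integer(as.character(predict(ref, held$X)))
  mine <- predict(model, held$X)
  expect_gte(mean(mine == theirs), 0.98)
})

test_that("the two-class case reduces to a single binary machine", {
  blobs <- gaussian_blobs(15)
  two <- blobs$y < 2
  X <- blobs$X[two, ]; y <- blobs$y[two]
  model <- fit_svm(X, y, kernel_spec("rbf", gamma = 1), C = 1)
  expect_identical(length(model$machines), 1L)
  direct <- fit_binary_svm(X, ifelse(y == 0, 1, -1),
                           kernel_spec("rbf", gamma = 1), C = 1)
  f <- decision_values(model$machines[[1]], X)
  expect_identical(predict(model, X), ifelse(f >= 0, 0L, 1L))
  expect_equal(f, decision_values(direct, X), tolerance = 1e-9)
})


test_that("degenerate inputs raise typed errors", {
  X <- matrix(rnorm(10), 5, 2)
  K <- kernel_matrix(X, kernel_spec("linear"))
  expect_error(solve_dual(K, rep(1, 5), C = 1), class = "koi_degenerate_error")
  expect_error(solve_dual(K, c(1, 1, 1, -1, -1), C = -1),
               class = "koi_argument_error")
  expect_error(fit_svm(X, c(0L, 0L, 1L, 1L, 2L), kernel_spec("linear")),
               class = "koi_training_error")
  sol <- fit_binary_svm(matrix(c(-1, 1), 2, 1), c(-1, 1), kernel_spec("linear"))
  expect_error(decision_values(sol, matrix(1, 1, 3)), class = "koi_shape_error")
})
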