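# The independent oracle throughout this file is direct dense linear
# algebra: K = XX' (or the explicit SE kernel matrix), alpha solved with
# base solve(), variances from the explicit Schur complement.

dense_gp <- function(X, y, lambda, spec, Xs) {
  K <- kernel_matrix(X, X, spec)
  A <- K + diag(lambda, nrow(X))
  alpha <- solve(A, y)
  L <- kernel_matrix(X, Xs, spec)
  list(alpha = alpha,
       mean = drop(crossprod(L, alpha)),
       var = kernel_diag(Xs, spec) - colSums(L * solve(A, L)))
}

test_that("kernel evaluations match their closed forms", {
  expect_equal(kernel_eval(c(1, 2), c(3, 4)), 11)
  se <- kernel_spec("squared_exponential", length_scale = 1)
  expect_equal(kernel_eval(c(1, 2), c(1, 2), se), 1)
  expect_equal(kernel_eval(c(0, 0), c(1, 1), se), exp(-1))
  expect_error(kernel_eval(c(1, 2), c(1, 2, 3)), "mismatch")
  expect_error(kernel_spec("squared_exponential"), "length_scale")
})

test_that("fit/predict/variance agree with dense linear algebra", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(5:50, 1); d <- sample(2:20, 1)
    X <- matrix(rnorm(n * d), n)
    y <- rnorm(n, sd = 3)
    lambda <- 10^runif(1, -6, 2)
    spec <- if (i %% 3 == 0)
      kernel_spec("squared_exponential", length_scale = runif(1, 1, 10))
    else kernel_spec("linear")
    Xs <- matrix(rnorm(8 * d), 8)
    ref <- dense_gp(X, y, lambda, spec, Xs)
    model <- gp_fit(X, y, lambda, spec)
    scale <- max(1, max(abs(ref$alpha)))
    expect_lt(max(abs(model$alpha - ref$alpha)) / scale, 1e-8)
    expect_lt(max(abs(predict_mean(model, Xs) - ref$mean)) /
                max(1, max(abs(ref$mean))), 1e-8)
    expect_lt(max(abs(predict_variance(model, Xs) - pmax(ref$var, 0))) /
                max(1, max(abs(ref$var))), 1e-8)
    # naive per-point sum, the textbook form of the predictor
    naive <- vapply(seq_len(nrow(Xs)), function(j)
      sum(model$alpha * apply(X, 1, kernel_eval, b = Xs[j, ], spec = spec)),
      numeric(1))
    expect_equal(predict_mean(model, Xs), naive, tolerance = 1e-8)
  }
})

test_that("linear-kernel GP equals the primal ridge solution", {
  set.seed(102)
  for (i in 1:5) {
    n <- sample(10:40, 1); d <- sample(2:8, 1)
    X <- matrix(rnorm(n * d), n); y <- rnorm(n)
    lambda <- 10^runif(1, -4, 1)
    Xs <- matrix(rnorm(5 * d), 5)
    w <- solve(crossprod(X) + diag(lambda, d), crossprod(X, y))
    model <- gp_fit(X, y, lambda)
    expect_equal(predict_mean(model, Xs), drop(Xs %*% w), tolerance = 1e-8)
  }
})

test_that("scalar and interpolation limits behave", {
  m <- gp_fit(matrix(1, 1, 1), 2, lambda = 0)
  expect_equal(m$alpha, 2)

  # lambda = 0 with an invertible kernel matrix interpolates exactly
  set.seed(103)
  X <- matrix(rnorm(8 * 10), 8)   # n < d so K = XX' is invertible
  y <- rnorm(8)
  m <- gp_fit(X, y, lambda = 0)
  expect_equal(predict_mean(m, X), y, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(m$train_variances), 1e-6)

  expect_equal(predict_mean(m, X[0, , drop = FALSE]), numeric(0))
  expect_error(predict_mean(m, matrix(0, 2, 3)), "mismatch")
})

test_that("ridge shrinkage: coefficient norm decreases along a doubling grid", {
  set.seed(104)
  X <- matrix(rnorm(30 * 5), 30); y <- rnorm(30)
  norms <- vapply(2^(0:12), function(l) sqrt(sum(gp_fit(X, y, l)$alpha^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("duplicating a fitted training point leaves predictions unchanged", {
  # duplication is a no-op only when the model already reproduces that
  # point's label (near-interpolation regime); with large lambda and noisy
  # labels it genuinely reweights the observation
  set.seed(105)
  X <- matrix(rnorm(20 * 4), 20)
  y <- drop(X %*% c(1, -1, 2, 0.5))  # representable labels
  Xs <- matrix(rnorm(6 * 4), 6)
  m1 <- gp_fit(X, y, 1e-8)
  m2 <- gp_fit(rbind(X, X[1, ]), c(y, y[1]), 1e-8)
  expect_equal(predict_mean(m1, Xs), predict_mean(m2, Xs), tolerance = 1e-6)
})

test_that("predictive variance depends on geometry only, never on labels", {
  set.seed(106)
  X <- matrix(rnorm(25 * 6), 25); y <- rnorm(25)
  Xs <- matrix(rnorm(10 * 6), 10)
  m1 <- gp_fit(X, y, 0.01)
  m2 <- gp_fit(X, sample(y), 0.01)
  expect_equal(predict_variance(m1, Xs), predict_variance(m2, Xs),
               tolerance = 1e-10)
  # bounded above by the prior variance k(x*, x*)
  expect_true(all(predict_variance(m1, Xs) <=
                    rowSums(Xs^2) + 1e-8))
})

test_that("centering shifts predictions by the training mean only", {
  set.seed(107)
  X <- matrix(rnorm(20 * 3), 20); y <- rnorm(20) + 50
  m <- gp_fit(X, y, 0.5, center = TRUE)
  expect_equal(m$y_center, mean(y))
  # a zero descriptor predicts the training mean under centering
  expect_equal(predict_mean(m, matrix(0, 1, 3)), mean(y))
})

test_that("noise selection minimizes cross-validated MAE on the grid", {
  set.seed(108)
  expect_equal(select_noise(matrix(rnorm(40 * 3), 40), rnorm(40),
                            grid = 0.37)$lambda, 0.37)

  # noise-free linear data: no regularization needed -> grid minimum
  X <- matrix(rnorm(60 * 4), 60)
  y <- drop(X %*% c(1, -2, 0.5, 3))
  sel <- select_noise(X, y, seed = 1)
  expect_equal(sel$lambda, min(default_lambda_grid()))

  expect_error(select_noise(matrix(rnorm(5 * 2), 5), rnorm(5), k = 10),
               "fewer folds")
  expect_error(select_noise(X, y, grid = c(2, 1)), "increasing")
})

test_that("selected noise level tracks a fine-grid exhaustive search", {
  set.seed(109)
  X <- matrix(rnorm(80 * 5), 80)
  y <- drop(X %*% rnorm(5)) + rnorm(80, sd = 2)
  grid <- default_lambda_grid()
  sel <- select_noise(X, y, grid = grid, seed = 5)
  # independent oracle: exhaustive search on a 10x finer grid with the same
  # folds, re-using only stratified_folds and plain dense algebra
  fine <- 10^seq(-8, 4, length.out = 121)
  folds <- stratified_folds(y, 10, 5)
  mae <- vapply(fine, function(l) {
    errs <- vapply(1:10, function(i) {
      tr <- folds$fold_of != i
      a <- solve(tcrossprod(X[tr, ]) + diag(l, sum(tr)), y[tr])
      mean(abs(drop(tcrossprod(X[!tr, ], X[tr, ]) %*% a) - y[!tr]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best_fine <- fine[which.min(mae)]
  # chosen coarse-grid value within two grid steps of the fine optimum
  expect_lte(abs(log10(sel$lambda) - log10(best_fine)), 2)
})

test_that("lambda = 0 on a singular kernel matrix advises regularization", {
  X <- matrix(1, 5, 2)  # rank-1, singular K
  expect_error(gp_fit(X, rnorm(5), 0), "lambda > 0")
  # the same geometry is fine once regularized
  expect_silent(gp_fit(X, rnorm(5), 1e-4))
})
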