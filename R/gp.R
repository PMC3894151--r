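# Gaussian process regression core.
#
# The predictor is the standard GP / kernel-ridge dual form
#     f(x)  = y_center + sum_i alpha_i k(x_i, x),
#     alpha = (K + lambda I)^{-1} (y - y_center),
# and the predictive variance the Schur complement
#     v(x)  = k(x, x) - l(x)^T (K + lambda I)^{-1} l(x),
# where K is the train/train kernel matrix and l(x) the train/test kernel
# column.  lambda is the assumed label-noise variance and is selected by
# stratified cross-validated MAE over a logarithmic grid (see select_noise).
# lambda is deliberately NOT added to test variances: the adaptive gate
# compares test variances against training-point variances, so a constant
# offset would cancel anyway and gating on epistemic uncertainty alone keeps
# the threshold interpretable.
#
# For the linear kernel with lambda > 0 the model is fitted through a thin
# SVD of the descriptor matrix (X = U S V'), which makes fitting O(n d^2)
# instead of O(n^3); the result is algebraically identical to the dense dual
# solve (checked against dense linear algebra in the test suite).

#' Kernel specification
#'
#' @param kind `"linear"` (`k(a,b) = a.b`, the default and the kernel used for
#'   the energy surrogate) or `"squared_exponential"`
#'   (`k(a,b) = exp(-||a-b||^2 / (2 l^2))`).
#' @param length_scale Positive length scale, required for
#'   `"squared_exponential"` and ignored for `"linear"`.
#' @return Object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(kind = c("linear", "squared_exponential"),
                        length_scale = NULL) {
  kind <- match.arg(kind)
  if (kind == "squared_exponential") {
    if (is.null(length_scale) || !is.finite(length_scale) || length_scale <= 0)
      stop_data("squared_exponential kernel needs a positive length_scale")
  } else {
    length_scale <- NULL
  }
  structure(list(kind = kind, length_scale = length_scale),
            class = "kernel_spec")
}

#' Evaluate a kernel between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @param spec A [kernel_spec()].
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(a, b, spec = kernel_spec("linear")) {
  if (length(a) != length(b))
    stop_data("kernel_eval: dimension mismatch (", length(a), " vs ",
              length(b), ")")
  switch(spec$kind,
         linear = sum(a * b),
         squared_exponential =
           exp(-sum((a - b)^2) / (2 * spec$length_scale^2)))
}

#' Kernel matrix between two sets of row vectors
#'
#' @param X n x d matrix.
#' @param Y m x d matrix (default `X`).
#' @param spec A [kernel_spec()].
#' @return n x m matrix of pairwise kernel values.
#' @export
kernel_matrix <- function(X, Y = X, spec = kernel_spec("linear")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop_data("kernel_matrix: dimension mismatch (", ncol(X), " vs ",
              ncol(Y), ")")
  if (spec$kind == "linear") return(tcrossprod(X, Y))
  # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y, clipped at 0 for roundoff
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * spec$length_scale^2))
}

# self-kernel values k(x_i, x_i) for the rows of X
kernel_diag <- function(X, spec) {
  switch(spec$kind,
         linear = rowSums(as.matrix(X)^2),
         squared_exponential = rep(1, nrow(as.matrix(X))))
}

#' Default noise-level grid
#'
#' 13 logarithmically spaced values, `10^-8` .. `10^4`.
#'
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-8, 4, length.out = 13L)

# ---- factorization backends ---------------------------------------------
# Each factor object supports solving (K + lambda I) Z = B for Z.

make_factor_svd <- function(X, lambda) {
  s <- svd(X)
  list(type = "svd", u = s$u, d = s$d, v = s$v, lambda = lambda)
}

solve_factor <- function(fac, B) {
  B <- as.matrix(B)
  if (fac$type == "svd") {
    utb <- crossprod(fac$u, B)
    proj <- fac$u %*% (utb / (fac$d^2 + fac$lambda))
    resid <- B - fac$u %*% utb
    # columns lying in the span of U have an analytically zero residual;
    # zero the roundoff remnant before it is amplified by 1/lambda
    rn <- sqrt(colSums(resid^2))
    bn <- sqrt(colSums(B^2))
    resid[, rn <= 1e-12 * pmax(bn, .Machine$double.xmin)] <- 0
    proj + resid / fac$lambda
  } else {
    backsolve(fac$r, backsolve(fac$r, B, transpose = TRUE))
  }
}

make_factor_chol <- function(K, lambda) {
  A <- K + diag(lambda, nrow(K))
  if (lambda == 0 && nrow(A) > 1L && rcond(A) < 1e-12)
    stop_data("kernel matrix is numerically singular; use lambda > 0")
  r <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(r) && lambda > 0) {
    # one jitter retry before giving up; pointless at lambda = 0, where a
    # singular kernel matrix means the model is genuinely unidentifiable
    r <- tryCatch(chol(A + diag(1e-10, nrow(A))), error = function(e) NULL)
  }
  if (is.null(r))
    stop_data("kernel matrix factorization failed; use lambda > 0")
  list(type = "chol", r = r, lambda = lambda)
}

#' Fit a Gaussian process regression model
#'
#' @param X n x d matrix of training descriptors.
#' @param y Length-n numeric vector of reference energies (kJ/mol).
#' @param lambda Noise hyper-parameter, >= 0. `lambda = 0` is permitted only
#'   when the kernel matrix is well-conditioned (exact interpolation).
#' @param spec A [kernel_spec()].
#' @param center If `TRUE`, the label mean is subtracted before fitting and
#'   added back at prediction time. Off by default; with the linear kernel a
#'   zero descriptor then predicts 0.
#' @return Object of class `"gp_model"` with elements `X_train`, `y_train`,
#'   `alpha`, `lambda`, `kernel`, `y_center` and `train_variances` (predictive
#'   variances of the training points, cached at fit time for the adaptive
#'   gate).
#' @export
gp_fit <- function(X, y, lambda, spec = kernel_spec("linear"),
                   center = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 1L) stop_data("gp_fit: need at least one training point")
  if (length(y) != n) stop_data("gp_fit: length(y) != nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_data("gp_fit: inputs must be finite")
  if (!is.finite(lambda) || lambda < 0)
    stop_data("gp_fit: lambda must be >= 0")

  y_center <- if (center) mean(y) else 0
  yc <- y - y_center

  if (spec$kind == "linear" && lambda > 0) {
    fac <- make_factor_svd(X, lambda)
  } else {
    fac <- make_factor_chol(kernel_matrix(X, X, spec), lambda)
  }
  alpha <- drop(solve_factor(fac, yc))

  model <- structure(
    list(X_train = X, y_train = y, alpha = alpha, lambda = lambda,
         kernel = spec, y_center = y_center, factor = fac,
         train_variances = NULL),
    class = "gp_model")
  model$train_variances <- predict_variance(model, X)
  model
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model: %d training points, d = %d, kernel = %s, lambda = %g>\n",
              nrow(x$X_train), ncol(x$X_train), x$kernel$kind, x$lambda))
  invisible(x)
}

#' Predict mean energies
#'
#' Implements `y_center + L' alpha` with L the train/test kernel matrix.
#'
#' @param model A fitted [gp_fit()] model.
#' @param Xs m x d matrix of test descriptors (m may be 0).
#' @return Length-m numeric vector, kJ/mol.
#' @export
predict_mean <- function(model, Xs) {
  Xs <- as.matrix(Xs)
  if (nrow(Xs) == 0L) return(numeric(0))
  if (ncol(Xs) != ncol(model$X_train))
    stop_data("predict_mean: descriptor dimension mismatch (",
              ncol(Xs), " vs ", ncol(model$X_train), ")")
  L <- kernel_matrix(model$X_train, Xs, model$kernel)
  model$y_center + drop(crossprod(L, model$alpha))
}

#' Predictive variance
#'
#' `diag(M) - diag(L' (K + lambda I)^{-1} L)`; the observation-noise term
#' lambda is not added (epistemic part only — see the package vignette).
#' Small negative values from roundoff are clipped to zero; negatives beyond
#' the numerical tolerance raise an error.
#'
#' @param model A fitted [gp_fit()] model.
#' @param Xs m x d matrix of test descriptors.
#' @return Length-m vector of nonnegative variances.
#' @export
predict_variance <- function(model, Xs) {
  Xs <- as.matrix(Xs)
  if (nrow(Xs) == 0L) return(numeric(0))
  if (ncol(Xs) != ncol(model$X_train))
    stop_data("predict_variance: descriptor dimension mismatch")
  kss <- kernel_diag(Xs, model$kernel)
  fac <- model$factor
  if (fac$type == "svd") {
    # linear kernel: v(x) = lambda * sum_j t_j^2/(s_j^2+lambda) + ||x - V t||^2
    # with t = V' x — both terms nonnegative, so no catastrophic cancellation
    Tm <- crossprod(fac$v, t(Xs))
    term1 <- fac$lambda * colSums(Tm^2 / (fac$d^2 + fac$lambda))
    resid <- t(Xs) - fac$v %*% Tm
    v <- term1 + colSums(resid^2)
  } else {
    L <- kernel_matrix(model$X_train, Xs, model$kernel)
    v <- kss - colSums(L * solve_factor(fac, L))
  }
  tol <- pmax(1e-8, 1e-10 * pmax(1, abs(kss)))  # roundoff scales with k(x,x)
  if (any(v < -tol))
    stop_data("predict_variance: negative variance beyond numerical ",
              "tolerance (min ", format(min(v)), ")")
  pmax(v, 0)
}

#' Select the noise level by stratified cross-validated MAE
#'
#' Runs k-fold energy-stratified cross-validation for every lambda on the
#' grid and returns the value minimizing the mean fold MAE, with ties broken
#' toward the smallest lambda.
#'
#' @param X n x d descriptor matrix.
#' @param y Length-n energies (kJ/mol).
#' @param grid Strictly increasing vector of positive lambdas
#'   (default [default_lambda_grid()]).
#' @param spec A [kernel_spec()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the stratified fold assignment.
#' @param center Passed to [gp_fit()].
#' @return List with `lambda` (the chosen value) and `table` (data frame of
#'   per-lambda CV MAE).
#' @export
select_noise <- function(X, y, grid = default_lambda_grid(),
                         spec = kernel_spec("linear"), k = 10L, seed = 0L,
                         center = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(grid) == 0L) stop_data("select_noise: empty lambda grid")
  if (is.unsorted(grid, strictly = TRUE))
    stop_data("select_noise: grid must be strictly increasing")
  if (any(grid <= 0)) stop_data("select_noise: grid values must be positive")
  if (n < k)
    stop_data("select_noise: n (", n, ") < k (", k, "); use fewer folds")

  folds <- stratified_folds(y, k, seed)
  abs_err <- matrix(NA_real_, nrow = k, ncol = length(grid))
  for (i in seq_len(k)) {
    tr <- folds$fold_of != i
    Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
    Xv <- X[!tr, , drop = FALSE]; yv <- y[!tr]
    ctr <- if (center) mean(yt) else 0
    # one factorization per fold, reused across the whole grid
    if (spec$kind == "linear") {
      s <- svd(Xt)
      uty <- crossprod(s$u, yt - ctr)
      for (g in seq_along(grid)) {
        w <- s$v %*% (s$d * drop(uty) / (s$d^2 + grid[g]))
        pred <- ctr + drop(Xv %*% w)
        abs_err[i, g] <- mean(abs(pred - yv))
      }
    } else {
      Kt <- kernel_matrix(Xt, Xt, spec)
      e <- eigen(Kt, symmetric = TRUE)
      L <- kernel_matrix(Xt, Xv, spec)
      qty <- crossprod(e$vectors, yt - ctr)
      for (g in seq_along(grid)) {
        alpha <- e$vectors %*% (drop(qty) / (pmax(e$values, 0) + grid[g]))
        pred <- ctr + drop(crossprod(L, alpha))
        abs_err[i, g] <- mean(abs(pred - yv))
      }
    }
  }
  cv_mae <- colMeans(abs_err)
  best <- which(cv_mae <= min(cv_mae) + 0)[1L]  # ties -> smallest lambda
  list(lambda = grid[best],
       table = data.frame(lambda = grid, cv_mae = cv_mae))
}
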