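# Energy-stratified cross-validation, error metrics, nested hyper-parameter
# selection and y-randomization significance testing.

#' Energy-stratified fold assignment
#'
#' Sort-and-deal stratification: indices are sorted by `y`, partitioned into
#' consecutive blocks of size `k`, and within each block dealt to distinct
#' folds in a seeded random order.  Fold sizes differ by at most one and every
#' fold sees the whole energy range.
#'
#' @param y Numeric response vector (energies, kJ/mol).
#' @param k Number of folds, `2 <= k <= length(y)`.
#' @param seed Integer seed.
#' @return Object of class `"fold_assignment"`: list with `fold_of`
#'   (integer vector, values 1..k), `k`, `seed`.
#' @export
stratified_folds <- function(y, k, seed = 0L) {
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L) stop_data("stratified_folds: k must be >= 2")
  if (n < k) stop_data("stratified_folds: n (", n, ") < k (", k, ")")
  ord <- order(y)
  fold_of <- integer(n)
  with_seed(seed, {
    pos <- 1L
    while (pos <= n) {
      block <- ord[pos:min(pos + k - 1L, n)]
      fold_of[block] <- sample.int(k, length(block))
      pos <- pos + k
    }
  })
  structure(list(fold_of = fold_of, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Regression error metrics
#'
#' RMSE and MAE in kJ/mol, MAE as a percentage of the training-set energy
#' range, and R^2 as the *squared Pearson correlation* between observed and
#' predicted values (not the coefficient of determination — the two differ
#' for biased predictors).
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @param train_range Positive range (max - min) of the training energies,
#'   used for the MAE percentage.
#' @return Object of class `"metric_report"`: list with `rmse`, `mae`,
#'   `mae_pct`, `r2` (`NA` when either vector has zero variance) and `n`.
#' @export
compute_metrics <- function(y_true, y_pred, train_range) {
  if (length(y_true) != length(y_pred))
    stop_data("compute_metrics: length mismatch")
  if (length(y_true) < 1L) stop_data("compute_metrics: empty input")
  if (!is.finite(train_range) || train_range <= 0)
    stop_data("compute_metrics: train_range must be positive")
  err <- y_pred - y_true
  r2 <- if (length(y_true) >= 2L &&
            stats::sd(y_true) > 0 && stats::sd(y_pred) > 0)
    stats::cor(y_true, y_pred)^2 else NA_real_
  structure(list(rmse = sqrt(mean(err^2)),
                 mae = mean(abs(err)),
                 mae_pct = 100 * mean(abs(err)) / train_range,
                 r2 = r2,
                 n = length(y_true)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("RMSE %.3f kJ/mol | MAE %.3f kJ/mol | MAE %.2f%% | R2 %s | n = %d\n",
              x$rmse, x$mae, x$mae_pct,
              if (is.na(x$r2)) "undef" else sprintf("%.3f", x$r2), x$n))
  invisible(x)
}

#' Repeated stratified nested cross-validation
#'
#' For each repetition the data are split into `k` energy-stratified folds;
#' for each outer fold the noise level is selected by [select_noise()] on the
#' training portion only (inner stratified CV), a model is fitted on the
#' training portion and evaluated on the held-out fold.  Every sample is
#' predicted exactly once per repetition by a model that never saw it.
#'
#' @param X m x d descriptor matrix.
#' @param y Energies, kJ/mol.
#' @param k Outer (and inner) fold count, default 10.
#' @param reps Repetitions, default 10 (so `k*reps` fold-level reports).
#' @param grid Lambda grid for the inner selection.
#' @param spec A [kernel_spec()].
#' @param seed Integer seed; repetition r uses `seed + r`.
#' @param center Passed to [gp_fit()]/[select_noise()].
#' @return Object of class `"nested_cv"`: `reports` (data frame with one row
#'   per outer fold: rep, fold, n, rmse, mae, mae_pct, r2, lambda) and
#'   `predictions` (n x reps matrix of out-of-fold predictions).
#' @export
nested_cv <- function(X, y, k = 10L, reps = 10L,
                      grid = default_lambda_grid(),
                      spec = kernel_spec("linear"), seed = 0L,
                      center = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L * k)
    stop_data("nested_cv: need at least 2k samples (n = ", n, ", k = ", k, ")")
  rows <- vector("list", k * reps)
  preds <- matrix(NA_real_, nrow = n, ncol = reps)
  r <- 0L
  for (rep in seq_len(reps)) {
    rep_seed <- as.integer(seed) + rep
    folds <- stratified_folds(y, k, rep_seed)
    for (i in seq_len(k)) {
      tr <- folds$fold_of != i
      Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
      sel <- select_noise(Xt, yt, grid = grid, spec = spec,
                          k = min(k, length(yt)),
                          seed = rep_seed * 100L + i, center = center)
      model <- gp_fit(Xt, yt, sel$lambda, spec = spec, center = center)
      yhat <- predict_mean(model, X[!tr, , drop = FALSE])
      preds[!tr, rep] <- yhat
      met <- compute_metrics(y[!tr], yhat, diff(range(yt)))
      r <- r + 1L
      rows[[r]] <- data.frame(rep = rep, fold = i, n = met$n,
                              rmse = met$rmse, mae = met$mae,
                              mae_pct = met$mae_pct, r2 = met$r2,
                              lambda = sel$lambda)
    }
  }
  structure(list(reports = do.call(rbind, rows), predictions = preds,
                 k = k, reps = reps, seed = as.integer(seed)),
            class = "nested_cv")
}

#' Summarize a nested cross-validation
#'
#' Reports mean and standard deviation of each metric both over all
#' `k*reps` fold-level reports and over the `reps` repetition means (the two
#' conventions differ only in the spread estimate).
#'
#' @param object A [nested_cv()] result.
#' @param ... Unused.
#' @return List with `by_fold` and `by_rep` data frames.
#' @export
summary.nested_cv <- function(object, ...) {
  rp <- object$reports
  stat <- function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v, na.rm = TRUE))
  by_fold <- as.data.frame(rbind(rmse = stat(rp$rmse), mae = stat(rp$mae),
                                 mae_pct = stat(rp$mae_pct), r2 = stat(rp$r2)))
  rep_means <- stats::aggregate(rp[c("rmse", "mae", "mae_pct", "r2")],
                                by = list(rep = rp$rep), FUN = mean,
                                na.rm = TRUE)
  by_rep <- as.data.frame(rbind(rmse = stat(rep_means$rmse),
                                mae = stat(rep_means$mae),
                                mae_pct = stat(rep_means$mae_pct),
                                r2 = stat(rep_means$r2)))
  list(by_fold = by_fold, by_rep = by_rep)
}

#' @export
print.nested_cv <- function(x, ...) {
  s <- summary(x)$by_fold
  cat(sprintf("<nested_cv: %d x %d-fold; RMSE %.3f+-%.3f, MAE %.3f+-%.3f, R2 %.3f+-%.3f>\n",
              x$reps, x$k, s["rmse", "mean"], s["rmse", "sd"],
              s["mae", "mean"], s["mae", "sd"],
              s["r2", "mean"], s["r2", "sd"]))
  invisible(x)
}

#' y-randomization (scrambling) validation
#'
#' Refits the whole nested-CV protocol after destroying the
#' descriptor-energy association, to rule out chance correlation:
#' `"permute_labels"` shuffles the energy vector as a block;
#' `"permute_descriptors"` independently shuffles each descriptor column
#' across samples (destroying the joint structure while preserving the
#' marginals).  Real and randomized fold-level MAE distributions are compared
#' with a two-sided Mann-Whitney U test, and the selected noise levels are
#' reported for both runs (scrambled data typically drive lambda up by orders
#' of magnitude).
#'
#' @param X,y,k,reps,grid,spec,center As in [nested_cv()].
#' @param mode `"permute_labels"` or `"permute_descriptors"`.
#' @param cv_seed Seed for the (shared) CV protocol.
#' @param perm_seed Seed for the permutation draw.
#' @param real Optionally a precomputed [nested_cv()] result on the real data
#'   (to avoid refitting it); must use the same `cv_seed`.
#' @param .permutation Test hook: an explicit permutation (integer vector of
#'   length n) used instead of a random draw; the identity permutation
#'   reproduces the real metrics exactly.
#' @return Object of class `"y_randomization"`: `real` and `randomized`
#'   nested-CV results, `p_value` (Mann-Whitney U on fold MAEs), `mode`,
#'   `lambda_real`, `lambda_randomized`.
#' @export
y_randomization <- function(X, y,
                            mode = c("permute_labels", "permute_descriptors"),
                            k = 10L, reps = 10L,
                            grid = default_lambda_grid(),
                            spec = kernel_spec("linear"),
                            cv_seed = 0L, perm_seed = 1L, center = FALSE,
                            real = NULL, .permutation = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(real))
    real <- nested_cv(X, y, k = k, reps = reps, grid = grid, spec = spec,
                      seed = cv_seed, center = center)
  perm_for <- function(j) {
    if (!is.null(.permutation)) return(.permutation)
    sample.int(n)
  }
  if (mode == "permute_labels") {
    Xr <- X
    yr <- with_seed(perm_seed, y[perm_for(0L)])
  } else {
    yr <- y
    Xr <- with_seed(perm_seed, {
      out <- X
      for (j in seq_len(ncol(X))) out[, j] <- X[perm_for(j), j]
      out
    })
  }
  randomized <- nested_cv(Xr, yr, k = k, reps = reps, grid = grid,
                          spec = spec, seed = cv_seed, center = center)
  p <- stats::wilcox.test(real$reports$mae, randomized$reports$mae,
                          alternative = "two.sided", exact = FALSE,
                          correct = TRUE)$p.value
  structure(list(real = real, randomized = randomized, p_value = p,
                 mode = mode,
                 lambda_real = real$reports$lambda,
                 lambda_randomized = randomized$reports$lambda),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("<y_randomization (%s): real MAE %.3f, randomized MAE %.3f, p = %.3g>\n",
              x$mode, mean(x$real$reports$mae),
              mean(x$randomized$reports$mae), x$p_value))
  invisible(x)
}
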