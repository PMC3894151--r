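# "Learning on the fly": per-conformation decision between cheap surrogate
# prediction and an expensive oracle call, gated by the kappa-quantile of the
# training points' predictive variances.  Rejected conformations are scored
# by the oracle, added to the training set, and the model is refitted; the
# threshold is recomputed after every retrain because the quantile is defined
# on the (now larger) training set.

#' Configuration for the adaptive controller
#'
#' @param initial_size Size of the initial stratified training set
#'   (default 50).
#' @param kappa Quantile of the training-point predictive variances used as
#'   the acceptance gate, in `[0, 1]` (default 0.95). Larger kappa accepts
#'   more conformations for prediction, trading accuracy for savings.
#' @param lambda_grid Grid for the noise-level selection on the initial set.
#' @param kernel A [kernel_spec()].
#' @param retrain_lambda `"fixed_after_init"` (default): lambda is selected
#'   once on the initial set and held fixed; `"reoptimize_each"` reruns the
#'   grid search after every retrain (quadratic cost).
#' @param retrain If `FALSE` the model and threshold are frozen: rejected
#'   items are still counted as "computed" but nothing is refitted (used for
#'   the nestedness diagnostics of the gate).
#' @param seed Integer seed (initial stratified sample, fold assignments).
#' @return Object of class `"adaptive_config"`.
#' @export
adaptive_config <- function(initial_size = 50L, kappa = 0.95,
                            lambda_grid = default_lambda_grid(),
                            kernel = kernel_spec("linear"),
                            retrain_lambda = c("fixed_after_init",
                                               "reoptimize_each"),
                            retrain = TRUE, seed = 0L) {
  retrain_lambda <- match.arg(retrain_lambda)
  if (initial_size < 2L) stop_data("initial_size must be >= 2")
  if (!is.finite(kappa) || kappa < 0 || kappa > 1)
    stop_data("kappa must be in [0, 1]")
  structure(list(initial_size = as.integer(initial_size), kappa = kappa,
                 lambda_grid = lambda_grid, kernel = kernel,
                 retrain_lambda = retrain_lambda, retrain = retrain,
                 seed = as.integer(seed)),
            class = "adaptive_config")
}

#' Variance gate threshold
#'
#' Empirical kappa-quantile (linear-interpolation definition) of the fitted
#' model's training-point predictive variances.
#'
#' @param model A [gp_fit()] model (needs >= 2 training points).
#' @param kappa Quantile in `[0, 1]`.
#' @return Positive scalar threshold.
#' @export
variance_threshold <- function(model, kappa) {
  if (!is.finite(kappa) || kappa < 0 || kappa > 1)
    stop_data("kappa must be in [0, 1]")
  if (length(model$train_variances) < 2L)
    stop_data("variance_threshold needs >= 2 training points")
  stats::quantile(model$train_variances, probs = kappa, type = 7,
                  names = FALSE)
}

# energy-stratified subsample: sort by energy, cut into `size` blocks, draw
# one member per block (seeded)
stratified_sample <- function(energies, size, seed) {
  n <- length(energies)
  if (size > n) stop_data("stratified sample larger than pool")
  ord <- order(energies)
  bounds <- floor(seq(0L, n, length.out = size + 1L))
  with_seed(seed, {
    vapply(seq_len(size), function(b) {
      block <- ord[(bounds[b] + 1L):bounds[b + 1L]]
      block[sample.int(length(block), 1L)]
    }, integer(1))
  })
}

#' Run the adaptive prediction/recomputation scheme over a stream
#'
#' Starts from an energy-stratified initial training set, then walks the
#' stream in order: a conformation whose predictive variance falls below the
#' current [variance_threshold()] is predicted by the surrogate; otherwise
#' the oracle is called, the conformation joins the training set, the model
#' is refitted and the threshold recomputed.
#'
#' @param stream An [ensemble()] of conformations, processed in order.
#' @param oracle Function `conformation -> energy (kJ/mol)`, the expensive
#'   reference method.
#' @param config An [adaptive_config()].
#' @param initial_pool Optional [ensemble()] to draw the initial stratified
#'   training set from (energies taken from the conformations or computed
#'   via the oracle).  When `NULL`, the first `initial_size` stream frames
#'   are scored by the oracle and used as the initial set; the remainder of
#'   the stream is then processed adaptively.
#' @return Object of class `"adaptive_result"`: `decisions` (character,
#'   `"predicted"`/`"computed"`, named by conf_id, one per processed stream
#'   item), `predictions` (named vector for the predicted items),
#'   `computed_energies` (named vector of oracle energies for the rejected
#'   items), `n_predicted`, `initial_size`, `final_train_size`,
#'   `stream_length`,
#'   `lambda`, and — computed against the oracle for diagnostics —
#'   `predicted_truth` plus `predicted_metrics` (a [compute_metrics()]
#'   report, `NULL` when nothing was predicted).
#' @export
run_on_the_fly <- function(stream, oracle, config = adaptive_config(),
                           initial_pool = NULL) {
  if (!inherits(stream, "ensemble")) stop_data("stream must be an ensemble")
  if (length(stream) < 1L) stop_data("empty stream")

  confs <- stream$conformations
  if (is.null(initial_pool)) {
    if (length(confs) <= config$initial_size)
      stop_data("stream shorter than initial_size; supply initial_pool")
    pool <- confs[seq_len(config$initial_size)]
    confs <- confs[-seq_len(config$initial_size)]
    pool_e <- vapply(pool, function(c) oracle_energy(oracle, c), numeric(1))
    init_idx <- seq_along(pool)  # the whole pool is the initial set
  } else {
    pool <- initial_pool$conformations
    pool_e <- vapply(pool, function(c) {
      if (!is.null(c$energy)) c$energy else oracle_energy(oracle, c)
    }, numeric(1))
    init_idx <- stratified_sample(pool_e, config$initial_size, config$seed)
  }

  X <- do.call(rbind, lapply(pool[init_idx], vectorize))
  y <- pool_e[init_idx]
  sel <- select_noise(X, y, grid = config$lambda_grid, spec = config$kernel,
                      k = min(10L, nrow(X)), seed = config$seed)
  lambda <- sel$lambda
  model <- gp_fit(X, y, lambda, spec = config$kernel)
  thresh <- variance_threshold(model, config$kappa)

  m <- length(confs)
  decisions <- character(m)
  ids <- vapply(confs, function(c) c$conf_id, character(1))
  predictions <- numeric(0)
  computed_energies <- numeric(0)
  for (i in seq_len(m)) {
    xi <- matrix(vectorize(confs[[i]]), nrow = 1L)
    v <- predict_variance(model, xi)
    # kappa = 0 disables the surrogate entirely (nothing can fall strictly
    # below the gate in spirit, even if a variance undercuts the training
    # minimum numerically)
    if (config$kappa > 0 && v < thresh) {
      decisions[i] <- "predicted"
      predictions[ids[i]] <- predict_mean(model, xi)
    } else {
      decisions[i] <- "computed"
      if (config$retrain) {
        e <- oracle_energy(oracle, confs[[i]])
        computed_energies[ids[i]] <- e
        X <- rbind(X, xi)
        y <- c(y, e)
        if (config$retrain_lambda == "reoptimize_each")
          lambda <- select_noise(X, y, grid = config$lambda_grid,
                                 spec = config$kernel,
                                 k = min(10L, nrow(X)),
                                 seed = config$seed)$lambda
        model <- gp_fit(X, y, lambda, spec = config$kernel)
        thresh <- variance_threshold(model, config$kappa)
      }
    }
  }
  names(decisions) <- ids

  predicted_metrics <- NULL
  predicted_truth <- NULL
  if (length(predictions) > 0L) {
    pred_confs <- confs[decisions == "predicted"]
    predicted_truth <- vapply(pred_confs,
                              function(c) oracle_energy(oracle, c),
                              numeric(1))
    names(predicted_truth) <- names(predictions)
    predicted_metrics <- compute_metrics(predicted_truth, predictions,
                                         diff(range(y)))
  }

  structure(list(decisions = decisions, predictions = predictions,
                 computed_energies = computed_energies,
                 n_predicted = sum(decisions == "predicted"),
                 initial_size = length(init_idx),
                 final_train_size = nrow(X),
                 stream_length = m,
                 lambda = lambda,
                 kappa = config$kappa,
                 predicted_truth = predicted_truth,
                 predicted_metrics = predicted_metrics),
            class = "adaptive_result")
}

# oracle may fail for a conformation; surface the id
oracle_energy <- function(oracle, conf) {
  e <- tryCatch(oracle(conf), error = function(err)
    stop_data("oracle failed for conformation '", conf$conf_id, "': ",
              conditionMessage(err)))
  if (!is.finite(e))
    stop_data("oracle returned a non-finite energy for '", conf$conf_id, "'")
  as.numeric(e)
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat(sprintf("<adaptive_result: kappa = %g, %d/%d predicted (%.0f%% oracle calls avoided), final train size %d>\n",
              x$kappa, x$n_predicted, x$stream_length,
              100 * x$n_predicted / x$stream_length, x$final_train_size))
  if (!is.null(x$predicted_metrics)) {
    cat("  predicted subset: ")
    print(x$predicted_metrics)
  }
  invisible(x)
}

#' Build a lookup-table oracle from an energy table
#'
#' @param energies Named numeric vector (conf_id -> kJ/mol), e.g. from
#'   [read_energy_table()].
#' @return A function `conformation -> energy` erroring on unknown ids.
#' @export
table_oracle <- function(energies) {
  force(energies)
  function(conf) {
    i <- match(conf$conf_id, names(energies))
    if (is.na(i))
      stop("no reference energy for '", conf$conf_id, "'")
    energies[[i]]
  }
}

#' Accuracy/savings trade-off over a kappa list
#'
#' One full adaptive run per kappa value with a common seed and initial
#' pool.  When `stream` is a list of ensembles (runs) and
#' `average_orderings = TRUE`, every permutation of the runs is evaluated and
#' the results are averaged over orderings.
#'
#' @param stream An [ensemble()], or a list of ensembles (runs).
#' @param oracle Oracle function as in [run_on_the_fly()].
#' @param kappa_list Ascending vector of kappa values.
#' @param config An [adaptive_config()] (its `kappa` is overridden).
#' @param initial_pool Passed to [run_on_the_fly()].
#' @param average_orderings Enumerate all run orderings (requires `stream`
#'   to be a list of ensembles).
#' @return Data frame with one row per kappa: `kappa`, `m_predicted`, `mae`,
#'   `r2` (MAE/R2 of the predicted subset vs the oracle; `NA` when nothing
#'   was predicted), and `n_orderings`.
#' @export
kappa_tradeoff <- function(stream, oracle, kappa_list,
                           config = adaptive_config(),
                           initial_pool = NULL,
                           average_orderings = FALSE) {
  if (is.unsorted(kappa_list))
    stop_data("kappa_list must be sorted ascending")
  orderings <- if (average_orderings) {
    if (!is.list(stream) || inherits(stream, "ensemble"))
      stop_data("average_orderings needs a list of run ensembles")
    perms <- all_permutations(length(stream))
    lapply(perms, function(p)
      ensemble(unlist(lapply(stream[p], function(e) e$conformations),
                      recursive = FALSE)))
  } else {
    if (is.list(stream) && !inherits(stream, "ensemble"))
      stream <- ensemble(unlist(lapply(stream, function(e) e$conformations),
                                recursive = FALSE))
    list(stream)
  }
  rows <- lapply(kappa_list, function(kap) {
    cfg <- config
    cfg$kappa <- kap
    res <- lapply(orderings, function(s)
      run_on_the_fly(s, oracle, cfg, initial_pool = initial_pool))
    m <- mean(vapply(res, function(r) r$n_predicted, numeric(1)))
    maes <- vapply(res, function(r)
      if (is.null(r$predicted_metrics)) NA_real_ else r$predicted_metrics$mae,
      numeric(1))
    r2s <- vapply(res, function(r)
      if (is.null(r$predicted_metrics)) NA_real_ else r$predicted_metrics$r2,
      numeric(1))
    data.frame(kappa = kap, m_predicted = m,
               mae = mean(maes, na.rm = TRUE), r2 = mean(r2s, na.rm = TRUE),
               n_orderings = length(res))
  })
  do.call(rbind, rows)
}

# all permutations of 1..n (n small: run orderings)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in 0L:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}
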