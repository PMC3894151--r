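# Small adaptive-controller scenarios built on the compact synthetic study;
# the paper-scale run lives in the acceptance suite.

small_oracle <- function(st) {
  function(conf) synthetic_energy(conf, st$spec, st$params)
}

test_that("the gate threshold is the interpolated quantile of train variances", {
  m <- structure(list(train_variances = c(1, 2, 3, 4)), class = "gp_model")
  expect_equal(variance_threshold(m, 0.5), 2.5)
  expect_equal(variance_threshold(m, 0), 1)
  expect_equal(variance_threshold(m, 1), 4)
  expect_error(variance_threshold(m, 1.5), "\\[0, 1\\]")
  expect_error(variance_threshold(m, -0.1), "\\[0, 1\\]")
})

test_that("kappa = 0 rejects everything and the accounting identity holds", {
  st <- small_study()
  oracle <- small_oracle(st)
  pool <- st$ensembles[[1]]
  stream <- st$ensembles[[2]]
  cfg <- adaptive_config(initial_size = 20, kappa = 0, seed = 1)
  res <- run_on_the_fly(stream, oracle, cfg, initial_pool = pool)
  expect_identical(res$n_predicted, 0L)
  expect_length(res$predictions, 0)
  expect_identical(res$final_train_size,
                   res$initial_size + res$stream_length)
  # every computed energy equals the oracle value exactly
  for (id in names(res$computed_energies)) {
    conf <- stream$conformations[[which(vapply(stream$conformations,
                                               function(c) c$conf_id,
                                               character(1)) == id)]]
    expect_identical(res$computed_energies[[id]], oracle(conf))
  }
})

test_that("copies of the training set are recognized and reproduced", {
  # a small, geometrically diverse pool keeps the kernel matrix
  # well-conditioned, so a tiny noise level interpolates the references
  spec <- toy_molecule_spec(8L)
  set.seed(22)
  pool <- ensemble(lapply(1:12, function(i)
    build_conformation(spec, runif(spec$n_torsions, -pi, pi),
                       conf_id = paste0("p", i))))
  energies <- stats::setNames(rnorm(12, 20, 5),
                              vapply(pool$conformations,
                                     function(c) c$conf_id, character(1)))
  for (i in seq_len(12))
    pool$conformations[[i]]$energy <- energies[[i]]
  copies <- lapply(pool$conformations, function(c) {
    c2 <- c; c2$conf_id <- paste0("copy_", c$conf_id); c2
  })
  copy_oracle <- function(conf) energies[[sub("^copy_", "", conf$conf_id)]]
  cfg <- adaptive_config(initial_size = 12, kappa = 0.95,
                         lambda_grid = 1e-10, seed = 2)
  res <- run_on_the_fly(ensemble(copies), copy_oracle, cfg,
                        initial_pool = pool)
  # in-domain duplicates are overwhelmingly accepted for prediction, and
  # each prediction interpolates the stored reference energy
  expect_gte(res$n_predicted, 10L)
  truth <- energies[sub("^copy_", "", names(res$predictions))]
  expect_lt(max(abs(res$predictions - truth)), 1e-4)
})

test_that("accounting identity: predicted + newly computed = stream length", {
  st <- small_study()
  oracle <- small_oracle(st)
  pool <- st$ensembles[[1]]
  stream <- st$ensembles[[3]]
  for (kap in c(0.3, 0.8, 1)) {
    res <- run_on_the_fly(stream, oracle,
                          adaptive_config(initial_size = 15, kappa = kap,
                                          seed = 3),
                          initial_pool = pool)
    expect_identical(res$n_predicted + (res$final_train_size -
                                          res$initial_size),
                     res$stream_length)
  }
})

test_that("with a frozen model the predicted sets are nested in kappa", {
  st <- small_study()
  oracle <- small_oracle(st)
  pool <- st$ensembles[[1]]
  stream <- st$ensembles[[2]]
  sets <- lapply(c(0.2, 0.5, 0.8, 0.95), function(kap) {
    res <- run_on_the_fly(stream, oracle,
                          adaptive_config(initial_size = 25, kappa = kap,
                                          retrain = FALSE, seed = 4),
                          initial_pool = pool)
    names(res$predictions)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("adaptive runs are reproducible for a fixed seed", {
  st <- small_study()
  oracle <- small_oracle(st)
  cfg <- adaptive_config(initial_size = 15, kappa = 0.9, seed = 5)
  r1 <- run_on_the_fly(st$ensembles[[2]], oracle, cfg,
                       initial_pool = st$ensembles[[1]])
  r2 <- run_on_the_fly(st$ensembles[[2]], oracle, cfg,
                       initial_pool = st$ensembles[[1]])
  expect_identical(r1$decisions, r2$decisions)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("oracle failures surface the conformer id", {
  st <- small_study()
  bad_oracle <- function(conf) stop("backend down")
  expect_error(
    run_on_the_fly(st$ensembles[[2]], bad_oracle,
                   adaptive_config(initial_size = 10, kappa = 0, seed = 6),
                   initial_pool = st$ensembles[[1]]),
    "r2_001")
})

test_that("kappa_tradeoff enumerates run orderings and degenerate kappas", {
  st <- small_study()
  oracle <- small_oracle(st)
  pool <- st$ensembles[[1]]
  tab <- kappa_tradeoff(st$ensembles[2:3], oracle, kappa_list = c(0, 0.9),
                        config = adaptive_config(initial_size = 15,
                                                 seed = 7),
                        initial_pool = pool, average_orderings = TRUE)
  expect_identical(tab$n_orderings, c(2L, 2L))  # 2! orderings of two runs
  expect_equal(tab$m_predicted[1], 0)
  expect_true(is.na(tab$mae[1]) || is.nan(tab$mae[1]))
  expect_gt(tab$m_predicted[2], 0)
  expect_error(kappa_tradeoff(pool, oracle, c(0.9, 0.1)), "ascending")
})

test_that("table oracles look energies up by conformer id", {
  oracle <- table_oracle(c(a = 1.5, b = -2))
  conf <- h2_at(1); conf$conf_id <- "a"
  expect_identical(oracle(conf), 1.5)
  conf$conf_id <- "missing"
  expect_error(oracle(conf), "missing")
})
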