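# An independently coded energy evaluator serves as the oracle for the
# analytic surface (same formulas, separate implementation path).

independent_energy <- function(torsions, spec, params) {
  tors_part <- 0
  for (t in seq_along(torsions)) {
    tors_part <- tors_part + params$amplitude[t] *
      (1 + cos(params$multiplicity[t] * torsions[t] - params$phase[t]))
  }
  conf <- build_conformation(spec, torsions)
  nb <- 0
  n <- spec$n_atoms
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i >= 4) {
        r <- sqrt(sum((conf$coords[i, ] - conf$coords[j, ])^2))
        nb <- nb + 4 * params$nb_epsilon *
          ((params$nb_sigma / r)^12 - (params$nb_sigma / r)^6)
      }
    }
  }
  tors_part + nb
}

test_that("chain construction is deterministic and extends at all-trans", {
  spec <- toy_molecule_spec(10L)
  c1 <- build_conformation(spec, rep(pi, spec$n_torsions))
  c2 <- build_conformation(spec, rep(pi, spec$n_torsions))
  expect_identical(c1$coords, c2$coords)

  end_to_end <- function(conf) sqrt(sum((conf$coords[10, ] - conf$coords[1, ])^2))
  ext <- end_to_end(c1)
  set.seed(71)
  for (i in 1:20) {
    alt <- build_conformation(spec, runif(spec$n_torsions, -pi, pi))
    expect_lte(end_to_end(alt), ext + 1e-9)
  }
})

test_that("requested torsions are recovered from the Cartesian geometry", {
  spec <- toy_molecule_spec(6L)
  for (phi in c(-2.8, -pi / 3, pi / 3, 1.0472, 2.5)) {
    conf <- build_conformation(spec, c(phi, -phi, phi / 2))
    got <- dihedral_angle(conf$coords[1, ], conf$coords[2, ],
                          conf$coords[3, ], conf$coords[4, ])
    expect_equal(got, phi, tolerance = 1e-6)
    got3 <- dihedral_angle(conf$coords[3, ], conf$coords[4, ],
                           conf$coords[5, ], conf$coords[6, ])
    expect_equal(got3, phi / 2, tolerance = 1e-6)
  }
})

test_that("the analytic surface has the stated limits", {
  spec <- toy_molecule_spec(8L)
  nullp <- energy_params(spec, amplitude = 0, nb_epsilon = 0, noise_sd = 0)
  expect_equal(synthetic_energy(runif(spec$n_torsions, -pi, pi), spec, nullp), 0)

  # single cosine well: A = 10, m = 1, phase 0
  p <- energy_params(spec, amplitude = c(10, rep(0, spec$n_torsions - 1)),
                     multiplicity = 1, nb_epsilon = 0, noise_sd = 0)
  tors <- rep(pi, spec$n_torsions)
  expect_equal(synthetic_energy(tors, spec, p), 0)
  tors[1] <- 0
  expect_equal(synthetic_energy(tors, spec, p), 20)
})

test_that("the surface agrees with an independently coded evaluator", {
  spec <- toy_molecule_spec(12L)
  params <- energy_params(spec, noise_sd = 0)
  set.seed(72)
  for (i in 1:20) {
    tors <- runif(spec$n_torsions, -pi, pi)
    expect_equal(synthetic_energy(tors, spec, params),
                 independent_energy(tors, spec, params), tolerance = 1e-9)
  }
})

test_that("per-conformer noise is reproducible and id-keyed", {
  spec <- toy_molecule_spec(8L)
  params <- energy_params(spec, noise_sd = 0.5, seed = 3)
  tors <- rep(pi, spec$n_torsions)
  e_a1 <- synthetic_energy(tors, spec, params, conf_id = "a")
  e_a2 <- synthetic_energy(tors, spec, params, conf_id = "a")
  e_b <- synthetic_energy(tors, spec, params, conf_id = "b")
  clean <- synthetic_energy(tors, spec, params)  # no id -> noiseless
  expect_identical(e_a1, e_a2)
  expect_false(e_a1 == e_b)
  expect_equal(clean,
               synthetic_energy(tors, spec,
                                energy_params(spec, noise_sd = 0)))
})

test_that("study generation is seed-reproducible to the byte", {
  spec <- toy_molecule_spec(8L)
  cfg <- study_config(n_runs = 2L, frames_per_run = 10L,
                      run_bias = c(-1, 1), seed = 9L)
  s1 <- generate_study(spec, energy_params(spec, seed = 9L), cfg)
  s2 <- generate_study(spec, energy_params(spec, seed = 9L), cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in c("run1.xyz", "run2.xyz", "energies.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the full study has the expected shape and run separation", {
  st <- full_study()
  expect_length(st$ensembles, 4L)
  expect_identical(nrow(st$energies), 960L)
  expect_identical(vapply(st$ensembles, length, integer(1)), rep(240L, 4))
  expect_false(anyDuplicated(st$energies$conf_id) > 0)

  # runs occupy distinct torsional basins: between-run mean torsion
  # separation exceeds 3x the within-run spread
  run_means <- vapply(st$ensembles, function(e) {
    mean(vapply(e$conformations, function(c) mean(attr(c, "torsions")),
                numeric(1)))
  }, numeric(1))
  run_sds <- vapply(st$ensembles, function(e) {
    mean(vapply(e$conformations, function(c) sd(attr(c, "torsions")),
                numeric(1)))
  }, numeric(1))
  gaps <- abs(diff(sort(run_means)))
  expect_gt(min(gaps), 3 * max(run_sds) / sqrt(st$spec$n_torsions))
  # energies recorded in the table match the conformations
  expect_equal(unname(ensemble_energies(st$ensembles[[1]])),
               st$energies$energy[st$energies$run == 1])
})

test_that("XYZ round trip preserves the study's conformer energies", {
  st <- small_study()
  d <- withr::local_tempdir()
  write_study(st, d)
  back <- read_xyz(file.path(d, "run1.xyz"))
  expect_equal(ensemble_energies(back),
               ensemble_energies(st$ensembles[[1]]), tolerance = 1e-9)
  tab <- read_energy_table(file.path(d, "energies.csv"))
  expect_length(tab, length(st$ensembles) * 40L)
})
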