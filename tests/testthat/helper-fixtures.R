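# Fixtures are generated in code; the expensive shared objects (the full
# synthetic study and its descriptor matrix) are built once per test run and
# cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the study at its default ("paper-scale") conditions: 4 runs x 240 frames,
# 12-atom chain, noise_sd 0.5 kJ/mol, seed 0
full_study <- function() {
  cached("full_study", function() {
    spec <- toy_molecule_spec()
    generate_study(spec, energy_params(spec, seed = 0L),
                   study_config(seed = 0L))
  })
}

full_study_features <- function() {
  cached("full_study_features", function() {
    pool <- pool_study(full_study())
    list(X = featurize_ensemble(pool),
         y = ensemble_energies(pool),
         pool = pool)
  })
}

# out-of-fold nested CV on the pooled study, shared by several tests
full_study_cv <- function() {
  cached("full_study_cv", function() {
    fs <- full_study_features()
    nested_cv(fs$X, fs$y, k = 10L, reps = 10L, seed = 0L)
  })
}

# a small, fast study for unit tests
small_study <- function() {
  cached("small_study", function() {
    spec <- toy_molecule_spec(8L)
    generate_study(spec,
                   energy_params(spec, seed = 1L),
                   study_config(n_runs = 3L, frames_per_run = 40L,
                                run_bias = c(-1.5, 0, 1.5), seed = 1L))
  })
}

# random rigid rotation matrix via QR, det +1
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# random valid conformation with all pairwise distances well separated
random_conformation <- function(n = 8L, conf_id = "rand") {
  repeat {
    xyz <- matrix(stats::runif(n * 3L, 0, 4), n, 3L) +
      3 * seq_len(n)  # spread along the diagonal to avoid clashes
    if (min(stats::dist(xyz)) > 0.8) break
  }
  conformation(sample(c(1L, 6L, 7L, 8L), n, replace = TRUE), xyz,
               conf_id = conf_id)
}

# small H2-like two-atom conformation at a given separation
h2_at <- function(r) {
  conformation(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, r)), conf_id = "h2")
}

# an ensemble of m random n-atom conformations sharing one atom sequence
random_ensemble <- function(m = 5L, n = 6L, energies = NULL) {
  z <- rep(c(6L, 1L), length.out = n)
  confs <- lapply(seq_len(m), function(i) {
    repeat {
      xyz <- matrix(stats::rnorm(n * 3L, sd = 2), n, 3L) + 4 * seq_len(n)
      if (min(stats::dist(xyz)) > 0.8) break
    }
    conformation(z, xyz, conf_id = paste0("c", i),
                 energy = if (is.null(energies)) NULL else energies[i])
  })
  ensemble(confs)
}

# seeded index sample used by the sampling-effect checks
with_seed_idx <- function(seed, n, size) {
  set.seed(seed)
  sample(n, size)
}
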