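# Synthetic conformer study: a toy flexible chain molecule with an analytic,
# reproducibly noisy energy oracle.
#
# The generator stands in for the expensive pipeline that produced the real
# reference data (semi-empirical MD snapshots re-relaxed and scored by
# dispersion-corrected DFT): several "MD runs" of a few hundred conformers
# each of one molecule, with run-specific sampling bias so that training on a
# single run generalizes worse than training on a pooled random subset.

#' Toy chain molecule specification
#'
#' A chain of `n_atoms` atoms with fixed bond lengths and angles; the only
#' degrees of freedom are the `n_atoms - 3` backbone torsions.  The default
#' alternates carbon and hydrogen nuclear charges so descriptor entries carry
#' heterogeneous charge products.
#'
#' @param n_atoms Integer >= 6 (default 12, giving a 66-dimensional
#'   descriptor).
#' @param atomic_numbers Nuclear charges along the chain.
#' @param bond_length Bond length, Angstrom (default 1.5).
#' @param bond_angle Bond angle, degrees (default 111).
#' @return Object of class `"toy_molecule_spec"`.
#' @export
toy_molecule_spec <- function(n_atoms = 12L,
                              atomic_numbers = rep(c(6L, 1L),
                                                   length.out = n_atoms),
                              bond_length = 1.5, bond_angle = 111) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 6L) stop_data("toy molecule needs n_atoms >= 6")
  if (length(atomic_numbers) != n_atoms)
    stop_data("atomic_numbers must have length n_atoms")
  if (bond_length <= 0 || bond_angle <= 0)
    stop_data("geometry parameters must be positive")
  structure(list(n_atoms = n_atoms,
                 atomic_numbers = as.integer(atomic_numbers),
                 bond_length = bond_length, bond_angle = bond_angle,
                 n_torsions = n_atoms - 3L),
            class = "toy_molecule_spec")
}

#' Analytic energy parameters for the toy molecule
#'
#' The oracle energy is a cosine torsional series plus a 12-6 Lennard-Jones
#' term over atom pairs at least four bonds apart, plus Gaussian observation
#' noise attached to the conformer id (so repeated oracle queries for the
#' same conformer are consistent, as they would be for a deterministic
#' quantum-chemistry code).
#'
#' @param spec A [toy_molecule_spec()] (fixes the number of torsion terms).
#' @param amplitude Per-torsion amplitudes A_t, kJ/mol (recycled).
#' @param multiplicity Per-torsion multiplicities m_t (recycled).
#' @param phase Per-torsion phases gamma_t, radians (recycled).
#' @param nb_epsilon,nb_sigma Lennard-Jones well depth (kJ/mol) and radius
#'   (Angstrom) for pairs >= 4 bonds apart.
#' @param noise_sd Observation-noise standard deviation, kJ/mol (default 0.5).
#' @param seed Integer seed for the per-conformer noise streams.
#' @return Object of class `"energy_params"`.
#' @export
energy_params <- function(spec = toy_molecule_spec(),
                          amplitude = c(6, 4, 2),
                          multiplicity = 1L,
                          phase = 0,
                          nb_epsilon = 0.1, nb_sigma = 2.0,
                          noise_sd = 0.5, seed = 0L) {
  nt <- spec$n_torsions
  if (any(amplitude < 0)) stop_data("amplitudes must be >= 0")
  if (noise_sd < 0) stop_data("noise_sd must be >= 0")
  structure(list(amplitude = rep_len(amplitude, nt),
                 multiplicity = rep_len(as.integer(multiplicity), nt),
                 phase = rep_len(phase, nt),
                 nb_epsilon = nb_epsilon, nb_sigma = nb_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "energy_params")
}

#' Study configuration: several biased "MD runs"
#'
#' Each run samples torsions from a Gaussian centered at a run-specific mean
#' (trans + `run_bias[r]`, radians); distinct biases place the runs in
#' different torsional basins, emulating independent MD trajectories with
#' imperfect conformational sampling.
#'
#' @param n_runs Number of runs (default 4).
#' @param frames_per_run Conformers per run (default 240).
#' @param run_bias Per-run mean torsion offset from trans (pi), radians;
#'   entries must be pairwise distinct.
#' @param torsion_jitter_sd Within-run torsion standard deviation, radians
#'   (default 0.25).
#' @param seed Integer seed.
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(n_runs = 4L, frames_per_run = 240L,
                         run_bias = c(-2.0, -0.7, 0.7, 2.0),
                         torsion_jitter_sd = 0.25, seed = 0L) {
  n_runs <- as.integer(n_runs)
  run_bias <- rep_len(run_bias, n_runs)
  if (anyDuplicated(run_bias)) stop_data("run_bias entries must be distinct")
  if (torsion_jitter_sd <= 0) stop_data("torsion_jitter_sd must be positive")
  structure(list(n_runs = n_runs,
                 frames_per_run = as.integer(frames_per_run),
                 run_bias = run_bias,
                 torsion_jitter_sd = torsion_jitter_sd,
                 seed = as.integer(seed)),
            class = "study_config")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle from four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Signed dihedral angle in radians, in (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Build a chain conformation from torsion angles
#'
#' Standard internal-to-Cartesian construction: fixed bond lengths and
#' angles, supplied torsions, atoms placed sequentially (natural extension
#' reference frame).  Deterministic for fixed input.
#'
#' @param spec A [toy_molecule_spec()].
#' @param torsions Numeric vector of `spec$n_torsions` dihedral angles,
#'   radians.
#' @param conf_id Identifier for the resulting conformation.
#' @return A [conformation()]; attribute `"torsions"` stores the input and
#'   attribute `"clash"` is `TRUE` when any pairwise distance is below
#'   0.5 Angstrom (caller may resample).
#' @export
build_conformation <- function(spec, torsions, conf_id = "conf") {
  if (length(torsions) != spec$n_torsions)
    stop_data("expected ", spec$n_torsions, " torsions, got ",
              length(torsions))
  b <- spec$bond_length
  theta <- spec$bond_angle * pi / 180
  n <- spec$n_atoms
  xyz <- matrix(0, n, 3L)
  xyz[2L, ] <- c(b, 0, 0)
  xyz[3L, ] <- xyz[2L, ] + b * c(cos(pi - theta), sin(pi - theta), 0)
  for (i in 4L:n) {
    A <- xyz[i - 3L, ]; B <- xyz[i - 2L, ]; C <- xyz[i - 1L, ]
    phi <- torsions[i - 3L]
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    nvec <- cross3(B - A, bc)
    nvec <- nvec / sqrt(sum(nvec^2))
    mvec <- cross3(nvec, bc)
    local <- b * c(-cos(theta), sin(theta) * cos(phi), -sin(theta) * sin(phi))
    xyz[i, ] <- C + local[1] * bc + local[2] * mvec + local[3] * nvec
  }
  clash <- min(stats::dist(xyz)) < 0.5
  conf <- conformation(spec$atomic_numbers, xyz, conf_id = conf_id)
  attr(conf, "torsions") <- as.numeric(torsions)
  attr(conf, "clash") <- clash
  conf
}

# noiseless analytic surface: torsional series + LJ over pairs >= 4 bonds
# apart (bond separation along the chain = |i - j|)
synthetic_energy_clean <- function(torsions, spec, params) {
  e <- sum(params$amplitude *
             (1 + cos(params$multiplicity * torsions - params$phase)))
  if (params$nb_epsilon > 0) {
    conf <- build_conformation(spec, torsions)
    d <- as.matrix(stats::dist(conf$coords))
    idx <- which(upper.tri(d), arr.ind = TRUE)
    far <- idx[, 2L] - idx[, 1L] >= 4L
    if (any(far)) {
      r <- d[idx[far, , drop = FALSE]]
      sr6 <- (params$nb_sigma / r)^6
      e <- e + sum(4 * params$nb_epsilon * (sr6^2 - sr6))
    }
  }
  e
}

#' Analytic oracle energy of a toy conformation
#'
#' `sum_t A_t (1 + cos(m_t phi_t - gamma_t))` plus a 12-6 Lennard-Jones term
#' over atom pairs at least four bonds apart, plus Gaussian noise drawn from
#' a stream seeded by the conformer id (omitted when `conf_id` is `NULL` or
#' `noise_sd` is 0 — the noiseless variant).
#'
#' @param torsions Torsion vector (radians) or a [conformation()] carrying a
#'   `"torsions"` attribute (as produced by [build_conformation()]).
#' @param spec A [toy_molecule_spec()].
#' @param params An [energy_params()].
#' @param conf_id Conformer id keying the noise stream; defaults to the
#'   conformation's own id when a conformation is supplied.
#' @return Energy in kJ/mol.
#' @export
synthetic_energy <- function(torsions, spec = toy_molecule_spec(),
                             params = energy_params(spec), conf_id = NULL) {
  if (inherits(torsions, "conformation")) {
    if (is.null(conf_id)) conf_id <- torsions$conf_id
    torsions <- attr(torsions, "torsions")
    if (is.null(torsions))
      stop_data("conformation carries no torsions attribute")
  }
  e <- synthetic_energy_clean(torsions, spec, params)
  if (!is.null(conf_id) && params$noise_sd > 0) {
    h <- (string_hash(conf_id) + params$seed * 9973L) %% 2147483647
    e <- e + with_seed(h, stats::rnorm(1L, 0, params$noise_sd))
  }
  e
}

#' Generate a full synthetic conformer study
#'
#' Draws `frames_per_run` torsion vectors per run from
#' `Normal(pi + run_bias[r], torsion_jitter_sd^2)` (wrapped to (-pi, pi]),
#' rebuilds clashed frames (bounded retries) and scores every conformer with
#' the noisy analytic oracle.  Fully reproducible from the study seed.
#'
#' @param spec A [toy_molecule_spec()].
#' @param params An [energy_params()].
#' @param study A [study_config()].
#' @param max_retries Resampling budget per frame (default 100).
#' @return Object of class `"synthetic_study"`: list with `ensembles` (one
#'   [ensemble()] per run, energies attached to each conformation),
#'   `energies` (data frame conf_id/energy/run), `spec`, `params`, `study`.
#' @export
generate_study <- function(spec = toy_molecule_spec(),
                           params = energy_params(spec),
                           study = study_config(),
                           max_retries = 100L) {
  ensembles <- vector("list", study$n_runs)
  rows <- list()
  with_seed(study$seed, {
    for (r in seq_len(study$n_runs)) {
      confs <- vector("list", study$frames_per_run)
      mu <- pi + study$run_bias[r]
      for (f in seq_len(study$frames_per_run)) {
        id <- sprintf("r%d_%03d", r, f)
        for (try in seq_len(max_retries)) {
          tor <- stats::rnorm(spec$n_torsions, mu, study$torsion_jitter_sd)
          tor <- ((tor + pi) %% (2 * pi)) - pi
          conf <- build_conformation(spec, tor, conf_id = id)
          if (!attr(conf, "clash")) break
          conf <- NULL
        }
        if (is.null(conf))
          stop_data("resampling budget exhausted for frame ", id,
                    "; increase torsion_jitter_sd or max_retries")
        e <- synthetic_energy(attr(conf, "torsions"), spec, params,
                              conf_id = id)
        conf$energy <- e
        confs[[f]] <- conf
        rows[[length(rows) + 1L]] <- data.frame(conf_id = id, energy = e,
                                                run = r)
      }
      ensembles[[r]] <- ensemble(confs, run_label = paste0("run", r))
    }
  })
  structure(list(ensembles = ensembles,
                 energies = do.call(rbind, rows),
                 spec = spec, params = params, study = study),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d runs x %d frames, %d-atom chain, noise_sd = %g kJ/mol>\n",
              x$study$n_runs, x$study$frames_per_run, x$spec$n_atoms,
              x$params$noise_sd))
  invisible(x)
}

#' Pool the runs of a synthetic study into one ensemble
#'
#' @param x A [generate_study()] result.
#' @return A single [ensemble()] containing all runs in order.
#' @export
pool_study <- function(x) {
  ensemble(unlist(lapply(x$ensembles, function(e) e$conformations),
                  recursive = FALSE),
           run_label = "pooled")
}

#' Write a synthetic study to disk
#'
#' One `run<r>.xyz` per run plus `energies.csv` and a `manifest.json`
#' recording all generator parameters.
#'
#' @param x A [generate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_study <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(x$ensembles))
    write_xyz(x$ensembles[[r]], file.path(dir, sprintf("run%d.xyz", r)))
  utils::write.csv(x$energies, file.path(dir, "energies.csv"),
                   row.names = FALSE)
  manifest <- list(
    molecule = unclass(x$spec),
    energy = unclass(x$params),
    study = unclass(x$study))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
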