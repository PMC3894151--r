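# Coulomb-matrix conformer descriptor.
#
# A conformation is encoded as the symmetric charge/inverse-distance matrix
# with M_ij = Z_i Z_j / r_ij (r in Angstrom) off the diagonal and
# M_ii = 0.5 Z_i^2.4 on it.  Because the molecule has fixed composition and
# atom ordering, the strict lower triangle concatenated row by row is a
# fixed-length, rotation/translation-invariant descriptor vector; no
# permutation-invariance trick (sorting, eigenspectrum) is applied, and the
# ensemble type's fixed-order invariant guards against accidental reindexing.

#' Coulomb matrix of a conformation
#'
#' @param conf A [conformation()].
#' @return Symmetric n x n matrix: `Z_i*Z_j/r_ij` off-diagonal,
#'   `0.5*Z_i^2.4` on the diagonal.
#' @export
coulomb_matrix <- function(conf) {
  if (!inherits(conf, "conformation")) stop_data("conf must be a conformation")
  z <- as.numeric(conf$atomic_numbers)
  d <- as.matrix(stats::dist(conf$coords))
  if (any(d[upper.tri(d)] <= 1e-6))
    stop_data("coincident atoms in '", conf$conf_id,
              "': inverse distance undefined")
  m <- outer(z, z) / d
  diag(m) <- 0.5 * z^2.4
  m
}

#' Vectorize a conformation into its descriptor
#'
#' Returns the strict lower triangle of the Coulomb matrix in row-major order
#' (pairs (2,1), (3,1), (3,2), (4,1), ...; 1-based atom indices), the
#' fixed-length representation used as machine-learning input.
#'
#' @param conf A [conformation()].
#' @param atom_mask Optional logical or integer vector selecting the atoms
#'   that enter the matrix (default: all).
#' @return Numeric vector of length `n*(n-1)/2`, named by atom pair `"i-j"`.
#' @export
vectorize <- function(conf, atom_mask = NULL) {
  if (!is.null(atom_mask)) {
    z <- conf$atomic_numbers[atom_mask]
    conf <- conformation(z, conf$coords[atom_mask, , drop = FALSE],
                         conf_id = conf$conf_id, energy = conf$energy)
  }
  m <- coulomb_matrix(conf)
  # row-major strict lower triangle of a symmetric matrix == column-major
  # strict upper triangle
  ut <- upper.tri(m)
  v <- m[ut]
  idx <- which(ut, arr.ind = TRUE)  # (row = j, col = i), i > j
  names(v) <- paste0(idx[, 2L], "-", idx[, 1L])
  v
}

#' Featurize an ensemble
#'
#' @param x An [ensemble()] with at least one conformation.
#' @param atom_mask Optional atom subset passed to [vectorize()].
#' @param standardize If `TRUE`, each descriptor dimension is centered and
#'   scaled to unit variance (constant columns are left centered only); the
#'   centers/scales are attached as attributes.  Off by default: it does not
#'   improve the surrogate and complicates reuse of the fitted model.
#' @return m x d numeric matrix, one descriptor row per conformation,
#'   rownames = conf ids, colnames = atom-pair labels.
#' @export
featurize_ensemble <- function(x, atom_mask = NULL, standardize = FALSE) {
  if (!inherits(x, "ensemble")) stop_data("x must be an ensemble")
  if (length(x) == 0L) stop_data("cannot featurize an empty ensemble")
  rows <- lapply(x$conformations, vectorize, atom_mask = atom_mask)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(x$conformations, function(c) c$conf_id, character(1))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    # pairs at fixed separation (bonded atoms etc.) give (near-)constant
    # columns; leave those centered but unscaled instead of dividing by
    # roundoff noise
    const <- scl <= 1e-10 * pmax(1, abs(ctr))
    scl[const] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    X[, const] <- 0
    attr(X, "center") <- ctr
    attr(X, "scale") <- scl
  }
  X
}
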