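# Conformer ensembles, multi-frame XYZ I/O and energy tables.
#
# Every downstream module relies on the fixed-atom-order contract enforced
# here: all conformations of an ensemble describe the same molecule with the
# same atom indexing.

# Symbols indexed by nuclear charge Z = 1..118.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Convert element symbols to nuclear charges
#'
#' @param symbols Character vector of element symbols (`"H"` .. `"Og"`).
#'   Strings that are already integers (e.g. `"6"`) are passed through.
#' @return Integer vector of nuclear charges Z.
#' @export
element_to_z <- function(symbols) {
  numeric_like <- grepl("^[0-9]+$", symbols)
  z <- integer(length(symbols))
  z[numeric_like] <- as.integer(symbols[numeric_like])
  idx <- match(symbols[!numeric_like], .ELEMENTS)
  if (anyNA(idx)) {
    bad <- unique(symbols[!numeric_like][is.na(idx)])
    stop_data("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  z[!numeric_like] <- idx
  if (any(z < 1)) stop_data("nuclear charges must be positive")
  z
}

#' Create a conformation
#'
#' A conformation is one geometry of a molecule: nuclear charges plus
#' Cartesian coordinates in Angstrom, optionally with a reference energy in
#' kJ/mol.
#'
#' @param atomic_numbers Integer vector of nuclear charges Z (length n >= 2).
#' @param coords Numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param conf_id Identifier string.
#' @param energy Optional reference energy, kJ/mol.
#' @return An object of class `"conformation"`.
#' @export
conformation <- function(atomic_numbers, coords, conf_id = "conf",
                         energy = NULL) {
  atomic_numbers <- as.integer(atomic_numbers)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(atomic_numbers)
  if (n < 2L) stop_data("a conformation needs at least 2 atoms")
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != n)
    stop_data("coords must be an n x 3 matrix matching atomic_numbers")
  if (!all(is.finite(coords))) stop_data("coordinates must be finite")
  if (any(atomic_numbers < 1L)) stop_data("nuclear charges must be positive")
  if (min(stats::dist(coords)) <= 1e-6)
    stop_data("conformation '", conf_id, "' has coincident atoms ",
              "(pairwise distance <= 1e-6 Angstrom)")
  structure(
    list(conf_id = as.character(conf_id),
         atomic_numbers = atomic_numbers,
         coords = coords,
         energy = if (is.null(energy)) NULL else as.numeric(energy)),
    class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation '%s': %d atoms%s>\n", x$conf_id,
              length(x$atomic_numbers),
              if (is.null(x$energy)) ""
              else sprintf(", E = %.4f kJ/mol", x$energy)))
  invisible(x)
}

#' Create an ensemble of conformations
#'
#' All members must share the identical atomic-number sequence (same molecule,
#' same atom indexing) and have unique conformer ids.
#'
#' @param conformations List of [conformation()] objects.
#' @param run_label Optional label (e.g. the MD run the frames came from).
#' @return An object of class `"ensemble"`.
#' @export
ensemble <- function(conformations, run_label = NULL) {
  if (!is.list(conformations))
    stop_data("conformations must be a list")
  if (length(conformations) > 0L) {
    ref <- conformations[[1L]]$atomic_numbers
    for (i in seq_along(conformations)) {
      ci <- conformations[[i]]
      if (!inherits(ci, "conformation"))
        stop_data("element ", i, " is not a conformation")
      if (!identical(ci$atomic_numbers, ref))
        stop_data("ensemble must share atom ordering: frame ", i,
                  " differs from frame 1")
    }
    ids <- vapply(conformations, function(c) c$conf_id, character(1))
    if (anyDuplicated(ids))
      stop_data("duplicate conf_id in ensemble: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(conformations = conformations,
                 run_label = run_label),
            class = "ensemble")
}

#' @export
length.ensemble <- function(x) length(x$conformations)

#' @export
print.ensemble <- function(x, ...) {
  n_at <- if (length(x) > 0L) length(x$conformations[[1L]]$atomic_numbers) else 0L
  cat(sprintf("<ensemble%s: %d conformations, %d atoms>\n",
              if (is.null(x$run_label)) "" else paste0(" '", x$run_label, "'"),
              length(x), n_at))
  invisible(x)
}

#' Extract the per-conformer energies of an ensemble
#'
#' @param x An [ensemble()].
#' @return Named numeric vector (kJ/mol); `NA` for members without energy.
#' @export
ensemble_energies <- function(x) {
  vapply(x$conformations,
         function(c) if (is.null(c$energy)) NA_real_ else c$energy,
         numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(x$conformations, function(c) c$conf_id, character(1)))
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ dialect: per frame an atom-count line, a comment line, then
#' one line per atom (`symbol x y z`; symbols may also be atomic numbers).
#' A token `E=<float>` on the comment line is stored as the frame's energy
#' (kJ/mol); a token `id=<string>` is used as the conformer id, otherwise ids
#' are `frame_1`, `frame_2`, ... in file order.
#'
#' @param path Path to the XYZ file.
#' @param run_label Optional run label for the resulting ensemble.
#' @return An [ensemble()], one conformation per frame in file order.
#' @export
read_xyz <- function(path, run_label = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) > 0L && grepl("^\\s*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop_data("empty XYZ file: ", path)

  confs <- list()
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop_data("frame ", frame, ": malformed atom-count line ('",
                lines[pos], "')")
    if (pos + 1L + n > length(lines))
      stop_data("frame ", frame, ": file truncated (expected ", n, " atoms)")
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    if (any(lengths(toks) < 4L))
      stop_data("frame ", frame, ": atom line with fewer than 4 fields")
    sym <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3)))
    if (!all(is.finite(xyz)))
      stop_data("frame ", frame, ": unparseable coordinate")
    z <- element_to_z(sym)

    e <- NULL
    m <- regmatches(comment,
                    regexec("(?:^|\\s)E=([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)",
                            comment))[[1L]]
    if (length(m) == 2L) e <- as.numeric(m[2L])
    idm <- regmatches(comment, regexec("(?:^|\\s)id=(\\S+)", comment))[[1L]]
    id <- if (length(idm) == 2L) idm[2L] else paste0("frame_", frame)

    confs[[frame]] <- conformation(z, xyz, conf_id = id, energy = e)
    pos <- pos + 2L + n
  }
  ensemble(confs, run_label = run_label)
}

#' Write an ensemble as a multi-frame XYZ file
#'
#' Energies, when present, are serialized as `E=<value>` on the comment line,
#' together with `id=<conf_id>` so that [read_xyz()] round-trips ids.
#'
#' @param x An [ensemble()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_xyz <- function(x, path) {
  if (!inherits(x, "ensemble")) stop_data("x must be an ensemble")
  if (length(x) == 0L) {
    warning("writing an empty ensemble: ", path)
    cat("", file = path)
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (c in x$conformations) {
    n <- length(c$atomic_numbers)
    comment <- paste0("id=", c$conf_id,
                      if (!is.null(c$energy))
                        sprintf(" E=%.10g", c$energy) else "")
    writeLines(c(as.character(n), comment), con)
    sym <- .ELEMENTS[c$atomic_numbers]
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f",
                       sym, c$coords[, 1], c$coords[, 2], c$coords[, 3]),
               con)
  }
  invisible(path)
}

#' Read a conformer energy table
#'
#' CSV with mandatory header columns `conf_id,energy` (kJ/mol).
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector mapping conf_id to energy.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("conf_id", "energy") %in% names(df)))
    stop_data("energy table must have columns conf_id,energy: ", path)
  if (anyDuplicated(df$conf_id)) {
    dup <- unique(df$conf_id[duplicated(df$conf_id)])
    stop_data("duplicate conf_id in energy table: ",
              paste(dup, collapse = ", "))
  }
  e <- suppressWarnings(as.numeric(df$energy))
  if (anyNA(e)) {
    bad <- which(is.na(e))[1L]
    stop_data("non-numeric energy in row ", bad, " of ", path)
  }
  stats::setNames(e, df$conf_id)
}

#' Relative energies
#'
#' Shifts a vector of energies so that its minimum is exactly zero
#' (Delta E relative to the ensemble minimum).
#'
#' @param energies Non-empty numeric vector, kJ/mol.
#' @return Numeric vector of the same length with minimum 0.
#' @export
relative_energies <- function(energies) {
  if (length(energies) == 0L) stop_data("empty energy vector")
  if (!all(is.finite(energies))) stop_data("energies must be finite")
  energies - min(energies)
}
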