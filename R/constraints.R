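# ROESY/NOE distance-constraint compliance scoring.
#
# Constraints are classified upper distance bounds between proton groups:
# < 5 A (weak), < 3.5 A (medium), < 2.5 A (strong).  Proton-methyl and
# methyl-methyl correlations use the arithmetic mean over all proton-pair
# distances.  Constraints that are always or never fulfilled across an
# ensemble carry no information for ranking conformers and are filtered out.

.CONSTRAINT_BOUNDS <- c(weak = 5.0, medium = 3.5, strong = 2.5)

#' Proton group
#'
#' One proton (single index) or the three protons of a methyl group.
#'
#' @param atom_indices 1-based atom indices, length 1 or 3.
#' @return Object of class `"proton_group"`.
#' @export
proton_group <- function(atom_indices) {
  atom_indices <- as.integer(atom_indices)
  if (!length(atom_indices) %in% c(1L, 3L))
    stop_data("a proton group has 1 (proton) or 3 (methyl) atoms")
  if (any(atom_indices < 1L) || anyDuplicated(atom_indices))
    stop_data("atom indices must be positive and distinct")
  structure(list(atom_indices = atom_indices), class = "proton_group")
}

#' Classified distance constraint
#'
#' @param left,right [proton_group()]s (or bare index vectors).
#' @param strength `"weak"`, `"medium"` or `"strong"`; fixes the upper bound
#'   at 5.0, 3.5 or 2.5 Angstrom respectively.
#' @return Object of class `"distance_constraint"`.
#' @export
distance_constraint <- function(left, right,
                                strength = c("weak", "medium", "strong")) {
  strength <- match.arg(strength)
  if (!inherits(left, "proton_group")) left <- proton_group(left)
  if (!inherits(right, "proton_group")) right <- proton_group(right)
  structure(list(left = left, right = right, strength = strength,
                 bound = .CONSTRAINT_BOUNDS[[strength]]),
            class = "distance_constraint")
}

#' @export
print.distance_constraint <- function(x, ...) {
  cat(sprintf("<constraint: {%s} - {%s}, %s (< %.1f A)>\n",
              paste(x$left$atom_indices, collapse = ","),
              paste(x$right$atom_indices, collapse = ","),
              x$strength, x$bound))
  invisible(x)
}

#' Read a constraint table
#'
#' CSV with columns `left_atoms`, `right_atoms` (semicolon-joined 1-based
#' atom indices) and `strength`.
#'
#' @param path Path to the CSV file.
#' @return List of [distance_constraint()]s.
#' @export
read_constraint_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("left_atoms", "right_atoms", "strength")
  if (!all(need %in% names(df)))
    stop_data("constraint table must have columns ",
              paste(need, collapse = ","), ": ", path)
  lapply(seq_len(nrow(df)), function(i) {
    parse_idx <- function(s) as.integer(strsplit(s, ";")[[1L]])
    tryCatch(
      distance_constraint(parse_idx(df$left_atoms[i]),
                          parse_idx(df$right_atoms[i]),
                          df$strength[i]),
      error = function(e)
        stop_data("constraint table row ", i, ": ", conditionMessage(e)))
  })
}

#' Group-averaged constraint distance
#'
#' Arithmetic mean over all left-member x right-member pair distances
#' (singleton-singleton: one distance; singleton-methyl: average of 3;
#' methyl-methyl: average of 9).  The r^-6 NOE average is available as an
#' option but the default is the plain mean.
#'
#' @param conf A [conformation()].
#' @param constraint A [distance_constraint()].
#' @param r6_average If `TRUE`, use `(mean(r^-6))^(-1/6)` instead of
#'   `mean(r)`.
#' @return Distance in Angstrom.
#' @export
constraint_distance <- function(conf, constraint, r6_average = FALSE) {
  li <- constraint$left$atom_indices
  ri <- constraint$right$atom_indices
  n <- nrow(conf$coords)
  if (any(c(li, ri) > n))
    stop_data("constraint references atom beyond molecule size (", n, ")")
  if (length(intersect(li, ri)) > 0L)
    stop_data("constraint groups share atom(s): ",
              paste(intersect(li, ri), collapse = ","))
  d <- vapply(li, function(a)
    vapply(ri, function(b)
      sqrt(sum((conf$coords[a, ] - conf$coords[b, ])^2)), numeric(1)),
    numeric(length(ri)))
  if (r6_average) (mean(d^-6))^(-1 / 6) else mean(d)
}

#' Count satisfied constraints for one conformer
#'
#' A constraint is satisfied iff its group-averaged distance is *strictly*
#' below its class bound (a distance exactly at the bound fails).
#'
#' @param conf A [conformation()].
#' @param constraints List of [distance_constraint()]s.
#' @param r6_average Passed to [constraint_distance()].
#' @return List with `count` (integer) and `satisfied` (logical vector, one
#'   entry per constraint).
#' @export
satisfied_count <- function(conf, constraints, r6_average = FALSE) {
  sat <- vapply(constraints, function(c)
    constraint_distance(conf, c, r6_average) < c$bound, logical(1))
  list(count = sum(sat), satisfied = sat)
}

#' Filter for informative constraints
#'
#' Keeps constraints satisfied by at least one and violated by at least one
#' ensemble member; constraints that are always or never fulfilled across
#' the whole ensemble are dropped (they cannot rank conformers).
#'
#' @param x An [ensemble()] (non-empty).
#' @param constraints List of [distance_constraint()]s.
#' @param r6_average Passed to [constraint_distance()].
#' @return List with `kept` (constraint list), `kept_index` (positions in
#'   the input list), and `dropped` (data frame: index, reason
#'   `"always"`/`"never"`).
#' @export
informative_constraints <- function(x, constraints, r6_average = FALSE) {
  if (!inherits(x, "ensemble") || length(x) == 0L)
    stop_data("x must be a non-empty ensemble")
  if (length(constraints) == 0L)
    return(list(kept = list(), kept_index = integer(0),
                dropped = data.frame(index = integer(0),
                                     reason = character(0))))
  sat <- vapply(x$conformations, function(conf)
    satisfied_count(conf, constraints, r6_average)$satisfied,
    logical(length(constraints)))
  sat <- matrix(sat, nrow = length(constraints))  # constraints x conformers
  n_sat <- rowSums(sat)
  keep <- n_sat > 0L & n_sat < ncol(sat)
  reason <- ifelse(n_sat == ncol(sat), "always", "never")
  list(kept = constraints[keep],
       kept_index = which(keep),
       dropped = data.frame(index = which(!keep),
                            reason = reason[!keep]))
}

#' Constraint-compliance matrix for an ensemble
#'
#' @param x An [ensemble()].
#' @param constraints List of [distance_constraint()]s.
#' @param r6_average Passed to [constraint_distance()].
#' @return List with `counts` (named integer vector per conformer) and
#'   `matrix` (conformers x constraints logical matrix).
#' @export
compliance_table <- function(x, constraints, r6_average = FALSE) {
  sat <- t(vapply(x$conformations, function(conf)
    satisfied_count(conf, constraints, r6_average)$satisfied,
    logical(length(constraints))))
  rownames(sat) <- vapply(x$conformations, function(c) c$conf_id,
                          character(1))
  list(counts = rowSums(sat), matrix = sat)
}
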