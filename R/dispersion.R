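#' Becke-Johnson damped dispersion parameters
#'
#' Parameter set for the pairwise `-C6/r^6 - C8/r^8` dispersion correction
#' with rational (Becke-Johnson) damping,
#' `E = -s6*C6/(r^6 + f0^6) - s8*C8/(r^8 + f0^8)`,
#' `f0 = a1*sqrt(C8/C6) + a2`. `s6` is fixed at 1.0 as is standard for this
#' damping scheme. The default `s8`, `a1`, `a2` are the values refit for a
#' range-separated hybrid functional with a DZVP-quality basis
#' (s8 = 0.9220, a1 = 0.3419, a2 = 5.2955 bohr).
#'
#' @param s8,a1 dimensionless damping parameters.
#' @param a2 damping offset in bohr (> 0).
#' @param s6 fixed at 1.0.
#' @return object of class `dispersion_params`.
#' @export
dispersion_params <- function(s8 = 0.9220, a1 = 0.3419, a2 = 5.2955,
                              s6 = 1.0) {
  stopifnot(a2 > 0, s8 >= 0)
  structure(list(s6 = s6, s8 = s8, a1 = a1, a2 = a2),
            class = "dispersion_params")
}

#' Dispersion coefficient tables
#'
#' Per-element-pair `C6` (Ha bohr^6) and `C8` (Ha bohr^8) coefficients. The
#' TSV format is `elemA elemB C6 C8` with one row per unordered pair.
#' `builtin_coefficient_table()` loads the compact table shipped with the
#' package (H, C, N, O, S, F, Cl, Br, I, Zn), built from free-atom-scale C6
#' values with geometric-mean combination; it is reference data for testing
#' the pairwise machinery, not a substitute for a full
#' coordination-number-interpolated model.
#'
#' @param path TSV file with columns elemA, elemB, C6, C8.
#' @return a tibble with columns `elemA`, `elemB`, `C6`, `C8`, symmetrised
#'   lookup via [d3bj_pair_energy()].
#' @export
read_coefficient_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("elemA", "elemB", "C6", "C8") %in% names(tab)))
  if (any(tab$C6 <= 0) || any(tab$C8 <= 0)) {
    stop("dispersion coefficients must be positive")
  }
  tibble::as_tibble(tab)
}

#' @rdname read_coefficient_table
#' @export
builtin_coefficient_table <- function() {
  read_coefficient_table(
    system.file("extdata", "dispersion_c6c8.tsv", package = "plscore"))
}

pair_lookup <- function(table, elemA, elemB) {
  keys <- paste(pmin(table$elemA, table$elemB),
                pmax(table$elemA, table$elemB))
  want <- paste(pmin(elemA, elemB), pmax(elemA, elemB))
  idx <- match(want, keys)
  if (anyNA(idx)) {
    bad <- unique(want[is.na(idx)])
    stop("no dispersion coefficients for pair(s): ",
         paste(bad, collapse = ", "))
  }
  idx
}

#' Pairwise BJ-damped dispersion energy
#'
#' Energy of one element pair at separation `r` (bohr), in Hartree. Finite
#' at r = 0 by construction of the damping.
#'
#' @param elemA,elemB element symbols present in `table`.
#' @param r separation in bohr (vectorised).
#' @param params a [dispersion_params()].
#' @param table a coefficient table (see [read_coefficient_table()]).
#' @return energy in Hartree (vector of `length(r)`).
#' @export
d3bj_pair_energy <- function(elemA, elemB, r, params = dispersion_params(),
                             table = builtin_coefficient_table()) {
  stopifnot(all(r >= 0))
  idx <- pair_lookup(table, elemA, elemB)
  c6 <- table$C6[idx]; c8 <- table$C8[idx]
  f0 <- params$a1 * sqrt(c8 / c6) + params$a2
  -params$s6 * c6 / (r^6 + f0^6) - params$s8 * c8 / (r^8 + f0^8)
}

#' Dispersion energy of a system
#'
#' Sum of [d3bj_pair_energy()] over all pairs, or over intermolecular pairs
#' only (between `groupA` and `groupB`, two disjoint atom-index vectors).
#' Coordinates are in Angstrom; the result is converted to kcal/mol.
#'
#' @param system a `pl_system` (see [as_system()]), or any object with an
#'   atom table.
#' @param params a [dispersion_params()].
#' @param table coefficient table.
#' @param pairs `"all"` or `"intermolecular"`.
#' @param groupA,groupB atom indices for `pairs = "intermolecular"`; must be
#'   disjoint.
#' @return energy in kcal/mol (<= 0).
#' @export
dispersion_energy <- function(system, params = dispersion_params(),
                              table = builtin_coefficient_table(),
                              pairs = c("all", "intermolecular"),
                              groupA = NULL, groupB = NULL) {
  pairs <- match.arg(pairs)
  sys <- as_system(system)
  n <- length(sys$element)
  if (n < 2) return(0)
  if (pairs == "all") {
    ij <- pair_indices(n)
  } else {
    if (is.null(groupA) || is.null(groupB)) {
      stop("intermolecular mode needs groupA and groupB")
    }
    if (length(intersect(groupA, groupB)) > 0) {
      stop("groupA and groupB overlap")
    }
    ij <- cbind(rep(groupA, each = length(groupB)),
                rep(groupB, times = length(groupA)))
  }
  dx <- sys$coords[ij[, 1], , drop = FALSE] -
    sys$coords[ij[, 2], , drop = FALSE]
  r_bohr <- sqrt(rowSums(dx^2)) * pl_constants$bohr_per_angstrom
  e_ha <- d3bj_pair_energy(sys$element[ij[, 1]], sys$element[ij[, 2]],
                           r_bohr, params, table)
  sum(e_ha) * pl_constants$hartree_kcal
}

pair_indices <- function(n) {
  if (n < 2) return(matrix(integer(), 0, 2))
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq_len(n)[-1])
  cbind(i, j)
}
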