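#' Rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over paired
#' points. Returns a proper rotation (determinant +1), translation and the
#' RMSD over the pairing after the transform. At least three non-collinear
#' pairs are required.
#'
#' @param mobile,reference n x 3 coordinate matrices (or objects accepted by
#'   [coords()]).
#' @param pairing two-column integer matrix of index pairs
#'   (mobile row, reference row); default pairs rows 1:n.
#' @return list with `rotation` (3 x 3), `translation` (length-3),
#'   `rmsd` (Angstrom) and `transform(xyz)` applying the map
#'   `xyz %*% t(R) + t`.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  mobile <- as_xyz(mobile); reference <- as_xyz(reference)
  if (is.null(pairing)) {
    if (nrow(mobile) != nrow(reference)) {
      stop("mobile and reference differ in size; supply a pairing")
    }
    pairing <- cbind(seq_len(nrow(mobile)), seq_len(nrow(mobile)))
  }
  A <- mobile[pairing[, 1], , drop = FALSE]
  B <- reference[pairing[, 2], , drop = FALSE]
  n <- nrow(A)
  if (n < 3) stop("superposition needs at least 3 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (collinear(A0) || collinear(B0)) {
    stop("degenerate (collinear) point configuration")
  }
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cb - R %*% ca)
  fitted <- A %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(
    rotation = R, translation = t_vec, rmsd = rmsd,
    transform = function(xyz) {
      xyz <- as_xyz(xyz)
      xyz %*% t(R) + matrix(t_vec, nrow(xyz), 3, byrow = TRUE)
    }
  )
}

collinear <- function(X0, tol = 1e-8) {
  s <- svd(X0, nu = 0, nv = 0)$d
  s[2] < tol * max(s[1], .Machine$double.eps)
}

as_xyz <- function(x) {
  if (is.matrix(x)) return(x)
  coords(x)
}

#' Closest protein-ligand approach
#'
#' Minimum Euclidean distance between any atom of `structure` and any atom of
#' any ligand in `ligands`. Used to rank candidate receptor structures for a
#' ligand series: the receptor with the largest closest-approach distance
#' accommodates the overlaid ligands best.
#'
#' @param structure a [structure_model()] (or anything with coordinates).
#' @param ligands list of [molecule()]s (a single molecule is accepted).
#' @return minimum distance in Angstrom.
#' @export
closest_approach <- function(structure, ligands) {
  if (inherits(ligands, "molecule")) ligands <- list(ligands)
  if (length(ligands) == 0) stop("empty ligand list")
  P <- as_xyz(structure)
  if (nrow(P) == 0) stop("structure has no atoms")
  L <- do.call(rbind, lapply(ligands, as_xyz))
  if (nrow(L) == 0) stop("ligands have no atoms")
  min(cross_dist_min(P, L))
}

# row-wise minimum distances from each P atom to the L set, blocked to keep
# memory bounded on large systems
cross_dist_min <- function(P, L, block = 2048L) {
  mins <- rep(Inf, nrow(P))
  for (s in seq(1, nrow(L), by = block)) {
    e <- min(s + block - 1L, nrow(L))
    Lb <- L[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(Lb^2), `+`) - 2 * tcrossprod(P, Lb)
    mins <- pmin(mins, sqrt(pmax(apply(d2, 1, min), 0)))
  }
  mins
}

#' Choose the representative receptor for a ligand series
#'
#' Measures [closest_approach()] for each candidate receptor against the
#' union of overlaid ligands and selects the candidate with the largest
#' value (ties go to the first). Candidates whose closest approach falls
#' below `clash_threshold` are flagged as clashing in the report.
#'
#' @param structures named list of candidate [structure_model()]s.
#' @param ligands list of overlaid [molecule()]s.
#' @param clash_threshold distance (Angstrom) below which a candidate is
#'   flagged as clashing with the ligand set (default 1.0).
#' @return tibble with one row per candidate (`candidate`,
#'   `closest_approach`, `clash`, `selected`); the chosen name is in
#'   `attr(, "selected")`.
#' @export
choose_receptor <- function(structures, ligands, clash_threshold = 1.0) {
  if (length(structures) == 0) stop("no candidate structures")
  nm <- names(structures) %||% as.character(seq_along(structures))
  d <- vapply(structures, closest_approach, 0, ligands = ligands)
  out <- tibble::tibble(
    candidate = nm, closest_approach = unname(d),
    clash = unname(d) < clash_threshold,
    selected = seq_along(d) == which.max(d)
  )
  attr(out, "selected") <- nm[which.max(d)]
  out
}
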