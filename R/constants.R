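# Physical constants and element reference data used across the package.
# Units: energies kcal/mol, lengths Angstrom unless stated otherwise.

#' Unit and physical constants
#'
#' Conversion factors and constants used throughout the package: the Hartree
#' to kcal/mol factor, the Angstrom to bohr factor, the Coulomb constant in
#' kcal * Angstrom / (mol * e^2), and the molar gas constant in kcal/mol/K.
#'
#' @format A named list with elements `hartree_kcal`, `bohr_per_angstrom`,
#'   `coulomb_kcal`, `gas_constant_kcal`.
#' @export
pl_constants <- list(
  hartree_kcal      = 627.509,
  bohr_per_angstrom = 1.8897259886,
  coulomb_kcal      = 332.0636,
  gas_constant_kcal = 1.98720e-3
)

# Covalent radii (Angstrom), Cordero-like values; used for bond perception
# and cap-geometry sanity checks.
.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26,
  Ni = 1.24, Cu = 1.32, Zn = 1.22, Br = 1.20, I = 1.39, Se = 1.20
)

# Van der Waals-ish radii (Angstrom) used by the test backend's surface term
# and as Born base radii for charged atoms.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, Zn = 1.39, Na = 2.27, K = 2.75, Ca = 2.31,
  Mg = 1.73, Ne = 1.54, Se = 1.90, Fe = 1.50, Mn = 1.50, Cu = 1.40, Ni = 1.60,
  He = 1.40, Li = 1.82
)

# Formal charges assigned to single-atom HETATM ions; overridable in the
# functions that consume it.
.default_ion_charges <- c(
  ZN = 2L, CA = 2L, MG = 2L, `NA` = 1L, K = 1L, CL = -1L, MN = 2L, FE = 2L,
  CU = 2L, NI = 2L, LI = 1L, BR = -1L, I = -1L
)

# Elements recognised as metals when classifying single-atom HETATM records.
.metal_elements <- c(
  "Zn", "Ca", "Mg", "Na", "K", "Mn", "Fe", "Cu", "Ni", "Li", "Co"
)

# Residue formal charges at neutral pH for the standard amino acids plus the
# capping residues; everything not listed must be supplied by the caller.
.default_residue_charges <- c(
  ALA = 0L, ARG = 1L, ASN = 0L, ASP = -1L, CYS = 0L, GLN = 0L, GLU = -1L,
  GLY = 0L, HIS = 0L, ILE = 0L, LEU = 0L, LYS = 1L, MET = 0L, PHE = 0L,
  PRO = 0L, SER = 0L, THR = 0L, TRP = 0L, TYR = 0L, VAL = 0L,
  HIP = 1L, HID = 0L, HIE = 0L, ASH = 0L, GLH = 0L, CYM = -1L, CYX = 0L,
  LYN = 0L, NME = 0L, FOR = 0L, ACE = 0L, HOH = 0L, WAT = 0L
)

.recognized_elements <- unique(c(names(.covalent_radii), names(.vdw_radii)))

covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# Normalise element symbols to canonical capitalisation ("CL" -> "Cl").
normalize_element <- function(x) {
  x <- trimws(x)
  bad <- !nzchar(x)
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  x[bad] <- NA_character_
  x
}
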