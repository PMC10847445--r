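#' Henderson-Hasselbalch deprotonated fraction
#'
#' Fraction of the deprotonated species in solution,
#' `f = 10^(pH - pKa) / (1 + 10^(pH - pKa))`. Strictly increasing in pH,
#' 0.5 at pH = pKa, and symmetric: `f(pH) + f(2 pKa - pH) = 1`.
#'
#' @param pH,pKa finite numerics (vectorised).
#' @return fraction in `[0, 1]`.
#' @export
deprotonated_fraction <- function(pH, pKa) {
  stopifnot(all(is.finite(pH)), all(is.finite(pKa)))
  x <- 10^(pH - pKa)
  x / (1 + x)
}

#' Free energies of the species in the proton-transfer cycle
#'
#' Free energies (kcal/mol) of the ligand protonation forms (from the energy
#' backend: gas-phase energy plus solvation free energy) and of the water
#' species, whose solvation free energies come from experimental
#' compilations and must be supplied explicitly; only the fields needed for
#' the active reaction direction are required.
#'
#' @param G_L,G_LH,G_LHplus,G_Lminus ligand forms, kcal/mol.
#' @param G_H2O,G_OHminus,G_H3Oplus water species, kcal/mol.
#' @return object of class `species_free_energies`.
#' @export
species_free_energies <- function(G_L = NA_real_, G_LH = NA_real_,
                                  G_LHplus = NA_real_, G_Lminus = NA_real_,
                                  G_H2O = NA_real_, G_OHminus = NA_real_,
                                  G_H3Oplus = NA_real_) {
  structure(list(G_L = G_L, G_LH = G_LH, G_LHplus = G_LHplus,
                 G_Lminus = G_Lminus, G_H2O = G_H2O, G_OHminus = G_OHminus,
                 G_H3Oplus = G_H3Oplus),
            class = "species_free_energies")
}

#' Protonation-change bookkeeping for one complex
#'
#' Records whether the ligand changes protonation upon binding and, if so,
#' in which direction: `"uptake"` (the solution form L binds as LH+, via
#' L + H2O -> LH+ + OH-) or `"release"` (the solution form LH binds as L-,
#' via LH + H2O -> L- + H3O+). `direction = "none"` makes the
#' proton-transfer term exactly zero. The assay pH has no default: it must
#' come from the experimental metadata.
#'
#' @param direction `"none"`, `"uptake"` or `"release"`.
#' @param pKa ligand pKa of the titratable group.
#' @param pH assay pH.
#' @param species_G a [species_free_energies()].
#' @return object of class `protonation_case`.
#' @export
protonation_case <- function(direction = c("none", "uptake", "release"),
                             pKa = NA_real_, pH = NA_real_,
                             species_G = species_free_energies()) {
  direction <- match.arg(direction)
  if (direction != "none") {
    if (!is.finite(pKa)) stop("protonation change requires a finite pKa")
    if (!is.finite(pH)) {
      stop("protonation change requires the assay pH; it has no default")
    }
  }
  structure(list(direction = direction, pKa = pKa, pH = pH,
                 species_G = species_G),
            class = "protonation_case")
}

need_species <- function(species_G, fields) {
  for (f in fields) {
    if (!is.finite(species_G[[f]])) {
      stop("missing species free energy: ", f)
    }
  }
  invisible(TRUE)
}

#' Proton-transfer free-energy term
#'
#' The free-energy cost of changing the ligand protonation state upon
#' binding, weighted by the Henderson-Hasselbalch solution fraction of the
#' species that must convert. For proton uptake,
#' `dG_H+ = f * (G(LH+) - G(L) + G(OH-) - G(H2O))` with
#' `f = deprotonated_fraction(pH, pKa)`; for proton release,
#' `dG_H+ = (1 - f) * (G(L-) - G(LH) + G(H3O+) - G(H2O))`. The `(1 - f)`
#' weighting of the release branch reads the printed form by symmetry with
#' the uptake branch: both weight the reaction energy by the solution
#' fraction of the form that has to change protonation. Direction `"none"`
#' returns exactly 0.
#'
#' @param case a [protonation_case()].
#' @return kcal/mol. `|term| <= |reaction energy|` always.
#' @export
proton_transfer_term <- function(case) {
  stopifnot(inherits(case, "protonation_case"))
  if (case$direction == "none") return(0)
  f <- deprotonated_fraction(case$pH, case$pKa)
  sg <- case$species_G
  if (case$direction == "uptake") {
    need_species(sg, c("G_LHplus", "G_L", "G_OHminus", "G_H2O"))
    f * (sg$G_LHplus - sg$G_L + sg$G_OHminus - sg$G_H2O)
  } else {
    need_species(sg, c("G_Lminus", "G_LH", "G_H3Oplus", "G_H2O"))
    (1 - f) * (sg$G_Lminus - sg$G_LH + sg$G_H3Oplus - sg$G_H2O)
  }
}

#' Ligand conformational-entropy model
#'
#' The default model charges a penalty of `penalty_per_bond` kcal/mol per
#' rotatable bond (default 1.0), reported as the positive `-T dS`
#' contribution to the binding score. A descriptor-based estimator can be
#' plugged in as a function `function(ligand) -> kcal/mol`.
#'
#' @param kind `"per_rotatable_bond"` or `"plugin"`.
#' @param penalty_per_bond kcal/mol per rotatable bond (>= 0).
#' @param plugin function used when `kind = "plugin"`.
#' @return object of class `entropy_model`.
#' @export
entropy_model <- function(kind = c("per_rotatable_bond", "plugin"),
                          penalty_per_bond = 1.0, plugin = NULL) {
  kind <- match.arg(kind)
  stopifnot(penalty_per_bond >= 0)
  if (kind == "plugin" && !is.function(plugin)) {
    stop("plugin entropy model requires a function")
  }
  structure(list(kind = kind, penalty_per_bond = penalty_per_bond,
                 plugin = plugin),
            class = "entropy_model")
}

#' Ligand entropy penalty
#'
#' The `-T dS` contribution for one ligand under an [entropy_model()]:
#' `penalty_per_bond * count_rotatable_bonds(ligand)` for the default model,
#' or the plugin's value. Monotone non-decreasing in the rotatable-bond
#' count.
#'
#' @param ligand a [molecule()] with bonds.
#' @param model an [entropy_model()].
#' @return kcal/mol (reported positive for binding).
#' @export
entropy_penalty <- function(ligand, model = entropy_model()) {
  stopifnot(inherits(model, "entropy_model"))
  if (model$kind == "plugin") {
    val <- tryCatch(model$plugin(ligand), error = function(e) {
      stop("entropy plugin failed: ", conditionMessage(e))
    })
    if (!is.finite(val)) stop("entropy plugin returned a non-finite value")
    return(val)
  }
  model$penalty_per_bond * count_rotatable_bonds(ligand)
}
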