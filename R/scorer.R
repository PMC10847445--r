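#' A scoring record for one protein-ligand complex
#'
#' Couples a pocket model with the ligand conformers observed or modeled in
#' it, the ligand net charge, the protonation-change bookkeeping and the
#' assay pH. All conformers must share the same atom composition; when the
#' ligand protonation changes upon binding, the conformers carry the
#' bound-form variant (the form seen in the complex), which is the form used
#' for the interaction, desolvation and strain terms.
#'
#' @param id complex identifier.
#' @param pocket a `pocket_model` (or anything [as_system()] accepts).
#' @param ligand_conformers list of [molecule()]s (>= 1).
#' @param ligand_net_charge integer; defaults to the first conformer's.
#' @param protonation a [protonation_case()].
#' @param assay_pH assay pH (carried to the benchmark stage).
#' @param provenance `"crystal"` or `"modeled"`.
#' @return object of class `complex_record`.
#' @export
complex_record <- function(id, pocket, ligand_conformers,
                           ligand_net_charge = NULL,
                           protonation = protonation_case("none"),
                           assay_pH = NA_real_,
                           provenance = c("crystal", "modeled")) {
  provenance <- match.arg(provenance)
  if (inherits(ligand_conformers, "molecule")) {
    ligand_conformers <- list(ligand_conformers)
  }
  stopifnot(length(ligand_conformers) >= 1)
  comp <- lapply(ligand_conformers, function(m) sort(m$atoms$element))
  if (!all(vapply(comp, identical, TRUE, comp[[1]]))) {
    stop("conformers differ in atom composition")
  }
  structure(
    list(id = id, pocket = pocket, ligand_conformers = ligand_conformers,
         ligand_net_charge = as.integer(
           ligand_net_charge %||% ligand_conformers[[1]]$net_charge),
         protonation = protonation, assay_pH = assay_pH,
         provenance = provenance),
    class = "complex_record"
  )
}

#' Select the most stable ligand conformer
#'
#' Evaluates the total (gas + solvation) energy of the pocket-ligand complex
#' for each conformer and returns the index of the lowest; ties go to the
#' first occurrence in input order. A single conformer returns 1 without any
#' backend call.
#'
#' @param backend an `energy_backend`.
#' @param record a [complex_record()].
#' @return integer conformer index (1-based).
#' @export
select_conformer <- function(backend, record) {
  stopifnot(inherits(record, "complex_record"))
  k <- length(record$ligand_conformers)
  if (k == 1) return(1L)
  pocket_sys <- as_system(record$pocket)
  e <- vapply(seq_len(k), function(i) {
    lig <- as_system(record$ligand_conformers[[i]],
                     net_charge = record$ligand_net_charge)
    res <- tryCatch(
      backend$evaluate(combine_systems(pocket_sys, lig), solvated = TRUE),
      error = function(e) stop("backend failed on conformer ", i, ": ",
                               conditionMessage(e)))
    res$e_gas + res$g_solv
  }, 0)
  which.min(e)
}

#' Score one protein-ligand complex
#'
#' Assembles the five-term end-point binding score
#' `total = dE_int + ddG_solv + dG_conf + dG_Hplus + TdS_penalty`:
#' the gas-phase interaction energy, the desolvation penalty, the ligand
#' strain (relaxing the free ligand in solvent from its bound pose), the
#' Henderson-Hasselbalch-weighted proton-transfer correction and the
#' rotatable-bond entropy penalty. More negative totals mean better
#' predicted binding. The stored total is the bitwise sum of the stored
#' components. Any component failure aborts the complex with an error naming
#' the term: partial results are never emitted.
#'
#' @param backend an `energy_backend`.
#' @param record a [complex_record()].
#' @param entropy an [entropy_model()].
#' @param relax_tol,relax_max_steps forwarded to the strain relaxation.
#' @return object of class `score_components` (also a one-row list), fields
#'   `de_int`, `ddg_solv`, `dg_conf`, `dg_hplus`, `tds_penalty`, `total`,
#'   `chosen_conformer`.
#' @export
score_complex <- function(backend, record, entropy = entropy_model(),
                          relax_tol = 0.1, relax_max_steps = 2000) {
  stopifnot(inherits(record, "complex_record"))
  term <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("scoring %s failed in term %s: %s", record$id, name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ci <- term("conformer_selection", select_conformer(backend, record))
  lig_mol <- record$ligand_conformers[[ci]]
  lig <- as_system(lig_mol, net_charge = record$ligand_net_charge)
  pocket_sys <- as_system(record$pocket)
  cplx <- combine_systems(pocket_sys, lig)

  de_int <- term("dE_int",
                 interaction_energy(backend, cplx, pocket_sys, lig))
  ddg_solv <- term("ddG_solv",
                   desolvation_penalty(backend, cplx, pocket_sys, lig))
  dg_conf <- term("dG_conf", as.numeric(
    ligand_strain(backend, lig, tol = relax_tol,
                  max_steps = relax_max_steps)))
  dg_hplus <- term("dG_Hplus", proton_transfer_term(record$protonation))
  tds <- term("TdS_penalty", entropy_penalty(lig_mol, entropy))

  structure(
    list(de_int = de_int, ddg_solv = ddg_solv, dg_conf = dg_conf,
         dg_hplus = dg_hplus, tds_penalty = tds,
         total = de_int + ddg_solv + dg_conf + dg_hplus + tds,
         chosen_conformer = as.integer(ci)),
    class = "score_components"
  )
}

#' @export
print.score_components <- function(x, ...) {
  cat(sprintf(paste0(
    "<score_components> total %.3f kcal/mol\n",
    "  dE_int %.3f | ddG_solv %.3f | dG_conf %.3f | dG_H+ %.3f | TdS %.3f",
    " (conformer %d)\n"),
    x$total, x$de_int, x$ddg_solv, x$dg_conf, x$dg_hplus, x$tds_penalty,
    x$chosen_conformer))
  invisible(x)
}

#' Score a series of complexes
#'
#' Batch driver over [score_complex()]. Returns one row per record in input
#' order; failures are recorded per row (status column) without aborting the
#' batch. With `cache = TRUE` the backend is wrapped in [cached_backend()],
#' so re-running the same series costs no backend evaluations.
#'
#' @param backend an `energy_backend`.
#' @param records list of [complex_record()]s (non-empty).
#' @param entropy an [entropy_model()].
#' @param cache memoise backend evaluations.
#' @param ... forwarded to [score_complex()].
#' @return tibble with columns `id`, the five components, `total`,
#'   `conformer`, `status` (`"ok"` or the error message) and `wall_time`
#'   (seconds); attribute `n_failed`.
#' @export
score_series <- function(backend, records, entropy = entropy_model(),
                         cache = FALSE, ...) {
  if (length(records) == 0) stop("empty record list")
  if (cache) backend <- cached_backend(backend)
  rows <- purrr::map(records, function(rec) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(score_complex(backend, rec, entropy, ...),
                    error = function(e) conditionMessage(e))
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "score_components")) {
      tibble::tibble(id = rec$id, de_int = out$de_int,
                     ddg_solv = out$ddg_solv, dg_conf = out$dg_conf,
                     dg_hplus = out$dg_hplus, tds_penalty = out$tds_penalty,
                     total = out$total, conformer = out$chosen_conformer,
                     status = "ok", wall_time = dt)
    } else {
      tibble::tibble(id = rec$id, de_int = NA_real_, ddg_solv = NA_real_,
                     dg_conf = NA_real_, dg_hplus = NA_real_,
                     tds_penalty = NA_real_, total = NA_real_,
                     conformer = NA_integer_, status = out, wall_time = dt)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- sum(out$status != "ok")
  out
}
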