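#' Convert an experimental affinity to a binding free energy
#'
#' `dG = R T ln(Ki_eff / 1 M)` with `R = 1.98720e-3` kcal/mol/K and
#' `T = 298.15` K by default. `Ki_eff` is the value itself for Kd and Ki
#' (treated as equivalent under competitive inhibition) and `value / 2` for
#' IC50, under the assumption that the substrate concentration in the assay
#' is close to the Michaelis-Menten constant; this halving is linear, so it
#' rescales free energies without affecting correlations.
#'
#' @param value affinity in mol/L (> 0, vectorised).
#' @param kind `"Kd"`, `"Ki"` or `"IC50"` (vectorised).
#' @param T temperature in K (default 298.15).
#' @return kcal/mol (negative for sub-molar affinities).
#' @export
affinity_to_dg <- function(value, kind = "Ki", T = 298.15) {
  kind <- match.arg(rep(kind, length.out = length(value)),
                    c("Kd", "Ki", "IC50"), several.ok = TRUE)
  if (any(!is.finite(value) | value <= 0)) {
    stop("affinity values must be positive and finite")
  }
  ki_eff <- ifelse(kind == "IC50", value / 2, value)
  pl_constants$gas_constant_kcal * T * log(ki_eff)
}

#' @rdname affinity_to_dg
#' @param dG binding free energy, kcal/mol.
#' @return `dg_to_affinity()`: the Ki (mol/L) whose conversion gives `dG`
#'   (the IC50 consistent with it is twice that).
#' @export
dg_to_affinity <- function(dG, kind = "Ki", T = 298.15) {
  ki <- exp(dG / (pl_constants$gas_constant_kcal * T))
  ifelse(kind == "IC50", 2 * ki, ki)
}

#' Squared Pearson correlation
#'
#' The square of the sample Pearson correlation between two vectors.
#' Requires n >= 3 and non-zero variance on both sides; invariant under
#' affine maps of either argument (and sign-blind, being squared).
#'
#' @param x,y equal-length numeric vectors.
#' @return value in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("pearson_r2 needs at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  stats::cor(x, y)^2
}

#' Per-target manifest summary
#'
#' Summarises a per-ligand manifest (one row per complex with columns
#' `target`, `ligand`, `affinity_kind`, `affinity_value`, `crystal`) into
#' one row per target with the ligand count, crystal count and pKi range
#' (`pKi = -log10(Ki_eff)`, IC50 halved as in [affinity_to_dg()]).
#'
#' @param manifest per-ligand tibble.
#' @return tibble with columns `target`, `ligands`, `crystals`, `pki_range`.
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(all(c("target", "affinity_kind", "affinity_value", "crystal")
                %in% names(manifest)))
  manifest |>
    dplyr::mutate(pki = -log10(
      ifelse(.data$affinity_kind == "IC50", .data$affinity_value / 2,
             .data$affinity_value))) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      ligands = dplyr::n(),
      crystals = sum(.data$crystal),
      pki_range = max(.data$pki) - min(.data$pki),
      .groups = "drop"
    )
}

#' Dataset inclusion filters
#'
#' Keeps targets whose pKi range exceeds `min_range` and whose ligand count
#' is at least `min_ligands`; excluded targets are reported, with reasons,
#' in `attr(, "exclusions")`.
#'
#' @param series per-target summary tibble (columns `target`, `ligands`,
#'   `pki_range`; see [summarize_manifest()]).
#' @param min_range minimum pKi range, exclusive (default 1.5).
#' @param min_ligands minimum ligand count, inclusive (default 10).
#' @return the included rows, with attribute `exclusions` (tibble of
#'   `target`, `reason`).
#' @export
apply_inclusion_filters <- function(series, min_range = 1.5,
                                    min_ligands = 10) {
  stopifnot(all(c("target", "ligands", "pki_range") %in% names(series)))
  reason <- dplyr::case_when(
    series$pki_range <= min_range & series$ligands < min_ligands ~
      "pKi range; ligand count",
    series$pki_range <= min_range ~ "pKi range",
    series$ligands < min_ligands ~ "ligand count",
    TRUE ~ NA_character_
  )
  out <- series[is.na(reason), , drop = FALSE]
  attr(out, "exclusions") <- tibble::tibble(
    target = series$target[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  out
}

#' Manifest statistics
#'
#' Totals over a per-target summary: complexes, crystal structures, modeled
#' structures (total minus crystals) and target count.
#'
#' @param series per-target summary tibble (see [summarize_manifest()]).
#' @return one-row tibble: `total`, `crystals`, `modeled`, `targets`.
#' @export
manifest_stats <- function(series) {
  if (nrow(series) == 0) {
    return(tibble::tibble(total = 0L, crystals = 0L, modeled = 0L,
                          targets = 0L))
  }
  stopifnot(all(c("ligands", "crystals") %in% names(series)))
  tibble::tibble(
    total = as.integer(sum(series$ligands)),
    crystals = as.integer(sum(series$crystals)),
    modeled = as.integer(sum(series$ligands) - sum(series$crystals)),
    targets = nrow(series)
  )
}

#' Benchmark composition of the public ten-target refined-experiment set
#'
#' Per-target composition of the publicly deposited PL-REX benchmark (ten
#' diverse protein targets with consistent affinities and refined
#' geometries): ligand counts, crystal-structure counts and experimental pKi
#' ranges, as published with the dataset. Useful for manifest arithmetic and
#' as a realistic envelope for synthetic fixtures.
#'
#' @return tibble with columns `target`, `protein`, `ligands`, `crystals`,
#'   `pki_range`.
#' @export
plrex_summary <- function() {
  tibble::tibble(
    target = c("01-CA2", "02-HIV-PR", "03-CK2", "04-AR", "05-Cath-D",
               "06-BACE1", "07-JAK1", "08-Trypsin", "09-CDK2", "10-MMP12"),
    protein = c("carbonic anhydrase II", "HIV-1 protease", "casein kinase 2",
                "aldose reductase", "cathepsin D", "beta-secretase 1",
                "Janus kinase 1", "trypsin", "cyclin-dependent kinase 2",
                "matrix metallopeptidase 12"),
    ligands = c(10L, 22L, 16L, 14L, 10L, 16L, 12L, 15L, 31L, 18L),
    crystals = c(10L, 12L, 16L, 14L, 3L, 16L, 12L, 15L, 31L, 18L),
    pki_range = c(2.2, 5.1, 1.9, 2.8, 3.5, 3.6, 3.4, 4.4, 3.6, 3.9)
  )
}

#' Evaluate scores against experimental affinities
#'
#' Joins a score table (from [score_series()]) to a per-ligand manifest,
#' converts affinities to binding free energies and computes the per-target
#' squared Pearson correlation between score totals and experimental dG,
#' plus unweighted aggregate statistics over targets (mean, population SD,
#' minimum and the worst target). Targets with fewer than 3 scored ligands
#' are excluded with a warning; a scored ligand with no affinity is an
#' error.
#'
#' @param scores tibble with columns `id`, `total`, `status`.
#' @param manifest per-ligand tibble with columns `target`, `ligand` (the
#'   score id), `affinity_kind`, `affinity_value`, `crystal`.
#' @param T temperature for the affinity conversion, K.
#' @return object of class `benchmark_report` with elements `per_target`
#'   (tibble `target`, `n`, `r2`), `aggregate` (list `mean_r2`, `sd_r2`,
#'   `min_r2`, `worst_target`, `n_targets`) and `stats` (from
#'   [manifest_stats()]).
#' @export
evaluate_benchmark <- function(scores, manifest, T = 298.15) {
  stopifnot(all(c("id", "total") %in% names(scores)))
  ok <- if ("status" %in% names(scores)) scores$status == "ok" else
    !is.na(scores$total)
  scored <- scores[ok, c("id", "total")]
  missing <- setdiff(scored$id, manifest$ligand)
  if (length(missing) > 0) {
    stop("scored ligand(s) with no affinity record: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  joined <- dplyr::inner_join(scored, manifest,
                              by = c(id = "ligand")) |>
    dplyr::mutate(dg_exp = affinity_to_dg(.data$affinity_value,
                                          .data$affinity_kind, T = T))
  per_target <- joined |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(n = dplyr::n(),
                     r2 = if (dplyr::n() >= 3) pearson_r2(.data$total,
                                                          .data$dg_exp)
                     else NA_real_,
                     .groups = "drop")
  small <- per_target$target[is.na(per_target$r2)]
  if (length(small) > 0) {
    warning("excluding undersized target(s): ", paste(small, collapse = ", "))
    per_target <- per_target[!is.na(per_target$r2), ]
  }
  if (nrow(per_target) == 0) stop("no target with at least 3 scored ligands")
  agg <- list(
    mean_r2 = mean(per_target$r2),
    sd_r2 = sqrt(mean((per_target$r2 - mean(per_target$r2))^2)),
    min_r2 = min(per_target$r2),
    worst_target = per_target$target[which.min(per_target$r2)],
    n_targets = nrow(per_target)
  )
  structure(
    list(per_target = per_target, aggregate = agg,
         stats = manifest_stats(summarize_manifest(manifest))),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(
    "<benchmark_report> %d target(s): mean R2 = %.3f +/- %.3f, min = %.3f (%s)\n",
    x$aggregate$n_targets, x$aggregate$mean_r2, x$aggregate$sd_r2,
    x$aggregate$min_r2, x$aggregate$worst_target))
  print(x$per_target, n = Inf)
  invisible(x)
}

#' Read / write scoring manifests
#'
#' Manifests are per-ligand tables (`target`, `ligand`, `affinity_kind`,
#' `affinity_value`, `assay_pH`, `crystal`, optionally `pKa`, `direction`)
#' serialised as YAML or JSON by file extension.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a tibble.
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path) else
    if (ext == "json") jsonlite::fromJSON(path, simplifyDataFrame = TRUE) else
      stop("unknown manifest format: ", ext)
  tibble::as_tibble(rows)
}

#' @rdname read_manifest
#' @param manifest a per-ligand tibble.
#' @export
write_manifest <- function(manifest, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(as.list(manifest), path)
  } else if (ext == "json") {
    jsonlite::write_json(manifest, path, dataframe = "columns", digits = NA)
  } else stop("unknown manifest format: ", ext)
  invisible(path)
}
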