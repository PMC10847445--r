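#' Tidy a benchmark report
#'
#' @param x a `benchmark_report` from [evaluate_benchmark()].
#' @param ... unused.
#' @return tibble with one row per target: `target`, `n`, `r2`.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) {
  x$per_target
}

#' One-row summary of a benchmark report
#'
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return one-row tibble: `n_targets`, `mean_r2`, `sd_r2`, `min_r2`,
#'   `worst_target`, `total`, `crystals`, `modeled`.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(
    n_targets = x$aggregate$n_targets,
    mean_r2 = x$aggregate$mean_r2, sd_r2 = x$aggregate$sd_r2,
    min_r2 = x$aggregate$min_r2, worst_target = x$aggregate$worst_target,
    total = x$stats$total, crystals = x$stats$crystals,
    modeled = x$stats$modeled
  )
}

#' Tidy score components
#'
#' @param x a `score_components` from [score_complex()].
#' @param ... unused.
#' @return long tibble with columns `term`, `kcal_mol`.
#' @method tidy score_components
#' @export
tidy.score_components <- function(x, ...) {
  tibble::tibble(
    term = c("dE_int", "ddG_solv", "dG_conf", "dG_Hplus", "TdS_penalty",
             "total"),
    kcal_mol = c(x$de_int, x$ddg_solv, x$dg_conf, x$dg_hplus,
                 x$tds_penalty, x$total)
  )
}

#' Plot per-target benchmark correlations
#'
#' Bar chart of the per-target squared Pearson correlations with the
#' aggregate mean as a dashed reference line.
#'
#' @param object a `benchmark_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  dat <- object$per_target
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$target, y = .data$r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$aggregate$mean_r2,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  title = "Per-target score vs experiment correlation",
                  subtitle = sprintf("mean %.2f +/- %.2f, min %.2f",
                                     object$aggregate$mean_r2,
                                     object$aggregate$sd_r2,
                                     object$aggregate$min_r2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot scores against experimental binding free energies
#'
#' Scatter of score totals versus experimental dG per target, with
#' per-target least-squares lines; the expected relation is positive
#' (more negative scores for tighter binders).
#'
#' @param scores a [score_series()] table.
#' @param manifest per-ligand manifest (see [evaluate_benchmark()]).
#' @param T temperature (K) for the affinity conversion.
#' @return a ggplot object.
#' @export
plot_score_correlation <- function(scores, manifest, T = 298.15) {
  ok <- if ("status" %in% names(scores)) scores$status == "ok" else
    rep(TRUE, nrow(scores))
  dat <- dplyr::inner_join(scores[ok, c("id", "total")], manifest,
                           by = c(id = "ligand")) |>
    dplyr::mutate(dg_exp = affinity_to_dg(.data$affinity_value,
                                          .data$affinity_kind, T = T))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dg_exp, y = .data$total)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "firebrick") +
    ggplot2::facet_wrap(~target, scales = "free") +
    ggplot2::labs(x = "experimental dG (kcal/mol)",
                  y = "score (kcal/mol)") +
    ggplot2::theme_minimal()
}
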