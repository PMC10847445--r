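#' Render input for an external semiempirical engine
#'
#' Produces a MOPAC-style input document: a keyword line carrying the method
#' token, `1SCF` for single-point evaluations, `CHARGE=n`, the `MOZYME`
#' linear-scaling keyword when the atom count exceeds `mozyme_threshold`,
#' and an `EPS=<dielectric>` solvent token when a solvated evaluation is
#' requested; then a comment line and a Cartesian block
#' `element x y z flag flag flag` with per-atom optimization flags (1 free,
#' 0 frozen). Rendering is bit-stable: identical system and settings yield
#' identical text.
#'
#' @param system a `pl_system` (net charge must be known).
#' @param method method keyword (default `"PM6-D3H4X"`).
#' @param solvated include the solvent token.
#' @param dielectric solvent relative permittivity (default 78.4).
#' @param single_point emit `1SCF` (default TRUE; otherwise a geometry
#'   optimization input).
#' @param frozen_mask logical per-atom mask; frozen atoms get flag 0.
#' @param mozyme_threshold atom count above which `MOZYME` is added
#'   (default 300).
#' @param comment comment line text.
#' @return character vector of input lines.
#' @export
render_engine_input <- function(system, method = "PM6-D3H4X",
                                solvated = FALSE, dielectric = 78.4,
                                single_point = TRUE, frozen_mask = NULL,
                                mozyme_threshold = 300, comment = "") {
  system <- as_system(system)
  n <- length(system$element)
  if (!all(system$element %in% .recognized_elements)) {
    stop("unknown element in system")
  }
  kw <- c(method,
          if (single_point) "1SCF",
          sprintf("CHARGE=%d", system$net_charge),
          if (n > mozyme_threshold) "MOZYME",
          if (solvated) sprintf("EPS=%.1f", dielectric))
  frozen <- frozen_mask %||% rep(FALSE, n)
  flag <- ifelse(frozen, 0L, 1L)
  c(paste(kw, collapse = " "),
    comment,
    "",
    sprintf("%-2s %14.8f %d %14.8f %d %14.8f %d",
            system$element, system$coords[, 1], flag,
            system$coords[, 2], flag, system$coords[, 3], flag))
}

#' Parse an external-engine output log
#'
#' Extracts the final heat of formation (kcal/mol) and, when present, the
#' solvation free energy from an engine log, and sets the convergence flag
#' from the normal-termination marker. A log carrying an error marker yields
#' a non-converged [energy_result()] whose `meta` holds the message; a log
#' with no energy line at all is an error.
#'
#' @param text engine log (string, lines, or path).
#' @return an [energy_result()].
#' @export
parse_engine_output <- function(text) {
  lines <- as_lines(text)
  err <- grep("ERROR|CALCULATION (IS TERMINATED|ABANDONED)", lines,
              value = TRUE)
  hof_line <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  num_re <- "-?[0-9]+\\.?[0-9]*"
  if (length(hof_line) == 0) {
    if (length(err) > 0) {
      return(energy_result(NA_real_, converged = FALSE,
                           meta = paste(err, collapse = "; ")))
    }
    stop("engine log lacks a FINAL HEAT OF FORMATION line (truncated log?)")
  }
  m <- regmatches(hof_line[1],
                  regexpr(paste0(num_re, "(?= KCAL)"), hof_line[1],
                          perl = TRUE))
  if (length(m) == 0) stop("cannot parse heat of formation value")
  e_gas <- as.numeric(m)

  g_solv <- NA_real_
  solv_line <- grep("FREE ENERGY OF SOLVATION|SOLVATION FREE ENERGY",
                    lines, value = TRUE)
  if (length(solv_line) > 0) {
    ms <- regmatches(solv_line[1], regexpr(num_re, solv_line[1]))
    if (length(ms) == 1) g_solv <- as.numeric(ms)
  }
  done <- any(grepl("== MOPAC DONE ==|NORMAL TERMINATION", lines))
  converged <- done && length(err) == 0
  energy_result(e_gas, g_solv, converged = converged,
                meta = if (length(err) > 0) paste(err, collapse = "; ") else
                  "parsed engine log")
}
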