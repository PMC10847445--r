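#' Synthetic-fixture configuration
#'
#' Settings for the deterministic generators that make the whole pipeline
#' testable without any external data: a toy helical pocket with ionizable
#' residues, structural waters and an optional divalent cation, and ligand
#' series whose "experimental" affinities follow a known linear relation
#' (plus Gaussian noise) to the test-backend score. Ranges default to the
#' envelope of the public benchmark the package targets: rotatable bonds 0
#' to 25 and ligand formal charges -1 to +2.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (seed, config).
#' @param n_residues pocket length (>= 4).
#' @param n_asp,n_lys numbers of charged (Asp -1 / Lys +1) residues planted.
#' @param with_zinc place a Zn2+ ion.
#' @param n_waters structural waters (1-10 in realistic use).
#' @param n_ligands ligands per target series.
#' @param n_targets targets in a benchmark fixture.
#' @param rotbond_range inclusive range of rotatable-bond counts.
#' @param charge_range inclusive range of ligand formal charges.
#' @param target_rho2 planted squared correlation between score and
#'   generated dG; used to derive the noise SD when `noise_sd` is `NULL`.
#' @param noise_sd Gaussian noise on the generated dG, kcal/mol
#'   (overrides `target_rho2`).
#' @param signal_slope,signal_intercept linear map from score to dG
#'   (kcal/mol per kcal/mol, kcal/mol). The default slope compresses the toy
#'   score spread into a realistic affinity window (pKi ranges of a few log
#'   units, as in experimental series); correlations are invariant to this
#'   scale.
#' @param conformer_fraction fraction of records given a second, jittered
#'   ligand conformer.
#' @param protonation_fraction fraction of records given a planted
#'   protonation change (with declared, non-physical species free energies).
#' @return list of class `fixture_config`; element `planted_pocket_charge`
#'   is the net charge the pocket is built to have.
#' @export
fixture_config <- function(seed = 1L, n_residues = 12L, n_asp = 1L,
                           n_lys = 1L, with_zinc = TRUE, n_waters = 3L,
                           n_ligands = 500L, n_targets = 10L,
                           rotbond_range = c(0L, 25L),
                           charge_range = c(-1L, 2L),
                           target_rho2 = 0.69, noise_sd = NULL,
                           signal_slope = 0.02, signal_intercept = -8.0,
                           conformer_fraction = 0.1,
                           protonation_fraction = 0.12) {
  if (n_residues < 4) stop("toy pocket needs at least 4 residues")
  stopifnot(rotbond_range[1] >= 0, rotbond_range[2] <= 25,
            charge_range[1] >= -1, charge_range[2] <= 2)
  structure(
    list(seed = as.integer(seed), n_residues = as.integer(n_residues),
         n_asp = n_asp, n_lys = n_lys, with_zinc = with_zinc,
         n_waters = n_waters, n_ligands = as.integer(n_ligands),
         n_targets = as.integer(n_targets),
         rotbond_range = as.integer(rotbond_range),
         charge_range = as.integer(charge_range),
         target_rho2 = target_rho2, noise_sd = noise_sd,
         signal_slope = signal_slope, signal_intercept = signal_intercept,
         conformer_fraction = conformer_fraction,
         protonation_fraction = protonation_fraction,
         planted_pocket_charge = as.integer(n_lys - n_asp +
                                              2 * as.integer(with_zinc))),
    class = "fixture_config"
  )
}

# run code under a fixed, named RNG without touching the caller's stream
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

helix_point <- function(t, radius = 2.3, omega = 100 * pi / 180,
                        rise = 1.5) {
  cbind(radius * cos(omega * t), radius * sin(omega * t), rise * t)
}

radial_unit <- function(t, omega = 100 * pi / 180) {
  cbind(cos(omega * t), sin(omega * t), 0)
}

#' Generate a toy pocket structure
#'
#' A small polypeptide on an ideal helical backbone (N/CA/C/O plus CB and a
#' charged side-chain atom where planted), with `n_asp` aspartates, `n_lys`
#' lysines, `n_waters` structural waters on the solvent side and optionally
#' a Zn2+ ion on the helix axis. The net formal charge equals
#' `config$planted_pocket_charge` exactly, and the output is bit-identical
#' across runs for the same (seed, config).
#'
#' @param config a [fixture_config()].
#' @return a [structure_model()].
#' @export
make_toy_pocket <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_fixture_seed(config$seed, {
    n <- config$n_residues
    # charged residues at deterministic but seed-shuffled interior positions
    interior <- sample(2:(n - 1))
    asp_at <- utils::head(interior, config$n_asp)
    lys_at <- utils::head(setdiff(interior, asp_at), config$n_lys)

    rows <- list()
    serial <- 1L
    for (i in seq_len(n)) {
      resname <- if (i %in% asp_at) "ASP" else if (i %in% lys_at) "LYS"
        else "ALA"
      tN <- i - 0.31; tCA <- i; tC <- i + 0.31
      pN <- helix_point(tN); pCA <- helix_point(tCA); pC <- helix_point(tC)
      pO <- pC + 1.23 * radial_unit(tC)
      pCB <- pCA + 1.53 * radial_unit(tCA)
      res <- list(
        c("N", "N", pN), c("CA", "C", pCA), c("C", "C", pC), c("O", "O", pO),
        c("CB", "C", pCB)
      )
      fc <- c(0L, 0L, 0L, 0L, 0L)
      if (resname == "ASP") {
        res <- c(res, list(c("OD1", "O", pCA + 2.9 * radial_unit(tCA))))
        fc <- c(fc, -1L)
      } else if (resname == "LYS") {
        res <- c(res, list(c("NZ", "N", pCA + 3.9 * radial_unit(tCA))))
        fc <- c(fc, 1L)
      }
      for (k in seq_along(res)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          serial = serial, name = res[[k]][1], element = res[[k]][2],
          x = as.numeric(res[[k]][3]), y = as.numeric(res[[k]][4]),
          z = as.numeric(res[[k]][5]),
          formal_charge = fc[k], partial_charge = NA_real_,
          chain = "A", resname = resname, resnum = i, icode = "",
          altloc = "", is_hetero = FALSE)
        serial <- serial + 1L
      }
    }
    atoms <- dplyr::bind_rows(rows)

    zmid <- 1.5 * (n + 1) / 2
    if (config$with_zinc) {
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        serial = serial, name = "ZN", element = "Zn",
        x = 0, y = 0, z = zmid, formal_charge = 2L, partial_charge = NA_real_,
        chain = "A", resname = "ZN", resnum = 900L, icode = "", altloc = "",
        is_hetero = TRUE))
      serial <- serial + 1L
    }
    if (config$n_waters > 0) {
      ang <- stats::runif(config$n_waters, 0, 2 * pi)
      zw <- stats::runif(config$n_waters, 0, 1.5 * n)
      rw <- 2.3 + 4.0
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        serial = serial + seq_len(config$n_waters) - 1L, name = "O",
        element = "O", x = rw * cos(ang), y = rw * sin(ang), z = zw,
        formal_charge = 0L, partial_charge = NA_real_, chain = "A",
        resname = "HOH", resnum = 1000L + seq_len(config$n_waters),
        icode = "", altloc = "", is_hetero = TRUE))
    }
    structure_model(atoms, title = sprintf("toy pocket (seed %d)",
                                           config$seed))
  })
}

# zigzag heavy-atom chain with n_rot + 3 atoms; charge planted by mutating
# terminal elements so the rotatable-bond count is unaffected
make_toy_ligand <- function(n_rot, charge, center, id = "LIG") {
  n_heavy <- n_rot + 3L
  bond <- 1.53; ang <- 111 * pi / 180
  xyz <- cbind(seq_len(n_heavy) * bond * sin(ang / 2),
               rep(c(0, bond * cos(ang / 2)), length.out = n_heavy), 0)
  # random rigid orientation + placement
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- quat_to_rot(q)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, center, `+`)
  xyz <- xyz + matrix(stats::rnorm(3 * n_heavy, sd = 0.05), ncol = 3)

  element <- rep("C", n_heavy)
  fc <- rep(0L, n_heavy)
  if (charge >= 1) { element[1] <- "N"; fc[1] <- 1L }
  if (charge == 2) { element[n_heavy] <- "N"; fc[n_heavy] <- 1L }
  if (charge == -1) { element[1] <- "O"; fc[1] <- -1L }

  atoms <- tibble::tibble(
    serial = seq_len(n_heavy),
    name = paste0(element, seq_len(n_heavy)), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    formal_charge = fc, partial_charge = NA_real_,
    chain = "A", resname = "LIG", resnum = 1L, icode = "", altloc = "",
    is_hetero = TRUE)
  bonds <- tibble::tibble(i = seq_len(n_heavy - 1L), j = seq_len(n_heavy - 1L) + 1L,
                          order = "1", in_ring = FALSE)
  molecule(atoms, bonds, net_charge = charge, title = id)
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate one toy target series with planted affinities
#'
#' Builds the toy pocket, places `n_ligands` ligand poses on its solvent
#' face (rotatable-bond counts and formal charges drawn from the configured
#' ranges), scores every complex with the test backend, and generates
#' "experimental" dG as `signal_slope * score + signal_intercept +
#' Normal(0, noise_sd)`; affinities are back-converted through the inverse
#' of [affinity_to_dg()] with kinds drawn from {Kd, Ki, IC50}. A configured
#' fraction of records gets a second conformer, a planted protonation change
#' (with declared placeholder species energies) and a modeled-not-crystal
#' flag. When `noise_sd` is `NULL` it is derived from `target_rho2` and the
#' realised score spread, so the analytic expectation of the per-target R2
#' is `var(signal) / (var(signal) + noise_sd^2)`.
#'
#' @param config a [fixture_config()].
#' @param target name used in the manifest (default `"T1"`).
#' @param backend an `energy_backend` (default the test backend).
#' @return list with `records` (list of [complex_record()]s), `manifest`
#'   (per-ligand tibble), `scores` (the [score_series()] table computed
#'   during generation), `pocket`, and `planted` (slope, intercept,
#'   noise_sd, rho2 = analytic expectation from the realised scores).
#' @export
make_toy_series <- function(config = fixture_config(), target = "T1",
                            backend = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  backend <- backend %||% make_test_backend()
  pocket_struct <- make_toy_pocket(config)

  with_fixture_seed(config$seed + 7L, {
    n <- config$n_ligands
    zmid <- 1.5 * (config$n_residues + 1) / 2
    site <- c(2.3 + 7.5, 0, zmid)

    P <- coords(pocket_struct$atoms)
    ligs <- lapply(seq_len(n), function(i) {
      k <- sample(seq(config$rotbond_range[1], config$rotbond_range[2]), 1)
      qc <- sample(seq(config$charge_range[1], config$charge_range[2]), 1)
      center <- site + stats::rnorm(3, sd = 0.4)
      lig <- make_toy_ligand(k, qc, center, id = sprintf("%s-L%03d", target, i))
      # slide radially outward until clear of the pocket surface
      dir <- unit(c(center[1], center[2], 0))
      for (push in 1:25) {
        d <- min(cross_dist_min(coords(lig$atoms), P))
        if (d >= 2.5) break
        shift <- (2.5 - d + 0.1) * dir
        lig$atoms$x <- lig$atoms$x + shift[1]
        lig$atoms$y <- lig$atoms$y + shift[2]
      }
      lig
    })

    sel <- select_residues(pocket_struct, ligs, cutoff = 10.0)
    spec <- pocket_spec(
      cutoff = 10.0,
      retained_water_keys = residue_table(waters(pocket_struct))$key,
      retained_ion_keys = residue_table(ions(pocket_struct))$key)
    pocket <- build_capped_pocket(pocket_struct, sel, spec)

    two_conf <- stats::runif(n) < config$conformer_fraction
    prot_flag <- stats::runif(n) < config$protonation_fraction
    prot_dir <- ifelse(stats::runif(n) < 0.5, "uptake", "release")
    pka <- round(stats::runif(n, 4, 10), 2)
    crystal <- stats::runif(n) >= 0.1
    kinds <- sample(c("Ki", "Kd", "IC50"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    # declared, non-physical placeholder free energies for the water species
    spg_base <- list(G_H2O = -60, G_OHminus = -110, G_H3Oplus = -95)

    records <- lapply(seq_len(n), function(i) {
      confs <- list(ligs[[i]])
      if (two_conf[i]) {
        alt <- ligs[[i]]
        alt$atoms[, c("x", "y", "z")] <- alt$atoms[, c("x", "y", "z")] +
          matrix(stats::rnorm(3 * nrow(alt$atoms), sd = 0.15), ncol = 3)
        confs <- list(ligs[[i]], alt)
      }
      prot <- if (prot_flag[i]) {
        dE <- stats::runif(1, 2, 12)  # reaction energy, kcal/mol
        sg <- if (prot_dir[i] == "uptake") {
          species_free_energies(G_L = -10, G_LHplus = -10 + dE +
                                  spg_base$G_H2O - spg_base$G_OHminus,
                                G_H2O = spg_base$G_H2O,
                                G_OHminus = spg_base$G_OHminus)
        } else {
          species_free_energies(G_LH = -10, G_Lminus = -10 + dE +
                                  spg_base$G_H2O - spg_base$G_H3Oplus,
                                G_H2O = spg_base$G_H2O,
                                G_H3Oplus = spg_base$G_H3Oplus)
        }
        protonation_case(prot_dir[i], pKa = pka[i], pH = 7.4, species_G = sg)
      } else protonation_case("none")
      complex_record(
        id = ligs[[i]]$title, pocket = pocket, ligand_conformers = confs,
        protonation = prot, assay_pH = 7.4,
        provenance = if (crystal[i]) "crystal" else "modeled")
    })

    scores <- score_series(backend, records)
    ok <- scores$status == "ok"
    s <- scores$total[ok]
    signal <- config$signal_slope * s
    noise_sd <- config$noise_sd %||%
      (stats::sd(signal) * sqrt(1 / config$target_rho2 - 1))
    dg <- config$signal_slope * scores$total + config$signal_intercept +
      stats::rnorm(n, 0, noise_sd)
    value <- dg_to_affinity(dg, kinds)
    rho2 <- if (noise_sd == 0) 1 else
      stats::var(signal) / (stats::var(signal) + noise_sd^2)

    manifest <- tibble::tibble(
      target = target, ligand = scores$id,
      affinity_kind = kinds, affinity_value = value,
      assay_pH = 7.4, crystal = crystal, pKa = pka,
      direction = ifelse(prot_flag, prot_dir, "none"))
    manifest <- manifest[ok, ]

    list(records = records, manifest = manifest, scores = scores,
         pocket = pocket,
         planted = list(slope = config$signal_slope,
                        intercept = config$signal_intercept,
                        noise_sd = noise_sd, rho2 = rho2))
  })
}

#' Generate a multi-target toy benchmark
#'
#' Runs [make_toy_series()] for `config$n_targets` targets with distinct
#' sub-seeds, concatenating the manifests and score tables.
#'
#' @param config a [fixture_config()].
#' @param backend an `energy_backend` (default the test backend).
#' @return list with `manifest`, `scores`, `planted` (per-target tibble with
#'   the analytic `rho2` expectation) and `series` (the per-target lists).
#' @export
make_toy_benchmark <- function(config = fixture_config(), backend = NULL) {
  backend <- backend %||% make_test_backend()
  series <- lapply(seq_len(config$n_targets), function(t) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * t
    make_toy_series(cfg, target = sprintf("T%02d", t), backend = backend)
  })
  list(
    manifest = dplyr::bind_rows(lapply(series, `[[`, "manifest")),
    scores = dplyr::bind_rows(lapply(series, `[[`, "scores")),
    planted = tibble::tibble(
      target = sprintf("T%02d", seq_len(config$n_targets)),
      rho2 = vapply(series, function(s) s$planted$rho2, 0),
      noise_sd = vapply(series, function(s) s$planted$noise_sd, 0)),
    series = series
  )
}

#' Synthesise an external-engine log
#'
#' Produces a log that [parse_engine_output()] inverts exactly: the energy
#' round-trips bit-for-bit through the printed decimal representation used.
#'
#' @param energy heat of formation, kcal/mol.
#' @param converged emit the normal-termination marker (otherwise an error
#'   marker).
#' @param g_solv optional solvation free energy to include, kcal/mol.
#' @return character vector of log lines.
#' @export
make_engine_log <- function(energy, converged = TRUE, g_solv = NULL) {
  lines <- c(
    " *  PM6-D3H4X calculation",
    sprintf("          FINAL HEAT OF FORMATION = %17.8f KCAL/MOL", energy),
    if (!is.null(g_solv))
      sprintf("          FREE ENERGY OF SOLVATION = %17.8f KCAL/MOL", g_solv),
    if (converged) " == MOPAC DONE ==" else
      " ERROR: SCF FAILED TO CONVERGE"
  )
  lines
}
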