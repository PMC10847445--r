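#' Energy systems
#'
#' A `pl_system` is the minimal object an energy backend evaluates: element
#' symbols, an n x 3 coordinate matrix (Angstrom), per-atom charges (e), the
#' net charge and, when known, the covalent bond list (row-index pairs).
#' `as_system()` builds one from a [molecule()], [structure_model()],
#' `pocket_model` or atom table; per-atom charges are the partial charges
#' when all are assigned, otherwise the formal charges; a molecule's bonds
#' are carried along so backends can treat bonded pairs properly.
#' `combine_systems()` concatenates systems (receptor + ligand -> complex)
#' preserving coordinates and re-indexing bonds.
#'
#' @param x object carrying an atom table, or an existing `pl_system`.
#' @param net_charge optional integer override.
#' @return object of class `pl_system`.
#' @export
as_system <- function(x, net_charge = NULL) {
  if (inherits(x, "pl_system")) {
    if (!is.null(net_charge)) x$net_charge <- as.integer(net_charge)
    return(x)
  }
  atoms <- if (is.data.frame(x)) x else x$atoms
  q <- if (all(is.finite(atoms$partial_charge))) atoms$partial_charge else
    as.double(atoms$formal_charge)
  nc <- net_charge %||%
    (if (!is.data.frame(x) && !is.null(x$net_charge)) x$net_charge else
       as.integer(round(sum(q))))
  bonds <- if (!is.data.frame(x) && !is.null(x$bonds)) {
    cbind(x$bonds$i, x$bonds$j)
  } else NULL
  structure(
    list(element = atoms$element, coords = coords(atoms), q = q,
         net_charge = as.integer(nc), bonds = bonds,
         cache = new.env(parent = emptyenv())),
    class = "pl_system"
  )
}

#' @rdname as_system
#' @param ... `pl_system`s (or coercible objects) to concatenate.
#' @export
combine_systems <- function(...) {
  parts <- lapply(list(...), as_system)
  offsets <- cumsum(c(0L, vapply(parts, function(p) nrow(p$coords), 0L)))
  bonds <- purrr::imap(parts, function(p, k) {
    if (is.null(p$bonds)) NULL else p$bonds + offsets[k]
  })
  bonds <- do.call(rbind, bonds)
  structure(
    list(
      element = unlist(lapply(parts, `[[`, "element")),
      coords = do.call(rbind, lapply(parts, `[[`, "coords")),
      q = unlist(lapply(parts, `[[`, "q")),
      net_charge = sum(vapply(parts, `[[`, 0L, "net_charge")),
      bonds = bonds,
      cache = new.env(parent = emptyenv())
    ),
    class = "pl_system"
  )
}

#' Energy results
#'
#' Container returned by every energy backend: gas-phase energy, solvation
#' free energy (NA when not requested), a convergence flag and free-text
#' engine provenance.
#'
#' @param e_gas gas-phase energy, kcal/mol.
#' @param g_solv solvation free energy, kcal/mol (NA when not computed).
#' @param converged logical.
#' @param meta provenance text.
#' @return object of class `energy_result`.
#' @export
energy_result <- function(e_gas, g_solv = NA_real_, converged = TRUE,
                          meta = "") {
  if (converged && !is.finite(e_gas)) stop("converged result with non-finite e_gas")
  structure(list(e_gas = e_gas, g_solv = g_solv, converged = converged,
                 meta = meta), class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> e_gas = %.6f kcal/mol, g_solv = %s, %s\n",
              x$e_gas,
              if (is.na(x$g_solv)) "NA" else sprintf("%.6f", x$g_solv),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Test-backend configuration
#'
#' Parameters of the self-contained classical backend: per-element
#' Lennard-Jones `sigma` (Angstrom) and `epsilon` (kcal/mol), the solvent
#' dielectric, and the Born-like solvation constants. When the system
#' carries bonds, bonded (1-2) pairs are excluded from the non-bonded terms
#' and described by a harmonic stretch `0.5 * bond_k * (r - r0)^2` with `r0`
#' the covalent-radius sum, and 1-3 pairs (sharing a bonded neighbour) have
#' their non-bonded interaction scaled by `one_three_scale`, which acts as a
#' soft angle-opening potential. Solvation is modelled per atom as a Born
#' term whose effective radius grows with a smooth Gaussian burial measure
#' `B_i = sum_j exp(-r_ij^2 / (2 w^2))`, plus a buried-surface term
#' `gamma * area_i * exp(-c * B_i)`; burying an atom therefore weakens its
#' (favourable) solvation, which is what produces a positive desolvation
#' penalty on complex formation. This backend exists so the full scoring
#' pipeline is exercisable end to end; it is a classical toy model, not a
#' physical model of any semiempirical or implicit-solvent method.
#'
#' @param lj named list `element -> c(sigma, eps)`; defaults cover the
#'   common organic elements plus halogens and a few metals.
#' @param dielectric solvent relative permittivity (default 78.4).
#' @param born_scale growth rate of the effective Born radius with burial.
#' @param burial_width Gaussian width `w` of the burial measure, Angstrom.
#' @param surface_gamma surface solvation constant, kcal/mol/Angstrom^2
#'   (negative: exposed surface is favourably solvated).
#' @param surface_decay burial decay constant `c` (per burial unit).
#' @param bond_k harmonic stretch force constant, kcal/mol/Angstrom^2.
#' @param one_three_scale scale on 1-3 non-bonded interactions.
#' @param include_dispersion add a [dispersion_energy()] term to `e_gas`.
#' @param dispersion_params,dispersion_table used when
#'   `include_dispersion = TRUE`.
#' @return list of class `test_backend_config`.
#' @export
test_backend_config <- function(lj = NULL, dielectric = 78.4,
                                born_scale = 0.2, burial_width = 3.0,
                                surface_gamma = -0.006, surface_decay = 0.5,
                                bond_k = 600, one_three_scale = 0.5,
                                include_dispersion = FALSE,
                                dispersion_params = NULL,
                                dispersion_table = NULL) {
  defaults <- list(
    H = c(2.50, 0.020), C = c(3.40, 0.070), N = c(3.25, 0.170),
    O = c(3.00, 0.210), S = c(3.60, 0.250), P = c(3.70, 0.200),
    F = c(2.95, 0.060), Cl = c(3.47, 0.300), Br = c(3.65, 0.320),
    I = c(3.95, 0.400), Zn = c(1.95, 0.013), Na = c(2.43, 0.028),
    K = c(3.04, 0.020), Ca = c(2.65, 0.100), Mg = c(2.10, 0.060),
    Ne = c(2.80, 0.069), He = c(2.60, 0.020)
  )
  if (!is.null(lj)) defaults[names(lj)] <- lj
  structure(
    list(lj = defaults, dielectric = dielectric, born_scale = born_scale,
         burial_width = burial_width, surface_gamma = surface_gamma,
         surface_decay = surface_decay, bond_k = bond_k,
         one_three_scale = one_three_scale,
         include_dispersion = include_dispersion,
         dispersion_params = dispersion_params %||% dispersion_params(),
         dispersion_table = dispersion_table),
    class = "test_backend_config"
  )
}

# per-system precomputation for the test backend, cached on the system
.tb_prepare <- function(system, config) {
  key <- "test_backend_prep"
  prep <- system$cache[[key]]
  if (!is.null(prep)) return(prep)
  n <- length(system$element)
  missing <- setdiff(unique(system$element), names(config$lj))
  if (length(missing) > 0) {
    stop("test backend lacks LJ parameters for element(s): ",
         paste(missing, collapse = ", "))
  }
  par <- do.call(rbind, config$lj[system$element])
  sig <- par[, 1]; eps <- par[, 2]
  ij <- pair_indices(n)
  sig_ij <- (sig[ij[, 1]] + sig[ij[, 2]]) / 2
  eps_ij <- sqrt(eps[ij[, 1]] * eps[ij[, 2]])
  q <- system$q
  born_num <- 166.0318 * (1 - 1 / config$dielectric) * q^2

  # bonded topology: 1-2 pairs excluded from non-bonded terms and given a
  # harmonic stretch; 1-3 pairs scaled
  scale <- rep(1, nrow(ij))
  bond_rows <- integer(0); bond_r0 <- numeric(0)
  if (!is.null(system$bonds) && nrow(system$bonds) > 0) {
    pk <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
    pair_key <- pk(ij[, 1], ij[, 2])
    b12 <- unique(pk(system$bonds[, 1], system$bonds[, 2]))
    nbr <- split(c(system$bonds[, 2], system$bonds[, 1]),
                 c(system$bonds[, 1], system$bonds[, 2]))
    b13 <- unlist(lapply(nbr, function(v) {
      if (length(v) < 2) return(NULL)
      cmb <- utils::combn(sort(unique(v)), 2)
      pk(cmb[1, ], cmb[2, ])
    }), use.names = FALSE)
    b13 <- setdiff(unique(b13), b12)
    scale[pair_key %in% b13] <- config$one_three_scale
    bond_rows <- which(pair_key %in% b12)
    scale[bond_rows] <- 0
    rc <- covalent_radius(system$element)
    bond_r0 <- rc[ij[bond_rows, 1]] + rc[ij[bond_rows, 2]]
  }

  prep <- list(
    n = n, ij = ij, scale = scale,
    # linear indices of each pair in an n x n matrix (upper + lower image),
    # for fast per-atom accumulation without rowsum()
    iu = (ij[, 2] - 1L) * n + ij[, 1],
    il = (ij[, 1] - 1L) * n + ij[, 2],
    bond_rows = bond_rows, bond_r0 = bond_r0, bond_k = config$bond_k,
    lj_a = scale * 4 * eps_ij * sig_ij^12,
    lj_b = scale * 4 * eps_ij * sig_ij^6,
    qq = scale * pl_constants$coulomb_kcal * q[ij[, 1]] * q[ij[, 2]],
    born_num = born_num,
    born_r = vdw_radius(system$element),
    surf = config$surface_gamma * 4 * pi * vdw_radius(system$element)^2,
    disp = if (config$include_dispersion) {
      idx <- pair_lookup(config$dispersion_table %||%
                           builtin_coefficient_table(),
                         system$element[ij[, 1]], system$element[ij[, 2]])
      tab <- config$dispersion_table %||% builtin_coefficient_table()
      c6 <- tab$C6[idx]; c8 <- tab$C8[idx]
      f0 <- config$dispersion_params$a1 * sqrt(c8 / c6) +
        config$dispersion_params$a2
      list(c6 = c6, c8 = c8, f06 = f0^6, f08 = f0^8,
           s6 = config$dispersion_params$s6, s8 = config$dispersion_params$s8)
    } else NULL
  )
  system$cache[[key]] <- prep
  prep
}

.tb_pair_geom <- function(prep, xyz) {
  ij <- prep$ij
  dx <- xyz[ij[, 1], , drop = FALSE] - xyz[ij[, 2], , drop = FALSE]
  r2 <- rowSums(dx^2)
  list(dx = dx, r2 = r2, r = sqrt(r2), xyz = xyz)
}

.tb_e_gas <- function(prep, geom) {
  if (prep$n < 2) return(0)
  inv6 <- 1 / geom$r2^3
  e <- sum(prep$lj_a * inv6^2 - prep$lj_b * inv6) + sum(prep$qq / geom$r)
  if (length(prep$bond_rows) > 0) {
    e <- e + sum(0.5 * prep$bond_k *
                   (geom$r[prep$bond_rows] - prep$bond_r0)^2)
  }
  if (!is.null(prep$disp)) {
    rb <- geom$r * pl_constants$bohr_per_angstrom
    e <- e + sum(prep$scale *
                   (-prep$disp$s6 * prep$disp$c6 / (rb^6 + prep$disp$f06) -
                      prep$disp$s8 * prep$disp$c8 / (rb^8 + prep$disp$f08))) *
      pl_constants$hartree_kcal
  }
  e
}

.tb_pair_matrix <- function(prep, w) {
  M <- matrix(0, prep$n, prep$n)
  M[prep$iu] <- w
  M[prep$il] <- w
  M
}

.tb_burial <- function(prep, geom, w) {
  phi <- exp(-geom$r2 / (2 * w^2))
  B <- if (length(phi) > 0) rowSums(.tb_pair_matrix(prep, phi)) else
    numeric(prep$n)
  list(phi = phi, B = B)
}

.tb_g_solv <- function(prep, geom, config) {
  bu <- .tb_burial(prep, geom, config$burial_width)
  reff <- prep$born_r * (1 + config$born_scale * bu$B)
  sum(-prep$born_num / reff) + sum(prep$surf * exp(-config$surface_decay * bu$B))
}

.tb_gradient <- function(prep, geom, config, solvated) {
  n <- prep$n
  grad <- matrix(0, n, 3)
  if (n < 2) return(grad)
  ij <- prep$ij
  r <- geom$r; r2 <- geom$r2
  inv6 <- 1 / r2^3
  # dE/dr for LJ + Coulomb
  dEdr <- (-12 * prep$lj_a * inv6^2 + 6 * prep$lj_b * inv6) / r -
    prep$qq / r2
  if (length(prep$bond_rows) > 0) {
    dEdr[prep$bond_rows] <- dEdr[prep$bond_rows] +
      prep$bond_k * (r[prep$bond_rows] - prep$bond_r0)
  }
  if (!is.null(prep$disp)) {
    k <- pl_constants$bohr_per_angstrom
    rb <- r * k
    dEdr <- dEdr + prep$scale * pl_constants$hartree_kcal * k *
      (prep$disp$s6 * prep$disp$c6 * 6 * rb^5 / (rb^6 + prep$disp$f06)^2 +
         prep$disp$s8 * prep$disp$c8 * 8 * rb^7 / (rb^8 + prep$disp$f08)^2)
  }
  wpair <- dEdr / r
  if (solvated) {
    bu <- .tb_burial(prep, geom, config$burial_width)
    reff <- prep$born_r * (1 + config$born_scale * bu$B)
    # dG/dB_i
    u <- prep$born_num * prep$born_r * config$born_scale / reff^2 -
      config$surface_decay * prep$surf * exp(-config$surface_decay * bu$B)
    # dphi/dx_i = -(phi / w^2) * (x_i - x_j)
    wpair <- wpair - (u[ij[, 1]] + u[ij[, 2]]) * bu$phi /
      config$burial_width^2
  }
  # grad_i = sum_j w_ij (x_i - x_j) with symmetric weights w_ij
  W <- .tb_pair_matrix(prep, wpair)
  xyz <- geom$xyz
  rowSums(W) * xyz - W %*% xyz
}

#' Construct the classical test backend
#'
#' Returns an energy backend satisfying the backend contract: a
#' deterministic map from (atoms, coordinates, net charge, solvated flag) to
#' gas-phase energy and solvation free energy, with analytic gradients. The
#' energy model is pairwise Lennard-Jones plus Coulomb (optionally plus the
#' BJ-damped dispersion term); solvation is the smooth Born-plus-surface
#' model described in [test_backend_config()]. The backend counts its
#' evaluations in `backend$calls` (`n_eval`, `n_grad`).
#'
#' @param config a [test_backend_config()].
#' @return object of class `energy_backend` with elements `evaluate(system,
#'   solvated, coords)`, `gradient(system, solvated, coords)`,
#'   `has_gradient`, `has_solvation`, `label`, `calls`.
#' @export
make_test_backend <- function(config = test_backend_config()) {
  calls <- new.env(parent = emptyenv())
  calls$n_eval <- 0L; calls$n_grad <- 0L
  evaluate <- function(system, solvated = FALSE, coords = NULL) {
    system <- as_system(system)
    calls$n_eval <- calls$n_eval + 1L
    prep <- .tb_prepare(system, config)
    geom <- .tb_pair_geom(prep, coords %||% system$coords)
    e <- .tb_e_gas(prep, geom)
    g <- if (solvated) .tb_g_solv(prep, geom, config) else NA_real_
    energy_result(e, g, converged = TRUE, meta = "plscore test backend")
  }
  gradient <- function(system, solvated = FALSE, coords = NULL) {
    system <- as_system(system)
    calls$n_grad <- calls$n_grad + 1L
    prep <- .tb_prepare(system, config)
    geom <- .tb_pair_geom(prep, coords %||% system$coords)
    .tb_gradient(prep, geom, config, solvated)
  }
  structure(
    list(evaluate = evaluate, gradient = gradient, has_gradient = TRUE,
         has_solvation = TRUE, label = "test_backend", calls = calls,
         config = config),
    class = "energy_backend"
  )
}

#' Memoising backend wrapper
#'
#' Wraps a backend so that repeated evaluations of the same (coordinates,
#' charges, solvated flag) are served from a cache, making batch scoring
#' resumable and cheap to re-run.
#'
#' @param backend an `energy_backend`.
#' @return an `energy_backend` delegating to `backend` on cache misses.
#' @export
cached_backend <- function(backend) {
  store <- new.env(parent = emptyenv())
  key_of <- function(system, solvated, coords) {
    rlang::hash(list(system$element, coords %||% system$coords, system$q,
                     system$net_charge, solvated))
  }
  evaluate <- function(system, solvated = FALSE, coords = NULL) {
    system <- as_system(system)
    k <- key_of(system, solvated, coords)
    hit <- store[[k]]
    if (!is.null(hit)) return(hit)
    res <- backend$evaluate(system, solvated, coords)
    store[[k]] <- res
    res
  }
  structure(
    list(evaluate = evaluate, gradient = backend$gradient,
         has_gradient = backend$has_gradient,
         has_solvation = backend$has_solvation,
         label = paste0("cached(", backend$label, ")"),
         calls = backend$calls, config = backend$config),
    class = "energy_backend"
  )
}

#' Attach a pairwise-correction plugin to a backend
#'
#' Wraps a backend so that an additive pairwise correction — any function
#' with the signature of [dispersion_energy()], `function(system) ->
#' kcal/mol` — is added to the gas-phase energy. This is the hook through
#' which externally parameterized pair corrections (hydrogen- or
#' halogen-bond terms, alternative dispersion models) enter the scoring
#' without modifying the backend; their parameters are supplied by the
#' plugin, not by this package. The wrapped backend reports no gradient
#' capability unless the plugin provides one via `gradient_fn`.
#'
#' @param backend an `energy_backend`.
#' @param pair_fn `function(system) -> kcal/mol`, e.g. a closure over
#'   [dispersion_energy()] with a chosen parameter set.
#' @param gradient_fn optional `function(system) -> n x 3 matrix` with the
#'   plugin's analytic gradient.
#' @return an `energy_backend`.
#' @export
correction_backend <- function(backend, pair_fn, gradient_fn = NULL) {
  stopifnot(is.function(pair_fn))
  evaluate <- function(system, solvated = FALSE, coords = NULL) {
    system <- as_system(system)
    res <- backend$evaluate(system, solvated, coords)
    sys_at <- if (is.null(coords)) system else {
      s2 <- system; s2$coords <- coords
      s2$cache <- new.env(parent = emptyenv())
      s2
    }
    res$e_gas <- res$e_gas + pair_fn(sys_at)
    res
  }
  gradient <- if (!is.null(gradient_fn)) {
    function(system, solvated = FALSE, coords = NULL) {
      system <- as_system(system)
      sys_at <- if (is.null(coords)) system else {
        s2 <- system; s2$coords <- coords
        s2$cache <- new.env(parent = emptyenv())
        s2
      }
      backend$gradient(system, solvated, coords) + gradient_fn(sys_at)
    }
  } else NULL
  structure(
    list(evaluate = evaluate, gradient = gradient,
         has_gradient = !is.null(gradient_fn) && isTRUE(backend$has_gradient),
         has_solvation = backend$has_solvation,
         label = paste0("corrected(", backend$label, ")"),
         calls = backend$calls, config = backend$config),
    class = "energy_backend"
  )
}

check_union <- function(complex_system, receptor_system, ligand_system) {
  nc <- nrow(complex_system$coords)
  nr <- nrow(receptor_system$coords); nl <- nrow(ligand_system$coords)
  if (nc != nr + nl ||
      !identical(complex_system$element,
                 c(receptor_system$element, ligand_system$element)) ||
      max(abs(complex_system$coords -
                rbind(receptor_system$coords, ligand_system$coords))) > 1e-8) {
    stop("complex is not the atom-wise union of receptor and ligand")
  }
  invisible(TRUE)
}

#' Gas-phase interaction energy
#'
#' `dE_int = E_gas(PL) - E_gas(P) - E_gas(L)`, all three evaluated at the
#' fixed complex geometry (the complex must be the atom-wise union of the
#' receptor and ligand systems).
#'
#' @param backend an `energy_backend`.
#' @param complex_system,receptor_system,ligand_system `pl_system`s.
#' @return kcal/mol.
#' @export
interaction_energy <- function(backend, complex_system, receptor_system,
                               ligand_system) {
  complex_system <- as_system(complex_system)
  receptor_system <- as_system(receptor_system)
  ligand_system <- as_system(ligand_system)
  check_union(complex_system, receptor_system, ligand_system)
  backend$evaluate(complex_system)$e_gas -
    backend$evaluate(receptor_system)$e_gas -
    backend$evaluate(ligand_system)$e_gas
}

#' Desolvation penalty
#'
#' `ddG_solv = G_solv(PL) - G_solv(P) - G_solv(L)` at the complex geometry.
#'
#' @inheritParams interaction_energy
#' @return kcal/mol (typically positive).
#' @export
desolvation_penalty <- function(backend, complex_system, receptor_system,
                                ligand_system) {
  if (!isTRUE(backend$has_solvation)) {
    stop("backend does not support solvated evaluation")
  }
  complex_system <- as_system(complex_system)
  receptor_system <- as_system(receptor_system)
  ligand_system <- as_system(ligand_system)
  check_union(complex_system, receptor_system, ligand_system)
  backend$evaluate(complex_system, solvated = TRUE)$g_solv -
    backend$evaluate(receptor_system, solvated = TRUE)$g_solv -
    backend$evaluate(ligand_system, solvated = TRUE)$g_solv
}

#' Local geometry relaxation
#'
#' Quasi-Newton (L-BFGS-B) minimisation of the backend energy over the free
#' atoms. Converged when the largest per-atom gradient norm over free atoms
#' is at most `tol`; frozen atoms are returned bit-identical to the input.
#' Deterministic for identical inputs.
#'
#' @param backend an `energy_backend` with gradient capability.
#' @param system a `pl_system`.
#' @param frozen_mask logical vector (length n) of atoms to hold fixed;
#'   `NULL` frees all atoms.
#' @param tol gradient tolerance, kcal/mol/Angstrom (default 0.1).
#' @param max_steps maximum L-BFGS-B iterations (default 2000).
#' @param solvated minimise `e_gas + g_solv` instead of `e_gas` alone.
#' @return the system with relaxed coordinates; attributes `energy`
#'   (final objective, kcal/mol), `grad_max` and `steps`.
#' @export
relax <- function(backend, system, frozen_mask = NULL, tol = 0.1,
                  max_steps = 2000, solvated = FALSE) {
  if (!isTRUE(backend$has_gradient)) {
    stop("backend does not provide gradients")
  }
  system <- as_system(system)
  n <- nrow(system$coords)
  frozen <- frozen_mask %||% rep(FALSE, n)
  stopifnot(length(frozen) == n)
  free <- !frozen

  total_at <- function(xyz) {
    res <- backend$evaluate(system, solvated = solvated, coords = xyz)
    res$e_gas + if (solvated) res$g_solv else 0
  }
  grad_at <- function(xyz) backend$gradient(system, solvated = solvated,
                                            coords = xyz)
  grad_max_free <- function(xyz) {
    g <- grad_at(xyz)[free, , drop = FALSE]
    if (nrow(g) == 0) 0 else sqrt(max(rowSums(g^2)))
  }

  xyz0 <- system$coords
  if (grad_max_free(xyz0) <= tol) {
    out <- system
    attr(out, "energy") <- total_at(xyz0)
    attr(out, "grad_max") <- grad_max_free(xyz0)
    attr(out, "steps") <- 0L
    return(out)
  }

  pack <- function(xyz) as.vector(xyz[free, , drop = FALSE])
  unpack <- function(p) {
    xyz <- xyz0
    xyz[free, ] <- matrix(p, ncol = 3)
    xyz
  }
  steps_used <- 0L
  p <- pack(xyz0)
  repeat {
    chunk <- min(500L, max_steps - steps_used)
    if (chunk <= 0) {
      stop(sprintf(
        "relaxation did not converge: gradient %.4g > tol %.4g after %d steps",
        grad_max_free(unpack(p)), tol, steps_used))
    }
    p_prev <- p
    fit <- stats::optim(
      p, fn = function(p) total_at(unpack(p)),
      gr = function(p) as.vector(grad_at(unpack(p))[free, , drop = FALSE]),
      method = "L-BFGS-B",
      control = list(maxit = chunk, factr = 10, pgtol = 0))
    steps_used <- steps_used + min(chunk, fit$counts[["function"]])
    p <- fit$par
    if (grad_max_free(unpack(p)) <= tol) break
    if (identical(p, p_prev)) {
      stop(sprintf(
        "relaxation stalled: gradient %.4g > tol %.4g after %d steps",
        grad_max_free(unpack(p)), tol, steps_used))
    }
  }
  xyz <- unpack(p)
  gm <- grad_max_free(xyz)
  if (gm > tol) {
    stop(sprintf(
      "relaxation did not converge: gradient %.4g > tol %.4g after %d steps",
      gm, tol, steps_used))
  }
  out <- system
  out$coords <- xyz
  out$cache <- system$cache  # composition unchanged; pair tables still valid
  attr(out, "energy") <- total_at(xyz)
  attr(out, "grad_max") <- gm
  attr(out, "steps") <- steps_used
  out
}

#' Ligand strain energy
#'
#' `dG_conf(L) = [E_gas + G_solv](bound geometry) - [E_gas + G_solv](relaxed
#' geometry)`, where the relaxed geometry results from [relax()] in solvent
#' starting at the bound pose. Non-negative up to the optimizer tolerance.
#'
#' @param backend an `energy_backend` with gradient and solvation support.
#' @param ligand_bound a `pl_system` at the bound-pose geometry.
#' @param tol,max_steps forwarded to [relax()].
#' @return kcal/mol, with attribute `relaxed` carrying the relaxed system.
#' @export
ligand_strain <- function(backend, ligand_bound, tol = 0.1,
                          max_steps = 2000) {
  ligand_bound <- as_system(ligand_bound)
  res0 <- backend$evaluate(ligand_bound, solvated = TRUE)
  relaxed <- relax(backend, ligand_bound, tol = tol, max_steps = max_steps,
                   solvated = TRUE)
  strain <- (res0$e_gas + res0$g_solv) - attr(relaxed, "energy")
  attr(strain, "relaxed") <- relaxed
  strain
}
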