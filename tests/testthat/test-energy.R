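test_that("BJ-damped pair dispersion matches the closed form", {
  tab <- data.frame(elemA = "C", elemB = "C", C6 = 10, C8 = 20)
  p <- dispersion_params()

  # independent evaluation of the closed form at the documented parameters
  f0 <- p$a1 * sqrt(20 / 10) + p$a2
  expected_r5 <- -1 * 10 / (5^6 + f0^6) - 0.9220 * 20 / (5^8 + f0^8)
  expect_equal(d3bj_pair_energy("C", "C", 5, p, tab), expected_r5,
               tolerance = 1e-14)
  expect_equal(d3bj_pair_energy("C", "C", 5, p, tab), -2.004e-4,
               tolerance = 1e-3)

  # finite at contact: the damping limit
  expect_equal(d3bj_pair_energy("C", "C", 0, p, tab),
               -10 / f0^6 - 0.9220 * 20 / f0^8, tolerance = 1e-14)

  # decays to zero from below, monotonically in r
  rs <- seq(0, 40, by = 0.5)
  es <- d3bj_pair_energy("C", "C", rs, p, tab)
  expect_true(all(es < 0))
  expect_true(all(diff(es) > 0))
  expect_lt(abs(es[length(es)]), 1e-8)

  expect_error(d3bj_pair_energy("C", "Zn", 3, p, tab), "C Zn")
})

test_that("system dispersion equals the exhaustive double-loop oracle", {
  expect_equal(dispersion_energy(atom_table(element = "C", x = 0, y = 0,
                                            z = 0)), 0)
  two <- atom_table(element = c("C", "N"), x = c(0, 3), y = 0, z = 0)
  p <- dispersion_params(); tab <- builtin_coefficient_table()
  expect_equal(dispersion_energy(two, p, tab),
               d3bj_pair_energy("C", "N", 3 * 1.8897259886, p, tab) * 627.509,
               tolerance = 1e-12)

  at <- random_cloud(10, elements = c("C", "N", "O", "S", "H"), seed = 21)
  got <- dispersion_energy(at, p, tab)
  want <- dispersion_oracle(at$element, coords(at), p, tab)
  expect_equal(got, want, tolerance = 1e-12)
  expect_lt(got, 0)

  # intermolecular restriction equals the cross-pair part of the oracle
  inter <- dispersion_energy(at, p, tab, pairs = "intermolecular",
                             groupA = 1:4, groupB = 5:10)
  full <- dispersion_oracle(at$element, coords(at), p, tab)
  gA <- dispersion_oracle(at$element[1:4], coords(at)[1:4, ], p, tab)
  gB <- dispersion_oracle(at$element[5:10], coords(at)[5:10, ], p, tab)
  expect_equal(inter, full - gA - gB, tolerance = 1e-10)
  expect_error(dispersion_energy(at, p, tab, pairs = "intermolecular",
                                 groupA = 1:4, groupB = 4:8), "overlap")
})

test_that("dispersion is invariant under rigid motion", {
  at <- random_cloud(8, seed = 31)
  p <- dispersion_params(); tab <- builtin_coefficient_table()
  e0 <- dispersion_energy(at, p, tab)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- coords(at) %*% R + matrix(c(4, -2, 7), 8, 3, byrow = TRUE)
  at2 <- at; at2$x <- xyz[, 1]; at2$y <- xyz[, 2]; at2$z <- xyz[, 3]
  expect_equal(dispersion_energy(at2, p, tab), e0, tolerance = 1e-10)
})

test_that("test backend reproduces LJ and Coulomb closed forms", {
  be <- make_test_backend()
  r0 <- 2^(1 / 6) * 3.40
  dimer <- as_system(atom_table(element = c("C", "C"), x = c(0, r0), y = 0,
                                z = 0))
  expect_equal(be$evaluate(dimer)$e_gas, -0.070, tolerance = 1e-12)
  expect_lt(max(abs(be$gradient(dimer))), 1e-10)

  # point-charge pair at 5 A with LJ switched off: pure Coulomb
  be0 <- make_test_backend(test_backend_config(lj = list(He = c(2.5, 0))))
  ions <- as_system(atom_table(element = c("He", "He"), x = c(0, 5), y = 0,
                               z = 0, formal_charge = c(1L, -1L)))
  expect_equal(be0$evaluate(ions)$e_gas, -332.0636 / 5, tolerance = 1e-12)

  expect_error(
    make_test_backend(test_backend_config(lj = list()))$evaluate(
      as_system(atom_table(element = "Fe", x = 0, y = 0, z = 0))),
    "Fe")
})

test_that("analytic gradients match central finite differences", {
  be <- make_test_backend()
  at <- random_cloud(8, seed = 17)
  at$formal_charge <- c(1L, -1L, rep(0L, 6))
  s <- as_system(at)
  for (solvated in c(FALSE, TRUE)) {
    g <- be$gradient(s, solvated)
    h <- 1e-5
    gn <- matrix(0, 8, 3)
    for (i in 1:8) for (k in 1:3) {
      xp <- s$coords; xp[i, k] <- xp[i, k] + h
      xm <- s$coords; xm[i, k] <- xm[i, k] - h
      ep <- be$evaluate(s, solvated, xp); em <- be$evaluate(s, solvated, xm)
      fp <- ep$e_gas + if (solvated) ep$g_solv else 0
      fm <- em$e_gas + if (solvated) em$g_solv else 0
      gn[i, k] <- (fp - fm) / (2 * h)
    }
    expect_lt(max(abs(g - gn)), 1e-6)
  }
})

test_that("test backend is size-consistent and deterministic", {
  be <- make_test_backend()
  a <- random_cloud(6, seed = 41)
  b <- random_cloud(6, seed = 42)
  b$x <- b$x + 500  # far separation
  ab <- as_system(dplyr::bind_rows(a, b))
  ea <- be$evaluate(as_system(a), TRUE)
  eb <- be$evaluate(as_system(b), TRUE)
  eab <- be$evaluate(ab, TRUE)
  expect_equal(eab$e_gas, ea$e_gas + eb$e_gas, tolerance = 1e-8)
  expect_equal(eab$g_solv, ea$g_solv + eb$g_solv, tolerance = 1e-8)
  expect_identical(be$evaluate(ab, TRUE)$e_gas, be$evaluate(ab, TRUE)$e_gas)
})

test_that("interaction energy is the supermolecular difference", {
  lb <- lookup_backend(list(`12` = -100, `8` = -60, `4` = -30))
  rec <- as_system(random_cloud(8, seed = 51))
  lig <- as_system(random_cloud(4, seed = 52))
  cplx <- combine_systems(rec, lig)
  expect_equal(interaction_energy(lb, cplx, rec, lig), -10)

  # atom mismatch between complex and fragment union is an error
  bad <- combine_systems(lig, rec)
  expect_error(interaction_energy(lb, bad, rec, lig), "union")

  # size consistency: ligand displaced 100 A, neutral fragments
  be <- make_test_backend()
  lig_far <- lig; lig_far$coords[, 1] <- lig_far$coords[, 1] + 100
  cplx_far <- combine_systems(rec, lig_far)
  expect_lt(abs(interaction_energy(be, cplx_far, rec, lig_far)), 1e-6)
})

test_that("desolvation penalty behaves like a burial cost", {
  lb <- lookup_backend(list(`12` = 0, `8` = 0, `4` = 0),
                       list(`12` = -20, `8` = -15, `4` = -10))
  rec <- as_system(random_cloud(8, seed = 61))
  lig <- as_system(random_cloud(4, seed = 62))
  expect_equal(desolvation_penalty(lb, combine_systems(rec, lig), rec, lig),
               5)
  nosolv <- lookup_backend(list(`12` = 0, `8` = 0, `4` = 0))
  expect_error(
    desolvation_penalty(nosolv, combine_systems(rec, lig), rec, lig),
    "solvat")

  # a charged ligand buried inside a cage pays more than one at the surface
  be <- make_test_backend()
  shell <- atom_table(element = rep("C", 14),
                      x = 3.5 * c(1, -1, 0, 0, 0, 0, .7, .7, -.7, -.7, .7, .7, -.7, -.7),
                      y = 3.5 * c(0, 0, 1, -1, 0, 0, .7, -.7, .7, -.7, .7, -.7, .7, -.7),
                      z = 3.5 * c(0, 0, 0, 0, 1, -1, .7, .7, .7, .7, -.7, -.7, -.7, -.7))
  ion <- atom_table(element = "Na", x = 0, y = 0, z = 0,
                    formal_charge = 1L)
  ion_out <- ion; ion_out$x <- 12
  srec <- as_system(shell)
  buried <- desolvation_penalty(be, combine_systems(srec, as_system(ion)),
                                srec, as_system(ion))
  surface <- desolvation_penalty(
    be, combine_systems(srec, as_system(ion_out)), srec, as_system(ion_out))
  expect_gt(buried, surface)
  expect_gt(buried, 0)

  # neutral nonpolar fragments: small positive penalty
  np <- desolvation_penalty(
    be, combine_systems(srec, as_system(random_cloud(4, seed = 63))),
    srec, as_system(random_cloud(4, seed = 63)))
  expect_gt(np, -0.5)
})

test_that("relaxation converges, respects frozen atoms, lowers energy", {
  be <- make_test_backend()
  # bonded diatomic stretched from equilibrium relaxes to r0 = 1.52
  mol <- chain_molecule(c("C", "C"), spacing = 2.2)
  s <- as_system(mol)
  out <- relax(be, s, tol = 1e-4)
  r_final <- sqrt(sum((out$coords[1, ] - out$coords[2, ])^2))
  e_bond <- function(r) 0.5 * 600 * (r - 1.52)^2
  lj <- function(r) 4 * 0.07 * ((3.4 / r)^12 - (3.4 / r)^6)
  # analytic minimum of the bond term alone (1-2 pairs are LJ-excluded)
  expect_equal(r_final, 1.52, tolerance = 1e-4)
  expect_lt(attr(out, "energy"), e_bond(2.2))

  # system already at the minimum returns the input unchanged
  again <- relax(be, out, tol = 1e-3)
  expect_identical(again$coords, out$coords)
  expect_equal(attr(again, "steps"), 0L)

  # frozen atoms are bit-identical; free atoms move
  mol3 <- chain_molecule(c("C", "C", "C"), spacing = 2.0)
  s3 <- as_system(mol3)
  frozen <- c(TRUE, FALSE, FALSE)
  out3 <- relax(be, s3, frozen_mask = frozen, tol = 1e-3)
  expect_identical(out3$coords[1, ], s3$coords[1, ])
  expect_false(identical(out3$coords[2, ], s3$coords[2, ]))

  # step starvation raises a non-convergence error (anharmonic system, so a
  # single quasi-Newton step cannot reach the minimum)
  set.seed(77)
  floppy <- plscore:::make_toy_ligand(6, 0, c(0, 0, 0))
  expect_error(relax(be, as_system(floppy), tol = 1e-9, max_steps = 1),
               "converge")
})

test_that("ligand strain matches the harmonic closed form", {
  # charges zero and surface term off: energy is the bond term alone
  cfg <- test_backend_config(surface_gamma = 0)
  be <- make_test_backend(cfg)
  delta <- 0.3
  mol <- chain_molecule(c("C", "C"), spacing = 1.52 + delta)
  strain <- ligand_strain(be, as_system(mol), tol = 1e-6)
  expect_equal(as.numeric(strain), 0.5 * 600 * delta^2, tolerance = 1e-6)

  # a ligand at its minimum has ~zero strain, and strain is never negative
  relaxed <- attr(strain, "relaxed")
  s0 <- ligand_strain(be, relaxed, tol = 1e-6)
  expect_equal(as.numeric(s0), 0, tolerance = 1e-8)
  be2 <- make_test_backend()
  for (seed in 1:3) {
    set.seed(seed)
    lig <- plscore:::make_toy_ligand(sample(0:8, 1), 0, c(0, 0, 0))
    st <- ligand_strain(be2, as_system(lig))
    expect_gte(as.numeric(st), -1e-6)
  }
})

test_that("pairwise-correction plugins add to the gas-phase energy only", {
  be <- make_test_backend()
  disp <- function(system) dispersion_energy(system)
  cbe <- correction_backend(be, disp)
  at <- random_cloud(6, seed = 81)
  s <- as_system(at)
  base <- be$evaluate(s, TRUE)
  corr <- cbe$evaluate(s, TRUE)
  expect_equal(corr$e_gas - base$e_gas, dispersion_energy(s),
               tolerance = 1e-10)
  expect_equal(corr$g_solv, base$g_solv)
  expect_false(cbe$has_gradient)
  # interaction energy picks up the intermolecular part of the correction
  lig <- as_system(random_cloud(3, seed = 82))
  cplx <- combine_systems(s, lig)
  d_int <- interaction_energy(cbe, cplx, s, lig) -
    interaction_energy(be, cplx, s, lig)
  inter <- dispersion_energy(cplx, pairs = "intermolecular",
                             groupA = 1:6, groupB = 7:9)
  expect_equal(d_int, inter, tolerance = 1e-9)
})

test_that("engine input rendering is complete and bit-stable", {
  s <- as_system(atom_table(element = c("O", "H", "H"),
                            x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0))
  txt <- render_engine_input(s)
  expect_match(txt[1], "PM6-D3H4X")
  expect_match(txt[1], "1SCF")
  expect_match(txt[1], "CHARGE=0")
  expect_false(grepl("MOZYME", txt[1]))
  expect_false(grepl("EPS", txt[1]))

  big <- as_system(random_cloud(301, seed = 71))
  expect_match(render_engine_input(big)[1], "MOZYME")

  solv <- render_engine_input(s, solvated = TRUE)
  expect_match(solv[1], "EPS=78.4")

  expect_identical(render_engine_input(s, solvated = TRUE),
                   render_engine_input(s, solvated = TRUE))

  # frozen atoms carry optimization flag 0
  fr <- render_engine_input(s, frozen_mask = c(TRUE, FALSE, FALSE))
  expect_match(fr[4], " 0 ")
  expect_match(fr[5], " 1 ")
})

test_that("engine output parsing extracts energies and convergence", {
  log <- make_engine_log(-123.45678)
  res <- parse_engine_output(log)
  expect_equal(res$e_gas, -123.45678)
  expect_true(res$converged)

  expect_error(parse_engine_output(" some preamble\n nothing else"),
               "HEAT OF FORMATION")

  bad <- make_engine_log(-50, converged = FALSE)
  res2 <- parse_engine_output(bad)
  expect_false(res2$converged)

  # gas/solvated log pair: solvation free energy is the difference
  gas <- parse_engine_output(make_engine_log(-100.5))
  solv <- parse_engine_output(make_engine_log(-112.25))
  expect_equal(solv$e_gas - gas$e_gas, -11.75)
  # and a log carrying the solvation line directly
  both <- parse_engine_output(make_engine_log(-100.5, g_solv = -11.75))
  expect_equal(both$g_solv, -11.75)
})
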