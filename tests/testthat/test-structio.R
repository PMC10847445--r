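test_that("PDB parsing builds the expected hierarchy and round-trips", {
  m <- parse_pdb(tripeptide_pdb())
  expect_s3_class(m, "structure_model")
  expect_equal(length(unique(m$atoms$chain)), 1)
  expect_equal(nrow(residue_table(m$atoms)), 3)
  expect_equal(nrow(m$atoms), 12)
  expect_true(all(m$atoms$group == "protein"))

  # write -> parse round trip preserves atoms, elements, coords, charges
  m$atoms$formal_charge[5] <- -1L
  back <- parse_pdb(paste(write_pdb(m), collapse = "\n"))
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_equal(back$atoms$element, m$atoms$element)
  expect_equal(coords(back$atoms), coords(m$atoms), tolerance = 1e-3)
  expect_equal(back$atoms$formal_charge, m$atoms$formal_charge)
})

test_that("altloc policy keeps only the configured copy", {
  txt <- paste(c(
    pdb_line("ATOM", 1, "N",  "SER", "A", 1, 0, 0, 0, "N"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 1, 1.5, 0, 0, "C"),
    pdb_line("ATOM", 3, "OG", "SER", "A", 1, 2.0, 1.0, 0, "O", altloc = "A"),
    pdb_line("ATOM", 4, "OG", "SER", "A", 1, 2.0, -1.0, 0, "O", altloc = "B")
  ), collapse = "\n")
  m <- parse_pdb(txt)
  expect_equal(nrow(m$atoms), 3)
  expect_true(all(m$atoms$altloc %in% c("", "A")))
  og <- m$atoms[m$atoms$name == "OG", ]
  expect_equal(og$y, 1.0)
  # policy B keeps the other copy
  mb <- parse_pdb(txt, altloc_policy = "B")
  expect_equal(mb$atoms[mb$atoms$name == "OG", ]$y, -1.0)
})

test_that("single-atom metal HETATMs are classified as ions with charge", {
  txt <- paste(c(
    tripeptide_pdb(),
    pdb_line("HETATM", 90, "ZN", "ZN", "A", 200, 5, 5, 5, "Zn")
  ), collapse = "\n")
  m <- parse_pdb(txt)
  zn <- ions(m)
  expect_equal(nrow(zn), 1)
  expect_equal(zn$formal_charge, 2L)
  # waters classified separately
  txt2 <- paste(c(tripeptide_pdb(),
                  pdb_line("HETATM", 91, "O", "HOH", "A", 300, 8, 8, 8, "O")),
                collapse = "\n")
  expect_equal(nrow(waters(parse_pdb(txt2))), 1)
})

test_that("malformed and empty PDB input raise informative errors", {
  expect_error(parse_pdb(""), "empty")
  bad <- paste(c(pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
                 "ATOM      2  CA"), collapse = "\n")
  expect_error(parse_pdb(bad), "line 2")
})

test_that("Mol2 parsing recovers atoms, bonds and net charge", {
  eth <- parse_mol2(ethanol_mol2())
  expect_equal(nrow(eth$atoms), 9)
  expect_equal(nrow(eth$bonds), 8)
  expect_equal(eth$net_charge, 0L)
  expect_equal(eth$title, "ethanol")

  # charges summing to -0.999 round to -1
  act <- parse_mol2(acetate_mol2())
  expect_equal(sum(act$atoms$partial_charge), -0.999, tolerance = 1e-9)
  expect_equal(act$net_charge, -1L)

  bz <- parse_mol2(benzene_mol2())
  expect_equal(sum(bz$bonds$order == "ar"), 6)
  expect_true(all(bz$bonds$in_ring))
})

test_that("Mol2 structural errors are caught", {
  no_bond <- sub("@<TRIPOS>BOND.*", "", ethanol_mol2())
  expect_error(parse_mol2(no_bond), "BOND")
  mismatch <- sub(" 9 8 1", " 8 8 1", ethanol_mol2())
  expect_error(parse_mol2(mismatch), "mismatch")
})

test_that("bond perception follows covalent radii and detects rings", {
  h2 <- molecule(atom_table(element = c("H", "H"), x = c(0, 0.74), y = 0,
                            z = 0))
  expect_equal(nrow(perceive_bonds(h2)$bonds), 1)

  ne2 <- molecule(atom_table(element = c("Ne", "Ne"), x = c(0, 3), y = 0,
                             z = 0))
  expect_equal(nrow(perceive_bonds(ne2)$bonds), 0)

  # cyclohexane carbons (ideal chair, C-C 1.54): 6 ring bonds
  ang <- (0:5) * pi / 3
  chair <- atom_table(element = rep("C", 6),
                      x = 1.46 * cos(ang), y = 1.46 * sin(ang),
                      z = rep(c(0.25, -0.25), 3))
  cy <- perceive_bonds(molecule(chair))
  expect_equal(nrow(cy$bonds), 6)
  expect_true(all(cy$bonds$in_ring))
  # independent brute-force cycle check: every bond lies on a cycle, i.e.
  # removing it leaves the endpoints connected
  adj <- function(bonds, drop) {
    b <- bonds[-drop, , drop = FALSE]
    nb <- lapply(1:6, function(v) c(b$j[b$i == v], b$i[b$j == v]))
    nb
  }
  for (k in seq_len(nrow(cy$bonds))) {
    nb <- adj(cy$bonds, k)
    seen <- c(cy$bonds$i[k]); frontier <- seen
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(nb[frontier])), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_true(cy$bonds$j[k] %in% seen)
  }
})

test_that("rotatable-bond counting implements the documented convention", {
  ethane <- chain_molecule(c("C", "C"))
  expect_equal(count_rotatable_bonds(ethane), 0L)
  butane <- chain_molecule(c("C", "C", "C", "C"))
  expect_equal(count_rotatable_bonds(butane), 1L)
  bz <- parse_mol2(benzene_mol2())
  expect_equal(count_rotatable_bonds(bz), 0L)
  # amide exclusion: build CCC(=O)NCC so the amide C-N sits mid-chain
  amide <- chain_molecule(c("C", "C", "C", "N", "C", "C"))
  # attach carbonyl O to atom 3 by a double bond
  amide$atoms <- dplyr::bind_rows(
    amide$atoms,
    atom_table(element = "O", x = 3 * 1.53, y = 1.23, z = 0))
  amide$bonds <- dplyr::bind_rows(amide$bonds,
                                  tibble::tibble(i = 3L, j = 7L, order = "2",
                                                 in_ring = FALSE))
  with_amide <- count_rotatable_bonds(amide)
  without_exclusion <- count_rotatable_bonds(amide, exclude_amide = FALSE)
  expect_equal(without_exclusion - with_amide, 1L)
  expect_error(count_rotatable_bonds(molecule(butane$atoms)),
               "perceive_bonds")
})

test_that("rotatable-bond count is invariant under reordering and motion", {
  set.seed(42)
  base <- parse_mol2(ethanol_mol2())
  n0 <- count_rotatable_bonds(base)
  for (k in 1:5) {
    perm <- sample(nrow(base$atoms))
    mol <- base
    mol$atoms <- mol$atoms[perm, ]
    inv <- order(perm)
    mol$bonds$i <- inv[base$bonds$i]
    mol$bonds$j <- inv[base$bonds$j]
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- coords(mol$atoms) %*% R + matrix(runif(3, -9, 9),
                                            nrow(mol$atoms), 3, byrow = TRUE)
    mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
    expect_equal(count_rotatable_bonds(mol), n0)
  }
})

test_that("superposition recovers rigid transforms and matches the
           quaternion oracle", {
  set.seed(7)
  A <- matrix(rnorm(12, sd = 3), 4, 3)
  self <- superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  shifted <- sweep(A, 2, c(5, 0, 0), `+`)
  expect_equal(superpose(shifted, A)$rmsd, 0, tolerance = 1e-10)

  # noisy copy: rmsd agrees with the quaternion characteristic-polynomial
  # oracle to 1e-8
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R + matrix(rnorm(12, sd = 0.1), 4, 3)
  fit <- superpose(A, B)
  expect_equal(fit$rmsd, quaternion_rmsd(A, B), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # idempotence: re-superposing the fitted coordinates changes rmsd < 1e-10
  fitted <- fit$transform(A)
  expect_lt(abs(superpose(fitted, B)$rmsd - fit$rmsd), 1e-10)

  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("closest approach equals the exhaustive pair scan and drives
           receptor choice", {
  prot <- structure_model(atom_table(element = "C", x = 0, y = 0, z = 0))
  lig <- molecule(atom_table(element = c("C", "C"), x = c(2, 5), y = 0,
                             z = 0))
  expect_equal(closest_approach(prot, lig), 2)
  expect_error(closest_approach(prot, list()), "empty")

  set.seed(13)
  P <- structure_model(random_cloud(400, seed = 13))
  L <- molecule(random_cloud(60, seed = 14))
  brute <- min(as.matrix(
    stats::dist(rbind(coords(P$atoms),
                      coords(L$atoms))))[1:400, 401:460])
  expect_equal(closest_approach(P, L), brute, tolerance = 1e-12)

  near <- structure_model(atom_table(element = "C", x = 0.8, y = 0, z = 0))
  far <- structure_model(atom_table(element = "C", x = 2.1, y = 0, z = 0))
  probe <- molecule(atom_table(element = "C", x = 0, y = 0, z = 0))
  rep <- choose_receptor(list(a = near, b = far), probe)
  expect_equal(attr(rep, "selected"), "b")
  expect_equal(rep$clash, c(TRUE, FALSE))
})

test_that("XYZ round trip preserves geometry and net charge", {
  lig <- parse_mol2(acetate_mol2())
  back <- read_xyz(paste(write_xyz(lig), collapse = "\n"))
  expect_equal(nrow(back$atoms), nrow(lig$atoms))
  expect_equal(coords(back$atoms), coords(lig$atoms), tolerance = 1e-7)
  expect_equal(back$net_charge, lig$net_charge)
})
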