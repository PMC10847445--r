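# Shared fixtures and independent oracles, all built in code.

pdb_line <- function(record, serial, name, resname, chain, resnum, x, y, z,
                     element, altloc = " ", charge = "  ") {
  nm <- if (nchar(element) == 1 && nchar(name) < 4) {
    sprintf(" %-3s", name)
  } else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
          record, serial, nm, altloc, resname, chain, resnum, x, y, z,
          1, 0, toupper(element), charge)
}

# three-residue synthetic peptide (backbone only), chain A
tripeptide_pdb <- function() {
  lines <- character(); s <- 0
  for (i in 1:3) {
    x0 <- (i - 1) * 3.8
    lines <- c(lines,
      pdb_line("ATOM", s + 1, "N",  "ALA", "A", i, x0 + 0.0, 0.0, 0.0, "N"),
      pdb_line("ATOM", s + 2, "CA", "ALA", "A", i, x0 + 1.5, 0.0, 0.0, "C"),
      pdb_line("ATOM", s + 3, "C",  "ALA", "A", i, x0 + 2.3, 1.2, 0.0, "C"),
      pdb_line("ATOM", s + 4, "O",  "ALA", "A", i, x0 + 2.3, 2.4, 0.0, "O"))
    s <- s + 4
  }
  paste(lines, collapse = "\n")
}

ethanol_mol2 <- function() {
  paste(c(
    "@<TRIPOS>MOLECULE", "ethanol", " 9 8 1 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1   0.000  0.000  0.000 C.3  1 ETH  -0.060",
    "  2 C2   1.530  0.000  0.000 C.3  1 ETH   0.050",
    "  3 O1   2.050  1.350  0.000 O.3  1 ETH  -0.400",
    "  4 H1  -0.390 -0.510  0.880 H    1 ETH   0.050",
    "  5 H2  -0.390 -0.510 -0.880 H    1 ETH   0.050",
    "  6 H3  -0.390  1.020  0.000 H    1 ETH   0.050",
    "  7 H4   1.920  0.510  0.880 H    1 ETH   0.050",
    "  8 H5   1.920  0.510 -0.880 H    1 ETH   0.050",
    "  9 H6   1.700  1.870  0.750 H    1 ETH   0.160",
    "@<TRIPOS>BOND",
    "  1 1 2 1", "  2 2 3 1", "  3 1 4 1", "  4 1 5 1", "  5 1 6 1",
    "  6 2 7 1", "  7 2 8 1", "  8 3 9 1"
  ), collapse = "\n")
}

acetate_mol2 <- function() {
  paste(c(
    "@<TRIPOS>MOLECULE", "acetate", " 7 6 1 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1   0.000  0.000  0.000 C.3  1 ACT  -0.200",
    "  2 C2   1.520  0.000  0.000 C.2  1 ACT   0.301",
    "  3 O1   2.130  1.060  0.000 O.co2 1 ACT  -0.550",
    "  4 O2   2.130 -1.060  0.000 O.co2 1 ACT  -0.550",
    "  5 H1  -0.390 -0.510  0.880 H    1 ACT   0.000",
    "  6 H2  -0.390 -0.510 -0.880 H    1 ACT   0.000",
    "  7 H3  -0.390  1.020  0.000 H    1 ACT   0.000",
    "@<TRIPOS>BOND",
    "  1 1 2 1", "  2 2 3 2", "  3 2 4 1", "  4 1 5 1", "  5 1 6 1",
    "  6 1 7 1"
  ), collapse = "\n")
}

benzene_mol2 <- function() {
  ang <- (0:5) * pi / 3
  atoms <- sprintf("  %d C%d %8.3f %8.3f 0.000 C.ar 1 BNZ 0.000",
                   1:6, 1:6, 1.39 * cos(ang), 1.39 * sin(ang))
  bonds <- sprintf("  %d %d %d ar", 1:6, 1:6, c(2:6, 1))
  paste(c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1 0 0", "SMALL",
          "USER_CHARGES", "@<TRIPOS>ATOM", atoms, "@<TRIPOS>BOND", bonds),
        collapse = "\n")
}

# simple chain molecule builder: elements along x at given spacing, bonded
# consecutively with given orders
chain_molecule <- function(elements, orders = NULL, spacing = 1.53,
                           charge = 0L) {
  n <- length(elements)
  at <- atom_table(element = elements, x = seq_len(n) * spacing, y = 0, z = 0)
  bonds <- if (n > 1) {
    tibble::tibble(i = 1:(n - 1), j = 2:n,
                   order = orders %||% rep("1", n - 1), in_ring = FALSE)
  } else NULL
  molecule(at, bonds, net_charge = charge)
}

# extended peptide chain with realistic backbone spacing (C(i)-N(i+1) ~1.33)
peptide_chain <- function(n, resnames = rep("ALA", n)) {
  rows <- lapply(seq_len(n), function(i) {
    x0 <- (i - 1) * 4.3
    atom_table(serial = (i - 1) * 4 + 1:4, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = x0 + c(0, 1.46, 2.98, 3.10),
               y = c(0, 0, 0.2, 1.42), z = 0,
               chain = "A", resname = resnames[i], resnum = i)
  })
  structure_model(dplyr::bind_rows(rows))
}

# quaternion characteristic-polynomial RMSD oracle (Theobald-style), fully
# independent of the SVD implementation under test
quaternion_rmsd <- function(A, B) {
  n <- nrow(A)
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  M <- crossprod(A0, B0)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  g <- sum(A0^2) + sum(B0^2)
  sqrt(max(0, (g - 2 * lam)) / n)
}

# exhaustive double-loop dispersion oracle
dispersion_oracle <- function(elements, xyz, params, table) {
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2)) * 1.8897259886
    k <- which((table$elemA == elements[i] & table$elemB == elements[j]) |
                 (table$elemA == elements[j] & table$elemB == elements[i]))[1]
    c6 <- table$C6[k]; c8 <- table$C8[k]
    f0 <- params$a1 * sqrt(c8 / c6) + params$a2
    total <- total - params$s6 * c6 / (r^6 + f0^6) -
      params$s8 * c8 / (r^8 + f0^8)
  }
  total * 627.509
}

# covariance-formula Pearson oracle
r2_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  (sxy / (sd(x) * sd(y)))^2
}

# a backend whose energies come from a lookup on atom count (for arithmetic
# contracts that need prescribed energies)
lookup_backend <- function(e_by_n, g_by_n = NULL) {
  structure(list(
    evaluate = function(system, solvated = FALSE, coords = NULL) {
      n <- length(system$element)
      energy_result(e_by_n[[as.character(n)]],
                    if (solvated) g_by_n[[as.character(n)]] else NA_real_)
    },
    gradient = NULL, has_gradient = FALSE,
    has_solvation = !is.null(g_by_n), label = "lookup"),
    class = "energy_backend")
}

# well-separated random atom cloud (no steric clashes)
random_cloud <- function(n, elements = c("C", "N", "O", "H"), min_sep = 2.8,
                         box = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  box <- box %||% (3.5 * n^(1/3) + 6)
  pts <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    p <- runif(3, 0, box)
    if (k == 0 || min(sqrt(rowSums(sweep(pts[1:k, , drop = FALSE], 2, p)^2)))
        >= min_sep) {
      k <- k + 1
      pts[k, ] <- p
    }
  }
  atom_table(element = sample(elements, n, TRUE),
             x = pts[, 1], y = pts[, 2], z = pts[, 3])
}
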