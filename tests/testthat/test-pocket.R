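# residues at controlled minimum distances from a probe ligand at the origin
chain_at_distances <- function(dists) {
  rows <- purrr::imap(dists, function(d, i) {
    atom_table(serial = (i - 1) * 4 + 1:4, name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = d + c(0, 1.2, 2.0, 2.0), y = c(0, 0, 1.0, 2.2), z = 0,
               chain = "A", resname = "ALA", resnum = i)
  })
  structure_model(dplyr::bind_rows(rows))
}

probe <- function() molecule(atom_table(element = "C", x = 0, y = 0, z = 0))

test_that("residue selection is an iff-distance rule, monotone in cutoff", {
  st <- chain_at_distances(c(3, 5, 7, 9, 12, 15))
  sel10 <- select_residues(st, probe(), 10)
  expect_equal(length(sel10), 4)
  expect_equal(sel10, residue_table(st$atoms)$key[1:4])

  # brute-force distance oracle
  key <- residue_key(st$atoms)
  dmin <- tapply(sqrt(rowSums(coords(st$atoms)^2)), key, min)
  expect_setequal(sel10, names(dmin)[dmin <= 10])

  expect_equal(length(select_residues(st, probe(), 1e6)), 6)
  expect_equal(length(select_residues(st, probe(), 0)), 0)
  expect_error(select_residues(st, list(), 10), "empty")

  # monotonicity across a cutoff ladder
  sels <- lapply(c(2, 4, 6, 8, 10, 13, 16), function(ct)
    select_residues(st, probe(), ct))
  for (k in seq_len(length(sels) - 1)) {
    expect_true(all(sels[[k]] %in% sels[[k + 1]]))
  }
})

test_that("cap count equals the number of cut peptide bonds", {
  st <- chain_at_distances(rep(5, 6))
  keys <- residue_table(st$atoms)$key

  whole <- build_capped_pocket(st, keys)
  expect_equal(nrow(whole$caps), 0)

  middle <- build_capped_pocket(st, keys[2:4])
  expect_equal(nrow(middle$caps), 2)
  expect_setequal(middle$caps$kind, c("N_terminal_CHO", "C_terminal_NHCH3"))

  split_sel <- build_capped_pocket(st, keys[c(2, 3, 5)])
  expect_equal(nrow(split_sel$caps), 4)
  expect_equal(sum(split_sel$caps$kind == "N_terminal_CHO"), 2)
  expect_equal(sum(split_sel$caps$kind == "C_terminal_NHCH3"), 2)

  expect_error(build_capped_pocket(st, "A/GLY/99/"), "absent")
  expect_error(build_capped_pocket(st, character()), "empty")
})

test_that("cap atoms are covalently consistent and neutral", {
  st <- peptide_chain(6)
  keys <- residue_table(st$atoms)$key
  pm <- build_capped_pocket(st, keys[2:4])

  cap_atoms <- pm$atoms[pm$atoms$resname %in% c("NME", "FOR"), ]
  expect_true(all(cap_atoms$formal_charge == 0))

  # each cap heavy atom sits within bonding distance of its anchor backbone
  # atom: NME N near the anchor C, FOR C near the anchor N
  anchor_c <- pm$atoms[pm$atoms$resnum == 4 & pm$atoms$name == "C", ]
  nme_n <- pm$atoms[pm$atoms$resname == "NME" & pm$atoms$name == "N", ]
  d_cn <- sqrt(sum((coords(anchor_c) - coords(nme_n))^2))
  expect_lt(d_cn, 1.3 * (0.76 + 0.71))

  anchor_n <- pm$atoms[pm$atoms$resnum == 2 & pm$atoms$name == "N", ]
  for_c <- pm$atoms[pm$atoms$resname == "FOR" & pm$atoms$name == "C", ]
  expect_lt(sqrt(sum((coords(anchor_n) - coords(for_c))^2)),
            1.3 * (0.76 + 0.71))

  # added hydrogens at standard bond lengths from their heavy atoms
  nme <- pm$atoms[pm$atoms$resname == "NME", ]
  ch3 <- nme[nme$name == "CH3", ]
  for (hn in c("HH31", "HH32", "HH33")) {
    h <- nme[nme$name == hn, ]
    expect_equal(sqrt(sum((coords(ch3) - coords(h))^2)), 1.09,
                 tolerance = 1e-6)
  }
})

test_that("pocket charge bookkeeping sums residues, ions and cofactors", {
  st <- chain_at_distances(rep(4, 4))
  st$atoms$resname[st$atoms$resnum == 2] <- "ASP"
  st$atoms$resname[st$atoms$resnum == 3] <- "LYS"
  keys <- residue_table(st$atoms)$key
  pm <- build_capped_pocket(st, keys)
  expect_equal(pm$net_charge, 0L)

  # adding a Zn ion raises it to +2
  zn <- atom_table(serial = 99L, name = "ZN", element = "Zn", x = 30, y = 0,
                   z = 0, formal_charge = 2L, resname = "ZN", resnum = 500L,
                   is_hetero = TRUE)
  st2 <- structure_model(dplyr::bind_rows(st$atoms[names(st$atoms) != "group"],
                                          zn))
  keys2 <- setdiff(residue_table(st2$atoms)$key, "A/ZN/500/")
  pm2 <- build_capped_pocket(
    st2, keys2, pocket_spec(retained_ion_keys = "A/ZN/500/"))
  expect_equal(pm2$net_charge, 2L)

  # unknown residue name without a charge entry errors
  st3 <- chain_at_distances(rep(4, 4))
  st3$atoms$resname[1:4] <- "XXX"
  expect_error(
    build_capped_pocket(st3, residue_table(st3$atoms)$key),
    "XXX")

  # trimming away 3 Asp and 1 Glu raises the charge by +4
  st4 <- chain_at_distances(rep(4, 8))
  st4$atoms$resname[st4$atoms$resnum %in% c(1, 2, 3)] <- "ASP"
  st4$atoms$resname[st4$atoms$resnum == 8] <- "GLU"
  k4 <- residue_table(st4$atoms)$key
  full <- build_capped_pocket(st4, k4)
  trimmed <- build_capped_pocket(st4, k4[4:7])
  expect_equal(trimmed$net_charge - full$net_charge, 4L)
})

test_that("boundary charged residues far from the ligand are reported", {
  st <- chain_at_distances(c(3, 5, 30, 32))
  st$atoms$resname[st$atoms$resnum == 3] <- "ASP"
  pm <- build_capped_pocket(st, residue_table(st$atoms)$key)
  expect_warning(
    q <- pocket_charge(pm, ligands = probe(), warn_distance = 8),
    "charged residue"
  )
  bc <- attr(q, "boundary_charges")
  expect_equal(nrow(bc), 1)
  expect_equal(bc$charge, -1L)
  expect_match(bc$key, "ASP")
})

test_that("pocket charge on the toy fixture equals the planted value", {
  cfg <- fixture_config(seed = 5, n_residues = 12, n_asp = 1, n_lys = 1,
                        with_zinc = TRUE)
  st <- make_toy_pocket(cfg)
  sel <- residue_table(st$atoms[st$atoms$group == "protein", ])$key
  pm <- build_capped_pocket(
    st, sel, pocket_spec(retained_ion_keys = residue_table(ions(st))$key,
                         retained_water_keys = residue_table(waters(st))$key))
  expect_equal(pm$net_charge, cfg$planted_pocket_charge)
  expect_equal(pm$net_charge, 2L)
})

test_that("selection granularity is whole residues and rebuild is
           order-insensitive", {
  st <- chain_at_distances(rep(5, 5))
  keys <- residue_table(st$atoms)$key
  pm1 <- build_capped_pocket(st, keys[2:4])
  # permute atom order within the input structure
  set.seed(9)
  st2 <- structure_model(st$atoms[sample(nrow(st$atoms)),
                                  names(st$atoms) != "group"])
  pm2 <- build_capped_pocket(st2, keys[2:4])
  expect_equal(pm1$net_charge, pm2$net_charge)
  expect_equal(nrow(pm1$caps), nrow(pm2$caps))
  a1 <- dplyr::arrange(pm1$atoms, .data$serial)
  a2 <- dplyr::arrange(pm2$atoms, .data$serial)
  expect_equal(a1$name, a2$name)
  expect_equal(coords(a1), coords(a2))
})

test_that("disulfide partners are pulled into the selection", {
  st <- chain_at_distances(rep(5, 6))
  at <- st$atoms[, names(st$atoms) != "group"]
  at$resname[at$resnum %in% c(2, 5)] <- "CYS"
  sg <- dplyr::bind_rows(
    atom_table(serial = 97L, name = "SG", element = "S", x = 20, y = 3,
               z = 0, resname = "CYS", resnum = 2L),
    atom_table(serial = 98L, name = "SG", element = "S", x = 21.9, y = 3,
               z = 0, resname = "CYS", resnum = 5L))
  st <- structure_model(dplyr::bind_rows(at, sg))
  keys <- residue_table(st$atoms)$key
  pm <- build_capped_pocket(st, keys[2])
  expect_true(any(grepl("CYS/5", pm$residues)))
})
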