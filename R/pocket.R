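#' Pocket construction parameters
#'
#' Collects the settings used to truncate a receptor around a series of
#' overlaid ligands: the selection cutoff (default 10 Angstrom; trimmed
#' variants typically use 6 or 5), explicit whitelists of structural waters,
#' ions and cofactors to retain (by residue key, see [residue_key()]), and a
#' documentation-only record of the optimization region cutoff.
#'
#' @param cutoff selection cutoff in Angstrom (> 0).
#' @param retained_water_keys,retained_ion_keys,retained_cofactor_keys
#'   character vectors of residue keys to carry into the pocket.
#' @param optimize_cutoff region (Angstrom) around the ligands that a
#'   downstream relaxation would free; recorded in the model metadata only.
#' @return object of class `pocket_spec`.
#' @export
pocket_spec <- function(cutoff = 10.0, retained_water_keys = character(),
                        retained_ion_keys = character(),
                        retained_cofactor_keys = character(),
                        optimize_cutoff = 4.0) {
  stopifnot(is.numeric(cutoff), cutoff > 0)
  structure(
    list(cutoff = cutoff, retained_water_keys = retained_water_keys,
         retained_ion_keys = retained_ion_keys,
         retained_cofactor_keys = retained_cofactor_keys,
         optimize_cutoff = optimize_cutoff),
    class = "pocket_spec"
  )
}

#' Select pocket residues around overlaid ligands
#'
#' A protein residue is selected iff the minimum distance from any of its
#' atoms to any atom of any ligand is at most `cutoff`. The ligand set is
#' the union of all overlaid ligands of the series, so the selection is
#' monotone in the cutoff.
#'
#' @param structure a [structure_model()].
#' @param ligands list of [molecule()]s in the same coordinate frame.
#' @param cutoff distance cutoff, Angstrom.
#' @return character vector of selected residue keys, in chain order.
#' @export
select_residues <- function(structure, ligands, cutoff) {
  if (inherits(ligands, "molecule")) ligands <- list(ligands)
  if (length(ligands) == 0) stop("empty ligand list")
  prot <- structure$atoms[structure$atoms$group == "protein", ]
  if (nrow(prot) == 0) return(character())
  L <- do.call(rbind, lapply(ligands, as_xyz))
  dmin <- cross_dist_min(coords(prot), L)
  key <- residue_key(prot)
  res_min <- tapply(dmin, key, min)
  selected <- names(res_min)[res_min <= cutoff]
  # preserve chain order
  intersect(unique(key), selected)
}

#' Build a capped pocket model
#'
#' Keeps the selected residues (whole residues only), appends whitelisted
#' waters/ions/cofactors, and terminates every cut peptide bond with a
#' neutral cap: the C-terminal side of a kept segment receives an -NH-CH3
#' cap (residue NME) and the N-terminal side a -CH=O cap (residue FOR).
#' Cap heavy atoms reuse the positions of the removed neighbouring residue's
#' backbone atoms (N/CA for the C-cap, C/O for the N-cap), which perturbs
#' the geometry least; hydrogens are added at standard bond lengths
#' (C-H 1.09, N-H 1.01 Angstrom). Cysteines connected by a disulfide bridge
#' to a selected cysteine are pulled into the selection so the boundary
#' never cuts an S-S bond.
#'
#' @param structure the full [structure_model()].
#' @param selection character vector of residue keys (from
#'   [select_residues()]).
#' @param spec a [pocket_spec()].
#' @param residue_charges named integer vector of per-residue formal charges
#'   used for the net-charge bookkeeping; defaults to the standard table
#'   (Asp/Glu -1, Lys/Arg +1, ...).
#' @return object of class `pocket_model` with elements `atoms` (including
#'   cap atoms), `caps` (tibble: kind, anchor key), `residues`, retained
#'   subset keys, `net_charge` and `atom_count`.
#' @export
build_capped_pocket <- function(structure, selection, spec = pocket_spec(),
                                residue_charges = NULL) {
  atoms <- structure$atoms
  key <- residue_key(atoms)
  if (length(selection) == 0) stop("empty residue selection")
  missing_sel <- setdiff(selection, key)
  if (length(missing_sel) > 0) {
    stop("selection references absent residue(s): ",
         paste(missing_sel, collapse = ", "))
  }
  selection <- pull_in_disulfide_partners(atoms, key, selection)

  prot <- atoms[atoms$group == "protein", ]
  pkey <- residue_key(prot)
  res <- prot |>
    dplyr::mutate(key = pkey) |>
    dplyr::distinct(.data$key, .data$chain, .data$resnum, .data$icode)
  res$kept <- res$key %in% selection

  kept_atoms <- prot[pkey %in% selection, ]
  caps <- list(); cap_atoms <- list()
  serial_next <- max(atoms$serial) + 1L

  for (ch in unique(res$chain)) {
    rc <- res[res$chain == ch, ]
    for (i in seq_len(nrow(rc))) {
      if (!rc$kept[i]) next
      # C-terminal cut: next residue exists but is not kept
      if (i < nrow(rc) && !rc$kept[i + 1]) {
        nb <- prot[pkey == rc$key[i + 1], ]
        anchor <- prot[pkey == rc$key[i], ]
        cap <- make_nme_cap(anchor, nb, rc$chain[i], rc$resnum[i + 1],
                            serial_next)
        serial_next <- serial_next + nrow(cap)
        caps[[length(caps) + 1]] <- tibble::tibble(
          kind = "C_terminal_NHCH3", anchor = rc$key[i])
        cap_atoms[[length(cap_atoms) + 1]] <- cap
      }
      # N-terminal cut: previous residue exists but is not kept
      if (i > 1 && !rc$kept[i - 1]) {
        nb <- prot[pkey == rc$key[i - 1], ]
        anchor <- prot[pkey == rc$key[i], ]
        cap <- make_for_cap(anchor, nb, rc$chain[i], rc$resnum[i - 1],
                            serial_next)
        serial_next <- serial_next + nrow(cap)
        caps[[length(caps) + 1]] <- tibble::tibble(
          kind = "N_terminal_CHO", anchor = rc$key[i])
        cap_atoms[[length(cap_atoms) + 1]] <- cap
      }
    }
  }

  retained <- atoms[key %in% c(spec$retained_water_keys,
                               spec$retained_ion_keys,
                               spec$retained_cofactor_keys), ]
  pocket_atoms <- dplyr::bind_rows(
    kept_atoms, dplyr::bind_rows(cap_atoms), retained)

  model <- structure(
    list(
      atoms = pocket_atoms,
      caps = if (length(caps)) dplyr::bind_rows(caps) else
        tibble::tibble(kind = character(), anchor = character()),
      residues = selection,
      water_keys = intersect(spec$retained_water_keys, key),
      ion_keys = intersect(spec$retained_ion_keys, key),
      cofactor_keys = intersect(spec$retained_cofactor_keys, key),
      cutoff = spec$cutoff,
      net_charge = NA_integer_,
      atom_count = nrow(pocket_atoms)
    ),
    class = "pocket_model"
  )
  model$net_charge <- pocket_charge(model, residue_charges)
  model
}

pull_in_disulfide_partners <- function(atoms, key, selection, ss_cut = 2.5) {
  sg <- atoms[atoms$resname %in% c("CYS", "CYX") & atoms$name == "SG", ]
  if (nrow(sg) < 2) return(selection)
  d <- as.matrix(stats::dist(coords(sg)))
  skey <- residue_key(sg)
  pair <- which(d < ss_cut & upper.tri(d), arr.ind = TRUE)
  for (r in seq_len(nrow(pair))) {
    a <- skey[pair[r, 1]]; b <- skey[pair[r, 2]]
    if (a %in% selection && !(b %in% selection)) selection <- c(selection, b)
    if (b %in% selection && !(a %in% selection)) selection <- c(selection, a)
  }
  selection
}

backbone_atom <- function(res_atoms, name) {
  hit <- res_atoms[res_atoms$name == name, ]
  if (nrow(hit) == 0) {
    stop(sprintf("residue %s lacks backbone atom %s",
                 residue_key(res_atoms)[1], name))
  }
  as.numeric(hit[1, c("x", "y", "z")])
}

cap_atom_row <- function(serial, name, element, pos, chain, resname, resnum) {
  tibble::tibble(
    serial = serial, name = name, element = element,
    x = pos[1], y = pos[2], z = pos[3],
    formal_charge = 0L, partial_charge = NA_real_,
    chain = chain, resname = resname, resnum = resnum, icode = "",
    altloc = "", is_hetero = FALSE, group = "protein"
  )
}

unit <- function(v) v / sqrt(sum(v^2))

# -NH-CH3 cap: N at removed residue's N, CH3 carbon at its CA.
make_nme_cap <- function(anchor, removed, chain, resnum, serial0) {
  n_pos <- backbone_atom(removed, "N")
  c_pos <- backbone_atom(removed, "CA")
  anchor_c <- backbone_atom(anchor, "C")
  # amide H: in-plane, away from both heavy neighbours
  h_n <- n_pos - 1.01 * unit(unit(anchor_c - n_pos) + unit(c_pos - n_pos))
  hs <- methyl_hydrogens(c_pos, n_pos)
  dplyr::bind_rows(
    cap_atom_row(serial0,      "N",   "N", n_pos, chain, "NME", resnum),
    cap_atom_row(serial0 + 1L, "CH3", "C", c_pos, chain, "NME", resnum),
    cap_atom_row(serial0 + 2L, "H",   "H", h_n,   chain, "NME", resnum),
    cap_atom_row(serial0 + 3L, "HH31", "H", hs[1, ], chain, "NME", resnum),
    cap_atom_row(serial0 + 4L, "HH32", "H", hs[2, ], chain, "NME", resnum),
    cap_atom_row(serial0 + 5L, "HH33", "H", hs[3, ], chain, "NME", resnum)
  )
}

# -CH=O cap: C at removed residue's C, O at its O.
make_for_cap <- function(anchor, removed, chain, resnum, serial0) {
  c_pos <- backbone_atom(removed, "C")
  o_pos <- backbone_atom(removed, "O")
  anchor_n <- backbone_atom(anchor, "N")
  h_c <- c_pos - 1.09 * unit(unit(o_pos - c_pos) + unit(anchor_n - c_pos))
  dplyr::bind_rows(
    cap_atom_row(serial0,      "C", "C", c_pos, chain, "FOR", resnum),
    cap_atom_row(serial0 + 1L, "O", "O", o_pos, chain, "FOR", resnum),
    cap_atom_row(serial0 + 2L, "H", "H", h_c,   chain, "FOR", resnum)
  )
}

# three tetrahedral hydrogens around a methyl carbon whose single heavy
# neighbour sits at `axis_to`
methyl_hydrogens <- function(c_pos, axis_to, bond = 1.09) {
  a <- unit(axis_to - c_pos)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * a) * a)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  theta <- pi - acos(-1 / 3)  # H-C-axis angle 109.47 deg from the axis
  out <- matrix(0, 3, 3)
  for (k in 0:2) {
    phi <- 2 * pi * k / 3
    dir <- -cos(pi - theta) * a +
      sin(pi - theta) * (cos(phi) * e1 + sin(phi) * e2)
    out[k + 1, ] <- c_pos + bond * unit(dir)
  }
  out
}

#' Pocket net charge with boundary-charge reporting
#'
#' Sums per-residue formal charges (from `residue_charges`, defaulting to the
#' standard amino-acid table), ion formal charges and cofactor charges; caps
#' are neutral. When `ligands` are supplied, charged residues whose closest
#' atom lies beyond `warn_distance` from the ligand set are listed in a
#' boundary-charge warning attribute (`attr(, "boundary_charges")`), since
#' exposed charges far from the ligands are artefacts of truncation.
#'
#' @param model a `pocket_model`.
#' @param residue_charges named integer vector (names = residue names)
#'   overriding/extending the default charge table.
#' @param ligands optional list of [molecule()]s for the boundary report.
#' @param warn_distance Angstrom (default 8).
#' @return integer net charge, with attribute `boundary_charges` (tibble)
#'   when `ligands` given.
#' @export
pocket_charge <- function(model, residue_charges = NULL, ligands = NULL,
                          warn_distance = 8.0) {
  tab <- .default_residue_charges
  if (!is.null(residue_charges)) {
    tab[toupper(names(residue_charges))] <- as.integer(residue_charges)
  }
  atoms <- model$atoms
  key <- residue_key(atoms)
  grp <- atoms$group
  res <- tibble::tibble(key = key, resname = atoms$resname, group = grp) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)

  res_q <- integer(nrow(res))
  for (r in seq_len(nrow(res))) {
    if (res$group[r] %in% c("ion", "cofactor")) {
      # ions/cofactors carry their charge on the atoms
      res_q[r] <- sum(atoms$formal_charge[key == res$key[r]])
    } else {
      q <- tab[toupper(res$resname[r])]
      if (is.na(q)) {
        stop("no charge entry for residue ", res$resname[r],
             "; extend residue_charges")
      }
      res_q[r] <- q
    }
  }
  total <- as.integer(sum(res_q))

  if (!is.null(ligands)) {
    if (inherits(ligands, "molecule")) ligands <- list(ligands)
    L <- do.call(rbind, lapply(ligands, as_xyz))
    dmin <- cross_dist_min(coords(atoms), L)
    res_d <- tapply(dmin, factor(key, levels = res$key), min)
    far <- res_q != 0 & as.numeric(res_d) > warn_distance
    boundary <- tibble::tibble(
      key = res$key[far], charge = res_q[far],
      min_ligand_distance = as.numeric(res_d)[far]
    )
    if (nrow(boundary) > 0) {
      warning(sprintf(
        "%d charged residue(s) beyond %.1f Angstrom of the ligands: %s",
        nrow(boundary), warn_distance, paste(boundary$key, collapse = ", ")))
    }
    attr(total, "boundary_charges") <- boundary
  }
  total
}

#' @export
print.pocket_model <- function(x, ...) {
  cat(sprintf(
    "<pocket_model> %d residues, %d caps, %d atoms, net charge %+d (cutoff %.1f A)\n",
    length(x$residues), nrow(x$caps), x$atom_count, x$net_charge, x$cutoff))
  invisible(x)
}
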