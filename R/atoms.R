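#' Atom tables and molecular containers
#'
#' Atoms are stored as a tibble with one row per atom and columns
#' `serial`, `name`, `element`, `x`, `y`, `z`, `formal_charge`,
#' `partial_charge`, `chain`, `resname`, `resnum`, `icode`, `altloc`,
#' `is_hetero`. All container classes in the package (`molecule`,
#' `structure_model`, `pocket_model`) wrap such a table, so dplyr verbs apply
#' directly to `$atoms`.
#'
#' @param serial integer atom serials (preserved for I/O only; all internal
#'   indexing is by table row).
#' @param name short atom labels (e.g. `"CA"`, `"O1"`).
#' @param element IUPAC element symbols; validated against the internal
#'   element table.
#' @param x,y,z Cartesian coordinates in Angstrom; must be finite.
#' @param formal_charge integer formal charges (e).
#' @param partial_charge optional real partial charges (e).
#' @param chain,resname,resnum,icode residue key components.
#' @param altloc alternate-location indicator, `""` or a single letter.
#' @param is_hetero logical, `TRUE` for HETATM-like records.
#' @return A tibble of class `tbl_df` with the columns listed above.
#' @export
atom_table <- function(serial = integer(), name = character(),
                       element = character(), x = double(), y = double(),
                       z = double(), formal_charge = 0L,
                       partial_charge = NA_real_, chain = "A",
                       resname = "LIG", resnum = 1L, icode = "",
                       altloc = "", is_hetero = FALSE) {
  n <- length(element)
  if (length(serial) == 0 && n > 0) serial <- seq_len(n)
  if (length(name) == 0 && n > 0) name <- element
  atoms <- tibble::tibble(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element),
    x = as.double(x), y = as.double(y), z = as.double(z),
    formal_charge = vctrs::vec_recycle(as.integer(formal_charge), n),
    partial_charge = vctrs::vec_recycle(as.double(partial_charge), n),
    chain = vctrs::vec_recycle(as.character(chain), n),
    resname = vctrs::vec_recycle(as.character(resname), n),
    resnum = vctrs::vec_recycle(as.integer(resnum), n),
    icode = vctrs::vec_recycle(as.character(icode), n),
    altloc = vctrs::vec_recycle(as.character(altloc), n),
    is_hetero = vctrs::vec_recycle(as.logical(is_hetero), n)
  )
  validate_atom_table(atoms)
  atoms
}

validate_atom_table <- function(atoms) {
  if (!all(atoms$element %in% .recognized_elements)) {
    stop("unrecognized element symbol(s): ",
         paste(setdiff(unique(atoms$element), .recognized_elements),
               collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  ok_altloc <- atoms$altloc == "" | grepl("^[A-Z]$", atoms$altloc)
  if (!all(ok_altloc)) stop("altloc must be blank or a single capital letter")
  invisible(atoms)
}

#' Coordinates of an atom table as a matrix
#' @param atoms an atom table (or a container with an `$atoms` element).
#' @return numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(atoms) {
  if (is.list(atoms) && !is.data.frame(atoms) && !is.null(atoms$atoms)) {
    atoms <- atoms$atoms
  }
  as.matrix(atoms[, c("x", "y", "z")])
}

set_coords <- function(obj, xyz) {
  if (is.data.frame(obj)) {
    obj$x <- xyz[, 1]; obj$y <- xyz[, 2]; obj$z <- xyz[, 3]
    return(obj)
  }
  obj$atoms <- set_coords(obj$atoms, xyz)
  obj
}

#' Residue keys
#'
#' A residue key identifies a residue by `(chain, resname, resnum, icode)`.
#' `residue_key()` builds the canonical string form `"chain/resname/resnum/icode"`,
#' used throughout selection and capping.
#'
#' @param atoms an atom table.
#' @return character vector of keys, one per row of `atoms`.
#' @export
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resname, atoms$resnum, atoms$icode, sep = "/")
}

#' @rdname residue_key
#' @export
residue_table <- function(atoms) {
  atoms |>
    dplyr::mutate(key = residue_key(atoms)) |>
    dplyr::distinct(.data$key, .data$chain, .data$resname, .data$resnum,
                    .data$icode)
}

#' Construct a small molecule
#'
#' A `molecule` couples an atom table with a bond table (`i`, `j`: 1-based
#' atom-row indices; `order` in `{1, 2, 3, "ar"}`; `in_ring` flag) and a net
#' charge. The net charge must equal the sum of atom formal charges when
#' those are assigned.
#'
#' @param atoms an [atom_table()].
#' @param bonds bond tibble or `NULL` (add later with [perceive_bonds()]).
#' @param net_charge integer net charge (e); defaults to the sum of formal
#'   charges.
#' @param title free-text label.
#' @return object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, net_charge = NULL, title = "") {
  validate_atom_table(atoms)
  if (is.null(net_charge)) net_charge <- sum(atoms$formal_charge)
  if (!is.null(bonds)) bonds <- validate_bond_table(bonds, nrow(atoms))
  structure(
    list(atoms = atoms, bonds = bonds,
         net_charge = as.integer(net_charge), title = title),
    class = "molecule"
  )
}

validate_bond_table <- function(bonds, n_atoms) {
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("i", "j") %in% names(bonds)))
  if (!"order" %in% names(bonds)) bonds$order <- "1"
  if (!"in_ring" %in% names(bonds)) bonds$in_ring <- NA
  bonds$order <- as.character(bonds$order)
  if (any(bonds$i == bonds$j)) stop("bond with i == j")
  if (any(bonds$i < 1 | bonds$j < 1 | bonds$i > n_atoms | bonds$j > n_atoms)) {
    stop("bond index out of range")
  }
  # store each bond once, i < j
  swap <- bonds$i > bonds$j
  tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  bonds <- dplyr::distinct(bonds, .data$i, .data$j, .keep_all = TRUE)
  bonds
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms, %s bonds, net charge %+d\n",
              if (nzchar(x$title)) x$title else "(untitled)",
              nrow(x$atoms),
              if (is.null(x$bonds)) "no" else as.character(nrow(x$bonds)),
              x$net_charge))
  invisible(x)
}

#' Construct a hierarchical structure model
#'
#' A `structure_model` holds an atom table plus a classification of each atom
#' as `protein`, `water`, `ion` or `cofactor` (column `group`). Residues are
#' ordered within each chain by `(resnum, icode)`.
#'
#' @param atoms an [atom_table()]; a `group` column is honoured if present,
#'   otherwise atoms are classified with [classify_atoms()].
#' @param title free-text label.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  validate_atom_table(atoms)
  if (!"group" %in% names(atoms)) atoms$group <- classify_atoms(atoms)
  atoms <- atoms |>
    dplyr::arrange(.data$chain, .data$resnum, .data$icode) |>
    (\(a) { a$row <- seq_len(nrow(a)); a })()
  atoms$row <- NULL
  structure(list(atoms = atoms, title = title), class = "structure_model")
}

#' @rdname structure_model
#' @export
classify_atoms <- function(atoms) {
  grp <- rep("protein", nrow(atoms))
  water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  grp[water] <- "water"
  # single-atom hetero residues whose element is a recognised metal (or a
  # halide counter-ion) are ions; remaining hetero residues are cofactors
  key <- residue_key(atoms)
  n_per_res <- stats::ave(seq_along(key), key, FUN = length)
  ion <- atoms$is_hetero & !water & n_per_res == 1 &
    (atoms$element %in% .metal_elements | atoms$element %in% c("Cl", "Br", "I"))
  grp[ion] <- "ion"
  grp[atoms$is_hetero & !water & !ion] <- "cofactor"
  grp
}

#' @export
print.structure_model <- function(x, ...) {
  tab <- table(x$atoms$group)
  res <- residue_table(x$atoms)
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, %d chain(s)\n",
              if (nzchar(x$title)) x$title else "(untitled)",
              nrow(x$atoms), nrow(res), length(unique(x$atoms$chain))))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Subsets by classification -------------------------------------------------

#' @rdname structure_model
#' @param x a `structure_model`.
#' @export
waters <- function(x) dplyr::filter(x$atoms, .data$group == "water")

#' @rdname structure_model
#' @export
ions <- function(x) dplyr::filter(x$atoms, .data$group == "ion")

#' @rdname structure_model
#' @export
cofactors <- function(x) dplyr::filter(x$atoms, .data$group == "cofactor")
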