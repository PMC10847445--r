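#' Parse a Tripos Mol2 document
#'
#' Reads the `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` sections of a Mol2
#' document into a [molecule()]. Partial charges, when present, are kept and
#' the molecule's net charge is their sum rounded to the nearest integer.
#' Bond ring membership is perceived from the molecular graph.
#'
#' @param text Mol2 document as a string, character vector of lines, or path.
#' @return a [molecule()].
#' @export
parse_mol2 <- function(text) {
  lines <- as_lines(text)
  sect <- cumsum(grepl("^@<TRIPOS>", lines))
  tags <- sub("^@<TRIPOS>", "", grep("^@<TRIPOS>", lines, value = TRUE))
  if (!"MOLECULE" %in% tags) stop("Mol2 input lacks a MOLECULE section")
  if (!"ATOM" %in% tags) stop("Mol2 input lacks an ATOM section")
  if (!"BOND" %in% tags) stop("Mol2 input lacks a BOND section")

  section <- function(tag) {
    idx <- which(tags == tag)[1]
    body <- lines[sect == idx]
    body <- body[-1]
    body[nzchar(trimws(body)) & !grepl("^#", body)]
  }

  mol_head <- section("MOLECULE")
  title <- if (length(mol_head) >= 1) trimws(mol_head[1]) else ""
  counts <- if (length(mol_head) >= 2) {
    suppressWarnings(as.integer(strsplit(trimws(mol_head[2]), "\\s+")[[1]]))
  } else integer()

  atom_lines <- section("ATOM")
  af <- strsplit(trimws(atom_lines), "\\s+")
  if (any(lengths(af) < 6)) stop("malformed Mol2 ATOM record")
  if (length(counts) >= 1 && !is.na(counts[1]) &&
      length(af) != counts[1]) {
    stop(sprintf("Mol2 atom count mismatch: header says %d, ATOM section has %d",
                 counts[1], length(af)))
  }
  get <- function(k) vapply(af, function(f) f[k], "")
  sybyl <- get(6)
  element <- normalize_element(sub("\\..*$", "", sybyl))
  pq <- if (all(lengths(af) >= 9)) suppressWarnings(as.numeric(get(9))) else NA_real_

  atoms <- tibble::tibble(
    serial = as.integer(get(1)), name = get(2), element = element,
    x = as.numeric(get(3)), y = as.numeric(get(4)), z = as.numeric(get(5)),
    formal_charge = 0L, partial_charge = as.double(pq),
    chain = "A",
    resname = if (all(lengths(af) >= 8)) substr(get(8), 1, 3) else "LIG",
    resnum = if (all(lengths(af) >= 7)) as.integer(get(7)) else 1L,
    icode = "", altloc = "", is_hetero = TRUE
  )
  validate_atom_table(atoms)

  bond_lines <- section("BOND")
  bf <- strsplit(trimws(bond_lines), "\\s+")
  if (any(lengths(bf) < 4)) stop("malformed Mol2 BOND record")
  bget <- function(k) vapply(bf, function(f) f[k], "")
  ord <- tolower(bget(4))
  ord[ord == "am"] <- "1"   # amide bonds are single for rotation purposes;
                            # the amide pattern is re-detected from orders+O
  ord[ord %in% c("un", "nc", "du")] <- "1"
  serial_to_row <- match(as.integer(bget(2)), atoms$serial)
  serial_to_row_j <- match(as.integer(bget(3)), atoms$serial)
  if (anyNA(serial_to_row) || anyNA(serial_to_row_j)) {
    stop("Mol2 BOND record references unknown atom id")
  }
  bonds <- tibble::tibble(i = serial_to_row, j = serial_to_row_j,
                          order = ord, in_ring = NA)
  net <- if (all(is.finite(atoms$partial_charge))) {
    as.integer(round(sum(atoms$partial_charge)))
  } else 0L

  mol <- molecule(atoms, bonds, net_charge = net, title = title)
  mol$bonds <- flag_ring_bonds(mol$bonds, nrow(mol$atoms))
  mol
}

#' Read / write XYZ geometries
#'
#' Plain XYZ: atom count, a comment line (which may carry the net charge as
#' `charge=N`), then `element x y z` rows.
#'
#' @param text XYZ document (string, lines, or path).
#' @return `read_xyz()`: a [molecule()] without bonds; `write_xyz()`:
#'   invisibly, the lines written.
#' @export
read_xyz <- function(text) {
  lines <- as_lines(text)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header")
  comment <- if (length(lines) >= 2) lines[2] else ""
  q <- 0L
  m <- regmatches(comment, regexpr("charge=-?[0-9]+", comment))
  if (length(m) == 1 && nzchar(m)) q <- as.integer(sub("charge=", "", m))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  atoms <- tibble::tibble(
    serial = seq_len(n),
    name = vapply(rows, `[`, "", 1),
    element = normalize_element(vapply(rows, `[`, "", 1)),
    x = as.numeric(vapply(rows, `[`, "", 2)),
    y = as.numeric(vapply(rows, `[`, "", 3)),
    z = as.numeric(vapply(rows, `[`, "", 4)),
    formal_charge = 0L, partial_charge = NA_real_,
    chain = "A", resname = "LIG", resnum = 1L, icode = "", altloc = "",
    is_hetero = TRUE
  )
  molecule(atoms, net_charge = q, title = trimws(comment))
}

#' @rdname read_xyz
#' @param x object carrying an atom table (and optionally a net charge).
#' @param path optional output path.
#' @export
write_xyz <- function(x, path = NULL) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  q <- if (is.data.frame(x)) sum(atoms$formal_charge) else
    (x$net_charge %||% sum(atoms$formal_charge))
  lines <- c(
    sprintf("%d", nrow(atoms)),
    sprintf("charge=%d", as.integer(q)),
    sprintf("%-2s %14.8f %14.8f %14.8f", atoms$element, atoms$x, atoms$y,
            atoms$z)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
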