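#' Parse a PDB document
#'
#' Reads ATOM/HETATM records from PDB v3.3 fixed-column text and returns a
#' [structure_model()]. Alternate locations are resolved at parse time: for
#' atoms with a non-blank altloc, only records whose altloc matches
#' `altloc_policy` are kept (blank altlocs are always kept). Water residues
#' (HOH/WAT) are classified as waters; single-atom HETATM records whose
#' element is a recognised metal (or halide) are classified as ions and given
#' their conventional formal charge (Zn +2, Ca +2, Mg +2, Na +1, K +1, Cl -1,
#' ...), overridable via `ion_charges`.
#'
#' @param text a PDB document as a single string or character vector of lines,
#'   or a path to a file.
#' @param altloc_policy single letter kept for duplicated altloc records
#'   (default `"A"`).
#' @param ion_charges named integer vector overriding the built-in ion charge
#'   table (names are residue names, e.g. `c(ZN = 2L)`).
#' @return a [structure_model()].
#' @export
parse_pdb <- function(text, altloc_policy = "A", ion_charges = NULL) {
  lines <- as_lines(text)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty PDB input")
  }
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0) stop("no ATOM/HETATM records in PDB input")

  parse_one <- function(ln, lineno) {
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d: fewer than 54 columns",
                   lineno))
    }
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    resnum <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(c(serial, x, y, z, resnum))) {
      stop(sprintf("malformed PDB record at line %d: non-numeric fixed field",
                   lineno))
    }
    list(
      record = substr(ln, 1, 6), serial = serial,
      name = trimws(substr(ln, 13, 16)), altloc = trimws(substr(ln, 17, 17)),
      resname = trimws(substr(ln, 18, 20)), chain = trimws(substr(ln, 22, 22)),
      resnum = resnum, icode = trimws(substr(ln, 27, 27)),
      x = x, y = y, z = z,
      element = trimws(substr(ln, 77, 78)),
      charge = trimws(substr(ln, 79, 80))
    )
  }

  parsed <- purrr::map2(lines[keep], keep, parse_one)
  df <- dplyr::bind_rows(purrr::map(parsed, tibble::as_tibble))

  # element: columns 77-78, falling back to the leading letters of the name
  elem <- normalize_element(df$element)
  fallback <- is.na(elem) | !nzchar(df$element)
  if (any(fallback)) {
    guess <- sub("^[0-9']*", "", df$name[fallback])
    two <- normalize_element(substr(guess, 1, 2))
    one <- normalize_element(substr(guess, 1, 1))
    pick <- ifelse(two %in% .recognized_elements, two,
                   ifelse(one %in% .recognized_elements, one, NA))
    elem[fallback] <- pick
  }
  if (anyNA(elem)) {
    bad <- keep[which(is.na(elem))[1]]
    stop(sprintf("cannot infer element at line %d", bad))
  }
  if (!all(elem %in% .recognized_elements)) {
    bad <- setdiff(unique(elem), .recognized_elements)
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "))
  }

  fc <- rep(0L, nrow(df))
  has_q <- grepl("^[0-9][+-]$", df$charge)
  fc[has_q] <- as.integer(substr(df$charge[has_q], 1, 1)) *
    ifelse(substr(df$charge[has_q], 2, 2) == "-", -1L, 1L)

  atoms <- tibble::tibble(
    serial = df$serial, name = df$name, element = elem,
    x = df$x, y = df$y, z = df$z,
    formal_charge = fc, partial_charge = NA_real_,
    chain = ifelse(nzchar(df$chain), df$chain, "A"),
    resname = df$resname, resnum = df$resnum, icode = df$icode,
    altloc = df$altloc, is_hetero = df$record == "HETATM"
  )

  # altloc policy: keep blank records and the policy copy
  atoms <- atoms[atoms$altloc == "" | atoms$altloc == altloc_policy, ]
  if (nrow(atoms) == 0) stop("no atoms left after altloc filtering")

  model <- structure_model(atoms)

  # conventional charges on classified ions
  tab <- .default_ion_charges
  if (!is.null(ion_charges)) tab[names(ion_charges)] <- as.integer(ion_charges)
  is_ion <- model$atoms$group == "ion"
  known <- toupper(model$atoms$resname[is_ion]) %in% names(tab)
  model$atoms$formal_charge[is_ion][known] <-
    tab[toupper(model$atoms$resname[is_ion][known])]
  model
}

#' Write atoms as PDB text
#'
#' Serialises an atom table, [molecule()], [structure_model()] or
#' `pocket_model` to PDB v3.3 fixed columns (ATOM/HETATM + TER + END).
#' Formal charges are written in columns 79-80 so that a parse/write/parse
#' round trip preserves them.
#'
#' @param x object carrying an atom table.
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly, the character vector of lines.
#' @export
write_pdb <- function(x, path = NULL) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  fmt_q <- function(q) {
    ifelse(q == 0, "  ", sprintf("%d%s", abs(q), ifelse(q < 0, "-", "+")))
  }
  # atom-name column convention: 1-letter elements start in column 14
  nm <- ifelse(nchar(atoms$element) == 1 & nchar(atoms$name) < 4,
               sprintf(" %-3s", atoms$name), sprintf("%-4s", atoms$name))
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
    ifelse(atoms$is_hetero, "HETATM", "ATOM"),
    atoms$serial %% 100000L, nm, atoms$altloc, atoms$resname,
    atoms$chain, atoms$resnum %% 10000L, atoms$icode,
    atoms$x, atoms$y, atoms$z, 1, 0,
    toupper(atoms$element), fmt_q(atoms$formal_charge)
  )
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}
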