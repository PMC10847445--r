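#' Perceive bonds from geometry
#'
#' Adds bonds between atoms whose distance is below `tolerance` times the sum
#' of their covalent radii. Hydrogens are bonded only to their nearest heavy
#' atom (never to other hydrogens, and only once). Ring membership is then
#' computed from the molecular graph.
#'
#' @param mol a [molecule()] (bonds, if any, are replaced).
#' @param tolerance multiplier on the covalent-radius sum (default 1.3).
#' @return the molecule with a populated bond table (all orders `"1"`).
#' @export
perceive_bonds <- function(mol, tolerance = 1.3) {
  atoms <- mol$atoms
  n <- nrow(atoms)
  if (n < 2) {
    mol$bonds <- tibble::tibble(i = integer(), j = integer(),
                                order = character(), in_ring = logical())
    return(mol)
  }
  xyz <- coords(atoms)
  d <- as.matrix(stats::dist(xyz))
  rad <- covalent_radius(atoms$element)
  thr <- outer(rad, rad, `+`) * tolerance
  adj <- d < thr & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  bonds <- tibble::tibble(i = idx[, 1], j = idx[, 2], order = "1",
                          in_ring = NA)
  # hydrogens: keep a single partner each — the nearest heavy atom, or the
  # nearest atom of any kind when no heavy partner is in range (H2)
  is_h <- atoms$element == "H"
  keep <- rep(TRUE, nrow(bonds))
  for (h in which(is_h)) {
    touch <- which((bonds$i == h | bonds$j == h) & keep)
    if (length(touch) == 0) next
    partner <- ifelse(bonds$i[touch] == h, bonds$j[touch], bonds$i[touch])
    cand <- touch[!is_h[partner]]
    if (length(cand) == 0) cand <- touch
    keep[touch] <- FALSE
    dd <- d[cbind(rep(h, length(cand)),
                  ifelse(bonds$i[cand] == h, bonds$j[cand], bonds$i[cand]))]
    keep[cand[which.min(dd)]] <- TRUE
  }
  bonds <- bonds[keep, ]
  mol$bonds <- flag_ring_bonds(bonds, n)
  mol
}

# Ring membership: a bond is in a ring iff it is not a bridge of the graph.
flag_ring_bonds <- function(bonds, n_atoms) {
  if (nrow(bonds) == 0) {
    bonds$in_ring <- logical(0)
    return(bonds)
  }
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_atoms - igraph::vcount(g)))
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(bonds))
  in_ring[as.integer(br)] <- FALSE
  bonds$in_ring <- in_ring
  bonds
}

#' Count rotatable bonds
#'
#' A bond is counted as rotatable when it is an acyclic single bond between
#' two heavy atoms, each endpoint has at least one further heavy-atom
#' neighbour (so terminal groups such as methyls do not count), and the bond
#' is not an amide C-N bond (a C-N single bond where the carbon also carries
#' a double-bonded oxygen). The convention is configurable via
#' `exclude_amide`. The count is invariant under atom reordering and rigid
#' motion since it depends only on the molecular graph.
#'
#' @param mol a [molecule()] with bonds (see [perceive_bonds()]).
#' @param exclude_amide exclude amide C-N bonds (default `TRUE`).
#' @return non-negative integer count.
#' @export
count_rotatable_bonds <- function(mol, exclude_amide = TRUE) {
  if (is.null(mol$bonds)) {
    stop("molecule has no bonds; run perceive_bonds() first")
  }
  bonds <- mol$bonds
  if (nrow(bonds) == 0) return(0L)
  if (anyNA(bonds$in_ring)) bonds <- flag_ring_bonds(bonds, nrow(mol$atoms))
  heavy <- mol$atoms$element != "H"
  # heavy-neighbour counts per atom
  deg <- tabulate(c(bonds$i[heavy[bonds$j]], bonds$j[heavy[bonds$i]]),
                  nbins = nrow(mol$atoms))
  cand <- bonds$order == "1" & !bonds$in_ring &
    heavy[bonds$i] & heavy[bonds$j] &
    deg[bonds$i] >= 2 & deg[bonds$j] >= 2
  if (exclude_amide && any(cand)) {
    elem <- mol$atoms$element
    carbonyl <- rep(FALSE, nrow(mol$atoms))
    dbl_o <- bonds$order == "2" &
      ((elem[bonds$i] == "C" & elem[bonds$j] == "O") |
       (elem[bonds$j] == "C" & elem[bonds$i] == "O"))
    carbonyl[c(bonds$i[dbl_o], bonds$j[dbl_o])] <- TRUE
    carbonyl[elem != "C"] <- FALSE
    amide <- (elem[bonds$i] == "C" & carbonyl[bonds$i] & elem[bonds$j] == "N") |
             (elem[bonds$j] == "C" & carbonyl[bonds$j] & elem[bonds$i] == "N")
    cand <- cand & !amide
  }
  sum(cand)
}
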