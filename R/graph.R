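# Molecular-graph utilities: ring perception, rotatable bonds, fragment
# partitioning for torsion driving.

mol_graph <- function(mol) {
  igraph::make_graph(
    edges = as.vector(t(cbind(mol$bonds$i, mol$bonds$j))),
    n = n_atoms(mol), directed = FALSE
  )
}

# TRUE for each bond that lies in a ring (an edge is in a cycle iff it is
# not a bridge).
ring_bond_flags <- function(mol) {
  if (nrow(mol$bonds) == 0) return(logical(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(mol$bonds))
  if (length(br) > 0) {
    ends <- igraph::ends(g, br)
    key_bridge <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
    key_bond <- paste(mol$bonds$i, mol$bonds$j)
    flags <- !(key_bond %in% key_bridge)
  } else {
    flags <- rep(TRUE, nrow(mol$bonds))
  }
  flags
}

# Indices of atoms bonded to atom k.
neighbors_of <- function(mol, k) {
  c(mol$bonds$j[mol$bonds$i == k], mol$bonds$i[mol$bonds$j == k])
}

h_neighbors <- function(mol, k) {
  nb <- neighbors_of(mol, k)
  sort(nb[mol$elements[nb] == "H"])
}

heavy_degree <- function(mol, k) {
  sum(mol$elements[neighbors_of(mol, k)] != "H")
}

bond_order_sum <- function(mol, k) {
  sum(mol$bonds$order[mol$bonds$i == k | mol$bonds$j == k])
}

#' Rotatable bonds of a molecule
#'
#' A bond is rotatable when it is a single, acyclic bond between two
#' non-terminal heavy atoms -- each endpoint must carry at least one further
#' heavy-atom neighbor, so bonds to hydrogens or to terminal groups never
#' count.  Amide C-N bonds are counted; the convention is deliberately the
#' simplest self-consistent one, since the step-count heuristic downstream
#' only needs a monotone flexibility measure.
#'
#' @param mol A [molecule()] with perceived bonds.
#' @return Data frame of rotatable bonds (columns `i`, `j`, `order`).
#' @export
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(empty_bonds())
  in_ring <- ring_bond_flags(mol)
  keep <- logical(nrow(b))
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    if (b$order[r] != 1L || in_ring[r]) next
    if (mol$elements[i] == "H" || mol$elements[j] == "H") next
    # non-terminal: each endpoint bonded to >= 1 heavy atom besides the other
    hi <- heavy_degree(mol, i) - 1L
    hj <- heavy_degree(mol, j) - 1L
    keep[r] <- hi >= 1L && hj >= 1L
  }
  b[keep, , drop = FALSE]
}

#' Count rotatable bonds (ROT)
#'
#' The flexibility count feeding the normal-walk step formula; see
#' [rotatable_bonds()] for the convention.
#'
#' @param mol A [molecule()] with perceived bonds.
#' @return Non-negative integer.
#' @export
rotatable_bond_count <- function(mol) {
  nrow(rotatable_bonds(mol))
}

# Atom indices of the connected component containing `anchor` after
# deleting the i-j bond.  Used to pick the fragment that rotates about a
# torsion axis.
bond_side <- function(mol, i, j, anchor) {
  g <- mol_graph(mol)
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
  comp <- igraph::components(g)$membership
  which(comp == comp[anchor])
}
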