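# Built-in conformer energy model: a purely repulsive steric clash score.
#
# E = sum over nonbonded pairs of k * max(0, 0.8*(rvdw_i + rvdw_j) - d_ij)^2
# with k = 100 kcal mol^-1 A^-2.  Pairs that are bonded (1-2) or share a
# bonded neighbor (1-3) are excluded: their distances are fixed by bond
# lengths and angles, not by torsions, so penalizing them would add a large
# constant to every geometry.  The score carries no torsional or attractive
# terms -- it exists to order clashed against open geometries, and any
# physics-grade energy model can replace it through the scorer/generator
# contracts.

.CLASH_K <- 100       # kcal mol^-1 A^-2
.CLASH_SCALE <- 0.8   # fraction of the vdW-radius sum where the penalty starts

# Logical mask over dist()-ordered atom pairs marking excluded (1-2, 1-3)
# pairs.  Cache per molecule when scoring many conformers.
clash_exclusion_mask <- function(mol) {
  n <- n_atoms(mol)
  excl <- matrix(FALSE, n, n)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) excl[b$i[r], b$j[r]] <- excl[b$j[r], b$i[r]] <- TRUE
  adj <- lapply(seq_len(n), function(k) neighbors_of(mol, k))
  for (k in seq_len(n)) {
    nb <- adj[[k]]
    if (length(nb) > 1) {
      for (a in nb) for (b2 in nb) if (a != b2) excl[a, b2] <- TRUE
    }
  }
  # dist() stores the lower triangle column-major; extract in the same order
  as.vector(excl[lower.tri(excl)])
}

#' Steric clash score of a geometry
#'
#' Purely repulsive pairwise penalty (kcal/mol) over nonbonded atom pairs;
#' zero for any geometry with no van der Waals overlap.  This is the
#' package's built-in energy model for ranking generated conformers.
#'
#' @param mol A [molecule()] providing elements and bonds.
#' @param coords Optional N x 3 coordinate matrix; defaults to the
#'   molecule's own geometry.
#' @param exclusion Optional precomputed [clash_exclusion_mask()].
#' @return Scalar energy in kcal/mol (>= 0).
#' @export
clash_energy <- function(mol, coords = mol$coords, exclusion = NULL) {
  n <- n_atoms(mol)
  if (n < 2) return(0)
  if (is.null(exclusion)) exclusion <- clash_exclusion_mask(mol)
  d <- as.vector(stats::dist(coords))
  r <- vdw_radius(mol$elements)
  # pairwise vdW-radius sums in dist() order
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  rsum <- r[idx[, 1]] + r[idx[, 2]]
  overlap <- pmax(0, .CLASH_SCALE * rsum - d)
  overlap[exclusion] <- 0
  .CLASH_K * sum(overlap^2)
}
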