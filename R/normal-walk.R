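# Similarity reduction: Kabsch/SVD superposition RMSD, ensemble RMSD
# statistics, and the stepped "normal walk" that removes redundant
# conformers from oversized ensembles.
#
# The walk summarizes an ensemble by the RMSD of every member to a
# reference conformer (the energy minimum), then traverses that RMSD
# distribution from its trailing tail (minimum) to its leading tail
# (maximum) in a number of steps proportional to the molecule's
# flexibility: steps = 20 * ROT, where ROT is the rotatable-bond count and
# 20 is a heuristic sampling density.  Conformers falling below the
# similarity score at each walk position are removed, leaving one
# representative per step.

#' Minimum RMSD under rigid superposition (Kabsch/SVD)
#'
#' Centers both coordinate sets, forms the 3x3 cross-covariance, takes its
#' SVD and applies the determinant sign correction so reflections are
#' excluded, then returns the root-mean-square deviation after the optimal
#' rotation.  Atom correspondence is positional: both matrices must share
#' one atom ordering.
#'
#' @param P,Q N x 3 coordinate matrices (Angstrom) with identical atom
#'   ordering.
#' @return RMSD in Angstrom; symmetric in its arguments.
#' @export
svd_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3) {
    stop("P and Q must be N x 3 matrices with equal atom counts")
  }
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))          # t(Pc) %*% Qc
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- Qc - Pc %*% t(rot)
  sqrt(sum(diff^2) / n)
}

#' Normal-walk step count
#'
#' steps = 20 * ROT, floored at 1 so rigid molecules (ROT = 0) still get a
#' single walk position.
#'
#' @param rot Non-negative rotatable-bond count.
#' @return Positive integer step count.
#' @export
walk_steps <- function(rot) {
  if (length(rot) != 1 || is.na(rot) || rot < 0 || rot != as.integer(rot)) {
    stop("rot must be a single non-negative integer")
  }
  max(1L, 20L * as.integer(rot))
}

#' Ensemble RMSD statistics
#'
#' Computes the per-conformer superposition RMSD to a reference conformer
#' (the lowest-energy member; ties and missing energies fall back to the
#' first), summarizes the distribution (mean, population SD, min, max over
#' the non-reference members), and attaches the walk step count.
#'
#' @param ens An [ensemble()] with >= 2 conformers.
#' @param rot Rotatable-bond count; defaults to
#'   [rotatable_bond_count()] of the ensemble's molecule.
#' @return An object of class `similarity_report`: list with
#'   `reference_id`, `reference_index`, `rmsds` (named, reference included
#'   at 0), `mean`, `sd`, `rmsd_min`, `rmsd_max`, `steps`.
#' @export
ensemble_rmsd_stats <- function(ens, rot = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  if (length(ens) < 2) stop("need >= 2 conformers to compute RMSD statistics")
  if (is.null(rot)) rot <- rotatable_bond_count(ens$molecule)
  ref_idx <- reference_index(ens)
  ref <- ens$conformers[[ref_idx]]$coords
  rmsds <- vapply(ens$conformers, function(cf) svd_rmsd(ref, cf$coords),
                  numeric(1))
  names(rmsds) <- ensemble_ids(ens)
  others <- rmsds[-ref_idx]
  structure(
    list(
      reference_id = ens$conformers[[ref_idx]]$conf_id,
      reference_index = ref_idx,
      rmsds = rmsds,
      mean = mean(others),
      sd = sqrt(mean((others - mean(others))^2)),
      rmsd_min = min(others),
      rmsd_max = max(others),
      steps = walk_steps(rot)
    ),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(paste0("<similarity_report> ref %s: mean %.3f, sd %.3f, ",
                     "range [%.3f, %.3f] A, %d walk steps\n"),
              x$reference_id, x$mean, x$sd, x$rmsd_min, x$rmsd_max, x$steps))
  invisible(x)
}

# Index of the reference conformer: lowest energy, ties to the lowest
# index; all energies missing -> first conformer.
reference_index <- function(ens) {
  e <- ensemble_energies(ens)
  if (all(is.na(e))) return(1L)
  which.min(replace(e, is.na(e), Inf))
}

#' Reduce a redundant ensemble by the normal walk
#'
#' Ensembles at or below `size_threshold` conformers are already an
#' acceptable final output and pass through unchanged.  Larger ensembles
#' are reduced: the reference-RMSD range `[rmsd_min, rmsd_max]` is
#' partitioned into `steps` equal-width walk intervals (trailing to leading
#' tail) and each occupied interval keeps exactly one representative, its
#' lowest-energy member (ties to the lowest index); everything else in the
#' interval falls below that walk position's similarity score and is
#' removed.  The reference conformer always survives.  A quantile variant
#' places the interval edges at quantiles of the fitted normal distribution
#' N(mean, sd) instead of spacing them evenly.
#'
#' @param ens An [ensemble()].
#' @param size_threshold Bypass threshold (default 50, the final-output
#'   rule); ensembles with `length <= size_threshold` are returned as is.
#' @param rot Rotatable-bond count; defaults to the molecule's.
#' @param variant `"equal"` (default) for equal-width walk intervals,
#'   `"quantile"` for edges at normal-distribution quantiles.
#' @return The reduced [ensemble()], preserving input order, with the
#'   similarity report attached as attribute `"report"` when reduction ran.
#' @export
normal_walk_reduce <- function(ens, size_threshold = 50L, rot = NULL,
                               variant = c("equal", "quantile")) {
  stopifnot(inherits(ens, "ensemble"))
  variant <- match.arg(variant)
  if (length(ens) <= size_threshold) return(ens)
  rep_ <- ensemble_rmsd_stats(ens, rot = rot)
  rmsds <- rep_$rmsds
  energies <- ensemble_energies(ens)
  energies <- replace(energies, is.na(energies), Inf)
  ref_idx <- rep_$reference_index

  if (rep_$rmsd_max - rep_$rmsd_min <= .Machine$double.eps^0.5) {
    # degenerate distribution: every member is the reference's twin
    warning("degenerate RMSD distribution (min == max); keeping the ",
            "reference and one representative")
    keep <- sort(unique(c(ref_idx, setdiff(seq_along(rmsds), ref_idx)[1])))
    out <- ensemble_subset(ens, keep)
    attr(out, "report") <- rep_
    return(out)
  }

  edges <- if (variant == "equal") {
    seq(rep_$rmsd_min, rep_$rmsd_max, length.out = rep_$steps + 1L)
  } else {
    p <- seq(0, 1, length.out = rep_$steps + 1L)
    q <- stats::qnorm(p, mean = rep_$mean, sd = max(rep_$sd, 1e-12))
    pmin(pmax(q, rep_$rmsd_min), rep_$rmsd_max)
  }
  # assign non-reference members to walk intervals; right-closed last bin
  member <- setdiff(seq_along(rmsds), ref_idx)
  bin <- findInterval(rmsds[member], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  keep <- ref_idx
  for (b in unique(bin)) {
    in_bin <- member[bin == b]
    best <- in_bin[order(energies[in_bin], in_bin)][1]
    keep <- c(keep, best)
  }
  keep <- sort(unique(keep))
  out <- ensemble_subset(ens, keep)
  attr(out, "report") <- rep_
  out
}
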