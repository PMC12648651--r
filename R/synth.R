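# Synthetic ensemble generation for testing and benchmarking.
#
# Real conformer ensembles differ by torsions; these fixtures differ by
# isotropic Gaussian coordinate noise plus a random rigid transform.  That
# is enough to exercise superposition RMSD, diversity filtering and the
# normal walk with a known ground truth, while staying far simpler than
# real conformational variation (see the methods vignette for what this
# does and does not emulate).

# Uniform random rotation matrix via a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a synthetic perturbed-coordinate ensemble
#'
#' Produces `n` conformers equal to a base geometry plus i.i.d. Gaussian
#' coordinate noise, each then rigidly rotated and translated at random.
#' Energies are assigned by the built-in [clash_energy()] model.  Fully
#' reproducible for a fixed seed.
#'
#' @param mol A [molecule()]; its own coordinates are the default base.
#' @param n Number of conformers (>= 1).
#' @param noise_sd Per-coordinate Gaussian noise standard deviation
#'   (Angstrom, >= 0).
#' @param seed Integer RNG seed.
#' @param base Optional [conformer()] supplying the base geometry.
#' @param rank_label Rank tag for the resulting [ensemble()].
#' @return An [ensemble()] of `n` conformers with clash-score energies.
#' @export
synth_ensemble <- function(mol, n, noise_sd = 0.3, seed = 1L, base = NULL,
                           rank_label = 1L) {
  stopifnot(inherits(mol, "molecule"))
  if (n < 1) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  base_coords <- if (is.null(base)) mol$coords else base$coords
  if (nrow(base_coords) != n_atoms(mol)) {
    stop("base conformer atom count does not match the molecule")
  }
  excl <- clash_exclusion_mask(mol)
  nat <- n_atoms(mol)
  confs <- withr::with_seed(seed, lapply(seq_len(n), function(k) {
    noisy <- base_coords +
      matrix(stats::rnorm(nat * 3, sd = noise_sd), nat, 3)
    rot <- random_rotation()
    shift <- stats::runif(3, -5, 5)
    coords <- sweep(noisy %*% t(rot), 2, -shift)
    conformer(sprintf("synth_%d", k), coords,
              energy = clash_energy(mol, coords, exclusion = excl))
  }))
  ensemble(mol, confs, rank_label = rank_label)
}
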