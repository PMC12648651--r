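# Conformer ensemble generation.
#
# The pipeline asks a generator for a pool of candidate geometries per
# charge model and then distills the pool with a similarity + energy
# filter, targeting a configurable number (default 1000) of unique
# low-energy conformers.  Falling short of the target is normal: redundancy
# is removed again downstream, so an undersized ensemble is not an error.
# The built-in generator drives every rotatable bond over a fixed torsion
# grid -- exhaustive on small systems, seeded-subsampled when the grid
# outgrows the target -- and scores each geometry with the clash model.
# Any external generator can be plugged in through the same contract.

#' Generator configuration
#'
#' @param num_of_conf Target number of unique low-energy conformers
#'   (default 1000).
#' @param rmsd_cutoff Superposed-RMSD similarity cutoff in Angstrom below
#'   which two conformers count as duplicates (default 0.5).
#' @param energy_window Energy window in kcal/mol above the ensemble
#'   minimum; higher-energy conformers are discarded (default 50).
#' @param torsion_grid_deg Torsion grid spacing in degrees; must divide
#'   360 (default 120, i.e. three settings per rotatable bond).
#' @param seed Integer seed used when the torsion grid must be subsampled.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(num_of_conf = 1000L, rmsd_cutoff = 0.5,
                             energy_window = 50, torsion_grid_deg = 120,
                             seed = 1L) {
  if (num_of_conf < 1) stop("num_of_conf must be >= 1")
  if (rmsd_cutoff < 0) stop("rmsd_cutoff must be >= 0")
  if (energy_window <= 0) stop("energy_window must be > 0")
  if (360 %% torsion_grid_deg != 0) stop("torsion_grid_deg must divide 360")
  structure(
    list(num_of_conf = as.integer(num_of_conf), rmsd_cutoff = rmsd_cutoff,
         energy_window = energy_window,
         torsion_grid_deg = as.integer(torsion_grid_deg),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Rodrigues rotation of points about a unit axis through `origin`.
rotate_about_axis <- function(coords, origin, axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  p <- sweep(coords, 2, origin)
  cosn <- cos(angle_rad); sinn <- sin(angle_rad)
  rot <- p * cosn +
    (cbind(u[2] * p[, 3] - u[3] * p[, 2],
           u[3] * p[, 1] - u[1] * p[, 3],
           u[1] * p[, 2] - u[2] * p[, 1])) * sinn +
    outer(as.vector(p %*% u), u) * (1 - cosn)
  sweep(rot, 2, -origin)
}

#' Built-in deterministic torsion-grid conformer generator
#'
#' Enumerates all combinations of torsion settings (360 /
#' `torsion_grid_deg` values per rotatable bond), rotating the smaller
#' molecular fragment about each bond, and assigns each geometry a
#' [clash_energy()].  When the full grid exceeds `num_of_conf`
#' combinations, a seeded uniform subsample of combinations is generated
#' instead.  A rigid molecule (no rotatable bonds) yields its single input
#' geometry.
#'
#' @param model A `charge_model` with a 3-D geometry.
#' @param config A [generator_config()].
#' @return List of [conformer()] objects with energies.
#' @export
torsion_grid_generate <- function(model, config = generator_config()) {
  stopifnot(inherits(model, "charge_model"))
  mol <- model$molecule
  base <- model$geometry$coords
  excl <- clash_exclusion_mask(mol)
  rb <- rotatable_bonds(mol)
  n_bonds <- nrow(rb)
  if (n_bonds == 0) {
    return(list(conformer("conf_1", base,
                          energy = clash_energy(mol, base, exclusion = excl))))
  }
  n_set <- 360L %/% config$torsion_grid_deg
  angles <- (seq_len(n_set) - 1L) * config$torsion_grid_deg * pi / 180
  # the atoms each bond rotates: the smaller side of the split
  frags <- vector("list", n_bonds)
  axes <- vector("list", n_bonds)
  for (r in seq_len(n_bonds)) {
    i <- rb$i[r]; j <- rb$j[r]
    side_j <- bond_side(mol, i, j, j)
    side_i <- setdiff(seq_len(n_atoms(mol)), side_j)
    if (length(side_j) <= length(side_i)) {
      frags[[r]] <- setdiff(side_j, j)
      axes[[r]] <- c(i, j)
    } else {
      frags[[r]] <- setdiff(side_i, i)
      axes[[r]] <- c(j, i)
    }
  }
  total <- n_set^n_bonds
  combos <- if (total <= config$num_of_conf) {
    as.matrix(do.call(expand.grid, rep(list(seq_len(n_set) - 1L), n_bonds)))
  } else {
    # seeded uniform subsample of distinct combination indices
    withr::with_seed(config$seed, {
      if (total <= .Machine$integer.max) {
        ids <- sample.int(total, config$num_of_conf) - 1
      } else {
        ids <- unique(floor(stats::runif(3 * config$num_of_conf) * total))
        ids <- ids[seq_len(min(length(ids), config$num_of_conf))]
      }
      sapply(seq_len(n_bonds), function(b) (ids %/% n_set^(b - 1)) %% n_set)
    })
  }
  combos <- matrix(as.integer(combos), ncol = n_bonds)
  lapply(seq_len(nrow(combos)), function(k) {
    coords <- base
    for (r in seq_len(n_bonds)) {
      setting <- combos[k, r]
      if (setting == 0L) next
      ax <- axes[[r]]
      coords[frags[[r]], ] <- rotate_about_axis(
        coords[frags[[r]], , drop = FALSE],
        origin = coords[ax[1], ], axis = coords[ax[2], ] - coords[ax[1], ],
        angle_rad = angles[setting + 1L]
      )
    }
    conformer(sprintf("conf_%d", k), coords,
              energy = clash_energy(mol, coords, exclusion = excl))
  })
}

#' Similarity + energy diversity filter
#'
#' Drops conformers above `energy_window` kcal/mol over the pool minimum,
#' then keeps conformers greedily in ascending energy order (ties by input
#' index), rejecting any within `rmsd_cutoff` superposed RMSD of an
#' already-kept conformer, and finally truncates to `num_of_conf`.  The
#' global minimum-energy conformer always survives.  An empty input yields
#' an empty ensemble with a warning, not an error.
#'
#' @param ens An [ensemble()] (or list of conformers plus `mol`).
#' @param config A [generator_config()].
#' @return The filtered [ensemble()].
#' @export
diversity_filter <- function(ens, config = generator_config()) {
  stopifnot(inherits(ens, "ensemble"))
  if (length(ens) == 0) {
    warning("diversity_filter: empty conformer pool; returning an empty ensemble")
    return(ens)
  }
  e <- ensemble_energies(ens)
  e <- replace(e, is.na(e), Inf)
  ord <- order(e, seq_along(e))
  emin <- e[ord[1]]
  kept <- integer(0)
  for (k in ord) {
    if (e[k] > emin + config$energy_window) next
    dup <- FALSE
    if (config$rmsd_cutoff > 0) {
      for (j in kept) {
        if (svd_rmsd(ens$conformers[[j]]$coords,
                     ens$conformers[[k]]$coords) < config$rmsd_cutoff) {
          dup <- TRUE
          break
        }
      }
    }
    if (!dup) kept <- c(kept, k)
    if (length(kept) >= config$num_of_conf) break
  }
  ensemble_subset(ens, sort(kept))
}

#' Generate a filtered conformer ensemble for a charge model
#'
#' Runs a generator (default: the built-in torsion grid), validates its
#' output against the charge model's atom count, pipes the pool through
#' [diversity_filter()], and optionally partitions the survivors into
#' individual XYZ files in an `opt_Rank[n]_ensemble` folder.
#'
#' @param model A ranked `charge_model`.
#' @param config A [generator_config()].
#' @param generator A generator function `(model, config) -> conformer
#'   list`; default [torsion_grid_generate()].
#' @param outdir Optional directory to write one XYZ per conformer into.
#' @return The filtered [ensemble()], rank-tagged from the model.
#' @export
generate_ensemble <- function(model, config = generator_config(),
                              generator = torsion_grid_generate,
                              outdir = NULL) {
  stopifnot(inherits(model, "charge_model"))
  pool <- generator(model, config)
  gen_name <- deparse(substitute(generator))[1]
  nat <- n_atoms(model$molecule)
  for (cf in pool) {
    if (!inherits(cf, "conformer") || nrow(cf$coords) != nat) {
      stop("generator '", gen_name, "' violated its contract: conformer atom ",
           "count does not match the charge model (", nat, ")")
    }
  }
  rank <- if (is.na(model$rank)) 1L else model$rank
  ens <- ensemble(model$molecule, pool, rank_label = rank)
  ens <- diversity_filter(ens, config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(ens$conformers)) {
      cf <- ens$conformers[[k]]
      write_xyz(cf, ens$molecule$elements,
                file.path(outdir, sprintf("conf_%d.xyz", k)))
    }
  }
  ens
}
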