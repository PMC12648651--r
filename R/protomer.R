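# Charge-model (protomer/deprotomer) enumeration and ranking.
#
# For an [M+H]+ or [M-H]- adduct of a neutral molecule, every titratable
# nitrogen or oxygen defines a candidate charge model: the same geometry
# with one proton added at, or removed from, that site.  Models are ranked
# by a two-tier scorer chain -- a cheap primary scorer over all models and a
# (possibly geometry-refining) secondary scorer over the top k, whose
# ranking supersedes the primary one.  Equilibrium populations are reported
# as gas-phase mole fractions from Boltzmann statistics.

# Gas constant in kcal mol^-1 K^-1.
.R_KCAL <- 1.98720425864e-3

.ADDUCTS <- c("[M+H]+", "[M-H]-")

normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", trimws(adduct))  # tolerate unicode minus
  up <- toupper(a)
  if (up %in% c("[M+H]+", "MH+", "M+H", "[M+H]")) return("[M+H]+")
  if (up %in% c("[M-H]-", "M-H-", "M-H", "[M-H]")) return("[M-H]-")
  stop("unknown adduct '", adduct, "'; supported: [M+H]+, [M-H]-")
}

#' Enumerate titratable charge sites
#'
#' For protonation ([M+H]+): every N or O whose bond-order sum leaves a
#' lone pair available (N below 4, O below 3 -- this excludes
#' valence-saturated sites such as nitro-group nitrogens).  For
#' deprotonation ([M-H]-): every N or O carrying at least one hydrogen.
#' Sites are returned in stable atom-index order.
#'
#' @param mol A neutral [molecule()] with perceived bonds.
#' @param adduct `"[M+H]+"` or `"[M-H]-"` (a few common aliases accepted).
#' @return Data frame with columns `atom_index`, `element`, `mode`.
#' @export
enumerate_sites <- function(mol, adduct) {
  stopifnot(inherits(mol, "molecule"))
  if (mol$formal_charge != 0L) stop("site enumeration requires a neutral molecule")
  adduct <- normalize_adduct(adduct)
  cand <- which(mol$elements %in% c("N", "O"))
  keep <- logical(length(cand))
  mode <- if (adduct == "[M+H]+") "protonation" else "deprotonation"
  for (k in seq_along(cand)) {
    a <- cand[k]
    if (mode == "protonation") {
      bos <- bond_order_sum(mol, a)
      keep[k] <- (mol$elements[a] == "N" && bos <= 3) ||
                 (mol$elements[a] == "O" && bos <= 2)
    } else {
      keep[k] <- length(h_neighbors(mol, a)) >= 1
    }
  }
  sites <- cand[keep]
  if (length(sites) == 0) {
    stop("no titratable site: molecule '", mol$name, "' has no ", mode,
         " candidate N or O atom for ", adduct)
  }
  data.frame(atom_index = sites, element = mol$elements[sites],
             mode = mode, stringsAsFactors = FALSE)
}

# Standard X-H bond lengths used when planting the new proton.
.XH_BOND <- c(N = 1.01, O = 0.96)

# Deterministic Fibonacci sphere of unit directions.
fibonacci_sphere <- function(n = 194L) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a charge model from a titratable site
#'
#' Protonation appends one hydrogen at the standard bond length (N-H
#' 1.01 A, O-H 0.96 A) along the least-crowded direction -- the unit
#' direction maximizing the minimum distance to all other atoms, selected
#' deterministically from a Fibonacci sphere.  Deprotonation removes the
#' lowest-index hydrogen bonded to the site.  All other atoms are
#' untouched, so sibling models share their geometry except at the charge
#' site.
#'
#' @param mol The neutral parent [molecule()].
#' @param site One row of [enumerate_sites()] output (or an equivalent
#'   list with `atom_index` and `mode`).
#' @return An object of class `charge_model`: list with `molecule` (the
#'   charged molecule), `site`, `adduct`, `geometry` (a [conformer()]),
#'   `primary_score`, `secondary_score`, `rank` (the latter three `NA`
#'   until ranked).
#' @export
build_charge_model <- function(mol, site) {
  stopifnot(inherits(mol, "molecule"))
  a <- as.integer(site$atom_index)
  mode <- as.character(site$mode)
  site_label <- paste0(mol$elements[a], a)
  if (mode == "protonation") {
    adduct <- "[M+H]+"
    blen <- .XH_BOND[[mol$elements[a]]]
    dirs <- fibonacci_sphere()
    pos <- mol$coords[a, ]
    others <- mol$coords[-a, , drop = FALSE]
    best <- which.max(apply(dirs, 1, function(u) {
      cand <- pos + blen * u
      min(sqrt(rowSums(sweep(others, 2, cand)^2)))
    }))
    new_h <- pos + blen * dirs[best, ]
    elements <- c(mol$elements, "H")
    coords <- rbind(mol$coords, new_h)
    bonds <- rbind(mol$bonds,
                   data.frame(i = a, j = length(elements), order = 1L))
    charged <- molecule(mol$name, elements, coords, bonds,
                        formal_charge = 1L, comment = mol$comment)
    charged_index <- a
  } else if (mode == "deprotonation") {
    adduct <- "[M-H]-"
    hs <- h_neighbors(mol, a)
    if (length(hs) == 0) stop("cannot deprotonate atom ", a, ": no bonded hydrogen")
    h <- min(hs)
    keep <- setdiff(seq_len(n_atoms(mol)), h)
    remap <- integer(n_atoms(mol)); remap[keep] <- seq_along(keep)
    b <- mol$bonds[mol$bonds$i != h & mol$bonds$j != h, , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
    charged <- molecule(mol$name, mol$elements[keep],
                        mol$coords[keep, , drop = FALSE], b,
                        formal_charge = -1L, comment = mol$comment)
    charged_index <- remap[a]
  } else {
    stop("unknown site mode '", mode, "'")
  }
  structure(
    list(
      molecule = charged,
      site = list(atom_index = a, element = mol$elements[a], mode = mode,
                  label = site_label, charged_index = charged_index),
      adduct = adduct,
      geometry = conformer(paste0(mol$name, "_", site_label), charged$coords),
      primary_score = NA_real_,
      secondary_score = NA_real_,
      rank = NA_integer_
    ),
    class = "charge_model"
  )
}

#' @export
print.charge_model <- function(x, ...) {
  cat(sprintf("<charge_model> %s %s at %s (rank %s)\n", x$molecule$name,
              x$adduct, x$site$label,
              if (is.na(x$rank)) "unranked" else x$rank))
  invisible(x)
}

#' Built-in surrogate site scorer
#'
#' Deterministic heuristic standing in for a trained charge-state ranker
#' plus energy model: a fixed base affinity by site element and
#' hybridization (sp3 amine nitrogens are the most basic protonation
#' sites; carboxyl-type oxygens the most acidic deprotonation sites) plus
#' the [clash_energy()] of the model geometry.  Lower is more stable.  Any
#' scorer with the same signature can replace it, including ones that
#' return a refined geometry.
#'
#' @param model A `charge_model`.
#' @return Scalar score (pseudo-kcal/mol, lower = more stable).
#' @export
builtin_surrogate_scorer <- function(model) {
  stopifnot(inherits(model, "charge_model"))
  elem <- model$site$element
  mol <- model$molecule
  site_now <- model$site$charged_index  # site index within the charged graph
  sp3 <- all(mol$bonds$order[mol$bonds$i == site_now | mol$bonds$j == site_now] == 1L)
  base <- if (model$site$mode == "protonation") {
    if (elem == "N") (if (sp3) -230 else -220) else (if (sp3) -200 else -190)
  } else {
    if (elem == "O") {
      if (carboxylate_like(mol, site_now)) -350 else -330
    } else -310
  }
  base + clash_energy(mol, model$geometry$coords)
}

# TRUE when the (charged-molecule) oxygen sits on a carbon that also bears
# a double-bonded oxygen -- the carboxylate resonance motif.
carboxylate_like <- function(mol, o_idx) {
  for (c_idx in neighbors_of(mol, o_idx)) {
    if (mol$elements[c_idx] != "C") next
    for (nb in neighbors_of(mol, c_idx)) {
      if (nb == o_idx || mol$elements[nb] != "O") next
      ord <- mol$bonds$order[(mol$bonds$i == c_idx & mol$bonds$j == nb) |
                             (mol$bonds$j == c_idx & mol$bonds$i == nb)]
      if (any(ord == 2L)) return(TRUE)
    }
  }
  FALSE
}

# Run one scorer on one model; scorers may return a bare score or
# list(score=, coords=) to refine the geometry.
apply_scorer <- function(scorer, model) {
  res <- scorer(model)
  if (is.list(res)) {
    if (!is.null(res$coords)) {
      model$geometry <- conformer(model$geometry$conf_id, res$coords)
      model$molecule$coords <- as_coords(res$coords, n_atoms(model$molecule))
    }
    score <- res$score
  } else {
    score <- res
  }
  if (!is.numeric(score) || length(score) != 1 || !is.finite(score)) {
    stop("scorer returned a non-finite score")
  }
  list(model = model, score = as.numeric(score))
}

#' Rank charge models with a two-tier scorer chain
#'
#' All models are scored by `primary` and sorted ascending; the best
#' `top_k` are then re-scored (and possibly re-geometrized) by `secondary`,
#' whose ordering supersedes the primary ordering within that subset.  The
#' final list is the secondary-ordered top block followed by the remaining
#' models in primary order, with ranks reassigned 1..K.  Ties break by
#' primary score, then site atom index.  A scorer failure drops the
#' affected model with a warning; if every model fails, the ranking errors
#' out.
#'
#' @param models List of `charge_model` objects.
#' @param primary,secondary Scorer functions (see
#'   [builtin_surrogate_scorer()]); `secondary` defaults to `primary`.
#' @param top_k How many primary-ranked models the secondary scorer
#'   refines; default all.
#' @return List of `charge_model` objects in final rank order, with
#'   `primary_score`, `secondary_score` and `rank` filled in.
#' @export
rank_charge_models <- function(models, primary = builtin_surrogate_scorer,
                               secondary = primary, top_k = length(models)) {
  if (length(models) < 1) stop("need at least one charge model")
  if (top_k < 1) stop("top_k must be >= 1")
  scored <- list()
  for (m in models) {
    res <- tryCatch(apply_scorer(primary, m), error = function(e) e)
    if (inherits(res, "error")) {
      warning("primary scorer failed on site ", m$site$label, " (",
              conditionMessage(res), "); model dropped")
      next
    }
    res$model$primary_score <- res$score
    scored[[length(scored) + 1]] <- res$model
  }
  if (length(scored) == 0) stop("all charge models failed primary scoring")
  p <- vapply(scored, `[[`, numeric(1), "primary_score")
  idx <- vapply(scored, function(m) m$site$atom_index, integer(1))
  scored <- scored[order(p, idx)]

  k <- min(top_k, length(scored))
  top <- scored[seq_len(k)]
  rest <- scored[-seq_len(k)]
  refined <- list()
  for (m in top) {
    res <- tryCatch(apply_scorer(secondary, m), error = function(e) e)
    if (inherits(res, "error")) {
      warning("secondary scorer failed on site ", m$site$label, " (",
              conditionMessage(res), "); model dropped")
      next
    }
    res$model$secondary_score <- res$score
    refined[[length(refined) + 1]] <- res$model
  }
  if (length(refined) == 0 && length(rest) == 0) {
    stop("all charge models failed secondary scoring")
  }
  if (length(refined) > 0) {
    s <- vapply(refined, `[[`, numeric(1), "secondary_score")
    p2 <- vapply(refined, `[[`, numeric(1), "primary_score")
    i2 <- vapply(refined, function(m) m$site$atom_index, integer(1))
    refined <- refined[order(s, p2, i2)]
  }
  final <- c(refined, rest)
  for (r in seq_along(final)) final[[r]]$rank <- r
  final
}

#' Gas-phase mole fractions from Boltzmann statistics
#'
#' x_i = exp(-(E_i - E_min)/(R T)) / sum_j exp(-(E_j - E_min)/(R T)) with
#' R = 1.98720425864e-3 kcal mol^-1 K^-1.  Invariant to adding a constant
#' to all energies; the weights sum to 1 within 1e-12.
#'
#' @param energies Numeric vector of energies in kcal/mol.
#' @param temperature Temperature in Kelvin (default 298.15).
#' @return Numeric vector of mole fractions summing to 1.
#' @export
mole_fractions <- function(energies, temperature = 298.15) {
  if (length(energies) == 0) stop("energies must be non-empty")
  if (!all(is.finite(energies))) stop("energies must be finite")
  if (temperature <= 0) stop("temperature must be > 0")
  w <- exp(-(energies - min(energies)) / (.R_KCAL * temperature))
  w / sum(w)
}
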