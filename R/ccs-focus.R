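# CCS prediction and reference-focused filtering.
#
# Every conformer gets a predicted collision cross-section; only those
# whose prediction falls inside an accuracy-derived window around the
# user's reference CCS survive.  The window is symmetric and relative:
# |CCS_pred - CCS_ref| <= window_fraction * CCS_ref, with window_fraction
# defaulting to the predictor's own 1-sigma relative error.  The built-in
# predictor is a Monte-Carlo projection approximation (orientation-averaged
# projected area of probe-inflated van der Waals disks), with a nitrogen
# buffer-gas probe radius; trained or physics-grade predictors plug in
# through the same contract.

#' CCS predictor contract
#'
#' Wraps a prediction function together with its fractional 1-sigma
#' relative accuracy (model metadata used to size the focus window).
#'
#' @param predict Function `(conformer, mol) -> CCS in Angstrom^2`.
#' @param accuracy Fractional relative error in (0, 1).
#' @return An object of class `ccs_predictor`.
#' @export
ccs_predictor <- function(predict, accuracy) {
  stopifnot(is.function(predict), accuracy > 0, accuracy < 1)
  structure(list(predict = predict, accuracy = accuracy),
            class = "ccs_predictor")
}

#' Monte-Carlo projection-approximation CCS
#'
#' Estimates the orientation-averaged projected area of the union of
#' atom-centered disks of radius r_vdw + probe_radius: for each of
#' `n_orientations` seeded uniformly random rigid rotations, atom centers
#' are projected onto a plane and the union-of-disks area is estimated by
#' rejection sampling with `n_points` points over the bounding box.  The
#' mean over orientations is returned; the standard error across
#' orientations is attached as attribute `"se"`.
#'
#' @param conf A [conformer()].
#' @param elements Element symbols matching the conformer's atoms.
#' @param n_orientations Number of random orientations (default 64).
#' @param n_points Rejection-sampling points per orientation (default 4096).
#' @param probe_radius Buffer-gas probe radius in Angstrom (default 1.55,
#'   nitrogen).
#' @param seed Integer RNG seed.
#' @return CCS estimate in Angstrom^2 with attribute `se`.
#' @export
pa_ccs <- function(conf, elements, n_orientations = 64L, n_points = 4096L,
                   probe_radius = 1.55, seed = 1L) {
  stopifnot(inherits(conf, "conformer"))
  if (n_orientations < 1 || n_points < 1) {
    stop("n_orientations and n_points must be >= 1")
  }
  if (length(elements) != nrow(conf$coords)) {
    stop("elements length must match the conformer atom count")
  }
  radii <- vdw_radius(elements) + probe_radius
  coords <- conf$coords
  areas <- withr::with_seed(seed, vapply(seq_len(n_orientations), function(o) {
    rot <- random_rotation()
    xy <- coords %*% t(rot)
    x <- xy[, 1]; y <- xy[, 2]
    xlim <- range(x - radii, x + radii)
    ylim <- range(y - radii, y + radii)
    px <- stats::runif(n_points, xlim[1], xlim[2])
    py <- stats::runif(n_points, ylim[1], ylim[2])
    inside <- rep(FALSE, n_points)
    for (a in seq_along(x)) {
      inside <- inside | ((px - x[a])^2 + (py - y[a])^2 <= radii[a]^2)
    }
    mean(inside) * diff(xlim) * diff(ylim)
  }, numeric(1)))
  est <- mean(areas)
  attr(est, "se") <- stats::sd(areas) / sqrt(n_orientations)
  est
}

#' Built-in projection-approximation predictor
#'
#' Packages [pa_ccs()] as a [ccs_predictor()].  The default accuracy of
#' 0.03 sizes the focus window at the 3 percent scale of experimental CCS
#' reproducibility in ion-mobility measurements.
#'
#' @param n_orientations,n_points,probe_radius,seed Passed to [pa_ccs()].
#' @param accuracy Fractional 1-sigma relative error (default 0.03).
#' @return A [ccs_predictor()].
#' @export
builtin_pa_predictor <- function(n_orientations = 64L, n_points = 4096L,
                                 probe_radius = 1.55, seed = 1L,
                                 accuracy = 0.03) {
  ccs_predictor(
    predict = function(conf, mol) {
      pa_ccs(conf, mol$elements, n_orientations = n_orientations,
             n_points = n_points, probe_radius = probe_radius, seed = seed)
    },
    accuracy = accuracy
  )
}

#' Focus-filter configuration
#'
#' @param ccs_ref User-supplied reference CCS in Angstrom^2 (> 0).
#' @param window_fraction Relative half-width of the acceptance window in
#'   (0, 1); `NULL` (default) uses the predictor's accuracy.
#' @param final_output_max Final-output conformer ceiling handed to the
#'   downstream reduction stage (default 50).
#' @return A list of class `focus_config`.
#' @export
focus_config <- function(ccs_ref, window_fraction = NULL,
                         final_output_max = 50L) {
  if (!is.numeric(ccs_ref) || ccs_ref <= 0) stop("ccs_ref must be > 0")
  if (!is.null(window_fraction) &&
      (window_fraction <= 0 || window_fraction >= 1)) {
    stop("window_fraction must lie in (0, 1)")
  }
  structure(list(ccs_ref = ccs_ref, window_fraction = window_fraction,
                 final_output_max = as.integer(final_output_max)),
            class = "focus_config")
}

#' Focus an ensemble around a reference CCS
#'
#' Annotates every conformer with its predicted CCS and keeps those with
#' `|ccs_pred - ccs_ref| <= window_fraction * ccs_ref`, preserving input
#' order.  An empty result is not an error: it returns an empty ensemble
#' carrying an `"advisory"` attribute recommending regeneration with a
#' conformer target far above 1000, and raises a warning.  A predictor
#' failure drops the affected conformer with a warning.
#'
#' @param ens A non-empty [ensemble()].
#' @param predictor A [ccs_predictor()]; default [builtin_pa_predictor()].
#' @param focus A [focus_config()] with the reference CCS.
#' @param outdir Optional `opt_Rank[n]_focus` directory: survivors are
#'   written as individual XYZ files plus a `ccs_pred.csv` sidecar
#'   (conf_id, ccs_pred, kept flag).
#' @return The focused [ensemble()], all members annotated with `ccs_pred`.
#' @export
focus_filter <- function(ens, predictor = builtin_pa_predictor(), focus,
                         outdir = NULL) {
  stopifnot(inherits(ens, "ensemble"), inherits(focus, "focus_config"),
            inherits(predictor, "ccs_predictor"))
  if (length(ens) == 0) stop("focus_filter needs a non-empty ensemble")
  wf <- if (is.null(focus$window_fraction)) predictor$accuracy else
    focus$window_fraction
  preds <- rep(NA_real_, length(ens))
  ok <- rep(TRUE, length(ens))
  for (k in seq_along(ens$conformers)) {
    p <- tryCatch(predictor$predict(ens$conformers[[k]], ens$molecule),
                  error = function(e) e)
    if (inherits(p, "error")) {
      warning("CCS prediction failed for ",
              ens$conformers[[k]]$conf_id, " (", conditionMessage(p),
              "); conformer dropped")
      ok[k] <- FALSE
    } else {
      preds[k] <- as.numeric(p)
      ens$conformers[[k]]$ccs_pred <- preds[k]
    }
  }
  kept <- ok & !is.na(preds) &
    abs(preds - focus$ccs_ref) <= wf * focus$ccs_ref
  out <- ensemble_subset(ens, which(kept))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(out$conformers)) {
      write_xyz(out$conformers[[k]], out$molecule$elements,
                file.path(outdir, sprintf("conf_%d.xyz", k)))
    }
    utils::write.csv(
      data.frame(conf_id = ensemble_ids(ens),
                 ccs_pred = round(preds, 4), kept = kept),
      file.path(outdir, "ccs_pred.csv"), row.names = FALSE, quote = FALSE
    )
  }
  if (length(out) == 0) {
    advisory <- paste0(
      "no conformer fell within ", format(100 * wf), "% of the reference CCS (",
      format(focus$ccs_ref), " A^2); regenerate with num_of_conf >> 1000 ",
      "to widen the sampled conformational space"
    )
    attr(out, "advisory") <- advisory
    warning("focus_filter: ", advisory)
  }
  out
}
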