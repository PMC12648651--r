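# End-to-end orchestration and ensemble evaluation.
#
# One call runs the whole chain with no intervention between stages:
# titratable-site enumeration -> charge-model ranking -> per-rank conformer
# generation -> CCS focusing -> normal-walk reduction of any focus ensemble
# above the 50-conformer final-output threshold -> Boltzmann-weighted CCS
# evaluation against the 3% experimental-viability criterion.  Output lands
# in Completed_Job/[molecule name]/ with per-rank geometry files, ensemble
# and focus folders, a results_sum.log summary and a zip of the final
# focus ensembles.

# Experimental viability threshold: weighted-CCS error (percent) at or
# below which an ensemble counts as matching the IM-MS measurement, whose
# own reproducibility sits at this scale.
.VIABILITY_PCT <- 3.0

#' Boltzmann-weighted ensemble CCS
#'
#' Weighted mean of conformer CCS values with weights
#' [mole_fractions()]`(energies, temperature)`.
#'
#' @param ccs_values CCS values in Angstrom^2.
#' @param energies Matching energies in kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return Weighted CCS in Angstrom^2.
#' @export
boltzmann_weighted_ccs <- function(ccs_values, energies,
                                   temperature = 298.15) {
  if (length(ccs_values) != length(energies)) {
    stop("ccs_values and energies must have equal length")
  }
  if (length(ccs_values) == 0) stop("need at least one conformer")
  w <- mole_fractions(energies, temperature)
  sum(w * ccs_values)
}

#' Percent CCS error against a reference
#'
#' `100 * |ccs_calc - ccs_ref| / ccs_ref`, with the experimental-viability
#' flag (error <= 3.0, boundary inclusive) attached as attribute
#' `"viable"`.
#'
#' @param ccs_calc Calculated (e.g. Boltzmann-weighted) CCS, Angstrom^2.
#' @param ccs_ref Reference CCS, Angstrom^2 (> 0).
#' @return Percent error with logical attribute `viable`.
#' @export
ccs_percent_error <- function(ccs_calc, ccs_ref) {
  if (!is.numeric(ccs_ref) || ccs_ref <= 0) stop("ccs_ref must be > 0")
  err <- 100 * abs(ccs_calc - ccs_ref) / ccs_ref
  structure(err, viable = err <= .VIABILITY_PCT)
}

sanitize_name <- function(name) {
  if (!nzchar(trimws(name))) stop("molecule_name must be non-empty")
  if (grepl("[/\\\\]", name)) stop("molecule_name must not contain path separators")
  gsub("\\s+", "_", trimws(name))
}

#' Pipeline configuration
#'
#' @param molecule_name Output folder label (whitespace becomes
#'   underscores; path separators are rejected).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @param ccs_ref Reference CCS in Angstrom^2, or `NULL` to skip focusing
#'   and error evaluation.
#' @param generator A [generator_config()].
#' @param window_fraction Focus window half-width; `NULL` uses the
#'   predictor accuracy.
#' @param temperature Kelvin for mole fractions and Boltzmann weighting.
#' @param seed Master seed for every stochastic stage.
#' @param top_k Charge models refined by the secondary scorer (default all).
#' @param size_threshold Final-output conformer ceiling triggering the
#'   normal walk (default 50).
#' @param output_root Root output directory (default `"Completed_Job"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(molecule_name, adduct, ccs_ref = NULL,
                            generator = NULL, window_fraction = NULL,
                            temperature = 298.15, seed = 1L, top_k = NULL,
                            size_threshold = 50L,
                            output_root = "Completed_Job") {
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(
    list(
      molecule_name = sanitize_name(molecule_name),
      adduct = normalize_adduct(adduct),
      ccs_ref = ccs_ref,
      generator = generator,
      window_fraction = window_fraction,
      temperature = temperature,
      seed = as.integer(seed),
      top_k = top_k,
      size_threshold = as.integer(size_threshold),
      output_root = output_root
    ),
    class = "pipeline_config"
  )
}

#' Run the full ensemble-sampling pipeline
#'
#' @param input A SMILES string, or a path to an XYZ file (bonds are then
#'   perceived from the geometry).
#' @param config A [pipeline_config()].
#' @param predictor A [ccs_predictor()]; defaults to the built-in
#'   projection-approximation predictor seeded from the config.
#' @param generator Conformer generator function; default
#'   [torsion_grid_generate()].
#' @param primary,secondary Charge-model scorers; default the built-in
#'   surrogate for both tiers.
#' @return An `evaluation_report`: per-rank ensemble sizes at each stage,
#'   relative energies, mole fractions, Boltzmann-weighted CCS, percent
#'   CCS error and the viability flag, plus the paths written.
#' @export
run_pipeline <- function(input, config, predictor = NULL,
                         generator = torsion_grid_generate,
                         primary = builtin_surrogate_scorer,
                         secondary = primary) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(predictor)) {
    predictor <- builtin_pa_predictor(seed = config$seed)
  }
  mol <- if (file.exists(input) &&
             grepl("\\.xyz$", input, ignore.case = TRUE)) {
    perceive_bonds(read_xyz(input, name = config$molecule_name))
  } else {
    parse_smiles(input, name = config$molecule_name, seed = config$seed)
  }

  sites <- enumerate_sites(mol, config$adduct)  # errors out when none
  models <- lapply(seq_len(nrow(sites)), function(k) {
    build_charge_model(mol, sites[k, ])
  })
  top_k <- if (is.null(config$top_k)) length(models) else config$top_k
  ranked <- rank_charge_models(models, primary = primary,
                               secondary = secondary, top_k = top_k)

  job_dir <- file.path(config$output_root, config$molecule_name)
  conf_dir <- file.path(job_dir, "Conformer")
  dir.create(conf_dir, recursive = TRUE, showWarnings = FALSE)

  scores <- vapply(ranked, function(m) {
    if (is.na(m$secondary_score)) m$primary_score else m$secondary_score
  }, numeric(1))
  rel_energy <- scores - min(scores)
  fractions <- mole_fractions(rel_energy, config$temperature)

  rank_reports <- vector("list", length(ranked))
  focus_dirs <- character(0)
  for (k in seq_along(ranked)) {
    model <- ranked[[k]]
    rank <- model$rank
    write_xyz(model$geometry, model$molecule$elements,
              file.path(job_dir, sprintf("opt_Rank%d_%s.xyz", rank,
                                         model$site$label)),
              comment = sprintf("%s rank=%d energy=%.6f",
                                config$molecule_name, rank, rel_energy[k]))
    ens_dir <- file.path(conf_dir, sprintf("opt_Rank%d_ensemble", rank))
    ens <- generate_ensemble(model, config$generator, generator = generator,
                             outdir = ens_dir)
    n_generated <- length(ens)

    focused <- NULL
    reduced <- NULL
    advisory <- NA_character_
    weighted <- NA_real_
    err <- NA_real_
    viable <- NA
    if (!is.null(config$ccs_ref) && n_generated > 0) {
      fc <- focus_config(config$ccs_ref,
                         window_fraction = config$window_fraction,
                         final_output_max = config$size_threshold)
      focus_dir <- file.path(conf_dir, sprintf("opt_Rank%d_focus", rank))
      focused <- withCallingHandlers(
        focus_filter(ens, predictor, fc, outdir = focus_dir),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (!is.null(attr(focused, "advisory"))) {
        advisory <- attr(focused, "advisory")
      }
      focus_dirs <- c(focus_dirs, focus_dir)
      reduced <- focused
      if (length(focused) > config$size_threshold) {
        reduced <- normal_walk_reduce(focused,
                                      size_threshold = config$size_threshold,
                                      rot = rotatable_bond_count(model$molecule))
        # the reduced set replaces the focus folder contents
        unlink(list.files(focus_dir, pattern = "^conf_\\d+\\.xyz$",
                          full.names = TRUE))
        for (i in seq_along(reduced$conformers)) {
          write_xyz(reduced$conformers[[i]], reduced$molecule$elements,
                    file.path(focus_dir, sprintf("conf_%d.xyz", i)))
        }
      }
      if (length(reduced) > 0) {
        weighted <- boltzmann_weighted_ccs(
          vapply(reduced$conformers, `[[`, numeric(1), "ccs_pred"),
          ensemble_energies(reduced), config$temperature
        )
        err_v <- ccs_percent_error(weighted, config$ccs_ref)
        err <- as.numeric(err_v)
        viable <- attr(err_v, "viable")
      }
    }
    rank_reports[[k]] <- list(
      rank = rank,
      site = model$site$label,
      mode = model$site$mode,
      relative_energy = rel_energy[k],
      mole_fraction = fractions[k],
      n_generated = n_generated,
      n_focused = if (is.null(focused)) NA_integer_ else length(focused),
      n_reduced = if (is.null(reduced)) NA_integer_ else length(reduced),
      weighted_ccs = weighted,
      ccs_error_pct = err,
      viable = viable,
      advisory = advisory
    )
  }

  report <- structure(
    list(
      molecule_name = config$molecule_name,
      adduct = config$adduct,
      ccs_ref = if (is.null(config$ccs_ref)) NA_real_ else config$ccs_ref,
      temperature = config$temperature,
      seed = config$seed,
      ranks = rank_reports,
      job_dir = job_dir
    ),
    class = "evaluation_report"
  )
  log_path <- file.path(job_dir, "results_sum.log")
  write_results_log(report, log_path)
  if (length(focus_dirs) > 0) {
    entries <- c("results_sum.log",
                 unlist(lapply(focus_dirs, function(d) {
                   file.path("Conformer", basename(d),
                             list.files(d))
                 })))
    write_zip(file.path(job_dir, paste0(config$molecule_name, ".zip")),
              entries, root = job_dir)
  }
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s %s, %d charge model(s)\n",
              x$molecule_name, x$adduct, length(x$ranks)))
  for (r in x$ranks) {
    cat(sprintf("  rank %d %s: gen %s, focus %s, final %s%s\n", r$rank,
                r$site, r$n_generated,
                if (is.na(r$n_focused)) "-" else r$n_focused,
                if (is.na(r$n_reduced)) "-" else r$n_reduced,
                if (is.na(r$ccs_error_pct)) "" else
                  sprintf(", CCS err %.2f%% (%s)", r$ccs_error_pct,
                          if (isTRUE(r$viable)) "viable" else "not viable")))
  }
  invisible(x)
}

#' Write the results summary log
#'
#' Plain-text log with a header and one block per rank: site, relative
#' energy, mole fraction, ensemble sizes at each stage, weighted CCS,
#' percent CCS error and the viability flag, in stable field order.
#'
#' @param report An `evaluation_report` from [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_log <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  fmt_num <- function(x) if (is.na(x)) "NA" else sprintf("%.6f", x)
  fmt_int <- function(x) if (is.na(x)) "NA" else as.character(x)
  lines <- c(
    "results summary",
    paste0("molecule: ", report$molecule_name),
    paste0("adduct: ", report$adduct),
    paste0("temperature_K: ", fmt_num(report$temperature)),
    paste0("ccs_ref_A2: ", fmt_num(report$ccs_ref)),
    paste0("seed: ", report$seed),
    ""
  )
  for (r in report$ranks) {
    lines <- c(lines,
      paste0("rank ", r$rank),
      paste0("  site: ", r$site, " (", r$mode, ")"),
      paste0("  relative_energy_kcal_mol: ", fmt_num(r$relative_energy)),
      paste0("  mole_fraction: ", fmt_num(r$mole_fraction)),
      paste0("  n_generated: ", fmt_int(r$n_generated)),
      paste0("  n_focused: ", fmt_int(r$n_focused)),
      paste0("  n_reduced: ", fmt_int(r$n_reduced)),
      paste0("  weighted_ccs_A2: ", fmt_num(r$weighted_ccs)),
      paste0("  ccs_error_pct: ", fmt_num(r$ccs_error_pct)),
      paste0("  viable: ", if (is.na(r$viable)) "NA" else r$viable),
      if (!is.na(r$advisory)) paste0("  advisory: ", r$advisory) else character(0),
      ""
    )
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results log: ", path)
  invisible(path)
}
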