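#' Pipeline run configuration
#'
#' Bundles all inputs and settings for a full analysis run: input paths,
#' anchoring, RAD thresholds, classification thresholds, fit settings and
#' the seed. Round-trips losslessly through JSON ([write_config()] /
#' [read_config()]).
#'
#' @param volumes path to the volume table (see [read_volume_table()]).
#' @param structure optional PDB path for RAD computation.
#' @param rad_table optional precomputed D/RA (or RAD) table path;
#'   overrides `structure`.
#' @param ss optional secondary-structure annotation TSV path.
#' @param anchor_T,anchor_fraction anchoring of folded populations
#'   (defaults 298.15 K, 0.70).
#' @param core_rad RAD threshold selecting buried-core reference residues.
#' @param exclude_rad RAD threshold above which residues count as exposed.
#' @param consistent_K,outlier_K classification thresholds, K.
#' @param v_u_rule unfolded-baseline rule for [volumes_to_populations()].
#' @param seed integer seed for all randomness in the run.
#' @param out_dir output directory (created on demand).
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(volumes = NULL, structure = NULL, rad_table = NULL,
                       ss = NULL, anchor_T = 298.15, anchor_fraction = 0.70,
                       core_rad = 0.1, exclude_rad = 0.5,
                       consistent_K = 1.5, outlier_K = 3.0,
                       v_u_rule = "top", seed = 1L, out_dir = NULL) {
  stopifnot(core_rad > 0, exclude_rad > 0, core_rad < exclude_rad,
            consistent_K > 0, outlier_K > consistent_K)
  structure(list(volumes = volumes, structure = structure,
                 rad_table = rad_table, ss = ss,
                 anchor_T = anchor_T, anchor_fraction = anchor_fraction,
                 core_rad = core_rad, exclude_rad = exclude_rad,
                 consistent_K = consistent_K, outlier_K = outlier_K,
                 v_u_rule = v_u_rule, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Fit stability curves for every residue in a volume table
#'
#' Reads the volume table, normalises, transforms to anchored populations
#' and fits each residue, logging every silent decision (anchor policy,
#' excluded temperatures, clipped points, flags). Flagged fits are included
#' in the output table with their flag, never dropped silently.
#'
#' @param config a [run_config()] with at least `volumes` set.
#' @return list with `fits` (named list of `stab_fit`), `populations`,
#'   `table` (Table-1-style parameter data frame), `dg_table` (per-T dG with
#'   propagated sigma for converged fits).
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$volumes)) stop("config$volumes is required")
  series <- read_volume_table(config$volumes)
  message("run_fit: ", length(series), " residue series; anchor f_F(",
          config$anchor_T, " K) = ", config$anchor_fraction,
          "; V_U rule = ", config$v_u_rule)
  populations <- list(); fits <- list()
  for (lbl in names(series)) {
    pop <- tryCatch(
      volumes_to_populations(normalize_volumes(series[[lbl]]),
                             anchor_T = config$anchor_T,
                             anchor_fraction = config$anchor_fraction,
                             v_u_rule = config$v_u_rule),
      error = function(e) e)
    if (inherits(pop, "error")) {
      message("  ", lbl, ": population transform failed (",
              conditionMessage(pop), ")")
      fits[[lbl]] <- new_stab_fit(lbl, NULL, series[[lbl]]$temperature,
                                  rep(NA_real_, nrow(series[[lbl]])),
                                  rep(NA_real_, nrow(series[[lbl]])),
                                  numeric(0), FALSE,
                                  conditionMessage(pop), 0L)
      next
    }
    if (attr(pop, "n_clipped") > 0)
      message("  ", lbl, ": ", attr(pop, "n_clipped"),
              " population point(s) clipped to [0,1]")
    fit <- tryCatch(fit_stability(pop), error = function(e) e)
    if (inherits(fit, "error")) {
      message("  ", lbl, ": fit failed (", conditionMessage(fit), ")")
      next
    }
    if (fit$flagged)
      message("  ", lbl, ": flagged (", paste(fit$flags, collapse = "; "), ")")
    populations[[lbl]] <- pop
    fits[[lbl]] <- fit
  }
  if (!length(fits)) stop("no fittable residues in ", config$volumes)
  tab <- write_param_table(fits)
  dg_rows <- lapply(fits[!vapply(fits, function(f) f$flagged, logical(1))],
                    function(f) {
                      T <- f$data$temperature
                      pr <- predict(f, T, se.fit = TRUE)
                      data.frame(residue_label = f$residue_label,
                                 temperature_K = T, dG_kcal_mol = pr$fit,
                                 sigma_dG_kcal_mol = pr$se.fit)
                    })
  dg_table <- if (length(dg_rows)) do.call(rbind, dg_rows) else NULL
  if (!is.null(dg_table)) rownames(dg_table) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(config$out_dir, "params.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dg_table))
      utils::write.table(dg_table, file.path(config$out_dir, "dg_curves.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fits = fits, populations = populations, table = tab,
       dg_table = dg_table)
}

#' Classify fitted residues against the buried-core reference
#'
#' Builds the reference curve from the RAD selection, classifies every
#' fitted residue, and summarises by secondary-structure element.
#'
#' @param config a [run_config()]; `rad_table` (or `structure`) required.
#' @param fit_out output of [run_fit()]; computed from `config` if missing.
#' @return list with `reference`, `records`, `ss_summary`.
#' @export
run_classify <- function(config, fit_out = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(fit_out)) fit_out <- run_fit(config)
  rad <- if (!is.null(config$rad_table)) read_rad_table(config$rad_table)
         else if (!is.null(config$structure))
           rad_records(read_structure(config$structure))
         else stop("config needs rad_table or structure for classification")
  ref <- build_reference(fit_out$populations, rad,
                         threshold = config$core_rad, fits = fit_out$fits)
  message("run_classify: reference built from ", length(ref$members),
          " residues with RAD < ", config$core_rad)
  records <- classify_residues(fit_out$fits, ref,
                               consistent_K = config$consistent_K,
                               outlier_K = config$outlier_K)
  ss_summary <- group_by_secondary_structure(records, config$ss)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(records,
                       file.path(config$out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ss_summary,
                       file.path(config$out_dir, "ss_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reference = ref, records = records, ss_summary = ss_summary)
}

#' Generate a synthetic dataset and a parameter-recovery report
#'
#' Writes a volume table in the exact dialect [read_volume_table()] consumes
#' and reports per-parameter recovery bias/spread over replicates.
#'
#' @param config a [run_config()] (seed and out_dir are used).
#' @param true_params ground-truth [thermo_params()].
#' @param n_residues residues in the emitted dataset.
#' @param n_reps replicates for the recovery report.
#' @param noise_sigma multiplicative noise sd.
#' @param grid temperature grid.
#' @return list with `path` (volume table, `NULL` when no out_dir),
#'   `recovery` (per-parameter bias and spread data frame), `errors`
#'   (per-replicate parameter errors).
#' @export
run_simulate <- function(config, true_params = thermo_params(28.5, 298.2, 3.73),
                         n_residues = 5L, n_reps = 25L, noise_sigma = 0.03,
                         grid = seq(278, 313, by = 2.5)) {
  stopifnot(inherits(config, "run_config"))
  true_params <- as_thermo_params(true_params)
  ## dataset
  rows <- list()
  for (i in seq_len(n_residues)) {
    spec <- synthetic_spec(true_params, grid = grid,
                           noise_sigma = noise_sigma,
                           seed = config$seed + i)
    gen <- generate_series(spec, residue_label = paste0("res", i))
    v <- gen$volumes
    rows[[i]] <- data.frame(residue_label = attr(v, "residue_label"),
                            temperature_K = v$temperature,
                            volume = v$volume,
                            reference_volume = v$reference)
  }
  dataset <- do.call(rbind, rows)
  path <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "synthetic_volumes.tsv")
    utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ## recovery report
  errs <- lapply(seq_len(n_reps), function(r) {
    spec <- synthetic_spec(true_params, grid = grid,
                           noise_sigma = noise_sigma,
                           seed = config$seed + 10000L + r)
    gen <- generate_series(spec)
    fit <- fit_generated(gen, spec, v_u_rule = config$v_u_rule)
    if (fit$flagged) return(NULL)
    p <- fit$params
    data.frame(rep = r,
               dHm_err = p$dHm - true_params$dHm,
               Tm_err = p$Tm - true_params$Tm,
               dCp_err = p$dCp - true_params$dCp,
               Tc_err = p$Tc - true_params$Tc,
               Ts_err = p$Ts - true_params$Ts)
  })
  errors <- do.call(rbind, errs)
  recovery <- data.frame(
    parameter = c("dHm", "Tm", "dCp", "Tc", "Ts"),
    bias = vapply(c("dHm_err", "Tm_err", "dCp_err", "Tc_err", "Ts_err"),
                  function(k) mean(errors[[k]]), numeric(1)),
    spread = vapply(c("dHm_err", "Tm_err", "dCp_err", "Tc_err", "Ts_err"),
                    function(k) stats::sd(errors[[k]]), numeric(1)),
    n_converged = nrow(errors), n_reps = n_reps)
  rownames(recovery) <- NULL
  if (!is.null(config$out_dir))
    utils::write.table(recovery, file.path(config$out_dir, "recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(path = path, dataset = dataset, recovery = recovery, errors = errors)
}
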