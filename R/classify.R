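#' Build the buried-core reference stability curve
#'
#' Averages the folded populations of the residues selected by the RAD
#' burial criterion (default: RAD < 0.1) at each temperature, then fits the
#' two-state model to the averaged series. The arithmetic mean at each
#' temperature runs over the members that have a value there. Residues whose
#' individual fits are flagged can be excluded by passing `fits`.
#'
#' Alternatively (`method = "parameters"`) the reference is the mean of the
#' members' fitted parameters; averaging populations is the default because
#' it weighs every temperature point rather than every fitted summary.
#'
#' @param populations named list of [population_series()] (names or
#'   `residue_label` attributes identify residues).
#' @param rad a `rad_table` (see [rad_records()] / [read_rad_table()]).
#' @param threshold RAD selection threshold (default 0.1).
#' @param fits optional named list of [fit_stability()] results used to drop
#'   flagged members.
#' @param method `"populations"` (default) or `"parameters"`.
#' @return An object of class `reference_curve`: list with `members`,
#'   `populations` (the averaged series), `fit` (a `stab_fit`), `params`.
#' @export
build_reference <- function(populations, rad, threshold = 0.1, fits = NULL,
                            method = c("populations", "parameters")) {
  method <- match.arg(method)
  labels <- vapply(populations, function(p) attr(p, "residue_label"),
                   character(1))
  names(populations) <- labels
  members <- intersect(labels, select_by_rad(rad, threshold))
  if (!is.null(fits)) {
    flagged <- vapply(fits, function(f) isTRUE(f$flagged), logical(1))
    members <- setdiff(members, names(fits)[flagged])
  }
  if (length(members) < 2L)
    stop("need at least 2 unflagged members with RAD < ", threshold,
         " to build a reference curve (got ", length(members), ")")
  member_pops <- populations[members]

  if (method == "parameters") {
    if (is.null(fits)) stop("method = 'parameters' requires fits")
    cf <- vapply(fits[members], coef, numeric(3))
    params <- thermo_params(mean(cf["dHm", ]), mean(cf["Tm", ]),
                            mean(cf["dCp", ]))
    avg <- average_populations(member_pops)
    fit <- NULL
  } else {
    avg <- average_populations(member_pops)
    fit <- fit_stability(avg)
    if (fit$flagged)
      warning("reference-curve fit is flagged: ",
              paste(fit$flags, collapse = "; "))
    params <- fit$params
  }
  structure(list(members = members, populations = avg, fit = fit,
                 params = params, threshold = threshold, method = method),
            class = "reference_curve")
}

average_populations <- function(pops) {
  temps <- sort(unique(unlist(lapply(pops, function(p) p$temperature))))
  f_F <- vapply(temps, function(tt) {
    vals <- unlist(lapply(pops, function(p) p$f_F[p$temperature == tt]))
    mean(vals)
  }, numeric(1))
  population_series("reference", temps, f_F)
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf("Reference stability curve (RAD < %s, %d members, %s-averaged)\n",
              format(x$threshold), length(x$members), x$method))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Classify a residue against the reference curve
#'
#' Compares a residue's melting and cold-denaturation temperatures with the
#' reference: `dTm = Tm - Tm_ref`, `dTc = Tc - Tc_ref`, and the mean absolute
#' shift `(|dTm| + |dTc|)/2`. A residue is `consistent` when the mean shift
#' is below `consistent_K` (default 1.5 K), an `outlier` above `outlier_K`
#' (default 3 K), `intermediate` in between, and `unclassifiable` when its
#' fit is flagged.
#'
#' @param fit a [fit_stability()] result (or a [thermo_params()]).
#' @param ref a [build_reference()] curve (or a [thermo_params()]).
#' @param consistent_K,outlier_K classification thresholds, K.
#' @param mech_fraction passed to [mechanism_decomposition()].
#' @return a one-row data frame of class `classification_record` with
#'   columns `residue_label`, `dTm`, `dTc`, `mean_abs_dT`, `category`,
#'   `mechanisms`, `ddHs`, `ddCp`, `dTs`.
#' @export
classify_residue <- function(fit, ref, consistent_K = 1.5, outlier_K = 3.0,
                             mech_fraction = 0.1) {
  stopifnot(consistent_K > 0, outlier_K > consistent_K)
  label <- if (inherits(fit, "stab_fit")) fit$residue_label else "residue"
  p <- if (inherits(fit, "stab_fit")) fit$params else as_thermo_params(fit)
  pref <- if (inherits(ref, "reference_curve")) ref$params
          else as_thermo_params(ref)
  flagged <- inherits(fit, "stab_fit") && fit$flagged
  if (flagged || is.null(p) || is.na(p$Tc) || is.na(pref$Tc)) {
    rec <- data.frame(residue_label = label, dTm = NA_real_, dTc = NA_real_,
                      mean_abs_dT = NA_real_, category = "unclassifiable",
                      mechanisms = "", ddHs = NA_real_, ddCp = NA_real_,
                      dTs = NA_real_, stringsAsFactors = FALSE)
    class(rec) <- c("classification_record", "data.frame")
    return(rec)
  }
  dTm <- p$Tm - pref$Tm
  dTc <- p$Tc - pref$Tc
  mad <- (abs(dTm) + abs(dTc)) / 2
  category <- if (mad < consistent_K) "consistent"
              else if (mad > outlier_K) "outlier"
              else "intermediate"
  mech <- mechanism_decomposition(p, pref, fraction = mech_fraction)
  rec <- data.frame(residue_label = label, dTm = dTm, dTc = dTc,
                    mean_abs_dT = mad, category = category,
                    mechanisms = paste(mech$labels, collapse = ","),
                    ddHs = mech$ddHs, ddCp = mech$ddCp, dTs = mech$dTs,
                    stringsAsFactors = FALSE)
  class(rec) <- c("classification_record", "data.frame")
  rec
}

#' Decompose a stability-curve difference into thermostability mechanisms
#'
#' Expresses how a residue's stability curve differs from the reference in
#' the classic three-mechanism taxonomy of thermostability change:
#' mechanism I -- a change in the peak free energy `dHs` (the curve lifts or
#' drops at unchanged shape); mechanism II -- a change in `dCp` (the curve
#' broadens or sharpens at unchanged maximum, since the curvature is
#' `-dCp/T`); mechanism III -- a lateral shift of the whole curve (a change
#' in `Ts`, driven by the entropy difference). Real curves are mixtures, so
#' every component whose magnitude exceeds `fraction` of its reference scale
#' is labelled. Scales: `|dHs_ref|` for I, `dCp_ref` for II, and the
#' reference stability width `Tm_ref - Tc_ref` for III (a fraction of an
#' absolute Kelvin temperature would be meaningless).
#'
#' @param p,ref [thermo_params()] (or `stab_fit` / `reference_curve`).
#' @param fraction labelling threshold as a fraction of the reference scale.
#' @return list with `ddHs`, `ddCp`, `dTs` (signed magnitudes) and `labels`
#'   (subset of `c("I", "II", "III")`).
#' @export
mechanism_decomposition <- function(p, ref, fraction = 0.1) {
  if (inherits(p, "stab_fit")) p <- p$params
  if (inherits(ref, "reference_curve")) ref <- ref$params
  p <- as_thermo_params(p); ref <- as_thermo_params(ref)
  ddHs <- p$dHs - ref$dHs
  ddCp <- p$dCp - ref$dCp
  dTs <- p$Ts - ref$Ts
  width <- if (!is.na(ref$Tc)) ref$Tm - ref$Tc else 20
  labels <- character(0)
  if (is.finite(ddHs) && abs(ddHs) > fraction * abs(ref$dHs))
    labels <- c(labels, "I")
  if (is.finite(ddCp) && abs(ddCp) > fraction * ref$dCp)
    labels <- c(labels, "II")
  if (is.finite(dTs) && abs(dTs) > fraction * width)
    labels <- c(labels, "III")
  list(ddHs = ddHs, ddCp = ddCp, dTs = dTs, labels = labels)
}

#' Classify many residues at once
#'
#' @param fits named list of [fit_stability()] results (or of
#'   [thermo_params()]).
#' @inheritParams classify_residue
#' @param ref a [build_reference()] curve or [thermo_params()].
#' @return a `classification_record` data frame, one row per residue.
#' @export
classify_residues <- function(fits, ref, consistent_K = 1.5, outlier_K = 3.0,
                              mech_fraction = 0.1) {
  recs <- lapply(fits, classify_residue, ref = ref,
                 consistent_K = consistent_K, outlier_K = outlier_K,
                 mech_fraction = mech_fraction)
  if (!is.null(names(fits))) {
    lbl <- vapply(recs, function(r) r$residue_label, character(1))
    fix <- lbl == "residue"
    for (i in which(fix)) recs[[i]]$residue_label <- names(fits)[i]
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("classification_record", "data.frame")
  out
}

#' Summarise classifications by secondary-structure element
#'
#' Groups classification records by secondary-structure element (helix,
#' strand, loop labels from an annotation table; residues without an
#' annotation are grouped as `"loop"`) and reports per-element residue
#' lists, mean temperature shifts, and counts per category.
#'
#' @param records a `classification_record` data frame.
#' @param ss annotation data frame with columns `residue_label`, `element`
#'   (e.g. `H1`, `H2`, `S1`..`S6`, `loop`); or a TSV path.
#' @return a data frame with one row per element: `element`, `n`,
#'   `residues`, `mean_dTm`, `mean_dTc`, `n_consistent`, `n_intermediate`,
#'   `n_outlier`, `n_unclassifiable`.
#' @export
group_by_secondary_structure <- function(records, ss = NULL) {
  stopifnot(is.data.frame(records))
  if (is.character(ss) && length(ss) == 1L)
    ss <- utils::read.table(ss, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  element <- rep("loop", nrow(records))
  if (!is.null(ss)) {
    stopifnot(all(c("residue_label", "element") %in% names(ss)))
    m <- match(records$residue_label, ss$residue_label)
    element[!is.na(m)] <- ss$element[m[!is.na(m)]]
  }
  groups <- split(seq_len(nrow(records)), element)
  rows <- lapply(names(groups), function(el) {
    idx <- groups[[el]]
    r <- records[idx, , drop = FALSE]
    data.frame(element = el, n = nrow(r),
               residues = paste(r$residue_label, collapse = ","),
               mean_dTm = mean(r$dTm, na.rm = TRUE),
               mean_dTc = mean(r$dTc, na.rm = TRUE),
               n_consistent = sum(r$category == "consistent"),
               n_intermediate = sum(r$category == "intermediate"),
               n_outlier = sum(r$category == "outlier"),
               n_unclassifiable = sum(r$category == "unclassifiable"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
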