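#' Per-residue peak-volume temperature series
#'
#' One residue's (temperature, raw peak volume, reference-peak volume)
#' records from a 2D NMR melting series. Reference volumes come from an
#' internal-standard peak acquired at the same temperature (they filter out
#' the instrumental non-linearity between volume and population);
#' normalisation divides each raw volume by the reference volume.
#'
#' @param residue_label residue identifier, e.g. `"70 Leu"` (side-chain
#'   indoles flagged as in `"131 Trp sc"`).
#' @param temperature temperatures, K, strictly increasing.
#' @param volume raw peak volumes (arbitrary units).
#' @param reference reference-peak volumes at the same temperatures; all > 0.
#' @return An object of class `volume_series`: a data frame with columns
#'   `temperature`, `volume`, `reference`, `normalized` and attribute
#'   `residue_label`.
#' @export
volume_series <- function(residue_label, temperature, volume,
                          reference = rep(1, length(temperature))) {
  stopifnot(length(temperature) == length(volume),
            length(temperature) == length(reference))
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperatures must be positive (absolute Kelvin)")
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  bad <- which(!is.finite(reference) | reference <= 0)
  if (length(bad))
    stop("non-positive reference volume at T = ",
         paste(temperature[bad], collapse = ", "), " K")
  out <- data.frame(temperature = as.numeric(temperature),
                    volume = as.numeric(volume),
                    reference = as.numeric(reference),
                    normalized = as.numeric(volume) / as.numeric(reference))
  structure(out, residue_label = as.character(residue_label),
            class = c("volume_series", "data.frame"))
}

#' @export
print.volume_series <- function(x, ...) {
  cat("Peak-volume series for residue", attr(x, "residue_label"),
      sprintf("(%d temperatures, %.1f-%.1f K)\n",
              nrow(x), min(x$temperature), max(x$temperature)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Normalise peak volumes by the reference peak
#'
#' Divides each raw volume by the reference-peak volume at the same
#' temperature. [volume_series()] already computes the normalised column;
#' this re-derives it (e.g. after editing raw values) and errors on
#' non-positive reference volumes, naming the offending temperature.
#'
#' @param series a [volume_series()].
#' @return the series with the `normalized` column recomputed.
#' @export
normalize_volumes <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  bad <- which(!is.finite(series$reference) | series$reference <= 0)
  if (length(bad))
    stop("non-positive reference volume at T = ",
         paste(series$temperature[bad], collapse = ", "), " K")
  series$normalized <- series$volume / series$reference
  series
}

#' Per-residue folded/unfolded population series
#'
#' @param residue_label residue identifier.
#' @param temperature temperatures, K.
#' @param f_F folded fractions in `[0, 1]`.
#' @param anchor_T,anchor_fraction the anchoring applied (see
#'   [volumes_to_populations()]); `NA` when populations were not anchored.
#' @param n_clipped number of points clipped into `[0, 1]`.
#' @return An object of class `population_series`: a data frame with columns
#'   `temperature`, `f_F`, `f_U`.
#' @export
population_series <- function(residue_label, temperature, f_F,
                              anchor_T = NA_real_,
                              anchor_fraction = NA_real_,
                              n_clipped = 0L) {
  stopifnot(length(temperature) == length(f_F))
  if (any(f_F < -1e-12) || any(f_F > 1 + 1e-12))
    stop("folded fractions must lie in [0, 1]")
  f_F <- pmin(1, pmax(0, f_F))
  out <- data.frame(temperature = as.numeric(temperature),
                    f_F = as.numeric(f_F),
                    f_U = 1 - as.numeric(f_F))
  structure(out, residue_label = as.character(residue_label),
            anchor_T = anchor_T, anchor_fraction = anchor_fraction,
            n_clipped = as.integer(n_clipped),
            class = c("population_series", "data.frame"))
}

#' @export
print.population_series <- function(x, ...) {
  cat("Population series for residue", attr(x, "residue_label"), "\n")
  if (!is.na(attr(x, "anchor_T")))
    cat(sprintf("  anchored: f_F(%.2f K) = %.3f; %d point(s) clipped to [0,1]\n",
                attr(x, "anchor_T"), attr(x, "anchor_fraction"),
                attr(x, "n_clipped")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Transform normalised volumes into folded populations
#'
#' Applies the two-state volume-to-population map: the apparent folded
#' fraction is `a(T) = (V(T) - V_U) / (V_F - V_U)` where `V_F` is the
#' maximum normalised volume and `V_U` the unfolded-state baseline. Under
#' the default rule (`v_u_rule = "top"`) `V_U` is the normalised volume at
#' the highest measured temperature, where the protein is assumed fully
#' unfolded; `v_u_rule = "zero"` sets `V_U = 0` (appropriate when the folded
#' peak carries no unfolded-state contribution, e.g. noiseless synthetic
#' data exactly proportional to the folded fraction).
#'
#' The apparent fractions are then anchored: multiplied by
#' `anchor_fraction / a(anchor_T)` so the folded population at the measured
#' temperature nearest `anchor_T` equals `anchor_fraction` (for Yfh1, 70%
#' folded at room temperature, as established independently by CD). Set
#' `anchor_fraction = NA` to skip anchoring. Fractions are clipped to
#' `[0, 1]` and the number of clipped points recorded.
#'
#' @param series a [volume_series()] with normalised volumes.
#' @param anchor_T anchor temperature, K (default 298.15); the nearest
#'   measured temperature is used.
#' @param anchor_fraction folded fraction imposed at the anchor (default
#'   0.70); `NA` disables anchoring.
#' @param v_u_rule `"top"` (unfolded baseline = top-temperature volume, the
#'   standard analysis) or `"zero"`.
#' @return a [population_series()].
#' @export
volumes_to_populations <- function(series, anchor_T = 298.15,
                                   anchor_fraction = 0.70,
                                   v_u_rule = c("top", "zero")) {
  stopifnot(inherits(series, "volume_series"))
  v_u_rule <- match.arg(v_u_rule)
  v <- series$normalized
  V_U <- if (v_u_rule == "top") v[length(v)] else 0
  V_F <- max(v)
  if (abs(V_F - V_U) < .Machine$double.eps * max(1, abs(V_F)))
    stop("degenerate series for residue ", attr(series, "residue_label"),
         ": V_F equals V_U (flat volume profile), populations undefined")
  a <- (v - V_U) / (V_F - V_U)
  n_clipped <- 0L
  if (!is.na(anchor_fraction)) {
    i <- which.min(abs(series$temperature - anchor_T))
    if (a[i] <= 0)
      stop("apparent folded fraction at the anchor temperature is not ",
           "positive; cannot anchor residue ", attr(series, "residue_label"))
    a <- a * (anchor_fraction / a[i])
    anchor_T_used <- series$temperature[i]
  } else {
    anchor_T_used <- NA_real_
  }
  n_clipped <- sum(a < 0 | a > 1)
  a <- pmin(1, pmax(0, a))
  population_series(attr(series, "residue_label"),
                    series$temperature, a,
                    anchor_T = anchor_T_used,
                    anchor_fraction = anchor_fraction,
                    n_clipped = n_clipped)
}

#' Read a per-residue volume table
#'
#' Long format: columns `residue_label`, `temperature_K`, `volume`,
#' `reference_volume` (TSV or CSV, sniffed from the header line). Wide
#' format: a `residue_label` column plus one column per temperature named
#' like `T278` / `278` / `X278.5`; reference volumes are taken from the row
#' whose label is `reference` (case-insensitive), defaulting to 1 when no
#' such row exists.
#'
#' @param path file path.
#' @return a named list of [volume_series()], one per residue.
#' @export
read_volume_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  long_cols <- c("residue_label", "temperature_K", "volume", "reference_volume")
  if (all(long_cols %in% names(df))) {
    split_df <- split(df, df$residue_label)
    out <- lapply(split_df, function(d) {
      d <- d[order(d$temperature_K), ]
      volume_series(d$residue_label[1L], d$temperature_K, d$volume,
                    d$reference_volume)
    })
    return(out[unique(df$residue_label)])
  }
  if (!"residue_label" %in% names(df))
    stop("volume table must have a residue_label column")
  temp_cols <- setdiff(names(df), "residue_label")
  temps <- suppressWarnings(as.numeric(sub("^[TtXx]", "", temp_cols)))
  if (any(is.na(temps)))
    stop("wide-format temperature columns could not be parsed: ",
         paste(temp_cols[is.na(temps)], collapse = ", "))
  ord <- order(temps)
  is_ref <- tolower(df$residue_label) %in% c("reference", "ref")
  ref <- if (any(is_ref)) as.numeric(df[which(is_ref)[1L], temp_cols])[ord]
         else rep(1, length(temps))
  rows <- df[!is_ref, , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i)
    volume_series(rows$residue_label[i],
                  temps[ord], as.numeric(rows[i, temp_cols])[ord], ref))
  names(out) <- rows$residue_label
  out
}

#' Write a Table-1-style parameter table
#'
#' One row per fitted residue with the fitted and derived thermodynamic
#' parameters in explicit units; see [run_fit()].
#'
#' @param fits a list of [fit_stability()] results.
#' @param path output TSV path (use `NULL` to return the data frame only).
#' @return the data frame, invisibly when written.
#' @export
write_param_table <- function(fits, path = NULL) {
  na_params <- list(dHm = NA_real_, dSm = NA_real_, dCp = NA_real_,
                    Tm = NA_real_, Tc = NA_real_, Ts = NA_real_,
                    dHs = NA_real_)
  rows <- lapply(fits, function(f) {
    p <- if (is.null(f$params)) na_params else f$params
    data.frame(residue_label = f$residue_label,
               dH_kcal_mol = p$dHm,
               dS_kcal_mol_K = p$dSm,
               dCp_kcal_mol_K = p$dCp,
               Tm_K = p$Tm, Tc_K = p$Tc, Ts_K = p$Ts,
               dHs_kcal_mol = p$dHs,
               converged = f$converged && !f$flagged,
               n_points = f$n_points,
               flags = paste(f$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
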