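## Gas constant in kcal mol^-1 K^-1; all free energies in this package are
## kcal/mol and all temperatures absolute Kelvin.
R_KCAL <- 1.987e-3

#' Two-state unfolding thermodynamic parameters
#'
#' Container for the three fitted parameters of the modified Gibbs-Helmholtz
#' stability curve -- the unfolding enthalpy at the melting point
#' (`dHm`, kcal/mol), the heat-melting temperature (`Tm`, K) and the
#' heat-capacity difference between unfolded and folded states
#' (`dCp`, kcal/mol/K) -- together with the derived quantities: unfolding
#' entropy at the melting point `dSm = dHm/Tm`, temperature of maximum
#' stability `Ts = Tm * exp(-dHm/(Tm*dCp))`, unfolding enthalpy at maximum
#' stability `dHs = dHm + dCp*(Ts - Tm)` (equal to the peak free energy,
#' since the entropy change vanishes at `Ts`), and the cold-denaturation
#' temperature `Tc` (the low-temperature zero of the stability curve,
#' `NA` if none exists above `tc_floor`).
#'
#' The sign convention is `dG = G_unfolded - G_folded`: positive free energy
#' means the folded state is more stable.
#'
#' @param dHm unfolding enthalpy at `Tm`, kcal/mol.
#' @param Tm heat-melting temperature, K (must be positive).
#' @param dCp heat-capacity difference, kcal/mol/K.
#' @param cov optional symmetric 3x3 covariance matrix over
#'   `(dHm, Tm, dCp)` from a least-squares fit.
#' @param tc_floor lowest temperature (K) searched for a cold-denaturation
#'   zero; below it the transition is deemed unobservable and `Tc` is `NA`.
#' @return An object of class `thermo_params`: a list with elements `dHm`,
#'   `Tm`, `dCp`, `dSm`, `Ts`, `dHs`, `Tc`, `cov`.
#' @examples
#' p <- thermo_params(dHm = 28.5, Tm = 298.2, dCp = 3.73)
#' p$Ts    # ~290.7 K
#' p$Tc    # ~283.1 K
#' @export
thermo_params <- function(dHm, Tm, dCp, cov = NULL, tc_floor = 150) {
  stopifnot(is.numeric(dHm), is.numeric(Tm), is.numeric(dCp),
            length(dHm) == 1L, length(Tm) == 1L, length(dCp) == 1L)
  dHm <- unname(dHm); Tm <- unname(Tm); dCp <- unname(dCp)
  if (!is.finite(Tm) || Tm <= 0)
    stop("Tm must be a positive absolute temperature (K)")
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (!all(dim(cov) == c(3L, 3L)))
      stop("cov must be a 3x3 matrix over (dHm, Tm, dCp)")
    if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
      stop("cov must be symmetric")
    dimnames(cov) <- list(c("dHm", "Tm", "dCp"), c("dHm", "Tm", "dCp"))
  }
  p <- structure(
    list(dHm = dHm, Tm = Tm, dCp = dCp,
         dSm = dHm / Tm, Ts = NA_real_, dHs = NA_real_, Tc = NA_real_,
         cov = cov),
    class = "thermo_params")
  if (is.finite(dCp) && dCp > 0) {
    p$Ts <- Tm * exp(-dHm / (Tm * dCp))
    p$dHs <- dHm + dCp * (p$Ts - Tm)
    tc <- tryCatch(
      suppressWarnings(cold_denaturation_temp(p, floor = tc_floor)),
      error = function(e) NA_real_)
    p$Tc <- tc
  }
  p
}

as_thermo_params <- function(p) {
  if (inherits(p, "thermo_params")) return(p)
  if (is.numeric(p) && length(p) == 3L)
    return(thermo_params(p[[1L]], p[[2L]], p[[3L]]))
  if (is.list(p) && all(c("dHm", "Tm", "dCp") %in% names(p)))
    return(thermo_params(p$dHm, p$Tm, p$dCp, cov = p$cov))
  stop("cannot interpret 'p' as thermo_params; supply thermo_params(), ",
       "a list with dHm/Tm/dCp, or a numeric vector c(dHm, Tm, dCp)")
}

#' @export
print.thermo_params <- function(x, digits = 4, ...) {
  cat("Two-state stability parameters (dG = G_U - G_F, kcal/mol)\n")
  cat(sprintf("  dHm = %s kcal/mol   Tm = %s K   dCp = %s kcal/mol/K\n",
              format(x$dHm, digits = digits), format(x$Tm, digits = digits),
              format(x$dCp, digits = digits)))
  cat(sprintf("  dSm = %s kcal/mol/K   Ts = %s K   dHs = %s kcal/mol   Tc = %s K\n",
              format(x$dSm, digits = digits), format(x$Ts, digits = digits),
              format(x$dHs, digits = digits),
              if (is.na(x$Tc)) "NA (no observable cold denaturation)"
              else format(x$Tc, digits = digits)))
  if (!is.null(x$cov))
    cat("  covariance over (dHm, Tm, dCp) attached\n")
  invisible(x)
}

#' Modified Gibbs-Helmholtz stability curve
#'
#' Free energy of unfolding at temperature `T` under a temperature-independent
#' heat-capacity difference:
#' `dG(T) = dHm*(1 - T/Tm) + dCp*((T - Tm) - T*log(T/Tm))`.
#' The curve is an inverted-parabola-like function with zeros at the
#' cold-denaturation temperature `Tc` and the melting temperature `Tm`, and
#' maximum at `Ts`.
#'
#' @param T temperature(s), K; must be positive.
#' @param p a [thermo_params()] object (or anything [thermo_params()] can be
#'   built from: a numeric `c(dHm, Tm, dCp)` or a named list).
#' @return dG in kcal/mol, vectorised over `T`.
#' @examples
#' gibbs_helmholtz(283.1, c(28.5, 298.2, 3.73))  # ~0 at Tc
#' @export
gibbs_helmholtz <- function(T, p) {
  p <- as_thermo_params(p)
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be positive (absolute Kelvin)")
  p$dHm * (1 - T / p$Tm) + p$dCp * ((T - p$Tm) - T * log(T / p$Tm))
}

#' Boltzmann populations of the two-state model
#'
#' Unfolded fraction at temperature `T` given the unfolding free energy:
#' `f_U = exp(-dG/RT) / (1 + exp(-dG/RT))`, with
#' R = 1.987e-3 kcal/mol/K. `folded_fraction()` returns `1 - f_U`.
#'
#' @param T temperature(s), K.
#' @param dG unfolding free energy, kcal/mol (vectorised).
#' @return fraction in `[0, 1]`.
#' @examples
#' unfolded_fraction(298.15, 0)  # 0.5 at a zero of the stability curve
#' @export
unfolded_fraction <- function(T, dG) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be positive (absolute Kelvin)")
  ## plogis(-dG/RT) is numerically stable for large |dG|
  stats::plogis(-dG / (R_KCAL * T))
}

#' @rdname unfolded_fraction
#' @export
folded_fraction <- function(T, dG) 1 - unfolded_fraction(T, dG)

#' Temperature of maximum stability
#'
#' Closed-form argmax of the stability curve,
#' `Ts = Tm * exp(-dSm/dCp) = Tm * exp(-dHm/(Tm*dCp))` -- the temperature at
#' which the unfolding entropy change vanishes. Requires `dCp > 0`
#' (otherwise the curve has no interior maximum).
#'
#' @inheritParams gibbs_helmholtz
#' @return Ts in K.
#' @export
max_stability_temp <- function(p) {
  p <- as_thermo_params(p)
  if (!is.finite(p$dCp) || p$dCp <= 0)
    stop("dCp must be positive: the stability curve has no interior maximum")
  p$Tm * exp(-p$dHm / (p$Tm * p$dCp))
}

#' Cold-denaturation temperature
#'
#' The low-temperature zero of the stability curve, found by bracketed root
#' search on `(floor, Ts)` to |dG| < 1e-9 kcal/mol. When the curve does not
#' cross zero above `floor` (default 150 K), cold denaturation is not
#' observable and `NA` is returned with a warning.
#'
#' @inheritParams gibbs_helmholtz
#' @param floor lowest temperature (K) considered physically meaningful.
#' @return Tc in K, or `NA` when no zero exists above `floor`.
#' @examples
#' cold_denaturation_temp(c(28.5, 298.2, 3.73))  # ~283.1 K
#' @export
cold_denaturation_temp <- function(p, floor = 150) {
  p <- as_thermo_params(p)
  if (!is.finite(p$dCp) || p$dCp <= 0)
    stop("dCp must be positive: in the dCp -> 0 limit dG is linear in T ",
         "with a single root at Tm and no cold denaturation")
  ts <- p$Tm * exp(-p$dHm / (p$Tm * p$dCp))
  if (gibbs_helmholtz(ts, p) <= 0)
    stop("stability curve is non-positive at its maximum; no folded regime")
  if (gibbs_helmholtz(floor, p) > 0) {
    warning("no observable cold denaturation above ", floor, " K")
    return(NA_real_)
  }
  root <- stats::uniroot(function(T) gibbs_helmholtz(T, p),
                         lower = floor, upper = ts,
                         f.lower = gibbs_helmholtz(floor, p),
                         f.upper = gibbs_helmholtz(ts, p),
                         tol = 1e-12)
  ## polish with a few Newton steps so |dG(Tc)| < 1e-9 kcal/mol
  tc <- root$root
  for (i in 1:5) {
    g <- gibbs_helmholtz(tc, p)
    if (abs(g) < 1e-12) break
    slope <- -p$dHm / p$Tm - p$dCp * log(tc / p$Tm)
    tc <- tc - g / slope
  }
  tc
}

#' Unfolding entropy at the melting point
#'
#' `dSm = dHm / Tm`, from `dG(Tm) = 0`.
#'
#' @inheritParams gibbs_helmholtz
#' @return dSm in kcal/mol/K.
#' @export
entropy_at_tm <- function(p) {
  p <- as_thermo_params(p)
  p$dHm / p$Tm
}

#' Curvature of the stability curve
#'
#' Second temperature derivative of the Gibbs-Helmholtz free energy,
#' `d2(dG)/dT2 = -dCp/T`. The heat-capacity difference thus sets how sharply
#' the stability curve bends (mechanism II of thermostability change:
#' a smaller dCp broadens the curve at unchanged maximum).
#'
#' @inheritParams gibbs_helmholtz
#' @return curvature in kcal/mol/K^2, vectorised over `T`.
#' @export
curvature <- function(T, p) {
  p <- as_thermo_params(p)
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be positive (absolute Kelvin)")
  -p$dCp / T
}

#' Naive intensity-based stability
#'
#' The free energy a two-state analysis would assign directly to an observed
#' folded-peak intensity fraction `I_f`:
#' `dG~(T) = -RT * log((1 - I_f)/I_f)`. Used to study how NMR artefacts that
#' attenuate peak volumes distort the apparent stability curve.
#'
#' @param T temperature(s), K.
#' @param I_f folded-peak intensity fraction, strictly inside (0, 1).
#' @return apparent dG in kcal/mol.
#' @export
naive_stability <- function(T, I_f) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperatures must be positive (absolute Kelvin)")
  if (any(I_f <= 0) || any(I_f >= 1))
    stop("I_f must lie strictly inside (0, 1): ",
         "the log-odds diverge at I_f = 0 or 1")
  -R_KCAL * T * log((1 - I_f) / I_f)
}

## --- linear reparameterisation of the Gibbs-Helmholtz family -------------
## With dCp fixed, dG(T) = c0 + c1*T - dCp*T*log(T), where
##   c0 = dHm - dCp*Tm
##   c1 = -dHm/Tm + dCp*(1 + log(Tm))
## This makes the family linear in (c0, c1, dCp) and is used to construct
## pure mechanism variants (lift, broaden, translate) and to fit a
## Gibbs-Helmholtz curve to free-energy values by exact least squares.

#' Linear coefficients of a Gibbs-Helmholtz curve
#'
#' Reparameterises the stability curve as `dG(T) = c0 + c1*T - dCp*T*log(T)`,
#' linear in `(c0, c1, dCp)`. `gh_from_linear()` inverts the map back to
#' `(dHm, Tm, dCp)` (solving for `Tm` by root search).
#'
#' @inheritParams gibbs_helmholtz
#' @return `gh_linear_coefs`: named numeric `c(c0, c1, dCp)`.
#' @export
gh_linear_coefs <- function(p) {
  p <- as_thermo_params(p)
  c(c0 = p$dHm - p$dCp * p$Tm,
    c1 = -p$dHm / p$Tm + p$dCp * (1 + log(p$Tm)),
    dCp = p$dCp)
}

#' @rdname gh_linear_coefs
#' @param c0,c1 linear coefficients.
#' @param dCp heat-capacity difference, kcal/mol/K (must be positive).
#' @param interval search interval for `Tm` (K).
#' @return `gh_from_linear`: a [thermo_params()] object.
#' @export
gh_from_linear <- function(c0, c1, dCp, interval = c(200, 500)) {
  if (dCp <= 0) stop("dCp must be positive")
  ## dG(T) = c0 + c1*T - dCp*T*log(T) has (up to) two zeros; Tm is the one
  ## above the maximum Ts = exp(c1/dCp - 1), so bracket on [Ts, upper].
  ts <- exp(c1 / dCp - 1)
  dg <- function(T) c0 + c1 * T - dCp * T * log(T)
  if (dg(ts) <= 0)
    stop("curve is non-positive at its maximum: no folded regime")
  if (dg(interval[2L]) >= 0)
    stop("no melting-side zero below ", interval[2L], " K")
  Tm <- stats::uniroot(dg, lower = ts, upper = interval[2L],
                       tol = 1e-12)$root
  thermo_params(dHm = c0 + dCp * Tm, Tm = Tm, dCp = dCp)
}

#' Least-squares Gibbs-Helmholtz fit to free-energy values
#'
#' Fits `dG(T) = c0 + c1*T - dCp*T*log(T)` to `(T, dG)` pairs by ordinary
#' (exact, linear) least squares and converts back to `(dHm, Tm, dCp)`.
#' Useful for fitting naive intensity-based stability values and for
#' projecting a translated curve back onto the Gibbs-Helmholtz family.
#'
#' @param T temperatures, K.
#' @param dG free energies, kcal/mol.
#' @return a [thermo_params()] object.
#' @export
fit_gibbs_helmholtz_dg <- function(T, dG) {
  stopifnot(length(T) == length(dG), length(T) >= 3L)
  X <- cbind(1, T, -T * log(T))
  beta <- stats::lm.fit(X, dG)$coefficients
  gh_from_linear(beta[[1L]], beta[[2L]], beta[[3L]])
}
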