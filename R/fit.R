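#' Fit a per-residue stability curve
#'
#' Fits the two-state model to a folded/unfolded population series by
#' damped (Levenberg-Marquardt) least squares: the unfolded fraction is
#' modelled as the Boltzmann population
#' `f_U(T) = exp(-dG/RT) / (1 + exp(-dG/RT))` with `dG(T)` the modified
#' Gibbs-Helmholtz curve in `(dHm, Tm, dCp)`. The highest measured
#' temperature is excluded from the fit: it serves as the unfolded-state
#' reference in the volume-to-population transform, where `f_U = 1` holds by
#' assumption rather than by measurement. The parameter covariance is taken
#' from the final Jacobian, and the derived quantities (`dSm`, `Ts`, `dHs`,
#' `Tc`) are populated on the returned parameters.
#'
#' Starting values default to: `Tm0` at the steepest high-temperature
#' population drop, `dHm0 = 25` kcal/mol, `dCp0 = 2.5` kcal/mol/K. On
#' failure the fit is retried from 5 jittered starts (deterministic jitter).
#' Fits that do not converge, or converge to unphysical optima
#' (`dHm <= 0`, `dCp <= 0`, or `Tm` outside 250-400 K), are flagged --
#' never silently reported.
#'
#' @param pop a [population_series()] (or a data frame with columns
#'   `temperature` and `f_U` or `f_F`).
#' @param init optional starting values: anything [thermo_params()] accepts.
#' @param exclude_top exclude the top grid temperature (default `TRUE`).
#' @param n_restarts number of jittered restarts after a failed fit.
#' @return An object of class `stab_fit` with elements `params`
#'   ([thermo_params()] with covariance), `residue_label`, `data` (the kept
#'   points), `fitted`, `residuals`, `excluded` (temperatures), `converged`,
#'   `flagged`, `flags`, `n_points`, `n_clipped`.
#' @seealso [predict.stab_fit()], [plot.stab_fit()], [propagate_errors()]
#' @examples
#' p <- thermo_params(28.5, 298.2, 3.73)
#' T <- seq(278, 313, by = 2.5)
#' pop <- population_series("70 Leu", T, folded_fraction(T, gibbs_helmholtz(T, p)))
#' fit <- fit_stability(pop)
#' coef(fit)
#' @export
fit_stability <- function(pop, init = NULL, exclude_top = TRUE,
                          n_restarts = 5L) {
  if (!inherits(pop, "population_series")) {
    stopifnot(is.data.frame(pop), "temperature" %in% names(pop))
    f_F <- if ("f_F" %in% names(pop)) pop$f_F else 1 - pop$f_U
    pop <- population_series("unnamed", pop$temperature, f_F)
  }
  label <- attr(pop, "residue_label")
  T_all <- pop$temperature
  excluded <- numeric(0)
  keep <- rep(TRUE, length(T_all))
  if (exclude_top) {
    keep[which.max(T_all)] <- FALSE
    excluded <- T_all[!keep]
  }
  T <- T_all[keep]
  fU <- pop$f_U[keep]
  if (length(unique(T)) < 6L)
    stop("at least 6 distinct temperatures are required to fit 3 parameters ",
         "with redundancy (", length(unique(T)), " available after exclusion)")

  flags <- character(0)
  if (stats::sd(fU) < 1e-12) {
    flags <- "flat population series: parameters unidentifiable"
    return(new_stab_fit(label, NULL, T, fU, rep(NA_real_, length(T)),
                        excluded, FALSE, flags, attr(pop, "n_clipped")))
  }

  start <- if (!is.null(init)) {
    ip <- as_thermo_params(init)
    c(dHm = ip$dHm, Tm = ip$Tm, dCp = ip$dCp)
  } else {
    default_start(T, fU)
  }

  resid_fn <- function(par) {
    dG <- par[["dHm"]] * (1 - T / par[["Tm"]]) +
      par[["dCp"]] * ((T - par[["Tm"]]) - T * log(T / par[["Tm"]]))
    stats::plogis(-dG / (R_KCAL * T)) - fU
  }

  fit <- try_lm_fit(resid_fn, start)
  if (is.null(fit) || !fit_ok(fit)) {
    ## deterministic jittered restarts
    for (j in seq_len(n_restarts)) {
      jitter <- 1 + 0.15 * sin(j * c(1.3, 2.1, 3.7))
      st <- start * jitter
      st[["Tm"]] <- start[["Tm"]] + 3 * sin(j * 1.7)
      cand <- try_lm_fit(resid_fn, st)
      if (!is.null(cand) && fit_ok(cand) &&
          (is.null(fit) || !fit_ok(fit) || cand$deviance < fit$deviance))
        fit <- cand
    }
  }

  if (is.null(fit)) {
    flags <- "Levenberg-Marquardt did not converge after restarts"
    return(new_stab_fit(label, NULL, T, fU, rep(NA_real_, length(T)),
                        excluded, FALSE, flags, attr(pop, "n_clipped")))
  }

  par <- fit$par
  converged <- fit$info %in% 1:4
  if (!converged)
    flags <- c(flags, paste0("no convergence (nls.lm info = ", fit$info, ")"))
  if (par[["dHm"]] <= 0) flags <- c(flags, "unphysical fit: dHm <= 0")
  if (par[["dCp"]] <= 0) flags <- c(flags, "unphysical fit: dCp <= 0")
  if (par[["Tm"]] < 250 || par[["Tm"]] > 400)
    flags <- c(flags, "unphysical fit: Tm outside [250, 400] K")

  ## covariance from the final Jacobian: sigma^2 * (J'J)^-1
  cov <- NULL
  if (length(flags) == 0L) {
    J <- fit$hessian_jac
    dof <- length(fU) - 3L
    s2 <- if (dof > 0) fit$deviance / dof else 0
    JtJ <- crossprod(J)
    cov <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
    if (is.null(cov)) flags <- c(flags, "singular Jacobian: no covariance")
    else cov <- (cov + t(cov)) / 2
  }

  params <- tryCatch(
    thermo_params(par[["dHm"]], par[["Tm"]], par[["dCp"]], cov = cov),
    error = function(e) NULL)
  if (is.null(params)) {
    flags <- c(flags, "fitted parameters outside the model domain")
    return(new_stab_fit(label, NULL, T, fU, rep(NA_real_, length(T)),
                        excluded, FALSE, flags, attr(pop, "n_clipped")))
  }
  fitted_fU <- unfolded_fraction(T, gibbs_helmholtz(T, params))
  new_stab_fit(label, params, T, fU, fitted_fU, excluded,
               converged, flags, attr(pop, "n_clipped"))
}

default_start <- function(T, fU) {
  ## Tm0: temperature of the steepest population drop in the upper half of
  ## the grid; fall back to the grid midpoint for monotone-flat series.
  dT <- diff(T)
  slope <- diff(1 - fU) / dT
  mid <- (T[-1] + T[-length(T)]) / 2
  hi <- mid >= stats::median(T)
  Tm0 <- if (any(hi) && any(is.finite(slope[hi]))) {
    mid[hi][which.min(slope[hi])]
  } else stats::median(T)
  c(dHm = 25, Tm = Tm0, dCp = 2.5)
}

try_lm_fit <- function(resid_fn, start) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  ## numeric Jacobian at the optimum (forward differences)
  par <- coef(out)
  r0 <- resid_fn(par)
  J <- vapply(seq_along(par), function(k) {
    h <- max(1e-7, 1e-7 * abs(par[[k]]))
    pk <- par; pk[[k]] <- pk[[k]] + h
    (resid_fn(pk) - r0) / h
  }, numeric(length(r0)))
  list(par = par, deviance = out$deviance, info = out$info,
       hessian_jac = J)
}

fit_ok <- function(fit) {
  is.finite(fit$deviance) && fit$info %in% 1:4 &&
    fit$par[["dHm"]] > 0 && fit$par[["dCp"]] > 0 &&
    fit$par[["Tm"]] > 250 && fit$par[["Tm"]] < 400
}

new_stab_fit <- function(label, params, T, fU, fitted_fU, excluded,
                         converged, flags, n_clipped) {
  structure(
    list(residue_label = label,
         params = params,
         data = data.frame(temperature = T, f_U = fU),
         fitted = fitted_fU,
         residuals = fU - fitted_fU,
         excluded = excluded,
         converged = converged && length(flags) == 0L,
         flagged = length(flags) > 0L,
         flags = flags,
         n_points = length(T),
         n_clipped = if (is.null(n_clipped)) 0L else n_clipped),
    class = "stab_fit")
}

#' @export
print.stab_fit <- function(x, ...) {
  cat("Two-state stability-curve fit for residue", x$residue_label, "\n")
  if (x$flagged) {
    cat("  FLAGGED:", paste(x$flags, collapse = "; "), "\n")
  }
  if (!is.null(x$params)) print(x$params)
  cat(sprintf("  %d points fitted; excluded T: %s; RMS residual %.2e\n",
              x$n_points,
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "none",
              sqrt(mean(x$residuals^2, na.rm = TRUE))))
  invisible(x)
}

#' @export
summary.stab_fit <- function(object, ...) {
  p <- object$params
  se <- if (!is.null(p) && !is.null(p$cov)) sqrt(diag(p$cov))
        else rep(NA_real_, 3)
  out <- list(residue_label = object$residue_label,
              coefficients = if (is.null(p)) NULL else
                cbind(Estimate = c(dHm = p$dHm, Tm = p$Tm, dCp = p$dCp),
                      `Std. Error` = se),
              derived = if (is.null(p)) NULL else
                c(dSm = p$dSm, Ts = p$Ts, dHs = p$dHs, Tc = p$Tc),
              converged = object$converged, flags = object$flags,
              rms_residual = sqrt(mean(object$residuals^2, na.rm = TRUE)),
              n_points = object$n_points)
  class(out) <- "summary.stab_fit"
  out
}

#' @export
print.summary.stab_fit <- function(x, ...) {
  cat("Residue:", x$residue_label, "\n")
  if (!is.null(x$coefficients)) {
    stats::printCoefmat(x$coefficients)
    cat("Derived: ", paste(names(x$derived),
                           format(x$derived, digits = 5),
                           sep = " = ", collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  cat(sprintf("n = %d, RMS residual = %.3e\n", x$n_points, x$rms_residual))
  invisible(x)
}

#' @export
coef.stab_fit <- function(object, ...) {
  p <- object$params
  if (is.null(p)) return(c(dHm = NA_real_, Tm = NA_real_, dCp = NA_real_))
  c(dHm = p$dHm, Tm = p$Tm, dCp = p$dCp)
}

#' @export
vcov.stab_fit <- function(object, ...) {
  if (is.null(object$params) || is.null(object$params$cov))
    stop("fit has no covariance (flagged or degenerate)")
  object$params$cov
}

#' @export
residuals.stab_fit <- function(object, ...) object$residuals

#' Predict the stability curve (with propagated uncertainty)
#'
#' Evaluates the fitted free-energy curve `dG(T)`; with `se.fit = TRUE` the
#' covariance-propagated standard error of `dG` is attached (see
#' [propagate_errors()]).
#'
#' @param object a [fit_stability()] result.
#' @param newdata temperatures (K); default: the fitted grid.
#' @param se.fit also return propagated standard errors.
#' @param what `"dG"` (default), `"f_U"` or `"f_F"`.
#' @param ... unused.
#' @return numeric vector, or a list with elements `fit` and `se.fit`.
#' @export
predict.stab_fit <- function(object, newdata = NULL, se.fit = FALSE,
                             what = c("dG", "f_U", "f_F"), ...) {
  what <- match.arg(what)
  if (is.null(object$params)) stop("cannot predict from a flagged fit")
  T <- if (is.null(newdata)) object$data$temperature else as.numeric(newdata)
  dG <- gibbs_helmholtz(T, object$params)
  val <- switch(what, dG = dG,
                f_U = unfolded_fraction(T, dG),
                f_F = folded_fraction(T, dG))
  if (!se.fit) return(val)
  if (what != "dG")
    stop("se.fit is available for the free-energy scale only")
  list(fit = val, se.fit = propagate_errors(object, T))
}

#' Covariance propagation of stability-curve uncertainty
#'
#' Propagates the fit covariance of `(dHm, Tm, dCp)` onto the free-energy
#' scale: `var dG(T) = g(T)' Sigma g(T)` with the closed-form gradient
#' `g = (1 - T/Tm, dHm*T/Tm^2 + dCp*(T/Tm - 1), (T - Tm) - T*log(T/Tm))`.
#'
#' @param fit a converged [fit_stability()] result (or a [thermo_params()]
#'   carrying a covariance).
#' @param T temperatures, K.
#' @return `sigma_dG(T)` in kcal/mol, non-negative, vectorised over `T`.
#' @export
propagate_errors <- function(fit, T) {
  p <- if (inherits(fit, "stab_fit")) fit$params else as_thermo_params(fit)
  if (is.null(p) || is.null(p$cov))
    stop("no covariance available: fit the curve first (or attach cov)")
  G <- gh_gradient(T, p)
  sqrt(pmax(0, rowSums((G %*% p$cov) * G)))
}

## gradient of the Gibbs-Helmholtz curve in (dHm, Tm, dCp); rows = T
gh_gradient <- function(T, p) {
  cbind(dHm = 1 - T / p$Tm,
        Tm = p$dHm * T / p$Tm^2 + p$dCp * (T / p$Tm - 1),
        dCp = (T - p$Tm) - T * log(T / p$Tm))
}

#' Plot a fitted stability curve
#'
#' Draws `dG(T)` over the fitted range with the covariance-propagated
#' one-sigma band in grey, plus the characteristic temperatures.
#'
#' @param x a [fit_stability()] result.
#' @param band draw the propagated one-sigma band.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stab_fit <- function(x, band = TRUE, ...) {
  if (is.null(x$params)) stop("cannot plot a flagged fit")
  Tr <- range(x$data$temperature)
  Tg <- seq(Tr[1] - 2, Tr[2] + 2, length.out = 200)
  dG <- gibbs_helmholtz(Tg, x$params)
  graphics::plot(Tg, dG, type = "l", lwd = 2,
                 xlab = "Temperature (K)",
                 ylab = expression(Delta * G ~ "(kcal/mol)"),
                 main = paste("Stability curve:", x$residue_label), ...)
  if (band && !is.null(x$params$cov)) {
    s <- propagate_errors(x, Tg)
    graphics::polygon(c(Tg, rev(Tg)), c(dG + s, rev(dG - s)),
                      col = adjustcolor("grey60", alpha.f = 0.5), border = NA)
    graphics::lines(Tg, dG, lwd = 2)
  }
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = c(x$params$Tc, x$params$Ts, x$params$Tm), lty = 2,
                   col = "grey40")
  invisible(x)
}

#' Simulate peak-volume data from a fitted stability curve
#'
#' Generates synthetic volume series from the fitted parameters on the
#' fitted temperature grid (see [generate_series()]).
#'
#' @param object a converged [fit_stability()] result.
#' @param nsim number of replicate series.
#' @param seed RNG seed.
#' @param noise_sigma multiplicative log-normal noise sd.
#' @param ... unused.
#' @return a list of [volume_series()].
#' @export
simulate.stab_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sigma = 0.03, ...) {
  if (is.null(object$params)) stop("cannot simulate from a flagged fit")
  grid <- sort(unique(c(object$data$temperature, object$excluded)))
  lapply(seq_len(nsim), function(i) {
    spec <- synthetic_spec(object$params, grid = grid,
                           noise_sigma = noise_sigma,
                           seed = if (is.null(seed)) i else seed + i - 1L)
    generate_series(spec)$volumes
  })
}
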