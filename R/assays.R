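#' Normalize plate viability signals to vehicle
#'
#' Expresses each well as a percentage of the vehicle (e.g. DMSO) mean.
#'
#' @param signal numeric vector of raw signals.
#' @param vehicle numeric vector of vehicle-well signals (>= 1 well).
#' @return numeric vector of percentages; vehicle wells average exactly 100.
#' @export
viability_normalize <- function(signal, vehicle) {
  if (!length(vehicle)) stop_("need at least one vehicle well")
  m <- mean(vehicle)
  if (!is.finite(m) || m <= 0) stop_("vehicle mean must be positive")
  100 * signal / m
}

#' Effective-kill calls from dual viability assays
#'
#' A compound is an effective killer when both its ATP-based (CellTiter-Glo)
#' and dehydrogenase-based (CCK-8) relative signals are strictly below 10%
#' of vehicle.
#'
#' @param compound_id character vector.
#' @param ctg raw CellTiter-Glo signals; \code{ctg_vehicle} its vehicle wells.
#' @param cck8 raw CCK-8 signals; \code{cck8_vehicle} its vehicle wells.
#' @param ctg_vehicle,cck8_vehicle vehicle-well signals per assay.
#' @param threshold_pct kill threshold, percent (default 10, strict "<").
#' @return data frame: \code{compound_id}, \code{ctg_pct}, \code{cck8_pct},
#'   \code{effective_kill}.
#' @export
viability_records <- function(compound_id, ctg, cck8, ctg_vehicle,
                              cck8_vehicle, threshold_pct = 10) {
  ctg_pct <- viability_normalize(ctg, ctg_vehicle)
  cck8_pct <- viability_normalize(cck8, cck8_vehicle)
  data.frame(compound_id = compound_id, ctg_pct = ctg_pct,
             cck8_pct = cck8_pct,
             effective_kill = ctg_pct < threshold_pct &
               cck8_pct < threshold_pct,
             stringsAsFactors = FALSE)
}

#' Background-corrected BRET ratio in milliBRET units
#'
#' The acceptor/donor ratio (e.g. 618 nm over 460 nm) of the sample minus
#' the same ratio of the no-ligand control, scaled by 1000 (mBU).
#'
#' @param donor,acceptor sample luminescence counts.
#' @param donor_ctrl,acceptor_ctrl no-ligand control counts.
#' @return list: \code{raw_ratio}, \code{control_ratio}, \code{ratio_mbu}.
#' @export
bret_ratio <- function(donor, acceptor, donor_ctrl, acceptor_ctrl) {
  if (any(c(donor, donor_ctrl) <= 0)) stop_("donor counts must be positive")
  raw <- acceptor / donor
  ctrl <- acceptor_ctrl / donor_ctrl
  list(raw_ratio = raw, control_ratio = ctrl,
       ratio_mbu = 1000 * (raw - ctrl))
}

#' Fit a Boltzmann sigmoid to a thermal-shift melt curve
#'
#' Model: \deqn{F(T) = B + (P - B) / (1 + exp((T_m - T)/s))} with low/high
#' baselines B, P, midpoint \eqn{T_m} (the reported melting temperature) and
#' slope s (degrees C). Levenberg-Marquardt least squares; initial values are
#' the 5th/95th signal percentiles for the baselines, the temperature of the
#' steepest finite-difference rise for \eqn{T_m}, and s = 2.
#'
#' @param temperature numeric vector, strictly increasing, degrees C.
#' @param fluorescence numeric vector of dye signals (AU).
#' @return object of class \code{boltzmann_fit}: \code{tm}, \code{slope},
#'   \code{baseline_low}, \code{baseline_high}, \code{rmse}, plus the data
#'   and underlying \code{nls} fit. Methods: \code{print}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{plot}.
#' @export
fit_melt_curve <- function(temperature, fluorescence) {
  if (length(temperature) < 10L) stop_("need >= 10 points across the melt")
  if (is.unsorted(temperature, strictly = TRUE))
    stop_("temperatures must be strictly increasing")
  B0 <- as.numeric(stats::quantile(fluorescence, 0.05))
  P0 <- as.numeric(stats::quantile(fluorescence, 0.95))
  dF <- diff(fluorescence) / diff(temperature)
  tm0 <- temperature[which.max(dF)]
  df <- data.frame(T = temperature, F = fluorescence)
  fit <- tryCatch(
    minpack.lm::nlsLM(F ~ B + (P - B) / (1 + exp((tm - T) / s)), data = df,
                      start = list(B = B0, P = P0, tm = tm0, s = 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_("melt-curve fit failed (%s); init B=%.3g P=%.3g tm=%.1f s=2",
            conditionMessage(e), B0, P0, tm0))
  cf <- stats::coef(fit)
  if (cf[["tm"]] < min(temperature) || cf[["tm"]] > max(temperature))
    warn_("fitted Tm (%.1f) outside the sampled temperature range", cf[["tm"]])
  structure(list(tm = cf[["tm"]], slope = cf[["s"]],
                 baseline_low = min(cf[["B"]], cf[["P"]]),
                 baseline_high = max(cf[["B"]], cf[["P"]]),
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 data = df, fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f C, slope = %.2f C, rmse = %.4g\n",
              x$tm, x$slope, x$rmse))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(tm = object$tm, slope = object$slope,
    baseline_low = object$baseline_low, baseline_high = object$baseline_high)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$data$T
       else if (is.list(newdata)) newdata$T else newdata
  stats::predict(object$fit, newdata = data.frame(T = T))
}

#' @export
residuals.boltzmann_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.boltzmann_fit <- function(x, ...) {
  plot(x$data$T, x$data$F, pch = 16, cex = 0.5, xlab = "temperature (C)",
       ylab = "fluorescence (AU)", ...)
  tt <- seq(min(x$data$T), max(x$data$T), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Ligand-induced melting-temperature shift
#'
#' @param fit_control,fit_treated \code{boltzmann_fit} objects for the
#'   apo/vehicle and ligand-treated conditions.
#' @return list with the two Tm values and \code{delta_tm} (treated - control).
#' @export
delta_tm <- function(fit_control, fit_treated) {
  list(tm_control = fit_control$tm, tm_treated = fit_treated$tm,
       delta_tm = fit_treated$tm - fit_control$tm)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: \deqn{y(c) = bottom + (top - bottom) / (1 + (c / IC50)^{hill})}
#' fitted by Levenberg-Marquardt least squares with the IC50 parameterized on
#' the log scale. Suited to inhibition data expressed as percent of vehicle.
#'
#' @param concentration positive numeric vector (e.g. micromolar).
#' @param pct_signal response at each concentration (percent of vehicle).
#' @return object of class \code{dose_response_fit}: \code{ic50},
#'   \code{hill}, \code{top}, \code{bottom}, \code{rmse}, data and the
#'   underlying fit. Same methods as \code{boltzmann_fit}.
#' @export
fit_dose_response <- function(concentration, pct_signal) {
  if (length(concentration) < 5L)
    stop_("need >= 5 concentrations spanning the transition")
  if (any(concentration <= 0)) stop_("concentrations must be positive")
  rng <- range(pct_signal)
  if (diff(rng) < 1e-8) stop_("flat response: IC50 not identifiable")
  ord <- order(concentration)
  if (stats::cor(concentration[ord], pct_signal[ord],
                 method = "spearman") > 0)
    warn_("response increases with dose; fit attempted but check the data")
  top0 <- max(pct_signal)
  bot0 <- min(pct_signal)
  mid <- (top0 + bot0) / 2
  lic0 <- log(concentration[which.min(abs(pct_signal - mid))])
  df <- data.frame(conc = concentration, y = pct_signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (log(conc) - lic50))),
      data = df,
      start = list(bottom = bot0, top = top0, lic50 = lic0, hill = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_("dose-response fit failed: %s", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(ic50 = exp(cf[["lic50"]]), hill = cf[["hill"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 data = df, fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL dose-response fit: IC50 = %.3g, hill = %.2f, top = %.1f, bottom = %.1f\n",
    x$ic50, x$hill, x$top, x$bottom))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.list(newdata)) newdata$conc else newdata
  stats::predict(object$fit, newdata = data.frame(conc = conc))
}

#' @export
residuals.dose_response_fit <- function(object, ...)
  stats::residuals(object$fit)

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$data$conc, x$data$y, log = "x", pch = 16,
       xlab = "concentration", ylab = "% of vehicle", ...)
  cc <- exp(seq(log(min(x$data$conc)), log(max(x$data$conc)),
                length.out = 200))
  graphics::lines(cc, predict(x, cc))
  graphics::abline(v = x$ic50, lty = 2)
  invisible(x)
}
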