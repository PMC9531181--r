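#' Photobleach correction of a degradation time course
#'
#' Fluorescence is first normalized within each well to its value at the
#' first time point, then the sample is divided by the matched
#' bleach-control ratio:
#' `corrected(t) = (F_t / F_0) / (F_t^ctrl / F_0^ctrl)`.
#' Photobleaching from the repeated readout flashes multiplies both wells
#' identically, so it cancels exactly; `corrected(0) = 1` by construction.
#'
#' @param time_min Shared time grid, minutes.
#' @param sample Fluorescence of the sample well on that grid.
#' @param control Fluorescence of the matched bleach-control well (substrate
#'   without protease) on the same grid.
#' @return Data frame `time_min`, `corrected`.  If the control reaches zero
#'   or below, the series is truncated there with a warning.
#' @export
bleach_correct <- function(time_min, sample, control) {
  if (length(sample) != length(control) ||
      length(sample) != length(time_min)) {
    stop("sample and control series must share the same time grid",
         call. = FALSE)
  }
  if (sample[1] <= 0 || control[1] <= 0) {
    stop("F_0 must be positive in both sample and control", call. = FALSE)
  }
  bad <- which(control <= 0)
  if (length(bad)) {
    warning(sprintf("bleach control reaches <= 0 at t = %g min; truncating",
                    time_min[bad[1]]), call. = FALSE)
    keep <- seq_len(bad[1] - 1L)
    time_min <- time_min[keep]
    sample <- sample[keep]
    control <- control[keep]
  }
  corrected <- (sample / sample[1]) / (control / control[1])
  data.frame(time_min = time_min, corrected = corrected)
}

# restrict a series to a fit window; default = first `frac` of the range,
# the regime where 1 - k*t is far from the floor and the model is linear
fit_window_idx <- function(time_min, window = NULL, frac = 0.2) {
  if (is.null(window)) {
    lim <- min(time_min) + frac * diff(range(time_min))
    idx <- which(time_min <= lim)
    if (length(idx) < 3L) idx <- seq_len(min(3L, length(time_min)))
  } else {
    idx <- which(time_min >= window[1] & time_min <= window[2])
    if (!length(idx)) stop("fit window outside the data range", call. = FALSE)
  }
  idx
}

r2_of_lm <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res <= 1e-24)
}

#' Fit the linear degradation model to a corrected trace
#'
#' Ordinary least squares of `F(t) = -k*t + B` on the photobleach-corrected
#' fraction of fluorescence; `k` is the fractional fluorescence loss rate
#' per minute.  When substrate and enzyme concentrations are supplied, `k`
#' is also converted to a molar turnover,
#' `rate = k * [substrate] / [enzyme]` (substrates per minute per hexamer).
#'
#' @param time_min Time, minutes.
#' @param corrected Corrected fraction of fluorescence (from
#'   [bleach_correct()]).
#' @param window Optional `c(t0, t1)` fit window, minutes; by default the
#'   first 20 percent of the time course is used (the linear regime).
#' @param substrate_conc,enzyme_conc Optional concentrations (same units)
#'   for the molar conversion.
#' @return List of class `degradation_fit`: `k_per_min`, `B`, `r2`,
#'   `n_points`, `window_min`, and `rate_per_enzyme` (or `NA`).
#' @export
fit_degradation <- function(time_min, corrected, window = NULL,
                            substrate_conc = NULL, enzyme_conc = NULL) {
  stopifnot(length(time_min) == length(corrected), all(is.finite(corrected)))
  idx <- fit_window_idx(time_min, window)
  if (length(idx) < 3L) stop("need >= 3 points in the fit window",
                             call. = FALSE)
  t <- time_min[idx]
  y <- corrected[idx]
  fit <- lm(y ~ t)
  k <- -unname(coef(fit)[2])
  rate <- if (!is.null(substrate_conc) && !is.null(enzyme_conc)) {
    k * substrate_conc / enzyme_conc
  } else NA_real_
  structure(list(k_per_min = k, B = unname(coef(fit)[1]),
                 r2 = r2_of_lm(y, fit$fitted.values),
                 n_points = length(idx), window_min = range(t),
                 rate_per_enzyme = rate),
            class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat(sprintf("degradation fit: k = %.4f /min, B = %.4f, r2 = %.4f (n = %d)\n",
              x$k_per_min, x$B, x$r2, x$n_points))
  invisible(x)
}

#' Calibrate the optical pathlength from an NADH standard series
#'
#' Fits `Abs340 = 6.22 (1/mM/cm) * lightpath (cm) * [NADH]` through the
#' origin; the slope divided by the molar extinction coefficient of NADH at
#' 340 nm (6.22 per mM per cm) gives the pathlength of the well.
#'
#' @param nadh_mM NADH concentrations of the standards, mM (at least one
#'   positive).
#' @param abs340 Measured absorbance at 340 nm.
#' @return List: `lightpath_cm`, `slope_abs_per_mM`, `r2`.
#' @export
calibrate_pathlength <- function(nadh_mM, abs340) {
  stopifnot(length(nadh_mM) == length(abs340))
  if (!any(nadh_mM > 0)) {
    stop("standard series has no positive concentration (zero spread)",
         call. = FALSE)
  }
  if (all(abs340 == 0)) stop("all absorbances are zero", call. = FALSE)
  slope <- sum(nadh_mM * abs340) / sum(nadh_mM^2)
  list(lightpath_cm = slope / 6.22, slope_abs_per_mM = slope,
       r2 = r2_of_lm(abs340, slope * nadh_mM))
}

#' NADH-coupled ATPase rate from an absorbance time course
#'
#' The coupled pyruvate-kinase / lactate-dehydrogenase relay oxidizes one
#' NADH per ATP hydrolyzed, so the decline of Abs340 reports the hydrolysis
#' rate.  The sample (and optional background) series are fitted with
#' `Abs340 = k*t + c`; the net rate is
#' `(|slope_sample| - |slope_background|) / (6.22 * lightpath)` in mM/min,
#' the background term being the leaky NADH consumption of the coupling mix.
#' Negative net rates are clipped to zero with a warning.
#'
#' @param time_min Time, minutes.
#' @param abs_sample Sample-well Abs340 series.
#' @param abs_background Optional background-well series on the same grid.
#' @param lightpath_cm Pathlength from [calibrate_pathlength()].
#' @param enzyme_mM Optional enzyme (hexamer) concentration, mM, for the
#'   per-enzyme rate (ATP per minute per hexamer).
#' @param window Optional `c(t0, t1)` linear-regime window, minutes.
#' @return List of class `atpase_fit`: `slope_abs_per_min`,
#'   `background_slope_abs_per_min`, `rate_mM_min`, `rate_per_enzyme`,
#'   `lightpath_cm`, `r2`, `background_subtracted`.
#' @export
fit_atpase <- function(time_min, abs_sample, abs_background = NULL,
                       lightpath_cm, enzyme_mM = NULL, window = NULL) {
  stop_if_not_scalar_pos(lightpath_cm, "lightpath_cm")
  idx <- fit_window_idx(time_min, window, frac = 1)
  t <- time_min[idx]
  fit_s <- lm(abs_sample[idx] ~ t)
  slope_s <- unname(coef(fit_s)[2])
  slope_b <- 0
  if (!is.null(abs_background)) {
    stopifnot(length(abs_background) == length(time_min))
    slope_b <- unname(coef(lm(abs_background[idx] ~ t))[2])
  }
  net <- (abs(slope_s) - abs(slope_b)) / (6.22 * lightpath_cm)
  if (net < 0) {
    warning("background NADH consumption exceeds the sample's; rate clipped at 0",
            call. = FALSE)
    net <- 0
  }
  structure(list(slope_abs_per_min = slope_s,
                 background_slope_abs_per_min = slope_b,
                 rate_mM_min = net,
                 rate_per_enzyme = if (is.null(enzyme_mM)) NA_real_
                                   else net / enzyme_mM,
                 lightpath_cm = lightpath_cm,
                 r2 = r2_of_lm(abs_sample[idx], fit_s$fitted.values),
                 background_subtracted = !is.null(abs_background)),
            class = "atpase_fit")
}

#' @export
print.atpase_fit <- function(x, ...) {
  cat(sprintf("ATPase fit: %.4g mM/min (lightpath %.3g cm%s)\n",
              x$rate_mM_min, x$lightpath_cm,
              if (x$background_subtracted) ", background subtracted" else ""))
  invisible(x)
}

#' ATP cost of degradation
#'
#' The energy expenditure per substrate: ATP hydrolysis rate divided by
#' substrate degradation rate, both per enzyme hexamer per minute.
#'
#' @param atpase_rate_per_enzyme ATP per minute per hexamer.
#' @param degradation_rate_per_enzyme Substrates per minute per hexamer
#'   (must be positive).
#' @return ATP hydrolyzed per substrate degraded.
#' @export
atp_cost <- function(atpase_rate_per_enzyme, degradation_rate_per_enzyme) {
  if (!is.numeric(degradation_rate_per_enzyme) ||
      degradation_rate_per_enzyme <= 0) {
    stop("degradation rate must be positive: ATP cost undefined",
         call. = FALSE)
  }
  atpase_rate_per_enzyme / degradation_rate_per_enzyme
}
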