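#' Parameters for the synthetic plate-reader generator
#'
#' Emulates the three bulk measurements the kinetics module consumes:
#' \describe{
#'   \item{degradation}{GFP-substrate fluorescence in sample wells,
#'     `F(t) = F0 * (1 - k_deg * t) * exp(-k_bleach * t)`, alongside
#'     substrate-only bleach-control wells `F0 * exp(-k_bleach * t)`.
#'     Photobleaching here is caused by the repeated readout flashes, so it
#'     multiplies both wells equally and divides out exactly.}
#'   \item{atpase}{NADH absorbance at 340 nm,
#'     `Abs340(t) = 6.22 * lightpath_cm * (NADH0 - (rate + background) * t)`,
#'     plus background-only wells (the leaky pyruvate-kinase /
#'     lactate-dehydrogenase coupling mix consumes NADH on its own).}
#'   \item{nadh_standard}{Absorbance of an NADH dilution series (default
#'     0 to 1.2 mM), used to calibrate the optical pathlength of the well.}
#' }
#'
#' @param mode One of `"degradation"`, `"atpase"`, `"nadh_standard"`.
#' @param k_deg_per_min Fractional fluorescence loss rate, 1/min.
#' @param k_bleach_per_min Photobleach rate, 1/min.
#' @param f0 Initial fluorescence, arbitrary units.
#' @param nadh0_mM Starting NADH concentration, mM.
#' @param nadh_rate_mM_min ATPase-driven NADH consumption, mM/min.
#' @param background_rate_mM_min PK/LDH leak rate, mM/min.
#' @param lightpath_cm Optical pathlength of the well, cm.
#' @param noise_sd Additive Gaussian noise SD (same units as `value`).
#' @param t_points_min Sampling times, minutes, strictly increasing.
#' @param n_replicates Wells per role.
#' @param nadh_standard_mM Concentrations of the standard series, mM.
#' @param seed Integer seed.
#' @return A validated list of class `plate_sim_params`.
#' @export
plate_sim_params <- function(mode = c("degradation", "atpase",
                                      "nadh_standard"),
                             k_deg_per_min = 0.02, k_bleach_per_min = 0.01,
                             f0 = 1000, nadh0_mM = 1,
                             nadh_rate_mM_min = 0.01,
                             background_rate_mM_min = 0.001,
                             lightpath_cm = 0.3, noise_sd = 0,
                             t_points_min = seq(0, 60, by = 2),
                             n_replicates = 3L,
                             nadh_standard_mM = seq(0, 1.2, by = 0.1),
                             seed = 1L) {
  mode <- match.arg(mode)
  p <- list(mode = mode, k_deg_per_min = k_deg_per_min,
            k_bleach_per_min = k_bleach_per_min, f0 = f0,
            nadh0_mM = nadh0_mM, nadh_rate_mM_min = nadh_rate_mM_min,
            background_rate_mM_min = background_rate_mM_min,
            lightpath_cm = lightpath_cm, noise_sd = noise_sd,
            t_points_min = t_points_min,
            n_replicates = as.integer(n_replicates),
            nadh_standard_mM = nadh_standard_mM, seed = as.integer(seed))
  for (nm in c("k_deg_per_min", "k_bleach_per_min", "nadh_rate_mM_min",
               "background_rate_mM_min", "noise_sd")) {
    stop_if_not_scalar_pos(p[[nm]], nm, strict = FALSE)
  }
  stop_if_not_scalar_pos(p$lightpath_cm, "lightpath_cm")
  stop_if_not_scalar_pos(p$f0, "f0")
  if (any(p$t_points_min < 0) || any(diff(p$t_points_min) <= 0)) {
    stop("`t_points_min` must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(p, class = "plate_sim_params")
}

#' Simulate a long-format plate-reader table
#'
#' @param params A [plate_sim_params()] object.
#' @return Data frame with columns `time_min`, `well`, `role`
#'   (`sample`, `bleach_control`, `background` or `standard`), `value` and
#'   `nadh_mM` (standards only, otherwise `NA`).  Series that would go
#'   negative within the time range are truncated at the last non-negative
#'   point, with a warning.
#' @export
simulate_plate <- function(params) {
  stopifnot(inherits(params, "plate_sim_params"))
  p <- params
  set.seed(p$seed)
  t <- p$t_points_min

  emit <- function(role, well, times, values, nadh = NA_real_) {
    neg <- values < 0
    if (any(neg)) {
      keep <- seq_len(which(neg)[1] - 1L)
      warning(sprintf("well %s driven negative at t = %g min; truncating",
                      well, times[which(neg)[1]]), call. = FALSE)
      times <- times[keep]
      values <- values[keep]
    }
    if (p$noise_sd > 0) values <- values + rnorm(length(values), 0, p$noise_sd)
    data.frame(time_min = times, well = well, role = role, value = values,
               nadh_mM = nadh)
  }

  out <- list()
  if (p$mode == "degradation") {
    for (i in seq_len(p$n_replicates)) {
      out[[length(out) + 1L]] <-
        emit("sample", sprintf("S%02d", i), t,
             p$f0 * (1 - p$k_deg_per_min * t) * exp(-p$k_bleach_per_min * t))
      out[[length(out) + 1L]] <-
        emit("bleach_control", sprintf("C%02d", i), t,
             p$f0 * exp(-p$k_bleach_per_min * t))
    }
  } else if (p$mode == "atpase") {
    eps_lp <- 6.22 * p$lightpath_cm
    for (i in seq_len(p$n_replicates)) {
      rate_tot <- p$nadh_rate_mM_min + p$background_rate_mM_min
      out[[length(out) + 1L]] <-
        emit("sample", sprintf("S%02d", i), t,
             eps_lp * (p$nadh0_mM - rate_tot * t))
      out[[length(out) + 1L]] <-
        emit("background", sprintf("B%02d", i), t,
             eps_lp * (p$nadh0_mM - p$background_rate_mM_min * t))
    }
  } else { # nadh_standard
    conc <- p$nadh_standard_mM
    for (i in seq_len(p$n_replicates)) {
      out[[length(out) + 1L]] <-
        emit("standard", sprintf("N%02d", i), rep(0, length(conc)),
             6.22 * p$lightpath_cm * conc, nadh = conc)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
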