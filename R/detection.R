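#' Parameters for per-frame punctum detection
#'
#' Controls the Laplacian-of-Gaussian (LoG) blob search, the sub-pixel 2D
#' Gaussian refinement window, and the brightness/shape filters applied to
#' the fits.
#'
#' @param log_sigma_min_px,log_sigma_max_px,log_n_scales LoG scale range
#'   (Gaussian sigma, pixels) and number of scales.
#' @param log_threshold Relative response threshold: a blob is a candidate
#'   when its scale-normalized LoG response exceeds
#'   `log_threshold * (max - min)` of the frame.  For a Gaussian spot at the
#'   matched scale the response peaks at about half the spot amplitude.
#' @param min_sep_factor Candidates closer than `min_sep_factor * sigma` of
#'   the stronger candidate are merged, keeping the stronger.
#' @param log_noise_floor_k Noise guard: per scale, candidates must also
#'   exceed `log_noise_floor_k` robust standard deviations (1.4826 MAD) of
#'   the response map, so that frames without real structure do not promote
#'   noise extrema to candidates.  Set to 0 to disable.
#' @param fit_window_px Half-width of the square Gaussian fit window,
#'   pixels; must be at least `2 * log_sigma_max_px`.
#' @param max_amp_factor Brightness cutoff: fitted amplitudes above
#'   `max_amp_factor` times the frame's median amplitude are rejected
#'   (aggregates, multi-fluorophore particles).
#' @param circ_ratio_max Circularity cutoff: detections with
#'   `max(sigma_x, sigma_y) / min(sigma_x, sigma_y)` above this are rejected.
#' @param dedup_radius_px Refined fits whose centres land within this
#'   distance of a better (lower residual) fit in the same frame are
#'   duplicates of the same punctum (two scale-space maxima of one blob)
#'   and are dropped.
#' @param sigma_min_factor,sigma_max_factor Fitted widths outside
#'   `[sigma_min_factor, sigma_max_factor]` times the detected blob scale
#'   invalidate the fit.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(log_sigma_min_px = 1, log_sigma_max_px = 2,
                             log_n_scales = 5L, log_threshold = 0.1,
                             min_sep_factor = 2, log_noise_floor_k = 6,
                             fit_window_px = 6L,
                             max_amp_factor = 5, circ_ratio_max = 2,
                             dedup_radius_px = 1,
                             sigma_min_factor = 0.3, sigma_max_factor = 3) {
  p <- list(log_sigma_min_px = log_sigma_min_px,
            log_sigma_max_px = log_sigma_max_px,
            log_n_scales = as.integer(log_n_scales),
            log_threshold = log_threshold,
            min_sep_factor = min_sep_factor,
            log_noise_floor_k = log_noise_floor_k,
            fit_window_px = as.integer(fit_window_px),
            max_amp_factor = max_amp_factor,
            circ_ratio_max = circ_ratio_max,
            dedup_radius_px = dedup_radius_px,
            sigma_min_factor = sigma_min_factor,
            sigma_max_factor = sigma_max_factor)
  stop_if_not_scalar_pos(p$log_sigma_min_px, "log_sigma_min_px")
  stop_if_not_scalar_pos(p$log_threshold, "log_threshold")
  if (p$log_sigma_max_px < p$log_sigma_min_px) {
    stop("LoG sigma range must be ordered", call. = FALSE)
  }
  if (p$log_n_scales < 1L) stop("need at least one LoG scale", call. = FALSE)
  if (p$fit_window_px < 2 * p$log_sigma_max_px) {
    stop("`fit_window_px` must be >= 2 * log_sigma_max_px", call. = FALSE)
  }
  if (p$max_amp_factor <= 1) stop("`max_amp_factor` must be > 1",
                                  call. = FALSE)
  if (p$circ_ratio_max < 1) stop("`circ_ratio_max` must be >= 1",
                                 call. = FALSE)
  structure(p, class = "detection_params")
}

log_scales <- function(params) {
  if (params$log_n_scales == 1L) {
    return((params$log_sigma_min_px + params$log_sigma_max_px) / 2)
  }
  seq(params$log_sigma_min_px, params$log_sigma_max_px,
      length.out = params$log_n_scales)
}

#' Detect blob candidates in one frame by the Laplacian-of-Gaussian method
#'
#' Computes the scale-normalized LoG response (`sigma^2 * -LoG`) at each
#' configured scale and returns the local response maxima above threshold,
#' with overlapping responses across scales merged keeping the stronger.
#'
#' @param frame_image 2D non-negative numeric matrix (rows = y, cols = x).
#' @param params A [detection_params()] object.
#' @return Data frame of candidates: `frame` (always 0 here), `x`, `y`
#'   (0-based pixel indices), `scale`, `response`.
#' @export
detect_blobs <- function(frame_image, params = detection_params()) {
  stopifnot(is.matrix(frame_image), all(frame_image >= 0))
  side <- 2L * params$fit_window_px + 1L
  if (nrow(frame_image) < side || ncol(frame_image) < side) {
    warning("image smaller than the fit window; no detections", call. = FALSE)
    return(data.frame(frame = integer(), x = numeric(), y = numeric(),
                      scale = numeric(), response = numeric()))
  }
  .log_detect_cpp(as.numeric(frame_image), nrow(frame_image),
                  ncol(frame_image), 1L, log_scales(params),
                  params$log_threshold, params$min_sep_factor,
                  params$log_noise_floor_k)
}

# batched Gaussian refinement of candidates against a stack
fit_candidates <- function(stack, H, W, n_frames, cands, params) {
  n <- nrow(cands)
  empty <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      amplitude = numeric(), sigma_x = numeric(),
                      sigma_y = numeric(), offset = numeric(),
                      fit_ok = logical(), reject_reason = character())
  if (n == 0L) return(empty)
  fit <- .gaussfit_cpp(stack, H, W, n_frames, as.integer(cands$frame),
                       cands$x, cands$y, cands$scale, params$fit_window_px,
                       50L, 1e-7)
  w <- params$fit_window_px
  lo <- params$sigma_min_factor
  hi <- params$sigma_max_factor
  clipped <- fit[, "converged"] < 0
  nonconv <- !clipped & fit[, "converged"] == 0
  bad_amp <- !clipped & fit[, "amplitude"] <= 0
  bad_sigma <- !clipped &
    (fit[, "sigma_x"] < cands$scale * lo | fit[, "sigma_x"] > cands$scale * hi |
     fit[, "sigma_y"] < cands$scale * lo | fit[, "sigma_y"] > cands$scale * hi)
  drift <- !clipped & (abs(fit[, "x"] - cands$x) > w |
                       abs(fit[, "y"] - cands$y) > w)
  fit_ok <- !(clipped | nonconv | bad_amp | bad_sigma | drift)
  reason <- rep(NA_character_, n)
  reason[drift] <- "center_drift"
  reason[bad_sigma] <- "sigma_out_of_range"
  reason[nonconv] <- "not_converged"
  reason[bad_amp] <- "nonpositive_amplitude"
  reason[clipped] <- "window_clipped"
  data.frame(frame = as.integer(cands$frame), x_px = fit[, "x"],
             y_px = fit[, "y"], amplitude = fit[, "amplitude"],
             sigma_x = fit[, "sigma_x"], sigma_y = fit[, "sigma_y"],
             offset = fit[, "offset"], rss = fit[, "rss"], fit_ok = fit_ok,
             reject_reason = reason)
}

# two refined fits of one blob (scale-space maxima that converged to the
# same punctum) are collapsed onto the better fit
dedup_detections <- function(det, radius) {
  if (nrow(det) < 2L) return(det)
  drop <- rep(FALSE, nrow(det))
  for (f in unique(det$frame)) {
    i <- which(det$frame == f & det$fit_ok)
    if (length(i) < 2L) next
    i <- i[order(det$rss[i])]
    kept_x <- numeric(0)
    kept_y <- numeric(0)
    for (j in i) {
      if (length(kept_x) &&
          any((det$x_px[j] - kept_x)^2 + (det$y_px[j] - kept_y)^2 <
              radius^2)) {
        drop[j] <- TRUE
      } else {
        kept_x <- c(kept_x, det$x_px[j])
        kept_y <- c(kept_y, det$y_px[j])
      }
    }
  }
  det$fit_ok[drop] <- FALSE
  det$reject_reason[drop] <- "duplicate"
  det
}

#' Refine one blob candidate with a 2D Gaussian fit
#'
#' Nonlinear least-squares fit of the 6-parameter model
#' `I(x, y) = A * exp(-((x-x0)^2/(2*sx^2) + (y-y0)^2/(2*sy^2))) + b`
#' over a `(2*fit_window_px + 1)` square window centred on the candidate
#' (Levenberg-Marquardt with analytic Jacobian).  `fit_ok` is `FALSE` when
#' the window is clipped by the image edge, the fit does not converge, the
#' amplitude is non-positive, the fitted widths fall far from the detected
#' blob scale, or the centre drifts outside the window; the reason is
#' recorded.
#'
#' @param frame_image 2D numeric matrix.
#' @param candidate One-row data frame with `x`, `y` (0-based) and `scale`,
#'   as produced by [detect_blobs()].
#' @param params A [detection_params()] object.
#' @return One-row data frame: `frame`, `x_px`, `y_px`, `amplitude`,
#'   `sigma_x`, `sigma_y`, `offset`, `fit_ok`, `reject_reason`.
#' @export
fit_gaussian2d <- function(frame_image, candidate,
                           params = detection_params()) {
  stopifnot(is.matrix(frame_image), nrow(candidate) == 1L)
  cand <- data.frame(frame = 0L, x = candidate$x, y = candidate$y,
                     scale = candidate$scale %||% 1.3)
  fit_candidates(as.numeric(frame_image), nrow(frame_image),
                 ncol(frame_image), 1L, cand, params)
}

#' Filter detections on brightness and circularity
#'
#' Keeps a detection iff its fit succeeded, its amplitude does not exceed
#' `max_amp_factor` times the median fitted amplitude of its frame, and its
#' width ratio `max(sigma_x, sigma_y)/min(sigma_x, sigma_y)` is at most
#' `circ_ratio_max`.  The frame median is always computed over all
#' successfully fitted detections of the frame, so the filter is idempotent
#' and independent of row order.
#'
#' @param detections Data frame from [fit_gaussian2d()] /
#'   [detect_movie()].
#' @param params A [detection_params()] object.
#' @return The input with `kept` (logical) and `reject_reason` updated;
#'   rejected rows carry `"too_bright"` or `"not_circular"`.
#' @export
filter_detections <- function(detections, params = detection_params()) {
  det <- detections
  n <- nrow(det)
  if (n == 0L) {
    det$kept <- logical(0)
    return(det)
  }
  kept <- det$fit_ok
  reason <- ifelse(det$fit_ok, NA_character_, det$reject_reason)
  for (f in unique(det$frame)) {
    i <- which(det$frame == f & det$fit_ok)
    if (!length(i)) next
    med <- median(det$amplitude[i])
    bright <- det$amplitude[i] > params$max_amp_factor * med
    ratio <- pmax(det$sigma_x[i], det$sigma_y[i]) /
      pmin(det$sigma_x[i], det$sigma_y[i])
    noncirc <- ratio > params$circ_ratio_max
    kept[i][bright | noncirc] <- FALSE
    reason[i][noncirc] <- "not_circular"
    reason[i][bright] <- "too_bright"
  }
  det$kept <- kept
  det$reject_reason <- reason
  det
}

#' Detect, refine and filter puncta over a whole movie
#'
#' Runs [detect_blobs()] on every frame, refines all candidates with the
#' batched Gaussian fitter, and applies [filter_detections()].
#'
#' @param movie A `tirf_movie` (or any list with `stack`).
#' @param params A [detection_params()] object.
#' @return Data frame of detections (one per candidate, kept or not) with
#'   columns `det_id`, `frame`, `x_px`, `y_px`, `amplitude`, `sigma_x`,
#'   `sigma_y`, `offset`, `fit_ok`, `kept`, `reject_reason`.  Frames are
#'   0-based.
#' @export
detect_movie <- function(movie, params = detection_params()) {
  stack <- movie$stack
  d <- dim(stack)
  cands <- .log_detect_cpp(as.numeric(stack), d[1], d[2], d[3],
                           log_scales(params), params$log_threshold,
                           params$min_sep_factor, params$log_noise_floor_k)
  det <- fit_candidates(as.numeric(stack), d[1], d[2], d[3], cands, params)
  det <- dedup_detections(det, params$dedup_radius_px)
  det <- filter_detections(det, params)
  det <- cbind(det_id = seq_len(nrow(det)), det)
  det
}
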