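#' Parameters for the synthetic TIRF movie generator
#'
#' Bundles and validates the physical and camera parameters of a simulated
#' single-molecule TIRF time course.  The simulator emulates surface-captured
#' substrate molecules: puncta appear at a Poisson rate, persist for
#' exponentially distributed dwell times, and are rendered as 2D Gaussian
#' point-spread functions over a constant background with shot (Poisson) and
#' additive Gaussian read noise.
#'
#' The expected steady-state surface density is
#' `arrival_rate_per_um2_s * tau_true_s` puncta per square micron.  Densities
#' above 1 punctum/um^2 are refused: crowded fields defeat the downstream
#' proximity filters, and the imaging regime this generator emulates keeps
#' the density below that bound by dilution.
#'
#' @param field_w_px,field_h_px Field of view, pixels.
#' @param pixel_size_um Pixel size, micron per pixel.  The default 0.065
#'   corresponds to a 100x objective with 6.5 um sensor pixels.
#' @param frame_interval_s Frame interval, seconds.
#' @param n_frames Number of frames.
#' @param tau_true_s Mean dwell time of the simulated binding events, s.
#' @param arrival_rate_per_um2_s New-event rate, events per um^2 per second.
#' @param psf_sigma_px Gaussian PSF width (sigma), pixels.
#' @param psf_sigma_y_px Optional distinct sigma along y, to generate
#'   elongated (non-circular) spots; default equal to `psf_sigma_px`.
#' @param amp_mean,amp_sd Mean and SD of the per-event peak amplitude
#'   (photon counts above background).
#' @param background Constant background level, counts/pixel.
#' @param read_noise_sd Additive Gaussian read noise SD, counts.
#' @param blink_off_prob Per-frame probability that a present punctum is dark
#'   (fluorophore blinking); runs of dark frames are truncated at
#'   `blink_max_consecutive`.
#' @param blink_max_consecutive Longest permitted run of dark frames.  Values
#'   above 3 are allowed but warned about: a 3-frame gap-bridging tracker
#'   cannot recover longer interruptions.
#' @param margin_px Events are placed at least this many pixels from the
#'   field edge so that every punctum carries a complete fit window.
#' @param seed Integer seed; identical seeds give bit-identical movies.
#' @return A validated list of class `movie_sim_params`.
#' @export
movie_sim_params <- function(field_w_px = 128L, field_h_px = 128L,
                             pixel_size_um = 0.065, frame_interval_s = 1,
                             n_frames = 300L, tau_true_s = 20,
                             arrival_rate_per_um2_s = 0.005,
                             psf_sigma_px = 1.3, psf_sigma_y_px = NULL,
                             amp_mean = 400, amp_sd = 40,
                             background = 100, read_noise_sd = 2,
                             blink_off_prob = 0, blink_max_consecutive = 3L,
                             margin_px = 8L, seed = 1L) {
  p <- list(field_w_px = as.integer(field_w_px),
            field_h_px = as.integer(field_h_px),
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            n_frames = as.integer(n_frames),
            tau_true_s = tau_true_s,
            arrival_rate_per_um2_s = arrival_rate_per_um2_s,
            psf_sigma_px = psf_sigma_px,
            psf_sigma_y_px = psf_sigma_y_px %||% psf_sigma_px,
            amp_mean = amp_mean, amp_sd = amp_sd,
            background = background, read_noise_sd = read_noise_sd,
            blink_off_prob = blink_off_prob,
            blink_max_consecutive = as.integer(blink_max_consecutive),
            margin_px = as.integer(margin_px),
            seed = as.integer(seed))
  for (nm in c("pixel_size_um", "frame_interval_s", "tau_true_s",
               "psf_sigma_px", "psf_sigma_y_px", "amp_mean", "background")) {
    stop_if_not_scalar_pos(p[[nm]], nm)
  }
  for (nm in c("arrival_rate_per_um2_s", "amp_sd", "read_noise_sd")) {
    stop_if_not_scalar_pos(p[[nm]], nm, strict = FALSE)
  }
  if (p$field_w_px < 8L || p$field_h_px < 8L || p$n_frames < 1L) {
    stop("field must be at least 8x8 px and n_frames >= 1", call. = FALSE)
  }
  if (p$blink_off_prob < 0 || p$blink_off_prob >= 1) {
    stop("`blink_off_prob` must lie in [0, 1)", call. = FALSE)
  }
  if (p$blink_max_consecutive < 0L) {
    stop("`blink_max_consecutive` must be >= 0", call. = FALSE)
  }
  if (p$blink_max_consecutive > 3L) {
    warning("blink_max_consecutive > 3: dark runs longer than 3 frames are ",
            "not recoverable by a 3-frame gap-bridging tracker", call. = FALSE)
  }
  dens <- p$arrival_rate_per_um2_s * p$tau_true_s
  if (dens > 1) {
    stop(sprintf(paste0("expected steady-state density %.2f puncta/um^2 ",
                        "exceeds 1/um^2; the analysis assumes a sparse field"),
                 dens), call. = FALSE)
  }
  if (2L * p$margin_px >= min(p$field_w_px, p$field_h_px)) {
    stop("`margin_px` leaves no room for events", call. = FALSE)
  }
  structure(p, class = "movie_sim_params")
}

# frames in which an interval [t0, t1) (seconds) is visible, by the
# >=50%-of-frame-overlap rule; returns c(first, last), last < first possible
visible_frame_span <- function(t0, t1, dt) {
  first <- round(t0 / dt)
  last <- round(t1 / dt) - 1
  cbind(first = first, last = last)
}

#' Draw the ground-truth event table of a simulated movie
#'
#' Generates Poisson arrivals with exponential dwell times and per-event
#' positions, amplitudes and blinking records, without rendering pixels.
#' Useful for testing the statistical structure of the generator cheaply.
#' `simulate_movie()` calls this internally, so for a given parameter set
#' both agree on the truth table.
#'
#' @param params A [movie_sim_params()] object.
#' @return A list with `truth` (data frame: `event_id`, `x_px`, `y_px`,
#'   `t_on_s`, `t_off_s`, `dwell_true_s`, `amplitude`, `first_frame`,
#'   `last_frame`) and `dark` (data frame `event_id`, `frame` of blinked-off
#'   frames).  Frame indices are 0-based; events wholly outside the movie's
#'   frame range keep their nominal span.
#' @export
simulate_events <- function(params) {
  stopifnot(inherits(params, "movie_sim_params"))
  set.seed(params$seed)
  p <- params
  area_um2 <- p$field_w_px * p$field_h_px * p$pixel_size_um^2
  duration_s <- p$n_frames * p$frame_interval_s
  n <- rpois(1L, p$arrival_rate_per_um2_s * area_um2 * duration_s)
  if (n == 0L) {
    truth <- data.frame(event_id = integer(), x_px = numeric(),
                        y_px = numeric(), t_on_s = numeric(),
                        t_off_s = numeric(), dwell_true_s = numeric(),
                        amplitude = numeric(), first_frame = integer(),
                        last_frame = integer())
    return(list(truth = truth,
                dark = data.frame(event_id = integer(), frame = integer())))
  }
  t_on <- sort(runif(n, 0, duration_s))
  dwell <- rexp(n, rate = 1 / p$tau_true_s)
  x <- runif(n, p$margin_px, p$field_w_px - 1 - p$margin_px)
  y <- runif(n, p$margin_px, p$field_h_px - 1 - p$margin_px)
  amp <- rnorm(n, p$amp_mean, p$amp_sd)
  while (any(amp <= 0)) {
    amp[amp <= 0] <- rnorm(sum(amp <= 0), p$amp_mean, p$amp_sd)
  }
  span <- visible_frame_span(t_on, t_on + dwell, p$frame_interval_s)
  truth <- data.frame(event_id = seq_len(n), x_px = x, y_px = y,
                      t_on_s = t_on, t_off_s = t_on + dwell,
                      dwell_true_s = dwell, amplitude = amp,
                      first_frame = as.integer(span[, "first"]),
                      last_frame = as.integer(span[, "last"]))
  dark_ev <- integer()
  dark_fr <- integer()
  if (p$blink_off_prob > 0) {
    for (i in seq_len(n)) {
      f0 <- max(truth$first_frame[i], 0L)
      f1 <- min(truth$last_frame[i], p$n_frames - 1L)
      if (f1 < f0) next
      frames <- f0:f1
      off <- runif(length(frames)) < p$blink_off_prob
      # cap consecutive dark runs so events stay recoverable
      run <- 0L
      for (k in seq_along(off)) {
        if (off[k]) {
          run <- run + 1L
          if (run > p$blink_max_consecutive) {
            off[k] <- FALSE
            run <- 0L
          }
        } else {
          run <- 0L
        }
      }
      if (any(off)) {
        dark_ev <- c(dark_ev, rep.int(i, sum(off)))
        dark_fr <- c(dark_fr, frames[off])
      }
    }
  }
  list(truth = truth, dark = data.frame(event_id = dark_ev, frame = dark_fr))
}

#' Simulate a TIRF movie with ground truth
#'
#' Renders the event table from [simulate_events()] into a pixel stack:
#' each present, non-blinked punctum contributes
#' `A * exp(-((x-x0)^2/(2*sx^2) + (y-y0)^2/(2*sy^2)))` counts, Poisson shot
#' noise is applied to signal plus background, and Gaussian read noise is
#' added (values clamped at zero).  Identical parameters (including the seed)
#' give bit-identical stacks.
#'
#' @param params A [movie_sim_params()] object.
#' @return An object of class `tirf_movie`: list with `stack`
#'   (`field_h_px` x `field_w_px` x `n_frames` array of counts),
#'   `frame_interval_s`, `pixel_size_um`, `truth`, `dark` and `params`.
#' @export
simulate_movie <- function(params) {
  stopifnot(inherits(params, "movie_sim_params"))
  p <- params
  ev <- simulate_events(p) # seeds the RNG; noise draws continue the stream
  H <- p$field_h_px
  W <- p$field_w_px
  n_fr <- p$n_frames
  stack <- array(p$background, dim = c(H, W, n_fr))
  truth <- ev$truth
  if (nrow(truth)) {
    f0 <- pmax(truth$first_frame, 0L)
    f1 <- pmin(truth$last_frame, n_fr - 1L)
    vis <- which(f1 >= f0)
    if (length(vis)) {
      reps <- f1[vis] - f0[vis] + 1L
      idx <- rep.int(vis, reps)
      frames <- unlist(lapply(vis, function(i) f0[i]:f1[i]), use.names = FALSE)
      if (nrow(ev$dark)) {
        key <- paste(idx, frames)
        dark_key <- paste(ev$dark$event_id, ev$dark$frame)
        on <- !(key %in% dark_key)
        idx <- idx[on]
        frames <- frames[on]
      }
      .render_spots_cpp(stack, H, W, n_fr,
                        as.integer(frames), truth$x_px[idx], truth$y_px[idx],
                        truth$amplitude[idx],
                        rep.int(p$psf_sigma_px, length(idx)),
                        rep.int(p$psf_sigma_y_px, length(idx)), 4.5)
    }
  }
  npx <- H * W
  for (f in seq_len(n_fr)) {
    v <- rpois(npx, stack[, , f])
    if (p$read_noise_sd > 0) v <- v + rnorm(npx, 0, p$read_noise_sd)
    stack[, , f] <- pmax(v, 0)
  }
  structure(list(stack = stack, frame_interval_s = p$frame_interval_s,
                 pixel_size_um = p$pixel_size_um, truth = truth,
                 dark = ev$dark, params = p),
            class = "tirf_movie")
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("tirf_movie: %d x %d px, %d frames @ %g s, %g um/px\n",
              d[2], d[1], d[3], x$frame_interval_s, x$pixel_size_um))
  cat(sprintf("  ground-truth events: %d\n", nrow(x$truth)))
  invisible(x)
}

#' Sample frame-quantized exponential dwell times
#'
#' Draws `n` dwell times from an exponential distribution with mean `tau_s`,
#' rounds each up to a whole number of frames, and enforces a 2-frame
#' minimum (single-frame traces are excluded by the trace filters, so they
#' never reach the dwell model).
#'
#' @param tau_s Mean dwell, seconds (> 0).
#' @param n Number of draws (>= 1).
#' @param frame_interval_s Frame interval, seconds.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` dwell times in seconds, each a multiple of
#'   `frame_interval_s` and at least `2 * frame_interval_s`.
#' @export
sample_dwells <- function(tau_s, n, frame_interval_s = 1, seed = NULL) {
  stop_if_not_scalar_pos(tau_s, "tau_s")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- rexp(as.integer(n), rate = 1 / tau_s)
  pmax(ceiling(d / frame_interval_s), 2) * frame_interval_s
}

#' Write / read a simulated movie as TIFF plus sidecar files
#'
#' The stack is written as a multi-page 16-bit TIFF (counts scaled by
#' 1/65535), metadata as a JSON sidecar, and the ground-truth event table as
#' CSV.  `read_movie()` reconstructs the `tirf_movie` (pixel values are
#' re-scaled to counts; 16-bit quantization applies).
#'
#' @param movie A `tirf_movie`.
#' @param dir Output directory (created if missing).
#' @param name Basename for the three files.
#' @return `write_movie()` returns the paths invisibly; `read_movie()`
#'   returns a `tirf_movie` (without simulation params).
#' @export
write_movie <- function(movie, dir, name = "movie") {
  stopifnot(inherits(movie, "tirf_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(movie$stack, 1)
  pages <- lapply(seq_len(dim(movie$stack)[3]),
                  function(f) movie$stack[, , f] / mx)
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L, compression = "none")
  meta <- list(frame_interval_s = movie$frame_interval_s,
               pixel_size_um = movie$pixel_size_um,
               count_scale = mx,
               n_frames = dim(movie$stack)[3],
               seed = movie$params$seed %||% NA)
  js <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  write.csv(movie$truth, csv, row.names = FALSE)
  invisible(c(tif = tif, json = js, truth = csv))
}

#' @rdname write_movie
#' @export
read_movie <- function(dir, name = "movie") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]] * meta$count_scale
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  structure(list(stack = stack, frame_interval_s = meta$frame_interval_s,
                 pixel_size_um = meta$pixel_size_um, truth = truth,
                 dark = NULL, params = NULL),
            class = "tirf_movie")
}
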