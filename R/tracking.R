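#' Parameters for trace linking and filtering
#'
#' @param link_radius_px Maximum frame-to-frame displacement for linking a
#'   detection to an open trace.  Molecules are surface-immobilized, so the
#'   default is small.
#' @param max_gap_frames A trace stays open through up to this many missing
#'   frames (fluorophore blinking, transiently failed fits) before closing.
#' @param exclusion_radius_um Birth-proximity exclusion radius: a trace that
#'   is born within this distance of another trace alive on the same frame
#'   is removed.
#' @param concurrent_both If `TRUE`, both members of a concurrent pair are
#'   removed, not just the newborn trace.  The default removes only the new
#'   trace: removing the pre-existing member too would censor traces at a
#'   rate proportional to their own dwell, which systematically shortens the
#'   kept dwell distribution (see the methods vignette).
#' @param same_site_radius_px Traces whose centroids fall within this radius
#'   at non-overlapping times are all removed (uncertain uniqueness of
#'   binding events at a repeatedly used site).  Defaults to
#'   `link_radius_px`; "same x-y coordinates" is necessarily a tolerance at
#'   sub-pixel precision.
#' @param count_gap_frames If `TRUE` (default) bridged gap frames count
#'   toward the dwell: a punctum is deemed present while blinked off.
#' @return A validated list of class `tracking_params`.
#' @export
tracking_params <- function(link_radius_px = 2, max_gap_frames = 3L,
                            exclusion_radius_um = 1,
                            concurrent_both = FALSE,
                            same_site_radius_px = NULL,
                            count_gap_frames = TRUE) {
  p <- list(link_radius_px = link_radius_px,
            max_gap_frames = as.integer(max_gap_frames),
            exclusion_radius_um = exclusion_radius_um,
            concurrent_both = isTRUE(concurrent_both),
            same_site_radius_px = same_site_radius_px %||% link_radius_px,
            count_gap_frames = isTRUE(count_gap_frames))
  stop_if_not_scalar_pos(p$link_radius_px, "link_radius_px")
  stop_if_not_scalar_pos(p$exclusion_radius_um, "exclusion_radius_um")
  stop_if_not_scalar_pos(p$same_site_radius_px, "same_site_radius_px")
  if (p$max_gap_frames < 0L) stop("`max_gap_frames` must be >= 0",
                                  call. = FALSE)
  structure(p, class = "tracking_params")
}

#' Link per-frame detections into single-punctum traces
#'
#' Greedy nearest-neighbour assignment: on each frame, the globally closest
#' (open trace, detection) pair within `link_radius_px` is linked first,
#' repeatedly; remaining detections found new traces.  Because the molecules
#' are surface-immobilized, distance is measured to the trace's running
#' centroid, which is robust against single-frame localization disturbances
#' from transient neighbours.  A trace stays open through up to
#' `max_gap_frames` consecutive missing frames, then closes.  Ties in
#' distance are broken deterministically towards the lower detection row
#' index, then the lower trace id.
#'
#' @param detections Data frame with at least `frame` (0-based), `x_px`,
#'   `y_px`; if a logical `kept` column is present only kept rows are
#'   linked.  Rows must be sorted by frame.
#' @param params A [tracking_params()] object.
#' @param n_frames Number of frames in the movie.
#' @return List with `traces` (data frame: `trace_id`, `first_frame`,
#'   `last_frame`, `centroid_x_px`, `centroid_y_px`, `n_detections`,
#'   `n_gaps_bridged`) and `detections` (the linked input rows plus
#'   `trace_id`).  Every linked detection belongs to exactly one trace.
#' @export
link_traces <- function(detections, params = tracking_params(),
                        n_frames = max(detections$frame) + 1L) {
  det <- detections
  if (!is.null(det$kept)) det <- det[det$kept, , drop = FALSE]
  if (is.unsorted(det$frame)) {
    stop("detections must be sorted by frame", call. = FALSE)
  }
  n <- nrow(det)
  trace_of <- integer(n)
  # open-trace state (parallel vectors, indexed by trace id)
  t_x <- t_y <- numeric(0) # last linked position
  t_last <- t_first <- t_ndet <- integer(0)
  t_sumx <- t_sumy <- numeric(0)
  open <- integer(0)
  r <- params$link_radius_px
  row_of_frame <- split(seq_len(n), det$frame)
  for (f in 0:(n_frames - 1L)) {
    rows <- row_of_frame[[as.character(f)]]
    if (length(open)) {
      stale <- f - t_last[open] - 1L > params$max_gap_frames
      open <- open[!stale]
    }
    if (!is.null(rows)) {
      m <- length(open)
      k <- length(rows)
      if (m && k) {
        D <- outer(t_sumx[open] / t_ndet[open], det$x_px[rows], "-")^2 +
          outer(t_sumy[open] / t_ndet[open], det$y_px[rows], "-")^2
        repeat {
          mn <- min(D)
          if (!is.finite(mn) || mn > r * r) break
          hit <- which(D == mn, arr.ind = TRUE)
          # deterministic tie-break: lowest detection index, then trace id
          hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
          i <- hit[1, 1]
          j <- hit[1, 2]
          id <- open[i]
          row <- rows[j]
          trace_of[row] <- id
          t_x[id] <- det$x_px[row]
          t_y[id] <- det$y_px[row]
          t_sumx[id] <- t_sumx[id] + det$x_px[row]
          t_sumy[id] <- t_sumy[id] + det$y_px[row]
          t_ndet[id] <- t_ndet[id] + 1L
          t_last[id] <- f
          D[i, ] <- Inf
          D[, j] <- Inf
        }
      }
      new_rows <- rows[trace_of[rows] == 0L]
      for (row in new_rows) {
        id <- length(t_x) + 1L
        t_x[id] <- det$x_px[row]
        t_y[id] <- det$y_px[row]
        t_sumx[id] <- det$x_px[row]
        t_sumy[id] <- det$y_px[row]
        t_first[id] <- f
        t_last[id] <- f
        t_ndet[id] <- 1L
        trace_of[row] <- id
        open <- c(open, id)
      }
    }
  }
  n_tr <- length(t_x)
  traces <- data.frame(trace_id = seq_len(n_tr), first_frame = t_first,
                       last_frame = t_last,
                       centroid_x_px = t_sumx / t_ndet,
                       centroid_y_px = t_sumy / t_ndet,
                       n_detections = t_ndet,
                       n_gaps_bridged = t_last - t_first + 1L - t_ndet)
  det$trace_id <- trace_of
  list(traces = traces, detections = det)
}

#' Apply the four trace-exclusion rules
#'
#' Sets each trace's status to `kept` or `removed` with a machine-readable
#' reason.  The rules, each evaluated against the full pre-filter trace set
#' (so that the kept set does not depend on evaluation order; the order only
#' decides which reason a multiply-excluded trace carries):
#' \enumerate{
#'   \item `boundary` — the trace starts on the first frame or ends on the
#'     last frame of the movie (its dwell is censored).
#'   \item `single_frame` — the trace starts and ends on the same frame
#'     (likely non-specific sticking or an impurity).
#'   \item `concurrent` — the trace is born within `exclusion_radius_um` of
#'     a trace alive on its birth frame (with `concurrent_both = TRUE` the
#'     resident trace is removed as well).
#'   \item `repeat_site` — the trace shares a site (centroids within
#'     `same_site_radius_px`) with a trace of non-overlapping time span;
#'     all traces at such a site are removed.
#' }
#'
#' @param traces Trace table from [link_traces()].
#' @param params A [tracking_params()] object.
#' @param n_frames Number of frames in the movie.
#' @param pixel_size_um Pixel size, used to convert the micron exclusion
#'   radius to pixels.
#' @return The trace table with `status` (`"kept"`/`"removed"`) and
#'   `reason` columns.
#' @export
filter_traces <- function(traces, params = tracking_params(), n_frames,
                          pixel_size_um) {
  tr <- traces
  n <- nrow(tr)
  reason <- rep(NA_character_, n)
  if (n == 0L) {
    tr$status <- character(0)
    tr$reason <- character(0)
    return(tr)
  }
  mark <- function(idx, why) {
    new <- idx[is.na(reason[idx])]
    reason[new] <<- why
  }
  # (1) censored at the movie boundaries
  mark(which(tr$first_frame == 0L | tr$last_frame == n_frames - 1L),
       "boundary")
  # (2) single-frame traces
  mark(which(tr$first_frame == tr$last_frame), "single_frame")
  # (3) birth within the exclusion radius of a concurrent trace
  excl_px <- params$exclusion_radius_um / pixel_size_um
  dx <- outer(tr$centroid_x_px, tr$centroid_x_px, "-")
  dy <- outer(tr$centroid_y_px, tr$centroid_y_px, "-")
  d2 <- dx * dx + dy * dy
  near_excl <- d2 < excl_px^2
  alive_at_birth <- outer(tr$first_frame, tr$first_frame, ">=") &
    outer(tr$first_frame, tr$last_frame, "<=")
  diag(alive_at_birth) <- FALSE
  conc <- near_excl & alive_at_birth # [i, j]: j alive when i is born
  mark(which(rowSums(conc) > 0L), "concurrent")
  if (params$concurrent_both) mark(which(colSums(conc) > 0L), "concurrent")
  # (4) repeated use of the same site at non-overlapping times
  near_site <- d2 < params$same_site_radius_px^2
  disjoint <- outer(tr$last_frame, tr$first_frame, "<") |
    outer(tr$first_frame, tr$last_frame, ">")
  rep_site <- near_site & disjoint
  mark(which(rowSums(rep_site) > 0L), "repeat_site")
  tr$status <- ifelse(is.na(reason), "kept", "removed")
  tr$reason <- reason
  tr
}

#' Extract dwell times from kept traces
#'
#' The dwell of a trace is `(last_frame - first_frame + 1) * frame_interval`
#' — the punctum is deemed present during bridged blinking gaps.  With
#' `count_gap_frames = FALSE` in the tracking parameters, bridged gap frames
#' are subtracted instead.
#'
#' @param traces Filtered trace table from [filter_traces()].
#' @param frame_interval_s Frame interval, seconds.
#' @param movie_id Provenance label; dwell sets pooled across movies are
#'   concatenated with `rbind()`.
#' @param params A [tracking_params()] object (for `count_gap_frames`).
#' @return Data frame with `movie_id`, `trace_id`, `dwell_s`.
#' @export
extract_dwells <- function(traces, frame_interval_s, movie_id = "movie",
                           params = tracking_params()) {
  kept <- traces[traces$status == "kept", , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no kept traces; empty dwell set", call. = FALSE)
    return(data.frame(movie_id = character(), trace_id = integer(),
                      dwell_s = numeric()))
  }
  frames <- kept$last_frame - kept$first_frame + 1L
  if (!params$count_gap_frames) frames <- frames - kept$n_gaps_bridged
  data.frame(movie_id = movie_id, trace_id = kept$trace_id,
             dwell_s = frames * frame_interval_s)
}
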