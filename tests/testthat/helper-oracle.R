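# Brute-force reference: enumerate traces directly from a simulated movie's
# ground-truth table and apply the exclusion rules by explicit loops,
# independently of the detection/tracking code paths.
brute_force_traces <- function(movie, params) {
  truth <- movie$truth
  n_frames <- dim(movie$stack)[3]
  segs <- list()
  for (i in seq_len(nrow(truth))) {
    f0 <- max(truth$first_frame[i], 0L)
    f1 <- min(truth$last_frame[i], n_frames - 1L)
    if (f1 < f0) next
    vis <- setdiff(f0:f1, movie$dark$frame[movie$dark$event_id == i])
    if (!length(vis)) next
    vis <- sort(vis)
    brk <- which(diff(vis) > params$max_gap_frames + 1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(vis))
    for (s in seq_along(starts)) {
      segs[[length(segs) + 1L]] <-
        data.frame(event_id = i, x = truth$x_px[i], y = truth$y_px[i],
                   first = vis[starts[s]], last = vis[ends[s]])
    }
  }
  tr <- do.call(rbind, segs)
  tr <- tr[order(tr$first, tr$event_id), ]
  n <- nrow(tr)
  removed <- rep(FALSE, n)
  # boundary and single-frame
  for (i in seq_len(n)) {
    if (tr$first[i] == 0L || tr$last[i] == n_frames - 1L) removed[i] <- TRUE
    if (tr$first[i] == tr$last[i]) removed[i] <- TRUE
  }
  # birth within the exclusion radius of a concurrently alive trace
  excl_px <- params$exclusion_radius_um / movie$pixel_size_um
  conc <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      alive <- tr$first[j] <= tr$first[i] && tr$last[j] >= tr$first[i]
      d <- sqrt((tr$x[i] - tr$x[j])^2 + (tr$y[i] - tr$y[j])^2)
      if (alive && d < excl_px) {
        conc[i] <- TRUE
        if (params$concurrent_both) conc[j] <- TRUE
      }
    }
  }
  removed <- removed | conc
  # repeated site at non-overlapping times
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((tr$x[i] - tr$x[j])^2 + (tr$y[i] - tr$y[j])^2)
      disjoint <- tr$last[i] < tr$first[j] || tr$first[i] > tr$last[j]
      if (d < params$same_site_radius_px && disjoint) {
        removed[i] <- TRUE
        removed[j] <- TRUE
      }
    }
  }
  tr$kept <- !removed
  tr
}

# match pipeline kept traces against brute-force kept traces: same frame
# span, position within tol pixels; returns TRUE on exact set equality
same_kept_sets <- function(pipeline_traces, bf, tol_px = 1) {
  kept_p <- pipeline_traces[pipeline_traces$status == "kept", ]
  kept_b <- bf[bf$kept, ]
  if (nrow(kept_p) != nrow(kept_b)) return(FALSE)
  used <- rep(FALSE, nrow(kept_b))
  for (i in seq_len(nrow(kept_p))) {
    hit <- which(!used &
                 kept_b$first == kept_p$first_frame[i] &
                 kept_b$last == kept_p$last_frame[i] &
                 abs(kept_b$x - kept_p$centroid_x_px[i]) < tol_px &
                 abs(kept_b$y - kept_p$centroid_y_px[i]) < tol_px)
    if (!length(hit)) return(FALSE)
    used[hit[1]] <- TRUE
  }
  all(used)
}

run_tracking <- function(movie, det_params = detection_params(),
                         trk_params = tracking_params()) {
  n_frames <- dim(movie$stack)[3]
  det <- detect_movie(movie, det_params)
  linked <- link_traces(det, trk_params, n_frames)
  filter_traces(linked$traces, trk_params, n_frames, movie$pixel_size_um)
}
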