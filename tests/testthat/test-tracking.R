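test_that("a stationary punctum seen in frames 0-4 yields one 5-frame trace", {
  det <- make_detections(0:4, x = 20, y = 20, amplitude = 300,
                         sigma_x = 1.3, sigma_y = 1.3)
  out <- link_traces(det, tracking_params(), n_frames = 10)
  expect_equal(nrow(out$traces), 1)
  expect_equal(out$traces$first_frame, 0)
  expect_equal(out$traces$last_frame, 4)
  expect_equal(out$traces$n_gaps_bridged, 0)
  expect_equal(out$traces$last_frame - out$traces$first_frame + 1, 5)
})

test_that("gaps of 3 frames are bridged, gaps of 4 split the trace", {
  det3 <- make_detections(c(0:2, 6:9), 20, 20, 300, 1.3, 1.3)
  out3 <- link_traces(det3, tracking_params(), n_frames = 12)
  expect_equal(nrow(out3$traces), 1)
  expect_equal(out3$traces$n_gaps_bridged, 3)
  expect_equal(out3$traces$last_frame - out3$traces$first_frame + 1, 10)

  det4 <- make_detections(c(0:2, 7:9), 20, 20, 300, 1.3, 1.3)
  out4 <- link_traces(det4, tracking_params(), n_frames = 12)
  expect_equal(nrow(out4$traces), 2)
})

test_that("equidistant assignments break ties to the lower detection index", {
  det <- rbind(make_detections(0L, 20, 20, 300, 1.3, 1.3),
               make_detections(1L, c(21, 19), c(20, 20), 300, 1.3, 1.3))
  out <- link_traces(det, tracking_params(), n_frames = 3)
  # the first row of frame 1 (x = 21) continues trace 1
  expect_equal(out$detections$trace_id, c(1L, 1L, 2L))
})

test_that("every linked detection belongs to exactly one trace", {
  p <- movie_sim_params(field_w_px = 96, field_h_px = 96, n_frames = 120,
                        tau_true_s = 8, arrival_rate_per_um2_s = 0.004,
                        seed = 31)
  m <- simulate_movie(p)
  det <- detect_movie(m)
  out <- link_traces(det, tracking_params(), 120)
  kept_rows <- out$detections
  expect_true(all(kept_rows$trace_id >= 1))
  counted <- sum(out$traces$n_detections)
  expect_equal(counted, nrow(kept_rows))
})

test_that("boundary and single-frame traces are removed with reasons", {
  traces <- data.frame(trace_id = 1:4,
                       first_frame = c(0L, 5L, 8L, 3L),
                       last_frame = c(4L, 19L, 8L, 10L),
                       centroid_x_px = c(10, 40, 70, 100),
                       centroid_y_px = 10, n_detections = 1L,
                       n_gaps_bridged = 0L)
  out <- filter_traces(traces, tracking_params(), n_frames = 20,
                       pixel_size_um = 0.065)
  expect_equal(out$status, c("removed", "removed", "removed", "kept"))
  expect_equal(out$reason[1], "boundary") # starts on frame 0
  expect_equal(out$reason[2], "boundary") # ends on the last frame
  expect_equal(out$reason[3], "single_frame")
})

test_that("concurrent births inside 1 um are excluded, outside are kept", {
  px <- 0.065
  mk <- function(x2) {
    data.frame(trace_id = 1:2, first_frame = c(5L, 5L),
               last_frame = c(15L, 14L),
               centroid_x_px = c(30, 30 + x2 / px), centroid_y_px = 30,
               n_detections = 5L, n_gaps_bridged = 0L)
  }
  close_pair <- filter_traces(mk(0.8), tracking_params(), 40, px)
  expect_equal(close_pair$status, c("removed", "removed"))
  expect_true(all(close_pair$reason == "concurrent"))
  far_pair <- filter_traces(mk(1.2), tracking_params(), 40, px)
  expect_equal(far_pair$status, c("kept", "kept"))
})

test_that("by default only the newborn member of a staggered pair is removed", {
  px <- 0.065
  tr <- data.frame(trace_id = 1:2, first_frame = c(5L, 9L),
                   last_frame = c(15L, 20L),
                   centroid_x_px = c(30, 30 + 0.5 / px), centroid_y_px = 30,
                   n_detections = 5L, n_gaps_bridged = 0L)
  out <- filter_traces(tr, tracking_params(), 40, px)
  expect_equal(out$status, c("kept", "removed"))
  both <- filter_traces(tr, tracking_params(concurrent_both = TRUE), 40, px)
  expect_equal(both$status, c("removed", "removed"))
})

test_that("all traces at a repeatedly used site are removed", {
  tr <- data.frame(trace_id = 1:3, first_frame = c(2L, 20L, 9L),
                   last_frame = c(8L, 28L, 14L),
                   centroid_x_px = c(30, 30.5, 80), centroid_y_px = 30,
                   n_detections = 4L, n_gaps_bridged = 0L)
  out <- filter_traces(tr, tracking_params(), 40, 0.065)
  expect_equal(out$status, c("removed", "removed", "kept"))
  expect_true(all(out$reason[1:2] == "repeat_site"))
})

test_that("kept traces satisfy all four predicates; kept set ignores row order", {
  p <- movie_sim_params(field_w_px = 128, field_h_px = 128, n_frames = 150,
                        tau_true_s = 8, arrival_rate_per_um2_s = 0.006,
                        seed = 13)
  m <- simulate_movie(p)
  tp <- tracking_params()
  det <- detect_movie(m)
  linked <- link_traces(det, tp, 150)
  out <- filter_traces(linked$traces, tp, 150, m$pixel_size_um)
  kept <- out[out$status == "kept", ]
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$first_frame > 0 & kept$last_frame < 149))
  expect_true(all(kept$first_frame < kept$last_frame))
  excl_px <- 1 / 0.065
  for (i in seq_len(nrow(kept))) {
    d <- sqrt((out$centroid_x_px - kept$centroid_x_px[i])^2 +
              (out$centroid_y_px - kept$centroid_y_px[i])^2)
    alive <- out$first_frame <= kept$first_frame[i] &
      out$last_frame >= kept$first_frame[i] &
      out$trace_id != kept$trace_id[i]
    expect_false(any(alive & d < excl_px))
    disjoint <- out$last_frame < kept$first_frame[i] |
      out$first_frame > kept$last_frame[i]
    expect_false(any(disjoint & d < tp$same_site_radius_px &
                     out$trace_id != kept$trace_id[i]))
  }
  perm <- sample(nrow(linked$traces))
  out_perm <- filter_traces(linked$traces[perm, ], tp, 150, m$pixel_size_um)
  expect_setequal(out_perm$trace_id[out_perm$status == "kept"],
                  out$trace_id[out$status == "kept"])
})

test_that("dwells are (last - first + 1) frame intervals", {
  tr <- data.frame(trace_id = 1:2, first_frame = c(10L, 3L),
                   last_frame = c(19L, 7L), centroid_x_px = c(10, 40),
                   centroid_y_px = 10, n_detections = c(10L, 5L),
                   n_gaps_bridged = 0L, status = "kept",
                   reason = NA_character_)
  expect_equal(extract_dwells(tr[1, ], 1)$dwell_s, 10)
  expect_equal(extract_dwells(tr[2, ], 2)$dwell_s, 10)
  tr$status <- "removed"
  expect_warning(out <- extract_dwells(tr, 1), "no kept traces")
  expect_equal(nrow(out), 0)
})

test_that("pipeline kept traces equal the brute-force truth-table filter", {
  # sparse field: puncta are optically resolvable, so detection is 1:1 with
  # events and the image-level pipeline must reproduce the rule set exactly
  for (seed in 1:2) {
    p <- movie_sim_params(field_w_px = 256, field_h_px = 256, n_frames = 250,
                          tau_true_s = 10, arrival_rate_per_um2_s = 0.001,
                          blink_off_prob = 0.05, seed = seed)
    m <- simulate_movie(p)
    tp <- tracking_params()
    out <- run_tracking(m, trk_params = tp)
    bf <- brute_force_traces(m, tp)
    expect_true(same_kept_sets(out, bf))
  }
})
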