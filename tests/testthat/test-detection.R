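test_that("a structureless image yields no blob candidates", {
  expect_equal(nrow(detect_blobs(matrix(100, 64, 64))), 0)
  set.seed(1)
  noise <- matrix(rpois(64 * 64, 100) + rnorm(64 * 64, 0, 2), 64, 64)
  expect_equal(nrow(detect_blobs(noise)), 0)
})

test_that("an image smaller than the fit window warns and returns nothing", {
  expect_warning(out <- detect_blobs(make_frame(8, 8)), "smaller")
  expect_equal(nrow(out), 0)
})

test_that("isolated spots are found once each, within a pixel", {
  set.seed(7)
  spots <- data.frame(x = 30.4, y = 21.7, amp = 500, sigma = 1.3)
  img <- make_frame(64, 64, spots) + rnorm(64 * 64, 0, 10) # amp = 50 x sd
  img[img < 0] <- 0
  b <- detect_blobs(img)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$x - 30.4), 1)
  expect_lt(abs(b$y - 21.7), 1)

  two <- data.frame(x = c(20, 30), y = c(40, 40), amp = 500, sigma = 1.3)
  b2 <- detect_blobs(make_frame(64, 64, two))
  expect_equal(nrow(b2), 2)
})

test_that("the Gaussian refinement recovers noise-free parameters to 1e-3", {
  truth <- list(x = 25.37, y = 18.81, amp = 420, sigma = 1.3, b = 100)
  img <- make_frame(48, 48,
                    data.frame(x = truth$x, y = truth$y, amp = truth$amp,
                               sigma = truth$sigma))
  cand <- detect_blobs(img)
  expect_equal(nrow(cand), 1)
  fit <- fit_gaussian2d(img, cand)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$x_px - truth$x), 1e-3)
  expect_lt(abs(fit$y_px - truth$y), 1e-3)
  expect_lt(abs(fit$amplitude / truth$amp - 1), 1e-3)
  expect_lt(abs(fit$sigma_x / truth$sigma - 1), 1e-3)
  expect_lt(abs(fit$sigma_y / truth$sigma - 1), 1e-3)
  expect_lt(abs(fit$offset / truth$b - 1), 1e-3)
})

test_that("degenerate windows do not produce usable fits", {
  flat <- make_frame(32, 32)
  fit <- fit_gaussian2d(flat, data.frame(x = 15, y = 15, scale = 1.3))
  expect_false(fit$fit_ok)
  # window clipped by the image edge
  img <- make_frame(32, 32, data.frame(x = 2, y = 16, amp = 400, sigma = 1.3))
  fit2 <- fit_gaussian2d(img, data.frame(x = 2, y = 16, scale = 1.3))
  expect_false(fit2$fit_ok)
  expect_equal(fit2$reject_reason, "window_clipped")
})

test_that("elongated spots are fitted but rejected as non-circular", {
  xs <- 0:47
  img <- matrix(100, 48, 48) +
    400 * outer(exp(-(xs - 24)^2 / (2 * 1.0^2)),
                exp(-(xs - 24)^2 / (2 * 3.0^2))) # sigma_x/sigma_y = 3
  cand <- detect_blobs(img)
  expect_gte(nrow(cand), 1)
  det <- fit_gaussian2d(img, cand[1, ], detection_params(fit_window_px = 8))
  expect_true(det$fit_ok)
  expect_gt(max(det$sigma_x, det$sigma_y) / min(det$sigma_x, det$sigma_y), 2)
  flt <- filter_detections(det)
  expect_false(flt$kept)
  expect_equal(flt$reject_reason, "not_circular")
})

test_that("brightness and circularity rules follow the configured cutoffs", {
  det <- make_detections(frame = rep(0L, 6), x = seq(10, 60, 10), y = 20,
                         amplitude = c(100, 100, 100, 100, 100, 1000),
                         sigma_x = 1.3, sigma_y = 1.3)
  out <- filter_detections(det, detection_params(max_amp_factor = 5))
  expect_equal(out$kept, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$reject_reason[6], "too_bright")

  det2 <- make_detections(0L, c(10, 20), 20, 100,
                          sigma_x = c(1.3, 2.5 * 1.3),
                          sigma_y = c(1.3, 1.3))
  out2 <- filter_detections(det2, detection_params(circ_ratio_max = 2))
  expect_equal(out2$kept, c(TRUE, FALSE))
  expect_equal(out2$reject_reason[2], "not_circular")

  # identical circular spots: everything retained
  det3 <- make_detections(0L, seq(5, 45, 10), 10, 200, 1.3, 1.3)
  expect_true(all(filter_detections(det3)$kept))
  # empty input passes through
  expect_equal(nrow(filter_detections(det3[0, ])), 0)
})

test_that("filter_detections is idempotent and order-independent", {
  set.seed(3)
  det <- make_detections(frame = rep(0:1, each = 8), x = runif(16, 5, 60),
                         y = runif(16, 5, 60),
                         amplitude = c(rexp(15, 1 / 100), 2000),
                         sigma_x = runif(16, 1, 1.6),
                         sigma_y = runif(16, 1, 3.5))
  once <- filter_detections(det)
  twice <- filter_detections(once)
  expect_equal(twice$kept, once$kept)
  perm <- sample(nrow(det))
  shuffled <- filter_detections(det[perm, ])
  expect_equal(shuffled$kept, once$kept[perm])
})

test_that("noise-free frames give perfect recall and no false positives", {
  set.seed(11)
  n_found <- 0
  n_spots <- 0
  for (rep in 1:10) {
    k <- 5
    # spots at least 5 px apart on a jittered grid
    gx <- rep(seq(10, 50, 10), 2)[1:k] + runif(k, -2, 2)
    gy <- rep(c(15, 40), each = 5)[1:k] + runif(k, -2, 2)
    spots <- data.frame(x = gx, y = gy, amp = 400, sigma = 1.3)
    b <- detect_blobs(make_frame(64, 64, spots))
    n_spots <- n_spots + k
    expect_equal(nrow(b), k) # no false positives
    for (i in seq_len(k)) {
      n_found <- n_found +
        any(abs(b$x - gx[i]) < 1.5 & abs(b$y - gy[i]) < 1.5)
    }
  }
  expect_equal(n_found, n_spots) # recall 1.0
})

test_that("localization error stays below 0.15 px RMSE at SNR >= 20", {
  # 500 spots with shot + read noise; SNR = amp / sd(bg noise) ~ 44
  set.seed(21)
  err2 <- numeric(0)
  for (rep in 1:50) {
    gx <- seq(8, 56, length.out = 10) + runif(10, -0.5, 0.5)
    gy <- rep(c(20, 44), 5) + runif(10, -0.5, 0.5)
    img <- make_frame(64, 64, data.frame(x = gx, y = gy, amp = 450,
                                         sigma = 1.3))
    img[] <- rpois(length(img), img) + rnorm(length(img), 0, 2)
    img[img < 0] <- 0
    mv <- list(stack = array(img, c(64, 64, 1)))
    det <- detect_movie(mv)
    det <- det[det$kept, ]
    for (i in 1:10) {
      d2 <- (det$x_px - gx[i])^2 + (det$y_px - gy[i])^2
      j <- which.min(d2)
      if (length(j) && d2[j] < 1) {
        err2 <- c(err2, (det$x_px[j] - gx[i])^2, (det$y_px[j] - gy[i])^2)
      }
    }
  }
  expect_gt(length(err2), 900) # nearly all of the 500 spots localized
  expect_lt(sqrt(mean(err2)), 0.15)
})
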