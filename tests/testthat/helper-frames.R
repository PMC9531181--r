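# build a synthetic frame directly (independent of the movie simulator):
# constant background plus symmetric Gaussian spots at given positions
make_frame <- function(w, h, spots = NULL, background = 100) {
  img <- matrix(background, nrow = h, ncol = w)
  if (!is.null(spots) && nrow(spots)) {
    xs <- 0:(w - 1)
    ys <- 0:(h - 1)
    for (i in seq_len(nrow(spots))) {
      gx <- exp(-(xs - spots$x[i])^2 / (2 * spots$sigma[i]^2))
      gy <- exp(-(ys - spots$y[i])^2 / (2 * spots$sigma[i]^2))
      img <- img + spots$amp[i] * outer(gy, gx)
    }
  }
  img
}

# hand-built detection rows for filter tests
make_detections <- function(frame, x, y, amplitude, sigma_x, sigma_y) {
  data.frame(frame = frame, x_px = x, y_px = y, amplitude = amplitude,
             sigma_x = sigma_x, sigma_y = sigma_y, offset = 100,
             fit_ok = TRUE, reject_reason = NA_character_)
}
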