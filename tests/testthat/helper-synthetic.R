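# Shared fixtures, all generated in code.

# A flat image with Gaussian spots added at given positions/amplitudes.
spot_image <- function(dim = c(64, 64), x, y, amp, sigma = 1.5,
                       background = 0) {
  img <- matrix(background, dim[1], dim[2])
  for (i in seq_along(x)) img <- pulsetrack:::add_spot(img, x[i], y[i],
                                                       amp[i], sigma)
  img
}

# A minimal valid interleaved movie with constant frames.
flat_movie <- function(n_cycles = 4, dim = c(32, 32), value = 10, dt = 2) {
  ph_movie(array(value, c(dim, 2 * n_cycles)),
           frame_ph = rep(c(7.4, 5.5), n_cycles), dt = dt)
}

# Events data frame from ground truth, restricted to full-window validity.
truth_events <- function(truth, n_cycles, window = c(-82, 40), dt = 2) {
  lo <- 1 - window[1] / dt
  hi <- n_cycles - window[2] / dt
  ev <- truth$scissions[truth$scissions$t0_cycle >= lo &
                        truth$scissions$t0_cycle <= hi, , drop = FALSE]
  ev$t0 <- ev$t0_cycle
  ev
}
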