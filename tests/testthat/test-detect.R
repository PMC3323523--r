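test_that("a noiseless Gaussian spot is localised to within 0.1 px", {
  img <- spot_image(c(64, 64), x = 20.0, y = 30.0, amp = 100, sigma = 1.5,
                    background = 10)
  d <- detect_spots(img, psf_sigma = 1.5, snr_min = 2)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 20), 0.1)
  expect_lt(abs(d$y - 30), 0.1)
  # subpixel centre
  img2 <- spot_image(c(64, 64), x = 20.4, y = 29.7, amp = 100, sigma = 1.5)
  d2 <- detect_spots(img2, 1.5, 2)
  expect_lt(abs(d2$x - 20.4), 0.1)
  expect_lt(abs(d2$y - 29.7), 0.1)
})

test_that("a flat image yields no detections", {
  expect_equal(nrow(detect_spots(matrix(5, 64, 64), 1.5, 2)), 0)
})

test_that("well-separated spots are each detected exactly once", {
  # brute-force oracle: local maxima of the noiseless image itself
  img <- spot_image(c(64, 64), x = c(20, 40), y = c(20, 40), amp = c(80, 80))
  brute <- 0
  for (r in 2:63) for (c in 2:63) {
    nb <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (img[r, c] == max(nb) && img[r, c] > 1) brute <- brute + 1
  }
  expect_equal(brute, 2)
  d <- detect_spots(img, 1.5, 2)
  expect_equal(nrow(d), 2)
})

test_that("detection survives generator-level noise at working SNR", {
  img <- spot_image(c(64, 64), x = 32, y = 32, amp = 60, background = 100)
  set.seed(42)
  found <- 0L
  for (i in 1:20) {
    noisy <- matrix(rpois(64 * 64, img) + rnorm(64 * 64, sd = 3), 64)
    d <- detect_spots(noisy, 1.5, 2)
    if (nrow(d) && min(sqrt((d$x - 32)^2 + (d$y - 32)^2)) < 2) found <- found + 1L
  }
  expect_gte(found, 19)
})

test_that("a drifting spot links into a single track", {
  det <- do.call(rbind, lapply(1:10, function(k)
    data.frame(cycle = k, x = 10 + k, y = 20, intensity = 1, snr = 5)))
  tr <- link_tracks(det, max_disp = 3, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("a gap longer than max_gap splits the track", {
  det <- data.frame(cycle = c(1, 2, 3, 7, 8), x = 10, y = 10,
                    intensity = 1, snr = 5)
  tr <- link_tracks(det, max_disp = 3, max_gap = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  # gap of exactly max_gap cycles bridges
  det2 <- data.frame(cycle = c(1, 2, 5), x = 10, y = 10,
                     intensity = 1, snr = 5)
  tr2 <- link_tracks(det2, max_disp = 3, max_gap = 2)
  expect_equal(length(unique(tr2$track_id)), 1)
})

test_that("greedy linking equals exhaustive matching for sparse spots", {
  # brute-force oracle: per transition, enumerate all one-to-one assignments
  # and take the minimum total cost (with max_disp forbidden)
  exhaustive_link <- function(det, max_disp) {
    cycles <- sort(unique(det$cycle))
    det$track_id <- NA_integer_
    nid <- 1L
    prev_idx <- integer(0)
    for (cy in cycles) {
      idx <- which(det$cycle == cy)
      if (length(prev_idx)) {
        np <- length(prev_idx); nd <- length(idx)
        best <- NULL; bestc <- Inf
        perms <- function(v) if (length(v) <= 1) list(v) else
          do.call(c, lapply(seq_along(v), function(i)
            lapply(perms(v[-i]), function(p) c(v[i], p))))
        # assign each previous spot to a detection or nothing
        for (p in perms(seq_len(nd))) {
          cost <- 0; assign <- rep(NA_integer_, np)
          for (a in seq_len(min(np, nd))) {
            dd <- sqrt((det$x[prev_idx[a]] - det$x[idx[p[a]]])^2 +
                       (det$y[prev_idx[a]] - det$y[idx[p[a]]])^2)
            if (dd <= max_disp) { cost <- cost + dd; assign[a] <- p[a] }
            else cost <- cost + 1000  # unmatched: large fixed penalty
          }
          cost <- cost + 1000 * sum(is.na(assign))
          if (cost < bestc - 1e-12) { bestc <- cost; best <- assign }
        }
        for (a in seq_len(np)) {
          if (!is.na(best[a]))
            det$track_id[idx[best[a]]] <- det$track_id[prev_idx[a]]
        }
      }
      for (i in idx[is.na(det$track_id[idx])]) {
        det$track_id[i] <- nid; nid <- nid + 1L
      }
      prev_idx <- idx
    }
    det
  }
  set.seed(7)
  for (rep in 1:5) {
    # 3 spots with spacing > 2 * max_disp, small jitter per cycle
    base <- data.frame(x = c(10, 30, 50), y = c(10, 35, 15))
    det <- do.call(rbind, lapply(1:6, function(k)
      data.frame(cycle = k, x = base$x + rnorm(3, sd = 0.5),
                 y = base$y + rnorm(3, sd = 0.5), intensity = 1, snr = 5)))
    g <- link_tracks(det, max_disp = 4, max_gap = 0)
    e <- exhaustive_link(det, max_disp = 4)
    # same partition of detections into tracks
    gsp <- split(paste(g$cycle, round(g$x, 3)), g$track_id)
    esp <- split(paste(e$cycle, round(e$x, 3)), e$track_id)
    expect_setequal(unname(vapply(gsp, paste, "", collapse = "|")),
                    unname(vapply(esp, paste, "", collapse = "|")))
  }
})

test_that("ROI measurement returns zeros on a uniform image", {
  ser <- array(7, c(32, 32, 5))
  tr <- measure_roi(ser, 16, 16, 3, c(5, 8))
  expect_equal(tr$values, rep(0, 5))
  expect_equal(tr$background, rep(7, 5))
})

test_that("ROI value matches the analytic disc-minus-annulus mean", {
  sigma <- 1.5; amp <- 120
  img <- spot_image(c(48, 48), x = 24.3, y = 22.6, amp = amp, sigma = sigma,
                    background = 50)
  ser <- array(img, c(48, 48, 1))
  tr <- measure_roi(ser, 24.3, 22.6, 3, c(5, 8))
  idx <- pulsetrack:::roi_indices(c(48, 48), 24.3, 22.6, 3, c(5, 8))
  g <- function(rc) mean(amp * exp(-((rc$c - 24.3)^2 + (rc$r - 22.6)^2) /
                                   (2 * sigma^2)))
  expect_equal(tr$values[1], g(idx$disc_rc) - g(idx$ann_rc),
               tolerance = 1e-10)
  # and equals amp * roi_psf_gain by construction
  expect_equal(tr$values[1],
               amp * roi_psf_gain(c(48, 48), 24.3, 22.6, sigma, 3, c(5, 8)),
               tolerance = 1e-10)
})

test_that("ROI preconditions are enforced", {
  ser <- array(0, c(32, 32, 2))
  expect_error(measure_roi(ser, 16, 16, 0), "radius")
  expect_error(measure_roi(ser, 3, 16, 3, c(5, 8)), "border")
})

test_that("ROI measurement is linear in image intensity", {
  set.seed(3)
  ser <- array(rpois(32 * 32 * 4, 50), c(32, 32, 4))
  t1 <- measure_roi(ser, 16, 16)
  t2 <- measure_roi(ser * 3.5, 16, 16)
  expect_equal(t2$values, 3.5 * t1$values, tolerance = 1e-12)
})
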