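test_that("out-of-range cycles are flagged missing, not zero-filled", {
  ser <- array(10, c(32, 32, 60))
  ev <- data.frame(event_id = 1L, t0 = 5L, x = 16, y = 16)
  tr <- extract_aligned_traces(ser, ev, window = c(-82, 40), dt = 2)
  # t_rel grid -82..40: offsets -41..20; cycles 5 + off < 1 for off < -4
  expect_equal(sum(is.na(tr$matrix[1, ])), 37)
  expect_true(all(is.na(tr$matrix[1, tr$t_rel < -8])))
  expect_false(anyNA(tr$matrix[1, tr$t_rel >= -8]))
})

test_that("zero events give an empty matrix without error", {
  ser <- array(10, c(32, 32, 60))
  tr <- extract_aligned_traces(ser, data.frame(event_id = integer(0),
                                               t0 = integer(0),
                                               x = numeric(0),
                                               y = numeric(0)))
  expect_equal(nrow(tr$matrix), 0)
})

test_that("noiseless traces reproduce the kernel in amplitude units", {
  cfg <- sim_config(n_cycles = 150, field_size = 64, noise = FALSE,
                    nucleation_rate = 0.008, min_separation = 24)
  k0 <- kinetic_profile(flicker_amp = 0)
  sim <- simulate_movie(cfg, kernel = k0, seed = 7)
  ev <- truth_events(sim$truth, 150)
  # keep events from CCS with a single scission (no overlapping bursts)
  single <- sim$truth$ccs$ccs_id[sim$truth$ccs$n_events == 1]
  ev <- ev[ev$ccs_id %in% single, , drop = FALSE]
  expect_gt(nrow(ev), 0)
  tr <- extract_aligned_traces(sim$movie$reporter, ev, window = c(-82, 40),
                               dt = 2)
  kv <- eval_kernel(k0, tr$t_rel)
  err <- max(abs(sweep(tr$matrix, 2, kv)), na.rm = TRUE)
  expect_lt(err, 1e-6 * k0$burst_amp)
})

test_that("ensemble mean and SEM follow their definitions", {
  tr <- structure(list(t_rel = seq(-4, 4, 2),
                       matrix = matrix(rep(c(1, 2, 3, 4, 5), 3), 3,
                                       byrow = TRUE),
                       event_ids = 1:3), class = "aligned_traces")
  sig <- ensemble_signature(tr)
  expect_equal(sig$mean, c(1, 2, 3, 4, 5))
  expect_equal(sig$sem, rep(0, 5))
  # single event: mean is the trace, sem 0 by convention
  tr1 <- tr; tr1$matrix <- tr$matrix[1, , drop = FALSE]; tr1$event_ids <- 1L
  sig1 <- ensemble_signature(tr1)
  expect_equal(sig1$mean, c(1, 2, 3, 4, 5))
  expect_equal(sig1$sem, rep(0, 5))
  expect_equal(sig1$n, rep(1L, 5))
})

test_that("the ensemble mean concentrates around the kernel (CLT)", {
  set.seed(9)
  t_rel <- seq(-20, 20, 2)
  kv <- eval_kernel(kinetic_profile(flicker_amp = 0), t_rel)
  n <- 500
  m <- matrix(rep(kv, each = n) + rnorm(n * length(kv), sd = 10), n)
  tr <- structure(list(t_rel = t_rel, matrix = m, event_ids = 1:n),
                  class = "aligned_traces")
  sig <- ensemble_signature(tr)
  expect_true(all(abs(sig$mean - kv) <= 3.5 * sig$sem + 1e-9))
})

test_that("the random envelope is degenerate on a constant reporter", {
  ser <- array(42, c(32, 32, 80))
  ev <- data.frame(event_id = 1:3, t0 = c(45, 50, 55), x = c(14, 16, 18),
                   y = 16)
  env <- random_envelope(ser, ev, window = c(-20, 20), dt = 2, B = 100,
                         seed = 1, psf_sigma = NULL)
  expect_equal(env$rand_lo, env$rand_hi)
  expect_equal(unname(env$rand_lo), rep(0, length(env$rand_lo)))
})

test_that("the envelope is reproducible under a seed and errors on short movies", {
  set.seed(4)
  ser <- array(rpois(32 * 32 * 80, 50), c(32, 32, 80))
  ev <- data.frame(event_id = 1:4, t0 = c(40, 45, 50, 55),
                   x = c(12, 14, 16, 18), y = 16)
  e1 <- random_envelope(ser, ev, c(-20, 20), 2, B = 100, seed = 5)
  e2 <- random_envelope(ser, ev, c(-20, 20), 2, B = 100, seed = 5)
  expect_identical(e1, e2)
  expect_error(random_envelope(ser, ev, c(-100, 100), 2, B = 100, seed = 1),
               "shorter")
})

test_that("normalisation maps the envelope to [-1, 1]", {
  sig <- structure(list(t_rel = 1:5, mean = rep(3, 5), sem = rep(0.1, 5),
                        n = rep(10L, 5), rand_lo = rep(1, 5),
                        rand_hi = rep(3, 5)),
                   class = "recruitment_signature")
  ns <- normalize_to_random(sig)
  expect_equal(ns$mean, rep(1, 5))    # mean at rand_hi -> 1
  sig$mean <- rep(2, 5)               # mean at centre -> 0
  expect_equal(normalize_to_random(sig)$mean, rep(0, 5))
  sig$rand_hi <- sig$rand_lo
  expect_error(normalize_to_random(sig), "degenerate")
})

test_that("normalised signatures are invariant to affine reporter transforms", {
  set.seed(11)
  ser <- array(rpois(32 * 32 * 90, 60), c(32, 32, 90))
  ev <- data.frame(event_id = 1:5, t0 = seq(42, 58, 4), x = seq(10, 22, 3),
                   y = 16)
  build <- function(s) {
    tr <- extract_aligned_traces(s, ev, c(-20, 20), 2)
    sig <- ensemble_signature(tr)
    with_envelope(sig, random_envelope(s, ev, c(-20, 20), 2, B = 200,
                                       seed = 3))
  }
  n1 <- normalize_to_random(build(ser))
  n2 <- normalize_to_random(build(ser * 2.5 + 17))
  expect_equal(n1$mean, n2$mean, tolerance = 1e-9)
})

test_that("peak records find the kernel peak with earliest-tie rule", {
  t_rel <- seq(-20, 20, 2)
  kv <- eval_kernel(kinetic_profile(flicker_amp = 0), t_rel)
  m <- matrix(rep(kv, each = 4), 4)
  tr <- structure(list(t_rel = t_rel, matrix = m, event_ids = 1:4),
                  class = "aligned_traces")
  pk <- peak_records(tr, peak_window = c(-20, 20))
  expect_equal(pk$records$t_peak, rep(-2, 4))
  expect_equal(pk$fraction_in(-4, -2), 1.0)
  # tie across two cycles resolves to the earliest
  m2 <- matrix(c(0, 5, 5, 0, 0), 1)
  tr2 <- structure(list(t_rel = seq(-4, 4, 2), matrix = m2, event_ids = 1L),
                   class = "aligned_traces")
  pk2 <- peak_records(tr2, peak_window = c(-4, 4))
  expect_equal(pk2$records$t_peak, -2)
  expect_error(peak_records(tr2, peak_window = c(-40, 4)), "outside")
})

test_that("pure-noise peak times are uniform over the window", {
  set.seed(13)
  t_rel <- seq(-20, 20, 2)
  m <- matrix(rnorm(2000 * length(t_rel)), 2000)
  tr <- structure(list(t_rel = t_rel, matrix = m, event_ids = 1:2000),
                  class = "aligned_traces")
  pk <- peak_records(tr, peak_window = c(-20, 20))
  gof <- stats::chisq.test(pk$histogram)
  expect_gt(gof$p.value, 0.01)
})

test_that("slope and amplitude behave on exact signatures", {
  sig <- structure(list(t_rel = seq(-30, 0, 2), mean = 2 * seq(-30, 0, 2),
                        sem = rep(0, 16), n = rep(5L, 16)),
                   class = "recruitment_signature")
  expect_equal(signature_slope(sig, c(-30, 0)), 2, tolerance = 1e-12)
  flat <- sig; flat$mean <- rep(4, 16)
  expect_equal(signature_slope(flat, c(-30, 0)), 0, tolerance = 1e-12)
  expect_error(signature_slope(sig, c(-3, 0)), "3")
  # amplitude: flat -> 0; offset-invariant
  t_rel <- seq(-82, 40, 2)
  kv <- eval_kernel(kinetic_profile(flicker_amp = 0), t_rel)
  sig2 <- structure(list(t_rel = t_rel, mean = kv, sem = rep(0, 62),
                         n = rep(5L, 62)), class = "recruitment_signature")
  a <- signature_amplitude(sig2)
  expect_equal(a, 100, tolerance = 0.02)
  sig2$mean <- sig2$mean + 55
  expect_equal(signature_amplitude(sig2), a, tolerance = 1e-9)
  flat2 <- sig2; flat2$mean <- rep(7, 62)
  expect_equal(signature_amplitude(flat2), 0)
})

test_that("slow and fast kernels order their fitted pre-scission slopes", {
  t_rel <- seq(-82, 40, 2)
  fast <- eval_kernel(kinetic_presets("wt"), t_rel)
  slow <- eval_kernel(kinetic_presets("slow_burst"), t_rel)
  mk <- function(v) structure(list(t_rel = t_rel, mean = v,
                                   sem = rep(0, length(v)),
                                   n = rep(5L, length(v))),
                              class = "recruitment_signature")
  s_fast <- signature_slope(mk(fast), c(-20, -2))
  s_slow <- signature_slope(mk(slow), c(-20, -2))
  expect_gt(s_fast, s_slow)
  expect_gt(s_slow, 0)
})

test_that("early-enriched kernels show a pre-scission plateau above random", {
  cfg <- sim_config(n_cycles = 200, field_size = 64, nucleation_rate = 0.03,
                    kinetic_class = "early_enriched")
  sim <- simulate_movie(cfg, seed = 31)
  ev <- truth_events(sim$truth, 200)
  expect_gt(nrow(ev), 3)
  tr <- extract_aligned_traces(sim$movie$reporter, ev, c(-82, 40), 2)
  sig <- ensemble_signature(tr)
  env <- random_envelope(sim$movie$reporter, ev, c(-82, 40), 2, B = 500,
                         seed = 32)
  sel <- sig$t_rel >= -80 & sig$t_rel <= -30
  expect_true(mean(sig$mean[sel] > env$rand_hi[sel]) > 0.8)
})
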