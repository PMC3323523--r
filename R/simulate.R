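#' Configuration for the synthetic alternating-pH movie generator
#'
#' The generator emulates the statistical structure of a pulsed-pH TIRF
#' experiment: transferrin-receptor--pHluorin imaged under perfusion that
#' alternates between pH 7.4 (surface + internal signal, "TfR7") and pH 5.5
#' (only pH-insulated, internalised signal, "TfR5"), together with an
#' mCherry-like reporter channel sampled once per pH cycle. Clathrin-coated
#' structures (CCS) nucleate as a spatial Poisson process, host scission
#' events as a renewal process with exponentially distributed waiting times,
#' and each scission is terminal (ends its host CCS) with probability
#' `p_terminal`.
#'
#' @param field_size image side length, pixels (square field, >= 32).
#' @param pixel_size µm per pixel.
#' @param dt s per pH cycle (one pH 7.4 + one pH 5.5 exposure).
#' @param n_cycles number of pH cycles; the raw stack has `2 * n_cycles`
#'   interleaved frames.
#' @param nucleation_rate CCS per µm² per min.
#' @param inter_scission_interval s; mean waiting time from nucleation to the
#'   first scission and between successive scissions at a persistent CCS.
#' @param p_terminal probability that a scission ends its host CCS.
#' @param psf_sigma Gaussian PSF sigma, pixels.
#' @param background counts per pixel.
#' @param ccs_amp peak amplitude (counts) of a CCS spot in the TfR7 channel.
#' @param scission_amp peak amplitude (counts) of a nascent vesicle spot in
#'   the TfR5 channel at the moment of scission.
#' @param tfr5_decay_tau s; exponential decay constant of the TfR5 spot after
#'   scission (vesicle departure/uncoating).
#' @param read_noise_sd Gaussian read-noise sd, counts; photon noise is
#'   Poisson. Set `noise = FALSE` for a noiseless movie.
#' @param noise logical; render Poisson + Gaussian noise?
#' @param min_separation px; hard-core radius between CCS centres (distinct
#'   diffraction-limited structures).
#' @param margin px; CCS are placed at least this far from the image border
#'   so that measurement apertures fit.
#' @param kinetic_class name of the default reporter kernel, see
#'   [kinetic_presets()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(field_size = 96, pixel_size = 0.13, dt = 2,
                       n_cycles = 400, nucleation_rate = 0.02,
                       inter_scission_interval = 100, p_terminal = 0.5,
                       psf_sigma = 1.5, background = 100, ccs_amp = 60,
                       scission_amp = 60, tfr5_decay_tau = 10,
                       read_noise_sd = 3, noise = TRUE,
                       min_separation = 6, margin = 10,
                       kinetic_class = "wt") {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (field_size < 32) stop("field_size must be >= 32 pixels", call. = FALSE)
  stopifnot(pixel_size > 0, n_cycles >= 1, nucleation_rate >= 0,
            inter_scission_interval > 0,
            p_terminal >= 0, p_terminal <= 1,
            psf_sigma > 0, background >= 0, ccs_amp >= 0, scission_amp >= 0,
            tfr5_decay_tau > 0, read_noise_sd >= 0,
            min_separation >= 0, margin >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Draw hard-core CCS positions; uniform with rejection, capped attempts.
place_ccs <- function(n, field_size, margin, min_sep) {
  xs <- numeric(0); ys <- numeric(0)
  lo <- 1 + margin; hi <- field_size - margin
  if (hi <= lo) stop("field too small for the placement margin", call. = FALSE)
  attempts <- 0L
  while (length(xs) < n && attempts < 200L * n + 200L) {
    attempts <- attempts + 1L
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  list(x = xs, y = ys, n = length(xs))
}

#' Simulate an alternating-pH movie with ground truth
#'
#' Renders the interleaved pH 7.4 / pH 5.5 pHluorin stack and the reporter
#' channel, and returns the full ground truth (CCS records, scission records,
#' the true kernel). The TfR7 channel shows a Gaussian spot at every live
#' CCS; the TfR5 channel shows a spot only from each scission time onwards,
#' decaying exponentially; the reporter channel renders the kernel evaluated
#' at `t - t0` for every scission plus the telegraph flicker at every live
#' CCS. Identical `(config, kernel, seed)` gives bitwise-identical output.
#'
#' @param config a [sim_config()].
#' @param kernel a [kinetic_profile()]; defaults to the preset named by
#'   `config$kinetic_class`.
#' @param seed integer seed.
#' @return A list with elements `movie` (a [ph_movie()] whose `reporter`
#'   field holds the per-cycle reporter series) and `truth` (class
#'   `ground_truth`: data frames `ccs` and `scissions`, plus `kernel`).
#' @export
simulate_movie <- function(config, kernel = NULL, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(kernel)) kernel <- kinetic_presets(config$kinetic_class)
  stopifnot(inherits(kernel, "kinetic_profile"))
  set.seed(seed)
  fs <- config$field_size
  n_cyc <- config$n_cycles
  dt <- config$dt
  t_total_s <- n_cyc * dt
  area_um2 <- (fs * config$pixel_size)^2
  lambda <- config$nucleation_rate * area_um2 * (t_total_s / 60)
  n_ccs <- stats::rpois(1L, lambda)

  pos <- place_ccs(n_ccs, fs, config$margin, config$min_separation)
  n_ccs <- pos$n

  ccs <- data.frame(ccs_id = seq_len(n_ccs) + 0L,
                    x = pos$x, y = pos$y,
                    nucleation_time = stats::runif(n_ccs, 0, t_total_s),
                    end_time = rep(t_total_s, n_ccs))
  sc <- vector("list", n_ccs)
  for (i in seq_len(n_ccs)) {
    t <- ccs$nucleation_time[i]; ord <- 0L; recs <- NULL
    repeat {
      t <- t + stats::rexp(1, 1 / config$inter_scission_interval)
      if (t >= t_total_s) break
      ord <- ord + 1L
      term <- stats::runif(1) < config$p_terminal
      recs <- rbind(recs, data.frame(ccs_id = ccs$ccs_id[i], ordinal = ord,
                                     t0_s = t, x = ccs$x[i], y = ccs$y[i],
                                     terminal = term))
      if (term) { ccs$end_time[i] <- t; break }
    }
    sc[[i]] <- recs
  }
  scissions <- do.call(rbind, sc)
  if (is.null(scissions)) {
    scissions <- data.frame(ccs_id = integer(0), ordinal = integer(0),
                            t0_s = numeric(0), x = numeric(0), y = numeric(0),
                            terminal = logical(0))
  }
  # first cycle (1-based) whose acquisition time (k-1)*dt is >= t0; events
  # falling after the last sampled cycle keep an index > n_cycles (never
  # visible in the rendered movie)
  scissions$t0_cycle <- as.integer(ceiling(scissions$t0_s / dt + 1))
  # scission times are quantised to the sampling grid: the movie cannot
  # represent sub-cycle timing, and event-aligned averages are defined on
  # cycle times
  scissions$t0_s <- (scissions$t0_cycle - 1) * dt
  # a terminal CCS stays visible through the cycle at which its scission is
  # first seen, and is gone from the next cycle on
  if (nrow(scissions)) {
    term <- scissions[scissions$terminal, , drop = FALSE]
    m <- match(term$ccs_id, ccs$ccs_id)
    ccs$end_time[m] <- pmin((term$t0_cycle - 1) * dt, t_total_s)
  }
  ccs$n_events <- vapply(ccs$ccs_id, function(id)
    sum(scissions$ccs_id == id), integer(1))

  # telegraph flicker state per CCS per cycle (symmetric two-state chain)
  p_switch <- 1 - exp(-kernel$flicker_rate * dt)
  flick <- matrix(FALSE, nrow = max(n_ccs, 1L), ncol = n_cyc)
  if (n_ccs > 0) {
    flick[, 1] <- stats::runif(n_ccs) < 0.5
    if (n_cyc > 1) for (k in 2:n_cyc) {
      sw <- stats::runif(n_ccs) < p_switch
      flick[, k] <- xor(flick[, k - 1], sw)
    }
  }

  t_cycle <- (seq_len(n_cyc) - 1) * dt
  frames <- array(config$background, dim = c(fs, fs, 2L * n_cyc))
  reporter <- array(config$background, dim = c(fs, fs, n_cyc))

  # precompute unit-amplitude PSF patches at each source position
  patch_at <- function(x0, y0) {
    hw <- ceiling(5 * config$psf_sigma)
    rs <- max(1L, floor(y0 - hw)):min(fs, ceiling(y0 + hw))
    cs <- max(1L, floor(x0 - hw)):min(fs, ceiling(x0 + hw))
    list(rs = rs, cs = cs, P = gauss2d(cs, rs, x0, y0, config$psf_sigma))
  }
  ccs_patch <- lapply(seq_len(n_ccs), function(i) patch_at(ccs$x[i], ccs$y[i]))
  ev_patch <- lapply(seq_len(nrow(scissions)),
                     function(j) patch_at(scissions$x[j], scissions$y[j]))

  alive <- if (n_ccs) outer(ccs$nucleation_time, t_cycle, "<=") &
                      outer(ccs$end_time, t_cycle, ">=") else
           matrix(FALSE, 0, n_cyc)
  if (nrow(scissions)) {
    trel <- outer(-scissions$t0_s, t_cycle, "+")
    amp5 <- config$scission_amp * exp(-trel / config$tfr5_decay_tau) *
      (trel >= 0)
    ampR <- matrix(eval_kernel(kernel, trel), nrow(scissions))
  }

  for (k in seq_len(n_cyc)) {
    f7 <- frames[, , 2L * k - 1L]
    f5 <- frames[, , 2L * k]
    fr <- reporter[, , k]
    for (i in which(alive[, k])) {
      p <- ccs_patch[[i]]
      f7[p$rs, p$cs] <- f7[p$rs, p$cs] + config$ccs_amp * p$P
      if (flick[i, k]) fr[p$rs, p$cs] <- fr[p$rs, p$cs] + kernel$flicker_amp * p$P
    }
    if (nrow(scissions)) {
      for (j in which(amp5[, k] > 1e-6)) {
        p <- ev_patch[[j]]
        f5[p$rs, p$cs] <- f5[p$rs, p$cs] + amp5[j, k] * p$P
      }
      for (j in which(ampR[, k] > 1e-6)) {
        p <- ev_patch[[j]]
        fr[p$rs, p$cs] <- fr[p$rs, p$cs] + ampR[j, k] * p$P
      }
    }
    frames[, , 2L * k - 1L] <- f7
    frames[, , 2L * k] <- f5
    reporter[, , k] <- fr
  }

  if (config$noise) {
    frames[] <- stats::rpois(length(frames), frames) +
      stats::rnorm(length(frames), sd = config$read_noise_sd)
    reporter[] <- stats::rpois(length(reporter), reporter) +
      stats::rnorm(length(reporter), sd = config$read_noise_sd)
  }

  movie <- ph_movie(frames,
                    frame_ph = rep(c(7.4, 5.5), n_cyc),
                    pixel_size = config$pixel_size, dt = dt,
                    reporter = reporter)
  truth <- structure(list(ccs = ccs, scissions = scissions, kernel = kernel,
                          config = config),
                     class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Simulate CCS event histories from the renewal process alone
#'
#' Draws scission-event histories (no imaging) under the generator's renewal
#' model: waiting times from nucleation to the first scission and between
#' successive scissions are iid exponential with mean `tau`; after each event
#' the CCS terminates with probability `p_terminal`. Useful for studying
#' maturation kinetics (time to the n-th event) free of imaging effects.
#'
#' @param n number of histories.
#' @param tau s; mean inter-event waiting time.
#' @param p_terminal per-event termination probability.
#' @param n_max maximum number of events recorded per history.
#' @param seed integer seed.
#' @return A `ccs_histories` data frame with columns `ccs_id`,
#'   `nucleation_time_s`, `n_events` and list-column `event_times_s`.
#' @export
simulate_ccs_histories <- function(n, tau, p_terminal = 0, n_max = 3,
                                   seed = 1L) {
  stopifnot(n >= 1, tau > 0, p_terminal >= 0, p_terminal <= 1, n_max >= 1)
  set.seed(seed)
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    times <- numeric(0); t <- 0
    repeat {
      t <- t + stats::rexp(1, 1 / tau)
      times <- c(times, t)
      if (length(times) >= n_max || stats::runif(1) < p_terminal) break
    }
    ev[[i]] <- times
  }
  out <- data.frame(ccs_id = seq_len(n), nucleation_time_s = 0,
                    n_events = lengths(ev))
  out$event_times_s <- ev
  class(out) <- c("ccs_histories", "data.frame")
  out
}

#' Configuration for simulated FRAP traces
#'
#' Emulates a spot-bleach FRAP experiment: `n_pre` pre-bleach frames at
#' intensity `I0`, then `n_post` post-bleach frames recovering as
#' `I0 * (floor + (1 - floor) * (mobile - A * exp(-K * t)))` with `t` in
#' seconds from the first post-bleach frame. A reference ROI decays
#' exponentially at `reference_bleach_rate` (acquisition photobleaching,
#' applied multiplicatively to both ROIs). Gaussian noise of sd `noise_sd`
#' is added to both ROIs.
#'
#' `mobile = 1` (the default) gives full nominal recovery to `I0`; lower
#' plateau values emulate an immobile fraction.
#'
#' @param A recovery amplitude, in \[0, 1\].
#' @param K recovery rate, per s.
#' @param I0 pre-bleach intensity, counts.
#' @param bleach_floor irrecoverable floor as a fraction of `I0`.
#' @param mobile plateau of the recovery, fraction of `I0`.
#' @param reference_bleach_rate per s.
#' @param noise_sd counts.
#' @param n_pre,n_post frame counts (pre >= 1, post >= 3).
#' @param frame_rate Hz.
#' @return An object of class `frap_sim_config`.
#' @export
frap_sim_config <- function(A = 0.8, K = 0.2, I0 = 1000, bleach_floor = 0,
                            mobile = 1, reference_bleach_rate = 0.002,
                            noise_sd = 0, n_pre = 10, n_post = 100,
                            frame_rate = 1) {
  stopifnot(A >= 0, A <= 1, K > 0, I0 > 0, bleach_floor >= 0,
            bleach_floor < 1, mobile > 0, mobile <= 1,
            reference_bleach_rate >= 0, noise_sd >= 0,
            n_pre >= 1, n_post >= 3, frame_rate > 0)
  structure(as.list(environment()), class = "frap_sim_config")
}

#' Simulate one FRAP trace
#'
#' @param config a [frap_sim_config()].
#' @param seed integer seed.
#' @return A list with `trace` (class `frap_trace`: data frame with columns
#'   `frame`, `time_s`, `bleach_roi`, `reference_roi`, `phase`), and the true
#'   `A` and `K`.
#' @export
simulate_frap_trace <- function(config, seed = 1L) {
  stopifnot(inherits(config, "frap_sim_config"))
  set.seed(seed)
  n <- config$n_pre + config$n_post
  frame <- seq_len(n)
  # time 0 at the first post-bleach frame
  time_s <- (frame - config$n_pre - 1) / config$frame_rate
  phase <- rep(c("pre", "post"), c(config$n_pre, config$n_post))
  t_abs <- (frame - 1) / config$frame_rate
  acq_bleach <- exp(-config$reference_bleach_rate * t_abs)
  fl <- config$bleach_floor
  recovery <- ifelse(phase == "pre", 1,
                     fl + (1 - fl) *
                       (config$mobile - config$A * exp(-config$K * pmax(time_s, 0))))
  bleach_roi <- config$I0 * recovery * acq_bleach +
    stats::rnorm(n, sd = config$noise_sd)
  reference_roi <- config$I0 * acq_bleach +
    stats::rnorm(n, sd = config$noise_sd)
  trace <- data.frame(frame = frame, time_s = time_s,
                      bleach_roi = bleach_roi,
                      reference_roi = reference_roi, phase = phase)
  class(trace) <- c("frap_trace", "data.frame")
  list(trace = trace, A = config$A, K = config$K)
}
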