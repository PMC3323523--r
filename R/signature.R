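#' Event-aligned reporter traces
#'
#' For every event, the reporter channel is measured at the event position
#' (background-subtracted disc-minus-annulus ROI, see [measure_roi()]) over
#' the cycles `t0 + t_rel / dt` for `t_rel` on a uniform grid spanning
#' `window`. Cycles falling outside the movie are flagged missing (`NA`),
#' never zero-filled. By default values are divided by the ROI aperture gain
#' ([roi_psf_gain()]) so traces are in peak-amplitude units of a
#' diffraction-limited spot, directly comparable to kernel amplitudes.
#'
#' @param reporter_series array `height x width x n_cycles`.
#' @param events data frame with `t0` (cycle), `x`, `y`.
#' @param window `c(t_min, t_max)` seconds, spanning 0; default `(-82, 40)`.
#' @param dt s per cycle.
#' @param radius,annulus ROI geometry.
#' @param psf_sigma when non-`NULL`, traces are scaled to peak-amplitude
#'   units via [roi_psf_gain()].
#' @return Class `aligned_traces`: list with `t_rel` (s), `matrix`
#'   (events x timepoints, `NA` = missing) and `event_ids`.
#' @export
extract_aligned_traces <- function(reporter_series, events,
                                   window = c(-82, 40), dt = 2,
                                   radius = 3, annulus = c(5, 8),
                                   psf_sigma = 1.5) {
  stopifnot(window[1] <= 0, window[2] >= 0, window[1] < window[2])
  t_rel <- seq(ceiling(window[1] / dt), floor(window[2] / dt)) * dt
  offs <- as.integer(round(t_rel / dt))
  n_cyc <- dim(reporter_series)[3L]
  ne <- nrow(events)
  mat <- matrix(NA_real_, nrow = ne, ncol = length(t_rel))
  keep <- logical(ne)
  for (i in seq_len(ne)) {
    tr <- tryCatch(
      measure_roi(reporter_series, events$x[i], events$y[i], radius, annulus),
      error = function(e) NULL)
    if (is.null(tr)) next
    vals <- tr$values
    if (!is.null(psf_sigma)) {
      g <- roi_psf_gain(dim(reporter_series)[1:2], events$x[i], events$y[i],
                        psf_sigma, radius, annulus)
      vals <- vals / g
    }
    cyc <- events$t0[i] + offs
    inb <- cyc >= 1L & cyc <= n_cyc
    if (!any(inb)) next
    mat[i, inb] <- vals[cyc[inb]]
    keep[i] <- TRUE
  }
  if (any(!keep) && ne)
    message(sum(!keep), " event(s) dropped (no in-window samples or ROI at border)")
  ids <- if ("event_id" %in% names(events)) events$event_id else seq_len(ne)
  structure(list(t_rel = t_rel, matrix = mat[keep, , drop = FALSE],
                 event_ids = ids[keep]),
            class = "aligned_traces")
}

#' Ensemble recruitment signature (mean and SEM)
#'
#' Pointwise mean and standard error over non-missing entries of the aligned
#' traces. With a single contributing event the SEM is defined as 0 (flagged
#' via `n`).
#'
#' @param traces an `aligned_traces` object.
#' @return Class `recruitment_signature`: list with `t_rel`, `mean`, `sem`,
#'   `n` (events per timepoint); envelope fields `rand_lo`/`rand_hi` are
#'   `NULL` until [random_envelope()] is attached.
#' @export
ensemble_signature <- function(traces) {
  stopifnot(inherits(traces, "aligned_traces"))
  m <- traces$matrix
  if (!nrow(m)) stop("no events in aligned traces", call. = FALSE)
  n <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sdv / sqrt(n), 0)
  structure(list(t_rel = traces$t_rel, mean = mu, sem = sem, n = n,
                 rand_lo = NULL, rand_hi = NULL),
            class = "recruitment_signature")
}

#' @export
print.recruitment_signature <- function(x, ...) {
  cat(sprintf("recruitment_signature: %d timepoints (%g..%g s), max n = %d\n",
              length(x$t_rel), min(x$t_rel), max(x$t_rel), max(x$n)))
  pk <- which.max(x$mean)
  cat(sprintf("  peak mean %.2f at t_rel = %g s; envelope: %s\n",
              x$mean[pk], x$t_rel[pk],
              if (is.null(x$rand_lo)) "absent" else "present"))
  invisible(x)
}

#' @export
as.data.frame.recruitment_signature <- function(x, ...) {
  data.frame(t_rel_s = x$t_rel, mean = x$mean, sem = x$sem, n = x$n,
             rand_lo = x$rand_lo %||% NA_real_,
             rand_hi = x$rand_hi %||% NA_real_)
}

#' @export
plot.recruitment_signature <- function(x, ...) {
  graphics::plot(x$t_rel, x$mean, type = "l", xlab = "time from scission (s)",
                 ylab = "fluorescence (counts)", ...)
  graphics::arrows(x$t_rel, x$mean - x$sem, x$t_rel, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  if (!is.null(x$rand_lo)) {
    graphics::lines(x$t_rel, x$rand_lo, lty = 3, col = "grey50")
    graphics::lines(x$t_rel, x$rand_hi, lty = 3, col = "grey50")
  }
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Randomised confidence envelope for a recruitment signature
#'
#' Null reference for event-aligned averaging: in each of `B` resamples every
#' event keeps its position but receives an alignment time drawn uniformly
#' from the cycles at which the full analysis window fits in the movie; the
#' ensemble mean is recomputed; the envelope is the pointwise
#' `alpha/2` and `1 - alpha/2` quantiles across resamples. Randomising time
#' but not position preserves each location's background structure.
#'
#' @inheritParams extract_aligned_traces
#' @param B number of resamples (>= 100).
#' @param alpha envelope level (default 0.05 for a 95% envelope).
#' @param seed integer seed.
#' @return List with `rand_lo`, `rand_hi` (length of the window grid).
#' @export
random_envelope <- function(reporter_series, events, window = c(-82, 40),
                            dt = 2, B = 1000, alpha = 0.05, seed = 1L,
                            radius = 3, annulus = c(5, 8), psf_sigma = 1.5) {
  stopifnot(B >= 100)
  t_rel <- seq(ceiling(window[1] / dt), floor(window[2] / dt)) * dt
  offs <- as.integer(round(t_rel / dt))
  n_cyc <- dim(reporter_series)[3L]
  lo_t0 <- 1L - min(offs); hi_t0 <- n_cyc - max(offs)
  if (hi_t0 < lo_t0)
    stop("movie shorter than the analysis window", call. = FALSE)
  ne <- nrow(events)
  full <- matrix(NA_real_, nrow = ne, ncol = n_cyc)
  for (i in seq_len(ne)) {
    tr <- measure_roi(reporter_series, events$x[i], events$y[i], radius,
                      annulus)
    v <- tr$values
    if (!is.null(psf_sigma)) {
      v <- v / roi_psf_gain(dim(reporter_series)[1:2], events$x[i],
                            events$y[i], psf_sigma, radius, annulus)
    }
    full[i, ] <- v
  }
  set.seed(seed)
  means <- matrix(0, nrow = B, ncol = length(offs))
  ii <- rep(seq_len(ne), length(offs))
  for (b in seq_len(B)) {
    t0b <- sample.int(hi_t0 - lo_t0 + 1L, ne, replace = TRUE) + lo_t0 - 1L
    idx <- cbind(ii, rep(t0b, length(offs)) + rep(offs, each = ne))
    means[b, ] <- colMeans(matrix(full[idx], nrow = ne))
  }
  list(rand_lo = apply(means, 2L, stats::quantile, probs = alpha / 2),
       rand_hi = apply(means, 2L, stats::quantile, probs = 1 - alpha / 2))
}

#' Attach an envelope to a signature
#' @param sig a `recruitment_signature`.
#' @param envelope result of [random_envelope()].
#' @export
with_envelope <- function(sig, envelope) {
  sig$rand_lo <- envelope$rand_lo
  sig$rand_hi <- envelope$rand_hi
  sig
}

#' Normalise a signature to its random confidence interval
#'
#' `value' = (mean - centre) / (rand_hi - centre)` with
#' `centre = (rand_lo + rand_hi) / 2`, so 0 marks the centre of the random
#' band and 1 its upper limit. Invariant under affine transforms of the
#' reporter channel.
#'
#' @param sig a `recruitment_signature` with envelope attached.
#' @return The signature with normalised `mean`, `sem`, `rand_lo`, `rand_hi`.
#' @export
normalize_to_random <- function(sig) {
  if (is.null(sig$rand_lo))
    stop("signature has no random envelope", call. = FALSE)
  centre <- (sig$rand_lo + sig$rand_hi) / 2
  span <- sig$rand_hi - centre
  if (any(span <= 0))
    stop("degenerate envelope: rand_hi equals its centre", call. = FALSE)
  sig$mean <- (sig$mean - centre) / span
  sig$sem <- sig$sem / span
  sig$rand_lo <- (sig$rand_lo - centre) / span
  sig$rand_hi <- rep(1, length(span))
  sig
}

#' Per-event fluorescence peak times
#'
#' Each event's trace is boxcar-smoothed (width `smooth` cycles; 1 = off)
#' and the peak time is the argmax within `peak_window`; ties resolve to the
#' earliest time. Events with an all-missing window are skipped.
#'
#' @param traces an `aligned_traces` object.
#' @param peak_window `c(t_a, t_b)` seconds, within the trace window.
#' @param smooth boxcar width, cycles.
#' @return List with `records` (data frame `event_id`, `t_peak`,
#'   `peak_value`), `histogram` (counts per grid time in the window) and
#'   `fraction_in` helper: `fraction_in(t_a, t_b)` gives the share of events
#'   peaking in `[t_a, t_b]`.
#' @export
peak_records <- function(traces, peak_window = c(-20, 20), smooth = 1) {
  stopifnot(inherits(traces, "aligned_traces"))
  t_rel <- traces$t_rel
  if (peak_window[1] < min(t_rel) || peak_window[2] > max(t_rel))
    stop("peak_window outside the trace window", call. = FALSE)
  m <- traces$matrix
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    m <- t(apply(m, 1L, function(v) {
      s <- stats::filter(v, k, sides = 2)
      as.numeric(ifelse(is.na(s), v, s))
    }))
  }
  sel <- which(t_rel >= peak_window[1] & t_rel <= peak_window[2])
  recs <- NULL
  for (i in seq_len(nrow(m))) {
    v <- m[i, sel]
    if (all(is.na(v))) next
    j <- which(v == max(v, na.rm = TRUE))[1L]  # earliest tie
    recs <- rbind(recs, data.frame(event_id = traces$event_ids[i],
                                   t_peak = t_rel[sel[j]],
                                   peak_value = v[j]))
  }
  if (is.null(recs))
    recs <- data.frame(event_id = integer(0), t_peak = numeric(0),
                       peak_value = numeric(0))
  hist <- vapply(t_rel[sel], function(t) sum(recs$t_peak == t), integer(1))
  names(hist) <- t_rel[sel]
  fraction_in <- function(t_a, t_b) {
    if (!nrow(recs)) return(NA_real_)
    mean(recs$t_peak >= t_a & recs$t_peak <= t_b)
  }
  list(records = recs, histogram = hist, fraction_in = fraction_in)
}

#' Recruitment slope over an interval
#'
#' Ordinary least-squares slope of the signature mean against time over
#' `interval` (needs >= 3 grid points).
#'
#' @param sig a `recruitment_signature`.
#' @param interval `c(t_a, t_b)` seconds.
#' @return Slope in counts per second.
#' @export
signature_slope <- function(sig, interval) {
  sel <- which(sig$t_rel >= interval[1] & sig$t_rel <= interval[2] &
               !is.na(sig$mean))
  if (length(sel) < 3)
    stop("fewer than 3 signature points in the interval", call. = FALSE)
  unname(stats::coef(stats::lm(sig$mean[sel] ~ sig$t_rel[sel]))[2L])
}

#' Recruitment amplitude relative to the early pre-scission baseline
#'
#' Peak of the signature mean over `peak_window` minus the average over the
#' early baseline window (default -82 to -42 s pre-scission). Invariant to
#' constant offsets of the reporter channel.
#'
#' @param sig a `recruitment_signature`.
#' @param baseline_window `c(t_a, t_b)` seconds.
#' @param peak_window `c(t_a, t_b)` seconds.
#' @return Amplitude in counts.
#' @export
signature_amplitude <- function(sig, baseline_window = c(-82, -42),
                                peak_window = c(-20, 4)) {
  base <- sig$mean[sig$t_rel >= baseline_window[1] &
                   sig$t_rel <= baseline_window[2]]
  pk <- sig$mean[sig$t_rel >= peak_window[1] & sig$t_rel <= peak_window[2]]
  max(pk, na.rm = TRUE) - mean(base, na.rm = TRUE)
}
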