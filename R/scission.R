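#' Screening thresholds for candidate scission events
#'
#' Candidate TfR5 appearances are screened for signal-to-noise, persistence
#' and fluorescence change, mirroring the standard pulsed-pH analysis chain.
#'
#' @param snr_min minimum detection SNR at the appearance cycle.
#' @param persistence_min minimum track persistence, cycles (>= 1).
#' @param step_min_sigmas required jump of the TfR5 ROI trace at appearance,
#'   in units of the pre-appearance trace sd.
#' @param pre_quiet cycles before appearance that must be free of TfR5
#'   detections near the candidate position.
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(snr_min = 2, persistence_min = 3,
                          step_min_sigmas = 3, pre_quiet = 3) {
  stopifnot(snr_min >= 0, persistence_min >= 1, step_min_sigmas >= 0,
            pre_quiet >= 0)
  structure(list(snr_min = snr_min, persistence_min = persistence_min,
                 step_min_sigmas = step_min_sigmas, pre_quiet = pre_quiet),
            class = "screen_params")
}

#' Find candidate scission events among TfR5 tracks
#'
#' A scission manifests as the abrupt appearance of an acid-resistant (pH
#' 5.5) spot. Two candidate sources are used:
#'
#' * *track starts*: one candidate per TfR5 track whose first detection is
#'   preceded by at least `pre_quiet` cycles containing no TfR5 detection
#'   within `max_disp` pixels of the track start. Tracks starting so early
#'   that the quiet window cannot be verified yield no candidate.
#' * *re-brightenings* (only when `tfr5_series` is supplied): a persistent
#'   CCS can host successive scissions so close in time that the new
#'   acid-resistant spot appears while the previous vesicle's spot is still
#'   decaying, and the tracker continues the old track instead of opening a
#'   new one. Such events are recovered as abrupt fluorescence increases
#'   inside an ongoing track: a detected cycle `c` (past the track's first
#'   `pre_quiet` cycles) whose ROI trace value steps above the mean of the
#'   `pre_quiet` preceding cycles by at least `step_min_sigmas` of their sd.
#'
#' @param tfr5_tracks linked TfR5 detections from [link_tracks()].
#' @param pre_quiet quiet window, cycles.
#' @param max_disp spatial radius for the quiet test, pixels.
#' @param tfr5_series optional TfR5 image series enabling the
#'   re-brightening candidate source.
#' @param step_min_sigmas step threshold for re-brightening candidates.
#' @param radius,annulus ROI geometry for the re-brightening trace.
#' @return Data frame of candidates: `track_id`, `t0` (cycle of first
#'   detection), `x`, `y`, `snr` (at t0), `n_cycles_present` (remaining
#'   track span) and `source` (`"track_start"` or `"rebright"`).
#' @export
find_candidates <- function(tfr5_tracks, pre_quiet = 3, max_disp = 4,
                            tfr5_series = NULL, step_min_sigmas = 3,
                            radius = 3, annulus = c(5, 8)) {
  tab <- track_table(tfr5_tracks)
  empty <- data.frame(track_id = integer(0), t0 = integer(0), x = numeric(0),
                      y = numeric(0), snr = numeric(0),
                      n_cycles_present = integer(0), source = character(0))
  if (!nrow(tab)) return(empty)
  out <- NULL
  for (i in seq_len(nrow(tab))) {
    t0 <- tab$start_cycle[i]
    if (t0 - pre_quiet < 1L) next  # cannot verify the quiet window
    prior <- tfr5_tracks[tfr5_tracks$cycle >= t0 - pre_quiet &
                         tfr5_tracks$cycle < t0, , drop = FALSE]
    if (nrow(prior)) {
      dd <- sqrt((prior$x - tab$x0[i])^2 + (prior$y - tab$y0[i])^2)
      if (any(dd <= max_disp)) next
    }
    first <- tfr5_tracks[tfr5_tracks$track_id == tab$track_id[i] &
                         tfr5_tracks$cycle == t0, , drop = FALSE]
    out <- rbind(out, data.frame(
      track_id = tab$track_id[i], t0 = t0, x = tab$x0[i], y = tab$y0[i],
      snr = if ("snr" %in% names(first)) first$snr[1L] else NA_real_,
      n_cycles_present = tab$end_cycle[i] - t0 + 1L,
      source = "track_start"))
  }
  if (!is.null(tfr5_series)) {
    for (i in seq_len(nrow(tab))) {
      if (tab$end_cycle[i] - tab$start_cycle[i] < pre_quiet + 1L) next
      det <- tfr5_tracks[tfr5_tracks$track_id == tab$track_id[i], ,
                         drop = FALSE]
      tr <- tryCatch(measure_roi(tfr5_series, tab$x_mean[i], tab$y_mean[i],
                                 radius, annulus), error = function(e) NULL)
      if (is.null(tr)) next
      v <- tr$values
      for (c0 in det$cycle[det$cycle >= tab$start_cycle[i] + pre_quiet]) {
        pre <- v[(c0 - pre_quiet):(c0 - 1L)]
        sdev <- stats::sd(pre)
        if (!is.finite(sdev)) next
        if (v[c0] - mean(pre) >= step_min_sigmas * sdev && sdev > 0) {
          d0 <- det[det$cycle == c0, , drop = FALSE]
          out <- rbind(out, data.frame(
            track_id = tab$track_id[i], t0 = c0, x = d0$x[1L], y = d0$y[1L],
            snr = if ("snr" %in% names(d0)) d0$snr[1L] else NA_real_,
            n_cycles_present = tab$end_cycle[i] - c0 + 1L,
            source = "rebright"))
        }
      }
    }
  }
  if (is.null(out)) return(empty)
  # deduplicate: keep the earliest candidate among any within max_disp and
  # one cycle of each other (a track start outranks a coincident re-brighten)
  out <- out[order(out$t0, out$source != "track_start"), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (q in seq_len(nrow(out))) {
    if (!keep[q]) next
    later <- which(keep & seq_len(nrow(out)) > q &
                   abs(out$t0 - out$t0[q]) <= 1 &
                   sqrt((out$x - out$x[q])^2 + (out$y - out$y[q])^2) <= max_disp)
    keep[later] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen candidate events for S/N, persistence and fluorescence change
#'
#' A candidate is accepted when (a) its detection SNR at `t0` is at least
#' `snr_min`, (b) its track persists at least `persistence_min` cycles, and
#' (c) the TfR5 ROI trace at its position steps up at `t0` by at least
#' `step_min_sigmas` standard deviations of the pre-appearance window
#' `[t0 - pre_quiet, t0 - 1]`. Candidates failing a screen are returned with
#' a reason code, never dropped silently.
#'
#' @param candidates data frame from [find_candidates()].
#' @param tfr5_series TfR5 image series (array) for ROI measurement.
#' @param params a [screen_params()].
#' @param radius,annulus ROI geometry, see [measure_roi()].
#' @return Data frame with the candidate columns plus `accepted` (logical),
#'   `reject_reason` (`NA`, `"snr"`, `"persistence"`, `"step"`,
#'   `"trace_short"` or `"border"`), `event_id` for accepted rows, and
#'   `step_sigmas`.
#' @export
screen_candidates <- function(candidates, tfr5_series, params = screen_params(),
                              radius = 3, annulus = c(5, 8)) {
  cand <- candidates
  n <- nrow(cand)
  cand$accepted <- logical(n)
  cand$reject_reason <- rep(NA_character_, n)
  cand$step_sigmas <- rep(NA_real_, n)
  n_cyc <- dim(tfr5_series)[3L]
  for (i in seq_len(n)) {
    if (!is.na(cand$snr[i]) && cand$snr[i] < params$snr_min) {
      cand$reject_reason[i] <- "snr"; next
    }
    if (cand$n_cycles_present[i] < params$persistence_min) {
      cand$reject_reason[i] <- "persistence"; next
    }
    t0 <- cand$t0[i]
    lo <- t0 - params$pre_quiet
    hi <- t0 + params$persistence_min - 1L
    if (lo < 1L || hi > n_cyc) {
      cand$reject_reason[i] <- "trace_short"; next
    }
    tr <- tryCatch(
      measure_roi(tfr5_series, cand$x[i], cand$y[i], radius, annulus),
      error = function(e) NULL)
    if (is.null(tr)) { cand$reject_reason[i] <- "border"; next }
    if (params$pre_quiet > 0L) {
      pre <- tr$values[lo:(t0 - 1L)]
      step <- tr$values[t0] - mean(pre)
      sdev <- stats::sd(pre)
      cand$step_sigmas[i] <- if (isTRUE(sdev > 0)) step / sdev else Inf
      thr <- params$step_min_sigmas * (if (is.na(sdev)) 0 else sdev)
      if (!(step >= thr)) { cand$reject_reason[i] <- "step"; next }
    }
    cand$accepted[i] <- TRUE
  }
  cand$event_id <- rep(NA_integer_, n)
  cand$event_id[cand$accepted] <- seq_len(sum(cand$accepted))
  class(cand) <- c("scission_events", "data.frame")
  cand
}

#' Associate events to host CCS tracks and classify terminal/non-terminal
#'
#' The host is the nearest TfR7 track (by its position at `t0`) within
#' `assoc_radius` pixels whose span covers `t0`. An event is *terminal* when
#' its host track's last detection falls within `closure_window` seconds
#' after `t0` (the CCS disappears with the vesicle), *non-terminal* when the
#' host persists longer. If the movie itself ends within the closure window
#' the call is undefined (`NA`) and the event is excluded from terminal
#' statistics. Ordinals number events by time within each host.
#'
#' @param events accepted rows of [screen_candidates()] output (or any data
#'   frame with `event_id`, `t0`, `x`, `y`).
#' @param tfr7_tracks linked TfR7 detections from [link_tracks()].
#' @param assoc_radius pixels.
#' @param closure_window seconds.
#' @param dt s per cycle.
#' @param n_cycles total cycles in the movie (for the end-of-movie rule).
#' @return The events with added `host_ccs` (TfR7 track id or `NA`),
#'   `terminal` (logical, `NA` when undefined) and `ordinal_n`.
#' @export
associate_and_classify <- function(events, tfr7_tracks, assoc_radius = 3,
                                   closure_window = 10, dt = 2,
                                   n_cycles = NULL) {
  ev <- events[if ("accepted" %in% names(events)) events$accepted else
               rep(TRUE, nrow(events)), , drop = FALSE]
  tab <- track_table(tfr7_tracks)
  ev$host_ccs <- rep(NA_integer_, nrow(ev))
  ev$terminal <- rep(NA, nrow(ev))
  ev$ordinal_n <- rep(NA_integer_, nrow(ev))
  if (is.null(n_cycles)) n_cycles <- max(c(tfr7_tracks$cycle, ev$t0, 0L))
  w_cyc <- closure_window / dt
  for (i in seq_len(nrow(ev))) {
    t0 <- ev$t0[i]
    span <- tab[tab$start_cycle <= t0 & tab$end_cycle >= t0, , drop = FALSE]
    if (!nrow(span)) next
    # position of each spanning track at (or nearest to) t0
    dd <- vapply(seq_len(nrow(span)), function(j) {
      d <- tfr7_tracks[tfr7_tracks$track_id == span$track_id[j], , drop = FALSE]
      k <- which.min(abs(d$cycle - t0))
      sqrt((d$x[k] - ev$x[i])^2 + (d$y[k] - ev$y[i])^2)
    }, numeric(1))
    j <- which.min(dd)
    if (dd[j] > assoc_radius) next
    ev$host_ccs[i] <- span$track_id[j]
    end_cy <- span$end_cycle[j]
    if (end_cy - t0 <= w_cyc) {
      # closes within the window -- terminal, unless the movie ends first
      ev$terminal[i] <- if (end_cy >= n_cycles && n_cycles - t0 <= w_cyc)
        NA else TRUE
    } else {
      ev$terminal[i] <- FALSE
    }
  }
  hosted <- !is.na(ev$host_ccs)
  if (any(hosted)) {
    for (h in unique(ev$host_ccs[hosted])) {
      sel <- which(!is.na(ev$host_ccs) & ev$host_ccs == h)
      ev$ordinal_n[sel[order(ev$t0[sel])]] <- seq_along(sel)
    }
  }
  ev
}

#' Call scission events in a movie
#'
#' Convenience wrapper running the full chain on one [ph_movie()]:
#' de-interlace, detect and track TfR5 and TfR7 spots, find and screen
#' candidates, associate hosts and classify. Events are assigned to the
#' perfusion block containing `t0`.
#'
#' @param movie a [ph_movie()].
#' @param psf_sigma pixels.
#' @param params a [screen_params()].
#' @param max_disp,max_gap tracking parameters, see [link_tracks()].
#' @param assoc_radius,closure_window association/classification parameters.
#' @param block_len frames per perfusion block.
#' @return List with `events` (classified accepted events incl. `block_id`),
#'   `candidates` (all screened candidates), `tfr5_tracks`, `tfr7_tracks`.
#' @export
call_scissions <- function(movie, psf_sigma = 1.5, params = screen_params(),
                           max_disp = 4, max_gap = 2, assoc_radius = 3,
                           closure_window = 10, block_len = 400,
                           k_sigma = 4) {
  ser <- deinterlace(movie)
  det5 <- detect_series(ser$tfr5, psf_sigma, params$snr_min, k_sigma)
  det7 <- detect_series(ser$tfr7, psf_sigma, params$snr_min, k_sigma)
  tr5 <- link_tracks(det5, max_disp, max_gap)
  tr7 <- link_tracks(det7, max_disp, max_gap)
  cand <- find_candidates(tr5, params$pre_quiet, max_disp,
                          tfr5_series = ser$tfr5,
                          step_min_sigmas = params$step_min_sigmas)
  scr <- screen_candidates(cand, ser$tfr5, params)
  ev <- associate_and_classify(scr, tr7, assoc_radius, closure_window,
                               dt = movie$dt, n_cycles = n_cycles(movie))
  if (nrow(ev)) {
    blocks <- segment_blocks(movie, block_len)
    ev$block_id <- block_of(blocks, 2L * ev$t0 - 1L)
  } else ev$block_id <- integer(0)
  list(events = ev, candidates = scr, tfr5_tracks = tr5, tfr7_tracks = tr7)
}

#' Scission incidence rate
#'
#' Events per µm² per minute, computed per perfusion block when the events
#' carry a `block_id`.
#'
#' @param events data frame of accepted events (may be empty).
#' @param cell_area µm² (> 0).
#' @param duration min per block (> 0); scalar or one value per block.
#' @return Data frame `block_id`, `n_events`, `rate`.
#' @export
incidence_rate <- function(events, cell_area, duration) {
  if (any(cell_area <= 0) || any(duration <= 0))
    stop("cell_area and duration must be > 0", call. = FALSE)
  if (!nrow(events))
    return(data.frame(block_id = 1L, n_events = 0L,
                      rate = 0 / (cell_area[1L] * duration[1L])))
  blocks <- if ("block_id" %in% names(events)) events$block_id
            else rep(1L, nrow(events))
  ub <- sort(unique(blocks))
  dur <- rep_len(duration, length(ub))
  data.frame(block_id = ub,
             n_events = vapply(ub, function(b) sum(blocks == b), integer(1)),
             rate = vapply(seq_along(ub), function(k)
               sum(blocks == ub[k]) / (cell_area * dur[k]), numeric(1)))
}

#' Match called events to ground-truth scissions
#'
#' Greedy one-to-one matching in ascending spatial distance; a call matches a
#' truth record when within `max_dist` pixels and `max_dt` cycles. Used for
#' recall/precision studies on synthetic movies.
#'
#' @param events called events (`t0`, `x`, `y`).
#' @param truth ground-truth scission records (`t0_cycle`, `x`, `y`).
#' @param max_dist pixels.
#' @param max_dt cycles.
#' @return List with `n_matched`, `recall`, `precision` and the match index
#'   vectors.
#' @export
match_events <- function(events, truth, max_dist = 3, max_dt = 1) {
  ne <- nrow(events); nt <- nrow(truth)
  if (!ne || !nt)
    return(list(n_matched = 0L, recall = ifelse(nt > 0, 0, NA_real_),
                precision = ifelse(ne > 0, 0, NA_real_),
                event_match = rep(NA_integer_, ne),
                truth_match = rep(NA_integer_, nt)))
  dx <- outer(events$x, truth$x, "-")
  dy <- outer(events$y, truth$y, "-")
  dtc <- abs(outer(events$t0, truth$t0_cycle, "-"))
  dist <- sqrt(dx^2 + dy^2)
  ok <- which(dist <= max_dist & dtc <= max_dt, arr.ind = TRUE)
  em <- rep(NA_integer_, ne); tm <- rep(NA_integer_, nt)
  if (nrow(ok)) {
    ok <- ok[order(dist[ok]), , drop = FALSE]
    for (q in seq_len(nrow(ok))) {
      a <- ok[q, 1L]; b <- ok[q, 2L]
      if (is.na(em[a]) && is.na(tm[b])) { em[a] <- b; tm[b] <- a }
    }
  }
  n <- sum(!is.na(em))
  list(n_matched = n, recall = n / nt, precision = n / ne,
       event_match = em, truth_match = tm)
}
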