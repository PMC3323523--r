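#' Build CCS maturation histories
#'
#' Isolates TfR7 track histories that (1) formed de novo during acquisition
#' -- the track starts at least `start_margin` seconds after the movie start
#' -- and (2) host at least one bona fide scission event. Event times are on
#' the movie clock (cycle acquisition times).
#'
#' @param tfr7_tracks linked TfR7 detections from [link_tracks()].
#' @param events classified events from [associate_and_classify()] (need
#'   `host_ccs` and `t0`).
#' @param start_margin s; minimum track start time to count as de novo.
#' @param dt s per cycle.
#' @return A `ccs_histories` data frame: `ccs_id` (TfR7 track id),
#'   `nucleation_time_s`, `end_time_s`, `n_events`, list-column
#'   `event_times_s`.
#' @export
build_histories <- function(tfr7_tracks, events, start_margin = 10, dt = 2) {
  tab <- track_table(tfr7_tracks)
  hosted <- events[!is.na(events$host_ccs), , drop = FALSE]
  out <- NULL
  ev_list <- list()
  for (i in seq_len(nrow(tab))) {
    nuc_s <- (tab$start_cycle[i] - 1L) * dt
    if (nuc_s < start_margin) next  # not demonstrably de novo
    ev <- hosted[hosted$host_ccs == tab$track_id[i], , drop = FALSE]
    if (!nrow(ev)) next
    times <- sort((ev$t0 - 1L) * dt)
    out <- rbind(out, data.frame(ccs_id = tab$track_id[i],
                                 nucleation_time_s = nuc_s,
                                 end_time_s = (tab$end_cycle[i] - 1L) * dt,
                                 n_events = nrow(ev)))
    ev_list[[length(ev_list) + 1L]] <- times
  }
  if (is.null(out)) {
    out <- data.frame(ccs_id = integer(0), nucleation_time_s = numeric(0),
                      end_time_s = numeric(0), n_events = integer(0))
    out$event_times_s <- list()
  } else {
    out$event_times_s <- ev_list
  }
  class(out) <- c("ccs_histories", "data.frame")
  out
}

#' Time from nucleation to the n-th scission event
#'
#' For each `n` up to `n_max`, the mean and sd of
#' `event_times[n] - nucleation_time` over all histories with at least `n`
#' events. Rows with no contributing history are omitted.
#'
#' @param histories a `ccs_histories` data frame ([build_histories()] or
#'   [simulate_ccs_histories()]).
#' @param n_max largest event ordinal (default 3).
#' @return Data frame `n`, `mean_time_s`, `sd_s`, `count`.
#' @export
time_to_nth <- function(histories, n_max = 3) {
  if (!nrow(histories)) stop("no histories", call. = FALSE)
  rows <- NULL
  for (n in seq_len(n_max)) {
    has <- histories$n_events >= n
    if (!any(has)) next
    tt <- vapply(which(has), function(i)
      histories$event_times_s[[i]][n] - histories$nucleation_time_s[i],
      numeric(1))
    rows <- rbind(rows, data.frame(n = n, mean_time_s = mean(tt),
                                   sd_s = if (length(tt) > 1) stats::sd(tt) else 0,
                                   count = length(tt)))
  }
  rows
}

#' Terminal / non-terminal event proportions
#'
#' Fractions over events with a defined terminal flag, with binomial
#' standard errors; computed per perfusion block when `block_id` is present.
#'
#' @param events classified events.
#' @return Data frame `block_id`, `n`, `fraction_terminal`,
#'   `fraction_nonterminal`, `se` (binomial).
#' @export
class_proportions <- function(events) {
  ev <- events[!is.na(events$terminal), , drop = FALSE]
  if (!nrow(ev)) stop("no events with a defined terminal flag", call. = FALSE)
  blocks <- if ("block_id" %in% names(ev)) ev$block_id else rep(1L, nrow(ev))
  ub <- sort(unique(blocks))
  do.call(rbind, lapply(ub, function(b) {
    t <- ev$terminal[blocks == b]
    p <- mean(t)
    data.frame(block_id = b, n = length(t), fraction_terminal = p,
               fraction_nonterminal = 1 - p,
               se = sqrt(p * (1 - p) / length(t)))
  }))
}
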