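#' Reporter recruitment kinetics at a scission event
#'
#' A `kinetic_profile` describes how a fluorescently tagged reporter (dynamin,
#' endophilin, actin, ...) is recruited to a clathrin-coated structure (CCS)
#' relative to the moment of membrane scission (t = 0). It has three parts:
#'
#' * a stochastic low-amplitude *flicker* (two-state telegraph process at the
#'   host CCS, on/off switching at `flicker_rate`, amplitude `flicker_amp`),
#' * a deterministic pre-scission *burst*: exponential rise with time constant
#'   `burst_rise_tau` to a peak of `burst_amp` at `burst_peak_offset` seconds
#'   (<= 0, i.e. before scission), then exponential decay with
#'   `burst_decay_tau`,
#' * an optional *early enrichment* plateau of `early_enrichment` counts over
#'   the `early_extent` seconds preceding scission, mimicking mutants that are
#'   stably pre-recruited long before scission.
#'
#' @param flicker_amp counts; amplitude of the telegraph flicker.
#' @param flicker_rate per s; switching rate of the telegraph process.
#' @param burst_amp counts; peak amplitude of the pre-scission burst.
#' @param burst_peak_offset s (<= 0); burst peak time relative to scission.
#' @param burst_rise_tau,burst_decay_tau s; rise/decay time constants.
#' @param early_enrichment counts; pre-scission plateau amplitude.
#' @param early_extent s; duration of the pre-scission plateau.
#' @return An object of class `kinetic_profile`.
#' @seealso [kinetic_presets()], [eval_kernel()]
#' @export
kinetic_profile <- function(flicker_amp = 30, flicker_rate = 0.2,
                            burst_amp = 100, burst_peak_offset = -2,
                            burst_rise_tau = 8, burst_decay_tau = 5,
                            early_enrichment = 0, early_extent = 90) {
  stopifnot(flicker_amp >= 0, flicker_rate >= 0, burst_amp >= 0,
            burst_peak_offset <= 0, burst_rise_tau > 0, burst_decay_tau > 0,
            early_enrichment >= 0, early_extent > 0)
  structure(list(flicker_amp = flicker_amp, flicker_rate = flicker_rate,
                 burst_amp = burst_amp, burst_peak_offset = burst_peak_offset,
                 burst_rise_tau = burst_rise_tau,
                 burst_decay_tau = burst_decay_tau,
                 early_enrichment = early_enrichment,
                 early_extent = early_extent),
            class = "kinetic_profile")
}

#' Named kinetic classes
#'
#' Three stylised recruitment phenotypes used throughout the synthetic
#' studies: `"wt"` (sharp burst peaking 2 s before scission), `"slow_burst"`
#' (slower, lower-amplitude build-up, as for catalytically impaired GTPase
#' mutants) and `"early_enriched"` (stable pre-recruitment long before
#' scission on top of a reduced burst).
#'
#' @param name one of `"wt"`, `"slow_burst"`, `"early_enriched"`.
#' @return A [kinetic_profile()].
#' @export
kinetic_presets <- function(name = c("wt", "slow_burst", "early_enriched")) {
  name <- match.arg(name)
  switch(name,
    wt = kinetic_profile(),
    slow_burst = kinetic_profile(burst_amp = 60, burst_rise_tau = 20,
                                 burst_decay_tau = 10),
    early_enriched = kinetic_profile(burst_amp = 50, burst_rise_tau = 12,
                                     early_enrichment = 40))
}

#' Evaluate the deterministic part of a recruitment kernel
#'
#' Returns the burst plus early-enrichment signal (counts) at times `t_rel`
#' seconds relative to scission. The stochastic flicker is not included: it is
#' only realised when a movie is rendered.
#'
#' @param kernel a [kinetic_profile()].
#' @param t_rel numeric vector of times (s) relative to scission.
#' @return numeric vector of counts, same length as `t_rel`.
#' @export
eval_kernel <- function(kernel, t_rel) {
  stopifnot(inherits(kernel, "kinetic_profile"))
  p <- kernel$burst_peak_offset
  burst <- ifelse(t_rel <= p,
                  kernel$burst_amp * exp((t_rel - p) / kernel$burst_rise_tau),
                  kernel$burst_amp * exp(-(t_rel - p) / kernel$burst_decay_tau))
  early <- kernel$early_enrichment *
    (t_rel < 0 & t_rel >= -kernel$early_extent)
  burst + early
}
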