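#' Bleach-correct and normalise a FRAP trace
#'
#' Divides the bleach-ROI series by the reference ROI (itself normalised to
#' its pre-bleach mean), removing acquisition photobleaching, then rescales
#' so that the mean pre-bleach value is 1. This defines the pre-bleach
#' intensity `I0 = 1` for all downstream quantities.
#'
#' @param trace a `frap_trace` data frame (columns `time_s`, `bleach_roi`,
#'   `reference_roi`, `phase`).
#' @return Class `frap_corrected`: data frame `time_s`, `corrected`,
#'   `phase`.
#' @export
bleach_correct <- function(trace) {
  stopifnot(all(c("time_s", "bleach_roi", "reference_roi", "phase") %in%
                names(trace)))
  zero <- which(trace$reference_roi == 0)
  if (length(zero))
    stop("reference ROI is zero at frame ", zero[1L], call. = FALSE)
  pre <- trace$phase == "pre"
  if (!any(pre)) stop("trace has no pre-bleach frames", call. = FALSE)
  ref_norm <- trace$reference_roi / mean(trace$reference_roi[pre])
  corr <- trace$bleach_roi / ref_norm
  corr <- corr / mean(corr[pre])
  out <- data.frame(time_s = trace$time_s, corrected = corr,
                    phase = trace$phase)
  class(out) <- c("frap_corrected", "data.frame")
  out
}

#' Fit the inverse-exponential FRAP recovery
#'
#' Nonlinear least squares of `F(t) = 1 - A * exp(-K * t)` to the
#' post-bleach portion of a corrected, normalised trace. Initial values:
#' `A = 1 - F(0)` and `K = 1 / t_half-recovery` (fallback 0.1/s); up to
#' three restarts from perturbed starts before giving up. The half-time of
#' recovery is `ln 2 / K`. The mobile fraction reported with the fit is
#' measured from the data tail (see [mobile_fraction()]), not from the
#' model.
#'
#' An optional three-parameter variant (`model = "floor"`) fits
#' `F(t) = C + A' * (1 - exp(-K * t))` for traces whose normalisation left a
#' non-unit plateau.
#'
#' @param corrected a `frap_corrected` data frame, or a numeric vector of
#'   post-bleach values (then supply `t`).
#' @param t post-bleach times (s), needed only for the vector interface.
#' @param model `"standard"` (two-parameter) or `"floor"`.
#' @return Class `frap_fit`: list with `A`, `K`, `half_time`,
#'   `mobile_fraction` (%), `rss`, `fitted`, `t`, `data`, `model`.
#' @export
fit_recovery <- function(corrected, t = NULL, model = c("standard", "floor")) {
  model <- match.arg(model)
  if (inherits(corrected, "frap_corrected") || is.data.frame(corrected)) {
    post <- corrected$phase == "post"
    y <- corrected$corrected[post]
    t <- corrected$time_s[post]
  } else {
    y <- as.numeric(corrected)
    if (is.null(t)) stop("supply post-bleach times t", call. = FALSE)
  }
  if (length(y) < 3L) stop("need >= 3 post-bleach points", call. = FALSE)
  a0 <- max(1 - y[1L], 0.05)
  half_level <- y[1L] + (1 - y[1L]) / 2
  ih <- which(y >= half_level)[1L]
  k0 <- if (!is.na(ih) && t[ih] > 0) 1 / t[ih] else 0.1
  df <- data.frame(t = t, y = y)
  fit <- NULL
  for (try_k in c(1, 0.3, 3)) {
    fit <- tryCatch({
      if (model == "standard")
        minpack.lm::nlsLM(y ~ 1 - A * exp(-K * t), data = df,
                          start = list(A = a0, K = k0 * try_k),
                          lower = c(A = 0, K = 1e-8),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ C + A * (1 - exp(-K * t)), data = df,
                          start = list(C = y[1L], A = a0, K = k0 * try_k),
                          lower = c(C = -Inf, A = 0, K = 1e-8),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("FRAP recovery fit did not converge (flat or degenerate trace?)",
         call. = FALSE)
  cf <- stats::coef(fit)
  K <- unname(cf["K"])
  if (K <= 1e-6 || (model == "standard" && unname(cf["A"]) <= 1e-8))
    stop("FRAP recovery fit degenerate: K or A indistinguishable from 0",
         call. = FALSE)
  mf <- 100 * mean(y[seq(max(1L, length(y) - 9L), length(y))])
  out <- list(A = unname(cf["A"]), K = K,
              C = if (model == "floor") unname(cf["C"]) else NULL,
              half_time = log(2) / K,
              mobile_fraction = mf,
              mobile_clipped = mf < 0 || mf > 100,
              rss = sum(stats::resid(fit)^2),
              fitted = stats::fitted(fit), t = t, data = y, model = model)
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP recovery fit (%s model): F(t) = 1 - A exp(-K t)\n",
              x$model))
  cat(sprintf("  A = %.4f, K = %.4f /s, half-time = %.2f s\n",
              x$A, x$K, x$half_time))
  cat(sprintf("  mobile fraction = %.1f%% (tail mean)%s, RSS = %.4g\n",
              x$mobile_fraction,
              if (x$mobile_clipped) " [outside 0-100, flagged]" else "",
              x$rss))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(A = object$A, K = object$K, half_time = object$half_time,
    mobile_fraction = object$mobile_fraction)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$t, x$data, xlab = "time post-bleach (s)",
                 ylab = "normalised fluorescence", ...)
  graphics::lines(x$t, x$fitted, col = "red3", lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Mobile fraction from the recovery tail
#'
#' `100 * I_t / I0` with `I0 = 1` after normalisation and `I_t` the mean of
#' the last `tail_frames` post-bleach corrected values.
#'
#' @param corrected a `frap_corrected` data frame or numeric post-bleach
#'   vector.
#' @param tail_frames frames averaged at the end of the recovery.
#' @return Mobile fraction, percent.
#' @export
mobile_fraction <- function(corrected, tail_frames = 10) {
  y <- if (is.data.frame(corrected))
    corrected$corrected[corrected$phase == "post"] else as.numeric(corrected)
  if (length(y) < tail_frames)
    stop("need >= tail_frames post-bleach points", call. = FALSE)
  100 * mean(y[seq(length(y) - tail_frames + 1L, length(y))])
}

#' Full FRAP analysis of one trace
#'
#' [bleach_correct()] then [fit_recovery()]; returns the `frap_fit`.
#'
#' @param trace a `frap_trace`.
#' @inheritParams fit_recovery
#' @export
fit_frap <- function(trace, model = "standard") {
  fit_recovery(bleach_correct(trace), model = model)
}
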