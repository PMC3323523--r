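# Separable convolution with edge replication. k is an odd-length kernel;
# applied along rows (dim = 1) or columns (dim = 2).
conv1 <- function(img, k, dim) {
  h <- (length(k) - 1L) %/% 2L
  n <- if (dim == 1L) nrow(img) else ncol(img)
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- img * 0
  for (j in seq_along(k)) {
    off <- j - h - 1L
    if (dim == 1L) out <- out + k[j] * img[idx(seq_len(n) + off), , drop = FALSE]
    else out <- out + k[j] * img[, idx(seq_len(n) + off), drop = FALSE]
  }
  out
}

# Negated Laplacian-of-Gaussian response (positive at bright blobs),
# scale-normalised by sigma^2. LoG = Gxx*g + g*Gyy, each term separable.
log_response <- function(img, sigma) {
  h <- ceiling(4 * sigma)
  x <- (-h):h
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  gxx <- (x^2 / sigma^4 - 1 / sigma^2) * g
  r <- conv1(conv1(img, gxx, 1L), g, 2L) + conv1(conv1(img, g, 1L), gxx, 2L)
  -sigma^2 * r
}

#' Detect diffraction-limited spots in one frame
#'
#' Laplacian-of-Gaussian detection at scale `psf_sigma`: 8-neighbourhood
#' local maxima of the (negated, scale-normalised) LoG response are refined
#' to subpixel position by an intensity-weighted centroid in a
#' `(2 * ceiling(3 * sigma) + 1)^2` window (weights are the local-background-
#' subtracted pixel values), and screened by SNR, defined as
#' `(peak - annulus mean) / annulus sd` over an annulus of radii
#' `(3 sigma, 3 sigma + 2)` pixels.
#'
#' @param image numeric matrix (counts).
#' @param psf_sigma expected spot sigma, pixels.
#' @param snr_min minimum SNR to keep a detection.
#' @param k_sigma absolute response threshold in units of the robust
#'   (MAD-based) noise sd of the LoG response map: maxima below
#'   `k_sigma * sd_noise` are discarded before SNR screening. A matched
#'   Gaussian spot of peak amplitude `a` has LoG response `a / 2`, so the
#'   default 4 keeps spots down to eight response noise sds of amplitude
#'   (half the nominal working amplitude at SNR ~ 5) while the expected
#'   number of false maxima per frame stays well below one.
#' @return A data frame with columns `x`, `y` (subpixel, 1-based),
#'   `intensity` (background-subtracted peak amplitude) and `snr`. A constant
#'   image yields zero rows.
#' @export
detect_spots <- function(image, psf_sigma = 1.5, snr_min = 2, k_sigma = 4) {
  stopifnot(is.matrix(image), psf_sigma > 0)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), snr = numeric(0))
  resp <- log_response(image, psf_sigma)
  nr <- nrow(resp); nc <- ncol(resp)
  hw <- ceiling(3 * psf_sigma)
  if (nr < 2 * hw + 3 || nc < 2 * hw + 3) return(empty)
  resp_min <- k_sigma * stats::mad(resp)
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > 0 & core >= resp_min
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core > resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  w <- which(is_max, arr.ind = TRUE)
  if (!nrow(w)) return(empty)
  rows <- unname(w[, 1L]) + 1L; cols <- unname(w[, 2L]) + 1L
  # keep maxima whose centroid window fits inside the frame
  keep <- rows > hw & rows <= nr - hw & cols > hw & cols <= nc - hw
  rows <- rows[keep]; cols <- cols[keep]
  if (!length(rows)) return(empty)

  ann <- roi_offsets(psf_sigma)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r0 <- rows[i]; c0 <- cols[i]
    ar <- r0 + ann$ann_r; ac <- c0 + ann$ann_c
    ok <- ar >= 1 & ar <= nr & ac >= 1 & ac <= nc
    av <- image[cbind(ar[ok], ac[ok])]
    mu <- mean(av); sdv <- stats::sd(av)
    peak <- image[r0, c0]
    snr <- if (is.na(sdv) || sdv == 0) Inf else (peak - mu) / sdv
    if (snr < snr_min) next
    patch <- image[(r0 - hw):(r0 + hw), (c0 - hw):(c0 + hw)]
    wts <- pmax(patch - mu, 0)
    s <- sum(wts)
    if (s <= 0) next
    dx <- sum(colSums(wts) * ((-hw):hw)) / s
    dy <- sum(rowSums(wts) * ((-hw):hw)) / s
    out[[i]] <- c(x = c0 + dx, y = r0 + dy, intensity = peak - mu, snr = snr)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  as.data.frame(do.call(rbind, out))
}

# Precompute annulus offsets (radii 3*sigma .. 3*sigma + 2) once per sigma.
roi_offsets <- local({
  cache <- list()
  function(sigma) {
    key <- sprintf("%.4f", sigma)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r_in <- 3 * sigma; r_out <- 3 * sigma + 2
    h <- ceiling(r_out)
    g <- expand.grid(r = (-h):h, c = (-h):h)
    d <- sqrt(g$r^2 + g$c^2)
    sel <- d > r_in & d <= r_out
    val <- list(ann_r = g$r[sel], ann_c = g$c[sel])
    cache[[key]] <<- val
    val
  }
})

#' Detect spots in every cycle of a series
#'
#' @param series array `height x width x n_cycles`.
#' @inheritParams detect_spots
#' @return Data frame of detections with a `cycle` column.
#' @export
detect_series <- function(series, psf_sigma = 1.5, snr_min = 2, k_sigma = 4) {
  stopifnot(is.array(series), length(dim(series)) == 3L)
  res <- lapply(seq_len(dim(series)[3L]), function(k) {
    d <- detect_spots(series[, , k], psf_sigma, snr_min, k_sigma)
    if (nrow(d)) d$cycle <- k
    d
  })
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (!length(res))
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                      snr = numeric(0), cycle = integer(0)))
  do.call(rbind, res)
}

#' Link per-cycle detections into tracks
#'
#' Greedy nearest-neighbour assignment per cycle transition: candidate
#' (track, detection) pairs are processed in ascending Euclidean distance,
#' assignments above `max_disp` are forbidden, and an unmatched track
#' persists through at most `max_gap` missing cycles before it closes. The
#' ascending-distance processing order makes linking deterministic.
#'
#' @param detections data frame from [detect_series()] (columns `cycle`, `x`,
#'   `y`, and optionally `intensity`, `snr`).
#' @param max_disp maximum displacement per cycle transition, pixels.
#' @param max_gap maximum number of consecutive missing cycles.
#' @return The detections data frame with an added integer `track_id`,
#'   ordered by track and cycle.
#' @export
link_tracks <- function(detections, max_disp = 4, max_gap = 2) {
  det <- detections[order(detections$cycle), , drop = FALSE]
  n <- nrow(det)
  det$track_id <- NA_integer_
  if (!n) return(det)
  next_id <- 1L
  # active tracks: id, last x, y, last cycle
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    last = integer(0))
  for (cyc in sort(unique(det$cycle))) {
    act <- act[cyc - act$last <= max_gap + 1L, , drop = FALSE]
    idx <- which(det$cycle == cyc)
    if (nrow(act) && length(idx)) {
      dx <- outer(act$x, det$x[idx], "-")
      dy <- outer(act$y, det$y[idx], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dist[cand]), , drop = FALSE]
        used_t <- logical(nrow(act)); used_d <- logical(length(idx))
        for (q in seq_len(nrow(cand))) {
          a <- cand[q, 1L]; b <- cand[q, 2L]
          if (used_t[a] || used_d[b]) next
          used_t[a] <- TRUE; used_d[b] <- TRUE
          det$track_id[idx[b]] <- act$id[a]
          act$x[a] <- det$x[idx[b]]; act$y[a] <- det$y[idx[b]]
          act$last[a] <- cyc
        }
      }
    }
    new <- idx[is.na(det$track_id[idx])]
    if (length(new)) {
      ids <- next_id + seq_along(new) - 1L
      det$track_id[new] <- ids
      next_id <- next_id + length(new)
      act <- rbind(act, data.frame(id = ids, x = det$x[new], y = det$y[new],
                                   last = cyc))
    }
  }
  det[order(det$track_id, det$cycle), , drop = FALSE]
}

#' Per-track summary
#'
#' @param tracks data frame from [link_tracks()].
#' @return One row per track: `track_id`, `start_cycle`, `end_cycle`,
#'   `n_detections`, start position (`x0`, `y0`) and mean position.
#' @export
track_table <- function(tracks) {
  if (!nrow(tracks))
    return(data.frame(track_id = integer(0), start_cycle = integer(0),
                      end_cycle = integer(0), n_detections = integer(0),
                      x0 = numeric(0), y0 = numeric(0),
                      x_mean = numeric(0), y_mean = numeric(0)))
  sp <- split(tracks, tracks$track_id)
  do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$cycle), ]
    data.frame(track_id = d$track_id[1L], start_cycle = min(d$cycle),
               end_cycle = max(d$cycle), n_detections = nrow(d),
               x0 = d$x[1L], y0 = d$y[1L],
               x_mean = mean(d$x), y_mean = mean(d$y))
  }))
}

#' Measure a background-subtracted ROI fluorescence trace
#'
#' Per cycle, the trace value is `mean(disc) - mean(annulus)`: the mean over
#' pixels within `radius` of `(x, y)` minus the mean over the annulus
#' `annulus[1] < r <= annulus[2]`. Values are never clipped at zero.
#'
#' @param series array `height x width x n_cycles`.
#' @param x,y ROI centre, pixels (1-based).
#' @param radius disc radius, pixels (> 0).
#' @param annulus background annulus radii `c(r_in, r_out)`.
#' @return An object of class `roi_trace`: list with `x`, `y`, `radius`,
#'   `annulus`, `values` (one per cycle) and `background` (annulus means).
#' @export
measure_roi <- function(series, x, y, radius = 3, annulus = c(5, 8)) {
  stopifnot(is.array(series), length(dim(series)) == 3L)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (annulus[1L] < radius || annulus[2L] <= annulus[1L])
    stop("annulus radii must satisfy radius <= r_in < r_out", call. = FALSE)
  d <- dim(series)
  idx <- roi_indices(d[1:2], x, y, radius, annulus)
  mat <- matrix(series, d[1L] * d[2L], d[3L])
  disc_mean <- colMeans(mat[idx$disc, , drop = FALSE])
  ann_mean <- colMeans(mat[idx$annulus, , drop = FALSE])
  structure(list(x = x, y = y, radius = radius, annulus = annulus,
                 values = disc_mean - ann_mean, background = ann_mean),
            class = "roi_trace")
}

#' Aperture gain of a Gaussian spot under ROI measurement
#'
#' The factor by which [measure_roi()] attenuates the peak amplitude of a
#' Gaussian spot of width `psf_sigma` centred on the ROI:
#' `mean(G over disc) - mean(G over annulus)`, computed exactly on the pixel
#' grid for the given subpixel centre. Dividing ROI values by this gain
#' converts disc-minus-annulus means back to peak-amplitude units.
#'
#' @inheritParams measure_roi
#' @param psf_sigma Gaussian sigma, pixels.
#' @param dim_hw image dimensions `c(height, width)`.
#' @return Scalar gain in (0, 1).
#' @export
roi_psf_gain <- function(dim_hw, x, y, psf_sigma, radius = 3,
                         annulus = c(5, 8)) {
  idx <- roi_indices(dim_hw, x, y, radius, annulus)
  g <- function(rc) mean(exp(-((rc$c - x)^2 + (rc$r - y)^2) / (2 * psf_sigma^2)))
  g(idx$disc_rc) - g(idx$ann_rc)
}
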