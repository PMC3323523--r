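#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed from a root seed and a stage name so that
# independent pipeline stages draw from independent, named streams.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) + 1000003 * h) %% .Machine$integer.max)
}

# Evaluate a centred 2-D Gaussian (peak amplitude 1) at pixel centres.
gauss2d <- function(xs, ys, x0, y0, sigma) {
  exp(-(outer(ys - y0, xs - x0, function(dy, dx) dy^2 + dx^2)) / (2 * sigma^2))
}

# Add an amplitude-`amp` Gaussian spot to `img` in place-ish (returns img).
# Only a local patch of half-width `hw` pixels is touched.
add_spot <- function(img, x0, y0, amp, sigma, hw = NULL) {
  if (amp == 0) return(img)
  if (is.null(hw)) hw <- ceiling(5 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  rs <- max(1L, floor(y0 - hw)):min(nr, ceiling(y0 + hw))
  cs <- max(1L, floor(x0 - hw)):min(nc, ceiling(x0 + hw))
  if (!length(rs) || !length(cs)) return(img)
  img[rs, cs] <- img[rs, cs] + amp * gauss2d(cs, rs, x0, y0, sigma)
  img
}

# Linear indices of pixels whose centres lie within `radius` of (x, y),
# and of the annulus r_in < r <= r_out. Errors if geometry leaves the image.
roi_indices <- function(dim_hw, x, y, radius, annulus) {
  h <- dim_hw[1L]; w <- dim_hw[2L]
  r_out <- annulus[2L]
  if (x - r_out < 0.5 || x + r_out > w + 0.5 ||
      y - r_out < 0.5 || y + r_out > h + 0.5) {
    stop(sprintf("ROI at (%.1f, %.1f) with outer radius %.1f touches the image border",
                 x, y, r_out), call. = FALSE)
  }
  cs <- floor(x - r_out):ceiling(x + r_out)
  rs <- floor(y - r_out):ceiling(y + r_out)
  cs <- cs[cs >= 1 & cs <= w]; rs <- rs[rs >= 1 & rs <= h]
  grid <- expand.grid(r = rs, c = cs)
  d <- sqrt((grid$c - x)^2 + (grid$r - y)^2)
  disc <- d <= radius
  ann <- d > annulus[1L] & d <= annulus[2L]
  list(disc = grid$r[disc] + (grid$c[disc] - 1L) * h,
       annulus = grid$r[ann] + (grid$c[ann] - 1L) * h,
       disc_rc = grid[disc, , drop = FALSE],
       ann_rc = grid[ann, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
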