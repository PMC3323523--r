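#' Alternating-pH movie container
#'
#' A `ph_movie` holds the interleaved pHluorin stack of a pulsed-pH TIRF
#' acquisition together with per-frame metadata. Frames carry the pH of the
#' perfusate at acquisition (7.4 or 5.5); labels must strictly alternate
#' within each perfusion block. Pixel coordinates are 1-based with origin at
#' the top-left; `x` indexes columns, `y` rows. The acquisition time of cycle
#' `k` is `(k - 1) * dt` seconds (timestamped at the pH 7.4 frame of the
#' pair).
#'
#' @param frames numeric array `height x width x n_frames` (counts).
#' @param frame_ph numeric vector of per-frame pH labels (7.4 or 5.5).
#' @param frame_block integer vector of per-frame perfusion-block ids;
#'   defaults to a single block.
#' @param pixel_size µm per pixel.
#' @param dt s per pH cycle (pair of frames).
#' @param reporter optional array `height x width x n_cycles`: the reporter
#'   channel, sampled once per cycle.
#' @return An object of class `ph_movie`.
#' @export
ph_movie <- function(frames, frame_ph, frame_block = NULL,
                     pixel_size = 0.13, dt = 2, reporter = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a height x width x n_frames array", call. = FALSE)
  n <- dim(frames)[3L]
  if (length(frame_ph) != n)
    stop("frame_ph: need one pH label per frame (missing field 'frame_ph'?)",
         call. = FALSE)
  if (!all(frame_ph %in% c(7.4, 5.5)))
    stop("frame_ph labels must be 7.4 or 5.5", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (is.null(frame_block)) frame_block <- rep(1L, n)
  if (length(frame_block) != n)
    stop("frame_block: need one block id per frame", call. = FALSE)
  for (b in unique(frame_block)) {
    ph <- frame_ph[frame_block == b]
    if (length(ph) > 1L) {
      same <- which(ph[-1L] == ph[-length(ph)])
      if (length(same)) {
        idx <- which(frame_block == b)[same[1L] + 1L]
        stop(sprintf("pH labels do not alternate: frame %d repeats pH %.1f",
                     idx, frame_ph[idx]), call. = FALSE)
      }
    }
  }
  if (!is.null(reporter) &&
      (!is.array(reporter) || any(dim(reporter)[1:2] != dim(frames)[1:2])))
    stop("reporter must share the frame dimensions", call. = FALSE)
  structure(list(frames = frames, frame_ph = frame_ph,
                 frame_block = as.integer(frame_block),
                 pixel_size = pixel_size, dt = dt, reporter = reporter),
            class = "ph_movie")
}

#' @export
print.ph_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ph_movie: %d x %d px, %d frames (%d cycles), dt = %g s, %g um/px\n",
              d[1], d[2], d[3], n_cycles(x), x$dt, x$pixel_size))
  cat(sprintf("  blocks: %s; reporter channel: %s\n",
              paste(unique(x$frame_block), collapse = ", "),
              if (is.null(x$reporter)) "absent" else "present"))
  invisible(x)
}

#' Number of complete pH cycles in a movie
#' @param movie a [ph_movie()].
#' @export
n_cycles <- function(movie) dim(movie$frames)[3L] %/% 2L

# internal: write one stack as a 32-bit float multi-page TIFF; values are
# affinely mapped into [0,1] (tiff clamps outside) and the map is returned.
write_stack <- function(arr, path) {
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[3L]),
                  function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  list(offset = lo, scale = scale)
}

read_stack <- function(path, offset, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr * scale + offset
}

#' Write a movie as TIFF stacks plus a JSON sidecar
#'
#' The pHluorin stack is written to `<stem>_phl.tif` (interleaved frames) and
#' the reporter channel, if present, to `<stem>_reporter.tif`. Per-frame pH
#' labels, block ids, pixel size, cycle time and the intensity scaling used
#' for 32-bit float storage go to `<stem>.json`.
#'
#' @param movie a [ph_movie()].
#' @param stem output path stem (directories must exist).
#' @return Invisibly, the sidecar path.
#' @export
save_movie <- function(movie, stem) {
  stopifnot(inherits(movie, "ph_movie"))
  phl_path <- paste0(stem, "_phl.tif")
  sc_phl <- write_stack(movie$frames, phl_path)
  meta <- list(frame_ph = movie$frame_ph, frame_block = movie$frame_block,
               pixel_size_um = movie$pixel_size, dt_s = movie$dt,
               phl_file = basename(phl_path),
               phl_offset = sc_phl$offset, phl_scale = sc_phl$scale)
  if (!is.null(movie$reporter)) {
    rep_path <- paste0(stem, "_reporter.tif")
    sc_rep <- write_stack(movie$reporter, rep_path)
    meta$reporter_file <- basename(rep_path)
    meta$reporter_offset <- sc_rep$offset
    meta$reporter_scale <- sc_rep$scale
  }
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}

#' Load a movie from TIFF + JSON sidecar
#'
#' @param path path to the pHluorin TIFF stack, or a path stem as used by
#'   [save_movie()].
#' @param metadata_path path to the JSON sidecar; defaults to `<stem>.json`.
#' @param assume_alternating if `TRUE` and the sidecar lacks `frame_ph`,
#'   labels are inferred from frame parity (first frame pH 7.4).
#' @return A validated [ph_movie()].
#' @export
load_movie <- function(path, metadata_path = NULL, assume_alternating = FALSE) {
  stem <- sub("(_phl)?\\.tif$", "", path)
  if (is.null(metadata_path)) metadata_path <- paste0(stem, ".json")
  if (!file.exists(metadata_path))
    stop("missing metadata sidecar: ", metadata_path, call. = FALSE)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (f in c("pixel_size_um", "dt_s"))
    if (is.null(meta[[f]]))
      stop("metadata is missing required field '", f, "'", call. = FALSE)
  phl_path <- if (file.exists(path) && grepl("\\.tif$", path)) path
              else file.path(dirname(metadata_path), meta$phl_file)
  frames <- read_stack(phl_path, meta$phl_offset %||% 0, meta$phl_scale %||% 1)
  n <- dim(frames)[3L]
  frame_ph <- meta$frame_ph
  if (is.null(frame_ph)) {
    if (!assume_alternating)
      stop("metadata is missing required field 'frame_ph' ",
           "(pass assume_alternating = TRUE to infer from parity)",
           call. = FALSE)
    frame_ph <- rep(c(7.4, 5.5), length.out = n)
  }
  reporter <- NULL
  if (!is.null(meta$reporter_file)) {
    reporter <- read_stack(file.path(dirname(metadata_path), meta$reporter_file),
                           meta$reporter_offset %||% 0,
                           meta$reporter_scale %||% 1)
  }
  ph_movie(frames, frame_ph = frame_ph, frame_block = meta$frame_block,
           pixel_size = meta$pixel_size_um, dt = meta$dt_s,
           reporter = reporter)
}

#' De-interlace a movie into pH 7.4 and pH 5.5 series
#'
#' Pairs each pH 7.4 frame with the immediately following pH 5.5 frame. An
#' odd trailing frame is dropped with a warning.
#'
#' @param movie a [ph_movie()].
#' @return A list with arrays `tfr7` and `tfr5`, each
#'   `height x width x n_cycles`.
#' @export
deinterlace <- function(movie) {
  stopifnot(inherits(movie, "ph_movie"))
  n <- dim(movie$frames)[3L]
  nc <- n %/% 2L
  if (n %% 2L == 1L)
    warning("odd trailing frame ", n, " dropped during de-interlacing")
  i7 <- 2L * seq_len(nc) - 1L
  if (movie$frame_ph[1L] == 5.5) { # pH 5.5-first acquisitions
    i7 <- i7 + 1L
    nc <- (n - 1L) %/% 2L
    i7 <- i7[seq_len(nc)]
  }
  list(tfr7 = movie$frames[, , i7, drop = FALSE],
       tfr5 = movie$frames[, , i7 + 1L, drop = FALSE])
}

#' Segment a movie into perfusion blocks
#'
#' Consecutive, disjoint blocks of `block_len` frames; the last block may be
#' short. Condition labels are attached positionally if supplied.
#'
#' @param movie a [ph_movie()] or a frame count.
#' @param block_len frames per block (default 400).
#' @param conditions optional character vector of per-block condition labels.
#' @return A data frame with `block_id`, `start_frame`, `end_frame`
#'   (inclusive, 1-based) and `condition`.
#' @export
segment_blocks <- function(movie, block_len = 400, conditions = NULL) {
  stopifnot(block_len > 0)
  n <- if (inherits(movie, "ph_movie")) dim(movie$frames)[3L] else as.integer(movie)
  starts <- seq(1L, n, by = block_len)
  ends <- pmin(starts + block_len - 1L, n)
  data.frame(block_id = seq_along(starts), start_frame = starts,
             end_frame = ends,
             condition = if (is.null(conditions)) NA_character_
                         else rep_len(conditions, length(starts)))
}

#' Block id containing each frame
#' @param blocks data frame from [segment_blocks()].
#' @param frame integer frame indices.
#' @return integer block ids.
#' @export
block_of <- function(blocks, frame) {
  findInterval(frame, blocks$start_frame)
}
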