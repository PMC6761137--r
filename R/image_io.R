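#' Image stack with physical pixel calibration
#'
#' Container for a multi-frame grayscale fluorescence acquisition (e.g. a
#' confocal z-stack of ZO-1 labelling). Frames are numeric matrices in the
#' original intensity units; no rescaling is performed because downstream
#' thresholds are data-driven.
#'
#' @param frames a numeric matrix or a list of numeric matrices, all of the
#'   same dimensions, with finite non-negative values.
#' @param pixel_size physical pixel size in micrometres per pixel (> 0).
#' @param channel_label free-text channel description (e.g. `"ZO-1"`).
#' @param source_id free-text identifier of the acquisition.
#' @return An object of class `tj_stack`.
#' @seealso [read_stack()], [max_project()]
#' @export
image_stack <- function(frames, pixel_size, channel_label = "", source_id = "") {
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) < 1L) {
    stop_tj("'frames' must be a matrix or a non-empty list of matrices")
  }
  dims <- dim(frames[[1L]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || !is.numeric(f)) stop_tj("frame %d is not a numeric matrix", k)
    if (!identical(dim(f), dims)) stop_tj("frame %d has different dimensions", k)
    if (!all(is.finite(f))) stop_tj("frame %d contains non-finite values", k)
    if (any(f < 0)) stop_tj("frame %d contains negative intensities", k)
    storage.mode(frames[[k]]) <- "double"
  }
  check_scalar_num(pixel_size, "pixel_size")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         channel_label = as.character(channel_label),
         source_id = as.character(source_id)),
    class = "tj_stack"
  )
}

#' Single calibrated 2-D image
#'
#' @param values numeric matrix of finite intensities.
#' @param pixel_size micrometres per pixel (> 0).
#' @return An object of class `tj_image`.
#' @export
image2d <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values) || !all(is.finite(values))) {
    stop_tj("'values' must be a finite numeric matrix")
  }
  check_scalar_num(pixel_size, "pixel_size")
  storage.mode(values) <- "double"
  structure(list(values = values, pixel_size = pixel_size), class = "tj_image")
}

#' @export
print.tj_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("Image stack: %d frame(s), %d x %d px, %.4g um/px",
              length(x$frames), d[1L], d[2L], x$pixel_size))
  if (nzchar(x$channel_label)) cat(sprintf(" [%s]", x$channel_label))
  cat("\n")
  invisible(x)
}

#' @export
print.tj_image <- function(x, ...) {
  cat(sprintf("Image: %d x %d px, %.4g um/px\n",
              nrow(x$values), ncol(x$values), x$pixel_size))
  invisible(x)
}

# Convert a TIFF resolution tag (pixels per unit) to um/px. With unit "none"
# the resolution is interpreted as pixels per micrometre.
resolution_to_pixel_size <- function(res, unit) {
  if (is.null(res) || !is.finite(res) || res <= 0) return(NA_real_)
  unit <- if (is.null(unit)) "none" else tolower(unit)
  per_um <- switch(unit,
    "inch" = res / 25400,
    "cm"   = res / 10000,
    res # "none" or unknown: pixels per micrometre
  )
  1 / per_um
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF into an [image_stack()].
#' Integer data are kept in their original units (no rescaling to `[0, 1]`).
#' The physical pixel size is taken from the `pixel_size` override if given,
#' else from the TIFF resolution tags (`ResolutionUnit` of inch or cm, or
#' pixels per micrometre when the unit is "none"); a file without resolvable
#' calibration is an error, never silently assumed to be 1 um/px.
#'
#' @param path path to the TIFF file.
#' @param pixel_size optional calibration override in micrometres per pixel.
#' @param channel_label,source_id labels stored on the result; `source_id`
#'   defaults to the file name.
#' @return An object of class `tj_stack`.
#' @export
read_stack <- function(path, pixel_size = NULL, channel_label = "",
                       source_id = basename(path)) {
  if (!file.exists(path)) stop_tj("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- vector("list", length(pages))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) {
      stop_tj("page %d of %s has %d channels; only grayscale TIFF is supported",
              k, path, dim(p)[3L])
    }
    at <- attributes(p)
    attributes(p) <- at["dim"]
    frames[[k]] <- p
  }
  if (is.null(pixel_size)) {
    at <- attributes(pages[[1L]])
    pixel_size <- resolution_to_pixel_size(at$x.resolution, at$resolution.unit)
    if (is.na(pixel_size)) {
      stop_tj("no pixel size: %s carries no resolution metadata and no override was given", path)
    }
  }
  tj_log("read_stack: %s, %d frame(s), %d x %d, %.4g um/px",
         path, length(frames), nrow(frames[[1L]]), ncol(frames[[1L]]), pixel_size)
  image_stack(frames, pixel_size, channel_label = channel_label, source_id = source_id)
}

# Little-endian baseline TIFF writer for calibrated unsigned grayscale stacks.
# Needed because tiff::writeTIFF cannot emit resolution tags; keeps
# round-trips of physical calibration self-contained.
write_tiff_calibrated <- function(frames, path, pixel_size, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  n <- length(frames)
  h <- nrow(frames[[1L]]); wd <- ncol(frames[[1L]])
  bytes_px <- bits / 8L
  strip_len <- h * wd * bytes_px
  writeBin(charToRaw("II"), con); w2(42L)
  w4(8L + strip_len + 16L) # first IFD follows the first strip and rationals
  n_tags <- 12L
  ifd_len <- 2L + n_tags * 12L + 4L
  # per page: [pixel strip][XRes rational][YRes rational][IFD]
  page_len <- strip_len + 16L + ifd_len
  res_ppum <- 1 / pixel_size # pixels per micrometre, unit "none"
  den <- 1000000L
  num <- round(res_ppum * den)

  for (k in seq_len(n)) {
    base <- 8L + (k - 1L) * page_len
    strip_off <- base
    xres_off <- base + strip_len
    yres_off <- xres_off + 8L
    ifd_off <- yres_off + 8L
    next_ifd <- if (k < n) base + page_len + strip_len + 16L else 0L

    v <- t(frames[[k]]) # TIFF is row-major
    v <- pmin(pmax(round(v), 0), maxval)
    iv <- as.integer(v)
    iv[iv > .Machine$integer.max] <- .Machine$integer.max
    if (bits == 8L) {
      writeBin(as.raw(iv), con)
    } else {
      writeBin(iv, con, size = 2L, endian = "little")
    }
    w4(c(num, den)) # XResolution
    w4(c(num, den)) # YResolution

    tag <- function(id, type, count, value, short = FALSE) {
      w2(id); w2(type); w4(count)
      if (short) { w2(value); w2(0L) } else w4(value)
    }
    w2(n_tags)
    tag(256L, 3L, 1L, wd, short = TRUE)        # ImageWidth
    tag(257L, 3L, 1L, h, short = TRUE)         # ImageLength
    tag(258L, 3L, 1L, bits, short = TRUE)      # BitsPerSample
    tag(259L, 3L, 1L, 1L, short = TRUE)        # Compression: none
    tag(262L, 3L, 1L, 1L, short = TRUE)        # Photometric: black is zero
    tag(273L, 4L, 1L, strip_off)               # StripOffsets
    tag(277L, 3L, 1L, 1L, short = TRUE)        # SamplesPerPixel
    tag(278L, 3L, 1L, h, short = TRUE)         # RowsPerStrip
    tag(279L, 4L, 1L, strip_len)               # StripByteCounts
    tag(282L, 5L, 1L, xres_off)                # XResolution
    tag(283L, 5L, 1L, yres_off)                # YResolution
    tag(296L, 3L, 1L, 1L, short = TRUE)        # ResolutionUnit: none (px/um)
    w4(next_ifd)
  }
  invisible(path)
}

#' Write an image stack to a calibrated TIFF
#'
#' Writes an uncompressed unsigned grayscale multi-page TIFF with resolution
#' tags carrying the pixel size (stored as pixels per micrometre with
#' `ResolutionUnit = none`), so that [read_stack()] recovers the calibration
#' without an override. Intensities are rounded and clipped to the unsigned
#' range of the chosen bit depth.
#'
#' @param stack a `tj_stack`.
#' @param path output path.
#' @param bits bit depth, 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "tj_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_tj("directory does not exist: %s", dir)
  write_tiff_calibrated(stack$frames, path, stack$pixel_size, bits = as.integer(bits))
  tj_log("write_stack: %s (%d frames, %d-bit)", path, length(stack$frames), bits)
  invisible(path)
}

#' Maximum-intensity projection
#'
#' Collapses a stack to a single image by taking, at every pixel position,
#' the maximum intensity over all frames.
#'
#' @param stack a `tj_stack`.
#' @return A `tj_image` with the same height/width and pixel size.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "tj_stack"))
  proj <- Reduce(pmax, stack$frames)
  tj_log("max_project: %d frame(s) -> %d x %d", length(stack$frames),
         nrow(proj), ncol(proj))
  image2d(proj, stack$pixel_size)
}

#' Write a segment table to CSV
#'
#' One row per measured membrane segment, ordered by segment id. Columns:
#' `segment_id`, `pixel_count`, `length_um` (pixel count times pixel size),
#' `geodesic_um` (orthogonal step 1, diagonal step sqrt(2), times pixel
#' size), `image_id`.
#'
#' @param segments a `tj_segments` object (see [measure_branches()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments_table <- function(segments, path) {
  stopifnot(inherits(segments, "tj_segments"))
  df <- as.data.frame(segments)
  df <- df[order(df$segment_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments_table()]
#'
#' @param path CSV path.
#' @return A data frame with the segment table columns.
#' @export
read_segments_table <- function(path) {
  if (!file.exists(path)) stop_tj("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
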