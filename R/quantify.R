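#' Quantify tight-junction fragmentation in an image
#'
#' Runs the full measurement pipeline on a junction-labelled image or stack:
#' maximum-intensity projection (for stacks), ridge enhancement by the
#' smallest Hessian eigenvalue, binarization, skeletonization, detection and
#' subtraction of junction points (pixels where three or more branches meet,
#' found by the hit-or-miss catalogue), and measurement of the remaining
#' skeleton branches as continuous membrane segments.
#'
#' @param x a `tj_stack`, `tj_image`, numeric matrix (with `pixel_size`), or a
#'   path to a grayscale TIFF.
#' @param scale_sigma Hessian smoothing scale in pixels (default 1.5).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value threshold for `threshold_method = "fixed"`.
#' @param min_branch_px minimum branch size in pixels (default 3).
#' @param pixel_size um/px; required for a bare matrix, optional override for
#'   a TIFF path.
#' @param image_id identifier attached to the measured segments; defaults to
#'   the stack's `source_id`.
#' @return An object of class `tj_quant` with the measured `segments`
#'   (a `tj_segments`), the intermediate `skeleton` and `junctions`, pixel
#'   bookkeeping counts and the parameters used.
#' @examples
#' sim <- simulate_zo1(f = 0.25, n_cells = 24, domain_size = c(144, 144), seed = 7)
#' q <- quantify_junctions(sim$stack)
#' q
#' large_segment_count(q, 5, 100)
#' @export
quantify_junctions <- function(x, scale_sigma = 1.5,
                               threshold_method = c("otsu", "fixed"),
                               threshold_value = NULL, min_branch_px = 3L,
                               pixel_size = NULL, image_id = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (is.character(x) && length(x) == 1L) x <- read_stack(x, pixel_size = pixel_size)
  if (is.matrix(x)) {
    if (is.null(pixel_size)) stop_tj("'pixel_size' is required for a bare matrix")
    x <- image2d(x, pixel_size)
  }
  if (inherits(x, "tj_stack")) {
    if (is.null(image_id)) image_id <- x$source_id
    img <- max_project(x)
  } else if (inherits(x, "tj_image")) {
    if (is.null(image_id)) image_id <- ""
    img <- x
  } else {
    stop_tj("'x' must be a tj_stack, tj_image, matrix or TIFF path")
  }
  ridge <- hessian_ridge(img, scale_sigma = scale_sigma)
  mask <- binarize(ridge, method = threshold_method, threshold = threshold_value)
  skel <- skeletonize(mask)
  junc <- detect_junctions(skel)
  branches <- remove_junctions(skel, junc)
  segs <- measure_branches(branches, min_branch_px = min_branch_px,
                           image_id = image_id)
  structure(list(
    segments = segs,
    skeleton = skel,
    junctions = junc,
    image_id = image_id,
    pixel_size = img$pixel_size,
    counts = c(mask_px = sum(mask$values),
               skeleton_px = sum(skel$values),
               junction_px = nrow(junc$coords),
               segment_px = sum(segs$segments$pixel_count),
               discarded_px = segs$discarded_px),
    params = list(scale_sigma = scale_sigma,
                  threshold_method = threshold_method,
                  threshold = mask$threshold,
                  min_branch_px = as.integer(min_branch_px))
  ), class = "tj_quant")
}

#' @export
print.tj_quant <- function(x, ...) {
  s <- x$segments$segments
  cat(sprintf("Junction quantification%s\n",
              if (nzchar(x$image_id)) paste0(" [", x$image_id, "]") else ""))
  cat(sprintf("  skeleton: %d px, %d junction px removed\n",
              x$counts[["skeleton_px"]], x$counts[["junction_px"]]))
  cat(sprintf("  segments: %d (>= %d px), total %.1f um, median %.2f um\n",
              nrow(s), x$params$min_branch_px,
              sum(s$length_um), if (nrow(s)) stats::median(s$length_um) else NA))
  invisible(x)
}

#' @export
summary.tj_quant <- function(object, large_min = 5, large_max = 100, ...) {
  s <- object$segments$segments
  out <- list(
    image_id = object$image_id,
    n_segments = nrow(s),
    total_length_um = sum(s$length_um),
    median_length_um = if (nrow(s)) stats::median(s$length_um) else NA_real_,
    length_quartiles_um = if (nrow(s)) stats::quantile(s$length_um, c(.25, .5, .75)) else NULL,
    n_large = large_segment_count(object, large_min, large_max),
    large_window_um = c(large_min, large_max),
    counts = object$counts,
    params = object$params
  )
  class(out) <- "summary.tj_quant"
  out
}

#' @export
print.summary.tj_quant <- function(x, ...) {
  cat(sprintf("Junction quantification summary%s\n",
              if (nzchar(x$image_id)) paste0(" [", x$image_id, "]") else ""))
  cat(sprintf("  segments: %d, total %.1f um, median %.2f um\n",
              x$n_segments, x$total_length_um, x$median_length_um))
  cat(sprintf("  large segments (%g, %g) um: %d\n",
              x$large_window_um[1L], x$large_window_um[2L], x$n_large))
  cat(sprintf("  pixels: mask %d, skeleton %d = junctions %d + segments %d + discarded %d\n",
              x$counts[["mask_px"]], x$counts[["skeleton_px"]],
              x$counts[["junction_px"]], x$counts[["segment_px"]],
              x$counts[["discarded_px"]]))
  invisible(x)
}

#' @export
as.data.frame.tj_quant <- function(x, ...) as.data.frame(x$segments)

#' Plot a junction quantification
#'
#' `type = "histogram"` draws the segment-length histogram; `type = "skeleton"`
#' shows the measured skeleton with junction points marked.
#'
#' @param x a `tj_quant`.
#' @param type `"histogram"` or `"skeleton"`.
#' @param breaks passed to [graphics::hist()] for the histogram.
#' @param ... further arguments passed to the underlying plot function.
#' @export
plot.tj_quant <- function(x, type = c("histogram", "skeleton"), breaks = "Sturges", ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    graphics::hist(x$segments$segments$length_um, breaks = breaks,
                   xlab = "Segment length (um)",
                   main = "Membrane segment lengths", ...)
  } else {
    v <- x$skeleton$values
    graphics::image(t(v)[, rev(seq_len(nrow(v)))], col = c("black", "white"),
                    axes = FALSE, asp = nrow(v) / ncol(v), ...)
    if (nrow(x$junctions$coords)) {
      nr <- nrow(v); nc <- ncol(v)
      graphics::points((x$junctions$coords[, "col"] - 1) / (nc - 1),
                       (nr - x$junctions$coords[, "row"]) / (nr - 1),
                       col = "red", pch = 16, cex = 0.4)
    }
  }
  invisible(x)
}
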