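segment_lengths <- function(x) {
  if (inherits(x, "tj_segments")) return(x$segments$length_um)
  if (inherits(x, "tj_quant")) return(x$segments$segments$length_um)
  if (is.numeric(x)) return(x)
  stop_tj("expected a tj_segments, tj_quant or numeric lengths")
}

#' Segment-length histogram
#'
#' Bins segment lengths into half-open bins `[e_i, e_{i+1})`. Lengths outside
#' the edge range are excluded from the counts but reported as `n_excluded`.
#'
#' @param segments a `tj_segments`, `tj_quant` or numeric vector of lengths (um).
#' @param bin_edges strictly increasing bin edges in micrometres (>= 2 values).
#' @return An object of class `tj_hist` with `bin_edges`, `counts`, `n_total`
#'   and `n_excluded`.
#' @export
length_histogram <- function(segments, bin_edges) {
  len <- segment_lengths(segments)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop_tj("'bin_edges' must be >= 2 strictly increasing values")
  }
  nb <- length(bin_edges) - 1L
  b <- findInterval(len, bin_edges) # [e_i, e_{i+1}) bins; b = 0 below, nb+1 at/above last edge
  inside <- b >= 1L & b <= nb & len < bin_edges[nb + 1L]
  counts <- tabulate(b[inside], nbins = nb)
  structure(list(bin_edges = bin_edges, counts = counts,
                 n_total = sum(counts), n_excluded = sum(!inside)),
            class = "tj_hist")
}

#' @export
print.tj_hist <- function(x, ...) {
  cat(sprintf("Length histogram: %d bins, %d segment(s) binned, %d excluded\n",
              length(x$counts), x$n_total, x$n_excluded))
  invisible(x)
}

#' @export
as.data.frame.tj_hist <- function(x, ...) {
  nb <- length(x$counts)
  data.frame(bin_lower_um = x$bin_edges[seq_len(nb)],
             bin_upper_um = x$bin_edges[seq_len(nb) + 1L],
             count = x$counts)
}

#' Count large segments inside a length window
#'
#' Number of segments with length strictly between `x` and `y` micrometres.
#'
#' @param segments a `tj_segments`, `tj_quant` or numeric vector of lengths.
#' @param x,y window bounds in micrometres, `0 <= x < y`.
#' @return An integer count.
#' @export
large_segment_count <- function(segments, x = 5, y = 100) {
  len <- segment_lengths(segments)
  if (!is.numeric(x) || !is.numeric(y) || x < 0 || x >= y) {
    stop_tj("need 0 <= x < y")
  }
  sum(len > x & len < y)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples. The U statistic is the
#' rank-sum statistic of the first group. When the combined sample size is at
#' most 20 and there are no ties, the p-value comes from the exact null
#' distribution of U; otherwise a normal approximation with tie correction
#' and continuity correction is used, and the method is recorded.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return An object of class `tj_mwtest` with `u_statistic`, `p_value`,
#'   `method` (`"exact"` or `"normal-approx"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b) || anyNA(a) || anyNA(b)) {
    stop_tj("both groups must be non-empty and free of missing values")
  }
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (n_a + n_b <= 20L && !ties) {
    method <- "exact"
    p <- if (u > n_a * n_b / 2) {
      2 * (1 - stats::pwilcox(u - 1, n_a, n_b))
    } else {
      2 * stats::pwilcox(u, n_a, n_b)
    }
    p <- min(1, p)
  } else {
    method <- "normal-approx"
    n <- n_a + n_b
    tt <- table(pooled)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    z <- u - n_a * n_b / 2
    z <- z - sign(z) * 0.5 # continuity correction
    p <- if (sigma2 <= 0) 1 else min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  }
  structure(list(u_statistic = u, p_value = p, method = method,
                 n_a = n_a, n_b = n_b),
            class = "tj_mwtest")
}

#' @export
print.tj_mwtest <- function(x, ...) {
  cat(sprintf("Mann-Whitney test (%s): U = %g (n = %d vs %d), two-sided p = %.4g\n",
              x$method, x$u_statistic, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' Compare large-segment abundance between two conditions
#'
#' Computes the large-segment count (length strictly inside `(x, y)` um) for
#' every image of each condition, then compares the two per-image count lists
#' with the Mann-Whitney test. The image is the sampling unit: conditions are
#' compared across images, not across pooled segments (pooling segments would
#' be pseudo-replication; a pooled per-segment comparison of the raw lengths
#' is available with `pooled = TRUE` but should be interpreted with care).
#'
#' @param condition_a,condition_b lists of `tj_segments`/`tj_quant` objects
#'   (or numeric length vectors), one element per image.
#' @param x,y large-segment window in micrometres (defaults 5 and 100).
#' @param names character vector of length 2 labelling the conditions.
#' @param pooled if `TRUE`, compare pooled per-segment lengths instead of
#'   per-image large-segment counts.
#' @return An object of class `tj_comparison`.
#' @export
compare_conditions <- function(condition_a, condition_b, x = 5, y = 100,
                               names = c("A", "B"), pooled = FALSE) {
  if (!is.list(condition_a) || !is.list(condition_b) ||
      length(condition_a) < 1L || length(condition_b) < 1L) {
    stop_tj("each condition needs at least one image (a non-empty list)")
  }
  if (pooled) {
    va <- unlist(lapply(condition_a, segment_lengths))
    vb <- unlist(lapply(condition_b, segment_lengths))
    metric <- sprintf("pooled segment length (um), window ignored")
  } else {
    va <- vapply(condition_a, large_segment_count, 0L, x = x, y = y)
    vb <- vapply(condition_b, large_segment_count, 0L, x = x, y = y)
    metric <- sprintf("per-image count of segments with %g um < length < %g um", x, y)
  }
  test <- mann_whitney(va, vb)
  structure(list(metric_name = metric, names = names,
                 group_a_values = va, group_b_values = vb,
                 u_statistic = test$u_statistic, p_value = test$p_value,
                 method = test$method, large_window = c(x = x, y = y)),
            class = "tj_comparison")
}

#' @export
print.tj_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison: %s\n", x$metric_name))
  cat(sprintf("  %s: %s\n", x$names[1L], paste(signif(x$group_a_values, 4), collapse = ", ")))
  cat(sprintf("  %s: %s\n", x$names[2L], paste(signif(x$group_b_values, 4), collapse = ", ")))
  cat(sprintf("  Mann-Whitney (%s): U = %g, two-sided p = %.4g\n",
              x$method, x$u_statistic, x$p_value))
  invisible(x)
}
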