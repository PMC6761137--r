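# Ground-truth validation experiments on the synthetic generator. These are
# the package's own simulation studies: they exercise the full measurement
# chain against known geometry and are reused by the test suite and the
# acceptance script.

#' End-to-end length-recovery experiment
#'
#' For each fragmentation level, generates monolayer images, measures them
#' with the calibrated protocol ([ridge_calibration()]), and compares the
#' recovered total segment length against the true retained boundary length
#' `(1 - f) * L_true`. Both length metrics are reported: the geodesic length
#' (diagonal steps sqrt(2); the physically comparable one) and the raw
#' pixel-count length (the particle-count metric, which undercounts diagonal
#' lines by up to 10%).
#'
#' @param f_levels fragmentation fractions to test.
#' @param n_seeds images per level.
#' @param n_cells,domain_size generator field size.
#' @param params a [render_params()] object (noise etc.).
#' @param base_seed integer; image seeds are derived from it.
#' @return A data frame with one row per (f, seed): achieved removed
#'   fraction, true retained length (um), recovered lengths and ratios, and
#'   the median recovered segment length (um).
#' @export
recovery_experiment <- function(f_levels = c(0, 0.25, 0.5), n_seeds = 6L,
                                n_cells = 80L, domain_size = c(256L, 256L),
                                params = render_params(), base_seed = 1L) {
  cal <- ridge_calibration(params)
  rows <- list()
  for (fi in seq_along(f_levels)) {
    f <- f_levels[fi]
    for (s in seq_len(n_seeds)) {
      seed <- base_seed + 1000L * fi + s
      sim <- simulate_zo1(f = f, n_cells = n_cells, domain_size = domain_size,
                          params = params, seed = seed)
      q <- quantify_junctions(sim$stack, scale_sigma = cal$scale_sigma,
                              threshold_method = "fixed",
                              threshold_value = cal$threshold_value)
      true_um <- sim$network$total_length_px * params$pixel_size *
        (1 - sim$fragmented$removed_fraction)
      seg <- q$segments$segments
      rows[[length(rows) + 1L]] <- data.frame(
        f = f, seed = seed,
        removed_fraction = sim$fragmented$removed_fraction,
        true_retained_um = true_um,
        recovered_geodesic_um = sum(seg$geodesic_um),
        recovered_pixel_um = sum(seg$length_um),
        ratio_geodesic = sum(seg$geodesic_um) / true_um,
        ratio_pixel = sum(seg$length_um) / true_um,
        median_segment_um = if (nrow(seg)) stats::median(seg$length_um) else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discrimination-power experiment
#'
#' Repeatedly simulates an intact condition (`f_a`) and a fragmented
#' condition (`f_b`), `n_images` images each, measures every image with the
#' calibrated protocol, and compares the per-image large-segment counts with
#' [compare_conditions()]. Returns the two-sided p-value of each replicate,
#' so the proportion reaching a significance level estimates the power of the
#' readout at these field sizes.
#'
#' @param n_rep number of independent replicates.
#' @param f_a,f_b fragmentation fractions of the two conditions.
#' @param n_images images per condition per replicate.
#' @param n_cells,domain_size generator field size.
#' @param large_min,large_max large-segment window (um).
#' @param params a [render_params()] object.
#' @param base_seed integer; all image seeds are derived from it.
#' @return Numeric vector of `n_rep` two-sided p-values.
#' @export
discrimination_experiment <- function(n_rep = 100L, f_a = 0, f_b = 0.4,
                                      n_images = 6L, n_cells = 24L,
                                      domain_size = c(144L, 144L),
                                      large_min = 5, large_max = 100,
                                      params = render_params(), base_seed = 1L) {
  cal <- ridge_calibration(params)
  measure <- function(f, seed) {
    sim <- simulate_zo1(f = f, n_cells = n_cells, domain_size = domain_size,
                        params = params, seed = seed)
    quantify_junctions(sim$stack, scale_sigma = cal$scale_sigma,
                       threshold_method = "fixed",
                       threshold_value = cal$threshold_value)
  }
  vapply(seq_len(n_rep), function(r) {
    qa <- lapply(seq_len(n_images), function(i) measure(f_a, base_seed + 10000L * r + i))
    qb <- lapply(seq_len(n_images), function(i) measure(f_b, base_seed + 10000L * r + 5000L + i))
    compare_conditions(qa, qb, x = large_min, y = large_max)$p_value
  }, 0)
}
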