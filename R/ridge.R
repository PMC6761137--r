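#' Binary mask
#'
#' @param values logical matrix.
#' @param pixel_size micrometres per pixel.
#' @param threshold threshold that produced the mask, if any.
#' @return An object of class `tj_mask`.
#' @export
binary_mask <- function(values, pixel_size, threshold = NA_real_) {
  if (!is.matrix(values) || !is.logical(values)) {
    stop_tj("'values' must be a logical matrix")
  }
  check_scalar_num(pixel_size, "pixel_size")
  structure(list(values = values, pixel_size = pixel_size, threshold = threshold),
            class = "tj_mask")
}

#' @export
print.tj_mask <- function(x, ...) {
  cat(sprintf("Binary mask: %d x %d px, %d foreground (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

# Map out-of-range indices into 1..n by mirror reflection (period 2n - 2),
# so convolutions use reflective boundary handling for any kernel radius.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  ifelse(j >= n, p - j, j) + 1L
}

# Cross-correlate each column of X with kernel k (radius r = (len-1)/2),
# reflective boundaries, via a banded dense matrix product.
corr_cols <- function(X, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(X)
  Xp <- X[reflect_index(seq.int(1L - r, n + r), n), , drop = FALSE]
  K <- matrix(0, n, n + 2L * r)
  idx <- cbind(rep(seq_len(n), each = 2L * r + 1L),
               as.vector(t(outer(seq_len(n), 0:(2L * r), `+`))))
  K[idx] <- rep(k, times = n)
  K %*% Xp
}

# Sampled Gaussian kernel and its first/second derivative kernels. The
# zeroth-order kernel is normalized to unit sum; derivative kernels are
# corrected to annihilate constants (g1, g2) so flat images give exactly
# zero response.
gauss_kernels <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- (-x / sigma^2) * g
  g1 <- g1 - mean(g1)
  g2 <- ((x^2 - sigma^2) / sigma^4) * g
  g2 <- g2 - mean(g2)
  list(g = g, g1 = g1, g2 = g2)
}

#' Ridge enhancement by the smallest Hessian eigenvalue
#'
#' Enhances thin bright linear structures (membrane labelling) by computing,
#' at every pixel, the 2x2 Hessian tensor of the Gaussian-smoothed image at
#' scale `scale_sigma` and taking its smallest eigenvalue `lambda_min`. Across
#' a bright ridge the intensity profile has strongly negative curvature, so
#' the returned ridge strength is `pmax(0, -lambda_min)`: positive on ridges,
#' zero on flat background. Derivatives are computed by separable convolution
#' with sampled Gaussian-derivative kernels (reflective boundaries); the sign
#' convention of the mixed derivative is immaterial because it enters the
#' eigenvalues only squared.
#'
#' @param image a `tj_image` (or numeric matrix plus `pixel_size`).
#' @param scale_sigma Gaussian smoothing scale in pixels (> 0). Default 1.5 px,
#'   matched to junction line widths of roughly 2-4 px.
#' @param pixel_size pixel size in um/px, required when `image` is a bare matrix.
#' @return An object of class `tj_ridge` with fields `strength` (non-negative
#'   matrix), `scale_sigma` and `pixel_size`.
#' @export
hessian_ridge <- function(image, scale_sigma = 1.5, pixel_size = NULL) {
  if (is.matrix(image)) {
    if (is.null(pixel_size)) stop_tj("'pixel_size' is required for a bare matrix")
    image <- image2d(image, pixel_size)
  }
  stopifnot(inherits(image, "tj_image"))
  check_scalar_num(scale_sigma, "scale_sigma")
  v <- image$values
  if (nrow(v) < 3L || ncol(v) < 3L) stop_tj("image must be at least 3 x 3")
  if (diff(range(v)) == 0) { # constant input: exactly zero response
    return(structure(list(strength = matrix(0, nrow(v), ncol(v)),
                          scale_sigma = scale_sigma,
                          pixel_size = image$pixel_size),
                     class = "tj_ridge"))
  }
  k <- gauss_kernels(scale_sigma)
  # rows = y, cols = x; correlate along each dimension separately
  d_rows <- function(X, kr) corr_cols(X, kr)
  d_cols <- function(X, kc) t(corr_cols(t(X), kc))
  Iyy <- d_cols(d_rows(v, k$g2), k$g)
  Ixx <- d_cols(d_rows(v, k$g), k$g2)
  Ixy <- d_cols(d_rows(v, k$g1), k$g1)
  lam_min <- (Ixx + Iyy) / 2 - sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  strength <- -lam_min
  strength[strength < 0] <- 0
  tj_log("hessian_ridge: %d x %d, sigma = %.3g, max strength = %.4g",
         nrow(v), ncol(v), scale_sigma, max(strength))
  structure(list(strength = strength, scale_sigma = scale_sigma,
                 pixel_size = image$pixel_size),
            class = "tj_ridge")
}

#' @export
print.tj_ridge <- function(x, ...) {
  cat(sprintf("Ridge map: %d x %d px, sigma = %.3g px, strength range [0, %.4g]\n",
              nrow(x$strength), ncol(x$strength), x$scale_sigma, max(x$strength)))
  invisible(x)
}

#' Analytic ridge strength of a Gaussian line profile
#'
#' For a straight line of Gaussian cross-section
#' `I(x) = amplitude * exp(-x^2 / (2 * width^2))`, optionally blurred by a
#' Gaussian point-spread function, the peak of the smallest-Hessian-eigenvalue
#' ridge strength at detection scale `scale_sigma` is
#' `amplitude * width / (width^2 + psf_sigma^2 + scale_sigma^2)^(3/2)`
#' (the convolutions compose into a single Gaussian, whose centerline
#' curvature this is). Used to verify the detector against closed form and to
#' derive calibrated thresholds for synthetic data with known rendering
#' parameters.
#'
#' @param amplitude line peak amplitude above background.
#' @param width Gaussian cross-section sd of the line, px.
#' @param scale_sigma Hessian detection scale, px.
#' @param psf_sigma optical blur sd, px (default 0).
#' @return The peak ridge strength, a single number.
#' @export
line_ridge_strength <- function(amplitude, width, scale_sigma, psf_sigma = 0) {
  amplitude * width / (width^2 + psf_sigma^2 + scale_sigma^2)^1.5
}

#' Otsu threshold
#'
#' Selects the threshold maximizing the between-class variance of the value
#' histogram, computed over 256 equal-width bins spanning the data range. The
#' returned threshold is the upper edge of the last low-class bin, so
#' `values > threshold` reproduces the optimal split.
#'
#' @param x numeric vector or matrix with at least two distinct finite values.
#' @return The threshold, a single number.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop_tj("no finite values")
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    stop_tj("degenerate input: all values equal, no threshold separates classes")
  }
  nb <- 256L
  edges <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  bin <- pmin(findInterval(v, edges, all.inside = TRUE), nb)
  h <- tabulate(bin, nbins = nb)
  mids <- (edges[-1L] + edges[-(nb + 1L)]) / 2
  n <- length(v)
  w0 <- cumsum(h)
  m0 <- cumsum(h * mids)
  mt <- m0[nb]
  k <- seq_len(nb - 1L)
  w1 <- n - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bc <- rep(-Inf, nb - 1L)
  bc[valid] <- (mt * w0[k][valid] / n - m0[k][valid])^2 * n /
    (w0[k][valid] * w1[valid] / n)
  kstar <- which.max(bc)
  edges[kstar + 1L]
}

#' Binarize a ridge map
#'
#' Foreground is every pixel whose ridge strength strictly exceeds the
#' threshold. With `method = "otsu"` the threshold maximizes between-class
#' variance over a 256-bin histogram of the strength values; an all-constant
#' map is a degenerate-input error. With `method = "fixed"` the supplied
#' `threshold` is used as-is.
#'
#' @param ridge a `tj_ridge` (or `tj_image`).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold numeric threshold, required for `method = "fixed"`.
#' @return A `tj_mask` carrying the threshold used.
#' @export
binarize <- function(ridge, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  v <- if (inherits(ridge, "tj_ridge")) ridge$strength
       else if (inherits(ridge, "tj_image")) ridge$values
       else stop_tj("'ridge' must be a tj_ridge or tj_image")
  thr <- if (method == "otsu") {
    otsu_threshold(v)
  } else {
    if (is.null(threshold)) stop_tj("method 'fixed' requires 'threshold'")
    check_scalar_num(threshold, "threshold", positive = FALSE)
  }
  mask <- v > thr
  tj_log("binarize[%s]: threshold = %.5g, %d foreground px", method, thr, sum(mask))
  binary_mask(mask, ridge$pixel_size, threshold = thr)
}
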