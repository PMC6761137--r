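# Sutherland-Hodgman clip of a convex polygon (rows = points, cols = x,y)
# by the half-plane {p : nx*px + ny*py <= c0}.
clip_halfplane <- function(P, nx, ny, c0) {
  n <- nrow(P)
  if (n == 0L) return(P)
  d <- P[, 1L] * nx + P[, 2L] * ny - c0
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 0; djn <- d[j] <= 0
    if (din) out <- rbind(out, P[i, ])
    if (xor(din, djn)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, P[i, ] + t * (P[j, ] - P[i, ]))
    }
  }
  out
}

torus_min_dist <- function(p, pts, W, H) {
  dx <- abs(pts[, 1L] - p[1L]); dx <- pmin(dx, W - dx)
  dy <- abs(pts[, 2L] - p[2L]); dy <- pmin(dy, H - dy)
  sqrt(dx^2 + dy^2)
}

#' Generate a synthetic epithelial monolayer boundary network
#'
#' Cell centers are drawn uniformly on a periodic (toroidal) domain with a
#' hard-core minimum spacing (rejection sampling); the junction network is the
#' Voronoi tessellation boundary of those centers, computed exactly by
#' half-plane clipping against the 3x3 periodic replication of the seeds.
#' Epithelial monolayers such as the RPE form convex polygonal cells, which
#' Voronoi geometry reproduces; the hard-core spacing prevents degenerate
#' sliver cells. Each boundary edge shared by two cells is stored once, as a
#' straight polyline with its Euclidean length in pixels.
#'
#' @param n_cells number of cells (>= 4).
#' @param domain_size `c(height, width)` of the periodic domain in pixels.
#' @param min_spacing_px hard-core minimum seed spacing; default
#'   `0.55 * sqrt(height * width / n_cells)`.
#' @param rng_seed integer seed for reproducible geometry (optional).
#' @param seeds optional n x 2 matrix of seed coordinates (x, y) in the
#'   domain, bypassing the random placement (used for hand-checkable
#'   geometries).
#' @return An object of class `tj_network`: `domain_size`, `cell_seeds`
#'   (n x 2 matrix of x, y), `edges` (list of 2 x 2 endpoint matrices),
#'   `edge_cells` (E x 2 matrix of the two cell indices sharing each edge),
#'   `edge_lengths_px`, `total_length_px`.
#' @export
generate_monolayer <- function(n_cells, domain_size = c(256L, 256L),
                               min_spacing_px = NULL, rng_seed = NULL,
                               seeds = NULL) {
  H <- domain_size[1L]; W <- domain_size[2L]
  if (!is.null(seeds)) {
    seeds <- as.matrix(seeds)
    n_cells <- nrow(seeds)
  }
  if (n_cells < 4L) stop_tj("'n_cells' must be >= 4")
  if (is.null(min_spacing_px)) min_spacing_px <- 0.55 * sqrt(H * W / n_cells)
  if (is.null(seeds)) seeds <- with_seed(rng_seed, {
    pts <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(pts) < n_cells) {
      p <- c(stats::runif(1L, 0, W), stats::runif(1L, 0, H))
      if (nrow(pts) == 0L || min(torus_min_dist(p, pts, W, H)) >= min_spacing_px) {
        pts <- rbind(pts, p)
      }
      tries <- tries + 1L
      if (tries > 500L * n_cells) {
        stop_tj("hard-core spacing %.3g infeasible after %d proposals",
                min_spacing_px, tries)
      }
    }
    pts
  })

  # 3x3 periodic replication; cell i is clipped against every replicated seed
  offsets <- as.matrix(expand.grid(ox = c(-W, 0, W), oy = c(-H, 0, H)))
  rep_seeds <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(k) {
    cbind(seeds[, 1L] + offsets[k, 1L], seeds[, 2L] + offsets[k, 2L])
  }))
  rep_orig <- rep(seq_len(n_cells), times = nrow(offsets))
  center_copy <- which(offsets[, 1L] == 0 & offsets[, 2L] == 0)

  half <- max(W, H) / 2
  edge_from <- integer(0); edge_to <- integer(0)
  edge_p <- list(); edge_mid <- list()
  for (i in seq_len(n_cells)) {
    s <- seeds[i, ]
    box <- rbind(s + c(-half, -half), s + c(half, -half),
                 s + c(half, half), s + c(-half, half))
    self_idx <- (center_copy - 1L) * n_cells + i
    d <- sqrt((rep_seeds[, 1L] - s[1L])^2 + (rep_seeds[, 2L] - s[2L])^2)
    ord <- order(d)
    ord <- ord[ord != self_idx]
    poly <- box
    for (j in ord) {
      rmax <- sqrt(max((poly[, 1L] - s[1L])^2 + (poly[, 2L] - s[2L])^2))
      if (d[j] > 2 * rmax + 1e-9) break
      nvec <- rep_seeds[j, ] - s
      mid <- (rep_seeds[j, ] + s) / 2
      poly <- clip_halfplane(poly, nvec[1L], nvec[2L], sum(mid * nvec))
      if (nrow(poly) < 3L) stop_tj("degenerate Voronoi cell for seed %d", i)
    }
    m <- nrow(poly)
    for (k in seq_len(m)) {
      k2 <- if (k == m) 1L else k + 1L
      p1 <- poly[k, ]; p2 <- poly[k2, ]
      len <- sqrt(sum((p2 - p1)^2))
      if (len < 1e-9) next
      mp <- (p1 + p2) / 2
      dd <- sqrt((rep_seeds[, 1L] - mp[1L])^2 + (rep_seeds[, 2L] - mp[2L])^2)
      dd[self_idx] <- Inf
      j <- which.min(dd)
      edge_from <- c(edge_from, i)
      edge_to <- c(edge_to, rep_orig[j])
      edge_p[[length(edge_p) + 1L]] <- rbind(p1, p2)
      edge_mid[[length(edge_mid) + 1L]] <- c(mp[1L] %% W, mp[2L] %% H)
    }
  }

  mids <- do.call(rbind, edge_mid)
  key <- sprintf("%d|%d|%.3f|%.3f",
                 pmin(edge_from, edge_to), pmax(edge_from, edge_to),
                 round(mids[, 1L], 3L), round(mids[, 2L], 3L))
  keep <- !duplicated(key)
  edges <- edge_p[keep]
  edge_cells <- cbind(edge_from[keep], edge_to[keep])
  lens <- vapply(edges, function(e) sqrt(sum((e[2L, ] - e[1L, ])^2)), 0)
  tj_log("generate_monolayer: %d cells, %d edges, total length %.1f px",
         n_cells, length(edges), sum(lens))
  structure(list(domain_size = c(H, W), cell_seeds = seeds, edges = edges,
                 edge_cells = edge_cells, edge_lengths_px = lens,
                 total_length_px = sum(lens)),
            class = "tj_network")
}

#' @export
print.tj_network <- function(x, ...) {
  cat(sprintf("Monolayer network: %d cells, %d boundary edges, total %.1f px (%d x %d domain)\n",
              nrow(x$cell_seeds), length(x$edges), x$total_length_px,
              x$domain_size[1L], x$domain_size[2L]))
  invisible(x)
}

#' Fragment a monolayer boundary network
#'
#' Emulates junction breakdown by erasing gaps of fixed length, placed
#' uniformly at random along the boundary without overlap, until a fraction
#' `f` of the total boundary length is removed (overshoot at most one gap
#' length). Edges shorter than the gap length can be erased whole. `f = 0`
#' returns the network unchanged; `f = 1` removes everything. The retained
#' arcs and their true physical lengths are recorded as ground truth.
#'
#' @param network a `tj_network`.
#' @param f fraction of total boundary length to remove, in `[0, 1]`.
#' @param gap_length_px gap length in pixels (> 0, <= total length).
#' @param pixel_size um/px used for the ground-truth lengths.
#' @param rng_seed integer seed (optional).
#' @return An object of class `tj_fragnet`: `retained_arcs` (list of 2 x 2
#'   endpoint matrices), `removed_fraction_f` (requested), `removed_fraction`
#'   (achieved), `true_segment_lengths_um`, `pixel_size`, `domain_size`,
#'   `total_length_px`.
#' @export
fragment_network <- function(network, f, gap_length_px = 10, pixel_size = 0.5,
                             rng_seed = NULL) {
  stopifnot(inherits(network, "tj_network"))
  if (f < 0 || f > 1) stop_tj("'f' must be in [0, 1]")
  check_scalar_num(gap_length_px, "gap_length_px")
  lens <- network$edge_lengths_px
  L <- network$total_length_px
  if (gap_length_px > L) stop_tj("'gap_length_px' exceeds the total boundary length")

  ne <- length(lens)
  gaps <- vector("list", ne)
  whole <- logical(ne)
  removed <- 0
  if (f >= 1) {
    whole[] <- TRUE
    removed <- L
  } else if (f > 0) {
    target <- f * L
    with_seed(rng_seed, {
      tries <- 0L
      while (removed < target) {
        tries <- tries + 1L
        if (tries > 20000L) {
          stop_tj("gap placement stalled at removed fraction %.3f (target %.3f)",
                  removed / L, f)
        }
        e <- sample.int(ne, 1L, prob = lens)
        if (whole[e]) next
        le <- lens[e]
        if (le <= gap_length_px) {
          if (length(gaps[[e]])) next
          whole[e] <- TRUE
          removed <- removed + le
        } else {
          u <- stats::runif(1L, 0, le - gap_length_px)
          iv <- c(u, u + gap_length_px)
          overlap <- any(vapply(gaps[[e]], function(g) iv[1L] < g[2L] && g[1L] < iv[2L], TRUE))
          if (overlap) next
          gaps[[e]] <- c(gaps[[e]], list(iv))
          removed <- removed + gap_length_px
        }
      }
    })
  }

  arcs <- list(); arc_len <- numeric(0)
  for (e in seq_len(ne)) {
    if (whole[e]) next
    le <- lens[e]
    p1 <- network$edges[[e]][1L, ]; p2 <- network$edges[[e]][2L, ]
    ivs <- gaps[[e]]
    if (length(ivs)) {
      starts <- vapply(ivs, `[`, 0, 1L)
      o <- order(starts)
      cuts <- c(0, unlist(ivs[o]), le)
    } else {
      cuts <- c(0, le)
    }
    for (k in seq(1L, length(cuts) - 1L, by = 2L)) {
      a <- cuts[k]; b <- cuts[k + 1L]
      if (b - a < 1e-9) next
      q1 <- p1 + (a / le) * (p2 - p1)
      q2 <- p1 + (b / le) * (p2 - p1)
      arcs[[length(arcs) + 1L]] <- rbind(q1, q2)
      arc_len <- c(arc_len, b - a)
    }
  }
  tj_log("fragment_network: f = %.3g -> removed %.3f of %.1f px, %d retained arcs",
         f, removed / L, L, length(arcs))
  structure(list(retained_arcs = arcs, removed_fraction_f = f,
                 removed_fraction = removed / L,
                 retained_length_px = sum(arc_len),
                 true_segment_lengths_um = arc_len * pixel_size,
                 pixel_size = pixel_size,
                 domain_size = network$domain_size,
                 total_length_px = L),
            class = "tj_fragnet")
}

#' @export
print.tj_fragnet <- function(x, ...) {
  cat(sprintf("Fragmented network: f = %.3g (achieved %.3f), %d retained arcs, %.1f px retained\n",
              x$removed_fraction_f, x$removed_fraction,
              length(x$retained_arcs), x$retained_length_px))
  invisible(x)
}

#' Rendering parameters for the synthetic microscope
#'
#' The boundary network is rendered as a bright line of Gaussian cross-section
#' on a dark background, then blurred by a Gaussian point-spread function and
#' corrupted by per-frame sensor noise:
#' `intensity = background + peak_intensity * exp(-d^2 / (2 * ridge_width_px^2))`
#' with `d` the distance to the nearest retained arc.
#'
#' @param ridge_width_px Gaussian cross-section width of the membrane line, px.
#' @param peak_intensity line peak amplitude above background, counts.
#' @param background background level, counts.
#' @param psf_sigma_px optical blur sigma, px (0 disables blur).
#' @param noise_model `list(type = "gaussian", sd = ...)` or `list(type = "poisson")`.
#' @param n_frames frames in the output stack (>= 1), each with independent noise.
#' @param pixel_size um/px calibration of the rendered image.
#' @param rng_seed integer seed for the noise (optional).
#' @return A list of class `tj_render_params`.
#' @export
render_params <- function(ridge_width_px = 2, peak_intensity = 100,
                          background = 10, psf_sigma_px = 1,
                          noise_model = list(type = "gaussian", sd = 10),
                          n_frames = 3L, pixel_size = 0.5, rng_seed = NULL) {
  check_scalar_num(ridge_width_px, "ridge_width_px")
  check_scalar_num(peak_intensity, "peak_intensity")
  check_scalar_num(background, "background")
  check_scalar_num(psf_sigma_px, "psf_sigma_px", positive = FALSE)
  if (psf_sigma_px < 0) stop_tj("'psf_sigma_px' must be >= 0")
  if (n_frames < 1L) stop_tj("'n_frames' must be >= 1")
  if (!is.list(noise_model) || !noise_model$type %in% c("gaussian", "poisson", "none")) {
    stop_tj("'noise_model' must be list(type = 'gaussian', sd = ...), list(type = 'poisson') or list(type = 'none')")
  }
  check_scalar_num(pixel_size, "pixel_size")
  structure(list(ridge_width_px = ridge_width_px, peak_intensity = peak_intensity,
                 background = background, psf_sigma_px = psf_sigma_px,
                 noise_model = noise_model, n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, rng_seed = rng_seed),
            class = "tj_render_params")
}

# Distance from pixel centers to the nearest retained arc, computed per arc
# inside a padded bounding window (contributions beyond the pad are
# numerically negligible for the Gaussian line profile).
distance_map <- function(arcs, H, W, pad) {
  D <- matrix(Inf, H, W)
  for (arc in arcs) {
    x1 <- arc[1L, 1L]; y1 <- arc[1L, 2L]; x2 <- arc[2L, 1L]; y2 <- arc[2L, 2L]
    cmin <- max(1L, floor(min(x1, x2) - pad)); cmax <- min(W, ceiling(max(x1, x2) + pad))
    rmin <- max(1L, floor(min(y1, y2) - pad)); rmax <- min(H, ceiling(max(y1, y2) + pad))
    if (cmin > cmax || rmin > rmax) next
    rr <- rmin:rmax; cc <- cmin:cmax
    px <- matrix(cc - 0.5, length(rr), length(cc), byrow = TRUE)
    py <- matrix(rr - 0.5, length(rr), length(cc))
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1) else 0
    dmat <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
    D[rr, cc] <- pmin(D[rr, cc], dmat)
  }
  D
}

#' Render a fragmented network as a fluorescence image stack
#'
#' Rasterizes the retained arcs (with periodic wrap-around, so the cropped
#' field has no border bias), applies the optical blur, and adds independent
#' sensor noise to each frame. Deterministic for a fixed `rng_seed`.
#'
#' @param fragmented a `tj_fragnet`.
#' @param params a [render_params()] object.
#' @param image_id free-text identifier stored on the stack.
#' @return A list with `stack` (a `tj_stack`) and `truth` (data frame of the
#'   true retained segment lengths in px and um).
#' @export
render_image <- function(fragmented, params = render_params(), image_id = "synthetic") {
  stopifnot(inherits(fragmented, "tj_fragnet"), inherits(params, "tj_render_params"))
  H <- fragmented$domain_size[1L]; W <- fragmented$domain_size[2L]
  w <- params$ridge_width_px
  pad <- ceiling(4 * w) + 1
  # periodic replication of arcs so lines crossing the domain border render on both sides
  arcs <- list()
  for (ox in c(-W, 0, W)) {
    for (oy in c(-H, 0, H)) {
      for (a in fragmented$retained_arcs) {
        b <- a + matrix(c(ox, ox, oy, oy), 2L, 2L)
        if (max(b[, 1L]) < 1 - pad || min(b[, 1L]) > W + pad ||
            max(b[, 2L]) < 1 - pad || min(b[, 2L]) > H + pad) next
        arcs[[length(arcs) + 1L]] <- b
      }
    }
  }
  D <- distance_map(arcs, H, W, pad)
  clean <- params$background + params$peak_intensity * exp(-D^2 / (2 * w^2))
  if (params$psf_sigma_px > 0) {
    g <- gauss_kernels(params$psf_sigma_px)$g
    clean <- t(corr_cols(t(corr_cols(clean, g)), g))
  }
  frames <- with_seed(params$rng_seed, {
    lapply(seq_len(params$n_frames), function(k) {
      fr <- switch(params$noise_model$type,
        gaussian = clean + stats::rnorm(length(clean), sd = params$noise_model$sd),
        poisson = matrix(stats::rpois(length(clean), lambda = pmax(clean, 0)),
                         nrow(clean), ncol(clean)),
        none = clean
      )
      if (is.null(dim(fr))) fr <- matrix(fr, nrow(clean), ncol(clean))
      pmax(fr, 0)
    })
  })
  truth <- data.frame(
    segment = seq_along(fragmented$true_segment_lengths_um),
    length_px = fragmented$true_segment_lengths_um / fragmented$pixel_size,
    length_um = fragmented$true_segment_lengths_um
  )
  list(stack = image_stack(frames, params$pixel_size, channel_label = "ZO-1",
                           source_id = image_id),
       truth = truth)
}

#' Calibrated measurement settings for a known rendering model
#'
#' When the line rendering parameters are known (synthetic data), the
#' measurement chain can be configured from first principles rather than
#' data-driven thresholds: the detection scale is matched to the rendered
#' line's total cross-section sd (`sqrt(ridge_width^2 + psf_sigma^2)`, the
#' textbook scale for ridge detection), and the binarization threshold is set
#' to half the analytic peak ridge strength of that line. The half-maximum
#' contour of a line's end passes through the true arc endpoint, so this
#' threshold localizes segment ends without the systematic end-extension that
#' a low data-driven threshold produces on blurred line ends.
#'
#' @param params a [render_params()] object.
#' @return A list with `scale_sigma` and `threshold_value`, suitable for
#'   [quantify_junctions()] with `threshold_method = "fixed"`.
#' @export
ridge_calibration <- function(params) {
  stopifnot(inherits(params, "tj_render_params"))
  sg <- sqrt(params$ridge_width_px^2 + params$psf_sigma_px^2)
  thr <- line_ridge_strength(params$peak_intensity, params$ridge_width_px,
                             scale_sigma = sg,
                             psf_sigma = params$psf_sigma_px) / 2
  list(scale_sigma = sg, threshold_value = thr)
}

#' One-call synthetic ZO-1 experiment
#'
#' Convenience wrapper chaining [generate_monolayer()], [fragment_network()]
#' and [render_image()]. A single `seed` reproduces the whole image: the
#' geometry, fragmentation and noise seeds are derived from it by fixed
#' offsets, so each stage is independently reproducible.
#'
#' @param f fragmentation fraction in `[0, 1]`.
#' @param n_cells,domain_size,min_spacing_px see [generate_monolayer()].
#' @param gap_length_px see [fragment_network()].
#' @param params a [render_params()] object; its `rng_seed` is overridden by
#'   the derived noise seed.
#' @param seed master integer seed.
#' @param image_id identifier stored on the stack.
#' @return A list with `stack`, `truth`, `network` and `fragmented`.
#' @export
simulate_zo1 <- function(f = 0, n_cells = 80L, domain_size = c(256L, 256L),
                         min_spacing_px = NULL, gap_length_px = 10,
                         params = render_params(), seed = 1L,
                         image_id = sprintf("synthetic_f%.2f_seed%d", f, seed)) {
  net <- generate_monolayer(n_cells, domain_size, min_spacing_px,
                            rng_seed = seed)
  frag <- fragment_network(net, f, gap_length_px,
                           pixel_size = params$pixel_size,
                           rng_seed = seed + 500009L)
  params$rng_seed <- seed + 1000003L
  out <- render_image(frag, params, image_id = image_id)
  out$network <- net
  out$fragmented <- frag
  out
}
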