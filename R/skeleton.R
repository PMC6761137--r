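# Neighbor offsets in raster order; bit k of a 3x3 configuration code is set
# when the neighbor at (dr, dc) is foreground. Must match src/thin.cpp.
neighbor_offsets <- function() {
  cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
        dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
}

# Count connected components among a set of 3x3 ring cells (given as offset
# rows of neighbor_offsets()), under 8- or 4-adjacency between the cells.
ring_components <- function(cells, connectivity) {
  n <- nrow(cells)
  if (n == 0L) return(list(n = 0L, membership = integer(0)))
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- abs(cells[i, ] - cells[j, ])
        adj <- if (connectivity == 8L) max(d) == 1L else sum(d) == 1L
        if (adj && lab[j] < lab[i]) { lab[i] <- lab[j]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  list(n = length(unique(lab)), membership = lab)
}

# 256-entry lookup tables over 3x3 neighbor configuration codes:
#  - simple: deleting the (foreground) center preserves local topology, i.e.
#    the foreground ring cells form exactly one 8-connected component and the
#    background ring cells form exactly one 4-connected component touching an
#    orthogonal neighbor position (Rosenfeld's 2-D simple-point criterion);
#  - deletable: simple with 2..7 foreground neighbors (endpoints and isolated
#    pixels are never deleted), used by the thinning pass.
lut_env <- new.env(parent = emptyenv())

config_luts <- function() {
  if (!is.null(lut_env$deletable)) {
    return(list(simple = lut_env$simple, deletable = lut_env$deletable))
  }
  off <- neighbor_offsets()
  orth <- which(abs(off[, 1L]) + abs(off[, 2L]) == 1L)
  simple <- logical(256L)
  for (code in 0:255) {
    fg <- which(bitwAnd(code, bitwShiftL(1L, 0:7)) != 0L)
    bg <- setdiff(1:8, fg)
    if (length(fg) == 0L || length(bg) == 0L) next
    fg_ok <- ring_components(off[fg, , drop = FALSE], 8L)$n == 1L
    bgc <- ring_components(off[bg, , drop = FALSE], 4L)
    # exactly one background 4-component that is 4-adjacent to the center
    touch <- unique(bgc$membership[match(intersect(bg, orth), bg)])
    bg_ok <- length(touch) == 1L
    simple[code + 1L] <- fg_ok && bg_ok
  }
  nn <- vapply(0:255, function(code) sum(bitwAnd(code, bitwShiftL(1L, 0:7)) != 0L), 0L)
  lut_env$simple <- simple
  lut_env$deletable <- simple & nn >= 2L & nn <= 7L
  list(simple = lut_env$simple, deletable = lut_env$deletable)
}

# result[i, j] = M[i + dr, j + dc], FALSE outside the image.
shift_logical <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(FALSE, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  rs <- ri + dr; cs <- ci + dc
  keep_r <- rs >= 1L & rs <= nr
  keep_c <- cs >= 1L & cs <= nc
  out[ri[keep_r], ci[keep_c]] <- M[rs[keep_r], cs[keep_c]]
  out
}

# Ring order (N, NE, E, SE, S, SW, W, NW) as row indices of neighbor_offsets().
ring_order <- c(2L, 3L, 5L, 8L, 7L, 6L, 4L, 1L)

# Number of distinct branches leaving the center pixel, per 3x3 configuration
# code: the count of 0 -> 1 transitions in the circular ring sequence
# (the crossing number). A skeleton pixel is a junction point when three or
# more branches leave it.
branch_count_lut <- function() {
  if (!is.null(lut_env$branches)) return(lut_env$branches)
  lut_env$branches <- vapply(0:255, function(code) {
    bits <- bitwAnd(code, bitwShiftL(1L, 0:7)) != 0L
    ring <- bits[ring_order]
    s <- c(ring, ring[1L])
    sum(!s[-9L] & s[-1L])
  }, 0L)
  lut_env$branches
}

# Per-pixel 3x3 configuration code (0..255) and neighbor count.
neighbor_code <- function(M) {
  off <- neighbor_offsets()
  code <- matrix(0L, nrow(M), ncol(M))
  nn <- matrix(0L, nrow(M), ncol(M))
  for (k in 1:8) {
    s <- shift_logical(M, off[k, 1L], off[k, 2L])
    code <- code + bitwShiftL(1L, k - 1L) * s
    nn <- nn + s
  }
  list(code = code, nn = nn)
}

#' Skeletonize a binary mask
#'
#' Morphological thinning to 1-pixel-wide medial curves by sequential
#' simple-point deletion with endpoint preservation (four directional
#' sub-passes per iteration, repeated to convergence). Deleting only simple
#' points guarantees that the skeleton is a subset of the mask and preserves
#' the number of 8-connected components exactly; the result is deterministic
#' for a fixed input.
#'
#' @param mask a `tj_mask` (or logical matrix plus `pixel_size`).
#' @param pixel_size um/px, required when `mask` is a bare matrix.
#' @return An object of class `tj_skeleton`.
#' @export
skeletonize <- function(mask, pixel_size = NULL) {
  if (is.matrix(mask)) {
    if (is.null(pixel_size)) stop_tj("'pixel_size' is required for a bare matrix")
    mask <- binary_mask(mask, pixel_size)
  }
  stopifnot(inherits(mask, "tj_mask"))
  luts <- config_luts()
  sk <- .thin_cpp(mask$values, luts$deletable)
  tj_log("skeletonize: %d -> %d foreground px", sum(mask$values), sum(sk))
  structure(list(values = sk, pixel_size = mask$pixel_size), class = "tj_skeleton")
}

#' @export
print.tj_skeleton <- function(x, ...) {
  cat(sprintf("Skeleton: %d x %d px, %d skeleton px\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

skeleton_values <- function(x) {
  if (inherits(x, "tj_skeleton") || inherits(x, "tj_mask")) return(x$values)
  if (is.matrix(x) && is.logical(x)) return(x)
  stop_tj("expected a tj_skeleton, tj_mask or logical matrix")
}

#' Detect junction points of a skeleton
#'
#' Junction points are skeleton pixels from which three or more branches
#' leave: the circular sequence of their 8 neighbors (N, NE, ..., NW) shows
#' at least three background-to-foreground transitions, i.e. at least three
#' distinct 8-connected skeleton arms touch the pixel. (A plain neighbor
#' count would also flag the pixels orthogonally adjacent to a crossing,
#' because the arms' diagonal pixels inflate their counts.) The default
#' method evaluates the union of binary hit-or-miss matches over the
#' catalogue of all 3x3 neighborhood templates with three or more departing
#' branches: each pixel's full 3x3 configuration is encoded as an 8-bit code
#' and matched against the catalogue, which is exactly the union of the
#' per-template hit-or-miss transforms. `method = "count"` counts the ring
#' transitions directly from shifted copies of the image; the two must agree
#' on every input.
#'
#' @param skeleton a `tj_skeleton` (or `tj_mask`/logical matrix).
#' @param method `"hit-or-miss"` (default) or `"count"`.
#' @return An object of class `tj_junctions` with `coords`, an n x 2 matrix of
#'   (row, col) pixel coordinates in raster order.
#' @export
detect_junctions <- function(skeleton, method = c("hit-or-miss", "count")) {
  method <- match.arg(method)
  M <- skeleton_values(skeleton)
  hit <- if (method == "hit-or-miss") {
    nc <- neighbor_code(M)
    in_catalogue <- branch_count_lut() >= 3L
    M & matrix(in_catalogue[nc$code + 1L], nrow(M), ncol(M))
  } else {
    off <- neighbor_offsets()[ring_order, , drop = FALSE]
    rings <- lapply(1:8, function(k) shift_logical(M, off[k, 1L], off[k, 2L]))
    trans <- matrix(0L, nrow(M), ncol(M))
    for (k in 1:8) {
      nxt <- if (k == 8L) 1L else k + 1L
      trans <- trans + (!rings[[k]] & rings[[nxt]])
    }
    M & trans >= 3L
  }
  idx <- which(hit)
  r <- (idx - 1L) %% nrow(M) + 1L
  cc <- (idx - 1L) %/% nrow(M) + 1L
  o <- order(r, cc)
  coords <- cbind(row = r[o], col = cc[o])
  tj_log("detect_junctions[%s]: %d junction px", method, nrow(coords))
  structure(list(coords = coords), class = "tj_junctions")
}

#' @export
print.tj_junctions <- function(x, ...) {
  cat(sprintf("Junction set: %d junction pixel(s)\n", nrow(x$coords)))
  invisible(x)
}

#' Subtract junction points from a skeleton
#'
#' Removes the junction pixels, splitting the skeleton into its continuous
#' branches. Every junction coordinate must lie on the skeleton. The removed
#' junction positions are carried on the result (`junction_values`), so that
#' branch labeling can refuse diagonal adjacencies that merely shortcut
#' around a subtracted junction: two branch pixels that touch only at a
#' corner whose shared orthogonal neighbor was a junction are arms of
#' different branches, connected through the junction alone.
#'
#' @param skeleton a `tj_skeleton`.
#' @param junctions a `tj_junctions` from [detect_junctions()].
#' @return A `tj_mask` with exactly `sum(skeleton) - nrow(junctions)`
#'   foreground pixels and a `junction_values` field.
#' @export
remove_junctions <- function(skeleton, junctions) {
  stopifnot(inherits(junctions, "tj_junctions"))
  M <- skeleton_values(skeleton)
  out <- M
  jmat <- matrix(FALSE, nrow(M), ncol(M))
  if (nrow(junctions$coords)) {
    if (!all(M[junctions$coords])) {
      stop_tj("junction pixel not on the skeleton")
    }
    out[junctions$coords] <- FALSE
    jmat[junctions$coords] <- TRUE
  }
  ps <- if (is.list(skeleton)) skeleton$pixel_size else NA_real_
  res <- binary_mask(out, if (is.na(ps)) 1 else ps)
  res$junction_values <- jmat
  res
}

# 8-connected component labeling; labels are assigned in raster order (row-
# major) of each component's first pixel, so outputs are byte-identical
# across runs. Returns foreground indices, (row, col), and membership.
# `cut_diag_at` (optional logical matrix) marks subtracted junction pixels:
# a diagonal adjacency is dropped when one of its two shared orthogonal
# cells is such a pixel, so branches do not reconnect around a removed
# junction point.
label_components8 <- function(M, cut_diag_at = NULL) {
  idx <- which(M)
  n <- length(idx)
  if (!n) {
    return(list(idx = integer(0), row = integer(0), col = integer(0),
                membership = integer(0), n_components = 0L,
                edges = matrix(integer(0), 0, 2), diag_edge = logical(0)))
  }
  nr <- nrow(M); ncm <- ncol(M)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  pos <- integer(nr * ncm)
  pos[idx] <- seq_len(n)
  ef <- list(); et <- list(); ed <- list()
  shifts <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts[s, 1L]; dc <- shifts[s, 2L]
    r2 <- r + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncm
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- M[j]
    is_diag <- abs(dr) + abs(dc) == 2L
    keep <- rep(TRUE, sum(hit))
    if (is_diag && !is.null(cut_diag_at)) {
      ro <- r[ok][hit]; co <- cc[ok][hit]
      # shared orthogonal cells of the diagonal pair (ro,co)-(ro+dr,co+dc)
      a <- (co + dc - 1L) * nr + ro        # (ro, co+dc)
      b <- (co - 1L) * nr + (ro + dr)      # (ro+dr, co)
      keep <- !(cut_diag_at[a] | cut_diag_at[b])
    }
    ef[[s]] <- pos[idx[ok][hit]][keep]
    et[[s]] <- pos[j[hit]][keep]
    ed[[s]] <- rep(is_diag, sum(keep))
  }
  from <- unlist(ef); to <- unlist(et); diag_edge <- unlist(ed)
  g <- igraph::make_undirected_graph(rbind(from, to), n = n)
  memb <- igraph::components(g)$membership
  # relabel by raster order of each component's first pixel
  raster_key <- (r - 1) * as.double(ncm) + cc
  first_key <- vapply(split(raster_key, memb), min, 0)
  new_lab <- rank(first_key, ties.method = "first")
  memb <- as.integer(new_lab[memb])
  list(idx = idx, row = r, col = cc, membership = memb,
       n_components = max(memb),
       edges = cbind(from, to), diag_edge = diag_edge)
}

#' Measure skeleton branches as membrane segments
#'
#' Labels the 8-connected components of a junction-free skeleton remainder in
#' deterministic raster order, discards components shorter than
#' `min_branch_px` pixels, and reports each survivor as a continuous membrane
#' segment. The primary length is `pixel_count * pixel_size` (component size,
#' as a particle-analysis measurement of a 1-px skeleton); a secondary
#' geodesic length (orthogonal step 1, diagonal step sqrt(2), times pixel
#' size) is carried alongside for sensitivity analysis.
#'
#' @param branch_mask a `tj_mask` (junction-free skeleton remainder).
#' @param min_branch_px minimum component size in pixels (default 3);
#'   1-2 px fragments are dominated by skeletonization artifacts.
#' @param image_id free-text identifier stored on the result.
#' @return An object of class `tj_segments`: a list with `segments` (data
#'   frame of `segment_id`, `pixel_count`, `length_um`, `geodesic_um`),
#'   `coords` (list of n x 2 coordinate matrices), `image_id`, `pixel_size`
#'   and `discarded_px` (pixels in components below `min_branch_px`).
#' @export
measure_branches <- function(branch_mask, min_branch_px = 3L, image_id = "") {
  stopifnot(inherits(branch_mask, "tj_mask"))
  if (min_branch_px < 1L) stop_tj("'min_branch_px' must be >= 1")
  lab <- label_components8(branch_mask$values, cut_diag_at = branch_mask$junction_values)
  ps <- branch_mask$pixel_size
  if (lab$n_components == 0L) {
    seg <- data.frame(segment_id = integer(0), pixel_count = integer(0),
                      length_um = numeric(0), geodesic_um = numeric(0))
    return(structure(list(segments = seg, coords = list(), image_id = image_id,
                          pixel_size = ps, discarded_px = 0L),
                     class = "tj_segments"))
  }
  sizes <- tabulate(lab$membership, nbins = lab$n_components)
  # geodesic steps per component, from the adjacency edges
  comp_of_edge <- lab$membership[lab$edges[, 1L]]
  n_orth <- tabulate(comp_of_edge[!lab$diag_edge], nbins = lab$n_components)
  n_diag <- tabulate(comp_of_edge[lab$diag_edge], nbins = lab$n_components)
  keep <- which(sizes >= min_branch_px)
  discarded <- sum(sizes[-keep]) # sizes[integer(0)] when all kept
  if (!length(keep)) discarded <- sum(sizes)
  o <- keep[order(keep)] # raster labeling already ordered
  seg <- data.frame(
    segment_id = seq_along(o),
    pixel_count = sizes[o],
    length_um = sizes[o] * ps,
    geodesic_um = (n_orth[o] + sqrt(2) * n_diag[o]) * ps
  )
  coords <- lapply(o, function(cid) {
    sel <- lab$membership == cid
    ord <- order(lab$row[sel], lab$col[sel])
    cbind(row = lab$row[sel][ord], col = lab$col[sel][ord])
  })
  tj_log("measure_branches: %d segment(s), %d px discarded (< %d px)",
         length(o), discarded, min_branch_px)
  structure(list(segments = seg, coords = coords, image_id = image_id,
                 pixel_size = ps, discarded_px = as.integer(discarded)),
            class = "tj_segments")
}

#' @export
print.tj_segments <- function(x, ...) {
  n <- nrow(x$segments)
  cat(sprintf("Segment set: %d segment(s)", n))
  if (n) {
    cat(sprintf(", total %.2f um, median %.2f um",
                sum(x$segments$length_um), stats::median(x$segments$length_um)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.tj_segments <- function(x, ...) {
  df <- x$segments
  df$image_id <- rep(x$image_id, nrow(df))
  df
}
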