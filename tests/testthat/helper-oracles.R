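# Independent brute-force oracles used to verify the package's vectorized /
# table-driven implementations. Kept deliberately naive: per-pixel loops,
# direct class-mean computations, full permutation enumeration.

# number of distinct branches leaving (r, c): 0 -> 1 transitions around the
# circular 8-neighbor ring, read off the matrix one neighbor at a time
oracle_branch_count <- function(M, r, c) {
  ring <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  vals <- vapply(ring, function(d) {
    rr <- r + d[1L]; cc <- c + d[2L]
    if (rr < 1L || cc < 1L || rr > nrow(M) || cc > ncol(M)) FALSE else M[rr, cc]
  }, TRUE)
  s <- c(vals, vals[1L])
  sum(!s[-9L] & s[-1L])
}

oracle_junction_matrix <- function(M) {
  out <- matrix(FALSE, nrow(M), ncol(M))
  for (r in seq_len(nrow(M))) {
    for (c in seq_len(ncol(M))) {
      if (M[r, c] && oracle_branch_count(M, r, c) >= 3L) out[r, c] <- TRUE
    }
  }
  out
}

junctions_as_matrix <- function(j, dims) {
  m <- matrix(FALSE, dims[1L], dims[2L])
  if (nrow(j$coords)) m[j$coords] <- TRUE
  m
}

# exhaustive Otsu search: quantize values to their 256-bin index by direct
# comparison, then try every candidate split and compute class means directly
oracle_otsu <- function(v) {
  v <- as.numeric(v)
  nb <- 256L
  edges <- seq(min(v), max(v), length.out = nb + 1L)
  q <- vapply(v, function(x) {
    b <- 1L
    while (b < nb && x >= edges[b + 1L]) b <- b + 1L
    b
  }, 0L)
  best <- -Inf; bestk <- 1L
  for (k in seq_len(nb - 1L)) {
    lo <- q[q <= k]; hi <- q[q > k]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; bestk <- k }
  }
  edges[bestk + 1L]
}

# full permutation enumeration of the rank-sum null distribution
oracle_mann_whitney <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  idx <- utils::combn(length(pooled), n_a)
  U <- colSums(matrix(r[idx], n_a)) - n_a * (n_a + 1) / 2
  C <- ncol(idx)
  list(u = u_obs,
       p = min(1, 2 * min(sum(U <= u_obs + 1e-9), sum(U >= u_obs - 1e-9)) / C))
}

# 8-connected component count by breadth-first search
oracle_component_count <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!M[r0, c0] || seen[r0, c0]) next
      count <- count + 1L
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1L] + dr; cc <- p[2L] + dc
          if ((dr || dc) && rr >= 1L && cc >= 1L && rr <= nr && cc <= nc &&
              M[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  count
}

# random blob masks: unions of discs on an empty field
random_blob_mask <- function(nr, nc, n_blobs = 5L, rmax = 4) {
  M <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_blobs)) {
    r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc); rad <- runif(1, 1, rmax)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    M <- M | ((rows - r0)^2 + (cols - c0)^2 <= rad^2)
  }
  M
}

# sparse random masks used as stand-in "skeletons" for junction detection
random_sparse_mask <- function(nr, nc, p = 0.25) {
  matrix(runif(nr * nc) < p, nr, nc)
}

make_plus <- function(arm = 5L) {
  n <- 2L * arm + 1L
  m <- matrix(FALSE, n, n)
  m[arm + 1L, ] <- TRUE
  m[, arm + 1L] <- TRUE
  m
}
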