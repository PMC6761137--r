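no_2x2_block <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  if (nr < 2L || nc < 2L) return(TRUE)
  blocks <- M[-nr, -nc] & M[-1L, -nc] & M[-nr, -1L] & M[-1L, -1L]
  !any(blocks)
}

test_that("skeletonization thins a bar to a single spanning curve", {
  m <- matrix(FALSE, 10, 26); m[4:6, 4:23] <- TRUE
  sk <- skeletonize(m, 0.5)
  expect_true(all(m[sk$values])) # subset of the mask
  expect_true(no_2x2_block(sk$values))
  expect_equal(oracle_component_count(sk$values), 1L)
  cols <- range(which(sk$values, arr.ind = TRUE)[, 2])
  expect_equal(cols, c(4L, 23L)) # spans the bar's extent
  expect_equal(nrow(detect_junctions(sk)$coords), 0L)
})

test_that("a single pixel and an empty mask are fixed points", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  expect_identical(skeletonize(m, 1)$values, m)
  expect_identical(skeletonize(matrix(FALSE, 5, 5), 1)$values, matrix(FALSE, 5, 5))
})

test_that("thinning preserves component count, subset and thinness on random blobs", {
  set.seed(77)
  for (i in 1:50) {
    M <- random_blob_mask(32, 32, n_blobs = sample(2:7, 1))
    sk <- skeletonize(M, 0.4)$values
    expect_true(all(M[sk]))
    expect_true(no_2x2_block(sk))
    expect_equal(oracle_component_count(sk), oracle_component_count(M))
  }
})

test_that("junction detection matches the branch-count oracle on all 512 neighborhoods", {
  for (code in 0:511) {
    bits <- as.logical(bitwAnd(code, bitwShiftL(1L, 0:8)) != 0L)
    M <- matrix(bits, 3, 3)
    hm <- junctions_as_matrix(detect_junctions(M), c(3, 3))
    ct <- junctions_as_matrix(detect_junctions(M, method = "count"), c(3, 3))
    br <- oracle_junction_matrix(M)
    expect_identical(hm, br)
    expect_identical(ct, br)
  }
})

test_that("junction detection matches the oracle on random sparse skeletons", {
  set.seed(101)
  for (i in 1:200) {
    M <- random_sparse_mask(24, 24, p = runif(1, 0.1, 0.4))
    hm <- junctions_as_matrix(detect_junctions(M), c(24, 24))
    ct <- junctions_as_matrix(detect_junctions(M, method = "count"), c(24, 24))
    expect_identical(hm, oracle_junction_matrix(M))
    expect_identical(hm, ct)
  }
})

test_that("a plus shape yields one junction and four clean branches", {
  plus <- make_plus(5L) # 21 px: 4 arms of 5 and a center
  sk <- skeletonize(plus, 0.2)
  expect_identical(sk$values, plus) # already thin
  j <- detect_junctions(sk)
  expect_equal(nrow(j$coords), 1L)
  expect_equal(unname(j$coords[1, ]), c(6L, 6L))

  branches <- remove_junctions(sk, j)
  expect_equal(sum(branches$values), 20L)
  segs <- measure_branches(branches, min_branch_px = 1)
  expect_equal(nrow(segs$segments), 4L)
  expect_equal(segs$segments$pixel_count, rep(5L, 4))
  expect_equal(segs$segments$length_um, rep(1.0, 4)) # 5 px at 0.2 um/px
})

test_that("a straight line has no junctions and one branch; a loop one segment", {
  m <- matrix(FALSE, 5, 20); m[3, 2:19] <- TRUE
  j <- detect_junctions(m)
  expect_equal(nrow(j$coords), 0L)
  segs <- measure_branches(remove_junctions(skeletonize(m, 0.5), j), 1)
  expect_equal(nrow(segs$segments), 1L)
  expect_equal(segs$segments$pixel_count, 18L)

  L <- matrix(FALSE, 12, 12)
  L[3, 3:10] <- TRUE; L[10, 3:10] <- TRUE; L[3:10, 3] <- TRUE; L[3:10, 10] <- TRUE
  skl <- skeletonize(L, 0.5)
  jl <- detect_junctions(skl)
  expect_equal(nrow(jl$coords), 0L)
  sl <- measure_branches(remove_junctions(skl, jl), 1)
  expect_equal(nrow(sl$segments), 1L)
})

test_that("junction subtraction is exact set subtraction with consistency checks", {
  plus <- make_plus(5L)
  sk <- skeletonize(plus, 0.2)
  j <- detect_junctions(sk)
  out <- remove_junctions(sk, j)
  expect_equal(sum(out$values), sum(sk$values) - nrow(j$coords))

  none <- structure(list(coords = matrix(integer(0), 0, 2,
                                         dimnames = list(NULL, c("row", "col")))),
                    class = "tj_junctions")
  expect_identical(remove_junctions(sk, none)$values, sk$values)

  bad <- structure(list(coords = cbind(row = 1L, col = 1L)), class = "tj_junctions")
  expect_error(remove_junctions(sk, bad), "not on the skeleton")
})

test_that("pixel bookkeeping is conserved on random skeletons", {
  set.seed(303)
  for (i in 1:50) {
    M <- skeletonize(random_blob_mask(40, 40, n_blobs = 6, rmax = 6), 0.5)
    j <- detect_junctions(M)
    branches <- remove_junctions(M, j)
    for (mbp in c(1L, 3L, 6L)) {
      segs <- measure_branches(branches, min_branch_px = mbp)
      expect_equal(sum(M$values),
                   nrow(j$coords) + sum(segs$segments$pixel_count) + segs$discarded_px)
    }
    # monotonicity: larger min_branch_px never yields more segments
    n_by_mbp <- vapply(c(1L, 2L, 4L, 8L), function(mbp) {
      nrow(measure_branches(branches, mbp)$segments)
    }, 0L)
    expect_true(all(diff(n_by_mbp) <= 0))
  }
})

test_that("branch labeling is deterministic and raster-ordered", {
  m <- matrix(FALSE, 9, 9)
  m[8, 1:3] <- TRUE; m[2, 5:8] <- TRUE; m[5, 2:4] <- TRUE
  s1 <- measure_branches(binary_mask(m, 1), 1)
  s2 <- measure_branches(binary_mask(m, 1), 1)
  expect_identical(s1$segments, s2$segments)
  firsts <- t(vapply(s1$coords, function(xy) xy[1, ], c(row = 0L, col = 0L)))
  expect_true(all(diff(order(firsts[, "row"], firsts[, "col"])) > 0))
  expect_equal(unname(firsts[1, "row"]), 2L) # top-most component labeled first
})
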