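test_that("length histograms bin half-open intervals and track exclusions", {
  h <- length_histogram(c(0.5, 1.5, 1.5, 9.0), c(0, 1, 2, 10))
  expect_equal(h$counts, c(1L, 2L, 1L))
  expect_equal(h$n_excluded, 0L)

  h2 <- length_histogram(c(-1, 0, 1, 2, 10, 11), c(0, 1, 2, 10))
  expect_equal(h2$counts, c(1L, 1L, 1L)) # 0, 1, 2 binned; -1, 10, 11 outside
  expect_equal(h2$n_excluded, 3L)

  empty <- measure_branches(binary_mask(matrix(FALSE, 4, 4), 1))
  expect_equal(length_histogram(empty, c(0, 5, 10))$counts, c(0L, 0L))
  expect_error(length_histogram(1:3, c(1, 1, 2)), "strictly increasing")
})

test_that("histogram counts match a per-value linear scan", {
  set.seed(13)
  lens <- runif(1000, 0, 30)
  edges <- c(0, sort(runif(8, 1, 25)), 30)
  h <- length_histogram(lens, edges)
  manual <- integer(length(edges) - 1L)
  for (x in lens) {
    for (b in seq_len(length(edges) - 1L)) {
      if (x >= edges[b] && x < edges[b + 1L]) manual[b] <- manual[b] + 1L
    }
  }
  expect_equal(h$counts, manual)
  expect_equal(h$n_total, sum(manual))
})

test_that("large-segment counts use strict inequalities", {
  expect_equal(large_segment_count(c(1, 2, 10, 12), 5, 20), 2L)
  expect_equal(large_segment_count(c(1, 2, 10, 12), 0, 1e9), 4L)
  expect_equal(large_segment_count(c(5, 20), 5, 20), 0L) # bounds excluded
  expect_error(large_segment_count(1:3, 5, 5), "x < y")
  set.seed(17)
  lens <- runif(500, 0, 50)
  expect_equal(large_segment_count(lens, 10, 30), sum(lens > 10 & lens < 30))
})

test_that("histogram counts over aligned bins reproduce the large-segment count", {
  set.seed(19)
  lens <- runif(400, 0, 40)
  x <- 5; y <- 20
  edges <- c(0, x, 10, 15, y, 40)
  h <- length_histogram(lens, edges)
  inside <- which(edges[-length(edges)] >= x & edges[-1] <= y)
  # strict vs half-open: values equal to x fall in the first inside bin,
  # values equal to y are outside; continuous lengths make ties measure-zero
  expect_equal(sum(h$counts[inside]), large_segment_count(lens, x, y))
})

test_that("Mann-Whitney exact p-values match known small cases", {
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$u_statistic, 0)
  expect_equal(t1$p_value, 0.1)
  expect_equal(t1$method, "exact")

  # mirrored groups: U maps to n_a*n_b - U with the same p
  t2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(t2$u_statistic, 9)
  expect_equal(t2$p_value, 0.1)

  # interleaved groups: U = 6 (ranks 1,3,5,7), p from the exact null = 48/70
  t3 <- mann_whitney(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  o3 <- oracle_mann_whitney(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  expect_equal(t3$u_statistic, 6)
  expect_equal(t3$u_statistic, o3$u)
  expect_equal(t3$p_value, o3$p)

  # a perfectly central U gives p = 1
  t4 <- mann_whitney(c(1, 4, 6, 7), c(2, 3, 5, 8))
  expect_equal(t4$u_statistic, 8)
  expect_equal(t4$p_value, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact p-values equal full permutation enumeration on random inputs", {
  set.seed(23)
  for (i in 1:60) {
    n_a <- sample(2:7, 1); n_b <- sample(2:7, 1)
    repeat {
      a <- round(rnorm(n_a, 0, 10), 3)
      b <- round(rnorm(n_b, 1, 10), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    got <- mann_whitney(a, b)
    want <- oracle_mann_whitney(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$u_statistic, want$u)
    expect_equal(got$p_value, want$p)
  }
})

test_that("ties fall back to the corrected normal approximation", {
  t_all_tied <- mann_whitney(c(3, 3, 3), c(3, 3, 3))
  expect_equal(t_all_tied$method, "normal-approx")
  expect_equal(t_all_tied$p_value, 1)

  set.seed(29)
  a <- sample(1:5, 8, TRUE); b <- sample(1:5, 8, TRUE)
  got <- mann_whitney(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("compare_conditions tests per-image large-segment counts", {
  seg_list <- function(lens_list) lapply(lens_list, identity)
  cmp <- compare_conditions(seg_list(list(c(12, 8), c(14, 9), c(13, 7))),
                            seg_list(list(2, 3, 1)), x = 5, y = 20)
  # per-image counts: A = 2,2,2 (both lengths inside (5,20)), B = 0,0,0
  expect_equal(unname(cmp$group_a_values), c(2L, 2L, 2L))
  expect_equal(unname(cmp$group_b_values), c(0L, 0L, 0L))
  expect_equal(cmp$method, "normal-approx") # tied counts

  # count-valued groups reproducing the U = 0 textbook case
  cmp2 <- compare_conditions(list(12, 14, 13), list(2, 3, 1), x = 0, y = 1e6)
  expect_equal(unname(cmp2$group_a_values), c(1L, 1L, 1L))
  expect_error(compare_conditions(list(), list(1)), "at least one image")
})
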