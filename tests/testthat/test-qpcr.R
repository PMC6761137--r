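make_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], condition = r[[2]], gene = r[[3]],
               ct = as.numeric(r[[4]]))
  }))
}

triplicate <- function(sample, condition, gene, cts) {
  data.frame(sample_id = sample, condition = condition, gene = gene, ct = cts)
}

test_that("delta-Ct is the difference of replicate means", {
  tab <- rbind(triplicate("s1", "control", "Gpx", c(24, 24, 24)),
               triplicate("s1", "control", "Actin", c(20, 20, 20)))
  d <- delta_ct(tab, "s1", "Gpx")
  expect_equal(as.numeric(d), 4)
  expect_equal(attr(d, "target_mean"), 24)
  expect_equal(attr(d, "reference_sd"), 0)

  same <- rbind(triplicate("s1", "control", "Gpx", c(21, 22, 23)),
                triplicate("s1", "control", "Actin", c(21, 22, 23)))
  expect_equal(as.numeric(delta_ct(same, "s1", "Gpx")), 0)

  set.seed(8)
  for (i in 1:20) {
    t_ct <- runif(3, 15, 35); r_ct <- runif(3, 15, 35)
    tab <- rbind(triplicate("s", "c", "g", t_ct), triplicate("s", "c", "Actin", r_ct))
    expect_equal(as.numeric(delta_ct(tab, "s", "g")), mean(t_ct) - mean(r_ct))
  }
  expect_error(delta_ct(triplicate("s1", "c", "Gpx", c(24, 24, 24)), "s1", "Gpx"),
               "reference gene")
})

test_that("relative expression is 2 to the minus delta-delta-Ct", {
  expect_equal(relative_expression(4, 4), 1)
  expect_equal(relative_expression(3, 4), 2)
  expect_equal(relative_expression(7, 4), 0.125)
  expect_error(relative_expression(NA_real_, 1), "finite")
})

test_that("expression reports normalize to the control condition", {
  tab <- rbind(
    triplicate("c1", "control", "Inos", c(26, 26, 26)),
    triplicate("c1", "control", "Actin", c(20, 20, 20)),
    triplicate("t1", "treated", "Inos", c(24, 24, 24)),
    triplicate("t1", "treated", "Actin", c(20, 20, 20))
  )
  rep_ <- expression_report(tab, "control")
  inos <- rep_[rep_$gene == "Inos", ]
  expect_equal(inos$relative_expression[inos$condition == "control"], 1)
  expect_equal(inos$relative_expression[inos$condition == "treated"], 4) # dCt 4 vs 6
  # the reference gene is exactly 1 everywhere
  expect_equal(rep_[rep_$gene == "Actin", "relative_expression"], c(1, 1))

  expect_error(expression_report(tab, "mock"), "control condition")
})

test_that("fold changes are shift-invariant and log-linear", {
  set.seed(88)
  genes <- c("Il6", "Catalase")
  build <- function(shift_s2 = 0, il6_drop = 0) {
    rbind(
      triplicate("s1", "control", "Actin", rnorm(3, 20, 0.1)),
      triplicate("s1", "control", "Il6", rnorm(3, 25, 0.1)),
      triplicate("s1", "control", "Catalase", rnorm(3, 27, 0.1)),
      triplicate("s2", "treated", "Actin", rnorm(3, 21, 0.1) + shift_s2),
      triplicate("s2", "treated", "Il6", rnorm(3, 23, 0.1) + shift_s2 - il6_drop),
      triplicate("s2", "treated", "Catalase", rnorm(3, 27.5, 0.1) + shift_s2)
    )
  }
  set.seed(99); base <- build()
  set.seed(99); shifted <- build(shift_s2 = 3)
  r1 <- expression_report(base, "control")
  r2 <- expression_report(shifted, "control")
  expect_equal(r1$relative_expression, r2$relative_expression, tolerance = 1e-12)

  set.seed(99); dropped <- build(il6_drop = 1) # one cycle earlier = doubled template
  r3 <- expression_report(dropped, "control")
  sel <- r3$gene == "Il6" & r3$condition == "treated"
  expect_equal(r3$relative_expression[sel], 2 * r1$relative_expression[sel],
               tolerance = 1e-12)
})

test_that("reports match an independent two-pass recomputation on random tables", {
  set.seed(123)
  genes <- c("Kir4.1", "Aqp1", "Il8")
  tab <- do.call(rbind, lapply(c("c1", "c2", "t1", "t2"), function(s) {
    cond <- if (startsWith(s, "c")) "control" else "treated"
    do.call(rbind, lapply(c(genes, "Actin"), function(g) {
      triplicate(s, cond, g, runif(3, 18, 32))
    }))
  }))
  rep_ <- expression_report(tab, "control")
  for (g in genes) {
    dct <- sapply(c("c1", "c2", "t1", "t2"), function(s) {
      mean(tab$ct[tab$sample_id == s & tab$gene == g]) -
        mean(tab$ct[tab$sample_id == s & tab$gene == "Actin"])
    })
    ctrl <- mean(dct[c("c1", "c2")])
    for (s in names(dct)) {
      got <- rep_$relative_expression[rep_$gene == g & rep_$sample_id == s]
      expect_equal(got, 2^-(dct[[s]] - ctrl), tolerance = 1e-12)
    }
  }
})

test_that("Ct tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(triplicate("s1", "control", "Actin", c(20, 20, 20)), path, row.names = FALSE)
  tab <- read_ct_table(path)
  expect_s3_class(tab, "ct_table")
  bad <- triplicate("s1", "control", "Actin", c(20, -1, 20))
  expect_error(ct_table(bad), "finite and positive")
  expect_error(ct_table(data.frame(a = 1)), "lacks column")
})
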