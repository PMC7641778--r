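test_that("cumulative QF is the sum over the closed post window", {
  w <- analysis_window("2020-05-01", "2020-05-25", "2020-06-03")
  s <- make_series(rep(0, 40), start = "2020-05-01")
  expect_equal(cumulative_qf(s, w), 0)
  vals <- rep(0, 40); vals[25:34] <- 1:10   # event day through +9
  s2 <- make_series(vals, start = "2020-05-01")
  expect_equal(cumulative_qf(s2, w), 55)
  short <- make_series(rep(1, 30), start = "2020-05-01")
  expect_error(cumulative_qf(short, w), "cover every day")
})

test_that("ranking reproduces the fold and percent-below-mean identities", {
  # division identities implied by the published contrasts:
  # QF 7300 against a mean of 1738.1 is 4.20-fold; 783 against 1740 is 55% below
  expect_equal(7300 / 1738.1, 4.2, tolerance = 5e-4)
  qfs <- c(DC = 7300, A = 100, B = 100)
  m <- make_panel(matrix(qfs, 3, 1, dimnames = list(names(qfs), "reform")))
  rk <- rank_states(m, "reform")
  expect_equal(rk$fold[rk$geography == "DC"], 7300 / mean(qfs))
  expect_equal(rk$rank, c(1L, 2L, 2L))  # ties share the min rank

  qf2 <- c(AR = 783, X = 2697)  # mean 1740
  m2 <- make_panel(matrix(qf2, 2, 1, dimnames = list(names(qf2), "reform")))
  rk2 <- rank_states(m2, "reform")
  expect_equal(rk2$pct_below_mean[rk2$geography == "AR"],
               (1 - 783 / 1740) * 100)
  expect_equal((1 - 783 / 1740) * 100, 55, tolerance = 1e-2)

  # equal panel: every fold is 1 under both comparison conventions
  m3 <- make_panel(matrix(5, 4, 1, dimnames = list(letters[1:4], "reform")))
  expect_true(all(rank_states(m3, "reform")$fold == 1))
  expect_true(all(rank_states(m3, "reform", "exclude_focal")$fold == 1))
  # rankings are invariant to a common rescaling
  rk_a <- rank_states(m, "reform")
  m_scaled <- make_panel(matrix(qfs * 3, 3, 1,
                                dimnames = list(names(qfs), "reform")))
  expect_equal(rank_states(m_scaled, "reform")$fold, rk_a$fold)
})

test_that("topic shares normalize rows and identify leaders", {
  qf <- matrix(c(370, 400, 180, 50,
                 100,   0,   0,  0,
                  25,  25,  25, 25),
               3, 4, byrow = TRUE,
               dimnames = list(c("AK", "B", "C"),
                               c("union", "training", "immunity",
                                 "militarization")))
  sh <- topic_shares(make_panel(qf))
  # 37% union share means 37% of the four-topic total was for union
  expect_equal(sh$shares["AK", "union"], 0.37)
  expect_equal(unname(rowSums(sh$shares)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(sh$leading["AK"]), "training")
  expect_equal(unname(sh$shares["B", ]), c(1, 0, 0, 0))
  expect_equal(unname(sh$leading["B"]), "union")
  expect_true(is.na(sh$leading["C"]))          # 4-way tie
  expect_equal(sh$ties$C, colnames(qf))
  # shares are invariant to rescaling a geography's row
  sh2 <- topic_shares(make_panel(qf * 10))
  expect_equal(sh2$shares, sh$shares)

  qf0 <- qf; qf0["B", ] <- 0
  expect_error(topic_shares(make_panel(qf0)), "zero total")
})

test_that("leading topic tally counts winners and reports ties", {
  qf <- matrix(c(10, 5, 1, 1,
                  9, 4, 1, 1,
                  8, 3, 1, 1,
                  2, 2, 1, 1),
               4, 4, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"),
                               c("training", "union", "immunity",
                                 "militarization")))
  tl <- leading_topic_tally(topic_shares(make_panel(qf)))
  expect_equal(tl$counts[["training"]], 3L)
  expect_equal(tl$counts[["union"]], 0L)
  expect_equal(tl$n_ties, 1L)
  expect_equal(sum(tl$counts) + tl$n_ties, 4L)
  expect_equal(tl$mean_leading_share[["training"]],
               mean(c(10 / 17, 9 / 15, 8 / 13)))
  expect_true(is.na(tl$mean_leading_share[["union"]]))
})

test_that("ICC equals the brute-force ANOVA oracle on random panels", {
  set.seed(70)
  for (rep in 1:20) {
    m <- matrix(rlnorm(20), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("t", 1:4)))
    expect_equal(icc(m, transform = "raw"), icc_anova_oracle(m),
                 tolerance = 1e-12)
  }
})

test_that("ICC limiting cases behave", {
  m <- matrix(rep(c(1, 5, 9), each = 4), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("t", 1:4)))
  expect_equal(icc(m, transform = "raw"), 1)        # no within-row variance
  set.seed(71)
  big <- matrix(rnorm(800), 200, 4,
                dimnames = list(paste0("g", 1:200), paste0("t", 1:4)))
  expect_lt(abs(icc(big, transform = "raw")), 0.1)  # iid cells: ICC ~ 0
  expect_lt(abs(icc(big, transform = "rank")), 0.1)
  expect_error(icc(matrix(1, 3, 3), transform = "raw"), "zero total variance")
})

test_that("group contrast computes the bottom-vs-top percentage", {
  qf <- matrix(c(4, 4, 1, 1), 4, 2,
               dimnames = list(c("hi1", "hi2", "lo1", "lo2"),
                               c("t1", "t2")))
  gc <- group_contrast(make_panel(qf), k = 2, B = 200, seed = 1)
  expect_equal(gc$percent_lower, 75)               # bottom mean 1, top mean 4
  expect_setequal(gc$top, c("hi1", "hi2"))
  # identical groups: contrast 0 and the CI contains it
  qf2 <- matrix(2, 4, 2, dimnames = dimnames(qf))
  gc2 <- group_contrast(make_panel(qf2), k = 2, B = 200, seed = 1)
  expect_equal(gc2$percent_lower, 0)
  expect_true(gc2$ci[1] <= 0 && 0 <= gc2$ci[2])
  expect_identical(gc2$ci,
                   group_contrast(make_panel(qf2), k = 2, B = 200, seed = 1)$ci)
  expect_error(group_contrast(make_panel(qf), k = 3), "too large")
})
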