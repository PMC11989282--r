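test_that("Clopper-Pearson bounds hit the closed-form boundary cases", {
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson(10, 10)[2]), 100)
  # 0/1: upper bound is 1 - (alpha/2)^(1/n) = 97.5%
  ci <- clopper_pearson(0, 1)
  expect_equal(unname(ci[2]), 97.5)
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(clopper_pearson(1, 2, alpha = 1.5), "alpha")
})

test_that("Clopper-Pearson agrees with the exact binomial test interval", {
  set.seed(160)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    x <- sample(0:n, 1)
    want <- 100 * binom.test(x, n)$conf.int
    got <- clopper_pearson(x, n)
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-10)
    # interval contains the point estimate
    expect_true(got[1] <= 100 * x / n && 100 * x / n <= got[2])
  }
  # bounds monotone in x
  lo <- vapply(0:30, function(x) clopper_pearson(x, 30)[1], numeric(1))
  hi <- vapply(0:30, function(x) clopper_pearson(x, 30)[2], numeric(1))
  expect_true(all(diff(lo) >= 0))
  expect_true(all(diff(hi) >= 0))
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(161)
  x <- rbinom(10000, 30, 0.5)
  cis <- vapply(x, function(xi) clopper_pearson(xi, 30), numeric(2))
  covered <- cis[1, ] <= 50 & 50 <= cis[2, ]
  expect_gte(mean(covered), 0.95)
})

test_that("response summary reproduces ITT rates on a 30-patient split", {
  resp <- c(rep("CR", 4), rep("PR", 11), rep("SD", 8), rep("PD", 7))
  co <- data.frame(response = resp)
  rs <- response_summary(co)
  expect_equal(rs$orr, 50)
  expect_equal(round(rs$dcr, 1), 76.7)
  expect_equal(round(unname(rs$orr_ci), 1), c(31.3, 68.7))
  # NE counts in the denominator only
  co2 <- data.frame(response = c(rep("CR", 3), "NE"))
  rs2 <- response_summary(co2)
  expect_equal(rs2$orr, 75)
  expect_error(response_summary(co, subset = rep(FALSE, 30)), "empty")
  rs3 <- response_summary(data.frame(response = rep("CR", 5)))
  expect_equal(rs3$orr, 100)
  expect_equal(unname(rs3$orr_ci[2]), 100)
})

test_that("Barnard's test handles symmetric and degenerate tables", {
  expect_equal(barnard_test(c(5, 5, 5, 5)), 1)
  expect_equal(barnard_test(c(0, 0, 3, 1)), 1)   # empty group
  expect_equal(barnard_test(c(2, 2, 2, 2)), 1)
  p <- barnard_test(c(0, 4, 3, 1))
  expect_true(p > 0 && p <= 1)
  expect_equal(p, oracle_barnard(0, 4, 3, 1), tolerance = 1e-12)
})

test_that("Fisher's exact test matches the hypergeometric oracle", {
  expect_equal(fisher_exact(c(1, 0, 0, 1)), 1)
  expect_equal(fisher_exact(c(10, 0, 0, 10)), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(fisher_exact(c(3, 0, 0, 0)), 1)  # degenerate margin
  set.seed(170)
  for (i in 1:30) {
    t <- sample(0:8, 4, replace = TRUE)
    p <- fisher_exact(t)
    expect_equal(p, oracle_fisher(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-9)
    # transposition invariance
    m <- matrix(t, 2, 2, byrow = TRUE)
    expect_equal(fisher_exact(m), fisher_exact(t(m)), tolerance = 1e-12)
  }
})

test_that("composite non-responder score combines the four predictors", {
  # two predictors present -> flagged
  cs <- composite_score(ihc = "negative", pcr = "positive",
                        ngs_ffpe = NA, ngs_lb = "negative")
  expect_true(cs$predictors[["discordance"]])
  expect_true(cs$predictors[["lb_mss"]])
  expect_equal(cs$n_present, 2L)
  expect_true(cs$flagged_nonresponder)

  # extreme LB clonality alone is enough
  cs2 <- composite_score(ihc = "positive", pcr = "positive",
                         ngs_ffpe = "positive", ngs_lb = "positive",
                         clonality_ffpe = 40, clonality_lb = 12)
  expect_equal(cs2$n_present, 1L)  # only the LB >= 7 predictor
  expect_true(cs2$extreme_lb_clonality)
  expect_true(cs2$flagged_nonresponder)

  # one predictor, not extreme -> not flagged
  cs3 <- composite_score(ihc = "positive", pcr = "positive",
                         ngs_ffpe = "positive", ngs_lb = "positive",
                         clonality_ffpe = 40, clonality_lb = 8)
  expect_equal(cs3$n_present, 1L)
  expect_false(cs3$flagged_nonresponder)

  # all predictors false
  cs4 <- composite_score(ihc = "positive", pcr = "positive",
                         ngs_ffpe = "positive", ngs_lb = "positive",
                         clonality_ffpe = 40, clonality_lb = 2)
  expect_equal(cs4$n_present, 0L)
  expect_false(cs4$flagged_nonresponder)

  # tissue clonality cutoff is <= 15, distinct from the 18% dichotomy
  cs5 <- composite_score(ihc = "positive", pcr = "positive",
                         ngs_ffpe = "positive", ngs_lb = "positive",
                         clonality_ffpe = 15, clonality_lb = 2)
  expect_true(cs5$predictors[["ffpe_clonality_le15"]])
  cs6 <- composite_score(ihc = "positive", pcr = "positive",
                         ngs_ffpe = "positive", ngs_lb = "positive",
                         clonality_ffpe = 15.01, clonality_lb = 2)
  expect_false(cs6$predictors[["ffpe_clonality_le15"]])

  # nothing evaluable -> missing score
  cs7 <- composite_score(NA, NA, NA, NA)
  expect_true(is.na(cs7$flagged_nonresponder))
})
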