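test_that("reference envelope takes per-bin maxima across references", {
  panel <- str_panel(data.frame(locus_id = "L1", chrom = "chr1", start = 0,
                                end = 16, repeat_unit = "A"))
  r1 <- sample_profile("R1", "REFERENCE", list(L1 = c(`15` = 10, `16` = 90)))
  r2 <- sample_profile("R2", "REFERENCE", list(L1 = c(`15` = 20, `16` = 80)))
  env <- build_envelope(list(r1, r2), panel, min_references = 2)
  expect_equal(env$bounds$L1, c(`15` = 0.2, `16` = 0.9))

  # single reference: envelope is its prevalence vector
  env1 <- build_envelope(list(r1), panel, min_references = 1)
  expect_equal(env1$bounds$L1, c(`15` = 0.1, `16` = 0.9))

  # point-mass references -> indicator of the reference length
  r3 <- sample_profile("R3", "REFERENCE", list(L1 = c(`16` = 100)))
  env3 <- build_envelope(list(r3, r3), panel, min_references = 2)
  expect_equal(env3$bounds$L1, c(`16` = 1))

  # a locus absent from every reference is an error
  panel2 <- str_panel(data.frame(locus_id = c("L1", "L2"), chrom = "chr1",
                                 start = c(0, 100), end = c(16, 120),
                                 repeat_unit = "A"))
  expect_error(build_envelope(list(r1, r2), panel2, min_references = 2),
               "missing from all")
})

test_that("area above reference measures excess sample mass", {
  # sample inside the envelope support
  expect_equal(area_above_reference(c(`16` = 100), c(`16` = 1)), 0)
  # one excess bin
  expect_equal(area_above_reference(c(`14` = 40, `16` = 60), c(`16` = 1)),
               0.4)
  # sample entirely outside the envelope support
  expect_equal(area_above_reference(c(`10` = 50, `11` = 50), c(`16` = 1)), 1)
  # zero depth -> non-evaluable
  expect_true(is.na(area_above_reference(c(`16` = 0), c(`16` = 1))))
})

test_that("clonality s is the mean per-locus excess area", {
  panel <- small_panel()
  refs <- list(profile_from_counts(list(BATX1 = c(`16` = 100),
                                        BATX2 = c(`22` = 100),
                                        DINU1 = c(`20` = 100)),
                                   "R1", "REFERENCE"))
  env <- build_envelope(refs, panel, min_references = 1)
  samp <- profile_from_counts(list(BATX1 = c(`13` = 20, `16` = 80),
                                   BATX2 = c(`18` = 40, `22` = 60),
                                   DINU1 = c(`20` = 100)))
  expect_equal(clonality_s(samp, env), mean(c(0.2, 0.4, 0)))
})

test_that("the clonality transform and its clamp behave analytically", {
  expect_equal(clonality_percent(11.42 / 88.81), 0)
  expect_equal(clonality_percent(0.5), 88.81 * 0.5 - 11.42) # 32.985
  expect_equal(clonality_percent(0), 0)
  expect_equal(clonality_percent(1), 88.81 - 11.42)
  expect_error(clonality_percent(1.2), "0, 1")
  # monotone non-decreasing in s
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(clonality_percent(s)) >= 0))
})

test_that("low/high classification respects sample-type thresholds", {
  expect_equal(classify_clonality(18, "FFPE"), "high")
  expect_equal(classify_clonality(17.99, "FFPE"), "low")
  expect_equal(classify_clonality(7, "LB"), "high")
  expect_equal(classify_clonality(6.99, "LB"), "low")
  expect_equal(classify_clonality(50, "REFERENCE"), "not_applicable")
})

test_that("clonality is not reported for MSS samples", {
  panel <- small_panel()
  refs <- list(profile_from_counts(list(BATX1 = c(`16` = 100),
                                        BATX2 = c(`22` = 100),
                                        DINU1 = c(`20` = 100)),
                                   "R1", "REFERENCE"))
  env <- build_envelope(refs, panel, min_references = 1)
  samp <- profile_from_counts(list(BATX1 = c(`13` = 50, `16` = 50),
                                   BATX2 = c(`22` = 100),
                                   DINU1 = c(`20` = 100)))
  pos <- estimate_clonality(samp, env, msi_status = "MSI_positive")
  expect_false(is.na(pos$clonality_pct))
  mss <- estimate_clonality(samp, env, msi_status = "MSS")
  expect_true(is.na(mss$clonality_pct))
  expect_equal(mss$clonality_class, "not_applicable")
})

test_that("estimated clonality tracks the simulated clone fraction", {
  cfg <- sim_config(n_loci = 12, n_reference = 30, depth_per_locus = 2000,
                    seed = 91)
  panel <- generate_panel(cfg)
  refs <- generate_reference_profiles(cfg, panel)
  env <- build_envelope(refs, panel)
  cfg2 <- cfg; cfg2$seed <- NULL
  set.seed(92)
  fs <- rep(seq(0.2, 0.9, by = 0.1), each = 10)
  est <- vapply(fs, function(f) {
    p <- generate_sample_profile(cfg2, panel, f)$profile
    estimate_clonality(p, env)$clonality_pct
  }, numeric(1))
  expect_gte(cor(fs, est, method = "spearman"), 0.95)
})
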