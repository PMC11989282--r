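test_that("locus alteration prevalence applies the 2 bp shortening rule", {
  expect_equal(locus_alteration_prevalence(c(`16` = 100), 16), 0)
  expect_equal(locus_alteration_prevalence(c(`14` = 30, `16` = 70), 16), 0.30)
  # 1 bp shortenings are stutter-suppressed, any lengthening counts
  expect_equal(locus_alteration_prevalence(c(`15` = 50, `16` = 50), 16), 0)
  expect_equal(locus_alteration_prevalence(c(`16` = 90, `17` = 10), 16), 0.10)
  # zero depth -> non-evaluable
  expect_true(is.na(locus_alteration_prevalence(c(`16` = 0), 16)))
})

test_that("the exact-2bp reading is available behind the rule switch", {
  cnt <- c(`12` = 20, `14` = 30, `16` = 50)
  expect_equal(locus_alteration_prevalence(cnt, 16, rule = "at_least_2"), 0.5)
  expect_equal(locus_alteration_prevalence(cnt, 16, rule = "exact2"), 0.3)
})

test_that("MSI score is the cumulative prevalence over evaluable loci", {
  panel <- small_panel()
  prof <- profile_from_counts(list(
    BATX1 = c(`14` = 30, `16` = 70),       # prevalence 0.3 (ref 16)
    BATX2 = c(`22` = 90, `23` = 10),       # prevalence 0.1 (ref 22)
    DINU1 = c(`20` = 0)))                  # zero depth -> excluded
  res <- msi_score(prof, panel)
  expect_equal(res$msi_score, 0.4)
  expect_equal(res$n_loci_evaluated, 2)
  expect_equal(res$msi_score_normalized, 0.2)

  # null sample: no clone, no stutter
  cfg <- quick_config(stutter_rate = 0, seed = 4)
  pnl <- generate_panel(cfg)
  gen <- generate_sample_profile(cfg, pnl, 0)
  expect_equal(msi_score(gen$profile, pnl)$msi_score, 0)
})

test_that("score matches the brute-force per-read oracle on random histograms", {
  set.seed(802)
  panel <- small_panel()
  for (i in 1:50) {
    ref <- sample(10:25, 1)
    lens <- sort(sample(max(1, ref - 6):(ref + 3), sample(2:6, 1)))
    counts <- setNames(rpois(length(lens), 40), lens)
    got <- locus_alteration_prevalence(counts, ref)
    want <- oracle_prevalence(counts, ref)
    expect_identical(got, want)
  }
})

test_that("mixing two profiles combines prevalences linearly in read counts", {
  panel <- small_panel()
  a <- list(BATX1 = c(`13` = 40, `16` = 60), BATX2 = c(`22` = 100),
            DINU1 = c(`18` = 25, `20` = 75))
  b <- list(BATX1 = c(`16` = 100), BATX2 = c(`19` = 50, `22` = 150),
            DINU1 = c(`20` = 100))
  mixed <- mapply(function(x, y) {
    bins <- union(names(x), names(y))
    out <- setNames(numeric(length(bins)), bins)
    out[names(x)] <- out[names(x)] + x
    out[names(y)] <- out[names(y)] + y
    out[order(as.integer(names(out)))]
  }, a, b, SIMPLIFY = FALSE)
  pm <- msi_score(profile_from_counts(mixed), panel)$per_locus_prevalence
  for (loc in names(a)) {
    ref <- panel$ref_length_bp[panel$locus_id == loc]
    pa <- locus_alteration_prevalence(a[[loc]], ref)
    pb <- locus_alteration_prevalence(b[[loc]], ref)
    w <- sum(a[[loc]]) / (sum(a[[loc]]) + sum(b[[loc]]))
    expect_equal(unname(pm[loc]), w * pa + (1 - w) * pb)
  }
})

test_that("threshold calibration follows the stated rules", {
  expect_error(calibrate_threshold(c(0.5, 0.6)), "at least")
  scores <- c(0.7, 0.8, 0.9)
  thr <- calibrate_threshold(scores, min_references = 3)
  expect_equal(as.numeric(thr), 0.8 + 3 * 0.1)
  # zero variance -> threshold equals the common value
  expect_equal(as.numeric(calibrate_threshold(rep(0.5, 25))), 0.5)
  # percentile rule returns an order statistic
  set.seed(6)
  s400 <- runif(400)
  thr99 <- calibrate_threshold(s400, rule = "percentile", percentile = 0.99)
  expect_equal(as.numeric(thr99), sort(s400)[ceiling(0.99 * 400)])
})

test_that("MSI calls use a strict threshold and a minimum-loci rule", {
  panel <- small_panel()
  mss <- profile_from_counts(list(BATX1 = c(`16` = 100),
                                  BATX2 = c(`22` = 100),
                                  DINU1 = c(`20` = 100)))
  r <- call_msi(mss, panel, threshold = 1.1, min_loci = 3)
  expect_equal(r$status, "MSS")

  pos <- profile_from_counts(list(BATX1 = c(`13` = 60, `16` = 40),
                                  BATX2 = c(`19` = 80, `22` = 20),
                                  DINU1 = c(`16` = 90, `20` = 10)))
  expect_equal(call_msi(pos, panel, 1.1, min_loci = 3)$status, "MSI_positive")
  # tie at the threshold is called MSS
  expect_equal(call_msi(pos, panel, threshold = 0.6 + 0.8 + 0.9,
                        min_loci = 3)$status, "MSS")
  # too few evaluable loci -> indeterminate
  expect_equal(call_msi(pos, panel, 1.1, min_loci = 4)$status,
               "indeterminate")
})

test_that("expected MSI score is monotone in clone fraction", {
  cfg <- sim_config(n_loci = 10, depth_per_locus = 1500, seed = 55)
  panel <- generate_panel(cfg)
  cfg2 <- cfg; cfg2$seed <- NULL
  fs <- seq(0, 1, by = 0.2)
  set.seed(55)
  means <- vapply(fs, function(f) {
    mean(vapply(1:8, function(i) {
      msi_score(generate_sample_profile(cfg2, panel, f)$profile,
                panel)$msi_score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the calibrated caller separates clones from stable samples", {
  cfg <- sim_config(n_loci = 39, n_reference = 50, depth_per_locus = 5000,
                    seed = 71)
  panel <- generate_panel(cfg)
  refs <- generate_reference_profiles(cfg, panel)
  thr <- calibrate_threshold(refs, panel = panel)
  cfg2 <- cfg; cfg2$seed <- NULL
  set.seed(72)
  calls_pos <- vapply(1:200, function(i) {
    p <- generate_sample_profile(cfg2, panel, 0.2)$profile
    call_msi(p, panel, thr)$status
  }, character(1))
  set.seed(73)
  calls_neg <- vapply(1:200, function(i) {
    p <- generate_sample_profile(cfg2, panel, 0)$profile
    call_msi(p, panel, thr)$status
  }, character(1))
  expect_gte(mean(calls_pos == "MSI_positive"), 0.99)
  expect_gte(mean(calls_neg == "MSS"), 0.99)
})
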