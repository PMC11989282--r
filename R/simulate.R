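#' Simulation configuration
#'
#' Collects every generator parameter in one validated list. Defaults
#' describe the assay and cohort the pipeline is designed for: a 39-locus
#' mononucleotide STR panel sequenced to 5000x average depth, 400
#' microsatellite-stable reference samples, PCR stutter shifting a read by
#' whole repeat units with a geometric step count, MSI clone alleles
#' carrying deletions of at least 2 repeat units, liquid-biopsy clone
#' fractions attenuated by a lognormal ctDNA factor, orthogonal IHC/PCR
#' calls with method-specific error and missingness, a logistic response
#' model on the four non-responder predictors, and Weibull
#' accelerated-failure-time progression-free survival whose configured
#' true hazard ratios mirror the multivariate model the pipeline fits.
#'
#' @param n_loci loci in the generated panel.
#' @param n_reference number of stable reference samples.
#' @param depth_per_locus reads per locus per sample.
#' @param stutter_rate per-read probability of a stutter shift.
#' @param stutter_geometric_p geometric parameter of the stutter step count
#'   (steps = 1 + Geom(p); shifts are +/- one repeat unit per step).
#' @param deletion_min_units minimum repeat units deleted in the MSI clone
#'   allele (>= 2 so the detector's 2 bp rule sees mononucleotide loci).
#' @param deletion_mean_units mean deleted units (shifted geometric).
#' @param ffpe_null_prob probability an enrolled patient's FFPE sample
#'   carries no detectable MSI clone (clone fraction 0).
#' @param lb_null_prob probability the plasma sample carries no ctDNA.
#' @param ctdna_meanlog,ctdna_sdlog lognormal attenuation of the FFPE clone
#'   fraction in plasma (capped at 1).
#' @param method_error list of false-negative/false-positive rates for the
#'   orthogonal methods: `ihc_fn`, `ihc_fp`, `pcr_fn`, `pcr_fp`.
#' @param miss_prob named probabilities that each method's result is
#'   missing for a patient (ihc, pcr, ngs_ffpe, ngs_lb).
#' @param response_intercept,response_weights logistic model for objective
#'   response on the four predictors (discordance, LB MSS, low FFPE
#'   clonality, high LB clonality).
#' @param aft list: `shape` (Weibull shape k), `intercept` (log median-ish
#'   time scale, log days), `hr` named true hazard ratios per covariate,
#'   converted internally to log-time coefficients via beta = -log(HR)/k.
#' @param censor_rate fraction administratively censored.
#' @param min_loci minimum evaluable loci for a determinate MSI call.
#' @param seed integer seed; all generators draw from one stream seeded
#'   here, with per-stage substreams spawned up front.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_loci = 39,
                       n_reference = 400,
                       depth_per_locus = 5000,
                       stutter_rate = 0.02,
                       stutter_geometric_p = 0.8,
                       deletion_min_units = 2,
                       deletion_mean_units = 3,
                       ffpe_null_prob = 0.08,
                       lb_null_prob = 0.25,
                       ctdna_meanlog = -1.2,
                       ctdna_sdlog = 0.8,
                       method_error = list(ihc_fn = 0.10, ihc_fp = 0.02,
                                           pcr_fn = 0.05, pcr_fp = 0.02),
                       miss_prob = c(ihc = 0.27, pcr = 0.03,
                                     ngs_ffpe = 0.23, ngs_lb = 0.07),
                       response_intercept = 0.4,
                       response_weights = c(discordance = -1.5,
                                            lb_mss = -1.5,
                                            ffpe_low_clonality = -1.0,
                                            lb_high_clonality = -1.5),
                       aft = list(shape = 1.5,
                                  intercept = log(250),
                                  hr = c(clonality_ffpe = 0.63,
                                         clonality_lb = 3.05,
                                         discordance = 2.16,
                                         age = 3.69,
                                         sex_female = 1.12,
                                         metastatic = 0.76,
                                         method_ihc = 1.08)),
                       censor_rate = 0.2,
                       min_loci = 10,
                       seed = NULL) {
  cfg <- list(n_loci = n_loci, n_reference = n_reference,
              depth_per_locus = depth_per_locus,
              stutter_rate = stutter_rate,
              stutter_geometric_p = stutter_geometric_p,
              deletion_min_units = deletion_min_units,
              deletion_mean_units = deletion_mean_units,
              ffpe_null_prob = ffpe_null_prob, lb_null_prob = lb_null_prob,
              ctdna_meanlog = ctdna_meanlog, ctdna_sdlog = ctdna_sdlog,
              method_error = method_error, miss_prob = miss_prob,
              response_intercept = response_intercept,
              response_weights = response_weights,
              aft = aft, censor_rate = censor_rate,
              min_loci = min_loci, seed = seed)
  probs <- c(stutter_rate, stutter_geometric_p, ffpe_null_prob, lb_null_prob,
             unlist(method_error), miss_prob, censor_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (depth_per_locus <= 0) stop("depth_per_locus must be > 0")
  if (deletion_min_units < 1 || deletion_mean_units < deletion_min_units) {
    stop("deletion_mean_units must be >= deletion_min_units >= 1")
  }
  if (aft$shape <= 0) stop("Weibull shape must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `path` invisibly / a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # named vectors as YAML maps so names survive the round trip
  x$miss_prob <- as.list(x$miss_prob)
  x$response_weights <- as.list(x$response_weights)
  x$aft$hr <- as.list(x$aft$hr)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$miss_prob <- unlist(x$miss_prob)
  x$response_weights <- unlist(x$response_weights)
  x$aft$hr <- unlist(x$aft$hr)
  do.call(sim_config, x)
}

#' Generate a synthetic mononucleotide STR panel
#'
#' Homopolymer (A/T) tracts of 15-27 bp, the clinical archetype of
#' MSI markers (BAT-25/26-like loci), with arbitrary genomic placements.
#'
#' @param config a [sim_config()] (uses `n_loci` and `seed`).
#' @return An [str_panel()].
#' @export
generate_panel <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_loci
  ref_len <- sample(15:27, n, replace = TRUE)
  start <- sample.int(1e8, n)
  df <- data.frame(
    locus_id = sprintf("MSAT%02d", seq_len(n)),
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    start = start, end = start + ref_len,
    repeat_unit = sample(c("A", "T"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  str_panel(df)
}

# Distribution of per-read length offsets (bp) induced by stutter:
# no shift w.p. 1 - rate; otherwise +/- (1 + Geom(p)) repeat units, signs
# equiprobable. Truncated at max_steps units and renormalized.
stutter_offset_dist <- function(stutter_rate, geometric_p, unit_len,
                                max_steps = 8) {
  steps <- seq_len(max_steps)
  pstep <- (1 - geometric_p)^(steps - 1) * geometric_p
  pstep <- pstep / sum(pstep)
  offsets <- c(0, steps * unit_len, -steps * unit_len)
  probs <- c(1 - stutter_rate, rep(stutter_rate / 2 * pstep, 2))
  list(offsets = offsets, probs = probs)
}

# Multinomial histogram for one locus: a (stable, clone) mixture with
# stutter applied to every read. Equivalent to drawing `depth` iid reads.
sim_locus_counts <- function(ref_len, unit_len, depth, clone_fraction,
                             clone_len, config) {
  sd_ <- stutter_offset_dist(config$stutter_rate,
                             config$stutter_geometric_p, unit_len)
  n_clone <- stats::rbinom(1, depth, clone_fraction)
  counts <- integer(0)
  add <- function(counts, center, n) {
    if (n == 0) return(counts)
    draw <- stats::rmultinom(1, n, sd_$probs)[, 1]
    len <- pmax(center + sd_$offsets, 1L)
    for (i in seq_along(len)) {
      key <- as.character(len[i])
      counts[key] <- if (key %in% names(counts)) counts[[key]] + draw[i]
                     else draw[i]
    }
    counts
  }
  counts <- add(counts, ref_len, depth - n_clone)
  counts <- add(counts, clone_len, n_clone)
  counts <- counts[counts > 0]
  counts[order(as.integer(names(counts)))]
}

#' Generate stable reference profiles
#'
#' Each locus's histogram is concentrated at the panel reference length
#' with symmetric stutter noise only (no MSI clone).
#'
#' @param config a [sim_config()].
#' @param panel an [str_panel()].
#' @param n number of profiles (default `config$n_reference`).
#' @param id_prefix sample id prefix.
#' @return List of `REFERENCE` [sample_profile()]s.
#' @export
generate_reference_profiles <- function(config, panel,
                                        n = config$n_reference,
                                        id_prefix = "REF") {
  if (!is.null(config$seed)) set.seed(config$seed)
  refs <- panel_ref_lengths(panel)
  units <- panel_unit_lengths(panel)
  lapply(seq_len(n), function(i) {
    hists <- lapply(panel$locus_id, function(loc) {
      sim_locus_counts(refs[[loc]], units[[loc]], config$depth_per_locus,
                       0, refs[[loc]], config)
    })
    names(hists) <- panel$locus_id
    sample_profile(sprintf("%s%04d", id_prefix, i), "REFERENCE", hists)
  })
}

#' Generate one tumor or plasma sample profile
#'
#' At each locus, reads come from the MSI clone allele with probability
#' `clone_fraction` and from the stable allele otherwise; the clone allele
#' is the reference tract shortened by `d` repeat units, `d` drawn once per
#' locus per sample from `deletion_min_units + Geom(p)` with mean
#' `deletion_mean_units`. Stutter applies to every read. Total depth per
#' locus equals `depth_per_locus` exactly.
#'
#' @param config a [sim_config()].
#' @param panel an [str_panel()].
#' @param clone_fraction fraction of reads from the MSI clone, in `[0, 1]`.
#' @param sample_type `"FFPE"` or `"LB"`.
#' @param sample_id sample identifier.
#' @return List with `profile` (a [sample_profile()]) and `truth`
#'   (one-row data.frame: sample_id, sample_type, clone_fraction).
#' @export
generate_sample_profile <- function(config, panel, clone_fraction,
                                    sample_type = "FFPE",
                                    sample_id = "S0001") {
  if (clone_fraction < 0 || clone_fraction > 1) {
    stop("clone_fraction must lie in [0, 1]")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  refs <- panel_ref_lengths(panel)
  units <- panel_unit_lengths(panel)
  p_del <- 1 / (config$deletion_mean_units - config$deletion_min_units + 1)
  hists <- lapply(panel$locus_id, function(loc) {
    d <- config$deletion_min_units + stats::rgeom(1, p_del)
    clone_len <- max(refs[[loc]] - d * units[[loc]], 1L)
    sim_locus_counts(refs[[loc]], units[[loc]], config$depth_per_locus,
                     clone_fraction, clone_len, config)
  })
  names(hists) <- panel$locus_id
  list(profile = sample_profile(sample_id, sample_type, hists),
       truth = data.frame(sample_id = sample_id, sample_type = sample_type,
                          clone_fraction = clone_fraction,
                          stringsAsFactors = FALSE))
}

# Perturb a true binary call with method-specific FN/FP rates.
noisy_call <- function(truth_positive, fn, fp) {
  if (truth_positive) {
    if (stats::runif(1) < fn) "negative" else "positive"
  } else {
    if (stats::runif(1) < fp) "positive" else "negative"
  }
}

#' Generate a full synthetic patient cohort
#'
#' End-to-end cohort generator: draws covariates and true FFPE/LB clone
#' fractions per patient, simulates STR profiles, calibrates the MSI
#' threshold and reference envelope on generated stable samples, produces
#' NGS calls and clonality estimates by actually running the MSI and
#' clonality modules, derives IHC/PCR calls from truth with method error
#' and missingness, draws objective response from a logistic model on the
#' four non-responder predictors, and draws progression-free survival from
#' a Weibull accelerated failure time model on scaled covariates with
#' administrative censoring.
#'
#' All enrolled patients are truly MSI-positive (trial inclusion
#' criterion); apparent MSS results arise from low clone fraction, absent
#' ctDNA, or method error.
#'
#' @param config a [sim_config()].
#' @param n_patients cohort size.
#' @param keep_profiles keep the per-sample profiles in the result
#'   (set `FALSE` to save memory in large simulations).
#' @return List: `cohort` (an [msi_cohort()]), `truth` (per-patient truth:
#'   clone fractions, true predictors, true linear predictor and latent
#'   time), `panel`, `reference_profiles`, `threshold`, `envelope`,
#'   `msi_calls` (data.frame of all sample-level calls), and `profiles`
#'   (if kept).
#' @export
generate_cohort <- function(config, n_patients, keep_profiles = TRUE) {
  stopifnot(n_patients > 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  # spawn per-stage substreams up front so later stages do not perturb
  # earlier draws when one stage's internals change
  stage_seed <- sample.int(.Machine$integer.max - 1, 6)

  set.seed(stage_seed[1])
  panel <- local({ c2 <- config; c2$seed <- NULL; generate_panel(c2) })
  set.seed(stage_seed[2])
  references <- local({
    c2 <- config; c2$seed <- NULL
    generate_reference_profiles(c2, panel)
  })
  threshold <- calibrate_threshold(references, panel = panel)
  envelope <- build_envelope(references, panel)

  # --- patient-level covariates and true clone fractions ---
  set.seed(stage_seed[3])
  age <- pmin(pmax(round(stats::rnorm(n_patients, 60, 12)), 25), 90)
  sex <- sample(c("female", "male"), n_patients, TRUE, c(0.47, 0.53))
  stage <- sample(c("II", "III", "IV"), n_patients, TRUE, c(0.20, 0.55, 0.25))
  setting <- sample(c("preoperative", "advanced_1L", "advanced_2L3L"),
                    n_patients, TRUE, c(0.67, 0.20, 0.13))
  braf <- sample(c("positive", "negative", "unknown"), n_patients, TRUE,
                 c(0.27, 0.50, 0.23))
  ras <- sample(c("positive", "negative", "unknown"), n_patients, TRUE,
                c(0.47, 0.30, 0.23))
  primary_method <- sample(c("PCR", "IHC"), n_patients, TRUE, c(0.8, 0.2))

  f_ffpe <- stats::rbeta(n_patients, 2, 2)
  f_ffpe[stats::runif(n_patients) < config$ffpe_null_prob] <- 0
  ctdna <- pmin(stats::rlnorm(n_patients, config$ctdna_meanlog,
                              config$ctdna_sdlog), 1)
  f_lb <- f_ffpe * ctdna
  f_lb[stats::runif(n_patients) < config$lb_null_prob] <- 0

  # --- sample profiles and NGS calls via the msi/clonality modules ---
  set.seed(stage_seed[4])
  c2 <- config; c2$seed <- NULL
  msi_rows <- vector("list", 2L * n_patients)
  profiles <- if (keep_profiles) vector("list", 2L * n_patients) else NULL
  ngs_ffpe <- ngs_lb <- character(n_patients)
  clon_ffpe <- clon_lb <- rep(NA_real_, n_patients)
  for (i in seq_len(n_patients)) {
    for (st in c("FFPE", "LB")) {
      f <- if (st == "FFPE") f_ffpe[i] else f_lb[i]
      sid <- sprintf("P%04d_%s", i, st)
      gen <- generate_sample_profile(c2, panel, f, st, sid)
      res <- call_msi(gen$profile, panel, threshold,
                      min_loci = config$min_loci)
      cl <- estimate_clonality(gen$profile, envelope, res$status)
      if (st == "FFPE") {
        ngs_ffpe[i] <- if (res$status == "MSI_positive") "positive"
                       else "negative"
        if (res$status == "MSI_positive") clon_ffpe[i] <- cl$clonality_pct
      } else {
        ngs_lb[i] <- if (res$status == "MSI_positive") "positive"
                     else "negative"
        if (res$status == "MSI_positive") clon_lb[i] <- cl$clonality_pct
      }
      k <- 2L * (i - 1L) + (st == "LB") + 1L
      msi_rows[[k]] <- data.frame(
        sample_id = sid, patient_id = sprintf("P%04d", i), sample_type = st,
        msi_score = res$msi_score, status = res$status,
        clonality_pct = if (res$status == "MSI_positive") cl$clonality_pct
                        else NA_real_,
        stringsAsFactors = FALSE)
      if (keep_profiles) profiles[[k]] <- gen$profile
    }
  }
  msi_calls <- do.call(rbind, msi_rows)

  # --- orthogonal IHC / PCR calls from truth, with error + missingness ---
  set.seed(stage_seed[5])
  err <- config$method_error
  ihc <- vapply(seq_len(n_patients), function(i)
    noisy_call(TRUE, err$ihc_fn, err$ihc_fp), character(1))
  pcr <- vapply(seq_len(n_patients), function(i)
    noisy_call(TRUE, err$pcr_fn, err$pcr_fp), character(1))
  mp <- config$miss_prob
  ihc[stats::runif(n_patients) < mp[["ihc"]]] <- NA
  pcr[stats::runif(n_patients) < mp[["pcr"]]] <- NA
  ngs_ffpe[stats::runif(n_patients) < mp[["ngs_ffpe"]]] <- NA
  ngs_lb[stats::runif(n_patients) < mp[["ngs_lb"]]] <- NA
  clon_ffpe[is.na(ngs_ffpe)] <- NA
  clon_lb[is.na(ngs_lb)] <- NA

  # --- response from the four non-responder predictors ---
  set.seed(stage_seed[6])
  calls_mat <- cbind(IHC = ihc, PCR = pcr, NGS_FFPE = ngs_ffpe,
                     NGS_LB = ngs_lb)
  disc <- apply(calls_mat, 1, function(r)
    discordance_flag(r["IHC"], r[c("PCR", "NGS_FFPE", "NGS_LB")]))
  pred <- cbind(
    discordance = ifelse(is.na(disc), FALSE, disc),
    lb_mss = !is.na(ngs_lb) & ngs_lb == "negative",
    ffpe_low_clonality = !is.na(clon_ffpe) & clon_ffpe <= 15,
    lb_high_clonality = !is.na(clon_lb) & clon_lb >= 7)
  eta <- config$response_intercept +
    pred %*% config$response_weights[colnames(pred)]
  responder <- stats::runif(n_patients) < stats::plogis(drop(eta))
  response <- ifelse(responder,
                     ifelse(stats::runif(n_patients) < 0.27, "CR", "PR"),
                     ifelse(stats::runif(n_patients) < 0.5, "SD", "PD"))
  response[stats::runif(n_patients) < 0.03] <- "NE"

  # --- Weibull AFT progression-free survival on scaled covariates ---
  # true continuous clonalities on the generator scale (percent)
  true_clon_ffpe <- pmax(88.81 * f_ffpe - 11.42, 0)
  true_clon_lb <- pmax(88.81 * f_lb - 11.42, 0)
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                    else x * 0
  X <- cbind(clonality_ffpe = zs(true_clon_ffpe),
             clonality_lb = zs(true_clon_lb),
             discordance = as.numeric(pred[, "discordance"]),
             age = zs(age),
             sex_female = as.numeric(sex == "female"),
             metastatic = as.numeric(stage == "IV"),
             method_ihc = as.numeric(primary_method == "IHC"))
  k_shape <- config$aft$shape
  beta <- -log(config$aft$hr[colnames(X)]) / k_shape
  lp <- drop(X %*% beta)
  # log T = intercept + x'beta + (1/k) * Gumbel(min)
  w <- log(stats::rweibull(n_patients, shape = 1, scale = 1)) # std Gumbel(min)
  latent_t <- exp(config$aft$intercept + lp + w / k_shape)
  tau <- stats::quantile(latent_t, 1 - config$censor_rate, type = 7)
  event <- latent_t <= tau
  pfs_time <- pmax(pmin(latent_t, tau), 1e-6)

  cohort <- msi_cohort(data.frame(
    patient_id = sprintf("P%04d", seq_len(n_patients)),
    age = age, sex = sex, stage = stage, setting = setting,
    primary_method = primary_method,
    ihc = ihc, pcr = pcr, ngs_ffpe = ngs_ffpe, ngs_lb = ngs_lb,
    clonality_ffpe = clon_ffpe, clonality_lb = clon_lb,
    response = response, pfs_time = as.numeric(pfs_time), event = event,
    braf_v600 = braf, ras = ras, stringsAsFactors = FALSE))

  truth <- data.frame(
    patient_id = cohort$patient_id,
    clone_fraction_ffpe = f_ffpe, clone_fraction_lb = f_lb,
    true_clonality_ffpe = true_clon_ffpe, true_clonality_lb = true_clon_lb,
    true_discordance = pred[, "discordance"],
    true_linear_predictor = lp, latent_time = as.numeric(latent_t),
    stringsAsFactors = FALSE)

  out <- list(cohort = cohort, truth = truth, panel = panel,
              reference_profiles = references,
              threshold = as.numeric(threshold), envelope = envelope,
              msi_calls = msi_calls)
  if (keep_profiles) out$profiles <- profiles
  out
}

#' Simulate survival data from a single-covariate Weibull AFT model
#'
#' Generates `log T = intercept + beta * x + (1/shape) * W` with `W` a
#' standard minimum Gumbel variate, where `beta = -log(hr) / shape`, plus
#' administrative censoring at the empirical `(1 - censor_rate)` quantile.
#' Used for parameter-recovery checks of the survival module.
#'
#' @param n sample size.
#' @param hr true hazard ratio of the covariate.
#' @param shape Weibull shape k.
#' @param intercept log-time intercept.
#' @param censor_rate administrative censoring fraction.
#' @param covariate `"binary"` (Bernoulli(0.5)) or `"normal"` (standard).
#' @param seed optional seed.
#' @return data.frame with `time`, `event`, `x`.
#' @export
simulate_aft_data <- function(n, hr = 1, shape = 1.5, intercept = log(250),
                              censor_rate = 0.2,
                              covariate = c("binary", "normal"),
                              seed = NULL) {
  covariate <- match.arg(covariate)
  if (!is.null(seed)) set.seed(seed)
  x <- if (covariate == "binary") stats::rbinom(n, 1, 0.5)
       else stats::rnorm(n)
  beta <- -log(hr) / shape
  w <- log(stats::rweibull(n, shape = 1, scale = 1))
  t_lat <- exp(intercept + beta * x + w / shape)
  tau <- stats::quantile(t_lat, 1 - censor_rate, type = 7)
  data.frame(time = as.numeric(pmin(t_lat, tau)), event = t_lat <= tau,
             x = x)
}
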