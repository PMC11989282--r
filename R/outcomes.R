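#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from Beta quantiles:
#' `lo = 100 * qbeta(alpha/2; x, n - x + 1)` (0 when `x = 0`) and
#' `hi = 100 * qbeta(1 - alpha/2; x + 1, n - x)` (100 when `x = n`),
#' reported on the percent scale.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return Named numeric `c(lo, hi)` in percent.
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n, n >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo = 100 * lo, hi = 100 * hi)
}

#' Response-rate summary with exact confidence intervals
#'
#' Counts best responses (RECIST: CR, PR, SD, PD, NE) and reports the
#' objective response rate ORR = (CR + PR) / n and disease control rate
#' DCR = (CR + PR + SD) / n with Clopper-Pearson 95% CIs. The denominator
#' is the intention-to-treat population: all patients in the subset,
#' including NE, who count in the denominator only.
#'
#' @param cohort an [msi_cohort()] (or any data.frame with `response`).
#' @param subset optional logical vector selecting patients.
#' @param alpha CI error rate.
#' @return List of counts, `orr`, `orr_ci`, `dcr`, `dcr_ci` (percent).
#' @export
response_summary <- function(cohort, subset = NULL, alpha = 0.05) {
  resp <- cohort$response
  if (!is.null(subset)) resp <- resp[subset]
  n <- length(resp)
  if (n < 1) stop("empty patient subset")
  cnt <- vapply(c("CR", "PR", "SD", "PD", "NE"),
                function(k) sum(resp == k, na.rm = TRUE), numeric(1))
  x_orr <- cnt[["CR"]] + cnt[["PR"]]
  x_dcr <- x_orr + cnt[["SD"]]
  list(n = n, n_cr = cnt[["CR"]], n_pr = cnt[["PR"]], n_sd = cnt[["SD"]],
       n_pd = cnt[["PD"]], n_ne = cnt[["NE"]],
       orr = 100 * x_orr / n, orr_ci = clopper_pearson(x_orr, n, alpha),
       dcr = 100 * x_dcr / n, dcr_ci = clopper_pearson(x_dcr, n, alpha))
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Compares success rates of two independent binomial groups (rows of the
#' table: `a/b` successes/failures in group 1, `c/d` in group 2) without
#' conditioning on the success margin. The test statistic is the pooled
#' score (Z) statistic; the two-sided p-value at nuisance success
#' probability `pi` sums the probability of every outcome table with
#' `|Z| >= |Z_obs|`, and the reported p maximizes over `pi` on a fixed
#' grid of equally spaced points in (0, 1).
#'
#' @param tab 2x2 matrix (rows = groups, columns = success/failure) or
#'   numeric `c(a, b, c, d)`.
#' @param n_grid number of nuisance-grid points (default 1001).
#' @return p-value in (0, 1]; degenerate margins give 1.
#' @export
barnard_test <- function(tab, n_grid = 1001) {
  tab <- as_table2x2(tab)
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  if (n1 == 0 || n2 == 0) return(1)
  z_obs <- score_z(tab[1, 1], tab[2, 1], n1, n2)
  if (abs(z_obs) < 1e-12) return(1) # symmetric null: every table as extreme
  x1 <- 0:n1; x2 <- 0:n2
  zmat <- outer(x1, x2, function(a, c) score_z(a, c, n1, n2))
  extreme <- abs(zmat) >= abs(z_obs) - 1e-10
  grid <- seq_len(n_grid) / (n_grid + 1)
  p <- 0
  for (pi in grid) {
    pr <- outer(stats::dbinom(x1, n1, pi), stats::dbinom(x2, n2, pi))
    p <- max(p, sum(pr[extreme]))
  }
  min(p, 1)
}

# Pooled score statistic for two binomial proportions; 0 when the pooled
# rate is degenerate (0 or 1).
score_z <- function(x1, x2, n1, n2) {
  pp <- (x1 + x2) / (n1 + n2)
  den <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  ifelse(den == 0, 0, (x1 / n1 - x2 / n2) / den)
}

as_table2x2 <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == 2))
  } else {
    stopifnot(length(tab) == 4)
    tab <- matrix(tab, 2, 2, byrow = TRUE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of tables at
#' most as probable as the observed one (the standard two-sided rule).
#'
#' @param tab 2x2 matrix or `c(a, b, c, d)`.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(tab) {
  tab <- as_table2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Composite non-responder score
#'
#' Four baseline methodological predictors of non-response to checkpoint
#' inhibition: (1) discordance between the expression-level (IHC) and
#' genomic (PCR/NGS) MSI determinations; (2) absence of MSI in the liquid
#' biopsy; (3) low MSI clonality in tumor tissue (15% and lower); (4) high
#' MSI clonality in liquid biopsy (7% and higher). A patient is flagged a
#' potential non-responder when two or more predictors are present, or on
#' extremely high LB clonality alone (10% and higher).
#'
#' Note the tissue-clonality predictor cutoff (<= 15) is deliberately
#' distinct from the 18% low/high dichotomization used elsewhere; both are
#' exposed as arguments.
#'
#' @param ihc,pcr,ngs_ffpe,ngs_lb method calls
#'   (`"positive"`/`"negative"`/NA).
#' @param clonality_ffpe,clonality_lb clonality percents (NA when the
#'   corresponding NGS call is negative or missing).
#' @param ffpe_low_max predictor-3 cutoff (inclusive).
#' @param lb_high_min predictor-4 cutoff (inclusive).
#' @param extreme_lb_min extreme-LB-clonality cutoff (inclusive).
#' @param discordance_require rule passed to [discordance_flag()].
#' @return List: `predictors` (named logical, NA when not evaluable),
#'   `n_present` (predictors present, i.e. TRUE), `extreme_lb_clonality`,
#'   `flagged_nonresponder` (NA when no predictor is evaluable).
#' @export
composite_score <- function(ihc, pcr, ngs_ffpe, ngs_lb,
                            clonality_ffpe = NA, clonality_lb = NA,
                            ffpe_low_max = 15, lb_high_min = 7,
                            extreme_lb_min = 10,
                            discordance_require = "any") {
  disc <- discordance_flag(ihc, c(pcr, ngs_ffpe, ngs_lb),
                           discordance_require)
  preds <- c(
    discordance = disc,
    lb_mss = if (is.na(ngs_lb)) NA else ngs_lb == "negative",
    ffpe_clonality_le15 = if (is.na(clonality_ffpe)) NA
                          else clonality_ffpe <= ffpe_low_max,
    lb_clonality_ge7 = if (is.na(clonality_lb)) NA
                       else clonality_lb >= lb_high_min)
  if (all(is.na(preds))) {
    return(list(predictors = preds, n_present = NA_integer_,
                extreme_lb_clonality = NA, flagged_nonresponder = NA))
  }
  n_present <- sum(preds, na.rm = TRUE)
  extreme <- !is.na(clonality_lb) && clonality_lb >= extreme_lb_min
  list(predictors = preds, n_present = as.integer(n_present),
       extreme_lb_clonality = extreme,
       flagged_nonresponder = n_present >= 2 || extreme)
}

#' Composite scores for a whole cohort
#'
#' @param cohort an [msi_cohort()].
#' @param ... passed to [composite_score()].
#' @return data.frame: patient_id, the four predictors, n_present,
#'   extreme_lb_clonality, flagged_nonresponder.
#' @export
composite_score_table <- function(cohort, ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    r <- cohort[i, ]
    cs <- composite_score(r$ihc, r$pcr, r$ngs_ffpe, r$ngs_lb,
                          r$clonality_ffpe, r$clonality_lb, ...)
    data.frame(patient_id = r$patient_id,
               discordance = cs$predictors[["discordance"]],
               lb_mss = cs$predictors[["lb_mss"]],
               ffpe_clonality_le15 = cs$predictors[["ffpe_clonality_le15"]],
               lb_clonality_ge7 = cs$predictors[["lb_clonality_ge7"]],
               n_present = cs$n_present,
               extreme_lb_clonality = cs$extreme_lb_clonality,
               flagged_nonresponder = cs$flagged_nonresponder,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
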