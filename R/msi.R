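#' Is an allele length "altered" relative to the reference tract?
#'
#' The alteration rule is the core detector decision and is isolated here:
#' a read is altered when its tract length is shortened by at least 2 bp
#' (`length <= ref - 2`) or lengthened by any amount (`length > ref`).
#' One-bp shortenings are deliberately excluded to suppress single-slip PCR
#' stutter at mononucleotide repeats. An `"exact2"` variant (shortened by
#' exactly 2 bp, or longer) is available since the shortening rule admits
#' both readings.
#'
#' @param length_bp integer vector of allele lengths (bp).
#' @param ref_length_bp reference tract length (bp).
#' @param rule `"at_least_2"` (default) or `"exact2"`.
#' @return Logical vector.
#' @export
is_altered_length <- function(length_bp, ref_length_bp,
                              rule = c("at_least_2", "exact2")) {
  rule <- match.arg(rule)
  shortened <- if (rule == "at_least_2") {
    length_bp <= ref_length_bp - 2
  } else {
    length_bp == ref_length_bp - 2
  }
  shortened | (length_bp > ref_length_bp)
}

#' Per-locus alteration prevalence
#'
#' Fraction of reads at one locus whose tract length is altered relative to
#' the panel reference (see [is_altered_length()]). A locus with zero depth
#' is non-evaluable and returns `NA`.
#'
#' @param counts named integer vector of read counts keyed by length (bp).
#' @param ref_length_bp reference tract length for the locus.
#' @param rule alteration rule, passed to [is_altered_length()].
#' @return Prevalence in `[0, 1]`, or `NA_real_` when depth is 0.
#' @export
locus_alteration_prevalence <- function(counts, ref_length_bp,
                                        rule = "at_least_2") {
  depth <- sum(counts)
  if (depth == 0) return(NA_real_)
  len <- as.integer(names(counts))
  sum(counts[is_altered_length(len, ref_length_bp, rule)]) / depth
}

#' Cumulative MSI score for a sample
#'
#' The MSI score is the cumulative prevalence, over all evaluable panel
#' loci, of reads supporting an altered tract length: the sum over loci of
#' [locus_alteration_prevalence()]. It therefore ranges in
#' `[0, n_loci_evaluated]`. Loci absent from the sample or with zero depth
#' are excluded and reported via `n_loci_evaluated`; a normalized score
#' (sum / n_loci_evaluated) is also returned so samples with missing loci
#' remain comparable, but the raw sum is the primary quantity.
#'
#' @param profile a [sample_profile()].
#' @param panel an [str_panel()].
#' @param rule alteration rule, see [is_altered_length()].
#' @return List with `sample_id`, `per_locus_prevalence` (named, `NA` for
#'   non-evaluable loci), `msi_score`, `msi_score_normalized`,
#'   `n_loci_evaluated`.
#' @export
msi_score <- function(profile, panel, rule = "at_least_2") {
  stopifnot(inherits(profile, "sample_profile"), inherits(panel, "str_panel"))
  refs <- panel_ref_lengths(panel)
  prev <- vapply(panel$locus_id, function(loc) {
    h <- profile$histograms[[loc]]
    if (is.null(h)) return(NA_real_)
    locus_alteration_prevalence(h, refs[[loc]], rule)
  }, numeric(1))
  n_eval <- sum(!is.na(prev))
  score <- if (n_eval > 0) sum(prev, na.rm = TRUE) else NA_real_
  list(sample_id = profile$sample_id,
       per_locus_prevalence = prev,
       msi_score = score,
       msi_score_normalized = if (n_eval > 0) score / n_eval else NA_real_,
       n_loci_evaluated = n_eval)
}

#' Calibrate the MSI positivity threshold on stable reference samples
#'
#' The platform's numeric cutoff is learned from microsatellite-stable
#' reference samples. Default rule: mean + `k` standard deviations of the
#' reference MSI scores (k = 3); alternatively an upper percentile of the
#' reference score distribution.
#'
#' @param references numeric vector of reference MSI scores, or a list of
#'   reference [sample_profile()]s (then `panel` is required).
#' @param rule `"mean_sd"` or `"percentile"`.
#' @param k SD multiplier for `"mean_sd"`.
#' @param percentile probability for `"percentile"` (type-1 quantile, i.e.
#'   an order statistic of the reference scores).
#' @param min_references minimum number of reference samples required.
#' @param panel panel, required when `references` are profiles.
#' @return Threshold (numeric scalar) with attributes `rule` and `n_reference`.
#' @export
calibrate_threshold <- function(references, rule = c("mean_sd", "percentile"),
                                k = 3, percentile = 0.99,
                                min_references = 20, panel = NULL) {
  rule <- match.arg(rule)
  scores <- if (is.numeric(references)) {
    references
  } else {
    if (is.null(panel)) stop("panel required when references are profiles")
    vapply(references, function(p) msi_score(p, panel)$msi_score, numeric(1))
  }
  scores <- scores[!is.na(scores)]
  if (length(scores) < min_references) {
    stop("need at least ", min_references, " reference scores, got ",
         length(scores))
  }
  thr <- switch(rule,
    mean_sd = mean(scores) + k * stats::sd(scores),
    percentile = unname(stats::quantile(scores, percentile, type = 1)))
  structure(thr, rule = rule, n_reference = length(scores))
}

#' Call MSI status for a sample
#'
#' A sample is MSI-positive when its cumulative MSI score strictly exceeds
#' the calibrated threshold (a score exactly at the threshold is called
#' MSS: conservative tie rule), and indeterminate when fewer than
#' `min_loci` loci were evaluable.
#'
#' @param profile a [sample_profile()].
#' @param panel an [str_panel()].
#' @param threshold positivity threshold (from [calibrate_threshold()]).
#' @param min_loci minimum evaluable loci for a determinate call.
#' @param rule alteration rule, see [is_altered_length()].
#' @return An `msi_result` list: sample_id, sample_type, per-locus
#'   prevalences, msi_score, threshold, n_loci_evaluated and
#'   `status` in `{"MSI_positive", "MSS", "indeterminate"}`.
#' @export
call_msi <- function(profile, panel, threshold, min_loci = 10,
                     rule = "at_least_2") {
  stopifnot(threshold >= 0)
  res <- msi_score(profile, panel, rule)
  res$sample_type <- profile$sample_type
  res$threshold <- as.numeric(threshold)
  res$status <- if (res$n_loci_evaluated < min_loci) {
    "indeterminate"
  } else if (res$msi_score > threshold) {
    "MSI_positive"
  } else {
    "MSS"
  }
  class(res) <- "msi_result"
  res
}

#' @export
print.msi_result <- function(x, ...) {
  cat("<msi_result> ", x$sample_id, ": score ",
      formatC(x$msi_score, digits = 4, format = "f"),
      " (threshold ", formatC(x$threshold, digits = 4, format = "f"),
      ", ", x$n_loci_evaluated, " loci) -> ", x$status, "\n", sep = "")
  invisible(x)
}

#' Summarise MSI calls for many samples
#'
#' @param profiles list of [sample_profile()]s.
#' @param panel panel.
#' @param threshold positivity threshold.
#' @param min_loci minimum evaluable loci.
#' @param rule alteration rule.
#' @return data.frame: sample_id, sample_type, n_loci, msi_score, threshold,
#'   status.
#' @export
call_msi_batch <- function(profiles, panel, threshold, min_loci = 10,
                           rule = "at_least_2") {
  rows <- lapply(profiles, function(p) {
    r <- call_msi(p, panel, threshold, min_loci, rule)
    data.frame(sample_id = r$sample_id, sample_type = r$sample_type,
               n_loci = r$n_loci_evaluated, msi_score = r$msi_score,
               threshold = r$threshold, status = r$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
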