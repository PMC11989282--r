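#' Build the stable-reference envelope of STR length distributions
#'
#' For each panel locus and each allele length bin, the envelope records a
#' reference prevalence bound computed across the stable reference samples.
#' The default rule is the per-bin maximum: the excess of a tumor sample
#' over the envelope is then mass at lengths beyond anything a stable
#' sample ever showed. Alternatives (`"mean"`, `"mean_2sd"`) are provided
#' because "the reference distribution(s)" admits a pooled reading.
#'
#' @param references list of reference [sample_profile()]s.
#' @param panel an [str_panel()].
#' @param rule `"max"` (default), `"mean"` or `"mean_2sd"`.
#' @param min_references minimum number of reference samples.
#' @return A `reference_envelope`: list with `bounds` (named list by
#'   locus_id; each a named numeric vector of prevalence bounds keyed by
#'   length bp), `rule`, `n_reference_samples`.
#' @export
build_envelope <- function(references, panel,
                           rule = c("max", "mean", "mean_2sd"),
                           min_references = 20) {
  rule <- match.arg(rule)
  stopifnot(inherits(panel, "str_panel"))
  if (length(references) < min_references) {
    stop("need at least ", min_references, " reference samples, got ",
         length(references))
  }
  bounds <- lapply(panel$locus_id, function(loc) {
    # prevalence vectors per reference sample, on the union of length bins
    prevs <- lapply(references, function(p) {
      h <- p$histograms[[loc]]
      if (is.null(h) || sum(h) == 0) return(NULL)
      h / sum(h)
    })
    prevs <- prevs[!vapply(prevs, is.null, logical(1))]
    if (length(prevs) == 0) {
      stop("locus ", loc, " missing from all reference samples")
    }
    bins <- sort(unique(as.integer(unlist(lapply(prevs, names)))))
    mat <- vapply(prevs, function(pv) {
      out <- stats::setNames(numeric(length(bins)), bins)
      out[names(pv)] <- pv
      out
    }, numeric(length(bins)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(bins))
    env <- switch(rule,
      max = apply(mat, 1, max),
      mean = rowMeans(mat),
      mean_2sd = rowMeans(mat) + 2 * apply(mat, 1, stats::sd))
    stats::setNames(pmin(env, 1), bins)
  })
  names(bounds) <- panel$locus_id
  structure(list(bounds = bounds, rule = rule,
                 n_reference_samples = length(references)),
            class = "reference_envelope")
}

#' Area of a sample histogram above the reference envelope
#'
#' Sum over length bins of `max(0, sample_prevalence - envelope_bound)`:
#' the probability mass the sample places where stable references do not.
#' Lies in `[0, 1]`; `NA` when the locus has zero depth.
#'
#' @param counts named integer vector of read counts keyed by length (bp).
#' @param envelope_locus named numeric vector of envelope bounds for the
#'   locus (prevalence per length bin; absent bins are 0).
#' @return Area in `[0, 1]`, or `NA_real_`.
#' @export
area_above_reference <- function(counts, envelope_locus) {
  depth <- sum(counts)
  if (depth == 0) return(NA_real_)
  prev <- counts / depth
  bound <- envelope_locus[names(prev)]
  bound[is.na(bound)] <- 0
  sum(pmax(0, prev - bound))
}

#' Mean area above the reference envelope for a sample
#'
#' The clonality statistic `s`: arithmetic mean, over evaluable loci, of
#' the per-locus [area_above_reference()].
#'
#' @param profile a [sample_profile()].
#' @param envelope a `reference_envelope` from [build_envelope()].
#' @return `s` in `[0, 1]` (NA when no locus is evaluable).
#' @export
clonality_s <- function(profile, envelope) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(envelope, "reference_envelope"))
  areas <- vapply(names(envelope$bounds), function(loc) {
    h <- profile$histograms[[loc]]
    if (is.null(h)) return(NA_real_)
    area_above_reference(h, envelope$bounds[[loc]])
  }, numeric(1))
  if (all(is.na(areas))) return(NA_real_)
  mean(areas, na.rm = TRUE)
}

#' Clonality transform: mean excess area to percent MSI clonality
#'
#' Linear calibration of the mean area above the reference envelope onto a
#' percent scale of MSI-bearing cell / ctDNA fraction:
#' `clonality = 88.81 * s - 11.42`, clamped to `[0, 100]` (clonality is a
#' percentage of cells; small excess areas within the stable envelope noise
#' map below 0 and are reported as 0).
#'
#' @param s mean area above reference, in `[0, 1]`.
#' @return Clonality percent in `[0, 100]`.
#' @export
clonality_percent <- function(s) {
  if (any(is.na(s))) stop("s must not be NA")
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  pmin(pmax(88.81 * s - 11.42, 0), 100)
}

#' Classify clonality as low or high by sample type
#'
#' Tumor tissue (FFPE) is high-clonality at 18% and above; liquid biopsy
#' (LB) at 7% and above (both thresholds inclusive at the boundary; values
#' strictly below are low). Reference samples get `"not_applicable"`.
#'
#' @param clonality_pct clonality percent in `[0, 100]`.
#' @param sample_type `"FFPE"`, `"LB"` or `"REFERENCE"`.
#' @param thresholds named numeric vector of high-clonality cutoffs.
#' @return `"low"`, `"high"` or `"not_applicable"`.
#' @export
classify_clonality <- function(clonality_pct, sample_type,
                               thresholds = c(FFPE = 18, LB = 7)) {
  sample_type <- match.arg(sample_type, c("FFPE", "LB", "REFERENCE"))
  if (sample_type == "REFERENCE") return("not_applicable")
  stopifnot(clonality_pct >= 0, clonality_pct <= 100)
  if (clonality_pct >= thresholds[[sample_type]]) "high" else "low"
}

#' Estimate MSI clonality for a sample
#'
#' Full chain: mean area above the reference envelope, linear transform to
#' percent, classification by sample type. Clonality is only defined for
#' MSI-positive samples; when `msi_status` is supplied and is not
#' `"MSI_positive"`, the class is `"not_applicable"` and the percent is NA.
#'
#' @param profile a [sample_profile()].
#' @param envelope a `reference_envelope`.
#' @param msi_status optional MSI call for the sample
#'   (`"MSI_positive"`, `"MSS"`, `"indeterminate"`).
#' @param thresholds high-clonality cutoffs, see [classify_clonality()].
#' @return A `clonality_result` list: sample_id, sample_type, s,
#'   clonality_pct, threshold_used, clonality_class.
#' @export
estimate_clonality <- function(profile, envelope, msi_status = "MSI_positive",
                               thresholds = c(FFPE = 18, LB = 7)) {
  s <- clonality_s(profile, envelope)
  applicable <- identical(msi_status, "MSI_positive") &&
    profile$sample_type != "REFERENCE" && !is.na(s)
  pct <- if (applicable) clonality_percent(s) else NA_real_
  cls <- if (applicable) {
    classify_clonality(pct, profile$sample_type, thresholds)
  } else {
    "not_applicable"
  }
  thr <- if (profile$sample_type %in% names(thresholds)) {
    thresholds[[profile$sample_type]]
  } else {
    NA_real_
  }
  structure(list(sample_id = profile$sample_id,
                 sample_type = profile$sample_type,
                 s = s, clonality_pct = pct,
                 threshold_used = thr, clonality_class = cls),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat("<clonality_result> ", x$sample_id, " (", x$sample_type, "): s = ",
      formatC(x$s, digits = 4, format = "f"), ", clonality = ",
      if (is.na(x$clonality_pct)) "NA" else
        formatC(x$clonality_pct, digits = 1, format = "f"),
      "% -> ", x$clonality_class, "\n", sep = "")
  invisible(x)
}
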