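#' Build a ratings matrix from a cohort
#'
#' Rows are patients, columns the four MSI/dMMR determination methods,
#' cells `"positive"`/`"negative"`/NA. dMMR (IHC) and MSI (PCR/NGS) are
#' treated as one binary phenotype.
#'
#' @param cohort an [msi_cohort()].
#' @return Character matrix with columns IHC, PCR, NGS_FFPE, NGS_LB and
#'   patient ids as row names.
#' @export
ratings_matrix <- function(cohort) {
  m <- cbind(IHC = cohort$ihc, PCR = cohort$pcr,
             NGS_FFPE = cohort$ngs_ffpe, NGS_LB = cohort$ngs_lb)
  rownames(m) <- cohort$patient_id
  m
}

#' Cohen's kappa for two raters on binary calls
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_e` from the product of the
#' two raters' marginal call rates. Undefined (NA) when `p_e = 1`, i.e.
#' when both raters are constant.
#'
#' @param a,b character vectors of calls (`"positive"`/`"negative"`),
#'   already complete (no NA).
#' @return Kappa, or NA when undefined.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  p_o <- mean(a == b)
  cats <- c("positive", "negative")
  pa <- vapply(cats, function(k) mean(a == k), numeric(1))
  pb <- vapply(cats, function(k) mean(b == k), numeric(1))
  p_e <- sum(pa * pb)
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise concordance between two methods
#'
#' Concordance rate (matching calls / complete pairs) and Cohen's kappa,
#' on the pairwise-complete subset (rows where both methods have a call).
#'
#' @param matrix ratings matrix from [ratings_matrix()].
#' @param method_a,method_b column names.
#' @return List: `rate`, `n_pairs`, `cohen_kappa`.
#' @export
pairwise_concordance <- function(matrix, method_a, method_b) {
  a <- matrix[, method_a]
  b <- matrix[, method_b]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no complete pairs for ", method_a, " vs ", method_b)
  list(rate = mean(a[ok] == b[ok]), n_pairs = sum(ok),
       cohen_kappa = cohen_kappa(a[ok], b[ok]))
}

#' All pairwise concordances
#'
#' @param matrix ratings matrix.
#' @return data.frame: method_a, method_b, rate, n_pairs, cohen_kappa.
#' @export
pairwise_concordance_table <- function(matrix) {
  methods <- colnames(matrix)
  pairs <- utils::combn(methods, 2)
  rows <- apply(pairs, 2, function(pr) {
    pc <- pairwise_concordance(matrix, pr[1], pr[2])
    data.frame(method_a = pr[1], method_b = pr[2], rate = pc$rate,
               n_pairs = pc$n_pairs, cohen_kappa = pc$cohen_kappa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fleiss's kappa across all methods
#'
#' Chance-corrected agreement of m raters on binary categories
#' (positive/negative), computed on rows complete for every method
#' (listwise deletion): `kappa = (P_bar - P_bar_e) / (1 - P_bar_e)` with
#' per-subject agreement `P_i = (sum_j n_ij^2 - m) / (m (m - 1))` and
#' chance agreement from squared category marginals.
#'
#' @param matrix ratings matrix.
#' @return Kappa (NA when `P_bar_e = 1`), with attribute `n_complete`.
#' @export
fleiss_kappa <- function(matrix) {
  ok <- stats::complete.cases(matrix)
  if (sum(ok) < 2) stop("need at least 2 complete rows for Fleiss's kappa")
  m <- ncol(matrix)
  sub <- matrix[ok, , drop = FALSE]
  n_pos <- rowSums(sub == "positive")
  counts <- cbind(pos = n_pos, neg = m - n_pos)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(counts) / (nrow(counts) * m)
  P_e <- sum(p_j^2)
  kap <- if (abs(1 - P_e) < .Machine$double.eps^0.5) NA_real_
         else (P_bar - P_e) / (1 - P_e)
  structure(kap, n_complete = nrow(sub))
}

#' Overall agreement of all methods
#'
#' Fraction of listwise-complete rows on which every method gives the same
#' call.
#'
#' @param matrix ratings matrix.
#' @return List: `rate`, `n_complete`.
#' @export
overall_agreement <- function(matrix) {
  ok <- stats::complete.cases(matrix)
  if (!any(ok)) stop("no rows complete for all methods")
  sub <- matrix[ok, , drop = FALSE]
  agree <- apply(sub, 1, function(r) length(unique(r)) == 1)
  list(rate = mean(agree), n_complete = sum(ok))
}

#' Discordance between IHC and genomic methods
#'
#' TRUE when the expression-level call (IHC, dMMR) differs from at least
#' one available genomic call (PCR or NGS) — the `"any"` rule; with
#' `require = "all"` the IHC call must differ from every available genomic
#' call. NA (not evaluable) when the IHC call or all genomic calls are
#' missing.
#'
#' @param ihc IHC call (`"positive"`/`"negative"`/NA).
#' @param genomic character vector of genomic calls (PCR, NGS FFPE, NGS LB).
#' @param require `"any"` (default) or `"all"`.
#' @return Logical or NA.
#' @export
discordance_flag <- function(ihc, genomic, require = c("any", "all")) {
  require <- match.arg(require)
  genomic <- genomic[!is.na(genomic)]
  if (is.na(ihc) || length(genomic) == 0) return(NA)
  diffs <- genomic != ihc
  if (require == "any") any(diffs) else all(diffs)
}

#' Full concordance analysis of a cohort
#'
#' @param cohort an [msi_cohort()].
#' @param require discordance rule, see [discordance_flag()].
#' @return List: `pairwise` (data.frame), `fleiss_kappa`,
#'   `overall` (rate + n), `discordance` (per-patient logical, NA when not
#'   evaluable).
#' @export
concordance_analysis <- function(cohort, require = "any") {
  m <- ratings_matrix(cohort)
  disc <- apply(m, 1, function(r)
    discordance_flag(r["IHC"], r[c("PCR", "NGS_FFPE", "NGS_LB")], require))
  list(pairwise = pairwise_concordance_table(m),
       fleiss_kappa = fleiss_kappa(m),
       overall = overall_agreement(m),
       discordance = disc)
}
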