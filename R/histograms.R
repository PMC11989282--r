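#' Construct a sample profile of STR length histograms
#'
#' A sample profile holds, for one FFPE, liquid-biopsy (LB) or reference
#' sample, the per-locus read-length histograms: for each locus a named
#' integer vector mapping the observed total tract length (bp) to the number
#' of supporting reads. The per-length read fractions (counts / depth) are
#' the "prevalences" on which MSI scoring and clonality estimation operate.
#'
#' @param sample_id sample identifier.
#' @param sample_type one of `"FFPE"`, `"LB"`, `"REFERENCE"`.
#' @param histograms named list (by locus_id); each element a named
#'   non-negative integer vector of read counts keyed by allele length in bp.
#' @return A `sample_profile` object.
#' @export
sample_profile <- function(sample_id, sample_type, histograms) {
  sample_type <- match.arg(sample_type, c("FFPE", "LB", "REFERENCE"))
  if (is.null(names(histograms)) || any(names(histograms) == "")) {
    stop("histograms must be a named list keyed by locus_id")
  }
  for (loc in names(histograms)) {
    h <- histograms[[loc]]
    if (length(h) > 0) {
      len <- suppressWarnings(as.integer(names(h)))
      if (any(is.na(len)) || any(len < 0)) {
        stop("allele lengths must be non-negative integers (locus ", loc, ")")
      }
      if (any(h < 0)) stop("negative read count at locus ", loc)
      histograms[[loc]] <- h[order(len)]
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 sample_type = sample_type,
                 histograms = histograms),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  depths <- vapply(x$histograms, sum, numeric(1))
  cat("<sample_profile> ", x$sample_id, " (", x$sample_type, "): ",
      length(x$histograms), " loci, median depth ",
      stats::median(depths), "\n", sep = "")
  invisible(x)
}

#' Read sample profiles from a long-format TSV
#'
#' Expects columns `sample_id`, `sample_type`, `locus_id`, `length_bp`,
#' `count`. Lengths with zero reads may be omitted. Duplicate
#' (sample, locus, length) rows are summed with a warning.
#'
#' @param path path to the histogram TSV.
#' @param panel optional `str_panel`; when given, rows whose `locus_id` is
#'   not in the panel are an error.
#' @return Named list of `sample_profile` objects, one per sample_id.
#' @export
read_histograms <- function(path, panel = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "sample_type", "locus_id", "length_bp", "count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("histogram file missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$count < 0)) stop("negative read count in histogram file")
  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$locus_id), panel$locus_id)
    if (length(unknown) > 0) {
      stop("locus_id not in panel: ", paste(unknown, collapse = ", "))
    }
  }
  key <- paste(df$sample_id, df$locus_id, df$length_bp, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (sample, locus, length) rows; counts summed")
    df <- stats::aggregate(count ~ sample_id + sample_type + locus_id +
                             length_bp, data = df, FUN = sum)
  }
  out <- list()
  for (sid in unique(df$sample_id)) {
    sub <- df[df$sample_id == sid, , drop = FALSE]
    stype <- unique(sub$sample_type)
    if (length(stype) != 1) {
      stop("inconsistent sample_type for sample ", sid)
    }
    hists <- lapply(split(sub, sub$locus_id), function(s) {
      stats::setNames(as.integer(s$count), as.character(s$length_bp))
    })
    out[[sid]] <- sample_profile(sid, stype, hists)
  }
  out
}

#' Write sample profiles to a long-format TSV
#'
#' @param profiles a `sample_profile` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histograms <- function(profiles, path) {
  if (inherits(profiles, "sample_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p$histograms), function(loc) {
      h <- p$histograms[[loc]]
      if (length(h) == 0) return(NULL)
      data.frame(sample_id = p$sample_id, sample_type = p$sample_type,
                 locus_id = loc, length_bp = as.integer(names(h)),
                 count = as.integer(h), stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
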