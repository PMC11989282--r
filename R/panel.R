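#' Construct and validate an STR panel
#'
#' A panel describes the microsatellite loci interrogated by the assay: one
#' row per locus with genomic coordinates (0-based, half-open, BED
#' convention), the repeat unit (1-6 bp over A/C/G/T) and the derived
#' reference tract length in bp, which is the comparison point for all
#' downstream alteration calls.
#'
#' @param df data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `repeat_unit`.
#' @return A validated `str_panel` data.frame with an added
#'   `ref_length_bp = end - start` column.
#' @export
str_panel <- function(df) {
  required <- c("locus_id", "chrom", "start", "end", "repeat_unit")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$locus_id <- as.character(df$locus_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$repeat_unit <- toupper(as.character(df$repeat_unit))
  if (anyDuplicated(df$locus_id)) {
    stop("duplicate locus_id in panel: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  }
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("panel coordinates must be integers")
  }
  bad <- df$end <= df$start
  if (any(bad)) {
    stop("panel rows with end <= start: ",
         paste(df$locus_id[bad], collapse = ", "))
  }
  if (any(!grepl("^[ACGT]{1,6}$", df$repeat_unit))) {
    stop("repeat_unit must be a 1-6 bp string over A/C/G/T")
  }
  df$ref_length_bp <- df$end - df$start
  rownames(df) <- NULL
  df <- df[, c(required, "ref_length_bp")]
  class(df) <- c("str_panel", "data.frame")
  df
}

#' Read an STR panel from a TSV file
#'
#' Expects a tab-separated file with header columns `locus_id`, `chrom`,
#' `start`, `end`, `repeat_unit`. Coordinates are 0-based half-open; lines
#' starting with `#` are treated as comments.
#'
#' @param path path to the panel TSV.
#' @return An `str_panel` data.frame (possibly with zero rows).
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = "character")
  str_panel(df)
}

#' Write an STR panel to TSV
#'
#' @param panel an `str_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "str_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STR panel; coordinates are 0-based, half-open (BED convention)",
             con)
  utils::write.table(
    panel[, c("locus_id", "chrom", "start", "end", "repeat_unit")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Reference tract length lookup, named by locus_id.
panel_ref_lengths <- function(panel) {
  stats::setNames(panel$ref_length_bp, panel$locus_id)
}

# Repeat-unit length (bp) lookup, named by locus_id.
panel_unit_lengths <- function(panel) {
  stats::setNames(nchar(panel$repeat_unit), panel$locus_id)
}
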