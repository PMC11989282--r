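#' Validate a patient cohort table
#'
#' One row per patient. Method calls (`ihc`, `pcr`, `ngs_ffpe`, `ngs_lb`)
#' are `"positive"`/`"negative"` with `NA` for not performed; dMMR by IHC
#' and MSI by PCR/NGS are treated as the same binary phenotype. Clonality
#' columns (percent) are only meaningful for samples whose NGS call is
#' positive. `response` follows RECIST (`CR`, `PR`, `SD`, `PD`) with `NE`
#' for not evaluable/censored; `pfs_time` is progression-free survival in
#' days; `event = TRUE` marks progression (missing defaults to censored,
#' with a warning).
#'
#' @param df data.frame of patient rows.
#' @return A validated `msi_cohort` data.frame.
#' @export
msi_cohort <- function(df) {
  required <- c("patient_id", "age", "sex", "stage", "setting",
                "ihc", "pcr", "ngs_ffpe", "ngs_lb",
                "clonality_ffpe", "clonality_lb",
                "response", "pfs_time", "event", "braf_v600", "ras")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in cohort")

  check_enum <- function(x, levels, col, allow_na = TRUE) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("invalid value(s) in ", col, ": ",
           paste(unique(x[bad]), collapse = ", "))
    }
    if (!allow_na && any(is.na(x))) stop("missing value in required column ", col)
    x
  }
  df$sex <- check_enum(df$sex, c("female", "male"), "sex", allow_na = FALSE)
  df$stage <- check_enum(df$stage, c("II", "III", "IV"), "stage",
                         allow_na = FALSE)
  df$setting <- check_enum(
    df$setting, c("preoperative", "advanced_1L", "advanced_2L3L"),
    "setting", allow_na = FALSE)
  for (m in c("ihc", "pcr", "ngs_ffpe", "ngs_lb")) {
    df[[m]] <- check_enum(df[[m]], c("positive", "negative"), m)
  }
  df$response <- check_enum(df$response, c("CR", "PR", "SD", "PD", "NE"),
                            "response", allow_na = FALSE)
  for (g in c("braf_v600", "ras")) {
    x <- check_enum(df[[g]], c("positive", "negative", "unknown"), g)
    x[is.na(x)] <- "unknown"
    df[[g]] <- x
  }
  df$age <- as.numeric(df$age)
  df$pfs_time <- as.numeric(df$pfs_time)
  if (any(is.na(df$pfs_time)) || any(df$pfs_time <= 0)) {
    stop("pfs_time must be > 0 for every patient")
  }
  ev <- df$event
  if (is.character(ev)) ev <- ev %in% c("TRUE", "true", "1", "yes")
  ev <- as.logical(ev)
  if (any(is.na(ev))) {
    warning("missing event flag for ",
            sum(is.na(ev)), " patient(s); treated as censored")
    ev[is.na(ev)] <- FALSE
  }
  df$event <- ev
  for (cl in c("clonality_ffpe", "clonality_lb")) {
    df[[cl]] <- as.numeric(df[[cl]])
    bad <- !is.na(df[[cl]]) & (df[[cl]] < 0 | df[[cl]] > 100)
    if (any(bad)) stop(cl, " must lie in [0, 100]")
  }
  rownames(df) <- NULL
  df <- df[, union(required, names(df))]
  class(df) <- c("msi_cohort", "data.frame")
  df
}

#' Read a patient cohort from CSV
#'
#' @param path path to the cohort CSV; missing values as empty fields or NA.
#' @return A validated `msi_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  msi_cohort(df)
}

#' Write a patient cohort to CSV
#'
#' @param cohort an `msi_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "msi_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
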