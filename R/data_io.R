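#' Expression cohort container
#'
#' A patients x features expression matrix with sample and feature
#' identifiers. Values must be finite and non-negative (RPM-like units).
#'
#' @param values numeric matrix, samples in rows
#' @param sample_ids character vector, one per row
#' @param feature_names character vector, one per column
#' @return an `expression_cohort` object
#' @export
expression_cohort <- function(values, sample_ids, feature_names) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(sample_ids)) {
    stop("row count (", nrow(values), ") != number of sample ids (",
         length(sample_ids), ")")
  }
  if (ncol(values) != length(feature_names)) {
    stop("column count (", ncol(values), ") != number of feature names (",
         length(feature_names), ")")
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature name: ",
         feature_names[duplicated(feature_names)][1])
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(as.character(sample_ids),
                           as.character(feature_names))
  structure(list(sample_ids = as.character(sample_ids),
                 feature_names = as.character(feature_names),
                 values = values),
            class = "expression_cohort")
}

#' @exportS3Method base::print
print.expression_cohort <- function(x, ...) {
  cat("<expression_cohort> ", length(x$sample_ids), " samples x ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Read an expression table
#'
#' Reads a delimited (TSV/CSV, sniffed from the first line) expression
#' table with one header row and one name column, in either orientation,
#' and returns a samples-in-rows [expression_cohort].
#'
#' @param path file path
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`
#' @param log2_transform apply log2(x + 1) to all values after reading;
#'   off by default (the modelling pipeline standardizes per CV fold, so
#'   this is an optional variance-stabilizing convenience only)
#' @return an [expression_cohort]
#' @export
load_expression <- function(path,
                            orientation = c("samples_in_rows",
                                            "features_in_rows"),
                            log2_transform = FALSE) {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE,
                           colClasses = "character",
                           comment.char = "", quote = "\"")
  vals <- as.matrix(tab)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell '", vals[bad[1, 1], bad[1, 2]],
         "' at row '", rownames(vals)[bad[1, 1]],
         "', column '", colnames(vals)[bad[1, 2]], "' in ", path)
  }
  if (orientation == "features_in_rows") num <- t(num)
  if (log2_transform) num <- log2(num + 1)
  expression_cohort(num, rownames(num), colnames(num))
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a clinical table
#'
#' Reads a TCGA-clinical-style delimited table with required columns
#' `patient_id`, `vital_status`, `days_to_death`,
#' `days_to_last_followup`. Empty cells and "NA" mean absent. Vital
#' status is matched case-insensitively against deceased/dead and
#' living/alive.
#'
#' @param path file path
#' @return data frame of clinical records, one row per patient entry;
#'   `vital_status` is a factor with levels deceased/living, day fields
#'   numeric with `NA` for absent
#' @export
load_clinical <- function(path) {
  sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           na.strings = c("", "NA"))
  need <- c("patient_id", "vital_status", "days_to_death",
            "days_to_last_followup")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("clinical table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  status_raw <- tolower(trimws(tab$vital_status))
  status <- ifelse(status_raw %in% c("deceased", "dead"), "deceased",
            ifelse(status_raw %in% c("living", "alive"), "living", NA))
  if (anyNA(status)) {
    stop("unrecognized vital_status value: ",
         tab$vital_status[which(is.na(status))[1]])
  }
  dtd <- suppressWarnings(as.numeric(tab$days_to_death))
  dtf <- suppressWarnings(as.numeric(tab$days_to_last_followup))
  bad_death <- which(status == "deceased" & is.na(dtd))
  if (length(bad_death) > 0) {
    stop("deceased patient '", tab$patient_id[bad_death[1]],
         "' has no days_to_death")
  }
  if (any(dtd < 0, na.rm = TRUE) || any(dtf < 0, na.rm = TRUE)) {
    stop("negative day values in clinical table")
  }
  data.frame(patient_id = tab$patient_id,
             vital_status = factor(status, levels = c("deceased", "living")),
             days_to_death = dtd,
             days_to_last_followup = dtf,
             stringsAsFactors = FALSE)
}

DAYS_PER_YEAR <- 365.25
MIN_SURVIVAL_DAYS <- 30

#' Assemble the survival modelling dataset
#'
#' Intersects an expression cohort with a clinical table and applies the
#' cohort filters: keep deceased patients present in both tables, drop
#' survival periods under 30 days (strictly: exactly 30 is retained),
#' deduplicate patient ids keeping the first occurrence. Survival is
#' converted to years at 365.25 days/year.
#'
#' @param expr an [expression_cohort]
#' @param clinical data frame from [load_clinical()]
#' @param verbose log the number of patients dropped at each filter stage
#' @return a `survival_dataset`: list with `cohort` (filtered
#'   [expression_cohort]) and `survival_years`
#' @export
build_dataset <- function(expr, clinical, verbose = FALSE) {
  dup <- duplicated(clinical$patient_id)
  if (verbose && any(dup)) {
    message(sum(dup), " duplicate clinical entr(ies) dropped")
  }
  clin <- clinical[!dup, , drop = FALSE]
  dec <- clin[clin$vital_status == "deceased", , drop = FALSE]
  keep <- dec$days_to_death >= MIN_SURVIVAL_DAYS
  if (verbose && any(!keep)) {
    message(sum(!keep), " patient(s) with survival < ", MIN_SURVIVAL_DAYS,
            " days excluded")
  }
  dec <- dec[keep, , drop = FALSE]
  common <- intersect(expr$sample_ids, dec$patient_id)
  if (verbose) {
    message(length(expr$sample_ids) - length(common),
            " expression sample(s) without eligible clinical record dropped")
  }
  if (length(common) == 0) stop("no eligible patients")
  rows <- match(common, expr$sample_ids)
  days <- dec$days_to_death[match(common, dec$patient_id)]
  cohort <- expression_cohort(expr$values[rows, , drop = FALSE],
                              common, expr$feature_names)
  structure(list(cohort = cohort,
                 survival_years = days / DAYS_PER_YEAR),
            class = "survival_dataset")
}

#' @exportS3Method base::print
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> ", length(x$survival_years), " deceased patients x ",
      length(x$cohort$feature_names), " features; survival ",
      sprintf("%.2f-%.2f", min(x$survival_years), max(x$survival_years)),
      " years\n", sep = "")
  invisible(x)
}

#' Assemble the living follow-up cohort
#'
#' Keeps living patients with a recorded follow-up time, for the
#' censored-cohort validation protocol. Follow-up is converted to years
#' at 365.25 days/year.
#'
#' @inheritParams build_dataset
#' @return a `followup_cohort`: list with `cohort` and `followup_years`
#' @export
build_followup_cohort <- function(expr, clinical, verbose = FALSE) {
  clin <- clinical[!duplicated(clinical$patient_id), , drop = FALSE]
  liv <- clin[clin$vital_status == "living" &
                !is.na(clin$days_to_last_followup) &
                clin$days_to_last_followup > 0, , drop = FALSE]
  common <- intersect(expr$sample_ids, liv$patient_id)
  if (verbose) {
    message(length(common), " living patient(s) with follow-up retained")
  }
  rows <- match(common, expr$sample_ids)
  days <- liv$days_to_last_followup[match(common, liv$patient_id)]
  cohort <- expression_cohort(expr$values[rows, , drop = FALSE],
                              common, expr$feature_names)
  structure(list(cohort = cohort,
                 followup_years = days / DAYS_PER_YEAR),
            class = "followup_cohort")
}

#' @exportS3Method base::print
print.followup_cohort <- function(x, ...) {
  cat("<followup_cohort> ", length(x$followup_years),
      " living patients\n", sep = "")
  invisible(x)
}
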