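#' Validate a survival model on a living follow-up cohort
#'
#' For a living patient, the true survival time is at least the
#' follow-up time, so an estimate strictly greater than the follow-up
#' is consistent with the observation. The protocol counts these
#' patients; the classification accuracy is their fraction of the
#' cohort. Ties (estimate exactly equal to follow-up) count as
#' not-exceeding. For the remaining patients — whose estimate fell at
#' or below an observed lower bound, i.e. is demonstrably short — the
#' MAE between estimate and follow-up is reported in years.
#'
#' @param model an `svr_model` (or anything with a `predict` method
#'   accepting an [expression_cohort]), or a plain function
#'   `cohort -> estimates` (handy for oracle predictors)
#' @param cohort a `followup_cohort`
#' @return a `validation_report`: n_patients,
#'   n_estimate_exceeds_followup, classification_accuracy,
#'   mae_remaining_years (NA when no patient remains), per_patient
#'   data frame (id, followup_years, estimated_years, exceeds)
#' @export
validate_on_followup <- function(model, cohort) {
  stopifnot(inherits(cohort, "followup_cohort"))
  est <- if (is.function(model)) model(cohort$cohort)
         else predict(model, cohort$cohort)
  stopifnot(length(est) == length(cohort$followup_years))
  fup <- cohort$followup_years
  exceeds <- est > fup
  n <- length(fup)
  remaining <- !exceeds
  mae_rem <- if (any(remaining)) {
    mean_absolute_error(fup[remaining], est[remaining])
  } else NA_real_
  structure(list(
    n_patients = n,
    n_estimate_exceeds_followup = sum(exceeds),
    classification_accuracy = sum(exceeds) / n,
    mae_remaining_years = mae_rem,
    per_patient = data.frame(id = cohort$cohort$sample_ids,
                             followup_years = fup,
                             estimated_years = est,
                             exceeds = exceeds)),
    class = "validation_report")
}

#' @exportS3Method base::print
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> %d/%d estimates exceed follow-up ",
                     "(accuracy %.1f%%); MAE over remaining %s years\n"),
              x$n_estimate_exceeds_followup, x$n_patients,
              100 * x$classification_accuracy,
              ifelse(is.na(x$mae_remaining_years), "-",
                     sprintf("%.2f", x$mae_remaining_years))))
  invisible(x)
}

#' Summary statistics of estimated and follow-up times
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the estimates
#' and the follow-ups, in years and months (months = years x 12
#' exactly). A single-patient cohort reports SD 0 with
#' `degenerate_sd = TRUE`.
#'
#' @param report a `validation_report`
#' @return list with mean/sd of estimates and follow-ups in years and
#'   months
#' @export
summarize_estimates <- function(report) {
  stopifnot(inherits(report, "validation_report"),
            report$n_patients >= 1)
  est <- report$per_patient$estimated_years
  fup <- report$per_patient$followup_years
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  list(mean_estimate_years = mean(est), sd_estimate_years = sd0(est),
       mean_followup_years = mean(fup), sd_followup_years = sd0(fup),
       mean_estimate_months = mean(est) * 12,
       sd_estimate_months = sd0(est) * 12,
       mean_followup_months = mean(fup) * 12,
       sd_followup_months = sd0(fup) * 12,
       degenerate_sd = length(est) < 2)
}

#' Write a validation report as per-patient TSV plus summary JSON
#'
#' @param report a `validation_report`
#' @param path_tsv,path_json output paths (either may be NULL)
#' @export
write_validation_report <- function(report, path_tsv = NULL,
                                    path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(report$per_patient, path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    s <- summarize_estimates(report)
    jsonlite::write_json(
      c(list(n_patients = report$n_patients,
             n_estimate_exceeds_followup =
               report$n_estimate_exceeds_followup,
             classification_accuracy = report$classification_accuracy,
             mae_remaining_years = report$mae_remaining_years), s),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
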