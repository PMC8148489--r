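#' Simulation configuration
#'
#' Study-condition defaults emulate the shape of a TCGA-style ovarian
#' miRNA-seq cohort: 369 profiled patients of whom 209 are deceased
#' (the modelling set) and 160 living (the follow-up validation set),
#' 415 right-skewed non-negative expression features, and survival in
#' years driven by a small planted feature subset.
#'
#' @param n_samples total patients simulated
#' @param n_features expression features
#' @param signal_features number k of planted survival-related features
#' @param effect_sizes k generating weights (years per SD of expression);
#'   default magnitudes decline from 0.8 to 0.4 with alternating sign
#' @param intercept_years baseline survival in years
#' @param noise_sd additive Gaussian noise SD, years
#' @param expression_law `"lognormal"` or `"gamma"` marginal law
#' @param nonlinear_fraction fraction of signal features whose
#'   standardized value is squared before weighting (mild nonlinearity)
#' @param censor_fraction fraction of patients routed to the living
#'   follow-up cohort
#' @param seed integer seed; the whole simulation is deterministic given it
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_samples = 369,
                              n_features = 415,
                              signal_features = 10,
                              effect_sizes = NULL,
                              intercept_years = 3,
                              noise_sd = 0.5,
                              expression_law = c("lognormal", "gamma"),
                              nonlinear_fraction = 0.2,
                              censor_fraction = 160 / 369,
                              seed = 1L) {
  expression_law <- match.arg(expression_law)
  k <- signal_features
  if (is.null(effect_sizes)) {
    effect_sizes <- seq(0.8, 0.4, length.out = k) *
      rep_len(c(1, -1), k)
  }
  stopifnot(k >= 1, k <= n_features,
            length(effect_sizes) == k,
            noise_sd >= 0,
            censor_fraction >= 0, censor_fraction < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 signal_features = as.integer(k),
                 effect_sizes = as.numeric(effect_sizes),
                 intercept_years = intercept_years,
                 noise_sd = noise_sd,
                 expression_law = expression_law,
                 nonlinear_fraction = nonlinear_fraction,
                 censor_fraction = censor_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an expression cohort with a planted survival signature
#'
#' Expression is drawn per feature from the configured right-skewed law.
#' Survival (years) is `intercept + sum(w_j * z_j)` over the planted
#' features, where `z_j` is the within-cohort z-score of feature j (so
#' effect sizes are comparable across features while emitted expression
#' stays on its natural scale); a `nonlinear_fraction` of the planted
#' features contribute `w_j * (min(|z_j|, 3)^2 - 1)` instead (winsorized
#' so heavy-tailed expression cannot let one sample dominate, centred so
#' the intercept stays the cohort mean). Gaussian noise is added,
#' and if any survival falls at or below the 30-day intake filter the
#' whole cohort is shifted up so no synthetic sample would be dropped
#' (a shift preserves the linear form up to its intercept). A
#' `censor_fraction` of patients is emitted as a living follow-up
#' cohort with `followup = u * true_survival`, u ~ U(0.2, 1.3), so
#' follow-up both under- and overshoots true survival.
#'
#' @param cfg a [simulation_config()]
#' @return list with `dataset` (a `survival_dataset` of the deceased),
#'   `followup` (a `followup_cohort` of the living; NULL if
#'   `censor_fraction` is 0) and `truth` (signal indices/names,
#'   generating coefficients, per-sample noiseless survival,
#'   per-living-sample true survival)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    d <- cfg$n_features
    k <- cfg$signal_features
    X <- switch(cfg$expression_law,
      lognormal = {
        meanlog <- stats::rnorm(d, mean = 2, sd = 1)
        sdlog <- stats::runif(d, 0.4, 1.0)
        vapply(seq_len(d),
               function(j) stats::rlnorm(n, meanlog[j], sdlog[j]),
               numeric(n))
      },
      gamma = {
        shape <- stats::runif(d, 1.2, 4)
        rate <- stats::runif(d, 0.05, 0.5)
        vapply(seq_len(d),
               function(j) stats::rgamma(n, shape[j], rate[j]),
               numeric(n))
      })
    sample_ids <- sprintf("SIM-%04d", seq_len(n))
    feature_names <- sprintf("mir-sim-%03d", seq_len(d))
    signal_idx <- sort(sample.int(d, k))
    n_sq <- floor(cfg$nonlinear_fraction * k)
    squared <- rep(c(FALSE, TRUE), c(k - n_sq, n_sq))

    Z <- scale(X[, signal_idx, drop = FALSE])
    # nonlinear terms use winsorized, centred squares: skewed expression
    # gives heavy-tailed z-scores, and an unbounded z^2 would let single
    # samples dominate the cohort; clamping at |z| = 3 keeps the
    # nonlinearity mild, and subtracting E[z^2] = 1 keeps the intercept
    # the cohort-mean survival
    Zsq <- pmin(pmax(Z, -3), 3)^2 - 1
    contrib <- sweep(ifelse(matrix(squared, n, k, byrow = TRUE), Zsq, Z),
                     2, cfg$effect_sizes, `*`)
    y_true <- cfg$intercept_years + rowSums(contrib)
    y <- y_true + stats::rnorm(n, 0, cfg$noise_sd)
    thr <- MIN_SURVIVAL_DAYS / DAYS_PER_YEAR
    lo <- min(y, y_true)
    if (lo <= thr) {
      shift <- thr + 0.1 - lo
      y <- y + shift
      y_true <- y_true + shift
    }

    n_cens <- round(cfg$censor_fraction * n)
    cens_idx <- if (n_cens > 0) sort(sample.int(n, n_cens)) else integer(0)
    dead_idx <- setdiff(seq_len(n), cens_idx)

    cohort_dead <- expression_cohort(X[dead_idx, , drop = FALSE],
                                     sample_ids[dead_idx], feature_names)
    dataset <- structure(list(cohort = cohort_dead,
                              survival_years = y[dead_idx]),
                         class = "survival_dataset")
    followup <- NULL
    true_surv_living <- numeric(0)
    if (n_cens > 0) {
      u <- stats::runif(n_cens, 0.2, 1.3)
      fup <- pmax(u * y_true[cens_idx], 1 / DAYS_PER_YEAR)
      cohort_liv <- expression_cohort(X[cens_idx, , drop = FALSE],
                                      sample_ids[cens_idx], feature_names)
      followup <- structure(list(cohort = cohort_liv,
                                 followup_years = fup),
                            class = "followup_cohort")
      true_surv_living <- y_true[cens_idx]
    }
    truth <- list(signal_indices = signal_idx,
                  signal_features = feature_names[signal_idx],
                  coefficients = cfg$effect_sizes,
                  squared = squared,
                  intercept_years = cfg$intercept_years,
                  true_survival = y_true[dead_idx],
                  true_survival_living = true_surv_living,
                  seed = cfg$seed)
    list(dataset = dataset, followup = followup, truth = truth)
  })
}

#' Write a simulated cohort in the dialects the readers consume
#'
#' Emits `expression.tsv` (all samples, samples in rows),
#' `clinical.tsv` (deceased rows with days_to_death, living rows with
#' days_to_last_followup; day values at full precision) and
#' `truth.json`, so that [load_expression()] + [load_clinical()] +
#' [build_dataset()] / [build_followup_cohort()] round-trip the cohort.
#'
#' @param sim result of [simulate_cohort()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_vals <- rbind(sim$dataset$cohort$values,
                    if (!is.null(sim$followup)) sim$followup$cohort$values)
  expr_path <- file.path(out_dir, "expression.tsv")
  expr_tab <- data.frame(sample_id = rownames(all_vals),
                         format(all_vals, digits = 10, trim = TRUE,
                                scientific = FALSE),
                         check.names = FALSE)
  utils::write.table(expr_tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dead <- data.frame(
    patient_id = sim$dataset$cohort$sample_ids,
    vital_status = "deceased",
    days_to_death = format(sim$dataset$survival_years * DAYS_PER_YEAR,
                           digits = 12, trim = TRUE, scientific = FALSE),
    days_to_last_followup = NA)
  clin <- dead
  if (!is.null(sim$followup)) {
    liv <- data.frame(
      patient_id = sim$followup$cohort$sample_ids,
      vital_status = "living",
      days_to_death = NA,
      days_to_last_followup = format(
        sim$followup$followup_years * DAYS_PER_YEAR,
        digits = 12, trim = TRUE, scientific = FALSE))
    clin <- rbind(clin, liv)
  }
  clin_path <- file.path(out_dir, "clinical.tsv")
  utils::write.table(clin, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(expression = expr_path, clinical = clin_path,
              truth = truth_path))
}
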