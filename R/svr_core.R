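#' nu-SVR hyperparameter configuration
#'
#' @param gamma RBF kernel width, > 0
#' @param cost regularisation parameter C, > 0
#' @param nu nu in (0, 1]: upper bound on the fraction of margin errors
#'   and lower bound on the fraction of support vectors; the tube width
#'   epsilon is determined by the solver, not exposed
#' @return an `svr_config`
#' @export
svr_config <- function(gamma, cost, nu) {
  stopifnot(is.numeric(gamma), gamma > 0,
            is.numeric(cost), cost > 0,
            is.numeric(nu), nu > 0, nu <= 1)
  structure(list(gamma = gamma, cost = cost, nu = nu),
            class = "svr_config")
}

#' Pearson correlation between real and estimated survival
#'
#' CC = sum((x - mean(x)) (z - mean(z))) /
#'      sqrt(sum((x - mean(x))^2) sum((z - mean(z))^2)).
#'
#' @param x real survival vector
#' @param z estimated survival vector, same length (>= 2)
#' @return value in \[-1, 1\]
#' @export
correlation_coefficient <- function(x, z) {
  if (length(x) != length(z)) stop("length mismatch: ", length(x),
                                   " vs ", length(z))
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(z) == 0) {
    stop("undefined correlation: both vectors constant")
  }
  if (stats::sd(x) == 0 || stats::sd(z) == 0) return(0)
  stats::cor(x, z)
}

#' Mean absolute error in years
#'
#' MAE = (1/N) sum |x_i - z_i|. (The source describing this estimator
#' prints a squared deviation under the MAE name; the name and the
#' reported units, years, indicate the exponent is a typo, so the
#' first-power absolute deviation is used.)
#'
#' @inheritParams correlation_coefficient
#' @return non-negative value, years
#' @export
mean_absolute_error <- function(x, z) {
  if (length(x) != length(z)) stop("length mismatch: ", length(x),
                                   " vs ", length(z))
  if (length(x) < 1) stop("need at least 1 observation")
  mean(abs(x - z))
}

#' Fit a nu-SVR survival model on a feature subset
#'
#' Features are standardized with training-set mean/SD (zero-variance
#' features get unit scale so they contribute nothing to the RBF
#' distance) and an RBF-kernel nu-SVR is fitted via libsvm. The handle
#' carries the scaling so prediction applies it to new data.
#'
#' @param train_X numeric matrix of the selected features, samples in rows
#' @param train_y survival in years
#' @param cfg an [svr_config()]
#' @param feature_names names of the selected features (defaults to
#'   `colnames(train_X)`)
#' @param standardize standardize features before the kernel (default
#'   TRUE; raw RPM scales make the RBF kernel degenerate)
#' @return an `svr_model` handle usable with `predict()`
#' @export
fit_svr <- function(train_X, train_y, cfg, feature_names = colnames(train_X),
                    standardize = TRUE) {
  stopifnot(inherits(cfg, "svr_config"))
  train_X <- as.matrix(train_X)
  if (ncol(train_X) == 0) stop("empty feature mask")
  if (nrow(train_X) < 2) stop("need at least 2 training samples")
  if (standardize) {
    center <- colMeans(train_X)
    scale_ <- apply(train_X, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  } else {
    center <- rep(0, ncol(train_X))
    scale_ <- rep(1, ncol(train_X))
  }
  Xs <- sweep(sweep(train_X, 2, center), 2, scale_, `/`)
  fit <- e1071::svm(Xs, train_y, type = "nu-regression", kernel = "radial",
                    gamma = cfg$gamma, cost = cfg$cost, nu = cfg$nu,
                    scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, cfg = cfg,
                 feature_names = feature_names,
                 center = center, scale = scale_),
            class = "svr_model")
}

#' Predict survival years from an svr_model
#'
#' @param object an `svr_model`
#' @param newdata matrix with the model's features in columns, or an
#'   [expression_cohort] (features looked up by name)
#' @param ... unused
#' @return numeric vector of estimated survival, years
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_cohort")) {
    miss <- setdiff(object$feature_names, newdata$feature_names)
    if (length(miss) > 0) {
      stop("features missing from cohort: ", paste(miss, collapse = ", "))
    }
    newdata <- newdata$values[, object$feature_names, drop = FALSE]
  }
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  as.numeric(stats::predict(object$fit, Xs))
}

#' Serialize an svr_model to JSON text
#'
#' Writes everything needed to reproduce predictions (support vectors,
#' dual coefficients, rho, kernel gamma, feature scaling) in a
#' versioned plain-text JSON file; [load_svr_model()] reconstructs a
#' handle whose predictions are computed directly from the kernel
#' expansion.
#'
#' @param model an `svr_model`
#' @param path output path
#' @export
save_svr_model <- function(model, path) {
  fit <- model$fit
  obj <- list(format = "svrsig-model", version = 1L,
              kernel = "radial",
              gamma = model$cfg$gamma, cost = model$cfg$cost,
              nu = model$cfg$nu,
              feature_names = model$feature_names,
              center = model$center, scale = model$scale,
              support_vectors = unname(as.matrix(fit$SV)),
              dual_coefs = as.numeric(fit$coefs),
              rho = fit$rho)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_svr_model
#' @return a `svr_model_json` handle usable with `predict()`
#' @export
load_svr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "svrsig-model")) {
    stop("not an svrsig model file: ", path)
  }
  obj$support_vectors <- as.matrix(obj$support_vectors)
  structure(obj, class = "svr_model_json")
}

#' @export
predict.svr_model_json <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_cohort")) {
    newdata <- newdata$values[, object$feature_names, drop = FALSE]
  }
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  SV <- object$support_vectors
  # RBF kernel expansion: f(x) = sum_s alpha_s exp(-gamma ||x - sv_s||^2) - rho
  d2 <- outer(rowSums(Xs^2), rowSums(SV^2), `+`) - 2 * Xs %*% t(SV)
  K <- exp(-object$gamma * pmax(d2, 0))
  as.numeric(K %*% object$dual_coefs - object$rho)
}

#' 10-fold cross-validated fitness of a feature mask
#'
#' Partitions the cohort into k near-equal folds by a seeded shuffle,
#' trains on the remainder of each fold and predicts it, then scores
#' the pooled out-of-fold predictions with [correlation_coefficient()]
#' and [mean_absolute_error()]. Deterministic given
#' (dataset, mask, cfg, k, seed). A precomputed fold assignment can be
#' passed so that many masks are scored on identical folds.
#'
#' @param dataset a `survival_dataset`
#' @param mask binary (0/1 or logical) vector over the dataset's features
#' @param cfg an [svr_config()]
#' @param k fold count (default 10)
#' @param seed fold-shuffle seed (ignored when `folds` given)
#' @param folds optional integer fold labels from an earlier partition
#' @param standardize passed to [fit_svr()]
#' @return a `fitness_result`: cc, mae_years, oof_predictions,
#'   fold_assignment
#' @export
cv_fitness <- function(dataset, mask, cfg, k = 10, seed = NULL,
                       folds = NULL, standardize = TRUE) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty feature mask")
  y <- dataset$survival_years
  n <- length(y)
  if (is.null(folds)) {
    if (k > n) stop("k (", k, ") exceeds sample count (", n, ")")
    folds <- make_folds(n, k, seed)
  }
  X <- dataset$cohort$values[, mask, drop = FALSE]
  preds <- numeric(n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- fit_svr(X[!test, , drop = FALSE], y[!test], cfg,
                     standardize = standardize)
    preds[test] <- predict(model, X[test, , drop = FALSE])
  }
  structure(list(cc = correlation_coefficient(y, preds),
                 mae_years = mean_absolute_error(y, preds),
                 oof_predictions = preds,
                 fold_assignment = folds),
            class = "fitness_result")
}

#' @exportS3Method base::print
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result> CC = %.4f, MAE = %.4f years (%d folds)\n",
              x$cc, x$mae_years, length(unique(x$fold_assignment))))
  invisible(x)
}
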