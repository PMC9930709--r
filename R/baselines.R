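#' Logistic-regression propensity scores
#'
#' Maximum-likelihood logistic fit (IRLS, tolerance 1e-8) of treatment on an
#' intercept plus the covariates; scores are the fitted probabilities
#' `exp(X'b) / (1 + exp(X'b))`. Perfect or near separation is reported as
#' non-convergence and the clipped scores are returned with a warning.
#'
#' @param covariates complete numeric matrix (no missing cells).
#' @param treatment 0/1 vector with both groups present.
#' @param method_label label stored in the returned scores.
#' @return list with `model` (class `logistic_model`: coefficients,
#'   converged, n_iterations) and `propensity` (a [propensity_result()]).
#' @export
fit_logistic_ps <- function(covariates, treatment, method_label = "logistic") {
  x <- as.matrix(covariates)
  if (anyNA(x)) stop("covariates must be complete")
  treatment <- as.numeric(treatment)
  if (!all(treatment %in% c(0, 1)) || length(unique(treatment)) < 2) {
    stop("treatment must contain both groups")
  }
  design <- cbind(`(Intercept)` = 1, x)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(design, treatment, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sep <- warned || !fit$converged || any(abs(fit$coefficients) > 50)
  if (sep) {
    warning("possible separation: logistic fit did not converge cleanly; ",
            "returning clipped scores")
  }
  model <- structure(list(coefficients = fit$coefficients,
                          converged = fit$converged && !sep,
                          n_iterations = fit$iter),
                     class = "logistic_model")
  list(model = model,
       propensity = propensity_result(fit$fitted.values, method_label))
}

#' Missing-indicator propensity scores
#'
#' Missing continuous cells are set to 0, one 0/1 missingness indicator
#' column is appended per incompletely observed covariate (indicators that
#' would be constant are silently dropped), and a logistic propensity model
#' is fitted on the augmented design.
#'
#' @param data an [observed_dataset()].
#' @return list with `propensity`, `model` and `design` (the augmented
#'   covariate matrix used for the fit, useful for covariate-adjusted
#'   effect regressions).
#' @export
missing_indicator_ps <- function(data) {
  stopifnot(inherits(data, "observed_dataset"))
  x <- data$covariates
  if (any(colSums(1 - data$mask) == 0)) stop("a column has no observed values")
  x[is.na(x)] <- 0
  incomplete <- which(colSums(data$mask) > 0)
  ind <- data$mask[, incomplete, drop = FALSE]
  if (ncol(ind)) colnames(ind) <- paste0("miss_", colnames(x)[incomplete])
  design <- cbind(x, ind)
  fit <- fit_logistic_ps(design, data$treatment, "missing_indicator")
  list(propensity = fit$propensity, model = fit$model, design = design)
}

#' Complete-case propensity scores
#'
#' Drops every row with a missing covariate and fits the logistic propensity
#' model on the remaining rows (the degenerate path used as the complete-data
#' reference in the real-world analysis).
#'
#' @param data an [observed_dataset()].
#' @return list with `propensity`, `model` and `rows` (indices of the
#'   retained rows).
#' @export
complete_case_ps <- function(data) {
  stopifnot(inherits(data, "observed_dataset"))
  keep <- rowSums(data$mask) == 0
  if (!any(keep)) stop("no complete rows")
  fit <- fit_logistic_ps(data$covariates[keep, , drop = FALSE],
                         data$treatment[keep], "complete_case")
  list(propensity = fit$propensity, model = fit$model, rows = which(keep))
}

# one Bayesian-linear-regression draw: posterior (noninformative prior) over
# coefficients and residual variance, then posterior-predictive draws for the
# missing rows. Ridge jitter on singular designs.
bayes_lm_draw <- function(X_obs, y_obs, X_mis) {
  q <- ncol(X_obs)
  XtX <- crossprod(X_obs)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular imputation design; adding ridge jitter 1e-6")
    ch <- chol(XtX + diag(1e-6 * mean(diag(XtX)) + 1e-12, q))
  }
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(X_obs, y_obs)))
  df <- max(nrow(X_obs) - q, 1)
  s2 <- sum((y_obs - X_obs %*% bhat)^2) / stats::rchisq(1, df)
  bdraw <- bhat + backsolve(ch, stats::rnorm(q)) * sqrt(s2)
  drop(X_mis %*% bdraw) + stats::rnorm(nrow(X_mis)) * sqrt(s2)
}

#' Multiple imputation by chained equations (Bayesian linear regression)
#'
#' For each of `m` imputations: missing cells start as random draws from the
#' column's observed values; then for `chain_iterations` sweeps each
#' incomplete column (left-to-right) is regressed on all other currently
#' completed covariates plus treatment (and, optionally, the outcome),
#' coefficients and residual variance are drawn from their posterior under
#' the standard noninformative prior, and the missing cells are replaced by
#' posterior-predictive normal draws.
#'
#' The outcome is *excluded* from the imputation model by default: including
#' it makes the downstream IPW effect estimate nearly unbiased, which is not
#' the behaviour of the multiple-imputation comparator this package mirrors
#' (see the methods vignette).
#'
#' @param data an [observed_dataset()]; incomplete columns must be continuous.
#' @param m number of imputations (default 5).
#' @param chain_iterations sweeps per imputation (default 5).
#' @param seed optional seed.
#' @param include_outcome add the outcome to the imputation model?
#' @return An object of class `imputation_set`: list with `m`,
#'   `chain_iterations` and `completed_datasets` (m complete covariate
#'   matrices; observed cells identical to the input's).
#' @export
mice_impute <- function(data, m = 5, chain_iterations = 5, seed = NULL,
                        include_outcome = FALSE) {
  stopifnot(inherits(data, "observed_dataset"))
  if (m < 1 || chain_iterations < 1) stop("m and chain_iterations must be >= 1")
  check_seed(seed)
  x0 <- data$covariates
  bin <- is_binary_cols(x0)
  incomplete <- which(colSums(data$mask) > 0)
  if (any(bin[incomplete])) stop("incomplete columns must be continuous")
  extras <- if (include_outcome) {
    cbind(treatment = data$treatment, outcome = data$outcome)
  } else {
    cbind(treatment = data$treatment)
  }
  completed <- vector("list", m)
  for (k in seq_len(m)) {
    x <- x0
    for (j in incomplete) {
      mis <- data$mask[, j] == 1
      x[mis, j] <- sample(x0[!mis, j], sum(mis), replace = TRUE)
    }
    if (length(incomplete)) {
      for (s in seq_len(chain_iterations)) {
        for (j in incomplete) {
          mis <- data$mask[, j] == 1
          Z <- cbind(1, x[, -j, drop = FALSE], extras)
          x[mis, j] <- bayes_lm_draw(Z[!mis, , drop = FALSE], x0[!mis, j],
                                     Z[mis, , drop = FALSE])
        }
      }
    }
    completed[[k]] <- covariate_matrix(x, colnames(x0), bin)
  }
  structure(list(m = m, chain_iterations = chain_iterations,
                 completed_datasets = completed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> m =", x$m, "| chain iterations =",
      x$chain_iterations, "\n")
  invisible(x)
}

#' Export an imputation set as CSV files with a manifest
#'
#' @param imputations an [mice_impute()] result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @export
write_imputation_set <- function(imputations, dir, prefix = "imputation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(imputations$m)
  for (k in seq_len(imputations$m)) {
    files[k] <- file.path(dir, sprintf("%s_%02d.csv", prefix, k))
    utils::write.csv(as.data.frame(imputations$completed_datasets[[k]]),
                     files[k], row.names = FALSE)
  }
  jsonlite::write_json(list(m = imputations$m,
                            chain_iterations = imputations$chain_iterations,
                            files = basename(files)),
                       file.path(dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE)
  invisible(files)
}

#' Pool effect estimates across imputations
#'
#' Applies `effect_estimator` within each completed dataset and pools by the
#' arithmetic mean (Rubin's rule for the point estimate). Failing
#' imputations are dropped with a warning.
#'
#' @param imputations an `imputation_set`.
#' @param treatment,outcome vectors shared across imputations.
#' @param effect_estimator `function(covariates, treatment, outcome)`
#'   returning a scalar effect estimate, e.g. [ipw_effect_estimator()].
#' @return pooled effect (numeric scalar).
#' @export
mi_pooled_effect <- function(imputations, treatment, outcome,
                             effect_estimator) {
  stopifnot(inherits(imputations, "imputation_set"))
  est <- vapply(imputations$completed_datasets, function(xc) {
    tryCatch(as.numeric(effect_estimator(xc, treatment, outcome)),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(est)) {
    warning(sum(is.na(est)), " of ", length(est), " imputations failed")
  }
  est <- est[!is.na(est)]
  if (!length(est)) stop("all imputations failed")
  mean(est)
}
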