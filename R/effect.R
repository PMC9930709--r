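#' Inverse probability weights
#'
#' `w_i = T_i / e_i + (1 - T_i) / (1 - e_i)`: treated subjects weighted by
#' the inverse propensity, controls by the inverse of its complement. No
#' trimming or stabilization (scores are clipped upstream, so the weights
#' are always finite and >= 1).
#'
#' @param scores a [propensity_result()] or numeric vector in (0, 1).
#' @param treatment 0/1 vector.
#' @param stabilized multiply by the marginal treatment/control fractions
#'   (non-default; off in every study pipeline).
#' @return numeric weight vector.
#' @export
ipw_weights <- function(scores, treatment, stabilized = FALSE) {
  e <- as_scores(scores)
  treatment <- as.numeric(treatment)
  if (length(e) != length(treatment)) stop("length mismatch")
  if (any(e <= 0) || any(e >= 1)) stop("scores must lie strictly in (0, 1)")
  w <- treatment / e + (1 - treatment) / (1 - e)
  if (stabilized) {
    pt <- mean(treatment)
    w <- w * (treatment * pt + (1 - treatment) * (1 - pt))
  }
  w
}

#' Weighted-regression treatment effect
#'
#' Weighted least squares of the outcome on an intercept and treatment,
#' optionally plus covariates; the effect estimate is the treatment
#' coefficient.
#'
#' @param outcome numeric vector.
#' @param treatment 0/1 vector.
#' @param covariates complete covariate matrix, required when
#'   `include_covariates = TRUE`.
#' @param weights positive finite weights (e.g. [ipw_weights()]).
#' @param include_covariates adjust for the covariates in the regression?
#' @param method_label label carried in the result.
#' @return An object of class `effect_estimate`: `beta_hat`, `weights`,
#'   `regression_spec`, `method_label`, and the full coefficient vector.
#' @export
weighted_effect <- function(outcome, treatment, covariates = NULL, weights,
                            include_covariates = !is.null(covariates),
                            method_label = "ipw") {
  outcome <- as.numeric(outcome)
  treatment <- as.numeric(treatment)
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  design <- cbind(`(Intercept)` = 1, treatment = treatment)
  if (include_covariates) {
    if (is.null(covariates)) stop("covariates required when adjusting")
    cov <- as.matrix(covariates)
    if (anyNA(cov)) stop("covariates must be complete for the regression")
    design <- cbind(design, cov)
  }
  qr_d <- qr(design * sqrt(weights))
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.wfit(design, outcome, weights)
  structure(list(beta_hat = unname(fit$coefficients["treatment"]),
                 weights = weights,
                 regression_spec = if (include_covariates)
                   "with_covariates" else "treatment_only",
                 method_label = method_label,
                 coefficients = fit$coefficients),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect_estimate>", x$method_label, "(", x$regression_spec, ")",
      "beta_hat =", signif(x$beta_hat, 6), "\n")
  invisible(x)
}

#' Effect-estimator closure for complete covariate data
#'
#' Returns `function(covariates, treatment, outcome)` running the standard
#' pipeline: logistic propensity fit, IPW weights, weighted effect
#' regression. Used as the per-imputation estimator in
#' [mi_pooled_effect()].
#'
#' @param include_covariates adjust the effect regression for covariates?
#' @return a function returning a scalar effect estimate.
#' @export
ipw_effect_estimator <- function(include_covariates = TRUE) {
  function(covariates, treatment, outcome) {
    ps <- fit_logistic_ps(covariates, treatment)$propensity
    w <- ipw_weights(ps, treatment)
    weighted_effect(outcome, treatment, covariates, w,
                    include_covariates = include_covariates)$beta_hat
  }
}

weighted_mean <- function(v, w) sum(v * w) / sum(w)

#' Standardized-mean-difference balance report
#'
#' Per covariate: (weighted treated mean - weighted control mean) divided by
#' the pooled *unweighted* group SD, `sqrt((s1^2 + s0^2) / 2)` -- the
#' convention of standard balance tables. A zero pooled SD yields SMD 0 with
#' a warning. The unweighted variant uses unit weights.
#'
#' @param covariates complete covariate matrix.
#' @param treatment 0/1 vector.
#' @param weights optional weights (e.g. IPW); `NULL` = unweighted only.
#' @return data.frame of class `balance_report` with columns `covariate`,
#'   `smd_unweighted`, `smd_weighted`.
#' @export
smd_report <- function(covariates, treatment, weights = NULL) {
  x <- as.matrix(covariates)
  if (anyNA(x)) stop("covariates must be complete (impute first)")
  treatment <- as.numeric(treatment)
  t1 <- treatment == 1
  if (is.null(weights)) weights <- rep(1, length(treatment))
  smd_one <- function(v, w) {
    s <- sqrt((stats::var(v[t1]) + stats::var(v[!t1])) / 2)
    if (is.na(s) || s == 0) {
      warning("zero pooled SD; SMD reported as 0")
      return(0)
    }
    (weighted_mean(v[t1], w[t1]) - weighted_mean(v[!t1], w[!t1])) / s
  }
  out <- data.frame(
    covariate = colnames(x),
    smd_unweighted = apply(x, 2, smd_one, w = rep(1, length(treatment))),
    smd_weighted = apply(x, 2, smd_one, w = weights),
    row.names = NULL)
  class(out) <- c("balance_report", "data.frame")
  out
}

#' Write a balance report as CSV
#'
#' @param report a [smd_report()] result.
#' @param path CSV path.
#' @param method optional method label added as a column.
#' @export
write_balance_csv <- function(report, path, method = NA_character_) {
  report$method <- method
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
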