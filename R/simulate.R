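#' Simulation scenario specification
#'
#' Describes one simulated world: two correlated standard-normal covariates,
#' a logistic treatment model, and a linear Gaussian outcome in which the
#' treatment effect is `true_effect` (1 in the effect scenario, 0 in the
#' null scenario).
#'
#' @param n_subjects number of subjects per dataset. The source study never
#'   states its per-dataset size; 1000 is the package default.
#' @param true_effect treatment effect on the outcome (0 or 1 in the study).
#' @param outcome_noise_sd SD of the outcome noise (1 in the study).
#' @param seed optional seed; `NULL` means "use the current RNG stream".
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_subjects = 1000, true_effect = 1,
                          outcome_noise_sd = 1, seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be an integer >= 2")
  }
  if (!is.numeric(outcome_noise_sd) || outcome_noise_sd <= 0) {
    stop("outcome_noise_sd must be > 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 true_effect = as.numeric(true_effect),
                 outcome_noise_sd = as.numeric(outcome_noise_sd),
                 seed = seed),
            class = "scenario_spec")
}

#' Generate the two simulated covariates
#'
#' `X1 ~ N(0,1)` and `X2 = 0.5 X1 + eps` with `eps ~ N(0, 0.75)` where 0.75
#' is a *variance*, so that `sd(X2) = 1` and `cor(X1, X2) = 0.5`.
#'
#' @param spec a [scenario_spec()].
#' @return n x 2 [covariate_matrix()] with columns `X1`, `X2`.
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  check_seed(spec$seed)
  n <- spec$n_subjects
  x1 <- stats::rnorm(n)
  x2 <- 0.5 * x1 + stats::rnorm(n, sd = sqrt(0.75))
  covariate_matrix(cbind(X1 = x1, X2 = x2))
}

#' Generate treatment assignment
#'
#' Bernoulli draws with `logit P(T=1 | X1, X2) = -0.8 + 0.5 X1 + 0.5 X2`
#' (treated fraction ~= 0.33).
#'
#' @param covariates complete covariate matrix with columns `X1`, `X2`.
#' @param seed optional seed.
#' @return numeric 0/1 vector.
#' @export
generate_treatment <- function(covariates, seed = NULL) {
  if (anyNA(covariates)) stop("covariates must be complete")
  check_seed(seed)
  p <- expit(-0.8 + 0.5 * covariates[, "X1"] + 0.5 * covariates[, "X2"])
  stats::rbinom(nrow(covariates), 1, p)
}

#' Generate the outcome
#'
#' `Y = X1 + X2 + true_effect * T + eps`, `eps ~ N(0, outcome_noise_sd^2)`.
#' With `true_effect = 0` this is the null scenario.
#'
#' @param covariates complete covariate matrix.
#' @param treatment 0/1 vector.
#' @param spec a [scenario_spec()] (noise SD and effect size are read from it).
#' @return numeric outcome vector.
#' @export
generate_outcome <- function(covariates, treatment, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (anyNA(covariates)) stop("covariates must be complete")
  if (length(treatment) != nrow(covariates)) stop("treatment length mismatch")
  covariates[, "X1"] + covariates[, "X2"] +
    spec$true_effect * treatment +
    stats::rnorm(nrow(covariates), sd = spec$outcome_noise_sd)
}

#' Simulate one complete dataset
#'
#' Covariates, treatment and outcome drawn per the scenario; the returned
#' dataset has an all-zero mask.
#'
#' @param spec a [scenario_spec()].
#' @return An [observed_dataset()].
#' @export
simulate_scenario <- function(spec) {
  check_seed(spec$seed)
  spec2 <- spec
  spec2$seed <- NULL  # single seeding above; ops below share the stream
  x <- generate_covariates(spec2)
  tr <- generate_treatment(x)
  y <- generate_outcome(x, tr, spec2)
  observed_dataset(x, tr, y)
}
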