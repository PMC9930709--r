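realworld_covariates <- c("age", "educ", "race", "married", "nodegree",
                          "re74", "re75")
realworld_binary <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)

#' Synthetic stand-in for the NSWD/PSID employment-training table
#'
#' Generates a table with the column layout and broad distributional shape
#' of the LaLonde job-training benchmark (185 treated, 429 controls; mixed
#' binary/continuous covariates; zero-inflated, right-skewed earnings
#' `re74`/`re75` correlated with each other and with age/education; outcome
#' `re78`). It is SYNTHETIC: none of its values come from the real survey,
#' and estimates computed from it (including the complete-data reference
#' effect) are not comparable to published numbers from the real table. It
#' exists so the whole real-world pipeline can run and be tested offline.
#'
#' @param n total rows (default 614).
#' @param n_treated treated rows (default 185).
#' @param true_effect treatment effect (in dollars) built into `re78`.
#' @param seed RNG seed.
#' @return data.frame with columns `treat`, `age`, `educ`, `race`,
#'   `married`, `nodegree`, `re74`, `re75`, `re78`.
#' @export
synthetic_lalonde <- function(n = 614, n_treated = 185, true_effect = 1500,
                              seed = 1L) {
  check_seed(seed)
  treat <- c(rep(1, n_treated), rep(0, n - n_treated))
  age <- round(ifelse(treat == 1, stats::rnorm(n, 26, 7),
                      stats::rnorm(n, 28, 10)))
  age <- pmin(pmax(age, 17), 55)
  educ <- round(ifelse(treat == 1, stats::rnorm(n, 10.3, 2),
                       stats::rnorm(n, 10.2, 2.8)))
  educ <- pmin(pmax(educ, 3), 16)
  race <- stats::rbinom(n, 1, ifelse(treat == 1, 0.84, 0.40))
  married <- stats::rbinom(n, 1, ifelse(treat == 1, 0.19, 0.51))
  nodegree <- stats::rbinom(n, 1, ifelse(treat == 1, 0.71, 0.54))
  # zero-inflated lognormal earnings, mildly tied to age/educ
  zero74 <- stats::rbinom(n, 1, ifelse(treat == 1, 0.71, 0.25))
  base <- 7.6 + 0.015 * (age - 27) + 0.06 * (educ - 10)
  re74 <- ifelse(zero74 == 1, 0,
                 exp(base + stats::rnorm(n, 0, 0.9)))
  zero75 <- stats::rbinom(n, 1, pmin(0.15 + 0.6 * zero74, 0.95))
  re75 <- ifelse(zero75 == 1, 0,
                 exp(0.3 + 0.92 * log(pmax(re74, 400)) +
                       stats::rnorm(n, 0, 0.5)))
  re78 <- pmax(0.55 * re74 + 0.3 * re75 +
                 120 * (age - 27) + 350 * (educ - 10) - 900 * nodegree +
                 true_effect * treat + stats::rnorm(n, 4500, 3500), 0)
  data.frame(treat = treat, age = age, educ = educ, race = race,
             married = married, nodegree = nodegree,
             re74 = re74, re75 = re75, re78 = round(re78, 2))
}

#' Convert a LaLonde-layout table to an observed dataset
#'
#' @param table data.frame with `treat`, `re78` and the 7 covariates
#'   `age, educ, race, married, nodegree, re74, re75` (`NA` = missing).
#' @return An [observed_dataset()] with binary columns flagged.
#' @export
as_realworld_dataset <- function(table) {
  need <- c("treat", "re78", realworld_covariates)
  if (!all(need %in% names(table))) {
    stop("table must contain columns ", paste(need, collapse = ", "))
  }
  cov <- covariate_matrix(as.matrix(table[realworld_covariates]),
                          realworld_covariates, realworld_binary)
  observed_dataset(cov, table$treat, table$re78)
}

#' Complete-data IPW reference effect
#'
#' The real-world evaluation standard: logistic propensity scores from the
#' complete table on the 7 covariates, IPW weights, and a weighted
#' regression of `re78` on treatment plus the same 7 covariates. The true
#' effect of real data being unknowable, this estimate plays the role of
#' beta in the RMSE. Deterministic given the table.
#'
#' @param table complete LaLonde-layout data.frame.
#' @return An `effect_estimate`.
#' @export
reference_effect <- function(table) {
  if (anyNA(table[c(realworld_covariates, "treat", "re78")])) {
    stop("the reference requires complete data")
  }
  data <- as_realworld_dataset(table)
  ps <- fit_logistic_ps(data$covariates, data$treatment, "complete_reference")
  w <- ipw_weights(ps$propensity, data$treatment)
  weighted_effect(data$outcome, data$treatment, data$covariates, w,
                  include_covariates = TRUE,
                  method_label = "complete_reference")
}

#' Three-method comparison on a real-world-layout table
#'
#' Computes the complete-data reference effect, then per repetition masks
#' `re74`/`re75` under each mechanism x rate, runs each method end-to-end
#' (propensity scores on the 7 covariates; effect regression adjusted for
#' the same covariates, as in the study's real-world analysis), and
#' summarizes mean/SD/RMSE against the reference.
#'
#' @param table complete LaLonde-layout data.frame.
#' @param mechanisms,rates,methods,repetitions,base_seed grid axes.
#' @param mice_m,mice_iterations,mtnn pipeline settings.
#' @param verbose print progress.
#' @return data.frame of class `metrics_table`; the reference effect is
#'   attached as `attr(., "reference_effect")`.
#' @export
realworld_comparison <- function(table, mechanisms = "MCAR",
                                 rates = seq(0.2, 0.8, by = 0.1),
                                 methods = c("missing_indicator",
                                             "multiple_imputation", "mtnn"),
                                 repetitions = 200, base_seed = 1L,
                                 mice_m = 5, mice_iterations = 5,
                                 mtnn = mtnn_config(), verbose = FALSE) {
  ref <- reference_effect(table)$beta_hat
  opts <- list(adjust_covariates = TRUE, mice_m = mice_m,
               mice_iterations = mice_iterations, mtnn = mtnn)
  rows <- list()
  for (mech in mechanisms) {
    for (rate in rates) {
      mspec <- missingness_spec(mech, rate,
                                target_columns = c("re74", "re75"))
      for (method in methods) {
        est <- rep(NA_real_, repetitions)
        for (r in seq_len(repetitions)) {
          set.seed(base_seed + r)
          est[r] <- tryCatch({
            masked_tab <- impose_realworld_missingness(table, mspec)
            masked <- as_realworld_dataset(masked_tab)
            suppressWarnings(
              estimate_effect_for_method(masked, method, opts))
          }, error = function(e) NA_real_)
        }
        ok <- est[!is.na(est)]
        s <- summarize_estimates(ok, ref)
        rows[[length(rows) + 1]] <- data.frame(
          mechanism = mech, rate = rate, method = method,
          true_effect = ref, mean = s["mean"], sd = s["sd"], rmse = s["rmse"],
          n_successes = length(ok),
          flagged = (repetitions - length(ok)) > 0.01 * repetitions,
          row.names = NULL)
        if (verbose) {
          message(sprintf("%s rate=%.1f %s: mean=%.1f rmse=%.1f",
                          mech, rate, method, s["mean"], s["rmse"]))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", "data.frame")
  attr(out, "reference_effect") <- ref
  out
}
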