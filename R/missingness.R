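#' Missingness mechanism specification
#'
#' @param mechanism one of `"MCAR"`, `"MAR"`, `"MNAR"`.
#' @param target_rate target missing rate in (0, 1).
#' @param target_columns labels of the columns to mask (default `"X2"`).
#' @param driver_columns labels of the columns driving the missingness logit.
#'   Must be empty for MCAR. For MNAR the driver of each target column is
#'   that column itself and is filled in automatically.
#' @param offset_C the constant of the missingness logit, or `"auto"` to
#'   calibrate it against the empirical driver sample so the expected rate
#'   equals `target_rate`.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                             target_rate, target_columns = "X2",
                             driver_columns = NULL, offset_C = "auto") {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(target_rate) || target_rate < 0 || target_rate >= 1) {
    stop("target_rate must lie in [0, 1)")
  }
  if (mechanism == "MCAR" && length(driver_columns)) {
    stop("MCAR has no driver columns")
  }
  if (mechanism == "MNAR") driver_columns <- target_columns
  if (mechanism == "MAR" && !length(driver_columns)) {
    driver_columns <- "X1"  # the study's simulated MAR driver
  }
  structure(list(mechanism = mechanism, target_rate = as.numeric(target_rate),
                 target_columns = target_columns,
                 driver_columns = driver_columns, offset_C = offset_C),
            class = "missingness_spec")
}

#' Calibrate the missingness offset constant
#'
#' Finds `C` such that `mean(expit(driver + C)) == target_rate` over the
#' empirical driver sample, by monotone root finding to tolerance 1e-6.
#' With centered drivers and `target_rate = 0.5` the solution is `C = 0`.
#'
#' @param mechanism `"MAR"` or `"MNAR"` (MCAR needs no constant).
#' @param target_rate rate in (0, 1).
#' @param driver_values numeric vector of finite driver values.
#' @return the offset constant `C`.
#' @export
calibrate_offset <- function(mechanism, target_rate, driver_values) {
  if (!mechanism %in% c("MAR", "MNAR")) {
    stop("offset calibration applies to MAR/MNAR only")
  }
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= 1) {
    stop("target_rate must lie in (0, 1)")
  }
  if (anyNA(driver_values) || any(!is.finite(driver_values))) {
    stop("driver values must be finite")
  }
  f <- function(C) mean(expit(driver_values + C)) - target_rate
  span <- max(abs(driver_values)) + abs(stats::qlogis(target_rate)) + 5
  stats::uniroot(f, c(-span, span), tol = 1e-9)$root
}

bernoulli_mask <- function(driver, rate, offset) {
  C <- if (identical(offset, "auto")) {
    calibrate_offset("MAR", rate, driver)
  } else {
    as.numeric(offset)
  }
  stats::rbinom(length(driver), 1, expit(driver + C))
}

#' Impose missingness on a simulated dataset
#'
#' MCAR masks exactly `round(n * rate)` cells per target column, chosen
#' uniformly without replacement. MAR and MNAR mask by independent
#' `Bernoulli(expit(driver_i + C))` draws with `C` calibrated per dataset
#' against the empirical driver sample (MAR driver: the row sum of the
#' driver columns; MNAR driver: the target column itself, pre-mask). The
#' pre-mask covariates are retained in `$truth` for test oracles only.
#'
#' @param data a complete [observed_dataset()].
#' @param spec a [missingness_spec()].
#' @param seed optional seed.
#' @return A masked [observed_dataset()].
#' @export
impose_missingness <- function(data, spec, seed = NULL) {
  stopifnot(inherits(data, "observed_dataset"),
            inherits(spec, "missingness_spec"))
  check_seed(seed)
  x <- data$covariates
  if (!all(spec$target_columns %in% colnames(x))) {
    stop("target columns not found in the dataset")
  }
  truth <- if (is.null(data$truth)) x else data$truth
  n <- nrow(x)
  mask <- data$mask
  for (col in spec$target_columns) {
    m <- if (spec$mechanism == "MCAR") {
      idx <- sample.int(n, round(n * spec$target_rate))
      as.numeric(seq_len(n) %in% idx)
    } else {
      driver <- if (spec$mechanism == "MNAR") {
        truth[, col]
      } else {
        rowSums(truth[, spec$driver_columns, drop = FALSE])
      }
      if (anyNA(driver)) stop("driver values must be observed")
      if (spec$target_rate == 0) rep(0, n) else
        bernoulli_mask(driver, spec$target_rate, spec$offset_C)
    }
    mask[, col] <- pmax(mask[, col], m)
    x[mask[, col] == 1, col] <- NA
  }
  for (col in spec$target_columns) {
    for (g in c(0, 1)) {
      if (all(is.na(x[data$treatment == g, col]))) {
        warning("column '", col, "' fully missing in treatment group ", g)
      }
    }
  }
  observed_dataset(x, data$treatment, data$outcome, mask = mask, truth = truth)
}

#' Impose real-world-style missingness on a LaLonde-layout table
#'
#' Masks `re74` and `re75`. Drivers are centered *and* scaled to unit SD
#' before entering the missingness logit (raw earnings are in dollars; an
#' unscaled logit would be a near-step function with no intermediate rates).
#' MCAR masks exactly `round(n * rate)` cells in each target column; MAR uses
#' the shared driver `z(age) + z(educ)` with independent Bernoulli draws per
#' column; MNAR drives each column by its own standardized value.
#'
#' @param table data.frame with columns `age`, `educ`, `re74`, `re75` (plus
#'   anything else, carried through).
#' @param spec a [missingness_spec()]; `target_columns` defaults to
#'   `c("re74","re75")` when the spec still names `X2`.
#' @param seed optional seed.
#' @return The table with `NA`s in the masked cells; the 0/1 mask is attached
#'   as `attr(., "mask")` and the original columns as `attr(., "truth")`.
#' @export
impose_realworld_missingness <- function(table, spec, seed = NULL) {
  stopifnot(is.data.frame(table), inherits(spec, "missingness_spec"))
  need <- c("age", "educ", "re74", "re75")
  if (!all(need %in% names(table))) {
    stop("table must contain columns ", paste(need, collapse = ", "))
  }
  targets <- spec$target_columns
  if (identical(targets, "X2")) targets <- c("re74", "re75")
  if (anyNA(table[need])) stop("driver columns must be fully observed")
  check_seed(seed)
  n <- nrow(table)
  z <- function(v) as.numeric(scale(v))
  mask <- matrix(0, n, length(targets), dimnames = list(NULL, targets))
  truth <- table[targets]
  for (col in targets) {
    mask[, col] <- if (spec$mechanism == "MCAR") {
      if (spec$target_rate == 0) rep(0, n) else
        as.numeric(seq_len(n) %in% sample.int(n, round(n * spec$target_rate)))
    } else if (spec$target_rate == 0) {
      rep(0, n)
    } else {
      driver <- if (spec$mechanism == "MAR") {
        z(table$age) + z(table$educ)
      } else {
        z(table[[col]])
      }
      bernoulli_mask(driver, spec$target_rate, spec$offset_C)
    }
    table[mask[, col] == 1, col] <- NA
  }
  attr(table, "mask") <- mask
  attr(table, "truth") <- truth
  table
}
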