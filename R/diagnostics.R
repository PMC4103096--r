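#' Outlier diagnostic report
#'
#' Tabulates, per observation, the moment-based quadratic distance, the
#' hat-matrix leverage trace, the Huber, Mallows and combined weights, and
#' flags: `flag_distance` when the distance exceeds its cutoff (equivalently
#' the Huber weight is below 1) and `flag_leverage` when the leverage trace
#' exceeds its cutoff (Mallows weight 0).  For a GMWM fit the final weight
#' state of the fit is used; for MLE/GMM fits a screening state is computed
#' at the estimate with unit weights.
#'
#' @param fit a `plrm_fit` object.
#' @param data the dataset (defaults to the one stored in `fit`).
#' @param control [gmwm_control] used when a screening state must be
#'   computed.
#' @return A data frame of class `outlier_report`, sorted by decreasing
#'   distance, with attributes `c_d` and `c_x`.
#' @export
outlier_report <- function(fit, data = fit$data, control = gmwm_control()) {
  stopifnot(inherits(fit, "plrm_fit"))
  ws <- if (!is.null(fit$weights)) fit$weights
        else weight_state(coef(fit), data, control = control)
  out <- data.frame(
    id = seq_len(data$n),
    d = ws$d, trace_h = ws$trace_h,
    w_d = ws$w_d, w_x = ws$w_x, w = ws$w,
    flag_distance = ws$d > ws$c_d,
    flag_leverage = ws$trace_h > ws$c_x)
  out <- out[order(-out$d), ]
  rownames(out) <- NULL
  attr(out, "c_d") <- ws$c_d
  attr(out, "c_x") <- ws$c_x
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' @export
print.outlier_report <- function(x, max_rows = 10L, ...) {
  cat("Outlier report: c_d =", signif(attr(x, "c_d"), 4),
      ", c_x =", signif(attr(x, "c_x"), 4), "\n")
  cat(sum(x$flag_distance), "distance-flagged,",
      sum(x$flag_leverage), "leverage-flagged of", nrow(x),
      "observations\n")
  print(utils::head(as.data.frame(x), max_rows))
  if (nrow(x) > max_rows) cat("...", nrow(x) - max_rows, "more rows\n")
  invisible(x)
}

#' Odds of a category versus the reference along one covariate
#'
#' Evaluates `exp(x^T beta_j)`, the odds of category `j` against the
#' reference, along a grid of one covariate with the others held fixed.
#' The curve is monotone increasing exactly when the varying covariate's
#' coefficient for category `j` is positive.
#'
#' @param fit a `plrm_fit` object.
#' @param category_j non-reference category, given as an integer `2..J` or a
#'   category label.
#' @param varying name (or index among the covariates) of the covariate to
#'   sweep.
#' @param fixed_values named vector of the remaining covariate values.
#' @param grid numeric grid for the varying covariate.
#' @return A data frame with the grid values and the odds.
#' @export
odds_curve <- function(fit, category_j, varying, fixed_values, grid) {
  stopifnot(inherits(fit, "plrm_fit"), all(is.finite(grid)))
  data <- fit$data
  covnames <- colnames(data$x)[-1L]
  if (is.character(category_j)) {
    category_j <- match(category_j, data$levels)
    if (is.na(category_j)) stop("unknown category label")
  }
  if (category_j < 2L || category_j > data$J)
    stop("`category_j` must be a non-reference category (2..J)")
  if (is.numeric(varying)) varying <- covnames[varying]
  if (!varying %in% covnames) stop("unknown covariate: ", varying)
  others <- setdiff(covnames, varying)
  if (!all(others %in% names(fixed_values)))
    stop("`fixed_values` must name every non-varying covariate: ",
         paste(setdiff(others, names(fixed_values)), collapse = ", "))
  x <- matrix(0, length(grid), data$p,
              dimnames = list(NULL, covnames))
  for (v in others) x[, v] <- fixed_values[[v]]
  x[, varying] <- grid
  eta <- cbind(1, x) %*% coef(fit)[category_j - 1L, ]
  data.frame(grid = grid, odds = exp(drop(eta)))
}

#' Coefficient, standard-error and odds-ratio table
#'
#' Wald inference from a converged fit: standard errors are square roots of
#' the diagonal of the asymptotic covariance, p-values come from the normal
#' reference for `estimate / SE`, and odds ratios are `exp(estimate)` with
#' `exp(estimate +/- z * SE)` confidence limits.  One-sided (upper) p-values
#' are the default, testing a positive association per contrast;
#' `sided = "two"` gives the usual two-sided values.
#'
#' @param fit a converged `plrm_fit` object.
#' @param sided `"one"` (upper-tail, default) or `"two"`.
#' @param conf_level confidence level for the odds-ratio interval.
#' @return A data frame of class `coefficient_table` with one row per
#'   parameter.
#' @export
coefficient_table <- function(fit, sided = c("one", "two"),
                              conf_level = 0.95) {
  stopifnot(inherits(fit, "plrm_fit"))
  sided <- match.arg(sided)
  if (!fit$converged) stop("fit did not converge")
  V <- vcov(fit)
  dg <- diag(V)
  if (any(dg < -1e-8)) stop("fit covariance is not positive semi-definite")
  se <- sqrt(pmax(dg, 0))
  if (any(se == 0)) stop("zero standard error; covariance is degenerate")
  estimate <- .flatten(coef(fit))
  z <- estimate / se
  p <- if (sided == "one") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    parameter = .parameter_names(fit$data$J, fit$data$p),
    term = rep(colnames(fit$data$x), fit$data$J - 1L),
    category = rep(fit$data$levels[-1L], each = fit$data$p + 1L),
    estimate = estimate, se = se, z = z, p_value = p,
    odds_ratio = exp(estimate),
    or_lower = exp(estimate - zc * se),
    or_upper = exp(estimate + zc * se),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' Synthetic hypertension-style survey fixture
#'
#' Generates a dataset emulating the structure of a blood-pressure survey:
#' `n` subjects classified into four ordered (but nominally modelled)
#' categories — Normal, Pre-hypertension, Stage 1, Stage 2 — with a binary
#' sex indicator and continuous age, BMI and daily sodium intake.  Responses
#' follow a known baseline-category logit model whose coefficients are
#' returned in the `"beta_true"` attribute for recovery tests.  About
#' `contamination` of the rows are corrupted: their sodium intake is pushed
#' to extreme values and their response is forced to the reference category,
#' the kind of gross recording error that drags a maximum-likelihood sodium
#' coefficient toward or past zero while the robust fit resists.  This is a
#' synthetic stand-in; it reproduces the survey's format, not its data.
#'
#' @param seed integer seed.
#' @param n sample size.
#' @param contamination fraction of corrupted rows.
#' @return A [plrm_data] object with attributes `beta_true` and
#'   `contaminated` (affected row indices).
#' @export
make_survey_fixture <- function(seed, n = 520, contamination = 0.03) {
  beta_true <- rbind(
    c(-6.6, 0.9, 0.055, 0.16, 0.18),   # Pre-hypertension vs Normal
    c(-13.4, 1.0, 0.110, 0.30, 0.23),  # Stage 1 vs Normal
    c(-17.0, 0.7, 0.150, 0.38, 0.23))  # Stage 2 vs Normal
  dimnames(beta_true) <- list(
    c("cat2", "cat3", "cat4"),
    c("(Intercept)", "sex", "age", "bmi", "sodium"))
  levels <- c("Normal", "Pre-hypertension", "Stage1", "Stage2")

  set.seed(seed)
  sex <- stats::rbinom(n, 1L, 0.45)
  age <- stats::rnorm(n, 48, 14)
  bmi <- stats::rnorm(n, 24, 3)
  sodium <- stats::rgamma(n, shape = 2.2, scale = 1.7)  # right-skewed, ~3.7g
  xm <- cbind(sex = sex, age = age, bmi = bmi, sodium = sodium)
  P <- .prob_matrix(beta_true, cbind(1, xm))
  y <- .sample_categories(P)

  k <- round(contamination * n)
  idx <- sample.int(n, n)[seq_len(k)]
  xm[idx, "sodium"] <- 14 + stats::rgamma(k, shape = 2, scale = 2)
  y[idx] <- 1L   # extreme intake recorded as Normal: misclassified
  out <- plrm_data(levels[y], xm, levels = levels)
  attr(out, "beta_true") <- beta_true
  attr(out, "contaminated") <- sort(idx)
  out
}
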