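#' True coefficient matrix of the reference simulation design
#'
#' The 3-category, 2-covariate design used throughout the package's Monte
#' Carlo study: category-2 coefficients `(1.0, -0.8, -1.0)` and category-3
#' coefficients `(-0.3, 0.7, -0.5)` over (intercept, x1, x2), with category
#' 1 as reference (its coefficient block is identically zero).
#'
#' @return A `2 x 3` coefficient matrix (rows: categories 2 and 3).
#' @export
default_beta_true <- function() {
  beta <- rbind(c(1.0, -0.8, -1.0),
                c(-0.3, 0.7, -0.5))
  dimnames(beta) <- list(c("cat2", "cat3"), c("(Intercept)", "x1", "x2"))
  beta
}

#' Simulate a clean dataset from the baseline-category logit model
#'
#' Covariates are drawn i.i.d. standard normal (identity covariance);
#' responses are single multinomial trials with probabilities given by the
#' model at `beta_true`.  A draw in which some category goes unobserved is
#' regenerated (up to 10 attempts) since such a dataset cannot identify the
#' model.
#'
#' @param n sample size.
#' @param beta_true `(J-1) x (p+1)` generating coefficient matrix; its
#'   column count fixes the number of covariates.
#' @param seed integer seed; the generator is deterministic given `(n, seed)`.
#' @return A [plrm_data] object with integer category labels `1..J`.
#' @export
simulate_dataset <- function(n, beta_true = default_beta_true(), seed) {
  beta_true <- as.matrix(beta_true)
  p <- ncol(beta_true) - 1L
  J <- nrow(beta_true) + 1L
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    xm <- matrix(stats::rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("x", seq_len(p))))
    P <- .prob_matrix(beta_true, cbind(1, xm))
    y <- .sample_categories(P)
    if (all(tabulate(y, J) > 0L))
      return(plrm_data(y, xm, levels = as.character(seq_len(J))))
  }
  stop("failed to simulate a dataset observing all ", J,
       " categories in 10 attempts", call. = FALSE)
}

# one multinomial(1, P[i, ]) draw per row, via inverse CDF
.sample_categories <- function(P) {
  cum <- t(apply(P, 1L, cumsum))
  u <- stats::runif(nrow(P))
  as.integer(rowSums(u > cum) + 1L)
}

#' Contaminate a dataset with high-leverage, misclassified outliers
#'
#' Replaces `round(rate * n)` randomly chosen observations: their covariates
#' are redrawn from a normal distribution centred at `outlier_mean` (identity
#' covariance) and their responses are deliberately misclassified — set to a
#' category different from the one the true model predicts (the modal
#' category) at the new covariates.  Replacement keeps `n` fixed;
#' `augment = TRUE` appends the outliers instead.
#'
#' @param data a [plrm_data] object generated from `beta_true`.
#' @param rate contamination fraction in `[0, 1)`.
#' @param outlier_mean covariate mean vector of the outliers.
#' @param seed integer seed for the contamination stream (independent of the
#'   stream that generated `data`).
#' @param beta_true generating coefficients used to find each outlier's
#'   predicted category.
#' @param misclassify `"uniform"` draws the corrupted response uniformly
#'   from the non-modal categories; `"least_likely"` uses the least probable
#'   category.
#' @param augment append outliers instead of replacing rows.
#' @return A [plrm_data] object with attribute `"contaminated"` holding the
#'   affected row indices.
#' @export
contaminate <- function(data, rate, outlier_mean = c(2, 3), seed,
                        beta_true = default_beta_true(),
                        misclassify = c("uniform", "least_likely"),
                        augment = FALSE) {
  stopifnot(inherits(data, "plrm_data"), rate >= 0, rate < 1)
  misclassify <- match.arg(misclassify)
  if (rate == 0) return(data)
  beta_true <- as.matrix(beta_true)
  if (length(outlier_mean) != data$p)
    stop("`outlier_mean` must have length p = ", data$p)
  k <- round(rate * data$n)
  if (k == 0L) {
    warning("rate * n rounds to 0 observations; dataset unchanged")
    return(data)
  }
  set.seed(seed)
  idx <- sample.int(data$n, data$n)[seq_len(k)]
  xout <- matrix(stats::rnorm(k * data$p), k, data$p) +
    matrix(outlier_mean, k, data$p, byrow = TRUE)
  P <- .prob_matrix(beta_true, cbind(1, xout))
  modal <- max.col(P, ties.method = "first")
  yout <- integer(k)
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(data$J), modal[i])
    yout[i] <- if (misclassify == "uniform") {
      others[sample.int(length(others), 1L)]
    } else {
      which.min(P[i, ])
    }
  }
  xm <- data$x[, -1L, drop = FALSE]
  y <- data$y
  if (augment) {
    xm <- rbind(xm, xout)
    y <- c(y, yout)
    idx <- data$n + seq_len(k)
  } else {
    xm[idx, ] <- xout
    y[idx] <- yout
  }
  out <- plrm_data(data$levels[y], xm, levels = data$levels)
  attr(out, "contaminated") <- sort(idx)
  out
}

#' Monte Carlo bias / MSE / coverage study
#'
#' For each replicate: simulate a clean dataset from `beta_true`, optionally
#' contaminate it, fit the requested estimators, and record the coefficient
#' estimates and Wald confidence intervals.  Reports per-parameter bias
#' `mean(est - true)`, MSE `mean((est - true)^2)` and empirical coverage of
#' the nominal-level intervals.  Replicates where an estimator errors are
#' dropped for that estimator and counted.  Each replicate runs on its own
#' sub-seed derived from `seed`, so any single replicate is reproducible in
#' isolation.
#'
#' @param n per-replicate sample size.
#' @param n_reps number of replicates.
#' @param beta_true generating coefficient matrix.
#' @param contamination_rate fraction of replaced outliers (0 = clean).
#' @param outlier_mean outlier covariate mean vector.
#' @param seed master integer seed.
#' @param estimators subset of `c("MLE", "GMWM")`.
#' @param conf_level nominal confidence level of the Wald intervals.
#' @param control [gmwm_control] passed to [fit_gmwm].
#' @param misclassify passed to [contaminate].
#' @return An object of class `mc_report`: list with `results` (data frame
#'   with columns estimator, parameter, true, bias, mse, coverage),
#'   `n_failed` (named count per estimator), `unreliable` flag (> 10%
#'   failures for some estimator) and the study settings.
#' @examples
#' rep <- run_monte_carlo(n = 100, n_reps = 20, seed = 3,
#'                        estimators = "MLE")
#' rep$results
#' @export
run_monte_carlo <- function(n, n_reps, beta_true = default_beta_true(),
                            contamination_rate = 0, outlier_mean = c(2, 3),
                            seed, estimators = c("MLE", "GMWM"),
                            conf_level = 0.95, control = gmwm_control(),
                            misclassify = "uniform") {
  estimators <- match.arg(estimators, c("MLE", "GMWM"), several.ok = TRUE)
  stopifnot(n_reps >= 1)
  if (contamination_rate > 0 && round(contamination_rate * n) < 1)
    stop("contamination_rate * n must round to at least 1 outlier")
  theta0 <- .flatten(as.matrix(beta_true))
  q <- length(theta0)
  nm <- .parameter_names(nrow(as.matrix(beta_true)) + 1L,
                         ncol(as.matrix(beta_true)) - 1L)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  cont_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  est <- lapply(estimators, function(e) matrix(NA_real_, n_reps, q))
  cov <- lapply(estimators, function(e) matrix(NA, n_reps, q))
  names(est) <- names(cov) <- estimators

  for (r in seq_len(n_reps)) {
    d <- simulate_dataset(n, beta_true, seed = rep_seeds[r])
    if (contamination_rate > 0)
      d <- contaminate(d, contamination_rate, outlier_mean,
                       seed = cont_seeds[r], beta_true = beta_true,
                       misclassify = misclassify)
    mle <- tryCatch(fit_mle(d), error = function(e) NULL)
    for (e in estimators) {
      fit <- if (e == "MLE") {
        mle
      } else {
        tryCatch(fit_gmwm(d, init = if (is.null(mle)) NULL else coef(mle),
                          control = control),
                 error = function(err) NULL)
      }
      if (is.null(fit)) next
      th <- .flatten(coef(fit))
      se <- sqrt(pmax(diag(vcov(fit)), 0))
      est[[e]][r, ] <- th
      cov[[e]][r, ] <- abs(th - theta0) <= zcrit * se
    }
  }

  rows <- list()
  n_failed <- integer(0)
  for (e in estimators) {
    ok <- stats::complete.cases(est[[e]])
    n_failed[e] <- sum(!ok)
    ee <- est[[e]][ok, , drop = FALSE]
    cc <- cov[[e]][ok, , drop = FALSE]
    rows[[e]] <- data.frame(
      estimator = e, parameter = nm, true = theta0,
      bias = colMeans(ee) - theta0,
      mse = colMeans((ee - matrix(theta0, nrow(ee), q, byrow = TRUE))^2),
      coverage = colMeans(cc),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  unreliable <- any(n_failed > 0.1 * n_reps)
  if (unreliable)
    warning("more than 10% of replicates failed for some estimator; ",
            "report flagged unreliable", call. = FALSE)
  structure(list(results = results, n_failed = n_failed,
                 unreliable = unreliable, n = n, n_reps = n_reps,
                 contamination_rate = contamination_rate,
                 conf_level = conf_level, seed = seed),
            class = "mc_report")
}

#' @export
print.mc_report <- function(x, digits = 4, ...) {
  cat("Monte Carlo report: n =", x$n, ", reps =", x$n_reps,
      ", contamination =", x$contamination_rate, "\n")
  if (any(x$n_failed > 0))
    cat("Failed replicates:",
        paste(names(x$n_failed), x$n_failed, sep = "=", collapse = ", "),
        "\n")
  df <- x$results
  df[c("bias", "mse", "coverage")] <-
    lapply(df[c("bias", "mse", "coverage")], round, digits)
  print(df)
  invisible(x)
}
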