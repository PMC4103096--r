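#' Baseline-category logit model: core quantities
#'
#' The model relates the log-odds of each non-reference category against the
#' reference (category 1) linearly to covariates:
#' \deqn{\log\{\pi_j(x)/\pi_1(x)\} = x^T \beta_j, \quad j = 2, \dots, J.}
#' The coefficient block is a `(J-1) x (p+1)` matrix whose row `j-1` holds
#' `beta_j`; the flattened parameter vector stacks these rows (category-2
#' block first).
#'
#' @name plrm-model
NULL

.flatten <- function(beta) as.vector(t(beta))

.unflatten <- function(theta, J, p) {
  matrix(theta, nrow = J - 1L, ncol = p + 1L, byrow = TRUE)
}

.check_beta <- function(beta, J, p) {
  beta <- as.matrix(beta)
  if (nrow(beta) != J - 1L || ncol(beta) != p + 1L)
    stop("coefficient matrix must be (J-1) x (p+1) = ",
         J - 1L, " x ", p + 1L, "; got ", nrow(beta), " x ", ncol(beta))
  beta
}

.parameter_names <- function(J, p, xnames = NULL) {
  if (is.null(xnames)) xnames <- c("(Intercept)", paste0("x", seq_len(p)))
  as.vector(t(outer(2:J, seq_len(p + 1L) - 1L,
                    function(j, k) paste0("beta", j, k))))
}

#' Block design expansion for one observation
#'
#' Expands an intercept-augmented covariate row `x` into the block-diagonal
#' design matrix `X_i` with one block per non-reference category, so that
#' `t(X_i) %*% theta` (with `theta` the flattened coefficient vector) yields
#' the `J-1` linear predictors.
#'
#' @param x_row numeric vector `(1, x_1, ..., x_p)` with leading intercept 1.
#' @param J number of response categories (>= 2).
#' @return A `(p+1)(J-1) x (J-1)` matrix whose column `k` carries `x_row` in
#'   block `k` and zeros elsewhere.
#' @examples
#' expand_design(c(1, 0.5), J = 3)
#' @export
expand_design <- function(x_row, J) {
  if (J < 2L) stop("invalid model: J must be at least 2")
  x_row <- as.numeric(x_row)
  kronecker(diag(J - 1L), matrix(x_row, ncol = 1L))
}

.linear_predictor <- function(beta, x) {
  eta <- x %*% t(beta)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor; check coefficients and covariates")
  eta
}

.prob_matrix <- function(beta, x) {
  # log-sum-exp over {0, eta_2, ..., eta_J}: stable for |eta| up to ~700
  eta <- .linear_predictor(beta, x)
  m <- pmax(apply(eta, 1L, max), 0)
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  cbind(exp(-lse), exp(eta - lse))
}

#' Category probabilities under a baseline-category logit model
#'
#' @param beta `(J-1) x (p+1)` coefficient matrix (row `j-1` is `beta_j`).
#' @param x_row a single intercept-augmented covariate vector, or a matrix of
#'   such rows.
#' @return A length-`J` probability vector (or an `n x J` matrix for matrix
#'   input); entries are strictly positive and sum to 1.
#' @examples
#' beta <- rbind(c(1, -0.8, -1.0), c(-0.3, 0.7, -0.5))
#' category_probabilities(beta, c(1, 0, 0))
#' @export
category_probabilities <- function(beta, x_row) {
  beta <- as.matrix(beta)
  xm <- if (is.matrix(x_row)) x_row else matrix(x_row, nrow = 1L)
  if (ncol(xm) != ncol(beta))
    stop("dimensions of `beta` and `x_row` disagree")
  P <- .prob_matrix(beta, xm)
  if (!is.matrix(x_row)) drop(P) else P
}

.loglik <- function(beta, data, P = NULL) {
  if (is.null(P)) P <- .prob_matrix(beta, data$x)
  sum(log(P[cbind(seq_len(data$n), data$y)]))
}

#' Fisher information of the polytomous logit model
#'
#' Computes \eqn{\sum_i w_i^2 X_i (D_i - \pi_i \pi_i^T) X_i^T} with
#' \eqn{D_i = \mathrm{diag}(\pi_i^*)}, the information matrix of the model
#' (at unit weights) and the weighted moment-covariance used by the robust
#' fit.  Weights enter squared because each weighted moment contribution
#' scales linearly in `w_i`.
#'
#' @param beta `(J-1) x (p+1)` coefficient matrix.
#' @param data a [plrm_data] object.
#' @param weights optional nonnegative per-observation weights (default 1).
#' @return A symmetric positive semi-definite `(p+1)(J-1)` square matrix.
#' @export
information_matrix <- function(beta, data, weights = NULL) {
  beta <- .check_beta(beta, data$J, data$p)
  P <- .prob_matrix(beta, data$x)
  .information(data$x, P, w2 = if (is.null(weights)) NULL else weights^2)
}

.information <- function(x, P, w2 = NULL) {
  Ps <- P[, -1L, drop = FALSE]
  Jm1 <- ncol(Ps)
  pp <- ncol(x)
  info <- matrix(0, Jm1 * pp, Jm1 * pp)
  for (k in seq_len(Jm1)) {
    for (l in k:Jm1) {
      v <- if (k == l) Ps[, k] * (1 - Ps[, k]) else -Ps[, k] * Ps[, l]
      if (!is.null(w2)) v <- v * w2
      blk <- crossprod(x, x * v)
      ri <- ((k - 1L) * pp + 1L):(k * pp)
      ci <- ((l - 1L) * pp + 1L):(l * pp)
      info[ri, ci] <- blk
      if (l > k) info[ci, ri] <- t(blk)
    }
  }
  (info + t(info)) / 2
}

# Inverse with pseudo-inverse fallback for ill-conditioned matrices.
.safe_solve <- function(A, warn_context = "matrix") {
  inv <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(inv)) {
    cond <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
    if (is.finite(cond) && cond < 1e12) return(inv)
  }
  warning(warn_context, " is singular or near-singular; using pseudo-inverse",
          call. = FALSE)
  MASS::ginv(A)
}

#' Fit the baseline-category logit model by maximum likelihood
#'
#' Newton--Raphson on the multinomial log-likelihood using the Fisher
#' information, with step-halving (up to 20 halvings) whenever a step would
#' decrease the log-likelihood.  The asymptotic covariance is the inverse
#' information at the optimum.
#'
#' @param data a [plrm_data] object.
#' @param init optional starting `(J-1) x (p+1)` coefficient matrix
#'   (default: all zeros).
#' @param tol convergence tolerance on the max-abs coefficient change.
#' @param max_iter maximum Newton iterations.
#' @param separation_bound abort with a separation error when any
#'   coefficient magnitude exceeds this bound during iteration.
#' @return A `plrm_fit` object; see [fit_gmwm] for the shared structure.
#' @examples
#' d <- simulate_dataset(200, seed = 1)
#' fit <- fit_mle(d)
#' coef(fit)
#' @export
fit_mle <- function(data, init = NULL, tol = 1e-8, max_iter = 100L,
                    separation_bound = 50) {
  stopifnot(inherits(data, "plrm_data"))
  beta <- if (is.null(init)) matrix(0, data$J - 1L, data$p + 1L)
          else .check_beta(init, data$J, data$p)
  Ys <- .ystar(data)
  ll <- .loglik(beta, data)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    P <- .prob_matrix(beta, data$x)
    R <- Ys - P[, -1L, drop = FALSE]
    U <- .flatten(crossprod(R, data$x))       # score = sample moment
    info <- .information(data$x, P)
    step <- tryCatch(solve(info, U), error = function(e)
      stop("singular information matrix (rank ", qr(info)$rank, " < ",
           nrow(info), ")", call. = FALSE))
    new_beta <- beta + .unflatten(step, data$J, data$p)
    new_ll <- suppressWarnings(.loglik(new_beta, data))
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + .unflatten(step, data$J, data$p)
      new_ll <- suppressWarnings(.loglik(new_beta, data))
      halvings <- halvings + 1L
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    ll <- new_ll
    trace <- c(trace, delta)
    if (max(abs(beta)) > separation_bound)
      stop("apparent separation: coefficient magnitude exceeded ",
           separation_bound, call. = FALSE)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("MLE did not converge in ", max_iter,
         " iterations (last changes: ",
         paste(signif(utils::tail(trace, 3L), 3L), collapse = ", "), ")",
         call. = FALSE)

  P <- .prob_matrix(beta, data$x)
  info <- .information(data$x, P)
  vcov <- .safe_solve(info, "information matrix")
  dimnames(beta) <- list(paste0("cat", 2:data$J), colnames(data$x))
  nm <- .parameter_names(data$J, data$p)
  dimnames(vcov) <- list(nm, nm)
  .new_fit(beta, vcov, estimator = "MLE", data = data,
           converged = TRUE, iterations = iter, objective = NA_real_,
           logLik = ll, trace = trace)
}

.new_fit <- function(beta, vcov, estimator, data, converged, iterations,
                     objective, logLik = NA_real_, weights = NULL,
                     trace = NULL) {
  structure(list(coefficients = beta, vcov = vcov, estimator = estimator,
                 converged = converged, iterations = iterations,
                 objective = objective, logLik = logLik,
                 weights = weights, trace = trace, data = data),
            class = "plrm_fit")
}

#' @export
coef.plrm_fit <- function(object, ...) object$coefficients

#' @export
vcov.plrm_fit <- function(object, ...) object$vcov

#' @export
print.plrm_fit <- function(x, digits = 4, ...) {
  cat("Baseline-category logit fit (", x$estimator, ")\n", sep = "")
  cat("n =", x$data$n, ", J =", x$data$J, ", reference =",
      x$data$levels[1L], "\n")
  cat("Converged:", x$converged, "in", x$iterations, "iterations\n")
  if (!is.na(x$objective))
    cat("Objective Q_n:", format(x$objective, digits = digits), "\n")
  if (!is.null(x$weights)) {
    w <- x$weights$w
    cat("Downweighted observations (w < 1):", sum(w < 1),
        "; zero-weight:", sum(w == 0), "\n")
  }
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}
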