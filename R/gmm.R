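#' Per-observation moment vectors
#'
#' The moment condition underlying the GMM view of the model is
#' \eqn{u_i(\beta) = X_i (y_i^* - \pi_i)} where \eqn{y_i^*} is the indicator
#' vector over categories `2..J` and \eqn{X_i} the block design expansion.
#' At the true parameter these have mean zero, and their sum is the
#' multinomial score.
#'
#' @param beta `(J-1) x (p+1)` coefficient matrix.
#' @param data a [plrm_data] object.
#' @return An `n x (p+1)(J-1)` matrix with `u_i` in row `i` (category-2
#'   block first).
#' @export
moment_vectors <- function(beta, data) {
  beta <- .check_beta(beta, data$J, data$p)
  P <- .prob_matrix(beta, data$x)
  R <- .ystar(data) - P[, -1L, drop = FALSE]
  .moment_matrix(R, data$x)
}

# rows u_i = kron(r_i, x_i): column (k-1)(p+1)+a holds R[,k] * x[,a]
.moment_matrix <- function(R, x) {
  pp <- ncol(x)
  out <- matrix(0, nrow(x), ncol(R) * pp)
  for (k in seq_len(ncol(R)))
    out[, ((k - 1L) * pp + 1L):(k * pp)] <- R[, k] * x
  out
}

#' Moment vector for a single observation
#'
#' @param beta coefficient matrix.
#' @param x_row intercept-augmented covariate vector.
#' @param y integer response category in `1..J`.
#' @param J number of categories.
#' @return The length-`(p+1)(J-1)` vector \eqn{X_i (y_i^* - \pi_i)}.
#' @export
moment <- function(beta, x_row, y, J) {
  beta <- as.matrix(beta)
  pi_star <- category_probabilities(beta, x_row)[-1L]
  ystar <- as.numeric(seq_len(J - 1L) + 1L == y)
  as.vector(expand_design(x_row, J) %*% (ystar - pi_star))
}

#' Sample moment (score) vector
#'
#' @inheritParams moment_vectors
#' @return The length-`(p+1)(J-1)` sum \eqn{U_n(\beta) = \sum_i u_i(\beta)}.
#' @export
sample_moment <- function(beta, data) {
  beta <- .check_beta(beta, data$J, data$p)
  P <- .prob_matrix(beta, data$x)
  R <- .ystar(data) - P[, -1L, drop = FALSE]
  .flatten(crossprod(R, data$x))
}

#' Empirical variance-covariance of the moment conditions
#'
#' Implements the empirical weighting-matrix choice
#' \eqn{\Sigma_n(\beta) = n^{-2} \sum_i u_i u_i^T - n^{-1} U_n U_n^T},
#' symmetrized to remove floating-point asymmetry.  The information-matrix
#' choice ([information_matrix]) is the package default everywhere, as it
#' yields the efficient GMM weighting.
#'
#' @inheritParams moment_vectors
#' @return A symmetric `(p+1)(J-1)` square matrix.
#' @export
empirical_covariance <- function(beta, data) {
  if (data$n < 2L) stop("need at least 2 observations")
  Um <- moment_vectors(beta, data)
  U <- colSums(Um)
  S <- crossprod(Um) / data$n^2 - tcrossprod(U) / data$n
  (S + t(S)) / 2
}

#' Quadratic GMM objective
#'
#' \eqn{Q_n(\beta) = U_n^T \Sigma_n^{-1} U_n}, nonnegative and zero exactly
#' when the sample moment vanishes.  Because the system is exactly
#' identified, the minimizer solves `U_n = 0` and coincides with the MLE.
#'
#' @inheritParams moment_vectors
#' @param sigma weighting-matrix choice: the model information matrix
#'   (default, efficient) or the empirical moment covariance.
#' @return A nonnegative scalar.
#' @export
gmm_objective <- function(beta, data, sigma = c("information", "empirical")) {
  sigma <- match.arg(sigma)
  beta <- .check_beta(beta, data$J, data$p)
  U <- sample_moment(beta, data)
  Sig <- switch(sigma,
                information = information_matrix(beta, data),
                empirical = empirical_covariance(beta, data))
  drop(crossprod(U, .safe_solve(Sig, "GMM weighting matrix") %*% U))
}

#' Fit by the (unweighted) generalized method of moments
#'
#' Solves the exactly-identified moment equations \eqn{U_n(\beta) = 0} by
#' damped Newton iteration with the analytic Jacobian
#' \eqn{-\sum_i X_i (D_i - \pi_i \pi_i^T) X_i^T}.  The solution coincides
#' with the MLE; the reported objective is the achieved \eqn{Q_n}.
#'
#' @inheritParams fit_mle
#' @param sigma weighting matrix used for the reported objective and (with
#'   `"empirical"`) the sandwich covariance; see [gmm_objective].
#' @return A `plrm_fit` object with `estimator = "GMM"`.
#' @export
fit_gmm <- function(data, sigma = c("information", "empirical"),
                    init = NULL, tol = 1e-8, max_iter = 100L,
                    separation_bound = 50) {
  sigma <- match.arg(sigma)
  stopifnot(inherits(data, "plrm_data"))
  beta <- if (is.null(init)) matrix(0, data$J - 1L, data$p + 1L)
          else .check_beta(init, data$J, data$p)
  sol <- .newton_moments(beta, data, w = NULL, cmat = NULL, tol = tol,
                         max_iter = max_iter,
                         separation_bound = separation_bound)
  beta <- sol$beta
  Qn <- gmm_objective(beta, data, sigma)
  G <- information_matrix(beta, data)   # -Jacobian of U_n
  vcov <- if (sigma == "information") {
    .safe_solve(G, "information matrix")
  } else {
    Sig_inv <- .safe_solve(empirical_covariance(beta, data),
                           "empirical moment covariance")
    .safe_solve(G %*% Sig_inv %*% G, "GMM covariance bread")
  }
  dimnames(beta) <- list(paste0("cat", 2:data$J), colnames(data$x))
  nm <- .parameter_names(data$J, data$p)
  dimnames(vcov) <- list(nm, nm)
  .new_fit(beta, vcov, estimator = "GMM", data = data,
           converged = sol$converged, iterations = sol$iterations,
           objective = Qn, trace = sol$trace)
}

# Damped Newton on the (optionally weighted, recentered) moment equations
#   U(beta) = sum_i w_i X_i (y_i^* - pi_i) - sum_i c_i = 0
# with weights and corrections held fixed.  Jacobian is
#   -sum_i w_i X_i (D_i - pi_i pi_i^T) X_i^T  (weights enter linearly).
.newton_moments <- function(beta, data, w = NULL, cmat = NULL,
                            tol = 1e-8, max_iter = 100L,
                            separation_bound = 50) {
  Ys <- .ystar(data)
  c_tot <- if (is.null(cmat)) 0 else colSums(cmat)
  Ufun <- function(beta) {
    P <- .prob_matrix(beta, data$x)
    R <- Ys - P[, -1L, drop = FALSE]
    if (!is.null(w)) R <- R * w
    list(U = .flatten(crossprod(R, data$x)) - c_tot, P = P)
  }
  cur <- Ufun(beta)
  unorm <- max(abs(cur$U))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    G <- .information(data$x, cur$P, w2 = w)  # w enters linearly here
    step <- tryCatch(solve(G, cur$U), error = function(e)
      as.vector(MASS::ginv(G) %*% cur$U))
    new_beta <- beta + .unflatten(step, data$J, data$p)
    nxt <- tryCatch(Ufun(new_beta), error = function(e) NULL)
    halvings <- 0L
    while ((is.null(nxt) || max(abs(nxt$U)) > unorm) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + .unflatten(step, data$J, data$p)
      nxt <- tryCatch(Ufun(new_beta), error = function(e) NULL)
      halvings <- halvings + 1L
    }
    if (is.null(nxt))
      stop("moment equations produced non-finite values", call. = FALSE)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    cur <- nxt
    unorm <- max(abs(cur$U))
    trace <- c(trace, delta)
    if (max(abs(beta)) > separation_bound)
      stop("apparent separation: coefficient magnitude exceeded ",
           separation_bound, call. = FALSE)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("moment-equation Newton solve did not converge in ", max_iter,
         " iterations", call. = FALSE)
  list(beta = beta, converged = converged, iterations = iter, trace = trace)
}
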