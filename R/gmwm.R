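#' Control parameters for the GMWM fit
#'
#' All defaults reproduce the estimator's standard tuning rules: the distance
#' cutoff \eqn{c_d = \chi^2_1(0.975)/n} and the leverage cutoff
#' \eqn{c_x = 2(p+1)(J-1)/n}.
#'
#' @param cd_quantile probability level of the chi-squared quantile in the
#'   distance cutoff (1 disables distance downweighting).
#' @param cd_df degrees of freedom of that chi-squared quantile.
#' @param cx_multiplier multiplier of the mean leverage trace in the leverage
#'   cutoff (`Inf` disables leverage trimming).
#' @param correction `"enumeration"` computes the consistency-correction
#'   vector exactly by summing over the `J` possible outcomes; `"none"`
#'   disables recentering (sensitivity analysis only — the estimating
#'   equations are then biased under downweighting).
#' @param vcov `"information"` (default) uses the inverse of the
#'   weight-adjusted information
#'   \eqn{G_w = \sum_i w_i X_i (D_i - \pi_i \pi_i^T) X_i^T}, which is well
#'   calibrated in simulation; `"sandwich"` uses
#'   \eqn{G_w^{-1} \Omega G_w^{-1}} with
#'   \eqn{\Omega = \sum_i u_i^w u_i^{wT}}.  The sandwich form treats the
#'   weights as fixed and empirically understates the variability induced
#'   by re-estimating them, so its intervals undercover.
#' @param tol outer-loop convergence tolerance on max-abs coefficient change.
#' @param max_iter maximum outer (weight-updating) iterations.
#' @param separation_bound coefficient-magnitude bound triggering a
#'   separation error.
#' @return A list of class `gmwm_control`.
#' @export
gmwm_control <- function(cd_quantile = 0.975, cd_df = 1, cx_multiplier = 2,
                         correction = c("enumeration", "none"),
                         vcov = c("information", "sandwich"),
                         tol = 1e-6, max_iter = 50L,
                         separation_bound = 50) {
  stopifnot(cd_quantile > 0, cd_quantile <= 1, cd_df > 0, cx_multiplier > 0)
  structure(list(cd_quantile = cd_quantile, cd_df = cd_df,
                 cx_multiplier = cx_multiplier,
                 correction = match.arg(correction),
                 vcov = match.arg(vcov),
                 tol = tol, max_iter = as.integer(max_iter),
                 separation_bound = separation_bound),
            class = "gmwm_control")
}

#' Distance and leverage cutoffs
#'
#' `distance_cutoff` returns \eqn{\chi^2_{df}(q)/n}, the threshold above
#' which an observation's moment-based quadratic distance triggers Huber
#' downweighting.  `leverage_cutoff` returns `multiplier * (p+1)(J-1) / n`,
#' i.e. (by default) twice the mean hat-matrix trace, above which an
#' observation is discarded as a leverage point.
#'
#' @param n sample size.
#' @param quantile,df chi-squared quantile level and degrees of freedom.
#' @param p number of covariates (excluding intercept).
#' @param J number of response categories.
#' @param multiplier multiple of the mean leverage trace.
#' @return A positive scalar cutoff.
#' @examples
#' distance_cutoff(100)   # ~0.0502
#' leverage_cutoff(100, p = 2, J = 3)   # 0.12
#' @export
distance_cutoff <- function(n, quantile = 0.975, df = 1) {
  stopifnot(n >= 1)
  stats::qchisq(quantile, df) / n
}

#' @rdname distance_cutoff
#' @export
leverage_cutoff <- function(n, p, J, multiplier = 2) {
  stopifnot(n >= 1, p >= 1, J >= 2)
  multiplier * (p + 1) * (J - 1) / n
}

#' Huber and Mallows observation weights
#'
#' `huber_weight` is \eqn{\min(1, c_d/d)} (1 at `d = 0`), capping each
#' observation's influence at `c_d`.  `mallows_weight` is the hard 0/1
#' leverage weight: 1 when the hat-matrix trace is at most `c_x`, else 0.
#' `combine_weights` multiplies the two.
#'
#' @param d nonnegative quadratic distance(s).
#' @param c_d distance cutoff.
#' @param trace_h nonnegative leverage trace(s).
#' @param c_x leverage cutoff.
#' @param w_d,w_x the two weight components.
#' @return Numeric weights, vectorized over the first argument.
#' @export
huber_weight <- function(d, c_d) {
  stopifnot(all(d >= 0), c_d > 0)
  ifelse(d <= c_d, 1, c_d / d)
}

#' @rdname huber_weight
#' @export
mallows_weight <- function(trace_h, c_x) {
  stopifnot(all(trace_h >= 0), c_x > 0)
  as.numeric(trace_h <= c_x)
}

#' @rdname huber_weight
#' @export
combine_weights <- function(w_d, w_x) w_d * w_x

# (J-1) x (J-1) quadratic-form entries q_i[k,l] = x_i^T S_{kl} x_i for the
# block decomposition of S; returns an n x (J-1) x (J-1) array.
.quad_entries <- function(S, x, Jm1) {
  pp <- ncol(x)
  arr <- array(0, c(nrow(x), Jm1, Jm1))
  for (k in seq_len(Jm1)) for (l in seq_len(Jm1)) {
    Skl <- S[((k - 1L) * pp + 1L):(k * pp),
             ((l - 1L) * pp + 1L):(l * pp), drop = FALSE]
    arr[, k, l] <- rowSums((x %*% Skl) * x)
  }
  arr
}

# d_i = r_i^T (X_i^T S X_i) r_i for residual rows R, given quad entries
.quad_form <- function(arr, R) {
  Jm1 <- ncol(R)
  d <- numeric(nrow(R))
  for (k in seq_len(Jm1)) for (l in seq_len(Jm1))
    d <- d + R[, k] * R[, l] * arr[, k, l]
  pmax(d, 0)
}

# trace(X_i^T S X_i V_i) with V_i = D_i - pi* pi*^T
.trace_h <- function(arr, Ps) {
  Jm1 <- ncol(Ps)
  tr <- numeric(nrow(Ps))
  for (k in seq_len(Jm1)) for (l in seq_len(Jm1)) {
    v <- if (k == l) Ps[, k] * (1 - Ps[, k]) else -Ps[, k] * Ps[, l]
    tr <- tr + arr[, k, l] * v
  }
  pmax(tr, 0)
}

#' Per-observation weight state of the GMWM
#'
#' Computes, at a given coefficient matrix, everything the robust fit needs
#' for one weight update: the quadratic distances \eqn{d_i} of the
#' per-observation moment vectors under the information matrix
#' \eqn{\Sigma_n(\beta)} at the current coefficients, the hat-matrix
#' leverage traces, the Huber and Mallows weights, their product, the
#' consistency-correction vectors \eqn{c_i} obtained by exact enumeration of
#' the conditional expectation over the `J` possible outcomes, and the
#' weighted moment covariance \eqn{\Sigma_n^w} (the squared-weight
#' information) used by the objective and the covariance estimate.
#' Distances, leverages and corrections are deliberately anchored to the
#' *unweighted* \eqn{\Sigma_n(\beta)}: anchoring them to \eqn{\Sigma_n^w}
#' instead makes downweighting self-reinforcing (a shrinking covariance
#' inflates every distance), which empirically collapses all weights to zero
#' on clean data.
#'
#' @param beta `(J-1) x (p+1)` coefficient matrix.
#' @param data a [plrm_data] object.
#' @param control a [gmwm_control] list.
#' @return A list of class `gmwm_weights` with elements `d`, `w_d`,
#'   `trace_h`, `w_x`, `w`, `cmat` (an `n x (p+1)(J-1)` matrix of
#'   correction vectors), `c_d`, `c_x`, `Sigma` (the unweighted
#'   information), `Sigma_w` and its inverse `Sigma_w_inv`.
#' @export
weight_state <- function(beta, data, control = gmwm_control()) {
  beta <- .check_beta(beta, data$J, data$p)
  n <- data$n
  Jm1 <- data$J - 1L
  P <- .prob_matrix(beta, data$x)
  Ps <- P[, -1L, drop = FALSE]
  Sigma <- .information(data$x, P)
  S <- .safe_solve(Sigma, "moment covariance")
  arr <- .quad_entries(S, data$x, Jm1)

  R_obs <- .ystar(data) - Ps
  d <- .quad_form(arr, R_obs)
  trace_h <- .trace_h(arr, Ps)

  c_d <- distance_cutoff(n, control$cd_quantile, control$cd_df)
  c_x <- leverage_cutoff(n, data$p, data$J, control$cx_multiplier)
  w_d <- if (is.finite(c_d)) huber_weight(d, c_d) else rep(1, n)
  w_x <- if (is.finite(c_x)) mallows_weight(trace_h, c_x) else rep(1, n)
  w <- combine_weights(w_d, w_x)

  cmat <- matrix(0, n, Jm1 * (data$p + 1L))
  if (control$correction == "enumeration" && is.finite(c_d)) {
    # c_i = sum_j pi_ij w_i(j) X_i (e_j^* - pi_i^*): the weight the
    # machinery would assign had the response been category j
    for (j in seq_len(data$J)) {
      Rj <- -Ps
      if (j >= 2L) Rj[, j - 1L] <- Rj[, j - 1L] + 1
      dj <- .quad_form(arr, Rj)
      wj <- w_x * huber_weight(dj, c_d)
      cmat <- cmat + .moment_matrix(Rj * (P[, j] * wj), data$x)
    }
  }

  Sigma_w <- .information(data$x, P, w2 = w^2)
  structure(list(d = d, w_d = w_d, trace_h = trace_h, w_x = w_x, w = w,
                 cmat = cmat, c_d = c_d, c_x = c_x,
                 Sigma = Sigma, Sigma_w = Sigma_w,
                 Sigma_w_inv = .safe_solve(Sigma_w,
                                           "weighted moment covariance")),
            class = "gmwm_weights")
}

#' Quadratic moment distances and leverage traces
#'
#' Convenience wrappers around [weight_state] returning only the distances
#' \eqn{d_i = u_i^T \Sigma_n(\beta)^{-1} u_i} or the hat-matrix traces
#' \eqn{\mathrm{tr}(X_i^T \Sigma_n(\beta)^{-1} X_i (D_i - \pi_i\pi_i^T))},
#' where \eqn{\Sigma_n(\beta)} is the model information matrix at `beta`.
#'
#' @inheritParams weight_state
#' @return A length-`n` nonnegative vector.
#' @export
quadratic_distances <- function(beta, data, control = gmwm_control()) {
  weight_state(beta, data, control)$d
}

#' @rdname quadratic_distances
#' @export
leverage_traces <- function(beta, data, control = gmwm_control()) {
  weight_state(beta, data, control)$trace_h
}

#' Consistency-correction vectors
#'
#' @inheritParams weight_state
#' @return An `n x (p+1)(J-1)` matrix whose row `i` is \eqn{c_i}, the
#'   conditional expectation of the weighted moment contribution given the
#'   covariates, so that \eqn{u_i^w = w_i X_i(y_i^* - \pi_i) - c_i} has
#'   exact conditional mean zero at the evaluation parameter.
#' @export
consistency_corrections <- function(beta, data, control = gmwm_control()) {
  weight_state(beta, data, control)$cmat
}

#' Weighted per-observation moment vectors
#'
#' \eqn{u_i^w = w_i X_i (y_i^* - \pi_i) - c_i}.  With all weights 1 and zero
#' corrections this reduces to [moment_vectors]; the unweighted GMM is the
#' special case of the GMWM.
#'
#' @inheritParams weight_state
#' @param state a `gmwm_weights` object from [weight_state] evaluated at the
#'   same `beta` (computed afresh when omitted).
#' @return An `n x (p+1)(J-1)` matrix with \eqn{u_i^w} in row `i`.
#' @export
weighted_moments <- function(beta, data, state = NULL,
                             control = gmwm_control()) {
  if (is.null(state)) state <- weight_state(beta, data, control = control)
  moment_vectors(beta, data) * state$w - state$cmat
}

#' Weighted GMM objective
#'
#' \eqn{Q_n^w(\beta) = U_n^{wT} \Sigma_n^{w-1} U_n^w} with
#' \eqn{U_n^w = \sum_i u_i^w}.
#'
#' @inheritParams weighted_moments
#' @return A nonnegative scalar.
#' @export
gmwm_objective <- function(beta, data, state = NULL,
                           control = gmwm_control()) {
  if (is.null(state)) state <- weight_state(beta, data, control = control)
  U <- colSums(weighted_moments(beta, data, state))
  max(drop(crossprod(U, state$Sigma_w_inv %*% U)), 0)
}

#' Fit the robust generalized method of weighted moments estimator
#'
#' Continuous-updating procedure: starting from the MLE, each outer
#' iteration (a) freezes the weight machinery at the current coefficients —
#' weighted moment covariance, quadratic distances, leverage traces, Huber
#' and Mallows weights, and consistency corrections — and (b) solves the
#' recentered weighted moment equations \eqn{U_n^w(\beta) = 0} by damped
#' Newton with the analytic Jacobian.  Iteration stops when the max-abs
#' coefficient change falls below `control$tol`.  Observations with zero
#' Mallows weight contribute nothing: their weighted moments and correction
#' vectors vanish and they are excluded from \eqn{\Sigma_n^w}.
#'
#' @param data a [plrm_data] object.
#' @param init optional starting coefficients (default: the MLE of `data`).
#' @param control a [gmwm_control] list.
#' @return An object of class `plrm_fit`: list with `coefficients` (the
#'   `(J-1) x (p+1)` estimate), `vcov`, `estimator = "GMWM"`, `converged`,
#'   `iterations`, `objective` (final \eqn{Q_n^w}), `weights` (the final
#'   `gmwm_weights` state) and the originating `data`.
#' @examples
#' d <- contaminate(simulate_dataset(300, seed = 7), rate = 0.05, seed = 8)
#' fit <- fit_gmwm(d)
#' fit
#' @export
fit_gmwm <- function(data, init = NULL, control = gmwm_control()) {
  stopifnot(inherits(data, "plrm_data"), inherits(control, "gmwm_control"))
  beta <- if (is.null(init)) coef(fit_mle(data))
          else .check_beta(init, data$J, data$p)
  inner_tol <- min(control$tol * 1e-2, 1e-8)
  keys <- character(0)
  w_last <- NULL
  cmat_last <- NULL
  converged <- FALSE
  cycle_broken <- FALSE
  iter <- 0L
  final <- NULL

  for (iter in seq_len(control$max_iter)) {
    ws <- weight_state(beta, data, control = control)
    if (all(ws$w == 0))
      stop("degenerate weighting: every observation received weight 0",
           call. = FALSE)
    # Recurrent Mallows 0/1 pattern: the hard leverage weight can flip a
    # boundary observation in and out indefinitely.  Break the cycle by
    # averaging the last two weight states (the average still has
    # conditionally centered moments, since c_i is linear in the weights),
    # freezing them, and solving once more.
    key <- paste(ws$w_x, collapse = "")
    seen_older <- length(keys) >= 2L && key != keys[length(keys)] &&
      key %in% keys[-length(keys)]
    if (seen_older && !is.null(w_last)) {
      warning("oscillating weight pattern detected; ",
              "averaging the last two weight states", call. = FALSE)
      ws$w <- (ws$w + w_last) / 2
      ws$cmat <- (ws$cmat + cmat_last) / 2
      cycle_broken <- TRUE
    }
    keys <- c(keys, key)
    w_last <- ws$w
    cmat_last <- ws$cmat

    sol <- .newton_moments(beta, data, w = ws$w, cmat = ws$cmat,
                           tol = inner_tol, max_iter = 100L,
                           separation_bound = control$separation_bound)
    delta <- max(abs(sol$beta - beta))
    beta <- sol$beta
    if (delta < control$tol || cycle_broken) {
      converged <- TRUE
      if (cycle_broken) final <- ws   # report the frozen averaged state
      break
    }
  }
  if (!converged)
    warning("GMWM outer loop reached max_iter = ", control$max_iter,
            " without meeting tol = ", control$tol, call. = FALSE)

  if (is.null(final)) final <- weight_state(beta, data, control = control)
  Uw <- moment_vectors(beta, data) * final$w - final$cmat
  U <- colSums(Uw)
  objective <- max(drop(crossprod(U, final$Sigma_w_inv %*% U)), 0)

  P <- .prob_matrix(beta, data$x)
  G_w <- .information(data$x, P, w2 = final$w)   # weights enter linearly
  vcov <- if (control$vcov == "sandwich") {
    Omega <- crossprod(Uw)
    G_inv <- .safe_solve(G_w, "weighted Jacobian")
    V <- G_inv %*% Omega %*% t(G_inv)
    (V + t(V)) / 2
  } else {
    .safe_solve(G_w, "weighted information")
  }
  dimnames(beta) <- list(paste0("cat", 2:data$J), colnames(data$x))
  nm <- .parameter_names(data$J, data$p)
  dimnames(vcov) <- list(nm, nm)
  .new_fit(beta, vcov, estimator = "GMWM", data = data,
           converged = converged, iterations = iter,
           objective = objective, weights = final)
}
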