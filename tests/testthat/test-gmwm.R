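test_that("distance and leverage cutoffs follow the stated rules", {
  expect_equal(distance_cutoff(100), qchisq(0.975, 1) / 100)
  expect_equal(distance_cutoff(100), 0.0502, tolerance = 1e-3)
  expect_equal(distance_cutoff(520), 0.00966, tolerance = 1e-3)
  expect_equal(distance_cutoff(1), qchisq(0.975, 1))
  expect_equal(leverage_cutoff(100, p = 2, J = 3), 0.12)
  expect_equal(leverage_cutoff(520, p = 4, J = 4), 30 / 520)
  expect_equal(leverage_cutoff(2 * 15, p = 4, J = 4), 1)
})

test_that("Huber and Mallows weights have the defining properties", {
  c_d <- 0.5
  expect_equal(huber_weight(c(0, 0.2, c_d), c_d), c(1, 1, 1))
  expect_equal(huber_weight(2 * c_d, c_d), 0.5)
  # bounded influence: w(d) * d <= c_d, approaching c_d as d grows
  d <- c(0.6, 1, 10, 1e6)
  expect_true(all(huber_weight(d, c_d) * d <= c_d + 1e-12))
  expect_equal(huber_weight(1e12, c_d) * 1e12, c_d)

  c_x <- 0.12
  expect_equal(mallows_weight(c(0, c_x), c_x), c(1, 1))   # inclusive at c_x
  expect_equal(mallows_weight(c_x + 1e-12, c_x), 0)
  expect_equal(combine_weights(c(1, 0.4, 0.4), c(1, 0, 1)), c(1, 0, 0.4))
})

test_that("quadratic distances match brute-force per-observation forms", {
  d <- toy_data()
  beta <- beta_ref()
  st <- weight_state(beta, d)
  Sinv <- solve(information_matrix(beta, d))
  M <- moment_vectors(beta, d)
  for (i in seq_len(d$n))
    expect_equal(st$d[i], drop(t(M[i, ]) %*% Sinv %*% M[i, ]),
                 tolerance = 1e-10)
  # zero moment vector gives zero distance: force it by matching y to the
  # modal category of a degenerate probability vector is unnecessary --
  # verify the quadratic form directly instead
  expect_true(all(st$d >= 0))
})

test_that("leverage traces sum to the parameter count at unit weights", {
  d <- simulate_dataset(150, seed = 41)
  beta <- coef(fit_mle(d))
  st <- weight_state(beta, d)
  expect_equal(sum(st$trace_h), (d$p + 1) * (d$J - 1), tolerance = 1e-8)

  # oracle: explicit hat-matrix trace per observation
  Sinv <- solve(information_matrix(beta, d))
  tr <- numeric(d$n)
  for (i in seq_len(d$n)) {
    Xi <- oracle_expand(d$x[i, ], d$J)
    ps <- category_probabilities(beta, d$x[i, ])[-1]
    Vi <- diag(ps, d$J - 1) - tcrossprod(ps)
    tr[i] <- sum(diag(t(Xi) %*% Sinv %*% Xi %*% Vi))
  }
  expect_equal(st$trace_h, tr, tolerance = 1e-10)

  # identical covariates: the design is rank-deficient, so the information
  # has rank (J-1) and the (pseudo-inverse) traces sum to that rank, equal
  # across observations and below the cutoff
  di <- plrm_data(rep(1:3, 20), cbind(x1 = rep(0.5, 60), x2 = rep(-1, 60)))
  sti <- suppressWarnings(weight_state(matrix(0, 2, 3), di))
  expect_equal(sti$trace_h, rep(2 / 60, 60), tolerance = 1e-8)
  expect_true(all(sti$w_x == 1))

  # an observation at the design centroid has below-average leverage
  corners <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4, 2)
  xc <- rbind(corners, corners, c(0, 0))
  dc <- plrm_data(c(1, 2, 3, 1, 2, 3, 1, 2, 3), xc)
  stc <- weight_state(matrix(0, 2, 3), dc)
  expect_lt(stc$trace_h[9], mean(stc$trace_h))
})

test_that("consistency corrections equal the brute-force outcome sum", {
  d <- toy_data()
  beta <- beta_ref() + 0.1
  ctl <- gmwm_control()
  st <- weight_state(beta, d, control = ctl)
  Sinv <- solve(information_matrix(beta, d))
  c_d <- distance_cutoff(d$n)

  for (i in seq_len(d$n)) {
    xi <- d$x[i, ]
    Xi <- oracle_expand(xi, d$J)
    ps <- category_probabilities(beta, xi)[-1]
    pfull <- category_probabilities(beta, xi)
    ci <- rep(0, 6)
    for (j in 1:3) {
      ej <- as.numeric(seq_len(2) + 1 == j)
      uij <- drop(Xi %*% (ej - ps))
      dij <- drop(t(uij) %*% Sinv %*% uij)
      wij <- st$w_x[i] * min(1, c_d / dij)
      ci <- ci + pfull[j] * wij * uij
    }
    expect_equal(st$cmat[i, ], ci, tolerance = 1e-12)
  }

  # equal hypothetical weights make the correction vanish exactly
  big <- gmwm_control(cd_quantile = 1)   # infinite distance cutoff
  st2 <- weight_state(beta, d, control = big)
  expect_equal(st2$cmat, matrix(0, d$n, 6), tolerance = 1e-12)

  # zero Mallows weight kills the correction
  expect_equal(st$cmat[st$w_x == 0, ], st$cmat[st$w_x == 0, ] * 0)
})

test_that("weighted moments recenter exactly and reduce to plain moments", {
  d <- simulate_dataset(80, seed = 43)
  beta <- beta_ref()
  st <- weight_state(beta, d)
  Uw <- weighted_moments(beta, d, st)
  expect_equal(dim(Uw), c(80L, 6L))

  # conditional mean of u^w over the J outcomes is exactly zero at beta
  for (i in c(1, 17, 55)) {
    xi <- d$x[i, ]
    pfull <- category_probabilities(beta, xi)
    Xi <- oracle_expand(xi, d$J)
    ps <- pfull[-1]
    Sinv <- solve(st$Sigma)
    c_d <- st$c_d
    acc <- rep(0, 6)
    for (j in 1:3) {
      ej <- as.numeric(seq_len(2) + 1 == j)
      uij <- drop(Xi %*% (ej - ps))
      dij <- drop(t(uij) %*% Sinv %*% uij)
      wij <- st$w_x[i] * min(1, c_d / dij)
      acc <- acc + pfull[j] * (wij * uij - st$cmat[i, ])
    }
    expect_equal(acc, rep(0, 6), tolerance = 1e-10)
  }

  # unit weights, zero corrections: u^w is the ordinary moment vector
  free <- gmwm_control(cd_quantile = 1, cx_multiplier = Inf)
  st_free <- weight_state(beta, d, control = free)
  expect_equal(weighted_moments(beta, d, st_free), moment_vectors(beta, d),
               tolerance = 1e-12)
  # and the weighted objective equals the information-weighted GMM objective
  expect_equal(gmwm_objective(beta, d, st_free),
               gmm_objective(beta, d, sigma = "information"),
               tolerance = 1e-8)
})

test_that("the weighted objective is not invariant to rescaling weights", {
  d <- toy_data()
  beta <- beta_ref()
  st <- weight_state(beta, d)
  q1 <- gmwm_objective(beta, d, st)
  st_half <- st
  st_half$w <- st$w * 0.5
  st_half$cmat <- st$cmat * 0.5   # keep the centering consistent
  q2 <- gmwm_objective(beta, d, st_half)
  expect_false(isTRUE(all.equal(q1, q2)))
})

test_that("with infinite cutoffs the GMWM collapses onto GMM and MLE", {
  free <- gmwm_control(cd_quantile = 1, cx_multiplier = Inf)
  for (s in c(47, 53)) {
    d <- simulate_dataset(200, seed = s)
    mle <- fit_mle(d)
    gmwm <- fit_gmwm(d, control = free)
    expect_lt(max(abs(coef(gmwm) - coef(mle))), 1e-8)
    expect_equal(gmwm$weights$w, rep(1, d$n))
  }
})

test_that("GMWM on clean data stays close to the MLE", {
  d <- simulate_dataset(500, seed = 59)
  mle <- fit_mle(d)
  gmwm <- suppressWarnings(fit_gmwm(d, init = coef(mle)))
  expect_true(gmwm$converged)
  se <- sqrt(diag(vcov(mle)))
  expect_true(all(abs(flatten_beta(coef(gmwm)) - flatten_beta(coef(mle)))
                  < 2 * se))
  # the solved weighted moment equations are satisfied
  expect_lt(gmwm$objective, 1e-8)
})

test_that("a zero-weight observation contributes nothing to the fit", {
  d <- simulate_dataset(300, seed = 61)
  # plant one gross outlier far out in covariate space
  xm <- d$x[, -1]
  xm[1, ] <- c(10, 15)
  y <- d$y; y[1] <- 3L
  dd <- plrm_data(d$levels[y], xm, levels = d$levels)
  fit <- suppressWarnings(fit_gmwm(dd))
  # the point is either trimmed by leverage or crushed by the Huber
  # weight (its distance is enormous); either way w is essentially zero
  expect_lt(fit$weights$w[1], 0.01)
  # removing the observation entirely gives (nearly) the same estimate:
  # its weighted moment contribution is negligible
  d_minus <- plrm_data(d$levels[y[-1]], xm[-1, ], levels = d$levels)
  fit_minus <- suppressWarnings(fit_gmwm(d_minus))
  expect_lt(max(abs(coef(fit) - coef(fit_minus))), 0.05)
})
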