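# Shared fixtures; all randomness is seeded so the suite is deterministic.

beta_ref <- function() default_beta_true()

theta_ref <- function() c(1, -0.8, -1, -0.3, 0.7, -0.5)

# tiny 6-observation, J = 3 dataset with hand-enterable covariates
toy_data <- function() {
  plrm_data(c(1L, 2L, 3L, 1L, 2L, 3L),
            cbind(x1 = c(0.5, -1, 2, 0, 1, -0.5),
                  x2 = c(1, 0, -0.5, 2, -1, 0.5)),
            levels = c("1", "2", "3"))
}

# flatten in the package's row-major block order without using internals
flatten_beta <- function(beta) as.vector(t(beta))

# brute-force expansion: build X_i explicitly and work at the matrix level
oracle_expand <- function(x_row, J) {
  q <- length(x_row) * (J - 1L)
  out <- matrix(0, q, J - 1L)
  for (k in seq_len(J - 1L)) {
    rows <- ((k - 1L) * length(x_row) + 1L):(k * length(x_row))
    out[rows, k] <- x_row
  }
  out
}

# brute-force information matrix via explicit per-observation X_i V_i X_i^T
oracle_information <- function(beta, data, weights = NULL) {
  J <- data$J
  q <- (data$p + 1L) * (J - 1L)
  if (is.null(weights)) weights <- rep(1, data$n)
  total <- matrix(0, q, q)
  for (i in seq_len(data$n)) {
    Xi <- oracle_expand(data$x[i, ], J)
    pi_star <- category_probabilities(beta, data$x[i, ])[-1L]
    Vi <- diag(pi_star, J - 1L) - tcrossprod(pi_star)
    total <- total + weights[i]^2 * Xi %*% Vi %*% t(Xi)
  }
  total
}
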