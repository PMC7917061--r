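# Small in-code fixtures shared across test files.

# Binary data from a linear normal-ogive factor model: loading matrix `lambda`
# (J x K), orthogonal factors unless phi given. Used as an independent route
# to data with known factorial dimensionality.
make_factor_data <- function(N, lambda, phi = NULL, thresholds = 0) {
  J <- nrow(lambda); K <- ncol(lambda)
  if (is.null(phi)) phi <- diag(K)
  f <- matrix(stats::rnorm(N * K), N, K) %*% chol(phi)
  uvar <- pmax(1 - rowSums((lambda %*% phi) * lambda), 0.05)
  y <- f %*% t(lambda) +
    matrix(stats::rnorm(N * J), N, J) %*% diag(sqrt(uvar), J)
  thr <- if (length(thresholds) == 1L) rep(thresholds, J) else thresholds
  1L * (y > matrix(thr, N, J, byrow = TRUE))
}

# Hand-built Q for K = 2 (not covered by the constrained generator, which
# targets the study's K in {4, 5, 6}).
q2 <- rbind(diag(2), diag(2), c(1, 1), c(1, 1))

# A small self-simulated CDM dataset for reuse.
small_sim <- function(K = 4, IQ = 0.8, N = 500, JK = 4, AC = 0, AT = 0,
                      M = "GDINA", seed = 101) {
  gen_dataset(sim_condition(K, IQ, N, JK, AC, AT, M), seed = seed)
}

# Independent brute-force marginal log-likelihood: plain loops over persons
# and the full latent class enumeration.
brute_loglik <- function(x, P, w) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    li <- 0
    for (l in seq_along(w)) {
      pr <- 1
      for (j in seq_len(ncol(x))) {
        pr <- pr * (if (x[i, j] == 1) P[j, l] else 1 - P[j, l])
      }
      li <- li + w[l] * pr
    }
    total <- total + log(li)
  }
  total
}
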