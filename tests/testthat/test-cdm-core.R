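test_that("profile enumeration is complete, distinct and canonically ordered", {
  s1 <- enumerate_profiles(1)
  expect_equal(unname(s1$profiles), matrix(0:1, 2, 1))
  s2 <- enumerate_profiles(2)
  expect_equal(nrow(s2$profiles), 4L)
  expect_true(all(c(0, 0) == s2$profiles[1, ]))
  expect_true(all(c(1, 1) == s2$profiles[4, ]))
  # attribute 1 is the fastest-varying bit
  expect_equal(unname(s2$profiles[, 1]), c(0L, 1L, 0L, 1L))
  s3 <- enumerate_profiles(3)
  expect_equal(nrow(unique(s3$profiles)), 8L)
  expect_equal(sum(s3$weights), 1)
  expect_error(enumerate_profiles(0), "1, 15")
  expect_error(enumerate_profiles(16), "1, 15")
})

test_that("DINA response probabilities follow the guessing/slip form", {
  expect_equal(dina_prob(0.1, 0.2, 1), 0.8)
  expect_equal(dina_prob(0.1, 0.2, 0), 0.1)
  # deterministic item: probability equals the mastery indicator
  expect_equal(dina_prob(0, 0, c(0, 1)), c(0, 1))
  expect_error(dina_prob(1.2, 0, 1), "0, 1")
})

test_that("G-DINA probabilities sum intercept, main and interaction effects", {
  d <- c(0.1, 0.25, 0.35, 0.1)
  expect_equal(gdina_prob(d, c(1, 1)), 0.80)
  expect_equal(gdina_prob(d, c(0, 1)), 0.45)
  expect_equal(gdina_prob(d, c(1, 0)), 0.35)
  expect_equal(gdina_prob(d, c(0, 0)), 0.10)
  expect_error(gdina_prob(c(0.5, 0.4, 0.4, 0.2), c(1, 1)), "outside")
})

test_that("delta and probability-table parameterizations are inverse bijections", {
  set.seed(11)
  for (Kstar in 1:4) {
    for (rep in 1:5) {
      p <- runif(2^Kstar)
      expect_equal(delta_to_prob(prob_to_delta(p)), p, tolerance = 1e-12)
    }
  }
  # worked example: the table {.1, .35, .45, .8} has these deltas
  expect_equal(prob_to_delta(c(0.1, 0.35, 0.45, 0.8)),
               c(0.1, 0.25, 0.35, 0.1), tolerance = 1e-12)
})

test_that("marginal log-likelihood matches full-enumeration oracle", {
  # single coin-flip item: log(0.5) whatever the response
  P <- matrix(0.5, 1, 2)
  expect_equal(marginal_loglik(matrix(1, 1, 1), P, c(0.5, 0.5)), log(0.5))
  expect_equal(marginal_loglik(matrix(0, 1, 1), P, c(0.5, 0.5)), log(0.5))

  set.seed(21)
  x <- matrix(rbinom(12, 1, 0.5), 4, 3)
  P <- matrix(runif(6, 0.1, 0.9), 3, 2)   # K = 1: two classes
  w <- c(0.3, 0.7)
  expect_equal(marginal_loglik(x, P, w), brute_loglik(x, P, w),
               tolerance = 1e-10)

  # a second random instance at K = 2
  x2 <- matrix(rbinom(24, 1, 0.5), 6, 4)
  P2 <- matrix(runif(16, 0.05, 0.95), 4, 4)
  w2 <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(marginal_loglik(x2, P2, w2), brute_loglik(x2, P2, w2),
               tolerance = 1e-10)

  # doubling every respondent doubles the log-likelihood
  expect_equal(marginal_loglik(rbind(x, x), P, w),
               2 * marginal_loglik(x, P, w))
})

test_that("EM recovers a separable deterministic DINA process", {
  set.seed(31)
  Q <- q2
  alpha <- gen_attribute_profiles(2000, 2, 0, 0)
  params <- lapply(seq_len(nrow(Q)), function(j) {
    attrs <- which(Q[j, ] == 1)
    probs <- rep(0, 2^length(attrs)); probs[2^length(attrs)] <- 1
    list(attrs = attrs, probs = probs)
  })
  x <- gen_responses(alpha, Q, params, "DINA")
  fit <- suppressWarnings(fit_em(x, Q, model = "DINA"))
  est <- dina_params(fit)
  expect_true(all(est$g < 0.01))
  expect_true(all(est$s < 0.01))
})

test_that("EM log-likelihood is monotone and consistent with the evaluator", {
  set.seed(41)
  for (rep in 1:3) {
    sim <- small_sim(N = 300, seed = 200 + rep)
    fit <- fit_em(sim$responses, sim$Q, model = "GDINA")
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    expect_equal(fit$loglik,
                 marginal_loglik(sim$responses, fit$P, fit$weights),
                 tolerance = 1e-8)
    expect_equal(rowSums(fit$posterior), rep(1, fit$N), tolerance = 1e-8)
  }
})

test_that("saturated G-DINA attains at least the DINA likelihood", {
  set.seed(51)
  sim <- small_sim(K = 4, IQ = 0.6, N = 500, M = "DINA", seed = 77)
  fd <- fit_em(sim$responses, sim$Q, model = "DINA")
  fg <- fit_em(sim$responses, sim$Q, model = "GDINA")
  expect_gte(fg$loglik, fd$loglik - 1e-6)
})

test_that("EM recovers generating G-DINA probability tables (K = 2, N = 2000)", {
  set.seed(61)
  Q <- q2
  alpha <- gen_attribute_profiles(2000, 2, 0, 0)
  params <- gen_item_params(Q, 0.8, "GDINA")
  x <- gen_responses(alpha, Q, params, "GDINA")
  fit <- fit_em(x, Q, model = "GDINA")
  Ptrue <- cdmdim:::item_prob_matrix(params, fit$profiles)
  rmse <- sqrt(mean((fit$P - Ptrue)^2))
  expect_lt(rmse, 0.05)
})

test_that("information criteria reproduce the worked real-data values", {
  ic <- information_criteria(-8441 / 2, n_params = 97, N = 400)
  expect_equal(unname(ic["AIC"]), 8635)
  expect_equal(unname(round(ic["BIC"])), 9022)
  ic0 <- information_criteria(-123.4, n_params = 0, N = 50)
  expect_equal(unname(ic0["AIC"]), 246.8)
})
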