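# Independent constraint checker written from the generation rules, used to
# audit the Q-matrix generator.
audit_qmatrix <- function(Q, K, JK) {
  J <- JK * K
  rs <- rowSums(Q)
  # (d) complexity proportions, rounded, one-attribute count >= 2K
  n1 <- max(2 * K, round(0.5 * J)); n3 <- round(0.1 * J); n2 <- J - n1 - n3
  if (sum(rs == 1) != n1 || sum(rs == 2) != n2 || sum(rs == 3) != n3) {
    return("complexity")
  }
  # (a) two disjoint identity blocks: every attribute has >= 2 single items
  if (any(colSums(Q[rs == 1, , drop = FALSE]) < 2)) return("identity")
  # (b) each attribute measured by at least one item beyond the blocks
  extra <- colSums(Q[rs == 1, , drop = FALSE]) - 2 +
    colSums(Q[rs > 1, , drop = FALSE])
  if (any(extra < 1)) return("coverage")
  # (c) pairwise column correlations below 0.50
  cc <- cor(Q); diag(cc) <- 0
  if (any(cc >= 0.50)) return("correlation")
  "ok"
}

test_that("the full design crosses to exactly 972 distinct conditions", {
  cond <- sim_conditions()
  expect_equal(nrow(cond), 972L)
  expect_equal(nrow(unique(cond[, -1])), 972L)
  expect_setequal(unique(cond$K), c(4, 5, 6))
  expect_setequal(unique(cond$M), c("DINA", "GDINA"))
})

test_that("generated Q-matrices satisfy all four generation constraints", {
  set.seed(71)
  for (K in c(4L, 5L, 6L)) {
    for (JK in c(4L, 8L)) {
      Q <- gen_qmatrix(K, JK)
      expect_equal(dim(Q), c(JK * K, K))
      expect_identical(audit_qmatrix(Q, K, JK), "ok")
    }
  }
  # worked split: K = 4, JK = 4 gives 8 / 6 / 2 items by complexity
  Q <- gen_qmatrix(4, 4)
  expect_equal(as.integer(table(rowSums(Q))), c(8L, 6L, 2L))
})

test_that("attribute thresholds form the symmetric equidistant sequence", {
  expect_equal(attribute_thresholds(5, 0.5), c(-0.5, -0.25, 0, 0.25, 0.5))
  expect_equal(attribute_thresholds(4, 0), rep(0, 4))
})

test_that("attribute profiles match their generating distribution", {
  set.seed(81)
  a <- gen_attribute_profiles(20000, 4, 0, 0)
  se <- sqrt(0.25 / 20000)
  expect_true(all(abs(colMeans(a) - 0.5) < 3 * se))

  a2 <- gen_attribute_profiles(20000, 3, 0.6, 0)
  # latent correlation recovered by the tetrachoric of the binary profiles
  R <- tetrachoric_matrix(a2)
  expect_true(all(abs(R[upper.tri(R)] - 0.6) < 0.05))

  expect_error(gen_attribute_profiles(10, 3, 1, 0), "AC")
})

test_that("item parameters respect quality bands, monotonicity and delta sums", {
  set.seed(91)
  Q <- gen_qmatrix(4, 4)
  for (IQ in c(0.4, 0.6, 0.8)) {
    params <- gen_item_params(Q, IQ, "GDINA")
    b <- cdmdim:::iq_bands(IQ)
    for (p in params) {
      expect_gte(p$probs[1], b$p0[1]); expect_lte(p$probs[1], b$p0[2])
      expect_gte(p$probs[2^length(p$attrs)], b$p1[1])
      expect_lte(p$probs[2^length(p$attrs)], b$p1[2])
      expect_true(cdmdim:::group_means_monotone(p$probs))
      if (length(p$attrs) > 1) {
        expect_true(all(cdmdim:::attr_delta_sums(p$probs) > 0.15))
      }
    }
  }
  # expected quality across many items approaches its level
  set.seed(92)
  Qbig <- gen_qmatrix(4, 8)
  ps <- gen_item_params(Qbig, 0.8, "GDINA")
  gap <- vapply(ps, function(p) p$probs[2^length(p$attrs)] - p$probs[1], 0)
  expect_equal(mean(gap), 0.8, tolerance = 0.05)
})

test_that("responses are Bernoulli draws from the class probabilities", {
  # deterministic DINA: responses equal the mastery indicator matrix
  set.seed(101)
  Q <- q2
  alpha <- gen_attribute_profiles(200, 2, 0, 0)
  params <- lapply(seq_len(nrow(Q)), function(j) {
    attrs <- which(Q[j, ] == 1)
    probs <- rep(0, 2^length(attrs)); probs[2^length(attrs)] <- 1
    list(attrs = attrs, probs = probs)
  })
  x <- gen_responses(alpha, Q, params, "DINA")
  eta <- vapply(seq_len(nrow(Q)), function(j) {
    as.integer(rowSums(alpha[, params[[j]]$attrs, drop = FALSE]) ==
                 length(params[[j]]$attrs))
  }, integer(nrow(alpha)))
  expect_equal(unname(x), unname(eta))

  # master-all class hits P(1) within Monte Carlo error
  sim <- small_sim(K = 4, IQ = 0.8, N = 2000, seed = 303)
  masters <- rowSums(sim$alpha) == 4
  if (sum(masters) > 100) {
    for (j in c(1, 8, 16)) {
      p1 <- sim$params[[j]]$probs[2^length(sim$params[[j]]$attrs)]
      se <- sqrt(p1 * (1 - p1) / sum(masters))
      expect_lt(abs(mean(sim$responses[masters, j]) - p1), 3 * se + 1e-9)
    }
  }

  # fixed seed reproduces the dataset bit for bit
  s1 <- gen_dataset(sim_condition(4, 0.6, 500, 4, 0.3, 0.5, "DINA"), seed = 5)
  s2 <- gen_dataset(sim_condition(4, 0.6, 500, 4, 0.3, 0.5, "DINA"), seed = 5)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$Q, s2$Q)
})

test_that("datasets round-trip through the plain-text bundle format", {
  sim <- small_sim(N = 60, seed = 404)
  dir <- tempfile("ds")
  write_dataset(sim, dir)
  x <- read_responses(file.path(dir, "responses.csv"))
  Q <- read_qmatrix(file.path(dir, "qmatrix_true.csv"))
  expect_equal(unname(x), unname(sim$responses))
  expect_equal(unname(Q), unname(sim$Q))
  unlink(dir, recursive = TRUE)
})
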