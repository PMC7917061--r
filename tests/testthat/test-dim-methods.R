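test_that("the leading-run retention rule counts eigenvalues correctly", {
  expect_equal(cdmdim:::count_leading(c(2.5, 1.2, 0.8), c(1.4, 1.0, 0.9)), 2L)
  expect_equal(cdmdim:::count_leading(c(0.9, 2.0), c(1.0, 1.0)), 0L)
  expect_equal(cdmdim:::count_leading(c(2, 2), c(1, 1)), 2L)
})

test_that("parallel analysis recovers one factor and rejects none", {
  set.seed(211)
  hits0 <- hits1 <- 0
  for (r in 1:8) {
    x1 <- make_factor_data(2000, matrix(0.8, 16, 1))
    s1 <- parallel_analysis(x1, "pearson", "mean")
    hits1 <- hits1 + (s1$khat == 1L)
    x0 <- matrix(rbinom(500 * 12, 1, 0.5), 500, 12)
    s0 <- parallel_analysis(x0, "pearson", "mean")
    hits0 <- hits0 + (s0$khat == 0L)
  }
  expect_gte(hits1, 7)
  expect_gte(hits0, 5)
})

test_that("PA sample eigenvalues are invariant to item order", {
  set.seed(221)
  x <- small_sim(N = 400, seed = 1200)$responses
  perm <- sample(ncol(x))
  set.seed(1); s1 <- parallel_analysis(x, n_perm = 20)
  set.seed(1); s2 <- parallel_analysis(x[, perm], n_perm = 20)
  expect_equal(s1$curve$sample, s2$curve$sample, tolerance = 1e-10)
})

test_that("tetrachoric-based PA variants run and return coherent objects", {
  set.seed(223)
  x <- make_factor_data(300, matrix(0.8, 8, 1))
  s <- parallel_analysis(x, "tetrachoric", "p95", n_perm = 25)
  expect_s3_class(s, "dim_suggestion")
  expect_equal(s$method, "PA_p95")
  expect_equal(s$khat, cdmdim:::count_leading(s$curve$sample, s$curve$reference))
})

test_that("MAP matches a brute-force partialling oracle and locates 0/1 factors", {
  # oracle: partial correlation of items i, j given m component scores,
  # via inversion of the joint (i, j, components) covariance matrix
  map_oracle <- function(R, m) {
    J <- ncol(R)
    if (m == 0) return((sum(R^2) - J) / (J * (J - 1)))
    e <- eigen(R, symmetric = TRUE)
    A <- e$vectors[, 1:m, drop = FALSE] %*% diag(sqrt(e$values[1:m]), m)
    tot <- 0
    for (i in 1:(J - 1)) {
      for (j in (i + 1):J) {
        S <- rbind(cbind(R[c(i, j), c(i, j)], A[c(i, j), , drop = FALSE]),
                   cbind(t(A[c(i, j), , drop = FALSE]), diag(m)))
        Om <- solve(S)
        tot <- tot + (-Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2]))^2
      }
    }
    2 * tot / (J * (J - 1))
  }
  set.seed(231)
  x <- make_factor_data(800, matrix(runif(10, 0.4, 0.8), 10, 1))
  R <- tetrachoric_matrix(x)
  s <- map_velicer(R, max_K = 5)
  for (m in 0:5) {
    expect_equal(unname(s$curve$map[as.character(m)]), map_oracle(R, m),
                 tolerance = 1e-10)
  }
  expect_equal(s$khat, 1L)
  expect_equal(map_velicer(diag(8))$khat, 0L)
})

test_that("VSS is near 1 for a perfectly reproduced structure and finds 2 factors", {
  lam <- matrix(0.8, 8, 1)
  R <- tcrossprod(lam); diag(R) <- 1
  s1 <- vss(NULL, v = 1, max_K = 3, R = R)
  expect_gt(s1$curve$vss["1"], 0.999)
  expect_equal(s1$khat, 1L)

  set.seed(241)
  lam2 <- rbind(cbind(rep(0.8, 6), 0), cbind(0, rep(0.8, 6)))
  x <- make_factor_data(2000, lam2)
  s2 <- vss(x, v = 1, max_K = 6)
  expect_equal(s2$khat, 2L)
})

test_that("DETECT index matches hand arithmetic and separates item blocks", {
  # fixed 4-item toy with hand-set conditional covariances
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 0.05
  C[3, 4] <- C[4, 3] <- 0.04
  C[1, 3] <- C[3, 1] <- -0.03
  C[1, 4] <- C[4, 1] <- -0.02
  C[2, 3] <- C[3, 2] <- -0.02
  C[2, 4] <- C[4, 2] <- -0.01
  part <- c(1, 1, 2, 2)
  cbar <- mean(C[upper.tri(C)])
  hand <- hand_c <- 0
  for (j in 1:3) for (k in (j + 1):4) {
    sgn <- if (part[j] == part[k]) 1 else -1
    hand <- hand + sgn * C[j, k]
    hand_c <- hand_c + sgn * (C[j, k] - cbar)
  }
  expect_equal(cdmdim:::detect_index(C, part), hand / 6, tolerance = 1e-12)
  expect_equal(cdmdim:::detect_index(C, part, center = TRUE), hand_c / 6,
               tolerance = 1e-12)

  set.seed(251)
  lam2 <- rbind(cbind(rep(0.85, 8), 0), cbind(0, rep(0.85, 8)))
  x <- make_factor_data(2000, lam2)
  s <- detect(x)
  expect_equal(s$khat, 2L)

  # essentially unidimensional data: conditional covariances near zero
  x1 <- make_factor_data(2000, matrix(0.8, 12, 1))
  C1 <- cdmdim:::conditional_covariances(x1)
  # small relative to the unconditional covariances (~0.15 here)
  expect_lt(mean(abs(C1[upper.tri(C1)])), 0.02)
})

test_that("EKC references follow the closed form and are coerced to >= 1", {
  set.seed(261)
  x <- small_sim(N = 400, seed = 1300)$responses
  R <- tetrachoric_matrix(x)
  s <- ekc(R, N = 400)
  J <- ncol(R)
  lambda <- s$curve$sample
  for (k in c(1, 3, 7)) {
    manual <- max(1, (J - sum(lambda[seq_len(k - 1)])) / (J - k + 1) *
                    (1 + sqrt(J / 400))^2)
    expect_equal(s$curve$reference[k], manual, tolerance = 1e-12)
  }
  expect_true(all(s$curve$reference >= 1))
  # first reference with no prior eigenvalues subtracted
  expect_equal(s$curve$reference[1], (1 + sqrt(J / 400))^2, tolerance = 1e-12)
  # huge N: references collapse to 1, so EKC equals the Kaiser-Guttman count
  s_inf <- ekc(R, N = 1e9)
  expect_true(all(abs(s_inf$curve$reference - 1) < 1e-3))
  expect_equal(s_inf$khat, cdmdim:::count_leading(lambda, rep(1, J)))
})

test_that("every suggestion is the optimum of its own returned curve", {
  set.seed(271)
  x <- small_sim(N = 400, seed = 1400)$responses
  sugs <- assess_dimensionality(
    x, methods = c("PA_rm", "MAP", "VSS1", "DETECT", "EKC"), n_perm = 25)
  expect_named(sugs, c("PA_rm", "MAP", "VSS1", "DETECT", "EKC"))
  expect_equal(sugs$MAP$khat,
               as.integer(names(which.min(sugs$MAP$curve$map))))
  expect_equal(sugs$VSS1$khat,
               as.integer(names(which.max(sugs$VSS1$curve$vss))))
  expect_equal(sugs$DETECT$khat,
               as.integer(names(which.max(sugs$DETECT$curve$detect))))
  for (s in sugs) expect_true(s$khat >= 0 && s$khat <= ncol(x))
})
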