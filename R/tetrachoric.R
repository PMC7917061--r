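# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch).
gauss_legendre_01 <- function(n = 32L) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1L)] <- b
  Jm[cbind(i + 1L, i)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1L, ]^2
  list(nodes = (nodes + 1) / 2, weights = weights / 2)
}

# Standard bivariate normal lower-quadrant CDF Phi2(h, k; rho), vectorized
# over equal-length h, k, rho. Uses Phi2 = Phi(h)Phi(k) + int_0^rho
# phi2(h, k; t) dt with Gauss-Legendre quadrature on the correlation path.
pbinorm <- function(h, k, rho, gl = gauss_legendre_01()) {
  n <- length(h)
  t <- outer(rho, gl$nodes)                       # n x G
  w <- outer(rho, gl$weights)
  om <- 1 - t^2
  dens <- exp(-(h^2 - 2 * t * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
  stats::pnorm(h) * stats::pnorm(k) + rowSums(w * dens)
}

# Pairwise ML tetrachoric estimate for vectors of 2x2 cell counts, thresholds
# fixed at the univariate margins (two-step estimator). The profile score in
# rho is strictly decreasing, so bisection on its sign finds the maximum.
tetrachoric_cells <- function(n11, n10, n01, n00, bound = 0.9999,
                              iter = 60L, gl = gauss_legendre_01()) {
  zero <- (n11 == 0) | (n10 == 0) | (n01 == 0) | (n00 == 0)
  n11 <- n11 + 0.5 * zero; n10 <- n10 + 0.5 * zero
  n01 <- n01 + 0.5 * zero; n00 <- n00 + 0.5 * zero
  N <- n11 + n10 + n01 + n00
  # X = 1 iff Z > tau; work with h = -tau so that pi11 = Phi2(h1, h2; rho)
  h1 <- stats::qnorm((n11 + n10) / N)
  h2 <- stats::qnorm((n11 + n01) / N)
  score <- function(rho) {
    p11 <- pbinorm(h1, h2, rho, gl)
    p10 <- pmax(stats::pnorm(h1) - p11, 1e-12)
    p01 <- pmax(stats::pnorm(h2) - p11, 1e-12)
    p00 <- pmax(1 - stats::pnorm(h1) - stats::pnorm(h2) + p11, 1e-12)
    p11 <- pmax(p11, 1e-12)
    n11 / p11 - n10 / p10 - n01 / p01 + n00 / p00
  }
  lo <- rep(-bound, length(n11))
  hi <- rep(bound, length(n11))
  s_lo <- score(lo)
  s_hi <- score(hi)
  at_lo <- s_lo <= 0
  at_hi <- s_hi >= 0
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    s <- score(mid)
    up <- s > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  rho <- (lo + hi) / 2
  rho[at_lo] <- -bound
  rho[at_hi] <- bound
  rho
}

#' Tetrachoric correlation of a 2 x 2 table
#'
#' Maximum-likelihood tetrachoric correlation with thresholds fixed at the
#' table margins (two-step estimator). Cell counts of zero receive a 0.5
#' continuity correction.
#'
#' @param n11,n10,n01,n00 Cell counts: both items correct, first only, second
#'   only, both incorrect.
#' @return The estimated latent correlation in `(-1, 1)`.
#' @export
tetrachoric_2x2 <- function(n11, n10, n01, n00) {
  tetrachoric_cells(n11, n10, n01, n00)
}

#' Tetrachoric correlation matrix
#'
#' Pairwise maximum-likelihood tetrachoric correlations of dichotomous items,
#' with thresholds fixed at the observed margins. A non-positive-semidefinite
#' result is smoothed by clipping eigenvalues at `1e-6` and rescaling to unit
#' diagonal; the `"smoothed"` attribute records whether this happened.
#'
#' @param x N x J binary response matrix.
#' @param smooth Smooth the matrix to positive semi-definiteness?
#' @return J x J symmetric matrix with unit diagonal.
#' @export
tetrachoric_matrix <- function(x, smooth = TRUE) {
  x <- check_responses(x)
  J <- ncol(x); N <- nrow(x)
  p <- colMeans(x)
  if (any(p == 0 | p == 1)) {
    stop("zero-variance item(s): ",
         paste(which(p == 0 | p == 1), collapse = ", "), call. = FALSE)
  }
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  s11 <- crossprod(x)
  n11 <- s11[pairs]
  n1 <- N * p
  n10 <- n1[pairs[, 1L]] - n11
  n01 <- n1[pairs[, 2L]] - n11
  n00 <- N - n11 - n10 - n01
  rho <- tetrachoric_cells(n11, n10, n01, n00)
  R <- diag(J)
  R[pairs] <- rho
  R[pairs[, c(2L, 1L)]] <- rho
  smoothed <- FALSE
  if (smooth) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < 1e-6) {
      smoothed <- TRUE
      v <- pmax(e$values, 1e-6)
      R <- e$vectors %*% (v * t(e$vectors))
      d <- sqrt(diag(R))
      R <- R / tcrossprod(d)
      diag(R) <- 1
    }
  }
  dimnames(R) <- list(colnames(x), colnames(x))
  attr(R, "smoothed") <- smoothed
  attr(R, "type") <- "tetrachoric"
  R
}
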