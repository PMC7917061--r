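# Principal-axis factor extraction from a correlation matrix. Communalities
# start at squared multiple correlations and are iterated; they are clamped to
# [0.001, 0.998] to keep Heywood cases from derailing the extraction.
paf_extract <- function(R, nfactors, max_iter = 100L, tol = 1e-6) {
  J <- ncol(R)
  if (nfactors >= J) stop("nfactors must be < number of items", call. = FALSE)
  Rinv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-4, J)))
  h2 <- pmin(pmax(1 - 1 / diag(Rinv), 0.1), 0.998)
  Rw <- R
  for (it in seq_len(max_iter)) {
    diag(Rw) <- h2
    e <- eigen(Rw, symmetric = TRUE)
    lam <- e$vectors[, seq_len(nfactors), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(nfactors)], 0)), nfactors)
    h2_new <- pmin(pmax(rowSums(lam^2), 0.001), 0.998)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  diag(Rw) <- h2
  e <- eigen(Rw, symmetric = TRUE)
  lam <- e$vectors[, seq_len(nfactors), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(nfactors)], 0)), nfactors)
  # sign convention: positive column sums
  sgn <- ifelse(colSums(lam) < 0, -1, 1)
  lam <- sweep(lam, 2L, sgn, `*`)
  lam
}

# Quartimin (oblimin, gamma = 0) criterion and gradient.
quartimin_crit <- function(L) {
  L2 <- L^2
  Nm <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
  X <- L2 %*% Nm
  list(f = sum(L2 * X) / 4, G = L * X)
}

# Oblique gradient-projection rotation (quartimin). Returns the rotated
# pattern matrix and factor correlation matrix Phi.
oblimin_rotate <- function(A, max_iter = 500L, eps = 1e-6) {
  K <- ncol(A)
  if (K < 2L) return(list(loadings = A, Phi = diag(1)))
  Tm <- diag(K)
  Tinv <- solve(Tm)
  L <- A %*% t(Tinv)
  vg <- quartimin_crit(L)
  G <- -t(t(L) %*% vg$G %*% Tinv)
  f <- vg$f
  al <- 1
  for (it in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    improved <- FALSE
    for (half in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)))
      Tinv_t <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tinv_t)) {
        Lt <- A %*% t(Tinv_t)
        vgt <- quartimin_crit(Lt)
        if (vgt$f < f - 0.5 * s^2 * al) {
          Tm <- Tt; Tinv <- Tinv_t; L <- Lt; f <- vgt$f
          G <- -t(t(L) %*% vgt$G %*% Tinv)
          improved <- TRUE
          break
        }
      }
      al <- al / 2
    }
    if (!improved) break
  }
  Phi <- crossprod(Tm)
  list(loadings = L, Phi = Phi)
}

#' Exploratory factor analysis of a correlation matrix
#'
#' Principal-axis extraction followed by oblimin (quartimin) oblique rotation.
#' This is the factor engine shared by the discrete-factor-loading Q-matrix
#' estimator and the very-simple-structure index.
#'
#' @param R Correlation matrix (Pearson or tetrachoric).
#' @param nfactors Number of factors to extract.
#' @return List with `loadings` (J x nfactors pattern matrix) and `Phi`
#'   (factor correlation matrix; identity for one factor).
#' @export
efa_oblimin <- function(R, nfactors) {
  A <- paf_extract(R, nfactors)
  out <- oblimin_rotate(A)
  rownames(out$loadings) <- colnames(R)
  out
}
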