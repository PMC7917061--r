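# Canonical method ids understood by the wrapper and the study harness.
known_method_ids <- c("PA_rm", "PA_r95", "PA_pm", "PA_p95", "MAP", "VSS1",
                      "VSS2", "DETECT", "EKC", "MC_AIC", "MC_BIC", "MC_r")

new_dim_suggestion <- function(method, khat, curve) {
  structure(list(method = method, khat = as.integer(khat), curve = curve),
            class = "dim_suggestion")
}

#' @export
print.dim_suggestion <- function(x, ...) {
  cat(sprintf("%s suggests %d dimension(s)\n", x$method, x$khat))
  invisible(x)
}

# Number of leading positions where `sample > reference`, stopping at the
# first failure.
count_leading <- function(sample, reference) {
  fail <- which(sample <= reference)
  if (length(fail) == 0L) length(sample) else fail[1L] - 1L
}

# Pearson correlation of a binary matrix via crossprod (population sds cancel
# in the ratio, so they are used throughout).
fast_cor <- function(x, mu = colMeans(x), sdv = sqrt(mu * (1 - mu))) {
  (crossprod(x) / nrow(x) - tcrossprod(mu)) / tcrossprod(sdv)
}

#' Parallel analysis with random column permutation
#'
#' Compares the principal-components eigenvalues of the sample correlation
#' matrix against reference eigenvalues obtained from copies of the data in
#' which every column is independently permuted (preserving the univariate
#' margins). The suggested dimensionality is the number of leading sample
#' eigenvalues exceeding their reference (mean or 95th percentile across
#' permutations), stopping at the first failure; 0 is a possible answer.
#'
#' @param x N x J binary response matrix.
#' @param corr Correlation type: `"pearson"` or `"tetrachoric"` (tetrachorics
#'   are recomputed on every permuted copy).
#' @param criterion Reference criterion: `"mean"` or `"p95"`.
#' @param n_perm Number of permuted copies.
#' @return A `dim_suggestion` with the sample and reference eigenvalue curves.
#' @export
parallel_analysis <- function(x, corr = c("pearson", "tetrachoric"),
                              criterion = c("mean", "p95"), n_perm = 100L) {
  corr <- match.arg(corr)
  criterion <- match.arg(criterion)
  x <- check_responses(x)
  N <- nrow(x); J <- ncol(x)
  mu <- colMeans(x)
  if (any(mu == 0 | mu == 1)) {
    stop("zero-variance item(s) in parallel analysis", call. = FALSE)
  }
  sdv <- sqrt(mu * (1 - mu))
  corr_fun <- if (corr == "pearson") {
    MU <- tcrossprod(mu)
    SD <- tcrossprod(sdv)
    function(z) (crossprod(z) / N - MU) / SD
  } else {
    function(z) tetrachoric_matrix(z)
  }
  sample_eig <- eigen(corr_fun(x), symmetric = TRUE, only.values = TRUE)$values
  ref <- matrix(NA_real_, n_perm, J)
  xp <- x
  for (p in seq_len(n_perm)) {
    for (attempt in 1:5) {
      for (j in seq_len(J)) xp[, j] <- x[sample.int(N), j]
      ev <- tryCatch(
        eigen(corr_fun(xp), symmetric = TRUE, only.values = TRUE)$values,
        error = function(e) NULL)
      if (!is.null(ev)) break
    }
    if (is.null(ev)) stop("permutation reference failed repeatedly", call. = FALSE)
    ref[p, ] <- ev
  }
  reference <- if (criterion == "mean") colMeans(ref)
               else apply(ref, 2L, stats::quantile, probs = 0.95, names = FALSE)
  khat <- count_leading(sample_eig, reference)
  method <- paste0("PA_", if (corr == "pearson") "r" else "p",
                   if (criterion == "mean") "m" else "95")
  new_dim_suggestion(method, khat,
                     list(sample = sample_eig, reference = reference))
}

#' Velicer's minimum average partial
#'
#' For `m = 0, ..., max_K` principal components partialled out of the
#' correlation matrix, computes the average squared off-diagonal partial
#' correlation (the MAP index); the suggested dimensionality is the `m`
#' minimizing the index (0 is possible).
#'
#' @param R Correlation matrix (tetrachoric in the CDM workflow).
#' @param max_K Largest number of components considered.
#' @return A `dim_suggestion`; the curve is named by `m = 0, ..., max_K`.
#' @export
map_velicer <- function(R, max_K = 9L) {
  J <- ncol(R)
  max_m <- min(max_K, J - 2L)
  e <- eigen(R, symmetric = TRUE)
  curve <- rep(NA_real_, max_m + 1L)
  names(curve) <- 0:max_m
  offdiag_n <- J * (J - 1)
  curve[1L] <- (sum(R^2) - J) / offdiag_n
  for (m in seq_len(max_m)) {
    A <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    C <- R - tcrossprod(A)
    d <- diag(C)
    if (any(d < 1e-10)) break  # singular residual: curve truncated here
    Pm <- C / sqrt(tcrossprod(d))
    curve[m + 1L] <- (sum(Pm^2) - J) / offdiag_n
  }
  khat <- as.integer(names(which.min(curve)))
  new_dim_suggestion("MAP", khat, list(map = curve))
}

#' Very simple structure criterion
#'
#' For each candidate dimensionality `K`, extracts and oblimin-rotates `K`
#' factors from the tetrachoric correlation matrix, keeps the `v` largest
#' absolute loadings per item (zeroing the rest), and measures how well this
#' simplified loading matrix reproduces the observed correlations:
#' `VSS = 1 - MS(residual) / MS(observed)` over off-diagonal entries. The
#' suggested dimensionality maximizes the index.
#'
#' @param x N x J binary response matrix (ignored when `R` is given).
#' @param v Complexity: retained loadings per item (1 or 2).
#' @param max_K Largest dimensionality evaluated.
#' @param R Optional precomputed correlation matrix.
#' @return A `dim_suggestion`; the curve is named by `K`.
#' @export
vss <- function(x, v = 1L, max_K = 9L, R = NULL) {
  if (is.null(R)) R <- tetrachoric_matrix(x)
  J <- ncol(R)
  max_K <- min(max_K, J - 1L)
  ms_obs <- (sum(R^2) - J) / (J * (J - 1))
  curve <- rep(NA_real_, max_K)
  names(curve) <- seq_len(max_K)
  for (K in seq_len(max_K)) {
    if (K < v) next
    sol <- tryCatch(efa_oblimin(R, K), error = function(e) NULL)
    if (is.null(sol)) next
    S <- sol$loadings
    if (K > v) {
      for (j in seq_len(J)) {
        keep <- order(abs(S[j, ]), decreasing = TRUE)[seq_len(v)]
        S[j, -keep] <- 0
      }
    }
    res <- R - S %*% sol$Phi %*% t(S)
    curve[K] <- 1 - ((sum(res^2) - sum(diag(res)^2)) / (J * (J - 1))) / ms_obs
  }
  khat <- as.integer(names(which.max(curve)))
  new_dim_suggestion(paste0("VSS", v), khat, list(vss = curve))
}

# Conditional covariances of all item pairs given the raw total score
# (score = "total", the convention of the reference DETECT implementations)
# or the pair's rest score (score = "rest"). Within-stratum covariances are
# averaged with stratum weights n_r / sum(n_r); strata with fewer than 2
# persons are skipped.
conditional_covariances <- function(x, score = c("total", "rest")) {
  score <- match.arg(score)
  x <- check_responses(x)
  N <- nrow(x); J <- ncol(x)
  S <- rowSums(x)
  C <- matrix(0, J, J)
  for (j in seq_len(J - 1L)) {
    xj <- x[, j]
    for (k in (j + 1L):J) {
      xk <- x[, k]
      r <- (if (score == "rest") S - xj - xk else S) + 1  # 1-based stratum
      agg <- rowsum(cbind(1, xj, xk, xj * xk), r)
      keep <- agg[, 1L] >= 2
      n <- agg[keep, 1L]
      cv <- agg[keep, 4L] / n - (agg[keep, 2L] / n) * (agg[keep, 3L] / n)
      C[j, k] <- C[k, j] <- sum(n * cv) / sum(n)
    }
  }
  C
}

# DETECT index of a partition: mean over item pairs of the signed conditional
# covariance, positive when the pair shares a cluster. `center = TRUE`
# subtracts the grand mean of the covariances before signing.
detect_index <- function(C, cluster, center = FALSE) {
  J <- ncol(C)
  ut <- upper.tri(C)
  same <- outer(cluster, cluster, `==`)[ut]
  dev <- if (center) (C - mean(C[ut]))[ut] else C[ut]
  sum(ifelse(same, dev, -dev)) / (J * (J - 1) / 2)
}

#' DETECT dimensionality index
#'
#' Estimates the conditional covariance of every item pair given the raw
#' total score, builds nested partitions of the items with Ward hierarchical
#' clustering on the conditional-covariance dissimilarity, and evaluates the
#' DETECT index (mean signed conditional covariance, positive within
#' clusters) for 1 to `max_K` clusters. The suggested dimensionality
#' maximizes the index.
#'
#' Conditioning on the total score makes the conditional covariances of pairs
#' measuring the same dominant dimension slightly negative on essentially
#' unidimensional data, which is what lends the classical index its known
#' tendency to prefer finer partitions; `score = "rest"` together with
#' `center = TRUE` gives a mean-centered rest-score variant instead.
#'
#' @param x N x J binary response matrix.
#' @param max_K Largest number of clusters evaluated.
#' @param score Conditioning score, `"total"` (classical) or `"rest"`.
#' @param center Subtract the grand mean covariance inside the index?
#' @return A `dim_suggestion`; the curve holds the index per cluster count.
#' @export
detect <- function(x, max_K = 9L, score = c("total", "rest"),
                   center = FALSE) {
  x <- check_responses(x)
  J <- ncol(x)
  if (J < 2L) stop("DETECT needs at least two items", call. = FALSE)
  C <- conditional_covariances(x, score = match.arg(score))
  d <- stats::as.dist(max(C[upper.tri(C)]) - C)
  hc <- stats::hclust(d, method = "ward.D2")
  max_K <- min(max_K, J)
  curve <- vapply(seq_len(max_K), function(k) {
    detect_index(C, stats::cutree(hc, k), center = center)
  }, 0)
  names(curve) <- seq_len(max_K)
  new_dim_suggestion("DETECT", which.max(curve),
                     list(detect = curve, ccov = C))
}

#' Empirical Kaiser criterion
#'
#' Compares sample eigenvalues against reference eigenvalues derived from the
#' Marchenko-Pastur sampling distribution under independence: reference `k` is
#' `max(1, (J - sum(lambda[1:(k-1)])) / (J - k + 1) * (1 + sqrt(J/N))^2)`.
#' The suggested dimensionality is the number of leading sample eigenvalues
#' exceeding their reference (stopping at the first failure).
#'
#' @param R Correlation matrix (tetrachoric in the CDM workflow).
#' @param N Sample size the correlations were estimated from.
#' @return A `dim_suggestion` with sample and reference eigenvalue curves.
#' @export
ekc <- function(R, N) {
  J <- ncol(R)
  if (N <= J) warning("EKC references assume N > J", call. = FALSE)
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  infl <- (1 + sqrt(J / N))^2
  ref <- numeric(J)
  for (k in seq_len(J)) {
    ref[k] <- max(1, (J - sum(lambda[seq_len(k - 1L)])) / (J - k + 1) * infl)
  }
  khat <- count_leading(lambda, ref)
  new_dim_suggestion("EKC", khat, list(sample = lambda, reference = ref))
}

#' Apply a set of dimensionality-assessment methods to response data
#'
#' Convenience wrapper running any subset of the implemented methods on one
#' response matrix. A tetrachoric matrix is computed once and shared by the
#' methods that need it.
#'
#' @param x N x J binary response matrix.
#' @param methods Character vector among `"PA_rm"`, `"PA_r95"`, `"PA_pm"`,
#'   `"PA_p95"` (parallel-analysis variants: Pearson/tetrachoric x mean/95th
#'   percentile), `"MAP"`, `"VSS1"`, `"VSS2"`, `"DETECT"`, `"EKC"`,
#'   `"MC_AIC"`, `"MC_BIC"`, `"MC_r"`.
#' @param n_perm Permutations for the parallel-analysis variants.
#' @param max_K Largest dimensionality considered by MAP/VSS/DETECT/MC.
#' @param model Fitted CDM for the model-comparison variants.
#' @return Named list of `dim_suggestion` objects.
#' @export
assess_dimensionality <- function(x, methods = c("PA_rm", "MAP", "DETECT"),
                                  n_perm = 100L, max_K = 9L,
                                  model = c("GDINA", "DINA")) {
  model <- match.arg(model)
  known <- known_method_ids
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- list()
  needs_tet <- any(methods %in% c("MAP", "VSS1", "VSS2", "EKC"))
  Rt <- if (needs_tet) tetrachoric_matrix(x) else NULL
  for (m in intersect(methods, c("PA_rm", "PA_r95", "PA_pm", "PA_p95"))) {
    corr <- if (substr(m, 4L, 4L) == "r") "pearson" else "tetrachoric"
    crit <- if (endsWith(m, "m")) "mean" else "p95"
    out[[m]] <- parallel_analysis(x, corr, crit, n_perm)
  }
  if ("MAP" %in% methods) out$MAP <- map_velicer(Rt, max_K)
  if ("VSS1" %in% methods) out$VSS1 <- vss(x, 1L, max_K, R = Rt)
  if ("VSS2" %in% methods) out$VSS2 <- vss(x, 2L, max_K, R = Rt)
  if ("DETECT" %in% methods) out$DETECT <- detect(x, max_K)
  if ("EKC" %in% methods) out$EKC <- ekc(Rt, nrow(x))
  mc_idx <- intersect(methods, c("MC_AIC", "MC_BIC", "MC_r"))
  if (length(mc_idx)) {
    mc <- mc_select(x, model = model, K_range = seq_len(max_K))
    for (m in mc_idx) out[[m]] <- mc$suggestions[[m]]
  }
  out[methods]
}
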