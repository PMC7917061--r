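#' Empirical Q-matrix estimation by discrete factor loadings (DFL)
#'
#' Factor-analyzes the tetrachoric correlation matrix with `K` factors
#' (principal axis, oblimin rotation), takes absolute loadings, and sets
#' `q_jk = 1` when the loading is at or above the mean absolute loading of the
#' item's row (the row dichotomization criterion). Rows can never end up
#' all-zero: the largest loading of a row always reaches its row mean.
#'
#' @param x N x J binary response matrix (ignored when `R` is supplied).
#' @param K Number of attributes to estimate.
#' @param R Optional precomputed tetrachoric correlation matrix.
#' @return A J x K binary Q-matrix.
#' @export
dfl_estimate <- function(x, K, R = NULL) {
  if (is.null(R)) R <- tetrachoric_matrix(x)
  if (K < 1L || K > ncol(R) - 1L) {
    stop("'K' must lie in [1, J - 1]", call. = FALSE)
  }
  sol <- efa_oblimin(R, K)
  dichotomize_loadings(sol$loadings)
}

# The DFL row-mean dichotomization rule, exposed separately so it can be
# exercised on hand-built loading matrices.
dichotomize_loadings <- function(loadings) {
  L <- abs(loadings)
  Q <- 1L * (L >= rowMeans(L))
  zero <- rowSums(Q) == 0L
  if (any(zero)) {  # numerically degenerate rows: keep the largest loading
    Q[cbind(which(zero), max.col(L[zero, , drop = FALSE]))] <- 1L
  }
  dimnames(Q) <- list(NULL, paste0("A", seq_len(ncol(Q))))
  Q
}

# Weighted variance of class success probabilities after collapsing classes
# to the reduced groups implied by attribute set `attrs`.
collapsed_variance <- function(p, w, profiles, attrs) {
  if (length(attrs) == 0L) return(0)
  g <- reduced_group_index(profiles, attrs)
  wg <- rowsum(w, g)
  pg <- rowsum(w * p, g) / pmax(wg, 1e-300)
  pc <- pg[g]
  pbar <- sum(w * p)
  sum(w * (pc - pbar)^2)
}

#' Proportion of variance accounted for by a candidate q-vector (PVAF)
#'
#' Ratio of the class-weight-weighted variance of an item's latent-class
#' success probabilities under a candidate q-vector (classes collapsed to the
#' candidate's reduced groups by weighted means) to the variance under the
#' full K-attribute q-vector.
#'
#' @param fit A `cdm_fit`.
#' @param item Item index.
#' @param q Candidate q-vector (binary, length K).
#' @param x Optional response matrix; when given, the saturated class success
#'   probabilities are the nonparametric posterior-weighted success
#'   proportions rather than the fitted model's probability table.
#' @return PVAF in `[0, 1]`; 0 with a warning for a non-discriminating item.
#' @export
pvaf <- function(fit, item, q, x = NULL) {
  stopifnot(inherits(fit, "cdm_fit"))
  p <- if (is.null(x)) fit$P[item, ] else class_success_probs(fit, x)[item, ]
  w <- fit$weights
  full <- collapsed_variance(p, w, fit$profiles, seq_len(fit$K))
  if (full < 1e-12) {
    warning("item ", item, " does not discriminate between classes",
            call. = FALSE)
    return(0)
  }
  collapsed_variance(p, w, fit$profiles, which(q == 1)) / full
}

# Hull elbow selection on (np, f) points sorted by increasing np: keep the
# upper convex hull, then pick the vertex maximizing the ratio of adjacent
# slopes st / st+1. Returns the index of the selected point.
hull_pick <- function(np, f) {
  stopifnot(!is.unsorted(np))
  keep <- seq_along(np)
  # drop points dominated by a simpler one (fit must increase along the hull)
  dominated <- f <= cummax(c(-Inf, f[-length(f)])) + 1e-12
  dominated[1L] <- FALSE
  keep <- keep[!dominated]
  # peel points under the chord of their neighbours until convex
  repeat {
    if (length(keep) <= 2L) break
    npk <- np[keep]; fk <- f[keep]
    m <- length(keep)
    i <- 2:(m - 1L)
    chord <- fk[i - 1L] + (fk[i + 1L] - fk[i - 1L]) *
      (npk[i] - npk[i - 1L]) / (npk[i + 1L] - npk[i - 1L])
    bad <- which(fk[i] <= chord + 1e-12)
    if (length(bad) == 0L) break
    keep <- keep[-(bad[1L] + 1L)]
  }
  if (length(keep) <= 2L) return(keep[length(keep)])
  npk <- np[keep]; fk <- f[keep]
  sl <- diff(fk) / diff(npk)
  ratio <- sl[-length(sl)] / pmax(sl[-1L], 1e-12)
  keep[which.max(ratio) + 1L]
}

#' Hull/PVAF Q-matrix validation
#'
#' Refines a provisional Q-matrix one item at a time. A CDM is fitted under
#' the provisional Q-matrix; saturated class success probabilities for each
#' item are then estimated nonparametrically (posterior-weighted success
#' proportions). For every candidate q-vector size `t = 1, ..., K` the best
#' candidate by PVAF is found; the retained q-vector sits at the elbow of the
#' convex hull of (number of reduced-group parameters `2^t`, PVAF) points,
#' anchored at `(1, 0)`. The output never contains an all-zero row.
#'
#' @param x N x J binary response matrix.
#' @param Q0 Provisional J x K binary Q-matrix.
#' @param model CDM used for the fit (`"GDINA"` or `"DINA"`).
#' @param fit Optional already-computed `cdm_fit` under `Q0`.
#' @return The validated J x K binary Q-matrix.
#' @export
hull_validate <- function(x, Q0, model = c("GDINA", "DINA"), fit = NULL) {
  model <- match.arg(model)
  x <- check_responses(x)
  Q0 <- check_qmatrix(Q0)
  if (is.null(fit)) fit <- fit_em(x, Q0, model = model)
  K <- ncol(Q0)
  P <- class_success_probs(fit, x)
  w <- fit$weights
  profiles <- fit$profiles
  cand_sets <- lapply(seq_len(K), function(t) utils::combn(K, t, simplify = FALSE))
  Qv <- matrix(0L, nrow(Q0), K, dimnames = dimnames(Q0))
  for (j in seq_len(nrow(Q0))) {
    p <- P[j, ]
    full <- collapsed_variance(p, w, profiles, seq_len(K))
    if (full < 1e-12) {            # non-discriminating: simplest q-vector
      Qv[j, 1L] <- 1L
      next
    }
    best_q <- vector("list", K)
    best_f <- numeric(K)
    for (t in seq_len(K)) {
      vals <- vapply(cand_sets[[t]], function(a) {
        collapsed_variance(p, w, profiles, a)
      }, 0) / full
      i <- which.max(vals)
      best_f[t] <- vals[i]
      best_q[[t]] <- cand_sets[[t]][[i]]
    }
    sel <- hull_pick(c(1, 2^seq_len(K)), c(0, best_f)) - 1L
    if (sel < 1L) sel <- 1L
    Qv[j, best_q[[sel]]] <- 1L
  }
  Qv
}

# All permutations of 1..K (K small).
all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in 0:(K - 1L)) {
      i <- i + 1L
      out[[i]] <- append(s, K, after = pos)
    }
  }
  out
}

#' Q-matrix recovery rate (QRR)
#'
#' Proportion of correctly specified q-entries between an estimated and a true
#' Q-matrix, maximized over column permutations of the estimated matrix
#' (attribute labels are arbitrary).
#'
#' @param Q_est,Q_true J x K binary matrices.
#' @return The recovery rate in `[0, 1]`, with the maximizing column
#'   permutation attached as attribute `"permutation"`.
#' @export
qrr <- function(Q_est, Q_true) {
  Q_est <- as.matrix(Q_est); Q_true <- as.matrix(Q_true)
  if (!all(dim(Q_est) == dim(Q_true))) {
    stop("Q-matrix dimensions differ", call. = FALSE)
  }
  K <- ncol(Q_true)
  if (K > 8L) stop("QRR permutation search supports K <= 8", call. = FALSE)
  best <- -1
  best_perm <- seq_len(K)
  for (perm in all_permutations(K)) {
    agree <- mean(Q_est[, perm, drop = FALSE] == Q_true)
    if (agree > best) {
      best <- agree
      best_perm <- perm
    }
  }
  structure(best, permutation = unlist(best_perm))
}
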