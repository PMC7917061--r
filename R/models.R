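#' DINA item response probability
#'
#' Probability of a correct response to an item with guessing parameter `g`
#' and slip parameter `s`, for examinees whose mastery indicator is `eta`
#' (`eta = 1` when all attributes required by the item are mastered):
#' `P = g^(1 - eta) * (1 - s)^eta`.
#'
#' @param g Guessing probability in `[0, 1]`.
#' @param s Slip probability in `[0, 1]`.
#' @param eta Mastery indicator(s), 0 or 1 (vectorized).
#' @return Success probabilities, same length as `eta`.
#' @examples
#' dina_prob(0.1, 0.2, c(0, 1)) # 0.1, 0.8
#' @export
dina_prob <- function(g, s, eta) {
  if (any(g < 0 | g > 1) || any(s < 0 | s > 1)) {
    stop("'g' and 's' must lie in [0, 1]", call. = FALSE)
  }
  if (!all(eta %in% c(0, 1))) stop("'eta' must be 0/1", call. = FALSE)
  ifelse(eta == 1, 1 - s, g)
}

# Design matrix mapping delta coefficients to the success probabilities of the
# 2^Kstar reduced latent groups (canonical order). Columns: intercept, main
# effects, pairwise interactions (combn order), ..., highest interaction.
delta_design <- function(Kstar) {
  red <- as.matrix(expand.grid(rep(list(0:1), Kstar), KEEP.OUT.ATTRS = FALSE))
  terms <- list(integer(0))
  for (ord in seq_len(Kstar)) {
    terms <- c(terms, utils::combn(Kstar, ord, simplify = FALSE))
  }
  M <- vapply(terms, function(tt) {
    if (length(tt) == 0L) rep(1, nrow(red))
    else apply(red[, tt, drop = FALSE], 1L, prod)
  }, numeric(nrow(red)))
  M
}

#' G-DINA item response probability
#'
#' Success probability under the saturated G-DINA parameterization: the
#' intercept plus the main effects of the mastered required attributes plus
#' all interaction effects among them.
#'
#' @param delta Numeric vector of length `2^Kstar`, ordered as intercept,
#'   main effects, two-way interactions (in `combn` order), and so on.
#' @param reduced_profile Binary vector of length `Kstar` giving mastery of
#'   the item's required attributes.
#' @return A success probability in `[0, 1]`; malformed `delta` sets whose
#'   implied probability leaves `[0, 1]` raise an error.
#' @examples
#' gdina_prob(c(0.1, 0.25, 0.35, 0.1), c(1, 1)) # 0.80
#' @export
gdina_prob <- function(delta, reduced_profile) {
  Kstar <- length(reduced_profile)
  if (length(delta) != 2^Kstar) {
    stop("'delta' must have length 2^Kstar = ", 2^Kstar, call. = FALSE)
  }
  if (!all(reduced_profile %in% c(0, 1))) {
    stop("'reduced_profile' must be 0/1", call. = FALSE)
  }
  M <- delta_design(Kstar)
  l <- profile_index(matrix(reduced_profile, nrow = 1L))
  p <- drop(M[l, , drop = FALSE] %*% delta)
  if (p < -1e-12 || p > 1 + 1e-12) {
    stop("delta set implies probability outside [0, 1]: ", format(p),
         call. = FALSE)
  }
  min(max(p, 0), 1)
}

#' Convert between delta coefficients and a reduced probability table
#'
#' The G-DINA probability table over the `2^Kstar` reduced latent groups and
#' the delta parameterization are related bijectively through the difference
#' contrast design matrix: `p = M %*% delta`.
#'
#' @param delta Delta coefficients (length `2^Kstar`).
#' @param probs Success probabilities per reduced group (length `2^Kstar`,
#'   canonical order).
#' @return The corresponding probability table / delta vector.
#' @export
delta_to_prob <- function(delta) {
  Kstar <- round(log2(length(delta)))
  drop(delta_design(Kstar) %*% delta)
}

#' @rdname delta_to_prob
#' @export
prob_to_delta <- function(probs) {
  Kstar <- round(log2(length(probs)))
  drop(solve(delta_design(Kstar), probs))
}

# J x 2^K matrix of P_j(alpha_l) from per-item reduced probability tables.
# items: list with fields attrs (attribute indices) and probs (2^Kstar table).
item_prob_matrix <- function(items, profiles) {
  L <- nrow(profiles)
  P <- matrix(NA_real_, length(items), L)
  for (j in seq_along(items)) {
    g <- reduced_group_index(profiles, items[[j]]$attrs)
    P[j, ] <- items[[j]]$probs[g]
  }
  P
}

# Per-person log-likelihood contributions by class: N x L matrix of
# sum_j x_ij log P_jl + (1 - x_ij) log(1 - P_jl), computed via one matmul.
class_loglik_matrix <- function(x, P) {
  eps <- 1e-300
  logP <- log(pmax(P, eps))
  log1P <- log(pmax(1 - P, eps))
  x %*% (logP - log1P) + matrix(colSums(log1P), nrow(x), ncol(P), byrow = TRUE)
}

# Stable posterior + log-likelihood from an N x L joint log-density matrix
# (row max located with max.col to avoid apply() overhead).
posterior_from_loglik <- function(ll) {
  n <- nrow(ll)
  m <- ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
  pu <- exp(ll - m)
  denom <- rowSums(pu)
  list(loglik = sum(m + log(denom)), posterior = pu / denom, rowmax = m)
}

#' Marginal log-likelihood of a CDM
#'
#' Computes `sum_i log sum_l w_l prod_j P_j(alpha_l)^x_ij (1-P_j(alpha_l))^(1-x_ij)`
#' with log-sum-exp stability. Class success probabilities exactly 0 or 1 that
#' contradict an observed response yield `-Inf` without error.
#'
#' @param x N x J binary response matrix.
#' @param P J x 2^K matrix of class success probabilities (canonical class
#'   order), e.g. from a fitted model or generating parameters.
#' @param weights Class weights (length `2^K`, summing to 1).
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(x, P, weights) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(P)) stop("x and P dimensions disagree", call. = FALSE)
  if (length(weights) != ncol(P)) stop("weights length != 2^K", call. = FALSE)
  ll <- class_loglik_matrix(x, P)
  ll <- ll + matrix(log(weights), nrow(ll), ncol(ll), byrow = TRUE)
  m <- ll[cbind(seq_len(nrow(ll)), max.col(ll, ties.method = "first"))]
  out <- m + log(rowSums(exp(ll - m)))
  out[is.infinite(m) & m < 0] <- -Inf
  sum(out)
}

#' Information criteria for a fitted CDM
#'
#' `AIC = -2 loglik + 2 p` and `BIC = -2 loglik + p log(N)`, where `p` counts
#' the free item parameters plus the `2^K - 1` structural class weights.
#'
#' @param fit A `cdm_fit` object, or a log-likelihood value.
#' @param n_params Number of free parameters (ignored when `fit` is a
#'   `cdm_fit`).
#' @param N Number of persons (defaults to the fit's sample size).
#' @return Named vector with elements `AIC` and `BIC`.
#' @examples
#' information_criteria(-8441 / 2, n_params = 97, N = 400) # AIC 8635, BIC ~9022
#' @export
information_criteria <- function(fit, n_params = NULL, N = NULL) {
  if (inherits(fit, "cdm_fit")) {
    loglik <- fit$loglik
    if (is.null(n_params)) n_params <- fit$n_params
    if (is.null(N)) N <- fit$N
  } else {
    loglik <- fit
    if (is.null(n_params) || is.null(N)) {
      stop("'n_params' and 'N' are required with a raw log-likelihood",
           call. = FALSE)
    }
  }
  c(AIC = -2 * loglik + 2 * n_params,
    BIC = -2 * loglik + n_params * log(N))
}
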