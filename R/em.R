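# Q-matrix validation used by the estimation and simulation code paths.
check_qmatrix <- function(Q) {
  Q <- as.matrix(Q)
  storage.mode(Q) <- "integer"
  if (!all(Q %in% c(0L, 1L))) stop("Q-matrix entries must be 0/1", call. = FALSE)
  if (any(rowSums(Q) == 0L)) stop("every Q-matrix row needs at least one 1", call. = FALSE)
  if (ncol(Q) < 1L) stop("K must be >= 1", call. = FALSE)
  Q
}

check_responses <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing responses are not supported", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("responses must be 0/1", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Group structure of an item: the reduced-latent-group index of each of the
# 2^K classes. Under DINA all groups collapse to master-all vs the rest.
item_groups <- function(profiles, attrs, model) {
  gidx <- reduced_group_index(profiles, attrs)
  if (model == "DINA") gidx <- 1L + as.integer(gidx == 2L^length(attrs))
  gidx
}

#' Fit a DINA or G-DINA model by marginal maximum likelihood (EM)
#'
#' Estimates item parameters and unstructured latent class weights for a
#' cognitive diagnosis model. Item parameters are expected-count weighted
#' success proportions per reduced latent group (for DINA, per mastery
#' indicator group); class weights are the posterior class means.
#'
#' Initial values are the observed item means with uniform jitter (groups then
#' ordered by the number of mastered attributes), class weights uniform.
#' Estimated probabilities are clamped to `[1e-4, 1 - 1e-4]`; a reduced group
#' with vanishing expected count keeps its previous value (boundary smoothing)
#' and is reported via a warning counter on the fit.
#'
#' @param x N x J binary response matrix.
#' @param Q J x K binary Q-matrix.
#' @param model `"GDINA"` (saturated) or `"DINA"`.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance: maximum absolute change of any item
#'   probability or class weight between iterations.
#' @param loglik_tol Optional secondary stopping rule: also stop when the
#'   log-likelihood improves by less than this amount in one iteration
#'   (disabled at 0, the default). Useful when only the maximized
#'   log-likelihood is needed (e.g. information-criterion scans), where the
#'   likelihood stabilizes long before the parameters do on flat ridges.
#' @param init_jitter Half-width of the uniform jitter used for starting
#'   values.
#' @return An object of class `cdm_fit` with elements `item_probs` (list of
#'   per-item reduced-group success probabilities), `weights`, `P` (J x 2^K
#'   class success probabilities), `posterior` (N x 2^K), `loglik`,
#'   `loglik_trace`, `n_params`, `n_iter`, `converged`, and bookkeeping fields.
#' @examples
#' sim <- gen_dataset(sim_condition(K = 4, IQ = 0.8, N = 300, JK = 4,
#'                                  AC = 0, AT = 0, M = "DINA"), seed = 1)
#' fit <- fit_em(sim$responses, sim$Q, model = "DINA")
#' information_criteria(fit)
#' @export
fit_em <- function(x, Q, model = c("GDINA", "DINA"), max_iter = 1000L,
                   tol = 1e-4, loglik_tol = 0, init_jitter = 0.05) {
  model <- match.arg(model)
  x <- check_responses(x)
  Q <- check_qmatrix(Q)
  N <- nrow(x); J <- ncol(x); K <- ncol(Q)
  if (N < 2L) stop("need N >= 2 persons", call. = FALSE)
  if (J != nrow(Q)) stop("ncol(x) must equal nrow(Q)", call. = FALSE)
  if (J < K) stop("need at least as many items as attributes", call. = FALSE)

  space <- enumerate_profiles(K)
  profiles <- space$profiles
  L <- nrow(profiles)
  attrs <- apply(Q == 1L, 1L, which, simplify = FALSE)
  gidx <- lapply(seq_len(J), function(j) item_groups(profiles, attrs[[j]], model))
  n_groups <- vapply(gidx, max, 0L)
  # number of mastered required attributes per reduced group, for ordering
  grp_order <- lapply(seq_len(J), function(j) {
    if (model == "DINA") 0:1
    else rowSums(as.matrix(expand.grid(rep(list(0:1), length(attrs[[j]])),
                                       KEEP.OUT.ATTRS = FALSE)))
  })

  clamp <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
  pbar <- colMeans(x)
  item_probs <- lapply(seq_len(J), function(j) {
    p <- clamp(pbar[j] + stats::runif(n_groups[j], -init_jitter, init_jitter))
    p[order(grp_order[[j]])] <- sort(p)
    p
  })
  weights <- rep(1 / L, L)

  build_P <- function(ip) {
    P <- matrix(0, J, L)
    for (j in seq_len(J)) P[j, ] <- ip[[j]][gidx[[j]]]
    P
  }

  estep <- function(item_probs, weights) {
    P <- build_P(item_probs)
    ll <- class_loglik_matrix(x, P)
    ll <- ll + matrix(log(weights), N, L, byrow = TRUE)
    posterior_from_loglik(ll)
  }

  trace <- numeric(0)
  converged <- FALSE
  n_boundary <- 0L
  iter <- 0L
  post <- NULL
  loglik <- -Inf
  repeat {
    e <- estep(item_probs, weights)
    loglik <- e$loglik
    post <- e$posterior
    trace <- c(trace, loglik)
    if (iter >= max_iter) break
    if (loglik_tol > 0 && iter >= 1L &&
        loglik - trace[length(trace) - 1L] < loglik_tol) {
      converged <- TRUE
      break
    }

    Nl <- colSums(post)
    w_new <- Nl / N
    R1 <- crossprod(x, post)            # J x L expected correct counts
    delta <- max(abs(w_new - weights))
    new_probs <- item_probs
    for (j in seq_len(J)) {
      agg <- rowsum(cbind(R1[j, ], Nl), gidx[[j]])
      pj <- item_probs[[j]]
      ok <- agg[, 2L] > 1e-8
      pj[ok] <- clamp(agg[ok, 1L] / agg[ok, 2L])
      if (!all(ok)) n_boundary <- n_boundary + sum(!ok)
      delta <- max(delta, max(abs(pj - item_probs[[j]])))
      new_probs[[j]] <- pj
    }
    item_probs <- new_probs
    weights <- w_new
    iter <- iter + 1L
    if (delta < tol) {
      converged <- TRUE
      # one final E-pass so loglik/posterior match the returned parameters
      e <- estep(item_probs, weights)
      loglik <- e$loglik
      post <- e$posterior
      trace <- c(trace, loglik)
      break
    }
  }
  if (n_boundary > 0L) {
    warning("boundary smoothing applied to ", n_boundary,
            " empty reduced-group updates", call. = FALSE)
  }

  n_params <- sum(n_groups) + (L - 1L)
  structure(list(model = model, Q = Q, K = K, N = N, J = J,
                 profiles = profiles, weights = weights,
                 item_attrs = attrs, item_probs = item_probs,
                 P = build_P(item_probs), posterior = post,
                 loglik = loglik, loglik_trace = trace,
                 n_params = n_params, n_iter = iter,
                 converged = converged, n_boundary = n_boundary),
            class = "cdm_fit")
}

#' @export
print.cdm_fit <- function(x, ...) {
  ic <- information_criteria(x)
  cat(sprintf("%s fit: N = %d, J = %d, K = %d\n", x$model, x$N, x$J, x$K))
  cat(sprintf("  logLik = %.2f (np = %d), AIC = %.1f, BIC = %.1f\n",
              x$loglik, x$n_params, ic["AIC"], ic["BIC"]))
  cat(sprintf("  EM: %d iterations, converged = %s\n", x$n_iter, x$converged))
  invisible(x)
}

#' Extract DINA guessing and slip parameters from a fit
#'
#' @param fit A `cdm_fit` object estimated with `model = "DINA"`.
#' @return Data frame with columns `g` and `s` (one row per item).
#' @export
dina_params <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"), fit$model == "DINA")
  g <- vapply(fit$item_probs, `[`, 0, 1L)
  s <- 1 - vapply(fit$item_probs, `[`, 0, 2L)
  data.frame(item = seq_len(fit$J), g = g, s = s)
}

# Nonparametric (two-step) class success probabilities: posterior-weighted
# success proportion of every item in every latent class. Saturated per item,
# used by the Hull/PVAF validation.
class_success_probs <- function(fit, x) {
  x <- check_responses(x)
  Nl <- colSums(fit$posterior)
  R1 <- crossprod(x, fit$posterior)
  P <- sweep(R1, 2L, pmax(Nl, 1e-12), `/`)
  P[, Nl < 1e-8] <- colMeans(x)  # empty classes carry no information
  P
}
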