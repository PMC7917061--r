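#' Simulation study conditions
#'
#' The fully crossed factorial design of the Monte Carlo study: number of
#' attributes `K` in {4, 5, 6}, item quality `IQ` in {0.40, 0.60, 0.80},
#' sample size `N` in {500, 1000, 2000}, items-per-attribute ratio `JK` in
#' {4, 8}, attribute correlation `AC` in {0, 0.30, 0.60}, attribute threshold
#' range `AT` in {0, 0.50, 1}, and generating model `M` in {DINA, GDINA} -
#' 972 conditions in total.
#'
#' @return Data frame with one row per condition and a `condition` id column.
#' @export
sim_conditions <- function() {
  g <- expand.grid(K = c(4L, 5L, 6L), IQ = c(0.40, 0.60, 0.80),
                   N = c(500L, 1000L, 2000L), JK = c(4L, 8L),
                   AC = c(0, 0.30, 0.60), AT = c(0, 0.50, 1),
                   M = c("DINA", "GDINA"),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cbind(condition = seq_len(nrow(g)), g)
}

#' Define a single simulation condition
#'
#' @param K,IQ,N,JK,AC,AT,M Factor levels; see [sim_conditions()].
#' @return A one-row condition data frame.
#' @export
sim_condition <- function(K, IQ, N, JK, AC, AT, M = c("GDINA", "DINA")) {
  M <- match.arg(M)
  data.frame(condition = NA_integer_, K = as.integer(K), IQ = IQ,
             N = as.integer(N), JK = as.integer(JK), AC = AC, AT = AT,
             M = M, stringsAsFactors = FALSE)
}

# Target row-complexity counts: proportions 0.50 / 0.40 / 0.10 of J, rounded,
# adjusted to sum to J with the one-attribute count never below 2K (so two
# identity blocks always fit).
complexity_counts <- function(K, JK) {
  J <- JK * K
  n1 <- max(2L * K, round(0.5 * J))
  n3 <- round(0.1 * J)
  n2 <- J - n1 - n3
  if (n2 < 0L) stop("infeasible complexity split for K = ", K, ", JK = ", JK,
                    call. = FALSE)
  c(n1 = n1, n2 = n2, n3 = n3)
}

# Independent checker for generated Q-matrices; also used by the test suite.
qmatrix_constraints_ok <- function(Q, K = ncol(Q), JK = nrow(Q) / K) {
  Q <- as.matrix(Q)
  rs <- rowSums(Q)
  counts <- complexity_counts(K, JK)
  if (!identical(c(sum(rs == 1), sum(rs == 2), sum(rs == 3)),
                 as.integer(counts))) return(FALSE)
  # two disjoint identity blocks among the single-attribute items
  singles <- Q[rs == 1, , drop = FALSE]
  per_attr <- colSums(singles)
  if (any(per_attr < 2L)) return(FALSE)
  # beyond the identity blocks each attribute is measured by >= 1 more item
  multi <- Q[rs > 1, , drop = FALSE]
  extra_singles <- per_attr - 2L
  if (any(extra_singles + colSums(multi) < 1L)) return(FALSE)
  cc <- suppressWarnings(stats::cor(Q))
  cc[is.na(cc)] <- 1
  diag(cc) <- 0
  all(cc < 0.50)
}

#' Generate a constrained random Q-matrix
#'
#' Draws a `J x K` binary Q-matrix (`J = JK * K`) satisfying: (a) at least two
#' embedded `K x K` identity blocks; (b) beyond those blocks, every attribute
#' measured by at least one further item; (c) all pairwise Pearson column
#' correlations below 0.50; (d) proportions of one-, two-, and three-attribute
#' items equal to 0.50/0.40/0.10 of `J` (rounded; the one-attribute count is
#' kept at `2K` or above). Row order is randomized.
#'
#' @param K Number of attributes.
#' @param JK Items-per-attribute ratio (`J = JK * K`).
#' @param max_tries Rejection-sampling budget.
#' @return A `J x K` binary Q-matrix.
#' @export
gen_qmatrix <- function(K, JK, max_tries = 10000L) {
  counts <- complexity_counts(K, JK)
  J <- JK * K
  for (i in seq_len(max_tries)) {
    singles <- c(rep(seq_len(K), 2L),
                 sample.int(K, counts["n1"] - 2L * K, replace = TRUE))
    rows1 <- matrix(0L, counts["n1"], K)
    rows1[cbind(seq_along(singles), singles)] <- 1L
    rows2 <- t(vapply(seq_len(counts["n2"]),
                      function(i) {
                        r <- integer(K); r[sample.int(K, 2L)] <- 1L; r
                      }, integer(K)))
    rows3 <- t(vapply(seq_len(counts["n3"]),
                      function(i) {
                        r <- integer(K); r[sample.int(K, 3L)] <- 1L; r
                      }, integer(K)))
    Q <- rbind(rows1, rows2, rows3)[sample.int(J), , drop = FALSE]
    if (qmatrix_constraints_ok(Q, K, JK)) {
      dimnames(Q) <- list(NULL, paste0("A", seq_len(K)))
      return(Q)
    }
  }
  stop("Q-matrix generation failed after ", max_tries,
       " tries (K = ", K, ", JK = ", JK, ")", call. = FALSE)
}

#' Generate binary attribute profiles
#'
#' Draws `N` profiles by thresholding an equicorrelated multivariate normal
#' vector: attribute `k` is mastered when the draw exceeds threshold `k`, with
#' thresholds forming an equidistant sequence from `-AT` to `AT` (all zero
#' when `AT = 0`).
#'
#' @param N Number of persons.
#' @param K Number of attributes.
#' @param AC Common latent correlation among attributes, in `[0, 1)`.
#' @param AT Threshold range (>= 0).
#' @return `N x K` binary matrix of mastery indicators.
#' @export
gen_attribute_profiles <- function(N, K, AC, AT) {
  if (AC < 0 || AC >= 1) stop("'AC' must lie in [0, 1)", call. = FALSE)
  if (AT < 0) stop("'AT' must be >= 0", call. = FALSE)
  sigma <- matrix(AC, K, K); diag(sigma) <- 1
  z <- matrix(stats::rnorm(N * K), N, K) %*% chol(sigma)
  thr <- attribute_thresholds(K, AT)
  alpha <- 1L * (z > matrix(thr, N, K, byrow = TRUE))
  colnames(alpha) <- paste0("A", seq_len(K))
  alpha
}

#' @rdname gen_attribute_profiles
#' @export
attribute_thresholds <- function(K, AT) {
  if (K == 1L) return(0)
  seq(-AT, AT, length.out = K)
}

# Uniform bands for P(0) and P(1) by item-quality level.
iq_bands <- function(IQ) {
  switch(as.character(IQ),
         "0.8" = list(p0 = c(0, 0.20), p1 = c(0.80, 1)),
         "0.6" = list(p0 = c(0.10, 0.30), p1 = c(0.70, 0.90)),
         "0.4" = list(p0 = c(0.20, 0.40), p1 = c(0.60, 0.80)),
         stop("'IQ' must be one of 0.40, 0.60, 0.80", call. = FALSE))
}

# Sum of the delta parameters associated with each required attribute: the
# main effect plus every interaction term containing that attribute.
attr_delta_sums <- function(probs) {
  Kstar <- round(log2(length(probs)))
  delta <- prob_to_delta(probs)
  terms <- list(integer(0))
  for (ord in seq_len(Kstar)) {
    terms <- c(terms, utils::combn(Kstar, ord, simplify = FALSE))
  }
  vapply(seq_len(Kstar), function(k) {
    sum(delta[vapply(terms, function(tt) k %in% tt, TRUE)])
  }, 0)
}

# Monotonicity in the sense used for generation: the mean success probability
# of reduced groups, grouped by number of mastered attributes, non-decreasing.
group_means_monotone <- function(probs) {
  Kstar <- round(log2(length(probs)))
  nm <- rowSums(as.matrix(expand.grid(rep(list(0:1), Kstar),
                                      KEEP.OUT.ATTRS = FALSE)))
  mm <- tapply(probs, nm, mean)
  all(diff(mm) >= -1e-12)
}

#' Generate item parameters under an item-quality level
#'
#' For each item, the success probabilities of the master-none and master-all
#' reduced groups are drawn from the item-quality band (`IQ = 0.80`:
#' `P(0) ~ U(0, 0.20)`, `P(1) ~ U(0.80, 1)`; `IQ = 0.60`: `U(0.10, 0.30)` /
#' `U(0.70, 0.90)`; `IQ = 0.40`: `U(0.20, 0.40)` / `U(0.60, 0.80)`), so the
#' expected item quality `P(1) - P(0)` is 0.80, 0.60 or 0.40. Under DINA the
#' item is `g = P(0)`, `s = 1 - P(1)`. Under G-DINA the intermediate reduced
#' groups are drawn uniformly between `P(0)` and `P(1)` by rejection sampling
#' under two constraints: group mean success non-decreasing in the number of
#' mastered attributes, and the per-attribute sum of delta parameters (main
#' effect plus all interactions containing the attribute) above 0.15.
#'
#' @param Q Binary Q-matrix.
#' @param IQ Item quality level (0.40, 0.60 or 0.80).
#' @param model Generating model, `"DINA"` or `"GDINA"`.
#' @param max_tries Rejection budget per item before redrawing `P(0)`, `P(1)`.
#' @return List of per-item parameter sets, each with `attrs` (required
#'   attribute indices), `probs` (reduced-group success table, canonical
#'   order) and, for DINA, `g` and `s`.
#' @export
gen_item_params <- function(Q, IQ, model = c("GDINA", "DINA"),
                            max_tries = 10000L) {
  model <- match.arg(model)
  Q <- check_qmatrix(Q)
  bands <- iq_bands(IQ)
  lapply(seq_len(nrow(Q)), function(j) {
    attrs <- which(Q[j, ] == 1L)
    Kstar <- length(attrs)
    for (outer in 1:100) {
      p0 <- stats::runif(1, bands$p0[1], bands$p0[2])
      p1 <- stats::runif(1, bands$p1[1], bands$p1[2])
      if (model == "DINA" || Kstar == 1L) {
        probs <- if (Kstar == 1L) c(p0, p1) else {
          pr <- rep(p0, 2L^Kstar); pr[2L^Kstar] <- p1; pr
        }
        return(list(attrs = attrs, probs = probs, g = p0, s = 1 - p1))
      }
      for (i in seq_len(max_tries)) {
        probs <- c(p0, stats::runif(2L^Kstar - 2L, p0, p1), p1)
        if (group_means_monotone(probs) &&
            all(attr_delta_sums(probs) > 0.15)) {
          return(list(attrs = attrs, probs = probs))
        }
      }
    }
    stop("item parameter generation failed for item ", j, call. = FALSE)
  })
}

#' Generate Bernoulli responses under a CDM
#'
#' @param alpha `N x K` binary attribute profiles.
#' @param Q Binary Q-matrix.
#' @param params Item parameter list from [gen_item_params()].
#' @param model `"DINA"` or `"GDINA"` (declares which generator produced
#'   `params`; the probability table drives the draws either way).
#' @return `N x J` binary response matrix.
#' @export
gen_responses <- function(alpha, Q, params, model = c("GDINA", "DINA")) {
  model <- match.arg(model)
  Q <- check_qmatrix(Q)
  K <- ncol(Q)
  profiles <- enumerate_profiles(K)$profiles
  P <- item_prob_matrix(params, profiles)
  li <- profile_index(alpha)
  prob <- t(P[, li, drop = FALSE])      # N x J success probabilities
  x <- matrix(stats::rbinom(length(prob), 1L, prob), nrow(prob), ncol(prob))
  colnames(x) <- paste0("item", seq_len(ncol(x)))
  x
}

#' Generate one complete synthetic dataset
#'
#' Draws Q-matrix, attribute profiles, item parameters and responses for one
#' simulation condition. With a `seed`, the dataset is bit-reproducible.
#'
#' @param condition One-row data frame as returned by [sim_condition()] or a
#'   row of [sim_conditions()].
#' @param seed Optional integer seed for the dataset's RNG stream.
#' @return An object of class `cdm_sim`: list with `condition`, `Q`, `alpha`,
#'   `params`, and `responses`.
#' @export
gen_dataset <- function(condition, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  cn <- as.list(condition)
  Q <- gen_qmatrix(cn$K, cn$JK)
  alpha <- gen_attribute_profiles(cn$N, cn$K, cn$AC, cn$AT)
  params <- gen_item_params(Q, cn$IQ, model = cn$M)
  x <- gen_responses(alpha, Q, params, model = cn$M)
  structure(list(condition = condition, Q = Q, alpha = alpha,
                 params = params, responses = x, seed = seed),
            class = "cdm_sim")
}

#' @export
print.cdm_sim <- function(x, ...) {
  cn <- x$condition
  cat(sprintf("Simulated CDM dataset: N = %d, J = %d, K = %d (%s, IQ = %.2f)\n",
              nrow(x$responses), ncol(x$responses), cn$K, cn$M, cn$IQ))
  invisible(x)
}

#' Write a generated dataset to a directory of plain-text files
#'
#' Responses, true Q-matrix and attribute profiles as headered CSV plus a JSON
#' metadata file with the condition and seed.
#'
#' @param sim A `cdm_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "cdm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$Q, file.path(dir, "qmatrix_true.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$alpha, file.path(dir, "profiles_true.csv"),
                   row.names = FALSE)
  meta <- c(as.list(sim$condition), list(seed = sim$seed))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
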