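#' Absolute-fit residual statistics for a fitted CDM
#'
#' Compares observed and model-predicted moments: the proportion correct of
#' each item (`p_j`), the Fisher-transformed Pearson correlation of each item
#' pair (`r_jj'`), and the log-odds ratio of each item pair (`l_jj'`).
#' Predicted moments come from the fitted class weights and item probability
#' tables. An item is flagged when any of its `J - 1` pairwise correlation
#' residual z-scores is significant at `alpha` after Bonferroni correction at
#' the item level (`alpha / (J - 1)`); only `r_jj'` drives the flags, the
#' other residuals are reported.
#'
#' @param fit A `cdm_fit`.
#' @param x The N x J response matrix the model was fitted to.
#' @param alpha Nominal significance level.
#' @return An object of class `residual_stats`: z-score matrices `z_r`, `z_l`,
#'   vector `z_p`, the item-level adjusted minimum pairwise p-value
#'   (`min_p_r`), the per-item flag vector and the flagged-item count.
#' @export
residual_stats <- function(fit, x, alpha = 0.05) {
  stopifnot(inherits(fit, "cdm_fit"))
  x <- check_responses(x)
  N <- nrow(x); J <- ncol(x)
  w <- fit$weights
  P <- fit$P
  p_pred <- drop(P %*% w)
  p11_pred <- P %*% (w * t(P))
  v_pred <- p_pred * (1 - p_pred)
  r_pred <- (p11_pred - tcrossprod(p_pred)) / sqrt(tcrossprod(v_pred))

  p_obs <- colMeans(x)
  n11 <- crossprod(x)
  p11_obs <- n11 / N
  v_obs <- p_obs * (1 - p_obs)
  r_obs <- (p11_obs - tcrossprod(p_obs)) / sqrt(tcrossprod(v_obs))

  clip <- function(r) pmin(pmax(r, -1 + 1e-10), 1 - 1e-10)
  z_r <- (atanh(clip(r_obs)) - atanh(clip(r_pred))) * sqrt(N - 3)
  diag(z_r) <- 0

  # pairwise 2x2 cells, observed and predicted, for the log-odds residuals
  n1 <- N * p_obs
  n10 <- outer(n1, rep(1, J)) - n11
  n01 <- t(n10)
  n00 <- N - n11 - n10 - n01
  cc <- (n11 == 0) | (n10 == 0) | (n01 == 0) | (n00 == 0)
  n11 <- n11 + 0.5 * cc; n10 <- n10 + 0.5 * cc
  n01 <- n01 + 0.5 * cc; n00 <- n00 + 0.5 * cc
  lor_obs <- log(n11 * n00 / (n10 * n01))
  c11 <- pmax(p11_pred, 1e-10)
  c10 <- pmax(outer(p_pred, rep(1, J)) - p11_pred, 1e-10)
  c01 <- t(c10)
  c00 <- pmax(1 - outer(p_pred, rep(1, J)) - t(outer(p_pred, rep(1, J))) +
                p11_pred, 1e-10)
  lor_pred <- log(c11 * c00 / (c10 * c01))
  se_lor <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
  z_l <- (lor_obs - lor_pred) / se_lor
  diag(z_l) <- 0

  z_p <- (p_obs - p_pred) / sqrt(pmax(v_pred, 1e-10) / N)

  p_r <- 2 * stats::pnorm(-abs(z_r))
  diag(p_r) <- NA
  p_r_adj <- pmin(p_r * (J - 1), 1)
  flagged <- apply(p_r_adj < alpha, 1L, any, na.rm = TRUE)
  structure(list(z_p = z_p, z_r = z_r, z_l = z_l,
                 p_r_adj = p_r_adj, min_p_r = min(p_r_adj, na.rm = TRUE),
                 flagged = flagged, n_flagged = sum(flagged), alpha = alpha),
            class = "residual_stats")
}

#' @export
print.residual_stats <- function(x, ...) {
  cat(sprintf("Residual fit: %d flagged item(s), min adjusted p(r) = %.3f\n",
              x$n_flagged, x$min_p_r))
  invisible(x)
}

# Selection rules on a per-K candidate table: lowest AIC/BIC, or the most
# parsimonious K among those attaining the minimum flagged-item count. Ties
# always break toward smaller K.
mc_decide <- function(table) {
  pick_min <- function(v) table$K[which.min(v)]  # which.min takes first = smallest K
  list(MC_AIC = pick_min(table$AIC),
       MC_BIC = pick_min(table$BIC),
       MC_r = pick_min(table$items_r))
}

#' Model-comparison estimate of the number of attributes
#'
#' For each candidate dimensionality `K`, estimates a Q-matrix from the data
#' (DFL), validates it (Hull/PVAF), fits the CDM under the validated Q-matrix,
#' and records `-2LL`, the parameter count, AIC, BIC, and the count of items
#' with some significant pairwise correlation residual. The suggested number
#' of attributes is the candidate with the lowest AIC, the lowest BIC, or the
#' most parsimonious candidate with the lowest flagged-item count.
#'
#' @param x N x J binary response matrix.
#' @param model CDM used throughout (`"GDINA"` or `"DINA"`).
#' @param K_range Candidate attribute counts (default 1 to 9).
#' @param alpha Significance level for the residual flags.
#' @param Q_override Optional named list of Q-matrices (names = K) that
#'   replace the empirical DFL + Hull pipeline for those candidates, e.g. the
#'   generating Q-matrix for upper-limit comparisons.
#' @param R Optional precomputed tetrachoric matrix (shared across candidates).
#' @param loglik_tol Secondary EM stopping rule for the candidate fits (see
#'   [fit_em()]); the scan compares maximized log-likelihoods, which stabilize
#'   well before the parameters on overspecified candidates.
#' @return An object of class `mc_result`: the per-candidate `table`, the
#'   validated Q-matrices, and `suggestions` (a `dim_suggestion` per index:
#'   `MC_AIC`, `MC_BIC`, `MC_r`).
#' @export
mc_select <- function(x, model = c("GDINA", "DINA"), K_range = 1:9,
                      alpha = 0.05, Q_override = NULL, R = NULL,
                      loglik_tol = 0.01) {
  model <- match.arg(model)
  x <- check_responses(x)
  J <- ncol(x)
  K_range <- K_range[K_range >= 1L & K_range < J]
  if (is.null(R)) R <- tetrachoric_matrix(x)
  rows <- list()
  Qs <- list()
  for (K in K_range) {
    res <- tryCatch({
      ov <- Q_override[[as.character(K)]]
      if (!is.null(ov)) {
        Qv <- check_qmatrix(ov)
        fit <- fit_em(x, Qv, model = model, loglik_tol = loglik_tol)
      } else {
        Q0 <- dfl_estimate(x, K, R = R)
        fit <- fit_em(x, Q0, model = model, loglik_tol = loglik_tol)
        Qv <- hull_validate(x, Q0, model = model, fit = fit)
        fit <- if (identical(Qv, Q0)) fit
               else fit_em(x, Qv, model = model, loglik_tol = loglik_tol)
      }
      ic <- information_criteria(fit)
      rs <- residual_stats(fit, x, alpha = alpha)
      list(row = data.frame(K = K, loglik = fit$loglik,
                            n_params = fit$n_params,
                            AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                            min_p_r = rs$min_p_r, items_r = rs$n_flagged,
                            converged = fit$converged),
           Q = Qv)
    }, error = function(e) {
      message("candidate K = ", K, " excluded: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      rows[[length(rows) + 1L]] <- res$row
      Qs[[as.character(K)]] <- res$Q
    }
  }
  if (length(rows) == 0L) stop("all candidates failed", call. = FALSE)
  table <- do.call(rbind, rows)
  khat <- mc_decide(table)
  suggestions <- lapply(names(khat), function(id) {
    crv <- switch(id, MC_AIC = table$AIC, MC_BIC = table$BIC,
                  MC_r = table$items_r)
    names(crv) <- table$K
    new_dim_suggestion(id, khat[[id]], list(criterion = crv))
  })
  names(suggestions) <- names(khat)
  structure(list(table = table, Q = Qs, suggestions = suggestions,
                 model = model), class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Model-comparison dimensionality assessment (", x$model, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 6)
  k <- vapply(x$suggestions, `[[`, 0L, "khat")
  cat(sprintf("Suggested K: AIC = %d, BIC = %d, r = %d\n",
              k["MC_AIC"], k["MC_BIC"], k["MC_r"]))
  invisible(x)
}

#' Combination-rule decision guidelines
#'
#' Applies the recommended decision steps to the suggestions of two or more
#' dimensionality-assessment methods: (a) if all agree, retain their value;
#' (b) if any two agree, retain the agreed value; (c) if none agree but some
#' pair lies within one attribute of each other, explore the values of the
#' methods in those close pairs; (d) otherwise explore every suggested value.
#'
#' @param suggestions Named numeric vector (or list) of suggested attribute
#'   counts, e.g. `c(PA_rm = 3, MC_AIC = 4, FF = 5)`. An externally computed
#'   suggestion (such as a factor-forest prediction) enters as just another
#'   element.
#' @return List with `step` (`"a"`-`"d"`), `decision` (`"retain"` or
#'   `"explore"`), `K` (the retained count or `NA`), and `explore` (the sorted
#'   set of counts to examine).
#' @export
combine_rules <- function(suggestions) {
  k <- unlist(suggestions)
  if (length(k) < 2L) stop("need at least two suggestions", call. = FALSE)
  if (length(unique(k)) == 1L) {
    return(list(step = "a", decision = "retain", K = k[[1L]],
                explore = unname(k[1L])))
  }
  tab <- table(k)
  if (any(tab >= 2L)) {
    kk <- as.integer(names(tab)[which.max(tab)])
    return(list(step = "b", decision = "retain", K = kk, explore = kk))
  }
  pairs <- utils::combn(length(k), 2L)
  close <- abs(k[pairs[1L, ]] - k[pairs[2L, ]]) <= 1L
  if (any(close)) {
    members <- unique(c(pairs[, close]))
    return(list(step = "c", decision = "explore", K = NA_integer_,
                explore = sort(unique(unname(k[members])))))
  }
  list(step = "d", decision = "explore", K = NA_integer_,
       explore = sort(unique(unname(k))))
}
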