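#' Accuracy metrics for a set of dimensionality suggestions
#'
#' Hit rate `HR = mean(khat == K)`, close hit rate
#' `CHR = mean(K - 1 <= khat <= K + 1)`, mean error `ME = mean(khat - K)` and
#' root mean squared error `RMSE = sqrt(mean((khat - K)^2))`. Missing
#' suggestions (method failures) are excluded and counted.
#'
#' @param khat Integer vector of suggested attribute counts (may contain NA).
#' @param K Generating number of attributes (scalar or vector like `khat`).
#' @return One-row data frame with `R` (non-missing count), `n_missing`, `HR`,
#'   `CHR`, `ME`, `RMSE`.
#' @examples
#' hit_metrics(c(4, 4, 5), 4) # HR = 2/3, CHR = 1, ME = 1/3
#' @export
hit_metrics <- function(khat, K) {
  if (length(khat) == 0L) stop("'khat' must be non-empty", call. = FALSE)
  if (length(K) == 1L) K <- rep(K, length(khat))
  ok <- !is.na(khat)
  khat <- khat[ok]; K <- K[ok]
  err <- khat - K
  data.frame(R = length(khat), n_missing = sum(!ok),
             HR = mean(err == 0),
             CHR = mean(abs(err) <= 1),
             ME = mean(err),
             RMSE = sqrt(mean(err^2)))
}

#' Agreement metrics for two or more methods
#'
#' `AR` is the proportion of datasets on which all methods suggested the same
#' count; `AHR` is the proportion of correct suggestions among those
#' agreements (NA when there are none).
#'
#' @param klist List of two or more equal-length suggestion vectors.
#' @param K Generating number of attributes (scalar or vector).
#' @return One-row data frame with `R`, `AR`, `AHR`.
#' @examples
#' agreement_metrics(list(c(4, 4, 3), c(4, 5, 3)), 4) # AR = 2/3, AHR = 1/2
#' @export
agreement_metrics <- function(klist, K) {
  if (!is.list(klist) || length(klist) < 2L) {
    stop("'klist' must list at least two suggestion vectors", call. = FALSE)
  }
  n <- unique(lengths(klist))
  if (length(n) != 1L) stop("suggestion vectors differ in length", call. = FALSE)
  if (length(K) == 1L) K <- rep(K, n)
  k1 <- klist[[1L]]
  agree <- Reduce(`&`, lapply(klist[-1L], function(v) v == k1))
  agree[is.na(agree)] <- FALSE
  data.frame(R = n, AR = mean(agree),
             AHR = if (any(agree)) mean(k1[agree] == K[agree]) else NA_real_)
}

#' Partial eta-squared of a design factor
#'
#' One-way fixed-effects ANOVA of a replicate-level outcome on one factor:
#' `eta_p^2 = SS_effect / (SS_effect + SS_error)`. Values above 0.060 and
#' 0.140 are conventionally read as medium and large effects.
#'
#' @param data Data frame of replicate-level outcomes.
#' @param outcome Name of the numeric outcome column.
#' @param factor Name of the factor column.
#' @return One-row data frame with the sums of squares, `eta_p_sq` and an
#'   effect-size label.
#' @export
partial_eta_squared <- function(data, outcome, factor) {
  f <- as.factor(data[[factor]])
  if (nlevels(f) < 2L) stop("factor '", factor, "' has a single level",
                            call. = FALSE)
  y <- data[[outcome]]
  fit <- stats::lm(y ~ f)
  a <- stats::anova(fit)
  ss_e <- a$`Sum Sq`[1L]
  ss_r <- a$`Sum Sq`[2L]
  # degenerate constant outcomes: no variance to apportion
  eta <- if (sum((y - mean(y))^2) < 1e-12) 0 else ss_e / (ss_e + ss_r)
  data.frame(factor = factor, outcome = outcome,
             ss_effect = ss_e, ss_error = ss_r, eta_p_sq = eta,
             size = if (eta > 0.140) "large" else if (eta > 0.060) "medium"
                    else "small")
}

#' Balanced systematic subset of the simulation design
#'
#' Takes every `step`-th condition of the fully crossed design. Because the
#' design is a mixed-radix crossing with factor periods built from 2s and 3s,
#' any `step` coprime to 6 cycles through the levels of every factor and
#' yields a near-balanced subset of about `972 / step` conditions.
#'
#' @param conditions Condition table (defaults to the full design).
#' @param step Sampling interval; must be coprime to 6.
#' @param offset Starting index (1-based).
#' @return A subset of the condition table.
#' @export
stratified_conditions <- function(conditions = sim_conditions(), step = 7L,
                                  offset = 1L) {
  if (step %% 2L == 0L || step %% 3L == 0L) {
    stop("'step' must be coprime to 6 for factor balance", call. = FALSE)
  }
  conditions[seq(offset, nrow(conditions), by = step), , drop = FALSE]
}

# Per-dataset RNG stream: one seed per (master seed, condition, replicate),
# kept under 2^31. Replicates are assumed <= 100 (< 101).
dataset_seed <- function(master, condition, replicate) {
  (as.integer(master) + 101L * as.integer(condition) +
     as.integer(replicate)) %% 2147483647L
}

#' Run a (scaled-down) dimensionality simulation study
#'
#' Generates datasets for each condition x replicate, applies the requested
#' dimensionality-assessment methods, and logs every suggestion. Each dataset
#' has its own RNG stream keyed by (seed, condition, replicate), so the log is
#' reproducible and independent of the order of evaluation; the assessment
#' step is re-seeded separately so that the logged suggestions do not depend
#' on which other methods are run.
#'
#' @param conditions Condition table ([sim_conditions()] or a subset).
#' @param reps Replicates per condition.
#' @param methods Methods passed to [assess_dimensionality()].
#' @param seed Master seed.
#' @param n_perm,max_K Passed to the methods.
#' @return Data frame (class `cdm_study_log`) with one row per dataset x
#'   method: the condition columns, `replicate`, `seed`, `method`, `khat`
#'   (NA on method failure).
#' @export
run_study <- function(conditions = sim_conditions(), reps = 3L,
                      methods = c("PA_rm", "DETECT"), seed = 1L,
                      n_perm = 100L, max_K = 9L) {
  rows <- vector("list", nrow(conditions) * reps)
  idx <- 0L
  for (i in seq_len(nrow(conditions))) {
    cn <- conditions[i, , drop = FALSE]
    for (r in seq_len(reps)) {
      ds_seed <- dataset_seed(seed, cn$condition, r)
      sim <- gen_dataset(cn, seed = ds_seed)
      khat <- vapply(methods, function(m) {
        set.seed((ds_seed + 104729L +
                    131L * match(m, known_method_ids)) %% 2147483647L)
        tryCatch(
          assess_dimensionality(sim$responses, methods = m, n_perm = n_perm,
                                max_K = max_K, model = cn$M)[[m]]$khat,
          error = function(e) NA_integer_)
      }, integer(1L))
      idx <- idx + 1L
      rows[[idx]] <- cbind(cn[rep(1L, length(methods)), , drop = FALSE],
                           data.frame(replicate = r, seed = ds_seed,
                                      method = methods, khat = unname(khat),
                                      row.names = NULL))
    }
  }
  log <- do.call(rbind, rows)
  rownames(log) <- NULL
  class(log) <- c("cdm_study_log", "data.frame")
  log
}

#' Aggregate a study log into accuracy metrics
#'
#' @param log A study log from [run_study()].
#' @param by Optional condition columns to split by (e.g. `"IQ"`).
#' @return Data frame of [hit_metrics()] per method (x group).
#' @export
study_metrics <- function(log, by = character()) {
  grp <- c("method", by)
  parts <- split(seq_len(nrow(log)), log[grp], drop = TRUE)
  out <- lapply(parts, function(ix) {
    cbind(log[ix[1L], grp, drop = FALSE],
          hit_metrics(log$khat[ix], log$K[ix]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method), , drop = FALSE]
}

#' Agreement metrics between methods from a study log
#'
#' @param log A study log from [run_study()].
#' @param methods Two or more method ids present in the log.
#' @param by Optional condition columns to split by (e.g. `"N"`).
#' @return Data frame of [agreement_metrics()] per group.
#' @export
study_agreement <- function(log, methods, by = character()) {
  wide <- lapply(methods, function(m) log[log$method == m, , drop = FALSE])
  n <- nrow(wide[[1L]])
  if (!all(vapply(wide, nrow, 0L) == n)) {
    stop("methods have unequal numbers of logged datasets", call. = FALSE)
  }
  base <- wide[[1L]]
  if (length(by) == 0L) {
    return(agreement_metrics(lapply(wide, `[[`, "khat"), base$K))
  }
  parts <- split(seq_len(n), base[by], drop = TRUE)
  out <- lapply(parts, function(ix) {
    cbind(base[ix[1L], by, drop = FALSE],
          agreement_metrics(lapply(wide, function(w) w$khat[ix]), base$K[ix]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
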