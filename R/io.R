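#' Read a response matrix or Q-matrix from CSV
#'
#' Responses are persons x items and Q-matrices items x attributes, both as
#' headered CSV of 0/1 entries.
#'
#' @param path File path.
#' @return Integer matrix.
#' @export
read_responses <- function(path) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  check_responses(x)
}

#' @rdname read_responses
#' @export
read_qmatrix <- function(path) {
  check_qmatrix(as.matrix(utils::read.csv(path, check.names = FALSE)))
}

#' Serialize a fitted CDM to JSON
#'
#' Writes item parameters (per-item reduced-group success probabilities and
#' required attributes), class weights, log-likelihood, parameter count and
#' convergence information. The posterior is omitted (it scales with N).
#'
#' @param fit A `cdm_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cdm_fit"))
  ic <- information_criteria(fit)
  out <- list(model = fit$model, N = fit$N, J = fit$J, K = fit$K,
              loglik = fit$loglik, n_params = fit$n_params,
              AIC = ic[["AIC"]], BIC = ic[["BIC"]],
              n_iter = fit$n_iter, converged = fit$converged,
              weights = fit$weights,
              items = lapply(seq_len(fit$J), function(j) {
                list(attrs = fit$item_attrs[[j]],
                     probs = fit$item_probs[[j]])
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize dimensionality suggestions to JSON
#'
#' @param suggestions Named list of `dim_suggestion` objects, as returned by
#'   [assess_dimensionality()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_suggestions_json <- function(suggestions, path) {
  out <- lapply(suggestions, function(s) {
    list(khat = s$khat, curve = s$curve)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study configuration (JSON or YAML)
#'
#' The configuration may name factor levels to subset (`K`, `IQ`, `N`, `JK`,
#' `AC`, `AT`, `M`), plus `reps`, `methods`, `seed`, `n_perm`, and `max_K`.
#'
#' @param path Configuration file (`.json`, `.yml`/`.yaml`).
#' @return A list suitable for [run_study_config()].
#' @export
read_study_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run a study from a configuration list
#'
#' @param config List from [read_study_config()].
#' @return Study log; see [run_study()].
#' @export
run_study_config <- function(config) {
  cond <- sim_conditions()
  for (f in c("K", "IQ", "N", "JK", "AC", "AT", "M")) {
    if (!is.null(config[[f]])) cond <- cond[cond[[f]] %in% config[[f]], ]
  }
  if (!is.null(config$step)) cond <- stratified_conditions(cond, config$step)
  run_study(cond,
            reps = config$reps %||% 3L,
            methods = config$methods %||% c("PA_rm", "DETECT"),
            seed = config$seed %||% 1L,
            n_perm = config$n_perm %||% 100L,
            max_K = config$max_K %||% 9L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
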