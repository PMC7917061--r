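#' Enumerate all attribute profiles
#'
#' Builds the latent class space for `K` dichotomous attributes: all `2^K`
#' binary attribute profiles together with a vector of class weights.
#'
#' The canonical profile order is binary counting with attribute 1 as the
#' fastest-varying bit, i.e. profile `l` (1-based) has
#' `alpha_k = bitwAnd(bitwShiftR(l - 1, k - 1), 1)`. All posterior and weight
#' indexing in the package follows this order.
#'
#' @param K Number of attributes (integer, `1 <= K <= 15`).
#' @param weights Optional class weights; defaults to uniform `1 / 2^K`.
#'
#' @return An object of class `class_space`: a list with `profiles`
#'   (a `2^K x K` binary matrix) and `weights` (a probability vector).
#' @examples
#' enumerate_profiles(2)$profiles
#' @export
enumerate_profiles <- function(K, weights = NULL) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L || K > 15L) {
    stop("'K' must be a single integer in [1, 15]", call. = FALSE)
  }
  profiles <- as.matrix(expand.grid(rep(list(0:1), K), KEEP.OUT.ATTRS = FALSE))
  dimnames(profiles) <- list(NULL, paste0("A", seq_len(K)))
  storage.mode(profiles) <- "integer"
  L <- nrow(profiles)
  if (is.null(weights)) {
    weights <- rep(1 / L, L)
  } else {
    if (length(weights) != L || any(weights < 0)) {
      stop("'weights' must be ", L, " non-negative values", call. = FALSE)
    }
    if (abs(sum(weights) - 1) > 1e-10) {
      stop("'weights' must sum to 1", call. = FALSE)
    }
  }
  structure(list(profiles = profiles, weights = weights, K = K),
            class = "class_space")
}

#' @export
print.class_space <- function(x, ...) {
  cat("Latent class space: K =", x$K, "attributes,",
      nrow(x$profiles), "profiles\n")
  invisible(x)
}

# Map attribute profiles (rows) to canonical class indices in 1..2^K.
profile_index <- function(alpha) {
  alpha <- as.matrix(alpha)
  as.integer(alpha %*% 2^(seq_len(ncol(alpha)) - 1L)) + 1L
}

# For item with required attributes `attrs` (indices into 1..K), the reduced
# latent group index (1..2^Kj*) of every class in the canonical class space.
reduced_group_index <- function(profiles, attrs) {
  if (length(attrs) == 0L) stop("item requires no attributes", call. = FALSE)
  profile_index(profiles[, attrs, drop = FALSE])
}
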