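#' Numerically stable softmax
#'
#' Computes `exp(x) / sum(exp(x))` along a vector after subtracting the
#' maximum, so large logits do not overflow.
#'
#' @param x Numeric vector of logits.
#' @return Numeric vector of the same length summing to 1.
#' @keywords internal
softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Unit-normalize rows of a matrix (or a single vector)
#'
#' Embeddings are unit-normalized before any similarity computation so that
#' plain dot products coincide with cosine similarity.
#'
#' @param x Numeric vector or matrix (rows are embeddings).
#' @param eps Norm floor guarding all-zero rows.
#' @return Object of the same shape with unit Euclidean norm rows.
#' @export
unit_normalize <- function(x, eps = 1e-12) {
  if (is.matrix(x)) {
    n <- sqrt(rowSums(x^2))
    x / pmax(n, eps)
  } else {
    x / max(sqrt(sum(x^2)), eps)
  }
}

#' Derive a child RNG seed from a base seed and a label
#'
#' Deterministic fan-out of one experiment seed into per-component seeds.
#' Result always lies in [0, 2^31 - 2].
#'
#' @param seed Integer base seed.
#' @param label Character tag naming the consumer.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# run expr with a local RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}
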