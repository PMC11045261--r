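#' Cosine similarity between two embeddings
#'
#' `s(v, w) = (v . w) / (||v|| ||w||)`; symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param v,w Nonzero numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("cosine similarity undefined for a zero vector")
  sum(v * w) / (nv * nw)
}

#' Sampler configuration for false-negative elimination
#'
#' @param prior_p Prior probability that a labeled negative semantically
#'   matches the anchor (Bernoulli prior of the matching event). Default
#'   1/10,000, the setting found most effective on a held-out validation
#'   split at full scale.
#' @param density_a Sampling-density hyperparameter `a` of the
#'   easy-negative weight `exp(-a * (s_neg - s_pos)^2)`. Default 0.5.
#' @param easy_threshold_lambda Posterior threshold `lambda` below which a
#'   negative is treated as easy. Default 0.01. The printed condition reads
#'   "<= lambda^2"; the accompanying text configures lambda = 0.01 as the
#'   threshold itself, which is the default reading here;
#'   `square_lambda = TRUE` switches to the literal `lambda^2`.
#' @param min_stats_count Minimum number of accumulated matched and
#'   unmatched similarities before the Gaussian stats are considered ready.
#' @param square_lambda Use `lambda^2` instead of `lambda` as the easy
#'   threshold.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(prior_p = 1e-4, density_a = 0.5,
                           easy_threshold_lambda = 0.01,
                           min_stats_count = 256L,
                           square_lambda = FALSE) {
  stopifnot(prior_p >= 0, prior_p <= 1, density_a > 0,
            easy_threshold_lambda > 0, easy_threshold_lambda < 1,
            min_stats_count >= 1)
  structure(list(prior_p = prior_p, density_a = density_a,
                 easy_threshold_lambda = easy_threshold_lambda,
                 min_stats_count = as.integer(min_stats_count),
                 square_lambda = isTRUE(square_lambda)),
            class = "sampler_config")
}

#' Running Gaussian statistics of matched / unmatched similarities
#'
#' Tracks the mean and standard deviation of the matched similarity set S+
#' and the unmatched set S- with Welford's online accumulator, so the
#' estimates track the evolving embedding space without storing the sets.
#'
#' @return Object of class `similarity_stats` with zero counts.
#' @export
similarity_stats <- function() {
  structure(list(count_pos = 0L, mean_pos = 0, m2_pos = 0,
                 count_neg = 0L, mean_neg = 0, m2_neg = 0),
            class = "similarity_stats")
}

# one-value-at-a-time Welford update; order-deterministic so feeding the
# same stream in different chunk sizes is bitwise identical
welford_push <- function(count, mean, m2, values) {
  for (x in values) {
    count <- count + 1L
    delta <- x - mean
    mean <- mean + delta / count
    m2 <- m2 + delta * (x - mean)
  }
  list(count = count, mean = mean, m2 = m2)
}

#' Append raw similarity values to the running statistics
#'
#' @param stats A `similarity_stats`.
#' @param pos_values Matched-pair similarities to append to S+.
#' @param neg_values Unmatched-pair similarities to append to S-.
#' @return Updated `similarity_stats`.
#' @export
stats_push <- function(stats, pos_values = numeric(), neg_values = numeric()) {
  p <- welford_push(stats$count_pos, stats$mean_pos, stats$m2_pos, pos_values)
  n <- welford_push(stats$count_neg, stats$mean_neg, stats$m2_neg, neg_values)
  stats$count_pos <- p$count; stats$mean_pos <- p$mean; stats$m2_pos <- p$m2
  stats$count_neg <- n$count; stats$mean_neg <- n$mean; stats$m2_neg <- n$m2
  stats
}

#' Update similarity statistics from a batch score matrix
#'
#' Diagonal entries hold the matched-pair scores. A diagonal entry joins S+
#' only when it strictly exceeds every off-diagonal entry in its row — the
#' selective positive filter that keeps unreliable matched scores out of
#' the matched distribution early in training. All off-diagonal entries
#' join S- unfiltered. Values are consumed in a fixed order (diagonal in
#' index order, off-diagonals in row-major order) so updates are
#' deterministic.
#'
#' @param stats A `similarity_stats`.
#' @param batch_scores Square score matrix with matched pairs on the
#'   diagonal.
#' @return Updated `similarity_stats`.
#' @export
update_stats <- function(stats, batch_scores) {
  m <- unclass(batch_scores)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`batch_scores` must be a square matrix")
  }
  b <- nrow(m)
  pos <- numeric(0)
  neg <- numeric(0)
  for (i in seq_len(b)) {
    off <- m[i, -i]
    if (b == 1L || all(m[i, i] > off)) pos <- c(pos, m[i, i])
    neg <- c(neg, off)
  }
  stats_push(stats, pos, neg)
}

#' @rdname update_stats
#' @param config A `sampler_config` supplying `min_stats_count`.
#' @return `stats_ready`: `TRUE` once both S+ and S- hold at least
#'   `min_stats_count` observations.
#' @export
stats_ready <- function(stats, config = sampler_config()) {
  stats$count_pos >= config$min_stats_count &&
    stats$count_neg >= config$min_stats_count
}

stats_sd <- function(count, m2, floor = 1e-6) {
  if (count < 2L) return(floor)
  max(sqrt(m2 / (count - 1L)), floor)
}

#' Parameter view of the running statistics
#'
#' @param stats A `similarity_stats`.
#' @return Named list `mu_pos`, `sigma_pos`, `mu_neg`, `sigma_neg`,
#'   `count_pos`, `count_neg`. Standard deviations are floored at 1e-6 so
#'   degenerate batches cannot collapse the Gaussian model.
#' @export
stats_params <- function(stats) {
  list(mu_pos = stats$mean_pos,
       sigma_pos = stats_sd(stats$count_pos, stats$m2_pos),
       mu_neg = stats$mean_neg,
       sigma_neg = stats_sd(stats$count_neg, stats$m2_neg),
       count_pos = stats$count_pos, count_neg = stats$count_neg)
}

#' Normal density used by the similarity model
#'
#' `f(s) = exp(-(s - mu)^2 / (2 sigma^2)) / (sigma sqrt(2 pi))` with sigma
#' floored at `sigma_floor`.
#'
#' @param s Similarity value(s).
#' @param mu Mean.
#' @param sigma Standard deviation.
#' @param sigma_floor Lower bound applied to `sigma`.
#' @return Density value(s).
#' @export
gaussian_density <- function(s, mu, sigma, sigma_floor = 1e-6) {
  sigma <- max(sigma, sigma_floor)
  exp(-(s - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

#' Posterior probability that a negative sample is a false negative
#'
#' Bayes' rule on the two-component Gaussian model of similarities:
#' `P(match | s) = p f+(s) / (p f+(s) + (1 - p) f-(s))` where `f+` and `f-`
#' are the matched and unmatched similarity densities and `p` is the
#' Bernoulli prior of the matching event.
#'
#' @param s Similarity value(s) of the negative sample to its anchor.
#' @param stats A ready `similarity_stats`.
#' @param config A `sampler_config`.
#' @return Posterior probability in `[0, 1]` (vectorized over `s`).
#' @export
false_negative_posterior <- function(s, stats, config = sampler_config()) {
  if (!stats_ready(stats, config)) {
    stop("similarity statistics not ready: need at least ",
         config$min_stats_count, " matched and unmatched observations")
  }
  prm <- stats_params(stats)
  posterior_from_params(s, prm$mu_pos, prm$sigma_pos,
                        prm$mu_neg, prm$sigma_neg, config$prior_p)
}

#' @rdname false_negative_posterior
#' @param mu_pos,sigma_pos,mu_neg,sigma_neg Explicit Gaussian parameters.
#' @param prior_p Prior probability of the matching event.
#' @export
posterior_from_params <- function(s, mu_pos, sigma_pos, mu_neg, sigma_neg,
                                  prior_p) {
  stop_if_not_scalar_prob(prior_p, "prior_p")
  if (prior_p == 0) return(rep(0, length(s)))
  if (prior_p == 1) return(rep(1, length(s)))
  # work with scaled log densities for numerical stability far in the tails
  lf_pos <- log(prior_p) - (s - mu_pos)^2 / (2 * max(sigma_pos, 1e-6)^2) -
    log(max(sigma_pos, 1e-6))
  lf_neg <- log1p(-prior_p) - (s - mu_neg)^2 / (2 * max(sigma_neg, 1e-6)^2) -
    log(max(sigma_neg, 1e-6))
  m <- pmax(lf_pos, lf_neg)
  exp(lf_pos - m) / (exp(lf_pos - m) + exp(lf_neg - m))
}

#' Sampling weight of a negative candidate
#'
#' Negatives whose false-negative posterior exceeds the easy threshold get
#' weight `exp(-posterior)`, so likely false negatives are down-weighted.
#' Easy negatives (posterior at or below the threshold) get
#' `exp(-a * (s_neg - s_pos)^2)`, concentrating sampling density near the
#' positive score.
#'
#' @param s_neg Similarity of the negative to the anchor.
#' @param s_pos Similarity of the anchor's positive pair.
#' @param posterior False-negative posterior of the negative.
#' @param config A `sampler_config`.
#' @return Weight in `(0, 1]` (vectorized).
#' @export
sampling_weight <- function(s_neg, s_pos, posterior,
                            config = sampler_config()) {
  lambda <- config$easy_threshold_lambda
  if (config$square_lambda) lambda <- lambda^2
  ifelse(posterior <= lambda,
         exp(-config$density_a * (s_neg - s_pos)^2),
         exp(-posterior))
}

#' Weighted sampling of negative indices without replacement
#'
#' Draws `k` distinct candidate indices with probability proportional to
#' weight. Weights are floored at 1e-12 — `exp(-x)` never reaches zero
#' analytically, the floor only guards numeric underflow — so the support
#' never collapses. Deterministic for a fixed seed.
#'
#' @param candidates Integer vector of candidate indices.
#' @param weights Positive sampling weights, one per candidate.
#' @param k Number of indices to draw.
#' @param rng_seed Seed for the draw.
#' @return Integer vector of `k` sampled indices.
#' @export
sample_negatives <- function(candidates, weights, k, rng_seed = 1L) {
  stopifnot(length(candidates) == length(weights))
  if (k > length(candidates)) {
    stop("`k` exceeds the number of candidates (", length(candidates), ")")
  }
  w <- pmax(weights, 1e-12)
  with_seed(rng_seed,
            candidates[sample.int(length(candidates), k, prob = w)])
}
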