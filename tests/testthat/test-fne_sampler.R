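test_that("cosine similarity has its closed-form values and error contract", {
  v <- c(0.3, -0.2, 0.9)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosine_similarity(v, 5 * v), 1)               # scale-invariant
  expect_equal(cosine_similarity(v, c(1, 2, 3)),
               cosine_similarity(c(1, 2, 3), v))             # symmetric
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("the positive filter admits only diagonals that beat their row", {
  s <- similarity_stats()
  s <- update_stats(s, rbind(c(0.9, 0.1), c(0.1, 0.8)))
  expect_equal(s$count_pos, 2L)
  expect_equal(s$count_neg, 2L)
  expect_equal(stats_params(s)$mu_pos, 0.85)
  expect_equal(stats_params(s)$mu_neg, 0.1)

  s2 <- update_stats(similarity_stats(), rbind(c(0.1, 0.9), c(0.1, 0.8)))
  expect_equal(s2$count_pos, 1L)      # row-0 diagonal rejected (0.1 < 0.9)
  expect_equal(stats_params(s2)$mu_pos, 0.8)
  expect_equal(s2$count_neg, 2L)

  expect_error(update_stats(similarity_stats(), matrix(0, 2, 3)), "square")
})

test_that("streaming statistics are invariant to chunking", {
  set.seed(5)
  pos <- rnorm(97, 0.7, 0.1); neg <- rnorm(211, 0.2, 0.15)
  push_chunks <- function(k) {
    s <- similarity_stats()
    for (i in seq(1, length(pos), by = k)) {
      s <- stats_push(s, pos_values = pos[i:min(i + k - 1, length(pos))])
    }
    for (i in seq(1, length(neg), by = k)) {
      s <- stats_push(s, neg_values = neg[i:min(i + k - 1, length(neg))])
    }
    s
  }
  a <- push_chunks(7); b <- push_chunks(13)
  expect_equal(stats_params(a)$mu_pos, stats_params(b)$mu_pos,
               tolerance = 1e-10)
  expect_equal(stats_params(a)$sigma_pos, stats_params(b)$sigma_pos,
               tolerance = 1e-10)
  expect_equal(stats_params(a)$sigma_neg, stats_params(b)$sigma_neg,
               tolerance = 1e-10)
  # against the closed-form estimators
  expect_equal(stats_params(a)$mu_pos, mean(pos), tolerance = 1e-10)
  expect_equal(stats_params(a)$sigma_neg, sd(neg), tolerance = 1e-10)
})

test_that("gaussian_density matches the closed form and integrates to one", {
  expect_equal(gaussian_density(0.5, 0.5, 1), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  for (x in c(0.05, 0.2)) {
    expect_equal(gaussian_density(0.3 + x, 0.3, 0.1),
                 gaussian_density(0.3 - x, 0.3, 0.1))
  }
  grid <- seq(-5, 5, length.out = 200001)
  dens <- gaussian_density(grid, 0.4, 0.7)
  expect_equal(sum(dens) * diff(grid[1:2]), 1, tolerance = 1e-4)
  # sigma floor guards degenerate batches
  expect_true(is.finite(gaussian_density(0.5, 0.5, 0)))
})

test_that("posterior matches the numeric Bayes oracle and its limits", {
  expect_equal(posterior_from_params(0.7, 0.8, 0.1, 0.3, 0.2, 0),
               0)
  expect_equal(posterior_from_params(0.7, 0.8, 0.1, 0.3, 0.2, 1),
               1)
  # equal densities at the midpoint: posterior returns the prior
  expect_equal(posterior_from_params(0.55, 0.8, 0.1, 0.3, 0.1, 0.5),
               0.5, tolerance = 1e-12)
  for (case in list(
    list(s = 0.7, mp = 0.8, sp = 0.1, mn = 0.3, sn = 0.2, p = 0.01),
    list(s = 0.45, mp = 0.7, sp = 0.08, mn = 0.2, sn = 0.15, p = 1e-4),
    list(s = 0.95, mp = 0.75, sp = 0.12, mn = 0.25, sn = 0.1, p = 0.05))) {
    expect_equal(
      posterior_from_params(case$s, case$mp, case$sp, case$mn, case$sn, case$p),
      oracle_posterior(case$s, case$mp, case$sp, case$mn, case$sn, case$p),
      tolerance = 1e-8)
  }
})

test_that("posterior requires ready statistics and respects the readiness gate", {
  cfg <- sampler_config(min_stats_count = 4L)
  s <- update_stats(similarity_stats(), rbind(c(0.9, 0.1), c(0.1, 0.8)))
  expect_false(stats_ready(s, cfg))
  expect_error(false_negative_posterior(0.5, s, cfg), "not ready")
  s <- update_stats(s, rbind(c(0.85, 0.2), c(0.15, 0.9)))
  expect_true(stats_ready(s, cfg))
  expect_true(all(false_negative_posterior(c(0.2, 0.9), s, cfg) >= 0))
})

test_that("posterior is strictly increasing in s for equal sigmas", {
  grid <- seq(-0.5, 1, length.out = 101)
  post <- posterior_from_params(grid, 0.7, 0.12, 0.2, 0.12, 1e-3)
  expect_true(all(diff(post) > 0))
})

test_that("sampling weights follow the two-branch rule and stay in (0, 1]", {
  cfg <- sampler_config()   # lambda = 0.01, a = 0.5
  # easy branch, equal scores: forced weight 1
  expect_equal(sampling_weight(0.5, 0.5, 0.001, cfg), 1)
  # hard branch at posterior 1
  expect_equal(sampling_weight(0.5, 0.5, 1, cfg), exp(-1))
  # easy branch with the default density a = 0.5 and unit score gap
  expect_equal(sampling_weight(1.3, 0.3, 0.001, cfg), exp(-0.5))
  set.seed(8)
  w <- sampling_weight(runif(200, -1, 1), runif(200, -1, 1), runif(200), cfg)
  expect_true(all(w > 0 & w <= 1))
  # weight 1 only in the easy branch at s_neg == s_pos
  expect_lt(sampling_weight(0.51, 0.5, 0.001, cfg), 1)
  expect_lt(sampling_weight(0.5, 0.5, 0.02, cfg), 1)
  # lambda^2 dialect
  cfg2 <- sampler_config(square_lambda = TRUE)
  expect_equal(sampling_weight(0.5, 0.5, 5e-4, cfg2),
               exp(-5e-4))  # 5e-4 > 0.01^2: hard branch under lambda^2
})

test_that("weighted sampling without replacement is seeded and proportional", {
  expect_equal(sample_negatives(7L, 1, 1L, rng_seed = 3L), 7L)
  expect_identical(sample_negatives(1:10, rep(1, 10), 4L, rng_seed = 5L),
                   sample_negatives(1:10, rep(1, 10), 4L, rng_seed = 5L))
  expect_error(sample_negatives(1:3, rep(1, 3), 4L), "exceeds")
  draws <- vapply(seq_len(20000),
                  function(s) sample_negatives(1:3, c(2, 1, 1), 1L, s),
                  integer(1))
  freq <- tabulate(draws, 3) / 20000
  se <- sqrt(c(0.5, 0.25, 0.25) * c(0.5, 0.75, 0.75) / 20000)
  expect_true(all(abs(freq - c(0.5, 0.25, 0.25)) < 3 * se))
  # zero weights are floored, never dropped from the support
  many <- vapply(seq_len(500),
                 function(s) sample_negatives(1:2, c(1, 0), 1L, s), integer(1))
  expect_gt(mean(many == 1L), 0.99)
})
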