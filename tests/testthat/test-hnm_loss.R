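test_that("basic triplet loss evaluates its hinge arithmetic", {
  # equal positive and negative scores force margin-sized terms
  expect_equal(basic_triplet_loss(0.9, 0.9, 0.9, margin = 0.2), 0.4)
  # satisfied constraints vanish
  expect_equal(basic_triplet_loss(0.9, 0.6, 0.5, margin = 0.2), 0)
  # mixed case: one active hinge
  expect_equal(basic_triplet_loss(0.9, 0.85, 0.5, margin = 0.2), 0.15)
})

test_that("loss never increases as a hard negative gets easier", {
  for (s_neg in seq(0.9, 0.5, length.out = 5)) {
    cur <- basic_triplet_loss(0.8, s_neg, 0.4, margin = 0.2)
    nxt <- basic_triplet_loss(0.8, s_neg - 0.05, 0.4, margin = 0.2)
    expect_lte(nxt, cur)
  }
})

test_that("score_matrix is the pairwise dot-product table", {
  q <- diag(4)
  m <- score_matrix(q, q)
  expect_equal(unclass(m), diag(4), ignore_attr = TRUE)
  set.seed(31)
  im <- unit_normalize(matrix(rnorm(4 * 6), 4, 6))
  tx <- unit_normalize(matrix(rnorm(4 * 6), 4, 6))
  m <- score_matrix(im, tx)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(m[i, j], cosine_similarity(im[i, ], tx[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("directional costs follow the clamp-and-mask workflow", {
  m <- rbind(c(0.9, 0.8), c(0.85, 0.7))
  costs <- directional_costs(m, margin = 0.2)
  expect_equal(costs$cost_s, rbind(c(0, 0.1), c(0.35, 0)))
  expect_equal(costs$cost_im, rbind(c(0, 0.3), c(0.15, 0)))
  # identity scores leave no active hinge
  id_costs <- directional_costs(diag(3), margin = 0.2)
  expect_true(all(id_costs$cost_s == 0) && all(id_costs$cost_im == 0))
  # diagonals always masked
  set.seed(2)
  r <- directional_costs(matrix(runif(25), 5, 5), margin = 0.2)
  expect_equal(diag(r$cost_s), rep(0, 5))
  expect_equal(diag(r$cost_im), rep(0, 5))
  expect_error(directional_costs(matrix(0, 2, 3)), "square")
})

test_that("hardest negatives are the masked row/column maxima with low-index ties", {
  m <- rbind(c(0.9, 0.8), c(0.85, 0.7))
  h <- hardest_negatives(m, margin = 0.2)
  expect_equal(h$hard_neg_s, c(0.1, 0.35))
  expect_equal(h$hard_neg_im, c(0.15, 0.3))
  expect_equal(h$idx_s, c(2L, 1L))
  expect_equal(h$idx_im, c(2L, 1L))
  # B = 2: the single off-diagonal per row/column is the maximum
  costs <- directional_costs(m, 0.2)
  expect_equal(h$hard_neg_s, apply(costs$cost_s, 1, max))
  # loop oracle on a random 5x5
  set.seed(12)
  r <- matrix(runif(25, -1, 1), 5, 5)
  h5 <- hardest_negatives(r, 0.2)
  c5 <- directional_costs(r, 0.2)
  for (i in 1:5) {
    expect_equal(h5$hard_neg_s[i], max(c5$cost_s[i, ]))
    expect_equal(h5$idx_s[i], which.max(c5$cost_s[i, ]))
  }
  # deterministic tie-break at the lowest index
  tie <- matrix(0.5, 3, 3); diag(tie) <- 0.5
  expect_equal(hardest_negatives(tie, 0.2)$idx_s, c(2L, 1L, 1L))
})

test_that("vectorized HNM loss equals the scalar-loop oracle at several sizes", {
  for (b in c(2, 3, 5)) {
    for (s in 1:3) {
      set.seed(100 * b + s)
      im <- unit_normalize(matrix(rnorm(b * 8), b, 8))
      tx <- unit_normalize(matrix(rnorm(b * 8), b, 8))
      m <- score_matrix(im, tx)
      expect_equal(hnm_triplet_loss(m, loss_config(hnm_variant = "as_printed")),
                   oracle_hnm(im, tx, 0.2, "as_printed"), tolerance = 1e-10)
      expect_equal(hnm_triplet_loss(m, loss_config(hnm_variant = "conventional")),
                   oracle_hnm(im, tx, 0.2, "conventional"), tolerance = 1e-10)
    }
  }
})

test_that("the as-printed workflow collapses to zero for B = 2 and identity scores", {
  m <- rbind(c(0.9, 0.8), c(0.85, 0.7))
  # (0.1 + 0.35 + 0.3 + 0.15) - (0.1 + 0.35) - (0.15 + 0.3) = 0
  expect_equal(hnm_triplet_loss(m, loss_config(hnm_variant = "as_printed")), 0)
  expect_equal(hnm_triplet_loss(diag(3), loss_config(hnm_variant = "as_printed")), 0)
  expect_equal(hnm_triplet_loss(diag(3),
                                loss_config(hnm_variant = "conventional")), 0)
})

test_that("both HNM variants are non-negative and finite on random batches", {
  for (s in 1:10) {
    set.seed(s)
    b <- sample(2:6, 1)
    m <- matrix(runif(b * b, -1, 1), b, b)
    for (v in c("as_printed", "conventional")) {
      val <- hnm_triplet_loss(m, loss_config(hnm_variant = v))
      expect_true(is.finite(val))
      expect_gte(val, -1e-12)
    }
  }
})

test_that("combined loss mixes the two objectives with weight alpha", {
  set.seed(44)
  s_pos <- runif(8, 0.4, 0.9)
  s_ht <- runif(8, 0.2, 0.8); s_hi <- runif(8, 0.2, 0.8)
  s_ft <- runif(8, 0.2, 0.8); s_fi <- runif(8, 0.2, 0.8)
  l1 <- combined_loss(s_pos, s_ht, s_hi, s_ft, s_fi,
                      loss_config(alpha = 1))
  expect_equal(l1$total, l1$hnm)
  l0 <- combined_loss(s_pos, s_ht, s_hi, s_ft, s_fi,
                      loss_config(alpha = 0))
  expect_equal(l0$total, l0$fne)
  # identical negatives: the mixture equals either loss for any alpha
  for (a in c(0.3, 0.5, 0.9)) {
    l <- combined_loss(s_pos, s_ht, s_hi, s_ht, s_hi, loss_config(alpha = a))
    expect_equal(l$total, l$hnm)
  }
  # from-scratch composition of the per-anchor hinges
  cfg <- loss_config(alpha = 0.5)
  by_hand <- 0
  for (i in 1:8) {
    lh <- max(0.2 - s_pos[i] + s_ht[i], 0) + max(0.2 - s_pos[i] + s_hi[i], 0)
    lf <- max(0.2 - s_pos[i] + s_ft[i], 0) + max(0.2 - s_pos[i] + s_fi[i], 0)
    by_hand <- by_hand + (0.5 * lh + 0.5 * lf) / 8
  }
  lc <- combined_loss(s_pos, s_ht, s_hi, s_ft, s_fi, cfg)
  expect_equal(lc$total, by_hand, tolerance = 1e-12)
})
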