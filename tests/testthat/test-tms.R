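test_that("zero-logit parameters give exactly uniform attention in both branches", {
  p <- tms_params(4)
  for (w in list(tms_forward_weights(p), tms_backward_weights(p))) {
    expect_equal(dim(w), c(1L, 4L, 4L))
    expect_true(all(abs(w - 0.25) < 1e-12))
  }
})

test_that("branch weights are row-stochastic for arbitrary parameters", {
  for (s in 1:5) {
    p <- tms_params(5, num_heads = 2L, init = "random", seed = s)
    for (w in list(tms_forward_weights(p), tms_backward_weights(p))) {
      for (h in 1:2) {
        expect_equal(rowSums(w[h, , ]), rep(1, 5), tolerance = 1e-6)
      }
      expect_true(all(w >= 0))
    }
  }
})

test_that("branch weights match the scalar-loop oracle", {
  for (s in c(2, 9)) {
    p <- tms_params(3, num_heads = 2L, init = "random", seed = s)
    expect_equal(tms_forward_weights(p),
                 oracle_tms_weights(p$forward_attention_weights, "forward"),
                 tolerance = 1e-12)
    expect_equal(tms_backward_weights(p),
                 oracle_tms_weights(p$backward_attention_weights, "backward"),
                 tolerance = 1e-12)
  }
  # the mean-divided and raw variants stay available for fidelity checks
  pm <- tms_params(3, init = "random", seed = 1, normalization = "mean")
  expect_equal(tms_forward_weights(pm),
               oracle_tms_weights(pm$forward_attention_weights, "forward",
                                  "mean"), tolerance = 1e-12)
  pn <- tms_params(3, init = "random", seed = 1, normalization = "none")
  expect_equal(tms_forward_weights(pn),
               oracle_tms_weights(pn$forward_attention_weights, "forward",
                                  "none"), tolerance = 1e-12)
})

test_that("sequence-length mismatches are rejected", {
  p <- tms_params(4)
  expect_error(tms_forward_weights(p, seq_len = 5), "sequence length")
  expect_error(tms_forward(p, matrix(0, 3, 2)), "sequence length")
  expect_error(tms_attend(array(1 / 3, c(1, 3, 3)), matrix(0, 4, 2)),
               "incompatible")
})

test_that("attend reduces to identity and sequence-mean in the limit cases", {
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(tms_attend(diag(4), x), x)
  expect_equal(tms_attend(matrix(1 / 4, 4, 4), x),
               matrix(colMeans(x), 4, 3, byrow = TRUE))
  # triple-loop oracle on random weights
  set.seed(21)
  w <- array(runif(2 * 4 * 4), c(2, 4, 4))
  expect_equal(tms_attend(w, x), oracle_attend(w, x), tolerance = 1e-12)
})

test_that("mixing uses the fixed 0.6/0.4 coefficients", {
  ones <- matrix(1, 3, 2); zeros <- matrix(0, 3, 2)
  expect_equal(tms_mix(ones, zeros), matrix(0.6, 3, 2))
  expect_equal(tms_mix(zeros, ones), matrix(0.4, 3, 2))
  z <- matrix(rnorm(6), 3, 2)
  expect_equal(tms_mix(z, z), z)
})

test_that("zero-initialized TMS maps every position to the sequence mean", {
  p <- tms_params(5)
  x <- matrix(rnorm(5 * 3), 5, 3)
  out <- tms_forward(p, x)
  expect_equal(out, matrix(colMeans(x), 5, 3, byrow = TRUE))
  expect_equal(dim(out), dim(x))
})

test_that("the full TMS pipeline equals the composed loop oracles", {
  for (s in c(4, 13)) {
    p <- tms_params(4, num_heads = 2L, init = "random", seed = s)
    set.seed(s)
    x <- matrix(rnorm(4 * 6), 4, 6)
    expect_equal(tms_forward(p, x), oracle_tms_forward(p, x),
                 tolerance = 1e-12)
    expect_equal(dim(tms_forward(p, x)), dim(x))
  }
})

test_that("TMS output stays within the per-coordinate convex hull of the input", {
  for (s in 1:5) {
    p <- tms_params(6, init = "random", seed = s)
    set.seed(100 + s)
    x <- matrix(rnorm(6 * 4), 6, 4)
    out <- tms_forward(p, x)
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    expect_true(all(sweep(out, 2, lo, `>=`) | abs(sweep(out, 2, lo)) < 1e-10))
    expect_true(all(sweep(out, 2, hi, `<=`) | abs(sweep(out, 2, hi)) < 1e-10))
  }
})

test_that("analytic TMS gradients agree with finite differences", {
  p <- tms_params(3, init = "random", seed = 6)
  set.seed(6)
  x <- matrix(rnorm(9), 3, 3)
  g <- matrix(rnorm(9), 3, 3)
  gr <- tms_backward(p, x, g)
  f <- function(pp, xx) sum(g * tms_forward(pp, xx))
  eps <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    p1 <- p; p2 <- p
    p1$forward_attention_weights[1, i, j] <-
      p1$forward_attention_weights[1, i, j] + eps
    p2$forward_attention_weights[1, i, j] <-
      p2$forward_attention_weights[1, i, j] - eps
    expect_equal(gr$d_forward[1, i, j], (f(p1, x) - f(p2, x)) / (2 * eps),
                 tolerance = 1e-4)
    p1 <- p; p2 <- p
    p1$backward_attention_weights[1, i, j] <-
      p1$backward_attention_weights[1, i, j] + eps
    p2$backward_attention_weights[1, i, j] <-
      p2$backward_attention_weights[1, i, j] - eps
    expect_equal(gr$d_backward[1, i, j], (f(p1, x) - f(p2, x)) / (2 * eps),
                 tolerance = 1e-4)
    x1 <- x; x2 <- x
    x1[i, j] <- x1[i, j] + eps; x2[i, j] <- x2[i, j] - eps
    expect_equal(gr$dx[i, j], (f(p, x1) - f(p, x2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
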