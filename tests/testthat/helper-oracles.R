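# Independent scalar-loop / quadrature oracles. These deliberately avoid the
# package's vectorized code paths: everything is explicit loops over indices
# or adaptive numerical integration, so agreement is a genuine cross-check.

oracle_softmax_row <- function(v) {
  e <- numeric(length(v))
  for (k in seq_along(v)) e[k] <- exp(v[k] - max(v))
  e / sum(e)
}

# forward/backward branch weights of the mixed self-attention layer,
# recomputed with explicit loops for an (H, L, L) logit array
oracle_tms_weights <- function(p, branch = c("forward", "backward"),
                               normalization = "row") {
  branch <- match.arg(branch)
  h <- dim(p)[1]; l <- dim(p)[2]
  raw <- array(0, dim(p))
  add_axis <- function(raw, axis) {
    if (axis == 3) {
      for (hh in 1:h) for (i in 1:l) {
        raw[hh, i, ] <- raw[hh, i, ] + oracle_softmax_row(p[hh, i, ])
      }
    } else if (axis == 2) {
      for (hh in 1:h) for (j in 1:l) {
        raw[hh, , j] <- raw[hh, , j] + oracle_softmax_row(p[hh, , j])
      }
    } else {
      for (i in 1:l) for (j in 1:l) {
        raw[, i, j] <- raw[, i, j] + oracle_softmax_row(p[, i, j])
      }
    }
    raw
  }
  axes <- if (branch == "forward") c(3, 2, 1) else c(1, 2)
  for (a in axes) raw <- add_axis(raw, a)
  if (normalization == "row") {
    for (hh in 1:h) for (i in 1:l) raw[hh, i, ] <- raw[hh, i, ] / sum(raw[hh, i, ])
  } else if (normalization == "mean") {
    raw <- raw / length(axes)
  }
  raw
}

oracle_attend <- function(w, x) {
  # w: (H, L, L); x: (L, d); triple loop matmul then head average
  h <- dim(w)[1]; l <- nrow(x); d <- ncol(x)
  out <- matrix(0, l, d)
  for (hh in 1:h) for (i in 1:l) for (k in 1:d) {
    acc <- 0
    for (j in 1:l) acc <- acc + w[hh, i, j] * x[j, k]
    out[i, k] <- out[i, k] + acc
  }
  out / h
}

oracle_tms_forward <- function(params, x) {
  wf <- oracle_tms_weights(params$forward_attention_weights, "forward",
                           params$normalization)
  wb <- oracle_tms_weights(params$backward_attention_weights, "backward",
                           params$normalization)
  params$mix_forward * oracle_attend(wf, x) +
    params$mix_backward * oracle_attend(wb, x)
}

oracle_pool <- function(x) {
  d <- ncol(x)
  out <- numeric(d)
  for (k in 1:d) {
    acc <- 0
    for (i in 1:nrow(x)) acc <- acc + x[i, k]
    out[k] <- acc / nrow(x)
  }
  out
}

# full six-step hard-negative workflow with scalar loops
oracle_hnm <- function(im, s, margin, variant = "as_printed") {
  b <- nrow(im)
  scores <- matrix(0, b, b)
  for (i in 1:b) for (j in 1:b) scores[i, j] <- sum(im[i, ] * s[j, ])
  cost_s <- matrix(0, b, b); cost_im <- matrix(0, b, b)
  for (i in 1:b) for (j in 1:b) {
    if (i != j) {
      cost_s[i, j] <- max(margin + scores[i, j] - scores[i, i], 0)
      cost_im[i, j] <- max(margin + scores[i, j] - scores[j, j], 0)
    }
  }
  hard_s <- numeric(b); hard_im <- numeric(b)
  for (i in 1:b) hard_s[i] <- max(cost_s[i, ])
  for (j in 1:b) hard_im[j] <- max(cost_im[, j])
  if (variant == "as_printed") {
    sum(cost_s) + sum(cost_im) - sum(hard_s) - sum(hard_im)
  } else {
    sum(hard_s) + sum(hard_im)
  }
}

# numeric Bayes oracle: conditioning on s <= S <= s + ds via adaptive
# quadrature of the two normal densities, then the ds -> 0 limit taken by
# a symmetric shrinking window
oracle_posterior <- function(s, mu_pos, sigma_pos, mu_neg, sigma_neg,
                             prior_p, h = 1e-6) {
  num <- prior_p * stats::integrate(function(t) stats::dnorm(t, mu_pos, sigma_pos),
                                    s - h, s + h, rel.tol = 1e-13)$value
  den <- num + (1 - prior_p) *
    stats::integrate(function(t) stats::dnorm(t, mu_neg, sigma_neg),
                     s - h, s + h, rel.tol = 1e-13)$value
  num / den
}

oracle_rank <- function(query, gallery) {
  sims <- numeric(nrow(gallery))
  for (i in seq_len(nrow(gallery))) {
    v <- query / sqrt(sum(query^2))
    g <- gallery[i, ] / sqrt(sum(gallery[i, ]^2))
    sims[i] <- sum(v * g)
  }
  order(-sims, seq_along(sims))
}

random_rotation <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

tiny_world_dir <- function(config) {
  dir <- file.path(tempdir(), paste0("world_", config$seed, "_",
                                     config$n_classes, "x", config$n_per_class))
  if (!dir.exists(dir)) render_image_caption_world(config, dir)
  dir
}
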