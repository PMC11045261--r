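#' Two-way mixed self-attention (TMS) parameters
#'
#' TMS enhances an (L, d) feature sequence with two learnable attention
#' branches whose weights are free parameters (not functions of the
#' input). The forward branch sums softmax applications of its parameter
#' array along the column, row and head axes; the backward branch sums
#' softmax applications along the head and row axes. The two attended
#' sequences are mixed with fixed coefficients 0.6 (forward) and 0.4
#' (backward).
#'
#' The summed softmax terms are not individually commensurate, so a
#' normalization convention is applied before attending:
#' * `"row"` (default): each row of the summed weights is renormalized to
#'   sum to 1, making every attended position an exact convex combination
#'   of the input positions — the reading under which the weights "form
#'   valid probability distributions" as a single attention matrix.
#' * `"mean"`: divide by the number of summed terms (3 forward,
#'   2 backward), keeping magnitudes stable without exact row sums.
#' * `"none"`: the raw sums, for fidelity experiments.
#'
#' @param seq_len Sequence length L the parameters are shaped for.
#' @param num_heads Number of attention heads (default 1); heads are
#'   averaged after attending.
#' @param init `"zero"` (uniform attention at initialization) or
#'   `"random"` (small seeded Gaussian logits).
#' @param seed Seed for random initialization.
#' @param mix_forward,mix_backward Fixed mixing coefficients; must sum
#'   to 1.
#' @param normalization Weight normalization convention, see above.
#' @return Object of class `tms_params` holding `(num_heads, L, L)` logit
#'   arrays `forward_attention_weights` and `backward_attention_weights`.
#' @export
tms_params <- function(seq_len, num_heads = 1L,
                       init = c("zero", "random"), seed = 1L,
                       mix_forward = 0.6, mix_backward = 0.4,
                       normalization = c("row", "mean", "none")) {
  init <- match.arg(init)
  normalization <- match.arg(normalization)
  stopifnot(seq_len >= 1, num_heads >= 1,
            abs(mix_forward + mix_backward - 1) < 1e-12)
  shape <- c(num_heads, seq_len, seq_len)
  make <- function(tag) {
    if (init == "zero") array(0, shape)
    else with_seed(derive_seed(seed, tag),
                   array(stats::rnorm(prod(shape), sd = 0.5), shape))
  }
  structure(list(
    forward_attention_weights = make("tms_forward"),
    backward_attention_weights = make("tms_backward"),
    num_heads = as.integer(num_heads), seq_len = as.integer(seq_len),
    mix_forward = mix_forward, mix_backward = mix_backward,
    normalization = normalization
  ), class = "tms_params")
}

# softmax of a (H, L, L) logit array along one axis (3 = columns within a
# row, 2 = rows within a column, 1 = across heads)
softmax_axis <- function(p, axis) {
  d <- dim(p)
  out <- p
  if (axis == 3L) {
    for (h in seq_len(d[1])) for (i in seq_len(d[2])) {
      out[h, i, ] <- softmax_vec(p[h, i, ])
    }
  } else if (axis == 2L) {
    for (h in seq_len(d[1])) for (j in seq_len(d[3])) {
      out[h, , j] <- softmax_vec(p[h, , j])
    }
  } else if (axis == 1L) {
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      out[, i, j] <- softmax_vec(p[, i, j])
    }
  } else stop("axis must be 1, 2 or 3")
  out
}

# gradient of sum(g * softmax_axis(p, axis)) with respect to p
softmax_axis_grad <- function(p, g, axis) {
  d <- dim(p)
  out <- array(0, d)
  bp <- function(pv, gv) {
    s <- softmax_vec(pv)
    s * (gv - sum(gv * s))
  }
  if (axis == 3L) {
    for (h in seq_len(d[1])) for (i in seq_len(d[2])) {
      out[h, i, ] <- bp(p[h, i, ], g[h, i, ])
    }
  } else if (axis == 2L) {
    for (h in seq_len(d[1])) for (j in seq_len(d[3])) {
      out[h, , j] <- bp(p[h, , j], g[h, , j])
    }
  } else {
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      out[, i, j] <- bp(p[, i, j], g[, i, j])
    }
  }
  out
}

tms_axes <- list(forward = c(3L, 2L, 1L), backward = c(1L, 2L))

# summed softmax terms plus the normalization bookkeeping needed by the
# backward pass
tms_branch_raw <- function(params, branch = c("forward", "backward")) {
  branch <- match.arg(branch)
  p <- params[[paste0(branch, "_attention_weights")]]
  axes <- tms_axes[[branch]]
  raw <- Reduce(`+`, lapply(axes, function(a) softmax_axis(p, a)))
  list(p = p, axes = axes, raw = raw)
}

tms_normalize <- function(raw, n_terms, normalization) {
  if (normalization == "row") {
    d <- dim(raw)
    out <- raw
    for (h in seq_len(d[1])) {
      rs <- apply(raw[h, , , drop = FALSE], 2, sum)
      out[h, , ] <- raw[h, , ] / rs
    }
    out
  } else if (normalization == "mean") {
    raw / n_terms
  } else raw
}

#' Forward / backward branch attention weights
#'
#' Returns the per-head `(num_heads, L, L)` attention weight array of one
#' branch after the configured normalization. Under the default `"row"`
#' convention every row of every head sums to 1.
#'
#' @param params A `tms_params`.
#' @param seq_len Optional check: error if the parameters were shaped for a
#'   different sequence length.
#' @return `(num_heads, L, L)` array of attention weights.
#' @export
tms_forward_weights <- function(params, seq_len = NULL) {
  if (!is.null(seq_len) && seq_len != params$seq_len) {
    stop("sequence length ", seq_len, " does not match TMS parameters (L = ",
         params$seq_len, ")")
  }
  b <- tms_branch_raw(params, "forward")
  tms_normalize(b$raw, length(b$axes), params$normalization)
}

#' @rdname tms_forward_weights
#' @export
tms_backward_weights <- function(params, seq_len = NULL) {
  if (!is.null(seq_len) && seq_len != params$seq_len) {
    stop("sequence length ", seq_len, " does not match TMS parameters (L = ",
         params$seq_len, ")")
  }
  b <- tms_branch_raw(params, "backward")
  tms_normalize(b$raw, length(b$axes), params$normalization)
}

#' Apply attention weights to a feature sequence
#'
#' Per head, the `(L, L)` weight matrix left-multiplies the `(L, d)`
#' feature matrix; heads are then averaged back to `(L, d)`.
#'
#' @param weights `(num_heads, L, L)` array or a single `(L, L)` matrix.
#' @param x `(L, d)` feature matrix.
#' @return `(L, d)` attended features.
#' @export
tms_attend <- function(weights, x) {
  x <- as.matrix(x)
  if (is.matrix(weights)) weights <- array(weights, c(1L, dim(weights)))
  d <- dim(weights)
  if (d[2] != d[3] || d[2] != nrow(x)) {
    stop("attention weights (", d[2], "x", d[3],
         ") incompatible with features of length ", nrow(x))
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (h in seq_len(d[1])) out <- out + weights[h, , ] %*% x
  out / d[1]
}

#' Mix forward- and backward-attended features
#'
#' Elementwise `0.6 * forward + 0.4 * backward` with the fixed default
#' coefficients.
#'
#' @param forward_attended,backward_attended Arrays of identical shape.
#' @param mix_forward,mix_backward Mixing coefficients.
#' @return Array of the same shape.
#' @export
tms_mix <- function(forward_attended, backward_attended,
                    mix_forward = 0.6, mix_backward = 0.4) {
  stopifnot(all(dim(as.matrix(forward_attended)) ==
                  dim(as.matrix(backward_attended))))
  mix_forward * forward_attended + mix_backward * backward_attended
}

#' Effective linear operators of a TMS layer
#'
#' Because the attention weights do not depend on the input, each branch is
#' a fixed `(L, L)` linear operator (heads averaged) and the whole layer is
#' `mixed = 0.6 * forward + 0.4 * backward`. Precomputing it makes batch
#' application a single matrix product.
#'
#' @param params A `tms_params`.
#' @return List of `(L, L)` matrices `forward`, `backward`, `mixed`.
#' @export
tms_operator <- function(params) {
  head_avg <- function(w) {
    m <- matrix(0, dim(w)[2], dim(w)[3])
    for (h in seq_len(dim(w)[1])) m <- m + w[h, , ]
    m / dim(w)[1]
  }
  fw <- head_avg(tms_forward_weights(params))
  bw <- head_avg(tms_backward_weights(params))
  list(forward = fw, backward = bw,
       mixed = params$mix_forward * fw + params$mix_backward * bw)
}

#' TMS-enhance a feature sequence
#'
#' Composition: branch weights, attend each branch, mix 0.6/0.4. Output
#' shape equals input shape; under `"row"` normalization every output
#' coordinate is a convex combination of that coordinate across the input
#' sequence.
#'
#' @param params A `tms_params`.
#' @param x `(L, d)` feature matrix with `L == params$seq_len`.
#' @return `(L, d)` enhanced features.
#' @export
tms_forward <- function(params, x) {
  x <- as.matrix(x)
  if (nrow(x) != params$seq_len) {
    stop("sequence length ", nrow(x), " does not match TMS parameters (L = ",
         params$seq_len, ")")
  }
  fwd <- tms_attend(tms_forward_weights(params), x)
  bwd <- tms_attend(tms_backward_weights(params), x)
  tms_mix(fwd, bwd, params$mix_forward, params$mix_backward)
}

# backprop through one branch: given dL/d(branch operator contribution)
# as the (L, L) gradient of the head-averaged normalized weights, return
# the gradient of the branch's logit parameters
tms_branch_grad <- function(params, branch, g_headavg) {
  b <- tms_branch_raw(params, branch)
  d <- dim(b$raw)
  # gradient w.r.t. the per-head normalized weights (head average)
  g_norm <- array(0, d)
  for (h in seq_len(d[1])) g_norm[h, , ] <- g_headavg / d[1]
  # through the normalization to the raw summed terms
  g_raw <- array(0, d)
  if (params$normalization == "row") {
    for (h in seq_len(d[1])) {
      raw_h <- b$raw[h, , ]
      rs <- rowSums(raw_h)
      a_h <- raw_h / rs
      gh <- g_norm[h, , ]
      g_raw[h, , ] <- (gh - rowSums(gh * a_h)) / rs
    }
  } else if (params$normalization == "mean") {
    g_raw <- g_norm / length(b$axes)
  } else {
    g_raw <- g_norm
  }
  # through each softmax term back to the logits
  Reduce(`+`, lapply(b$axes, function(a) softmax_axis_grad(b$p, g_raw, a)))
}

#' Analytic gradients of a TMS layer
#'
#' Given the upstream gradient `g = dL/d(output)` for one `(L, d)` input,
#' returns gradients with respect to the input features and both logit
#' parameter arrays. Used by the training loop and verified against finite
#' differences in the test suite.
#'
#' @param params A `tms_params`.
#' @param x `(L, d)` input features.
#' @param g `(L, d)` upstream gradient.
#' @return List with `dx` `(L, d)`, `d_forward` and `d_backward`
#'   `(num_heads, L, L)` arrays.
#' @export
tms_backward <- function(params, x, g) {
  x <- as.matrix(x); g <- as.matrix(g)
  op <- tms_operator(params)
  dx <- t(op$mixed) %*% g
  g_op <- g %*% t(x)  # dL/d(mixed operator)
  list(dx = dx,
       d_forward = tms_branch_grad(params, "forward",
                                   params$mix_forward * g_op),
       d_backward = tms_branch_grad(params, "backward",
                                    params$mix_backward * g_op))
}
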