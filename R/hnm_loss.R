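#' Loss configuration for the combined FNE-HNM triplet objective
#'
#' @param margin Triplet ranking margin (default 0.2).
#' @param alpha Mixing weight between the hard-negative-mining loss and the
#'   false-negative-elimination loss in the total objective
#'   `alpha * L_HNM + (1 - alpha) * L_FNE`. The combination weight is not
#'   pinned down by the method description, so the symmetric default 0.5 is
#'   used.
#' @param hnm_variant Either `"as_printed"` — the six-step workflow whose
#'   final loss is `sum(cost_s) + sum(cost_im) - sum(hard_neg_s) -
#'   sum(hard_neg_im)` — or `"conventional"` — the standard
#'   hardest-negative objective `sum(hard_neg_s) + sum(hard_neg_im)`.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(margin = 0.2, alpha = 0.5,
                        hnm_variant = c("as_printed", "conventional")) {
  stopifnot(margin > 0, alpha >= 0, alpha <= 1)
  structure(list(margin = margin, alpha = alpha,
                 hnm_variant = match.arg(hnm_variant)),
            class = "loss_config")
}

#' Basic symmetric triplet loss for one anchor pair
#'
#' `[margin - s_pos + s_neg_text]+ + [margin - s_pos + s_neg_img]+`: one
#' hinge per retrieval direction, each clamped at zero. `s_pos` is the
#' matched image-text similarity, `s_neg_text` the similarity of the image
#' anchor to its negative caption, `s_neg_img` the similarity of the
#' negative image to the caption anchor.
#'
#' @param s_pos,s_neg_text,s_neg_img Similarity scores (vectorized).
#' @param margin Ranking margin.
#' @return Non-negative loss value(s).
#' @export
basic_triplet_loss <- function(s_pos, s_neg_text, s_neg_img, margin = 0.2) {
  pmax(margin - s_pos + s_neg_text, 0) + pmax(margin - s_pos + s_neg_img, 0)
}

#' Batch similarity score matrix
#'
#' Entry (i, j) is the dot product of image embedding i with text embedding
#' j; with unit-normalized embeddings this is their cosine similarity and
#' the matched pairs sit on the diagonal.
#'
#' @param im `(B, d)` matrix of image embeddings.
#' @param s `(B, d)` matrix of text embeddings.
#' @return `(B, B)` score matrix of class `score_matrix`.
#' @export
score_matrix <- function(im, s) {
  stopifnot(is.matrix(im), is.matrix(s), ncol(im) == ncol(s),
            nrow(im) == nrow(s))
  structure(im %*% t(s), class = c("score_matrix", "matrix"))
}

#' Directional hinge cost matrices
#'
#' `cost_s = clamp(margin + scores - d1, 0)` with `d1` the row-wise
#' expansion of the diagonal (caption retrieval), and `cost_im` the
#' analogous column-wise expansion (image retrieval). Diagonals are zeroed:
#' a pair is never its own negative.
#'
#' @param m A square score matrix.
#' @param margin Ranking margin.
#' @return List with matrices `cost_s` and `cost_im`.
#' @export
directional_costs <- function(m, margin = 0.2) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("score matrix must be square")
  d <- diag(m)
  cost_s <- pmax(margin + m - d, 0)                 # d1: diagonal down rows
  cost_im <- pmax(margin + sweep(m, 2, d), 0)       # d2: diagonal across cols
  diag(cost_s) <- 0
  diag(cost_im) <- 0
  list(cost_s = cost_s, cost_im = cost_im)
}

#' Hardest negatives per query
#'
#' Row maxima of the masked caption-retrieval cost matrix and column maxima
#' of the masked image-retrieval cost matrix, with argmax indices. Ties are
#' broken by the lowest index so selection is deterministic.
#'
#' @param m A square score matrix.
#' @param margin Ranking margin.
#' @return List with `hard_neg_s`, `hard_neg_im` (cost values) and
#'   `idx_s`, `idx_im` (column/row index of the selected negative).
#' @export
hardest_negatives <- function(m, margin = 0.2) {
  costs <- directional_costs(m, margin)
  idx_s <- apply(costs$cost_s, 1, which.max)
  idx_im <- apply(costs$cost_im, 2, which.max)
  list(hard_neg_s = costs$cost_s[cbind(seq_along(idx_s), idx_s)],
       hard_neg_im = costs$cost_im[cbind(idx_im, seq_along(idx_im))],
       idx_s = as.integer(idx_s), idx_im = as.integer(idx_im))
}

#' Hard-negative-mining triplet loss over a batch score matrix
#'
#' The `as_printed` variant follows the six-step workflow literally:
#' `sum(cost_s) + sum(cost_im) - sum(hard_neg_s) - sum(hard_neg_im)`. Since
#' each row/column sum dominates its own maximum, this is always
#' non-negative, but it removes rather than keeps the hardest terms, which
#' contradicts the stated purpose of mining the most challenging negatives;
#' the `conventional` variant therefore computes the standard VSE++-style
#' objective `sum(hard_neg_s) + sum(hard_neg_im)`.
#'
#' @param m A square score matrix.
#' @param config A `loss_config`.
#' @return Scalar loss.
#' @export
hnm_triplet_loss <- function(m, config = loss_config()) {
  costs <- directional_costs(m, config$margin)
  hard <- hardest_negatives(m, config$margin)
  if (config$hnm_variant == "as_printed") {
    sum(costs$cost_s) + sum(costs$cost_im) -
      sum(hard$hard_neg_s) - sum(hard$hard_neg_im)
  } else {
    sum(hard$hard_neg_s) + sum(hard$hard_neg_im)
  }
}

#' Combined FNE-HNM triplet objective
#'
#' Both component losses are the symmetric two-hinge triplet loss evaluated
#' with their respective negative similarities: the HNM loss with the
#' batch-hardest negatives and the FNE loss with posterior-weighted sampled
#' negatives. The total is `alpha * L_HNM + (1 - alpha) * L_FNE`.
#'
#' @param s_pos Vector of matched-pair similarities (one per anchor pair).
#' @param s_hnm_text,s_hnm_img Similarities to the HNM-selected negative
#'   caption / image per anchor.
#' @param s_fne_text,s_fne_img Similarities to the FNE-sampled negative
#'   caption / image per anchor.
#' @param config A `loss_config`.
#' @return List with `total`, `hnm` and `fne` mean losses over the batch.
#' @export
combined_loss <- function(s_pos, s_hnm_text, s_hnm_img,
                          s_fne_text, s_fne_img, config = loss_config()) {
  l_hnm <- mean(basic_triplet_loss(s_pos, s_hnm_text, s_hnm_img,
                                   config$margin))
  l_fne <- mean(basic_triplet_loss(s_pos, s_fne_text, s_fne_img,
                                   config$margin))
  list(total = config$alpha * l_hnm + (1 - config$alpha) * l_fne,
       hnm = l_hnm, fne = l_fne)
}
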