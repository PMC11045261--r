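#' Rank a gallery against a query by cosine similarity
#'
#' Descending similarity order; exact ties are broken by the lowest gallery
#' index so rankings are deterministic.
#'
#' @param query Embedding vector.
#' @param gallery `(G, d)` matrix of gallery embeddings.
#' @return Integer vector of gallery indices, best match first.
#' @export
rank_gallery <- function(query, gallery) {
  gallery <- as.matrix(gallery)
  q <- unit_normalize(as.numeric(query))
  sims <- as.numeric(unit_normalize(gallery) %*% q)
  order(-sims, seq_along(sims))
}

#' Recall at K
#'
#' Fraction of queries whose ground-truth counterpart appears within the
#' top `k` ranked gallery items: `R@K = TP / (TP + FN)` where TP counts
#' queries hit within the top K and FN those missed.
#'
#' @param gt_ranks Integer vector: rank of the ground-truth item for each
#'   query (1 = best).
#' @param k Cutoff.
#' @return Value in `[0, 1]`.
#' @export
recall_at_k <- function(gt_ranks, k) {
  stopifnot(length(gt_ranks) >= 1, all(gt_ranks >= 1))
  mean(gt_ranks <= k)
}

#' Bidirectional retrieval evaluation
#'
#' Ranks the text gallery for every image query (image-to-text) and the
#' image gallery for every text query (text-to-image) and summarizes both
#' directions with Recall at K. Ground truth is one-to-one: image i matches
#' text i.
#'
#' @param image_embs,text_embs `(G, d)` matrices of paired embeddings.
#' @param ks Recall cutoffs (default 1, 5, 10).
#' @return Object of class `retrieval_result`: a list with per-direction
#'   ground-truth ranks and a `recall` table, e.g.
#'   `result$recall$image_to_text[["R@1"]]`.
#' @export
evaluate_bidirectional <- function(image_embs, text_embs, ks = c(1, 5, 10)) {
  image_embs <- unit_normalize(as.matrix(image_embs))
  text_embs <- unit_normalize(as.matrix(text_embs))
  stopifnot(nrow(image_embs) == nrow(text_embs))
  g <- nrow(image_embs)
  ks <- ks[ks <= g]
  scores <- image_embs %*% t(text_embs)
  rank_of_gt <- function(s) {
    # rank of the matched column within each row, ties to lowest index
    vapply(seq_len(nrow(s)), function(i) {
      ord <- order(-s[i, ], seq_len(ncol(s)))
      which(ord == i)
    }, integer(1))
  }
  i2t <- rank_of_gt(scores)
  t2i <- rank_of_gt(t(scores))
  recall_tab <- function(r) {
    out <- lapply(ks, function(k) recall_at_k(r, k))
    names(out) <- paste0("R@", ks)
    out
  }
  structure(list(
    i2t_ranks = i2t, t2i_ranks = t2i, ks = ks,
    recall = list(image_to_text = recall_tab(i2t),
                  text_to_image = recall_tab(t2i))
  ), class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat("Bidirectional retrieval over a gallery of", length(x$i2t_ranks),
      "pairs\n")
  for (d in names(x$recall)) {
    v <- unlist(x$recall[[d]])
    cat(sprintf("  %-13s %s\n", d,
                paste(sprintf("%s=%.3f", names(v), v), collapse = "  ")))
  }
  invisible(x)
}

#' Write retrieval results as JSON
#'
#' @param result A `retrieval_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_retrieval_json <- function(result, path) {
  jsonlite::write_json(result$recall, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
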