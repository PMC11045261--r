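#' Construct an encoder pair configuration
#'
#' Two interchangeable backends produce fine-grained feature sequences in a
#' shared d-dimensional space:
#'
#' * `"tiny"` — deterministic desk-scale encoders. The image side splits
#'   the image into square patches and summarizes each patch with simple
#'   pixel statistics placed in patch-specific coordinate blocks; the text
#'   side tokenizes on whitespace and hashes tokens into a fixed
#'   vocabulary. Each side then applies a trainable affine projection into
#'   the shared space, initialized as a seeded random linear map, so the
#'   whole pipeline is a pure function of (input, seed).
#' * `"pretrained"` — the slot for large pretrained vision/text transformer
#'   backbones with a pass-through projection head. Such weights are not
#'   bundled; calling this backend raises an explicit error suggesting the
#'   tiny backend.
#'
#' @param backend `"tiny"` or `"pretrained"`.
#' @param dim Shared-space dimension d (default 256).
#' @param image_side Expected square image side length in pixels.
#' @param patch Patch side length; `image_side` must be a multiple.
#' @param vocab_size Hashed token vocabulary size of the tiny text backend.
#' @param text_len Fixed token capacity used when padding is requested by
#'   the trainer; plain encoding keeps the natural token count.
#' @param normalize_embeddings Unit-normalize pooled embeddings (default
#'   `TRUE`), so dot products equal cosine similarities.
#' @param seed Seed of the random projection initialization.
#' @return Object of class `encoder_pair` with trainable parameter arrays
#'   `w_img`, `b_img`, `w_txt`, `b_txt`.
#' @export
encoder_pair <- function(backend = c("tiny", "pretrained"), dim = 256L,
                         image_side = 32L, patch = 8L, vocab_size = 64L,
                         text_len = 8L, normalize_embeddings = TRUE,
                         seed = 1L) {
  backend <- match.arg(backend)
  if (backend == "pretrained") {
    stop("pretrained transformer backbones are not bundled with this ",
         "package; use backend = \"tiny\" for desk-scale runs",
         call. = FALSE)
  }
  if (image_side %% patch != 0) stop("`image_side` must be a multiple of `patch`")
  n_patches <- (image_side %/% patch)^2
  f_img <- 6L * n_patches  # per-patch mean+sd RGB in patch-specific blocks
  f_txt <- as.integer(vocab_size)
  init <- function(tag, nr, nc) {
    with_seed(derive_seed(seed, tag),
              matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc))
  }
  structure(list(
    backend = backend, dim = as.integer(dim),
    image_side = as.integer(image_side), patch = as.integer(patch),
    n_patches = as.integer(n_patches),
    vocab_size = as.integer(vocab_size), text_len = as.integer(text_len),
    normalize_embeddings = isTRUE(normalize_embeddings), seed = as.integer(seed),
    w_img = init("w_img", f_img, dim), b_img = numeric(dim),
    w_txt = init("w_txt", f_txt, dim), b_txt = numeric(dim)
  ), class = "encoder_pair")
}

#' Raw patch statistics of an image
#'
#' Splits a square RGB image into non-overlapping patches (row-major) and
#' summarizes patch p with its per-channel mean and standard deviation,
#' stored in the p-th 6-wide coordinate block of an otherwise-zero feature
#' vector. Keeping patches in distinct blocks preserves spatial layout
#' under mean pooling, so a linear readout can still see where lesions sit.
#'
#' @param img `(side, side, 3)` numeric array in `[0, 1]`.
#' @param enc An `encoder_pair`.
#' @return `(n_patches, 6 * n_patches)` raw feature matrix.
#' @export
image_patch_features <- function(img, enc) {
  side <- enc$image_side
  if (length(dim(img)) != 3L || dim(img)[1] != side || dim(img)[2] != side) {
    stop("image must be a (", side, ", ", side, ", 3) array for this backend")
  }
  g <- side %/% enc$patch
  m <- g * g
  out <- matrix(0, m, 6L * m)
  p <- 0L
  for (r in seq_len(g)) for (cc in seq_len(g)) {
    p <- p + 1L
    rows <- ((r - 1L) * enc$patch + 1L):(r * enc$patch)
    cols <- ((cc - 1L) * enc$patch + 1L):(cc * enc$patch)
    block <- img[rows, cols, , drop = FALSE]
    stats6 <- c(apply(block, 3, mean), apply(block, 3, stats::sd))
    out[p, ((p - 1L) * 6L + 1L):(p * 6L)] <- stats6
  }
  out
}

#' Hash whitespace tokens into the tiny vocabulary
#'
#' Deterministic string hash mapped into `1..vocab_size`.
#'
#' @param caption Non-empty caption string.
#' @param vocab_size Vocabulary size.
#' @return Integer vector of token ids.
#' @export
hash_tokens <- function(caption, vocab_size = 64L) {
  if (!is.character(caption) || length(caption) != 1L || !nzchar(trimws(caption))) {
    stop("caption must be a single non-empty string")
  }
  toks <- strsplit(trimws(tolower(caption)), "\\s+")[[1]]
  vapply(toks, function(tk) {
    h <- 0
    for (ch in utf8ToInt(tk)) h <- (h * 31 + ch) %% 1048573
    as.integer(h %% vocab_size) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

token_onehots <- function(ids, vocab_size) {
  out <- matrix(0, length(ids), vocab_size)
  out[cbind(seq_along(ids), ids)] <- 1
  out
}

#' Encode an image into a shared-space feature sequence
#'
#' Patch statistics are projected into the shared space by the trainable
#' affine map of the encoder pair, yielding one d-vector per patch.
#'
#' @param img `(side, side, 3)` numeric array.
#' @param enc An `encoder_pair`.
#' @return `feature_sequence` object: list with `features` (an
#'   `(m, d)` matrix), `modality`, and the raw pre-projection features.
#' @export
encode_image <- function(img, enc) {
  raw <- image_patch_features(img, enc)
  structure(list(features = raw %*% enc$w_img +
                   matrix(enc$b_img, nrow(raw), enc$dim, byrow = TRUE),
                 raw = raw, modality = "image"),
            class = "feature_sequence")
}

#' Encode a caption into a shared-space feature sequence
#'
#' Tokens are hashed to one-hot vocabulary rows and projected with the
#' trainable text map; one d-vector per token. With `pad_to`, sequences are
#' right-padded with all-zero raw rows (or truncated) to a fixed length so
#' a single TMS parameter set can serve the whole batch.
#'
#' @param caption Non-empty caption string.
#' @param enc An `encoder_pair`.
#' @param pad_to Optional fixed sequence length.
#' @return `feature_sequence` object with an `(l, d)` feature matrix.
#' @export
encode_text <- function(caption, enc, pad_to = NULL) {
  ids <- hash_tokens(caption, enc$vocab_size)
  raw <- token_onehots(ids, enc$vocab_size)
  if (!is.null(pad_to)) {
    if (nrow(raw) > pad_to) raw <- raw[seq_len(pad_to), , drop = FALSE]
    if (nrow(raw) < pad_to) {
      raw <- rbind(raw, matrix(0, pad_to - nrow(raw), enc$vocab_size))
    }
  }
  structure(list(features = raw %*% enc$w_txt +
                   matrix(enc$b_txt, nrow(raw), enc$dim, byrow = TRUE),
                 raw = raw, modality = "text"),
            class = "feature_sequence")
}

#' Pool a feature sequence into a global embedding
#'
#' Arithmetic mean over the sequence axis — `v = (1/m) sum_i v_i` for
#' patches, `w = (1/l) sum_j w_j` for words — followed by optional unit
#' normalization.
#'
#' @param sequence A `feature_sequence` or plain `(L, d)` matrix.
#' @param normalize Unit-normalize the pooled vector (default `TRUE`).
#' @return Length-d embedding vector.
#' @export
pool_sequence <- function(sequence, normalize = TRUE) {
  x <- if (inherits(sequence, "feature_sequence")) sequence$features
       else as.matrix(sequence)
  if (nrow(x) < 1L) stop("cannot pool an empty sequence")
  v <- colMeans(x)
  if (normalize) unit_normalize(v) else v
}
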