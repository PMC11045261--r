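#' Momentum memory bank of negative embeddings
#'
#' Fixed-capacity FIFO queues of unit-normalized image and text embeddings
#' produced by the momentum encoders. The bank enlarges the negative pool
#' far beyond the batch, which is what makes retrieval performance robust
#' to small batch sizes. Entries carry no gradients — the bank has pure
#' buffer semantics.
#'
#' @param capacity Maximum entries per modality queue (default 8,192).
#' @param dim Embedding dimension.
#' @param momentum Momentum-encoder coefficient in (0, 1); the momentum
#'   parameters track the online parameters as
#'   `momentum * old + (1 - momentum) * online`. Default 0.995, standard
#'   momentum-encoder practice.
#' @return Object of class `memory_bank`.
#' @export
memory_bank <- function(capacity = 8192L, dim, momentum = 0.995) {
  stopifnot(capacity >= 1, dim >= 1, momentum > 0, momentum < 1)
  structure(list(capacity = as.integer(capacity), dim = as.integer(dim),
                 momentum = momentum,
                 image_queue = matrix(numeric(0), 0, dim),
                 text_queue = matrix(numeric(0), 0, dim)),
            class = "memory_bank")
}

#' Enqueue a batch of embeddings, evicting the oldest beyond capacity
#'
#' @param bank A `memory_bank`.
#' @param batch `(n, d)` matrix of embeddings (rows are unit-normalized on
#'   entry).
#' @param modality `"image"` or `"text"`.
#' @return Updated `memory_bank`.
#' @export
bank_enqueue <- function(bank, batch, modality = c("image", "text")) {
  modality <- match.arg(modality)
  if (is.null(batch) || NROW(batch) == 0L) return(bank)
  batch <- unit_normalize(as.matrix(batch))
  stopifnot(ncol(batch) == bank$dim)
  key <- paste0(modality, "_queue")
  q <- rbind(bank[[key]], batch)
  if (nrow(q) > bank$capacity) {
    q <- q[(nrow(q) - bank$capacity + 1L):nrow(q), , drop = FALSE]
  }
  bank[[key]] <- q
  bank
}

#' Current queue contents / length
#'
#' @param bank A `memory_bank`.
#' @param modality `"image"` or `"text"`.
#' @return `bank_entries`: the `(n, d)` queue matrix, oldest entry first.
#' @export
bank_entries <- function(bank, modality = c("image", "text")) {
  modality <- match.arg(modality)
  bank[[paste0(modality, "_queue")]]
}

#' @rdname bank_entries
#' @export
bank_size <- function(bank, modality = c("image", "text")) {
  nrow(bank_entries(bank, modality))
}

#' Momentum update of encoder parameters
#'
#' Each momentum parameter moves towards its online counterpart:
#' `momentum * old + (1 - momentum) * online`. Works on numeric arrays and
#' (recursively) on lists of arrays with matching structure.
#'
#' @param online_params Online (trained) parameters.
#' @param momentum_params Slowly-updated momentum copies.
#' @param momentum Coefficient in `[0, 1]`; 1 freezes the momentum copy,
#'   0 copies the online parameters outright.
#' @return Updated momentum parameters with the same structure.
#' @export
momentum_update <- function(online_params, momentum_params, momentum) {
  stop_if_not_scalar_prob(momentum, "momentum")
  if (is.list(online_params)) {
    stopifnot(is.list(momentum_params),
              length(online_params) == length(momentum_params))
    out <- mapply(momentum_update, online_params, momentum_params,
                  MoreArgs = list(momentum = momentum), SIMPLIFY = FALSE)
    names(out) <- names(momentum_params)
    return(out)
  }
  momentum * momentum_params + (1 - momentum) * online_params
}
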