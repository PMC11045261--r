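#' Experiment configuration
#'
#' Bundles all component configurations for a training/evaluation run. The
#' defaults mirror the full-scale training recipe (batch 32, 110 epochs,
#' memory 8,192, margin 0.2, initial learning rate 4e-5); desk-scale runs
#' on synthetic worlds override the sizes and the learning rate, which at
#' full scale is tuned to transformer fine-tuning, not to tiny linear
#' encoders.
#'
#' @param world A `world_config` for a rendered synthetic dataset, or
#'   `NULL` when `image_dir`/`caption_table` point at a real dataset.
#' @param image_dir,caption_table Real-mode dataset paths.
#' @param data_dir Where to render the synthetic world (default: a
#'   session temporary directory).
#' @param dim Shared embedding dimension.
#' @param image_side,patch Tiny image backend geometry.
#' @param text_len Fixed token capacity captions are padded/truncated to.
#' @param vocab_size Tiny text backend vocabulary size.
#' @param batch_size Pairs per optimizer step.
#' @param epochs Training epochs.
#' @param initial_learning_rate Peak learning rate after warm-up.
#' @param min_learning_rate Decay floor.
#' @param memory_capacity Momentum memory bank capacity per modality.
#' @param momentum Momentum-encoder coefficient.
#' @param loss A `loss_config`.
#' @param sampler A `sampler_config`.
#' @param split_ratios Train/val/test ratios.
#' @param eval_ks Recall cutoffs.
#' @param num_heads TMS attention heads.
#' @param seed Global seed; fans out deterministically to every stochastic
#'   component.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(world = NULL, image_dir = NULL,
                              caption_table = NULL, data_dir = NULL,
                              dim = 256L, image_side = 32L, patch = 8L,
                              text_len = 8L, vocab_size = 64L,
                              batch_size = 32L, epochs = 110L,
                              initial_learning_rate = 4e-5,
                              min_learning_rate = 1e-6,
                              memory_capacity = 8192L, momentum = 0.995,
                              loss = loss_config(),
                              sampler = sampler_config(),
                              split_ratios = c(0.8, 0.1, 0.1),
                              eval_ks = c(1, 5, 10),
                              num_heads = 1L, seed = 1L) {
  if (is.null(world) && (is.null(image_dir) || is.null(caption_table))) {
    stop("provide either a synthetic `world` or `image_dir` + `caption_table`")
  }
  structure(list(world = world, image_dir = image_dir,
                 caption_table = caption_table, data_dir = data_dir,
                 dim = as.integer(dim), image_side = as.integer(image_side),
                 patch = as.integer(patch), text_len = as.integer(text_len),
                 vocab_size = as.integer(vocab_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 min_learning_rate = min_learning_rate,
                 memory_capacity = as.integer(memory_capacity),
                 momentum = momentum, loss = loss, sampler = sampler,
                 split_ratios = split_ratios, eval_ks = eval_ks,
                 num_heads = as.integer(num_heads), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields of the YAML map onto `experiment_config()` arguments;
#' nested `loss`, `sampler` and `world` maps onto their constructors.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$loss)) y$loss <- do.call(loss_config, y$loss)
  if (!is.null(y$sampler)) y$sampler <- do.call(sampler_config, y$sampler)
  if (!is.null(y$world)) y$world <- do.call(world_config, y$world)
  do.call(experiment_config, y)
}

# ---- internal model plumbing -------------------------------------------

new_model <- function(config) {
  enc <- encoder_pair(backend = "tiny", dim = config$dim,
                      image_side = config$image_side, patch = config$patch,
                      vocab_size = config$vocab_size,
                      text_len = config$text_len, seed = config$seed)
  list(enc = enc,
       tms_img = tms_params(enc$n_patches, num_heads = config$num_heads),
       tms_txt = tms_params(config$text_len, num_heads = config$num_heads))
}

model_params <- function(model) {
  list(w_img = model$enc$w_img, b_img = model$enc$b_img,
       w_txt = model$enc$w_txt, b_txt = model$enc$b_txt,
       tms_img_f = model$tms_img$forward_attention_weights,
       tms_img_b = model$tms_img$backward_attention_weights,
       tms_txt_f = model$tms_txt$forward_attention_weights,
       tms_txt_b = model$tms_txt$backward_attention_weights)
}

set_model_params <- function(model, p) {
  model$enc$w_img <- p$w_img; model$enc$b_img <- p$b_img
  model$enc$w_txt <- p$w_txt; model$enc$b_txt <- p$b_txt
  model$tms_img$forward_attention_weights <- p$tms_img_f
  model$tms_img$backward_attention_weights <- p$tms_img_b
  model$tms_txt$forward_attention_weights <- p$tms_txt_f
  model$tms_txt$backward_attention_weights <- p$tms_txt_b
  model
}

# embed raw feature matrices through projection -> TMS -> mean pool -> l2
embed_batch <- function(raw_list, w, b, tms) {
  op <- tms_operator(tms)$mixed
  d <- ncol(w)
  out <- matrix(0, length(raw_list), d)
  cache <- vector("list", length(raw_list))
  for (i in seq_along(raw_list)) {
    x <- raw_list[[i]] %*% w + matrix(b, nrow(raw_list[[i]]), d, byrow = TRUE)
    y <- op %*% x
    e <- colMeans(y)
    nrm <- sqrt(sum(e^2))
    out[i, ] <- e / max(nrm, 1e-12)
    cache[[i]] <- list(x = x, e = e, nrm = max(nrm, 1e-12))
  }
  list(embs = out, cache = cache, op = op)
}

# backpropagate dL/dU (rows = anchors) into projection + TMS gradients
backprop_batch <- function(raw_list, fwd, du, tms) {
  d <- ncol(du)
  dw <- matrix(0, ncol(raw_list[[1]]), d)
  db <- numeric(d)
  g_op <- matrix(0, nrow(fwd$op), ncol(fwd$op))
  l <- nrow(raw_list[[1]])
  for (i in seq_along(raw_list)) {
    cc <- fwd$cache[[i]]
    u <- cc$e / cc$nrm
    g <- du[i, ]
    de <- (g - sum(g * u) * u) / cc$nrm
    dy <- matrix(de, l, d, byrow = TRUE) / l       # pooling: colMeans
    dx <- t(fwd$op) %*% dy
    g_op <- g_op + dy %*% t(cc$x)
    dw <- dw + t(raw_list[[i]]) %*% dx
    db <- db + colSums(dx)
  }
  list(dw = dw, db = db,
       d_tms_f = tms_branch_grad(tms, "forward", tms$mix_forward * g_op),
       d_tms_b = tms_branch_grad(tms, "backward", tms$mix_backward * g_op))
}

# per-coordinate standardization of raw feature sequences, estimated on
# the training split; removes the shared baseline (leaf-color background,
# constant template tokens) that would otherwise make all embeddings of a
# class nearly parallel
feature_standardizer <- function(raw_list, train_idx) {
  arr <- simplify2array(raw_list[train_idx])      # (L, f, n_train)
  center <- apply(arr, c(1, 2), mean)
  scale <- pmax(apply(arr, c(1, 2), stats::sd), 1e-3)
  list(center = center, scale = scale)
}

apply_standardizer <- function(raw_list, std) {
  lapply(raw_list, function(r) (r - std$center) / std$scale)
}

prepare_dataset <- function(config) {
  if (!is.null(config$world)) {
    dir <- config$data_dir %||% file.path(tempdir(),
                                          paste0("cmrice_world_",
                                                 config$world$seed))
    rendered <- render_image_caption_world(config$world, dir)
    side <- config$world$image_side
    pairs <- load_pairs(dir, rendered$caption_table, side = side)
  } else {
    pairs <- load_pairs(config$image_dir, config$caption_table,
                        side = config$image_side)
  }
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

precompute_raw <- function(pairs, enc, text_len) {
  list(
    img = lapply(pairs, function(p) image_patch_features(p$image, enc)),
    txt = lapply(pairs, function(p) {
      ids <- hash_tokens(p$caption, enc$vocab_size)
      raw <- token_onehots(ids, enc$vocab_size)
      if (nrow(raw) > text_len) raw <- raw[seq_len(text_len), , drop = FALSE]
      if (nrow(raw) < text_len) {
        raw <- rbind(raw, matrix(0, text_len - nrow(raw), enc$vocab_size))
      }
      raw
    })
  )
}

#' Train the retrieval model
#'
#' Runs the full training loop at desk scale: per optimizer step the batch
#' is encoded (projection, TMS enhancement, mean pooling, unit
#' normalization), similarity statistics are updated, hard negatives are
#' mined batch-locally and false-negative-aware negatives are sampled from
#' the momentum memory bank, the combined triplet objective is formed, and
#' all trainable parameters take a plain SGD step at the WBA-scheduled
#' learning rate. Momentum copies of the encoders are updated each step
#' and their batch embeddings enqueued into the bank. Validation recall is
#' computed each epoch; the best-validation parameters are retained.
#'
#' @param config An `experiment_config`.
#' @param checkpoint Optional path; when given, the best model is saved
#'   there with `saveRDS`.
#' @param verbose Print per-epoch validation recall.
#' @return Object of class `retrieval_fit`: list with the best `model`,
#'   the final `model_last`, per-step `logs` (loss terms and learning
#'   rate), `val_history`, the `split`, cached raw features, and the
#'   `config`.
#' @export
train_retrieval <- function(config, checkpoint = NULL, verbose = FALSE) {
  pairs <- prepare_dataset(config)
  ids <- vapply(pairs, `[[`, character(1), "image_id")
  split <- make_split(ids, config$split_ratios,
                      seed = derive_seed(config$seed, "split"))
  model <- new_model(config)
  raw <- precompute_raw(pairs, model$enc, config$text_len)
  names(raw$img) <- ids; names(raw$txt) <- ids
  train_idx <- match(split$train_ids, ids)
  std_img <- feature_standardizer(raw$img, train_idx)
  std_txt <- feature_standardizer(raw$txt, train_idx)
  raw$img <- apply_standardizer(raw$img, std_img)
  raw$txt <- apply_standardizer(raw$txt, std_txt)
  model$standardizers <- list(img = std_img, txt = std_txt)

  n_train <- length(split$train_ids)
  batch <- min(config$batch_size, n_train)
  steps_per_epoch <- max(1L, n_train %/% batch)
  max_iter <- config$epochs * steps_per_epoch
  sched <- scheduler_state(max_iter,
                           initial_learning_rate = config$initial_learning_rate,
                           min_learning_rate = config$min_learning_rate)
  bank <- memory_bank(config$memory_capacity, config$dim, config$momentum)
  mom_model <- model
  stats <- similarity_stats()
  margin <- config$loss$margin
  alpha <- config$loss$alpha

  logs <- list()
  val_history <- list()
  best <- list(score = -Inf, params = model_params(model))
  step_id <- 0L

  for (epoch in seq_len(config$epochs)) {
    stats <- similarity_stats()  # epoch-window running statistics
    order_ids <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)),
                           sample(split$train_ids))
    for (stp in seq_len(steps_per_epoch)) {
      step_id <- step_id + 1L
      take <- order_ids[((stp - 1L) * batch + 1L):(stp * batch)]
      img_raw <- raw$img[take]
      txt_raw <- raw$txt[take]

      fwd_i <- embed_batch(img_raw, model$enc$w_img, model$enc$b_img,
                           model$tms_img)
      fwd_t <- embed_batch(txt_raw, model$enc$w_txt, model$enc$b_txt,
                           model$tms_txt)
      u <- fwd_i$embs; tt <- fwd_t$embs
      s <- u %*% t(tt)
      stats <- update_stats(stats, s)

      # momentum embeddings feed the bank before sampling, so the pool is
      # always the bank itself (batch included via its momentum copies)
      mom_i <- embed_batch(img_raw, mom_model$enc$w_img, mom_model$enc$b_img,
                           mom_model$tms_img)$embs
      mom_t <- embed_batch(txt_raw, mom_model$enc$w_txt, mom_model$enc$b_txt,
                           mom_model$tms_txt)$embs
      bank <- bank_enqueue(bank, mom_i, "image")
      bank <- bank_enqueue(bank, mom_t, "text")

      hard <- hardest_negatives(s, margin)
      s_pos <- diag(s)
      s_hnm_text <- s[cbind(seq_len(batch), hard$idx_s)]
      s_hnm_img <- s[cbind(hard$idx_im, seq_len(batch))]

      fne <- sample_fne_negatives(u, tt, s_pos, bank, stats, config$sampler,
                                  seed = derive_seed(config$seed,
                                                     paste0("fne", step_id)))

      losses <- combined_loss(s_pos, s_hnm_text, s_hnm_img,
                              fne$s_text, fne$s_img, config$loss)
      stp_lr <- wba_step(sched)
      sched <- stp_lr$state
      lr <- stp_lr$lr
      if (!is.finite(losses$total)) {
        stop("non-finite loss at step ", step_id,
             "; batch score range [", min(s), ", ", max(s), "], lr ", lr)
      }

      # hinge subgradients w.r.t. the online embeddings
      du <- matrix(0, batch, config$dim)
      dt <- matrix(0, batch, config$dim)
      for (i in seq_len(batch)) {
        wgt <- 1 / batch
        if (margin - s_pos[i] + s_hnm_text[i] > 0) {       # HNM, text negative
          j <- hard$idx_s[i]
          du[i, ] <- du[i, ] + alpha * wgt * (tt[j, ] - tt[i, ])
          dt[i, ] <- dt[i, ] - alpha * wgt * u[i, ]
          dt[j, ] <- dt[j, ] + alpha * wgt * u[i, ]
        }
        if (margin - s_pos[i] + s_hnm_img[i] > 0) {        # HNM, image negative
          j <- hard$idx_im[i]
          dt[i, ] <- dt[i, ] + alpha * wgt * (u[j, ] - u[i, ])
          du[i, ] <- du[i, ] - alpha * wgt * tt[i, ]
          du[j, ] <- du[j, ] + alpha * wgt * tt[i, ]
        }
        if (margin - s_pos[i] + fne$s_text[i] > 0) {       # FNE, bank text
          du[i, ] <- du[i, ] + (1 - alpha) * wgt *
            (fne$neg_text[i, ] - tt[i, ])
          dt[i, ] <- dt[i, ] - (1 - alpha) * wgt * u[i, ]
        }
        if (margin - s_pos[i] + fne$s_img[i] > 0) {        # FNE, bank image
          dt[i, ] <- dt[i, ] + (1 - alpha) * wgt *
            (fne$neg_img[i, ] - u[i, ])
          du[i, ] <- du[i, ] - (1 - alpha) * wgt * tt[i, ]
        }
      }

      gi <- backprop_batch(img_raw, fwd_i, du, model$tms_img)
      gt <- backprop_batch(txt_raw, fwd_t, dt, model$tms_txt)

      model$enc$w_img <- model$enc$w_img - lr * gi$dw
      model$enc$b_img <- model$enc$b_img - lr * gi$db
      model$enc$w_txt <- model$enc$w_txt - lr * gt$dw
      model$enc$b_txt <- model$enc$b_txt - lr * gt$db
      model$tms_img$forward_attention_weights <-
        model$tms_img$forward_attention_weights - lr * gi$d_tms_f
      model$tms_img$backward_attention_weights <-
        model$tms_img$backward_attention_weights - lr * gi$d_tms_b
      model$tms_txt$forward_attention_weights <-
        model$tms_txt$forward_attention_weights - lr * gt$d_tms_f
      model$tms_txt$backward_attention_weights <-
        model$tms_txt$backward_attention_weights - lr * gt$d_tms_b

      mom_model <- set_model_params(
        mom_model, momentum_update(model_params(model),
                                   model_params(mom_model), config$momentum))

      logs[[step_id]] <- data.frame(step = step_id, epoch = epoch,
                                    loss_hnm = losses$hnm,
                                    loss_fne = losses$fne,
                                    loss_total = losses$total, lr = lr)
    }

    val <- evaluate_split(model, raw, split$val_ids, config$eval_ks)
    score <- val$recall$image_to_text[["R@1"]] +
      val$recall$text_to_image[["R@1"]]
    val_history[[epoch]] <- data.frame(
      epoch = epoch,
      i2t_r1 = val$recall$image_to_text[["R@1"]],
      t2i_r1 = val$recall$text_to_image[["R@1"]])
    if (score >= best$score) {
      best <- list(score = score, params = model_params(model))
    }
    if (verbose) {
      message(sprintf("epoch %3d  val R@1 i2t=%.3f t2i=%.3f", epoch,
                      val$recall$image_to_text[["R@1"]],
                      val$recall$text_to_image[["R@1"]]))
    }
  }

  fit <- structure(list(
    model = set_model_params(model, best$params),
    model_last = model,
    logs = do.call(rbind, logs),
    val_history = do.call(rbind, val_history),
    split = split, raw = raw, config = config
  ), class = "retrieval_fit")
  if (!is.null(checkpoint)) saveRDS(fit, checkpoint)
  fit
}

# FNE negative sampling from the bank for every anchor (k = 1 each)
sample_fne_negatives <- function(u, tt, s_pos, bank, stats, sampler, seed) {
  b <- nrow(u)
  bt <- bank_entries(bank, "text")
  bi <- bank_entries(bank, "image")
  sims_t <- u %*% t(bt)   # image anchor vs candidate texts
  sims_i <- tt %*% t(bi)  # text anchor vs candidate images
  ready <- stats_ready(stats, sampler)
  pick <- function(sims_row, s_pos_i, n_cand, seed_i) {
    if (ready) {
      post <- false_negative_posterior(sims_row, stats, sampler)
      w <- sampling_weight(sims_row, s_pos_i, post, sampler)
    } else {
      w <- rep(1, n_cand)  # cold start: uniform, pure HNM-style pool
    }
    sample_negatives(seq_len(n_cand), w, 1L, seed_i)
  }
  idx_t <- integer(b); idx_i <- integer(b)
  for (i in seq_len(b)) {
    idx_t[i] <- pick(sims_t[i, ], s_pos[i], nrow(bt),
                     derive_seed(seed, paste0("t", i)))
    idx_i[i] <- pick(sims_i[i, ], s_pos[i], nrow(bi),
                     derive_seed(seed, paste0("i", i)))
  }
  list(neg_text = bt[idx_t, , drop = FALSE],
       neg_img = bi[idx_i, , drop = FALSE],
       s_text = sims_t[cbind(seq_len(b), idx_t)],
       s_img = sims_i[cbind(seq_len(b), idx_i)])
}

evaluate_split <- function(model, raw, ids, ks) {
  u <- embed_batch(raw$img[ids], model$enc$w_img, model$enc$b_img,
                   model$tms_img)$embs
  tt <- embed_batch(raw$txt[ids], model$enc$w_txt, model$enc$b_txt,
                    model$tms_txt)$embs
  evaluate_bidirectional(u, tt, ks)
}

#' Evaluate a trained model on its test split
#'
#' Negative-sampling machinery plays no role at inference: embeddings are
#' computed and galleries ranked by cosine similarity only.
#'
#' @param fit A `retrieval_fit` (or a checkpoint path to one).
#' @param which Split to evaluate: `"test"` (default), `"val"` or
#'   `"train"`.
#' @return A `retrieval_result`.
#' @export
evaluate_retrieval <- function(fit, which = c("test", "val", "train")) {
  if (is.character(fit)) fit <- readRDS(fit)
  which <- match.arg(which)
  ids <- fit$split[[paste0(switch(which, test = "test", val = "val",
                                  train = "train"), "_ids")]]
  evaluate_split(fit$model, fit$raw, ids, fit$config$eval_ks)
}
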