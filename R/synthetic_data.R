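#' Configuration of a synthetic image-caption world
#'
#' The generator emulates the statistical structure the sampler assumes:
#' matched image-caption similarities concentrated around `matched_mu` and
#' unmatched similarities around `unmatched_mu` (both approximately
#' Gaussian), four disease classes, and a controllable fraction of planted
#' false negatives — caption/image pairs labeled negative whose similarity
#' is drawn from the matched distribution, mimicking semantically
#' duplicated captions of same-disease leaves.
#'
#' @param n_classes Number of disease classes (default 4: bacterial leaf
#'   blight, blast, brown spot, tungro).
#' @param n_per_class Pairs per class.
#' @param embedding_dim Shared-space dimension of the direct embedding
#'   world. The default 32 makes the spread of unmatched similarities land
#'   near `unmatched_sigma` at the default targets (the unmatched mean is
#'   exact by construction, its spread is set by the dimension).
#' @param matched_mu,matched_sigma Target matched-similarity distribution.
#' @param unmatched_mu,unmatched_sigma Target unmatched-similarity
#'   distribution; `matched_mu > unmatched_mu > 0` required for a
#'   separable world.
#' @param false_negative_rate Fraction of captions replanted as false
#'   negatives of another same-class image.
#' @param image_side Side length of rendered images.
#' @param seed World seed; worlds are bitwise reproducible per seed.
#' @return Object of class `world_config`.
#' @export
world_config <- function(n_classes = 4L, n_per_class = 50L,
                         embedding_dim = 32L,
                         matched_mu = 0.7, matched_sigma = 0.1,
                         unmatched_mu = 0.2, unmatched_sigma = 0.15,
                         false_negative_rate = 0.05,
                         image_side = 32L, seed = 1L) {
  if (abs(matched_mu) >= 1 || abs(unmatched_mu) >= 1) {
    stop("similarity targets must lie strictly inside (-1, 1)")
  }
  stopifnot(matched_mu > unmatched_mu, unmatched_mu > 0,
            matched_sigma > 0, unmatched_sigma > 0,
            false_negative_rate >= 0, false_negative_rate <= 1,
            n_classes >= 1, n_per_class >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 embedding_dim = as.integer(embedding_dim),
                 matched_mu = matched_mu, matched_sigma = matched_sigma,
                 unmatched_mu = unmatched_mu,
                 unmatched_sigma = unmatched_sigma,
                 false_negative_rate = false_negative_rate,
                 image_side = as.integer(image_side),
                 seed = as.integer(seed)),
            class = "world_config")
}

rnorm_clipped <- function(n, mu, sigma, lo = -0.99, hi = 0.99) {
  pmin(pmax(stats::rnorm(n, mu, sigma), lo), hi)
}

#' Generate a paired-embedding world directly in the shared space
#'
#' Construction: every image embedding shares a common component of weight
#' `sqrt(lambda)` (with `lambda = unmatched_mu / matched_mu`) plus an
#' idiosyncratic orthogonal component, so unmatched cosines average
#' `unmatched_mu` exactly. Each caption embedding is built from its image
#' with a per-pair target cosine drawn from
#' `N(matched_mu, matched_sigma)`, so matched cosines follow the matched
#' distribution exactly. A `false_negative_rate` fraction of captions is
#' then re-planted to additionally satisfy a matched-distribution cosine
#' with a different same-class image; those (image, caption) pairs are the
#' planted false negatives and are flagged as ground truth.
#'
#' @param config A `world_config`.
#' @return List of class `world_sample`: `image_embs`, `text_embs`
#'   (`(n, d)` unit-row matrices), `class_labels`, `fn_pairs` (data.frame
#'   with columns `i`, `j`: caption `j` is a planted false negative of
#'   image `i`), `matched_targets` (the drawn matched cosines), `config`.
#' @export
generate_embedding_world <- function(config = world_config()) {
  n <- config$n_classes * config$n_per_class
  d <- config$embedding_dim
  if (d < 4L) stop("embedding_dim must be at least 4")
  lambda <- config$unmatched_mu / config$matched_mu
  if (lambda >= 1) stop("infeasible targets: unmatched_mu must be below matched_mu")
  with_seed(config$seed, {
    g <- c(1, rep(0, d - 1))  # common direction: first coordinate
    # idiosyncratic components orthogonal to g
    xi <- matrix(stats::rnorm(n * (d - 1)), n, d - 1)
    xi <- xi / sqrt(rowSums(xi^2))
    v <- cbind(sqrt(lambda), sqrt(1 - lambda) * xi)
    classes <- rep(seq_len(config$n_classes), each = config$n_per_class)

    c_match <- rnorm_clipped(n, config$matched_mu, config$matched_sigma)
    t_embs <- matrix(0, n, d)
    for (i in seq_len(n)) {
      w <- stats::rnorm(d)
      w <- w - sum(w * v[i, ]) * v[i, ]
      w <- w / sqrt(sum(w^2))
      t_embs[i, ] <- c_match[i] * v[i, ] + sqrt(1 - c_match[i]^2) * w
    }

    # plant false negatives: caption j is rebuilt to satisfy a
    # matched-distribution cosine with its own image AND with the most
    # similar other image of the same class (false negatives arise from
    # near-duplicate leaves, so the nearest neighbour is the natural
    # partner; it also keeps the two-cosine constraint feasible on the
    # sphere, avoiding truncation of the planted similarity draws)
    n_fn <- round(config$false_negative_rate * n)
    fn_pairs <- data.frame(i = integer(0), j = integer(0))
    if (n_fn > 0) {
      js <- sample.int(n, n_fn)
      for (j in js) {
        same <- setdiff(which(classes == classes[j]), j)
        if (length(same) == 0L) next
        gammas <- as.numeric(v[same, , drop = FALSE] %*% v[j, ])
        i <- same[which.max(gammas)]
        gamma <- max(gammas)
        s2 <- c_match[j]
        sol <- NULL
        for (try in 1:20) {
          s1 <- rnorm_clipped(1, config$matched_mu, config$matched_sigma)
          a <- (s1 - gamma * s2) / (1 - gamma^2)
          b <- (s2 - gamma * s1) / (1 - gamma^2)
          res2 <- 1 - (a^2 + b^2 + 2 * a * b * gamma)
          if (res2 >= 0) { sol <- list(a = a, b = b, res2 = res2); break }
        }
        if (is.null(sol)) next
        # residual direction orthogonal to span{v_i, v_j}: orthonormalize
        # the pair first, then project out both components
        u1 <- v[i, ]
        u2 <- v[j, ] - sum(v[j, ] * u1) * u1
        u2 <- u2 / sqrt(sum(u2^2))
        nvec <- stats::rnorm(d)
        nvec <- nvec - sum(nvec * u1) * u1 - sum(nvec * u2) * u2
        nrm <- sqrt(sum(nvec^2))
        if (nrm < 1e-8) next
        t_embs[j, ] <- sol$a * v[i, ] + sol$b * v[j, ] +
          sqrt(sol$res2) * nvec / nrm
        fn_pairs <- rbind(fn_pairs, data.frame(i = i, j = j))
      }
    }
    structure(list(image_embs = v, text_embs = t_embs,
                   class_labels = classes, fn_pairs = fn_pairs,
                   matched_targets = c_match, config = config),
              class = "world_sample")
  })
}

disease_palette <- function() {
  list(
    blight = list(token = "blight", leaf = c(0.45, 0.62, 0.25)),
    blast = list(token = "blast", leaf = c(0.35, 0.55, 0.35)),
    brownspot = list(token = "brownspot", leaf = c(0.50, 0.58, 0.20)),
    tungro = list(token = "tungro", leaf = c(0.60, 0.65, 0.15))
  )
}

spot_attributes <- function() {
  list(count = c("one", "two", "three", "four"),
       size = c("small", "large"),
       shade = c("dark", "pale"),
       location = c("upper", "lower", "left", "right"))
}

render_leaf_image <- function(side, leaf_rgb, count, size, shade, location) {
  img <- array(rep(leaf_rgb, each = side * side), c(side, side, 3))
  # lesion color: brownish, darker or paler
  spot_rgb <- if (shade == "dark") c(0.35, 0.18, 0.08) else c(0.75, 0.55, 0.35)
  half <- side %/% 2
  region <- switch(location,
    upper = list(rows = 1:half, cols = 1:side),
    lower = list(rows = (half + 1):side, cols = 1:side),
    left = list(rows = 1:side, cols = 1:half),
    right = list(rows = 1:side, cols = (half + 1):side))
  r <- if (size == "small") max(1L, side %/% 16) else max(2L, side %/% 8)
  n_spots <- match(count, spot_attributes()$count)
  for (k in seq_len(n_spots)) {
    cy <- sample(region$rows, 1)
    cx <- sample(region$cols, 1)
    rows <- max(1, cy - r):min(side, cy + r)
    cols <- max(1, cx - r):min(side, cx + r)
    for (ch in 1:3) img[rows, cols, ch] <- spot_rgb[ch]
  }
  img <- img + array(stats::rnorm(side * side * 3, 0, 0.02), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Render an on-disk image-caption dataset
#'
#' Writes PNG leaf images and a tab-separated caption table in the layout
#' `load_pairs` reads. Each image carries a class-specific leaf color plus
#' lesion spots whose count, size, shade and location are drawn per image;
#' its caption is a fixed seven-token template naming exactly those
#' attributes (`"<class> leaf <size> <count> <shade> spots <location>"`),
#' echoing the attribute-style annotation of real disease captions. The
#' attribute vocabulary is deliberately small, so attribute collisions
#' between different images produce naturally occurring false-negative
#' captions.
#'
#' @param config A `world_config` (its `n_classes` must be at most 4).
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with `dir`, `caption_table` (path) and the
#'   caption `records` data.frame.
#' @export
render_image_caption_world <- function(config = world_config(), dir) {
  pal <- disease_palette()
  if (config$n_classes > length(pal)) {
    stop("at most ", length(pal), " rendered disease classes are available")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  att <- spot_attributes()
  classes <- names(pal)[seq_len(config$n_classes)]
  with_seed(config$seed, {
    rows <- list()
    idx <- 0L
    for (cl in classes) for (k in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", cl, k)
      count <- sample(att$count, 1)
      size <- sample(att$size, 1)
      shade <- sample(att$shade, 1)
      location <- sample(att$location, 1)
      img <- render_leaf_image(config$image_side, pal[[cl]]$leaf,
                               count, size, shade, location)
      png::writePNG(img, file.path(dir, paste0(id, ".png")))
      caption <- paste(pal[[cl]]$token, "leaf", size, count, shade,
                       "spots", location)
      rows[[idx]] <- data.frame(image_id = id, caption = caption,
                                class_label = cl,
                                stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    tab <- file.path(dir, "captions.tsv")
    write_caption_table(records, tab)
    invisible(list(dir = dir, caption_table = tab, records = records))
  })
}

#' Area under the ROC curve via the rank-sum statistic
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 vector; `TRUE` marks positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior-recovery simulation on a planted-false-negative world
#'
#' Generates an embedding world, accumulates similarity statistics from
#' batch score matrices exactly as training would, evaluates the
#' false-negative posterior on a pool of labeled negatives (a planted
#' fraction among them), and measures how well the posterior separates
#' planted from true negatives.
#'
#' @param config A `world_config`.
#' @param n_negatives Number of negative (image, caption) pairs scored.
#' @param batch_size Batch size used when accumulating statistics.
#' @param sampler A `sampler_config`.
#' @return List with `auroc`, `mean_posterior_planted`,
#'   `mean_posterior_true`, the accumulated `stats` and the number of
#'   planted negatives in the pool.
#' @export
simulate_posterior_recovery <- function(config = world_config(
                                          n_per_class = 250L,
                                          false_negative_rate = 0.05),
                                        n_negatives = 1000L,
                                        batch_size = 32L,
                                        sampler = sampler_config()) {
  world <- generate_embedding_world(config)
  n <- nrow(world$image_embs)
  scores <- world$image_embs %*% t(world$text_embs)

  stats <- similarity_stats()
  idx <- with_seed(derive_seed(config$seed, "stat_batches"), sample.int(n))
  for (b in seq_len(n %/% batch_size)) {
    take <- idx[((b - 1) * batch_size + 1):(b * batch_size)]
    stats <- update_stats(stats, scores[take, take, drop = FALSE])
    if (stats_ready(stats, sampler)) break
  }

  planted <- world$fn_pairs
  n_planted <- nrow(planted)
  if (n_planted == 0) stop("world has no planted false negatives")
  n_true <- n_negatives - n_planted
  true_pairs <- with_seed(derive_seed(config$seed, "true_negatives"), {
    out <- matrix(0L, 0, 2)
    while (nrow(out) < n_true) {
      i <- sample.int(n, n_true)
      j <- sample.int(n, n_true)
      keep <- i != j & !(paste(i, j) %in% paste(planted$i, planted$j))
      out <- unique(rbind(out, cbind(i[keep], j[keep])))
    }
    out[seq_len(n_true), , drop = FALSE]
  })
  s_planted <- scores[cbind(planted$i, planted$j)]
  s_true <- scores[true_pairs]
  post <- false_negative_posterior(c(s_planted, s_true), stats, sampler)
  lab <- c(rep(TRUE, n_planted), rep(FALSE, length(s_true)))
  list(auroc = auroc(post, lab),
       mean_posterior_planted = mean(post[lab]),
       mean_posterior_true = mean(post[!lab]),
       stats = stats, n_planted = n_planted)
}
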