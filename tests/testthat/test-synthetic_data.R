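test_that("embedding worlds hit their similarity targets", {
  cfg <- world_config(n_per_class = 500L, seed = 17L)    # n = 2000 pairs
  w <- generate_embedding_world(cfg)
  s <- w$image_embs %*% t(w$text_embs)
  matched <- diag(s)
  n <- length(matched)
  # matched similarities: exact draws from N(mu+, sigma+)
  expect_lt(abs(mean(matched) - cfg$matched_mu),
            3 * cfg$matched_sigma / sqrt(n))
  # unmatched mean is exact by construction; unmatched similarities are
  # correlated across pairs sharing an image, so each image contributes
  # about one effective independent observation
  un <- s; diag(un) <- NA
  expect_lt(abs(mean(un, na.rm = TRUE) - cfg$unmatched_mu),
            3 * cfg$unmatched_sigma / sqrt(n))
  # all embeddings unit-normalized
  expect_equal(rowSums(w$image_embs^2), rep(1, n), tolerance = 1e-10)
  expect_equal(rowSums(w$text_embs^2), rep(1, n), tolerance = 1e-10)
})

test_that("worlds are bitwise reproducible per seed and flag-free at rate zero", {
  cfg <- world_config(n_per_class = 20L, seed = 5L)
  expect_identical(generate_embedding_world(cfg), generate_embedding_world(cfg))
  cfg2 <- world_config(n_per_class = 20L, seed = 6L)
  expect_false(identical(generate_embedding_world(cfg)$image_embs,
                         generate_embedding_world(cfg2)$image_embs))
  none <- generate_embedding_world(world_config(n_per_class = 20L,
                                                false_negative_rate = 0,
                                                seed = 5L))
  expect_equal(nrow(none$fn_pairs), 0L)
})

test_that("infeasible similarity targets are rejected", {
  expect_error(world_config(matched_mu = 1.2), "inside")
  expect_error(world_config(matched_mu = 0.3, unmatched_mu = 0.5))
})

test_that("planted false negatives look exactly like positives by similarity", {
  w <- generate_embedding_world(world_config(n_per_class = 250L, seed = 17L))
  s <- w$image_embs %*% t(w$text_embs)
  planted <- s[cbind(w$fn_pairs$i, w$fn_pairs$j)]
  expect_gt(length(planted), 30L)
  # flags sit on labeled-negative pairs only
  expect_true(all(w$fn_pairs$i != w$fn_pairs$j))
  # a location test cannot separate planted sims from matched sims
  p <- t.test(planted, diag(s))$p.value
  expect_gt(p, 0.01)
  # but they are far from the true-negative distribution
  expect_gt(mean(planted), w$config$unmatched_mu + 2 * w$config$unmatched_sigma)
})

test_that("the rendered world writes a loadable image-caption dataset", {
  cfg <- world_config(n_classes = 4L, n_per_class = 25L, image_side = 32L,
                      seed = 23L)
  dir <- file.path(tempdir(), "rendered_world_23")
  out <- render_image_caption_world(cfg, dir)
  expect_equal(nrow(out$records), 100L)
  expect_length(list.files(dir, pattern = "\\.png$"), 100L)
  # seven-token attribute captions
  expect_true(all(lengths(strsplit(out$records$caption, " ")) == 7L))
  # round-trip through the loader preserves the records in table order
  pairs <- load_pairs(dir, out$caption_table, side = 32L)
  expect_identical(vapply(pairs, `[[`, character(1), "caption"),
                   out$records$caption)
  expect_identical(vapply(pairs, `[[`, character(1), "class_label"),
                   out$records$class_label)
  # rendering twice with the same seed is identical on disk
  dir_b <- file.path(tempdir(), "rendered_world_23b")
  out_b <- render_image_caption_world(cfg, dir_b)
  expect_identical(out$records, out_b$records)
  f <- file.path(dir, paste0(out$records$image_id[1], ".png"))
  f_b <- file.path(dir_b, paste0(out_b$records$image_id[1], ".png"))
  expect_identical(png::readPNG(f), png::readPNG(f_b))
  # a different seed changes the pixel content
  cfg2 <- world_config(n_classes = 4L, n_per_class = 25L, image_side = 32L,
                       seed = 24L)
  dir2 <- file.path(tempdir(), "rendered_world_24")
  out2 <- render_image_caption_world(cfg2, dir2)
  f2 <- file.path(dir2, paste0(out2$records$image_id[1], ".png"))
  expect_false(identical(png::readPNG(f), png::readPNG(f2)))
})

test_that("auroc matches the rank-sum definition on a hand case", {
  # scores 1..4, positives at the top two: perfect separation
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both")
})
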