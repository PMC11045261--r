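#' Read a caption table
#'
#' Two dialects are accepted: tab-separated values with a header line
#' (`image_id`, `caption`, `class_label`) and JSON-lines with the same
#' fields (one object per line, chosen when the file extension is
#' `.jsonl`). Each image carries exactly one caption.
#'
#' @param path Caption table file.
#' @return `data.frame` with character columns `image_id`, `caption`,
#'   `class_label`.
#' @export
read_caption_table <- function(path) {
  if (!file.exists(path)) stop("caption table not found: ", path)
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                    stringsAsFactors = FALSE))
    tab <- do.call(rbind, rows)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", quote = "")
  }
  need <- c("image_id", "caption", "class_label")
  if (!all(need %in% names(tab))) {
    stop("caption table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  if (any(!nzchar(tab$image_id)) || anyDuplicated(tab$image_id)) {
    stop("image ids must be non-empty and unique")
  }
  if (any(!nzchar(tab$caption))) stop("captions must be non-empty")
  tab
}

#' Write a caption table as TSV
#'
#' @param records `data.frame` with columns `image_id`, `caption`,
#'   `class_label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caption_table <- function(records, path) {
  utils::write.table(records[, c("image_id", "caption", "class_label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

find_image_file <- function(image_dir, id) {
  for (ext in c(".png", ".PNG", ".jpg", ".jpeg", ".JPG", ".JPEG")) {
    f <- file.path(image_dir, paste0(id, ext))
    if (file.exists(f)) return(f)
  }
  # allow the table to carry the filename itself
  f <- file.path(image_dir, id)
  if (file.exists(f)) return(f)
  stop("image file for id \"", id, "\" not found in ", image_dir)
}

load_one_image <- function(file, side) {
  img <- tryCatch(EBImage::readImage(file),
                  error = function(e) stop("unreadable image: ", file,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) == 2L) {  # grayscale: replicate channels
    img <- EBImage::rgbImage(img, img, img)
  }
  if (any(dim(img)[1:2] != side)) {
    img <- EBImage::resize(img, w = side, h = side)  # bilinear
  }
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2, 1, 3))  # EBImage is (x, y, c); return (row, col, channel)
}

#' Load an image-caption pair dataset
#'
#' Reads the caption table, then decodes and bilinearly resizes each
#' referenced image to a square of the configured side length. Records are
#' returned in caption-table order. A missing or unreadable image is a
#' hard error naming the offending id.
#'
#' @param image_dir Directory holding the image files (PNG or JPEG), named
#'   `<image_id>.<ext>`.
#' @param caption_table Path to the caption table (TSV or JSONL).
#' @param side Target square side length in pixels. The default 256 is the
#'   training input size; desk-scale synthetic worlds use smaller sides.
#' @return List of records, each a list with `image` (a
#'   `(side, side, 3)` array in `[0, 1]`), `image_id`, `caption`,
#'   `class_label`.
#' @export
load_pairs <- function(image_dir, caption_table, side = 256L) {
  tab <- read_caption_table(caption_table)
  lapply(seq_len(nrow(tab)), function(i) {
    f <- find_image_file(image_dir, tab$image_id[i])
    list(image = load_one_image(f, side),
         image_id = tab$image_id[i],
         caption = tab$caption[i],
         class_label = tab$class_label[i])
  })
}

#' Deterministic train/validation/test split
#'
#' Shuffles the ids with the given seed and assigns floor-based counts per
#' the ratios; remainder records go to the training set (the least
#' size-sensitive part). The three parts are disjoint and cover all ids.
#'
#' @param ids Character or integer vector of at least 3 unique ids.
#' @param ratios Length-3 positive vector `(train, val, test)` summing
#'   to 1. Default 8:1:1.
#' @param seed Split seed.
#' @return Object of class `dataset_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
make_split <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ids) < 3L) stop("need at least 3 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-9)
  n <- length(ids)
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test  # floor remainder goes to train
  shuffled <- with_seed(seed, sample(ids))
  structure(list(
    train_ids = shuffled[seq_len(n_train)],
    val_ids = shuffled[n_train + seq_len(n_val)],
    test_ids = shuffled[n_train + n_val + seq_len(n_test)]
  ), class = "dataset_split")
}

#' Persist / restore a split as JSON id lists
#'
#' @param split A `dataset_split`.
#' @param path JSON file path.
#' @return `write_split`: `path` invisibly; `read_split`: the
#'   `dataset_split`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split)[c("train_ids", "val_ids", "test_ids")],
                       path)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(train_ids = as.character(x$train_ids),
                 val_ids = as.character(x$val_ids),
                 test_ids = as.character(x$test_ids)),
            class = "dataset_split")
}

#' K-fold cross-validation folds
#'
#' Utility for fivefold evaluation loops: deterministic shuffle, then k
#' near-equal folds.
#'
#' @param ids Unique id vector.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return List of k character vectors (the held-out ids per fold).
#' @export
make_kfold <- function(ids, k = 5L, seed = 1L) {
  if (length(ids) < k) stop("need at least k ids")
  shuffled <- with_seed(seed, sample(ids))
  split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
}
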