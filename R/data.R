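#' Construct and validate a labeled dataset
#'
#' The container consumed by the trainer: a samples x features matrix with
#' values in `[0, 1]` and a 0-based integer label per row.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels integer vector of 0-based class codes, one per row.
#' @param name dataset tag.
#' @param class_names optional character vector naming the classes, in code
#'   order.
#'
#' @return An object of class `"labeled_dataset"`.
#' @export
labeled_dataset <- function(features, labels, name = "dataset",
                            class_names = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  ds <- structure(list(features = features, labels = labels, name = name,
                       class_names = class_names,
                       n_classes = max(labels) + 1L),
                  class = "labeled_dataset")
  validate_dataset(ds)
  ds
}

#' @rdname labeled_dataset
#' @param ds a `labeled_dataset`.
#' @export
validate_dataset <- function(ds) {
  if (nrow(ds$features) != length(ds$labels))
    stop("feature row count does not match label count")
  if (any(!is.finite(ds$features))) stop("non-finite feature values")
  if (any(ds$labels < 0L) || any(ds$labels >= ds$n_classes))
    stop("labels must lie in [0, n_classes)")
  if (any(ds$features < 0) || any(ds$features > 1))
    stop("features must be normalized to [0, 1]")
  invisible(ds)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset '%s': %d samples, %d features, %d classes\n",
              x$name, nrow(x$features), ncol(x$features), x$n_classes))
  invisible(x)
}

#' Min-max normalize features
#'
#' Scales each feature column to `[0, 1]` using the column range of `stats`
#' (a matrix, by default the data itself).  Constant columns map to zero.
#' When statistics from a training split are supplied, transformed values are
#' clipped into `[0, 1]`.
#'
#' @param x numeric matrix.
#' @param stats optional matrix whose column ranges define the scaling.
#' @return The normalized matrix.
#' @export
normalize_features <- function(x, stats = NULL) {
  ref <- if (is.null(stats)) x else stats
  lo <- apply(ref, 2, min); hi <- apply(ref, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1          # constant column -> all zeros
  out <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  out[, hi == lo] <- 0
  pmin(pmax(out, 0), 1)
}

#' Read an IDX-format image/label pair
#'
#' Reads the big-endian IDX files of the MNIST dialect (magic `0x00000803`
#' for images, `0x00000801` for labels), flattens images row-major, and
#' scales pixels to `[0, 1]`.
#'
#' @param images_path path to the IDX image file.
#' @param labels_path path to the IDX label file.
#' @param name dataset tag.
#' @return A [labeled_dataset()].
#' @export
read_idx <- function(images_path, labels_path, name = "idx") {
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 2051L)
    stop(sprintf("bad IDX image magic %d (expected 2051 / 0x00000803)", magic))
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  nr <- readBin(con, "integer", 1, size = 4, endian = "big")
  nc <- readBin(con, "integer", 1, size = 4, endian = "big")
  raw <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(raw) != n * nr * nc) stop("truncated IDX image file")

  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (magic2 != 2049L)
    stop(sprintf("bad IDX label magic %d (expected 2049 / 0x00000801)", magic2))
  nl <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (nl != n) stop("IDX label count does not match image count")
  labels <- readBin(con2, "integer", nl, size = 1, signed = FALSE)
  if (length(labels) != nl) stop("truncated IDX label file")

  # raw is pixel-major within image, images consecutive; row-major flatten
  feats <- matrix(raw, nrow = n, ncol = nr * nc, byrow = TRUE) / 255
  labeled_dataset(feats, labels, name = name,
                  class_names = as.character(sort(unique(labels))))
}

#' Read a CSV feature table with a label column
#'
#' All non-label columns must be numeric; labels are coded 0..K-1 in order
#' of first appearance and features are min-max normalized.
#'
#' @param path CSV file with a header row.
#' @param label_column name of the label column.
#' @param name dataset tag.
#' @return A [labeled_dataset()].
#' @export
read_csv_dataset <- function(path, label_column, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop(sprintf("label column '%s' not found", label_column))
  lab_raw <- as.character(df[[label_column]])
  feat_df <- df[setdiff(names(df), label_column)]
  for (j in seq_along(feat_df)) {
    v <- feat_df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric feature cell at row %d, column '%s'",
                   if (is.na(bad)) 1L else bad, names(feat_df)[j]))
    }
  }
  lev <- unique(lab_raw)
  labels <- match(lab_raw, lev) - 1L
  feats <- normalize_features(as.matrix(feat_df))
  labeled_dataset(feats, labels, name = name, class_names = lev)
}

#' Synthetic Gaussian class clusters with controllable overlap
#'
#' Generates `n_classes` unit-variance Gaussian clusters whose means sit at
#' the vertices of a regular simplex with pairwise distance `separation`.
#' A fraction `overlap_fraction` of each class is drawn not around its own
#' mean but near the midpoint to a neighbouring class mean (displaced
#' slightly toward the labelled class so the label remains weakly
#' identifiable): these are the "hard" samples that stay novel after early
#' training.  Features are min-max normalized to `[0, 1]`.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class samples per class.
#' @param dims feature dimension; must be >= `n_classes`.
#' @param separation distance between adjacent class means, in units of the
#'   cluster standard deviation.
#' @param overlap_fraction share of each class drawn near class-boundary
#'   midpoints, in `[0, 1)`.
#' @param seed integer seed; generation is deterministic given it.
#' @return A [labeled_dataset()].
#' @export
#' @examples
#' ds <- synth_clusters(3, 50, dims = 4, separation = 10,
#'                      overlap_fraction = 0, seed = 1)
#' table(ds$labels)
synth_clusters <- function(n_classes = 3, n_per_class = 200, dims = 4,
                           separation = 6, overlap_fraction = 0.2, seed = 1) {
  if (n_classes < 2 || n_per_class < 1 || dims < 1)
    stop("counts must be positive (and n_classes >= 2)")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  if (dims < n_classes)
    stop("dims must be >= n_classes for the simplex mean placement")
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  # orthogonal placement: pairwise mean distance = separation for all pairs
  means <- matrix(0, n_classes, dims)
  for (c in seq_len(n_classes)) means[c, c] <- separation / sqrt(2)
  n_over <- round(overlap_fraction * n_per_class)
  n_core <- n_per_class - n_over
  feats <- matrix(0, n_classes * n_per_class, dims)
  labels <- integer(n_classes * n_per_class)
  row <- 1L
  for (c in seq_len(n_classes)) {
    nb <- (c %% n_classes) + 1L       # neighbouring class for midpoints
    core <- matrix(stats::rnorm(n_core * dims), n_core, dims) +
      matrix(means[c, ], n_core, dims, byrow = TRUE)
    if (n_over > 0) {
      # centre displaced 10% of the gap from the midpoint toward class c
      centre <- 0.6 * means[c, ] + 0.4 * means[nb, ]
      over <- matrix(stats::rnorm(n_over * dims), n_over, dims) +
        matrix(centre, n_over, dims, byrow = TRUE)
      pts <- rbind(core, over)
    } else pts <- core
    idx <- row:(row + n_per_class - 1L)
    feats[idx, ] <- pts
    labels[idx] <- c - 1L
    row <- row + n_per_class
  }
  .Random.seed_restore(old)
  labeled_dataset(normalize_features(feats), labels,
                  name = sprintf("synthetic-%dx%d", n_classes, n_per_class),
                  class_names = as.character(seq_len(n_classes) - 1L))
}

#' Stratified train/test split
#'
#' Splits a dataset by label so each class contributes the same test
#' fraction (within one sample).  The train split is renormalized with its
#' own feature ranges and those ranges are applied to the test split
#' (clipped into `[0, 1]`).
#'
#' @param ds a [labeled_dataset()].
#' @param test_fraction in `(0, 1)`.
#' @param seed integer seed.
#' @param renormalize recompute min-max scaling from the training split.
#' @return A list with elements `train` and `test`, both `labeled_dataset`s.
#' @export
train_test_split <- function(ds, test_fraction = 0.25, seed = 1,
                             renormalize = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  tab <- table(ds$labels)
  if (any(tab < 2)) stop("every class needs at least 2 samples to stratify")
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (cl in as.integer(names(tab))) {
    ids <- which(ds$labels == cl)
    n_test <- round(test_fraction * length(ids))
    n_test <- max(1L, min(n_test, length(ids) - 1L))
    test_idx <- c(test_idx, sample(ids, n_test))
  }
  .Random.seed_restore(old)
  train_idx <- setdiff(seq_along(ds$labels), test_idx)
  ftr <- ds$features[train_idx, , drop = FALSE]
  fte <- ds$features[test_idx, , drop = FALSE]
  if (renormalize) {
    fte <- normalize_features(fte, stats = ftr)
    ftr <- normalize_features(ftr)
  }
  list(
    train = labeled_dataset(ftr, ds$labels[train_idx],
                            name = paste0(ds$name, "-train"),
                            class_names = ds$class_names),
    test = labeled_dataset(fte, ds$labels[test_idx],
                           name = paste0(ds$name, "-test"),
                           class_names = ds$class_names)
  )
}
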