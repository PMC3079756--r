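#' Construct a classification dataset
#'
#' Container for a tabular classification problem: a numeric feature matrix
#' (rows are patterns) plus 0-based integer class labels.
#'
#' @param features numeric matrix, one row per pattern.
#' @param labels integer vector of 0-based class indices, one per row.
#' @param n_classes number of classes; defaults to `max(labels) + 1`.
#' @param name dataset name used in summaries and file output.
#' @return an object of class `ngn_dataset` with fields `features`,
#'   `labels`, `n_inputs`, `n_classes`, `name`.
#' @export
classification_dataset <- function(features, labels, n_classes = NULL,
                                   name = "dataset") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("number of labels must equal number of feature rows")
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("a classification dataset needs at least 2 classes")
  if (any(labels < 0L | labels >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  structure(
    list(features = features, labels = labels,
         n_inputs = ncol(features), n_classes = n_classes,
         name = as.character(name)),
    class = "ngn_dataset"
  )
}

#' @export
print.ngn_dataset <- function(x, ...) {
  cat(sprintf("<ngn_dataset> %s: %d patterns, %d inputs, %d classes\n",
              x$name, nrow(x$features), x$n_inputs, x$n_classes))
  invisible(x)
}

#' Load a delimited classification dataset
#'
#' Reads a delimited text file (one pattern per row), maps class values to
#' 0-based indices in order of first appearance, and drops any row that
#' contains the missing-value token (the drop count is reported with
#' [message()]). UCI-style `.data` files load with the defaults (comma
#' delimiter, class in the last column, no header).
#'
#' @param path file path.
#' @param class_column column holding the class: an index, a column name
#'   (implies a header row), or `NULL` for the last column.
#' @param delimiter field separator.
#' @param missing_token cell value marking a missing entry.
#' @param header whether the file has a header row; defaults to `TRUE` when
#'   `class_column` is a name.
#' @param name dataset name; defaults to the file name.
#' @return an `ngn_dataset`.
#' @export
load_delimited <- function(path, class_column = NULL, delimiter = ",",
                           missing_token = "?",
                           header = is.character(class_column),
                           name = basename(path)) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = header,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0L) stop("empty file: ", path)
  if (is.null(class_column)) {
    cls_idx <- ncol(raw)
  } else if (is.character(class_column)) {
    cls_idx <- match(class_column, names(raw))
    if (is.na(cls_idx)) stop("class column not found: ", class_column)
  } else {
    cls_idx <- as.integer(class_column)
    if (cls_idx < 1L || cls_idx > ncol(raw)) stop("class column index out of range")
  }
  keep <- !apply(raw == missing_token, 1L, any)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("load_delimited: dropped %d row(s) containing '%s'",
                    n_dropped, missing_token))
  }
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no rows left after dropping missing values")
  cls_values <- raw[[cls_idx]]
  levels_seen <- unique(cls_values)
  if (length(levels_seen) < 2L) stop("fewer than 2 distinct classes")
  labels <- match(cls_values, levels_seen) - 1L
  feat_raw <- raw[, -cls_idx, drop = FALSE]
  features <- suppressWarnings(
    vapply(feat_raw, as.numeric, numeric(nrow(feat_raw)))
  )
  features <- matrix(features, nrow = nrow(feat_raw))
  if (anyNA(features)) {
    stop("non-numeric feature cell that is not the missing token")
  }
  ds <- classification_dataset(features, labels,
                               n_classes = length(levels_seen), name = name)
  attr(ds, "class_levels") <- levels_seen
  ds
}

#' Rescale every feature column to [-1, 1]
#'
#' Linear min-max rescaling per column; a constant column maps to 0. The
#' astrocyte activity criterion is a sign test on activations, so inputs
#' must be centred around zero. Idempotent up to floating tolerance.
#'
#' @param ds an `ngn_dataset`.
#' @return the dataset with rescaled features.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "ngn_dataset"))
  if (nrow(ds$features) == 0L) stop("empty dataset")
  X <- ds$features
  for (j in seq_len(ncol(X))) {
    lo <- min(X[, j]); hi <- max(X[, j])
    X[, j] <- if (hi > lo) 2 * (X[, j] - lo) / (hi - lo) - 1 else 0
  }
  ds$features <- X
  ds
}

#' Stratified repeated 2-fold split plans
#'
#' Builds the split plans for repeated 2-fold cross-validation: each
#' repetition shuffles the patterns within each class and halves them, so
#' the two folds are stratified complements and train/test sizes differ by
#' at most one pattern. Five repetitions (the default) give the 10 plans of
#' the 5x2 cross-validation protocol.
#'
#' @param ds an `ngn_dataset` with at least 2 patterns per class.
#' @param seed integer seed; plans are deterministic given the seed.
#' @param n_repetitions number of 2-fold repetitions (default 5).
#' @return a list of `2 * n_repetitions` plans, each a list with
#'   `train_indices`, `test_indices`, `fold_id` (1 or 2), `repetition_id`.
#' @export
make_5x2_splits <- function(ds, seed, n_repetitions = 5L) {
  stopifnot(inherits(ds, "ngn_dataset"))
  counts <- tabulate(ds$labels + 1L, nbins = ds$n_classes)
  if (any(counts < 2L)) stop("every class needs at least 2 patterns")
  with_seed(seed, {
    plans <- vector("list", 2L * n_repetitions)
    for (rep_id in seq_len(n_repetitions)) {
      fold_a <- integer(0)
      fold_b <- integer(0)
      for (cls in seq_len(ds$n_classes) - 1L) {
        idx <- sample(which(ds$labels == cls))
        h <- length(idx) %/% 2L
        if (length(idx) %% 2L == 1L && length(fold_b) < length(fold_a)) {
          # odd class: give the extra pattern to the currently smaller fold
          fold_b <- c(fold_b, idx[seq_len(h + 1L)])
          fold_a <- c(fold_a, idx[-seq_len(h + 1L)])
        } else {
          fold_a <- c(fold_a, idx[seq_len(h + (length(idx) %% 2L))])
          fold_b <- c(fold_b, idx[-seq_len(h + (length(idx) %% 2L))])
        }
      }
      fold_a <- sort(fold_a); fold_b <- sort(fold_b)
      plans[[2L * rep_id - 1L]] <- list(train_indices = fold_a,
                                        test_indices = fold_b,
                                        fold_id = 1L, repetition_id = rep_id)
      plans[[2L * rep_id]] <- list(train_indices = fold_b,
                                   test_indices = fold_a,
                                   fold_id = 2L, repetition_id = rep_id)
    }
    plans
  })
}

#' Subset a dataset by pattern indices
#'
#' @param ds an `ngn_dataset`.
#' @param indices row indices to keep.
#' @return the subsetted `ngn_dataset`.
#' @export
subset_dataset <- function(ds, indices) {
  classification_dataset(ds$features[indices, , drop = FALSE],
                         ds$labels[indices], n_classes = ds$n_classes,
                         name = ds$name)
}

#' Generate a Gaussian-cluster classification dataset
#'
#' Balanced synthetic classification data: class c is an isotropic
#' unit-variance Gaussian centred at `separation / sqrt(2)` times the c-th
#' unit vector, so every pair of class means is exactly `separation` apart
#' (requires `n_classes <= n_inputs`). Deterministic given the seed.
#'
#' @param n_per_class patterns per class.
#' @param n_inputs feature dimensionality.
#' @param n_classes number of classes.
#' @param separation Euclidean distance between any two class means; with
#'   unit noise, values around 2-4 span hard to easy problems.
#' @param seed integer seed.
#' @return an `ngn_dataset` with `n_per_class * n_classes` patterns in
#'   class-block order.
#' @export
generate_gaussian_dataset <- function(n_per_class, n_inputs, n_classes = 2L,
                                      separation = 2.5, seed = 1L) {
  if (n_per_class < 1L || n_inputs < 1L || n_classes < 2L) {
    stop("n_per_class and n_inputs must be positive; n_classes >= 2")
  }
  if (separation < 0) stop("separation must be >= 0")
  if (n_classes > n_inputs) {
    stop("equidistant class means require n_classes <= n_inputs")
  }
  with_seed(seed, {
    scale <- separation / sqrt(2)
    n <- n_per_class * n_classes
    X <- matrix(stats::rnorm(n * n_inputs), nrow = n)
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    for (cls in seq_len(n_classes)) {
      rows <- which(labels == cls - 1L)
      X[rows, cls] <- X[rows, cls] + scale
    }
    # interleave the classes: a class-blocked row order would let the glial
    # sweep encode labels in its weight drift instead of in the inputs
    ord <- sample.int(n)
    classification_dataset(X[ord, , drop = FALSE], labels[ord],
                           n_classes = n_classes,
                           name = sprintf("gaussian_s%.2g", separation))
  })
}

#' Class means of the Gaussian generator
#'
#' The configured class centres of [generate_gaussian_dataset()], one row
#' per class.
#'
#' @inheritParams generate_gaussian_dataset
#' @return a `n_classes x n_inputs` matrix.
#' @export
gaussian_class_means <- function(n_inputs, n_classes, separation) {
  M <- matrix(0, nrow = n_classes, ncol = n_inputs)
  for (cls in seq_len(n_classes)) M[cls, cls] <- separation / sqrt(2)
  M
}

#' Write / read a dataset as CSV
#'
#' Round-trips an `ngn_dataset` through a plain CSV with feature columns
#' `x1..xp` and a final `class` column holding the 0-based label.
#'
#' @param ds an `ngn_dataset`.
#' @param path output file.
#' @return `path`, invisibly (`dataset_to_csv`); an `ngn_dataset`
#'   (`dataset_from_csv`).
#' @export
dataset_to_csv <- function(ds, path) {
  df <- as.data.frame(ds$features)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$class <- ds$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dataset_to_csv
#' @export
dataset_from_csv <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE)
  classification_dataset(as.matrix(df[, names(df) != "class", drop = FALSE]),
                         df$class, name = basename(path))
}
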