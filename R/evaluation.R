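#' Paired comparison protocol configuration
#'
#' The comparison protocol trains a plain network (glia off) and its
#' neuron-glia counterpart from the same initial-weight population on the
#' same data split, for every combination of cross-validation split and
#' initial population. At the defaults — 5 repetitions of stratified 2-fold
#' cross-validation crossed with 10 initial-weight populations — this
#' yields exactly 100 paired test results per configuration.
#'
#' @param training an `ngn_training_config` template; its `glia` field is
#'   the neuron-glia arm's setting (the plain arm runs the same template
#'   with glia disabled).
#' @param n_cv_repetitions repetitions of 2-fold cross-validation (5).
#' @param n_folds folds per repetition; must be 2.
#' @param n_weight_populations initial-weight populations per split (10).
#' @param base_seed master seed from which split and run seeds derive.
#' @return an object of class `ngn_protocol`.
#' @export
protocol_config <- function(training, n_cv_repetitions = 5L, n_folds = 2L,
                            n_weight_populations = 10L, base_seed = 1L) {
  stopifnot(inherits(training, "ngn_training_config"))
  if (n_folds != 2L) stop("the protocol is defined for 2-fold cross-validation")
  structure(list(training = training,
                 n_cv_repetitions = as.integer(n_cv_repetitions),
                 n_folds = 2L,
                 n_weight_populations = as.integer(n_weight_populations),
                 base_seed = as.integer(base_seed)),
            class = "ngn_protocol")
}

#' Steady accuracy of a run
#'
#' The training or test accuracy reached at the end of the run (the last
#' recorded snapshot).
#'
#' @param history an `ngn_history`.
#' @param which `"training"` or `"test"`.
#' @return an accuracy fraction.
#' @export
steady_accuracy <- function(history, which = c("training", "test")) {
  which <- match.arg(which)
  sn <- history$snapshots
  if (is.null(sn) || nrow(sn) == 0L) stop("empty run history")
  col <- if (which == "training") "train_accuracy" else "test_accuracy"
  sn[[col]][nrow(sn)]
}

#' Generation at which 95% of the steady accuracy is reached
#'
#' The training/test time of a run: the generation of the first snapshot
#' whose accuracy is at least 0.95 times the steady accuracy. Resolution is
#' limited by the snapshot interval (`eval_every`).
#'
#' @inheritParams steady_accuracy
#' @return a generation index.
#' @export
time_to_95 <- function(history, which = c("training", "test")) {
  which <- match.arg(which)
  sn <- history$snapshots
  if (is.null(sn) || nrow(sn) == 0L) stop("empty run history")
  col <- if (which == "training") "train_accuracy" else "test_accuracy"
  acc <- sn[[col]]
  steady <- acc[length(acc)]
  sn$generation[which(acc >= 0.95 * steady)[1]]
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Thin wrapper around [stats::wilcox.test()] (paired, two-sided). Zero
#' paired differences are dropped, as in the underlying test; when every
#' difference is zero the comparison is degenerate and `p = 1` is returned
#' by convention.
#'
#' @param x,y paired numeric vectors of equal length >= 5.
#' @return a list with `statistic` and `p.value`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 5L) stop("at least 5 pairs are required")
  if (all(x == y)) return(list(statistic = NA_real_, p.value = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p a p-value.
#' @return a string.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
}

#' Run the paired NN-vs-NGN comparison protocol
#'
#' For every cross-validation split and every initial-weight population,
#' trains the plain network and the neuron-glia network from the same
#' initial population on the same fold (paired design) and records steady
#' training/test accuracies and 95%-of-steady times for both arms.
#' Aggregates report mean and SEM per metric, performance indexes (ratio
#' of NGN to NN mean steady accuracy) and paired Wilcoxon tests.
#'
#' @param ds an `ngn_dataset` (features should be normalized; the astrocyte
#'   activity criterion is a sign test).
#' @param cfg an `ngn_protocol`.
#' @param train_fn the training function; the default is [train_network()].
#'   A stub with the same signature can be injected to test the protocol
#'   structure cheaply.
#' @return an object of class `ngn_comparison`: `records` (one row per
#'   paired run) and `summary` (means, SEMs, performance indexes, Wilcoxon
#'   p-values).
#' @export
run_protocol <- function(ds, cfg, train_fn = train_network) {
  stopifnot(inherits(cfg, "ngn_protocol"))
  splits <- make_5x2_splits(ds, seed = cfg$base_seed,
                            n_repetitions = cfg$n_cv_repetitions)
  nn_cfg <- cfg$training
  nn_cfg$glia$enabled <- FALSE
  ngn_cfg <- cfg$training
  rows <- list()
  for (sp in splits) {
    tr <- subset_dataset(ds, sp$train_indices)
    te <- subset_dataset(ds, sp$test_indices)
    for (w in seq_len(cfg$n_weight_populations)) {
      run_seed <- derive_seed(cfg$base_seed, sp$repetition_id, sp$fold_id, w)
      h_nn <- train_fn(tr, te, nn_cfg, run_seed)
      h_ngn <- train_fn(tr, te, ngn_cfg, run_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = sp$repetition_id, fold = sp$fold_id, population = w,
        seed = run_seed,
        nn_train_acc = steady_accuracy(h_nn, "training"),
        ngn_train_acc = steady_accuracy(h_ngn, "training"),
        nn_test_acc = steady_accuracy(h_nn, "test"),
        ngn_test_acc = steady_accuracy(h_ngn, "test"),
        nn_train_time = time_to_95(h_nn, "training"),
        ngn_train_time = time_to_95(h_ngn, "training"),
        nn_test_time = time_to_95(h_nn, "test"),
        ngn_test_time = time_to_95(h_ngn, "test"))
    }
  }
  records <- do.call(rbind, rows)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  metric <- function(nn, ngn) {
    # Wilcoxon needs >= 5 pairs; tiny exploratory protocols skip the test
    w <- if (length(nn) >= 5L) wilcoxon_paired(ngn, nn) else
      list(statistic = NA_real_, p.value = NA_real_)
    list(nn_mean = mean(nn), nn_sem = sem(nn),
         ngn_mean = mean(ngn), ngn_sem = sem(ngn),
         p.value = w$p.value, stars = significance_stars(w$p.value))
  }
  summary <- list(
    n_runs = nrow(records),
    train_accuracy = metric(records$nn_train_acc, records$ngn_train_acc),
    test_accuracy = metric(records$nn_test_acc, records$ngn_test_acc),
    train_time = metric(records$nn_train_time, records$ngn_train_time),
    test_time = metric(records$nn_test_time, records$ngn_test_time),
    performance_index_training =
      mean(records$ngn_train_acc) / mean(records$nn_train_acc),
    performance_index_test =
      mean(records$ngn_test_acc) / mean(records$nn_test_acc))
  structure(list(records = records, summary = summary,
                 dataset = ds$name,
                 glia = format_glial_config(cfg$training$glia),
                 architecture = paste(cfg$training$arch$layer_sizes,
                                      collapse = "-")),
            class = "ngn_comparison")
}

#' @export
print.ngn_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ngn_comparison> %s, arch %s, glia %s (%d paired runs)\n",
              x$dataset, x$architecture, x$glia, s$n_runs))
  cat(sprintf("  steady train acc: NN %.3f+-%.3f vs NGN %.3f+-%.3f %s\n",
              s$train_accuracy$nn_mean, s$train_accuracy$nn_sem,
              s$train_accuracy$ngn_mean, s$train_accuracy$ngn_sem,
              s$train_accuracy$stars))
  cat(sprintf("  steady test acc:  NN %.3f+-%.3f vs NGN %.3f+-%.3f %s\n",
              s$test_accuracy$nn_mean, s$test_accuracy$nn_sem,
              s$test_accuracy$ngn_mean, s$test_accuracy$ngn_sem,
              s$test_accuracy$stars))
  cat(sprintf("  performance index: training %.3f, test %.3f\n",
              s$performance_index_training, s$performance_index_test))
  invisible(x)
}

#' Write a comparison result to disk
#'
#' Writes the per-run paired records as CSV and the aggregate summary as
#' JSON next to it.
#'
#' @param cmp an `ngn_comparison`.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return the two paths, invisibly.
#' @export
comparison_to_files <- function(cmp, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  utils::write.csv(cmp$records, csv, row.names = FALSE)
  jsonlite::write_json(
    list(dataset = cmp$dataset, architecture = cmp$architecture,
         glia = cmp$glia, summary = cmp$summary),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
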