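#' The built-in problem / architecture / glia grid
#'
#' The four benchmark classification problems with their reference
#' feed-forward architectures (five per problem, spanning one to three
#' hidden layers) and the four glial settings "2,4", "3,6", "2,6" and
#' "3,8". Population sizes are 150 individuals, except Heart Disease which
#' uses 100.
#'
#' @return an object of class `ngn_grid`: `problems` (each with
#'   `n_inputs`, `n_classes`, `population_size`, `architectures`) and
#'   `glial_configs`.
#' @export
builtin_grid <- function() {
  structure(list(
    problems = list(
      heart_disease = list(
        n_inputs = 13L, n_classes = 2L, population_size = 100L,
        architectures = c("13-4-1", "13-4-3-1", "13-13-8-1",
                          "13-5-4-3-1", "13-13-4-4-1")),
      iris_flower = list(
        n_inputs = 4L, n_classes = 3L, population_size = 150L,
        architectures = c("4-5-3", "4-5-7-3", "4-4-10-3",
                          "4-7-5-7-3", "4-4-5-5-3")),
      breast_cancer = list(
        n_inputs = 9L, n_classes = 2L, population_size = 150L,
        architectures = c("9-7-1", "9-7-5-1", "9-9-14-1",
                          "9-12-8-4-1", "9-9-7-7-1")),
      ionosphere = list(
        n_inputs = 34L, n_classes = 2L, population_size = 150L,
        architectures = c("34-9-1", "34-9-4-1", "34-34-18-1",
                          "34-12-8-4-1", "34-34-9-9-1"))),
    glial_configs = c("2,4", "3,6", "2,6", "3,8")),
    class = "ngn_grid")
}

#' Number of hidden layers of an architecture string
#'
#' @param arch_text dash-notation architecture string.
#' @return integer count of hidden layers.
#' @export
hidden_layer_count <- function(arch_text) {
  length(parse_architecture(arch_text)$layer_sizes) - 2L
}

#' Desk-scale run profile
#'
#' Reduced problem sizes for a single workstation: the reference-scale
#' experiments (population 100-150, thousands of generations, 100 paired
#' runs per cell) were sized for a compute cluster. The desk profile keeps
#' the full protocol structure but shrinks the budgets.
#'
#' @param population_size GA population.
#' @param max_generations generation budget.
#' @param n_cv_repetitions cross-validation repetitions.
#' @param n_weight_populations initial-weight populations.
#' @param n_patterns patterns per synthetic stand-in dataset.
#' @param separation class-mean separation of synthetic stand-ins.
#' @param eval_every snapshot interval in generations.
#' @return a named list of overrides.
#' @export
desk_scale <- function(population_size = 30L, max_generations = 300L,
                       n_cv_repetitions = 1L, n_weight_populations = 1L,
                       n_patterns = 200L, separation = 2.5,
                       eval_every = 10L) {
  list(population_size = as.integer(population_size),
       max_generations = as.integer(max_generations),
       n_cv_repetitions = as.integer(n_cv_repetitions),
       n_weight_populations = as.integer(n_weight_populations),
       n_patterns = as.integer(n_patterns), separation = separation,
       eval_every = as.integer(eval_every))
}

# resolve a grid problem to a dataset: a user-supplied file, or a synthetic
# Gaussian stand-in with the problem's dimensionality
resolve_problem_dataset <- function(name, prob, data_files, scale, seed) {
  if (!is.null(data_files[[name]])) {
    normalize_dataset(load_delimited(data_files[[name]]))
  } else {
    n_per_class <- max(2L, ceiling(scale$n_patterns / prob$n_classes))
    ds <- generate_gaussian_dataset(n_per_class, prob$n_inputs,
                                    prob$n_classes, scale$separation, seed)
    ds$name <- paste0(name, "_synthetic")
    ds
  }
}

#' Sweep a problems x architectures x glial-settings grid
#'
#' Runs the paired comparison protocol for every cell of the grid, writes
#' each cell's paired records (CSV) and summary (JSON) under `out_dir`, and
#' returns pooled performance-index tables by hidden-layer count and by
#' problem. Problems without a data file run on a synthetic Gaussian
#' stand-in of matching dimensionality.
#'
#' @param grid an `ngn_grid` (see [builtin_grid()]).
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param data_files named list of file paths, keyed by problem name;
#'   missing entries fall back to synthetic data.
#' @param scale a [desk_scale()] profile.
#' @param train_fn training function passed through to [run_protocol()].
#' @return invisibly, a list with `cells` (one row per grid cell:
#'   performance indexes, steady accuracies, p-values), `pooled_by_layers`
#'   and `pooled_by_problem` (mean performance indexes).
#' @export
run_grid <- function(grid, out_dir, seed = 1L, data_files = list(),
                     scale = desk_scale(), train_fn = train_network) {
  stopifnot(inherits(grid, "ngn_grid"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- list()
  for (pname in names(grid$problems)) {
    prob <- grid$problems[[pname]]
    ds <- resolve_problem_dataset(pname, prob, data_files, scale,
                                  derive_seed(seed, match(pname,
                                                          names(grid$problems))))
    for (arch_text in prob$architectures) {
      for (glia_text in grid$glial_configs) {
        tcfg <- training_config(
          arch = parse_architecture(arch_text),
          glia = parse_glial_config(glia_text),
          ga = ga_config(population_size = min(prob$population_size,
                                               scale$population_size)),
          max_generations = scale$max_generations,
          eval_every = scale$eval_every)
        pcfg <- protocol_config(
          tcfg, n_cv_repetitions = scale$n_cv_repetitions,
          n_weight_populations = scale$n_weight_populations,
          base_seed = derive_seed(seed, match(pname, names(grid$problems)),
                                  match(arch_text, prob$architectures),
                                  match(glia_text, grid$glial_configs)))
        cmp <- run_protocol(ds, pcfg, train_fn = train_fn)
        stem <- file.path(out_dir, sprintf("%s_%s_%s", pname,
                                           gsub("-", "_", arch_text),
                                           gsub(",", "_", glia_text)))
        comparison_to_files(cmp, stem)
        message(sprintf("run_grid: %s arch %s glia %s -> %s.json",
                        pname, arch_text, glia_text, stem))
        cells[[length(cells) + 1L]] <- data.frame(
          problem = pname, architecture = arch_text, glia = glia_text,
          hidden_layers = hidden_layer_count(arch_text),
          nn_train_acc = cmp$summary$train_accuracy$nn_mean,
          ngn_train_acc = cmp$summary$train_accuracy$ngn_mean,
          nn_test_acc = cmp$summary$test_accuracy$nn_mean,
          ngn_test_acc = cmp$summary$test_accuracy$ngn_mean,
          perf_index_training = cmp$summary$performance_index_training,
          perf_index_test = cmp$summary$performance_index_test,
          p_train = cmp$summary$train_accuracy$p.value,
          p_test = cmp$summary$test_accuracy$p.value)
      }
    }
  }
  cells <- do.call(rbind, cells)
  pooled_by_layers <- stats::aggregate(
    cells[, c("perf_index_training", "perf_index_test")],
    by = list(hidden_layers = cells$hidden_layers), FUN = mean)
  pooled_by_problem <- stats::aggregate(
    cells[, c("perf_index_training", "perf_index_test")],
    by = list(problem = cells$problem), FUN = mean)
  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(pooled_by_layers, file.path(out_dir, "pooled_by_layers.csv"),
                   row.names = FALSE)
  utils::write.csv(pooled_by_problem,
                   file.path(out_dir, "pooled_by_problem.csv"),
                   row.names = FALSE)
  invisible(list(cells = cells, pooled_by_layers = pooled_by_layers,
                 pooled_by_problem = pooled_by_problem))
}

#' Best glial setting per problem
#'
#' Selects, for each problem in a grid sweep, the glial setting with the
#' highest mean steady test accuracy (argmax over the settings present in
#' `cells`).
#'
#' @param cells the `cells` table returned by [run_grid()].
#' @return a data frame with one row per problem: the selected glia and its
#'   performance indexes.
#' @export
best_glial_config <- function(cells) {
  do.call(rbind, lapply(split(cells, cells$problem), function(sub) {
    by_glia <- stats::aggregate(
      sub[, c("ngn_test_acc", "perf_index_training", "perf_index_test")],
      by = list(glia = sub$glia), FUN = mean)
    best <- by_glia[which.max(by_glia$ngn_test_acc), ]
    data.frame(problem = sub$problem[1], glia = best$glia,
               ngn_test_acc = best$ngn_test_acc,
               perf_index_training = best$perf_index_training,
               perf_index_test = best$perf_index_test)
  }))
}
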