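#' Training configuration for the hybrid learning loop
#'
#' Bundles the architecture, glial setting and GA setting with the run
#' controls of the two-phase hybrid method. Phase 1 passes every training
#' pattern through each candidate network for a full glial cycle and
#' accumulates the MSE; phase 2 applies one GA generation. With
#' `glia$enabled = FALSE` the loop degenerates to a plain GA-trained neural
#' network — the two arms share every line of GA code.
#'
#' @param arch an `ngn_arch`.
#' @param glia an `ngn_glia` (default: the (3,6) reference setting).
#' @param ga an `ngn_ga`.
#' @param max_generations generation budget (replaces wall-clock stop
#'   times, which are hardware-bound).
#' @param stop_on_zero_error stop early when the best MSE reaches 0.
#' @param lamarckian if `FALSE` (Baldwinian, the default) phase 1 measures
#'   the MSE of the glial sweep but the inherited genome survives, so the
#'   sweep is repeatable from the stored genome and accuracies are
#'   consistent with the fitness; if `TRUE` the sweep-modified genome is
#'   written back into the evolving individual. Lamarckian write-back
#'   compounds the multiplicative weight modulation across generations
#'   (one sweep scales a consistently inactive neuron's weights by
#'   0.5 to a power of order the pattern count), which collapses weights
#'   numerically in long runs — it is retained as a switch, not a default.
#' @param eval_every generations between recorded accuracy snapshots.
#' @return an object of class `ngn_training_config`.
#' @export
training_config <- function(arch, glia = glial_config(), ga = ga_config(),
                            max_generations = 300L,
                            stop_on_zero_error = TRUE,
                            lamarckian = FALSE, eval_every = 10L) {
  stopifnot(inherits(arch, "ngn_arch"), inherits(glia, "ngn_glia"),
            inherits(ga, "ngn_ga"))
  max_generations <- as.integer(max_generations)
  if (max_generations < 1L) stop("max_generations must be >= 1")
  structure(list(arch = arch, glia = glia, ga = ga,
                 max_generations = max_generations,
                 stop_on_zero_error = isTRUE(stop_on_zero_error),
                 lamarckian = isTRUE(lamarckian),
                 eval_every = as.integer(eval_every)),
            class = "ngn_training_config")
}

#' Phase-1 evaluation of one individual
#'
#' Presents every training pattern (in dataset order) to the individual's
#' network for a full glial pattern cycle, with the astrocyte counters
#' reset at each cycle start. After the last pattern the MSE — the mean
#' over patterns of the summed squared error of the final-iteration binary
#' output — is attached to the individual. Under transient glia every
#' pattern's cycle starts from the individual's genome; under cumulative
#' glia the weight changes carry over from pattern to pattern, and with
#' Lamarckian inheritance the returned individual carries the sweep-end
#' genome instead of the one it entered with.
#'
#' @param ind an individual (list with `genome`, `mse`).
#' @param train an `ngn_dataset`.
#' @param cfg an `ngn_training_config`.
#' @return the evaluated individual.
#' @export
phase1_evaluate <- function(ind, train, cfg) {
  arch <- cfg$arch
  Y <- target_matrix(train, arch$layer_sizes[length(arch$layer_sizes)])
  cumulative <- cfg$glia$persistence == "cumulative"
  res <- cpp_phase1(ind$genome, arch$layer_sizes, arch$use_bias,
                    arch$output_threshold, train$features, Y,
                    cfg$glia$sensitivity_n, cfg$glia$cycle_m,
                    cfg$glia$potentiation_fraction,
                    cfg$glia$depression_fraction, cfg$glia$enabled,
                    cumulative)
  ind$mse <- res$mse
  if (cfg$lamarckian && cumulative) ind$genome <- res$genome
  ind
}

#' Classification accuracy with test-phase glia
#'
#' Evaluates a genome on a dataset under the glial setting used in
#' training: every pattern is presented for a full pattern cycle (counters
#' reset at each cycle start) and the prediction is read from the final
#' iteration. All glial weight changes happen on a scratch copy — the
#' stored genome is never altered by evaluation.
#'
#' By default the evaluation regime follows `glia$persistence`: under
#' transient glia the scratch copy is re-initialized before every pattern
#' (`"reset"`; the result is independent of pattern order and, on the
#' training set, consistent with the phase-1 MSE); under cumulative glia
#' the scratch copy is modified across the evaluation set in dataset order
#' (`"sweep"`), mirroring the cumulative training sweep. With glia disabled
#' both regimes reduce to the plain feed-forward accuracy.
#'
#' @param arch an `ngn_arch`.
#' @param genome numeric weight genome.
#' @param ds an `ngn_dataset`.
#' @param glia an `ngn_glia`.
#' @param mode `"reset"` (per-pattern scratch copy) or `"sweep"`
#'   (cumulative scratch copy); default follows `glia$persistence`.
#' @return the fraction of correctly classified patterns.
#' @export
evaluate_with_glia <- function(arch, genome, ds, glia, mode = NULL) {
  if (is.null(mode)) {
    mode <- if (glia$persistence == "cumulative") "sweep" else "reset"
  }
  mode <- match.arg(mode, c("reset", "sweep"))
  n_out <- arch$layer_sizes[length(arch$layer_sizes)]
  if (n_out > 1L && n_out != ds$n_classes) {
    stop("output layer width must equal the class count")
  }
  cpp_accuracy(genome, arch$layer_sizes, arch$use_bias,
               arch$output_threshold, ds$features, ds$labels,
               glia$sensitivity_n, glia$cycle_m,
               glia$potentiation_fraction, glia$depression_fraction,
               glia$enabled, mode == "sweep")
}

#' Train a network with the two-phase hybrid method
#'
#' Alternates phase-1 evaluation of the whole population (glial weight
#' modulation + MSE) with one GA generation, until the generation budget is
#' exhausted or — when `stop_on_zero_error` — the best MSE reaches zero.
#' Accuracy snapshots of the current best individual (training and test
#' accuracy, both via [evaluate_with_glia()]) are recorded every
#' `eval_every` generations and at the final generation. Fully
#' deterministic given `seed`; the glial rule itself consumes no
#' randomness.
#'
#' @param train,test `ngn_dataset`s sharing `n_inputs` and `n_classes`.
#' @param cfg an `ngn_training_config`.
#' @param seed integer seed controlling the initial population and all GA
#'   randomness.
#' @return an object of class `ngn_history`: list with `snapshots` (data
#'   frame of `generation`, `best_mse`, `train_accuracy`, `test_accuracy`),
#'   `final_genome`, `final_mse`, `seed` and a config echo.
#' @export
train_network <- function(train, test, cfg, seed) {
  stopifnot(inherits(train, "ngn_dataset"), inherits(test, "ngn_dataset"))
  if (train$n_inputs != test$n_inputs || train$n_classes != test$n_classes) {
    stop("train and test datasets are incompatible")
  }
  arch <- cfg$arch
  if (train$n_inputs != arch$layer_sizes[1]) {
    stop("dataset inputs do not match the architecture")
  }
  with_seed(seed, {
    pop <- initialize_population(cfg$ga, genome_length(arch))
    snaps <- list()
    best <- NULL
    for (gen in seq_len(cfg$max_generations)) {
      for (i in seq_along(pop$individuals)) {
        if (is.na(pop$individuals[[i]]$mse)) {
          pop$individuals[[i]] <- phase1_evaluate(pop$individuals[[i]],
                                                  train, cfg)
        }
      }
      best <- best_individual(pop)
      stopped <- cfg$stop_on_zero_error && best$mse == 0
      if (gen %% cfg$eval_every == 0L || gen == cfg$max_generations ||
          stopped) {
        snaps[[length(snaps) + 1L]] <- data.frame(
          generation = gen,
          best_mse = best$mse,
          train_accuracy = evaluate_with_glia(arch, best$genome, train,
                                              cfg$glia),
          test_accuracy = evaluate_with_glia(arch, best$genome, test,
                                             cfg$glia))
      }
      if (stopped) break
      if (gen < cfg$max_generations) pop <- next_generation(pop, cfg$ga)
    }
    structure(list(snapshots = do.call(rbind, snaps),
                   final_genome = best$genome,
                   final_mse = best$mse,
                   seed = seed,
                   config = list(architecture = paste(arch$layer_sizes,
                                                      collapse = "-"),
                                 glia = if (cfg$glia$enabled)
                                   format_glial_config(cfg$glia) else "off",
                                 population_size = cfg$ga$population_size,
                                 max_generations = cfg$max_generations,
                                 lamarckian = cfg$lamarckian)),
              class = "ngn_history")
  })
}

#' @export
print.ngn_history <- function(x, ...) {
  last <- x$snapshots[nrow(x$snapshots), ]
  cat(sprintf(paste0("<ngn_history> %s, glia %s: %d generations, ",
                     "steady train %.3f / test %.3f (best MSE %.4f)\n"),
              x$config$architecture, x$config$glia, last$generation,
              last$train_accuracy, last$test_accuracy, last$best_mse))
  invisible(x)
}

#' Serialize / deserialize a run history as JSON
#'
#' @param history an `ngn_history`.
#' @param path output file.
#' @return `path` invisibly (`history_to_json`); an `ngn_history`
#'   (`history_from_json`).
#' @export
history_to_json <- function(history, path) {
  jsonlite::write_json(unclass(history), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname history_to_json
#' @export
history_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$snapshots <- as.data.frame(obj$snapshots)
  obj$final_genome <- as.numeric(obj$final_genome)
  structure(obj, class = "ngn_history")
}
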