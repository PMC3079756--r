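# fixtures are built in code at test time

# small separable dataset used across trainer tests
toy_dataset <- function(seed = 1, n_per_class = 20, n_inputs = 4,
                        separation = 4) {
  normalize_dataset(generate_gaussian_dataset(n_per_class, n_inputs,
                                              n_classes = 2,
                                              separation = separation,
                                              seed = seed))
}

# write a small delimited file and return its path
write_demo_file <- function(lines, ext = ".data") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a stub trainer with the train_network() signature: instant, deterministic,
# and it records every call so protocol tests can fingerprint the pairing
make_stub_trainer <- function() {
  calls <- new.env(parent = emptyenv())
  calls$log <- list()
  fn <- function(train, test, cfg, seed) {
    calls$log[[length(calls$log) + 1L]] <- list(
      glia_enabled = cfg$glia$enabled, seed = seed,
      train_fingerprint = sum(train$features) + sum(train$labels),
      n_train = nrow(train$features), n_test = nrow(test$features))
    acc <- 0.5 + 0.4 * (seed %% 100) / 100 + 0.05 * cfg$glia$enabled
    structure(list(
      snapshots = data.frame(generation = c(10L, 20L, 30L),
                             best_mse = c(0.3, 0.2, 0.1),
                             train_accuracy = c(0.8, 0.9, 1) * acc,
                             test_accuracy = c(0.8, 0.9, 1) * acc * 0.9),
      final_genome = numeric(3), final_mse = 0.1, seed = seed,
      config = list()), class = "ngn_history")
  }
  list(fn = fn, calls = calls)
}

# independent single-counter simulator used as an oracle against the
# vectorized counter update
oracle_counter_events <- function(flags, n) {
  counter <- 0L
  a <- 0L
  d <- 0L
  trace <- integer(length(flags))
  for (i in seq_along(flags)) {
    counter <- counter + if (flags[i]) 1L else -1L
    counter <- max(min(counter, n), -n)
    if (flags[i] && counter == n) a <- a + 1L
    if (!flags[i] && counter == -n) d <- d + 1L
    trace[i] <- counter
  }
  list(activations = a, depressions = d, trace = trace)
}
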