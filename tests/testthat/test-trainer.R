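test_that("phase 1 without glia reduces to the plain feed-forward MSE", {
  set.seed(40)
  ds <- toy_dataset(seed = 41, n_per_class = 10)
  arch <- architecture(c(4, 3, 1))
  cfg <- training_config(arch, glia = glial_config(3, 6, enabled = FALSE),
                         ga = ga_config(population_size = 2))
  g <- runif(genome_length(arch), -1, 1)
  ind <- phase1_evaluate(list(genome = g, mse = NA_real_), ds, cfg)
  plain_errs <- vapply(seq_len(nrow(ds$features)), function(i) {
    fp <- forward_pass(arch, g, ds$features[i, ])
    sum((fp$binary_output - ds$labels[i])^2)
  }, numeric(1))
  expect_equal(ind$mse, mean(plain_errs), tolerance = 1e-12)
  expect_identical(ind$genome, g)
})

test_that("a perfectly classifying genome has MSE zero", {
  # 1 input, direct 1-1 net, weight 5: x > 0.1 -> binary 1
  ds <- classification_dataset(matrix(c(-1, -0.5, 0.5, 1), ncol = 1),
                               c(0, 0, 1, 1))
  arch <- architecture(c(1, 1), use_bias = FALSE)
  cfg <- training_config(arch, glia = glial_config(2, 4, enabled = FALSE),
                         ga = ga_config(population_size = 2))
  ind <- phase1_evaluate(list(genome = 5, mse = NA_real_), ds, cfg)
  expect_equal(ind$mse, 0)
})

test_that("the hand-traced 1-1 toy cycle yields the expected phase-1 MSE", {
  # single always-active pattern, target 1: final-iteration net input is
  # 1.25^2 = 1.5625 >= 0.5, so the error is 0; with target 0 it is 1
  ds1 <- classification_dataset(matrix(c(1, 1), ncol = 1), c(1, 0),
                                n_classes = 2)
  arch <- architecture(c(1, 1), use_bias = FALSE)
  cfg <- training_config(arch, glia = glial_config(2, 4),
                         ga = ga_config(population_size = 2))
  ind <- phase1_evaluate(list(genome = 1, mse = NA_real_), ds1, cfg)
  expect_equal(ind$mse, 0.5)
})

test_that("training is deterministic and respects the generation budget", {
  tr <- toy_dataset(seed = 42, n_per_class = 10)
  te <- toy_dataset(seed = 43, n_per_class = 10)
  cfg <- training_config(architecture(c(4, 3, 1)),
                         ga = ga_config(population_size = 8),
                         max_generations = 1L, eval_every = 1L,
                         stop_on_zero_error = FALSE)
  h <- train_network(tr, te, cfg, seed = 2)
  expect_equal(nrow(h$snapshots), 1L)
  expect_equal(h$snapshots$generation, 1L)

  cfg$max_generations <- 12L
  cfg$eval_every <- 5L
  h1 <- train_network(tr, te, cfg, seed = 2)
  h2 <- train_network(tr, te, cfg, seed = 2)
  expect_identical(h1, h2)
  expect_equal(h1$snapshots$generation, c(5L, 10L, 12L))
  expect_true(all(diff(h1$snapshots$best_mse) <= 0))
})

test_that("zero glial fractions reproduce the glia-off trainer bit-exactly", {
  tr <- toy_dataset(seed = 44, n_per_class = 8)
  te <- toy_dataset(seed = 45, n_per_class = 8)
  arch <- architecture(c(4, 3, 1))
  base <- training_config(arch, ga = ga_config(population_size = 6),
                          max_generations = 10L, eval_every = 5L)
  off <- base
  off$glia <- glial_config(3, 6, enabled = FALSE)
  zero <- base
  zero$glia <- glial_config(3, 6, potentiation_fraction = 0,
                            depression_fraction = 0)
  h_off <- train_network(tr, te, off, seed = 9)
  h_zero <- train_network(tr, te, zero, seed = 9)
  expect_identical(h_off$snapshots, h_zero$snapshots)
  expect_identical(h_off$final_genome, h_zero$final_genome)
})

test_that("glial evaluation modes behave as documented", {
  set.seed(46)
  ds <- toy_dataset(seed = 47, n_per_class = 10)
  arch <- architecture(c(4, 3, 1))
  g <- runif(genome_length(arch), -1, 1)
  off <- glial_config(3, 6, enabled = FALSE)
  plain <- mean(vapply(seq_len(nrow(ds$features)), function(i) {
    predict_class(arch, g, ds$features[i, ]) == ds$labels[i]
  }, logical(1)))
  expect_equal(evaluate_with_glia(arch, g, ds, off), plain)

  # reset mode is invariant to pattern order
  on <- glial_config(3, 6)
  perm <- sample(nrow(ds$features))
  shuffled <- subset_dataset(ds, perm)
  expect_equal(evaluate_with_glia(arch, g, ds, on, mode = "reset"),
               evaluate_with_glia(arch, g, shuffled, on, mode = "reset"))

  # reset mode matches per-pattern R cycles
  acc_r <- mean(vapply(seq_len(nrow(ds$features)), function(i) {
    rc <- run_pattern_cycle(arch, g, ds$features[i, ], ds$labels[i], on)
    rc$activations$binary_output == ds$labels[i]
  }, logical(1)))
  expect_equal(evaluate_with_glia(arch, g, ds, on, mode = "reset"), acc_r)
})

test_that("an all-zero genome predicts class 0 everywhere", {
  ds <- classification_dataset(matrix(runif(20, -1, 1), ncol = 2),
                               rep(1L, 10), n_classes = 2)
  arch <- architecture(c(2, 2, 1))
  g <- numeric(genome_length(arch))
  expect_equal(evaluate_with_glia(arch, g, ds, glial_config(2, 4,
                                                            enabled = FALSE)),
               0)
})

test_that("both arms learn a separable problem", {
  tr <- toy_dataset(seed = 48, n_per_class = 40)
  te <- toy_dataset(seed = 49, n_per_class = 40)
  for (on in c(FALSE, TRUE)) {
    cfg <- training_config(architecture(c(4, 3, 1)),
                           glia = glial_config(3, 6, enabled = on),
                           ga = ga_config(population_size = 30),
                           max_generations = 300L, eval_every = 50L)
    h <- train_network(tr, te, cfg, seed = 50 + on)
    expect_gte(steady_accuracy(h, "training"), 0.95)
  }
})

test_that("histories round-trip through JSON", {
  tr <- toy_dataset(seed = 51, n_per_class = 6)
  cfg <- training_config(architecture(c(4, 3, 1)),
                         ga = ga_config(population_size = 4),
                         max_generations = 3L, eval_every = 1L)
  h <- train_network(tr, tr, cfg, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  history_to_json(h, path)
  back <- history_from_json(path)
  expect_equal(back$snapshots, h$snapshots)
  expect_equal(back$final_genome, h$final_genome)
})
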