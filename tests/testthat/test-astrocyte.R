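test_that("glial configs validate and parse the n,m notation", {
  for (nm in list(c(2, 4), c(3, 6), c(2, 6), c(3, 8))) {
    cfg <- glial_config(nm[1], nm[2])
    expect_equal(c(cfg$sensitivity_n, cfg$cycle_m), nm)
  }
  expect_error(glial_config(5, 4), "sensitivity_n <= cycle_m")
  expect_error(glial_config(0, 4), "sensitivity_n")
  expect_error(glial_config(2, 4, potentiation_fraction = 1), "fractions")
  cfg <- parse_glial_config("3,6")
  expect_equal(format_glial_config(cfg), "3,6")
  expect_error(parse_glial_config("3-6"), "n,m")
})

test_that("neuron activity is a strict sign test", {
  expect_true(is_neuron_active(0.7))
  expect_false(is_neuron_active(-0.3))
  expect_false(is_neuron_active(0))
})

test_that("counters clamp at +/-n and fire events at the clamp", {
  arch <- architecture(c(2, 1))
  cfg <- glial_config(2, 4)
  st <- new_glial_state(arch)
  st$counters <- c(0L, 2L)
  st <- update_counters(st, c(TRUE, TRUE), cfg)
  expect_equal(st$counters, c(1L, 2L))
  expect_equal(st$activation_events, c(FALSE, TRUE))  # re-activation at +n
  st$counters <- c(-2L, 1L)
  st <- update_counters(st, c(FALSE, TRUE), cfg)
  expect_equal(st$counters, c(-2L, 2L))
  expect_equal(st$depression_events, c(TRUE, FALSE))
  expect_equal(st$activation_events, c(FALSE, TRUE))  # first arrival at +n
  expect_error(update_counters(st, TRUE, cfg), "one activity flag")
})

test_that("counters never leave [-n, n] and match a scalar oracle", {
  set.seed(14)
  arch <- architecture(c(1, 1))
  for (case in 1:20) {
    n <- sample(1:4, 1)
    m <- sample(n:10, 1)
    flags <- sample(c(TRUE, FALSE), m, replace = TRUE)
    cfg <- glial_config(n, m)
    st <- new_glial_state(arch)
    a <- 0L; d <- 0L
    for (f in flags) {
      st <- update_counters(st, f, cfg)
      expect_true(abs(st$counters) <= n)
      a <- a + st$activation_events
      d <- d + st$depression_events
    }
    oracle <- oracle_counter_events(flags, n)
    expect_equal(a, oracle$activations)
    expect_equal(d, oracle$depressions)
  }
})

test_that("modulation scales outgoing weights by 1.25 / 0.5, sign-preserving", {
  arch <- architecture(c(2, 2, 1), use_bias = TRUE)
  g <- c(1.0, -0.8, 0.3, 0.4,   # input -> hidden weights
         0.1, 0.2,              # hidden biases
         0.6, 0.7,              # hidden -> output weights
         0.5)                   # output bias
  st <- new_glial_state(arch)
  st$activation_events <- c(TRUE, FALSE, FALSE, FALSE)
  out <- apply_glial_modulation(g, arch, st, glial_config(2, 4))
  expect_equal(out[1], 1.25)      # outgoing weight of input neuron 1
  expect_equal(out[3], 0.3 * 1.25)
  expect_equal(out[c(2, 4:9)], g[c(2, 4:9)])  # everything else untouched
  st$activation_events <- c(FALSE, TRUE, FALSE, FALSE)
  st$depression_events <- c(FALSE, FALSE, TRUE, FALSE)
  out2 <- apply_glial_modulation(g, arch, st, glial_config(2, 4))
  expect_equal(out2[2], -1.0)     # -0.8 * 1.25: sign preserved
  expect_equal(out2[7], 0.3)      # 0.6 * 0.5 on the hidden neuron
  expect_equal(out2[c(5, 6, 9)], g[c(5, 6, 9)])  # biases never touched
})

test_that("a constantly active 1-1 toy cycle ends at 1.25^3", {
  arch <- architecture(c(1, 1), use_bias = FALSE)
  res <- run_pattern_cycle(arch, 1.0, 1.0, 1, glial_config(2, 4))
  expect_equal(res$genome, 1.25^3)
  expect_equal(res$n_activations, 3L)
  expect_equal(res$n_depressions, 0L)
  # final iteration sees 1.25^2 = 1.5625 >= 0.5 -> binary 1 -> error 0
  expect_equal(res$error, 0)
})

test_that("disabled glia makes the cycle a single forward pass, bit-exact", {
  set.seed(15)
  arch <- architecture(c(3, 2, 1))
  g <- runif(genome_length(arch), -1, 1)
  x <- runif(3, -1, 1)
  off <- glial_config(3, 6, enabled = FALSE)
  res <- run_pattern_cycle(arch, g, x, 1, off)
  fp <- forward_pass(arch, g, x)
  expect_identical(res$genome, g)
  expect_identical(res$activations$net_output, fp$net_output)
  expect_identical(res$error, sum((fp$binary_output - 1)^2))
})

test_that("cycle-end weights factor as w0 * 1.25^a * 0.5^d per neuron", {
  set.seed(16)
  for (case in 1:8) {
    arch <- architecture(c(sample(2:4, 1), sample(2:4, 1), 1))
    cfg <- glial_config(sample(2:3, 1), sample(4:8, 1))
    g <- runif(genome_length(arch), -1, 1)
    x <- runif(arch$layer_sizes[1], -1, 1)
    res <- run_pattern_cycle(arch, g, x, 1, cfg)
    s <- arch$layer_sizes
    factors <- 1.25^res$n_activations * 0.5^res$n_depressions
    # outgoing weight block of layer 1 then layer 2 (bias slots skipped)
    w_in <- matrix(g[seq_len(s[1] * s[2])], nrow = s[1])
    w_in_mod <- matrix(res$genome[seq_len(s[1] * s[2])], nrow = s[1])
    expect_equal(w_in_mod, w_in * factors[seq_len(s[1])], tolerance = 1e-12)
    off <- s[1] * s[2] + s[2]
    w_h <- matrix(g[off + seq_len(s[2] * s[3])], nrow = s[2])
    w_h_mod <- matrix(res$genome[off + seq_len(s[2] * s[3])], nrow = s[2])
    expect_equal(w_h_mod, w_h * factors[s[1] + seq_len(s[2])],
                 tolerance = 1e-12)
    # event counts never exceed the per-cycle ceiling
    expect_true(all(res$n_activations <=
                      max_activations(cfg$sensitivity_n, cfg$cycle_m)))
  }
})

test_that("activation ceilings match the printed limits and brute force", {
  expect_equal(max_activations(2, 4), 3L)
  expect_equal(max_activations(3, 6), 4L)
  expect_equal(max_activations(2, 6), 5L)
  expect_equal(max_activations(3, 8), 6L)
  expect_equal(max_activations(5, 5), 1L)
  for (m in 1:8) for (n in 1:m) {
    expect_equal(max_activations(n, m), max_activations(n, m, "enumerate"))
    expect_equal(max_activations(n, m), m - n + 1L)
  }
  expect_error(max_activations(4, 3), "n <= m")
})

test_that("R pattern cycles and the compiled phase-1 sweep agree", {
  set.seed(17)
  arch <- architecture(c(4, 3, 1))
  ds <- toy_dataset(seed = 18, n_per_class = 8)
  Y <- matrix(as.numeric(ds$labels), ncol = 1)
  for (persistence in c("transient", "cumulative")) {
    cfg <- training_config(arch,
                           glia = glial_config(3, 6,
                                               persistence = persistence),
                           ga = ga_config(population_size = 2))
    g <- runif(genome_length(arch), -1, 1)
    # R reference sweep
    gg <- g
    errs <- numeric(nrow(ds$features))
    for (i in seq_len(nrow(ds$features))) {
      start <- if (persistence == "cumulative") gg else g
      rc <- run_pattern_cycle(arch, start, ds$features[i, ], Y[i, ],
                              cfg$glia)
      gg <- rc$genome
      errs[i] <- rc$error
    }
    ind <- phase1_evaluate(list(genome = g, mse = NA_real_), ds, cfg)
    expect_equal(ind$mse, mean(errs), tolerance = 1e-12)
  }
})
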