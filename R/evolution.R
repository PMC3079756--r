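#' Genetic algorithm configuration
#'
#' Settings of the real-valued GA: Montecarlo (fitness-proportionate /
#' roulette-wheel) selection with fitness `1 / (1 + MSE)`, single-point
#' crossover, per-offspring gene-reset mutation, and Darwinian generational
#' substitution with single-individual elitism. Reference settings:
#' population 150 (100 for the Heart Disease problem), crossover rate 0.90,
#' mutation rate 0.10.
#'
#' @param population_size number of individuals (>= 2).
#' @param crossover_rate probability a selected pair exchanges tails.
#' @param mutation_rate probability an offspring has one gene redrawn.
#' @param init_range range of the uniform initial-weight draw (and of
#'   mutation redraws).
#' @param elitism carry the lowest-MSE individual over unchanged.
#' @param seed optional seed for [initialize_population()]; `NULL` uses the
#'   current RNG stream.
#' @return an object of class `ngn_ga`.
#' @export
ga_config <- function(population_size = 150L, crossover_rate = 0.90,
                      mutation_rate = 0.10, init_range = c(-1, 1),
                      elitism = TRUE, seed = NULL) {
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (length(init_range) != 2L || init_range[1] >= init_range[2]) {
    stop("init_range must be an increasing interval")
  }
  structure(list(population_size = population_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 init_range = as.numeric(init_range),
                 elitism = isTRUE(elitism), seed = seed),
            class = "ngn_ga")
}

new_individual <- function(genome, mse = NA_real_) {
  list(genome = genome, mse = mse)
}

new_population <- function(individuals, generation = 0L) {
  structure(list(individuals = individuals,
                 generation = as.integer(generation)),
            class = "ngn_population")
}

#' @export
print.ngn_population <- function(x, ...) {
  mses <- population_mse(x)
  cat(sprintf("<ngn_population> %d individuals, generation %d, best MSE %s\n",
              length(x$individuals), x$generation,
              if (all(is.na(mses))) "unset" else format(min(mses, na.rm = TRUE))))
  invisible(x)
}

#' MSE vector of a population
#'
#' @param pop an `ngn_population`.
#' @return numeric vector of per-individual MSEs (`NA` where unset).
#' @export
population_mse <- function(pop) {
  vapply(pop$individuals, function(ind) ind$mse, numeric(1))
}

#' Best (lowest-MSE) individual of a population
#'
#' @param pop an `ngn_population` with all MSEs set.
#' @return the best individual (list with `genome`, `mse`).
#' @export
best_individual <- function(pop) {
  mses <- population_mse(pop)
  if (anyNA(mses)) stop("all individuals must have an MSE")
  pop$individuals[[which.min(mses)]]
}

#' Initialize a population of random weight genomes
#'
#' Draws `population_size` genomes with i.i.d. uniform weights from
#' `init_range`; deterministic when `cfg$seed` is set. The same initial
#' population seeds both the plain-network and the neuron-glia arm of a
#' paired comparison.
#'
#' @param cfg an `ngn_ga`.
#' @param genome_length genome length (see [genome_length()]).
#' @return an `ngn_population` at generation 0 with unset MSEs.
#' @export
initialize_population <- function(cfg, genome_length) {
  if (genome_length < 1L) stop("genome_length must be positive")
  draw <- function() {
    inds <- vector("list", cfg$population_size)
    for (i in seq_len(cfg$population_size)) {
      inds[[i]] <- new_individual(
        stats::runif(genome_length, cfg$init_range[1], cfg$init_range[2]))
    }
    new_population(inds)
  }
  if (is.null(cfg$seed)) draw() else with_seed(cfg$seed, draw())
}

#' Montecarlo (fitness-proportionate) selection
#'
#' Draws `k` individuals with replacement, each with probability
#' proportional to the fitness `1 / (1 + MSE)`.
#'
#' @param pop an `ngn_population` with all MSEs set.
#' @param k number of individuals to draw.
#' @return a list of `k` individuals.
#' @export
montecarlo_select <- function(pop, k) {
  mses <- population_mse(pop)
  if (anyNA(mses)) stop("all individuals must have an MSE before selection")
  fitness <- 1 / (1 + mses)
  idx <- sample.int(length(fitness), k, replace = TRUE,
                    prob = fitness / sum(fitness))
  pop$individuals[idx]
}

#' Single-point crossover of two genomes
#'
#' With probability `rate`, a cut point is drawn uniformly between
#' positions 1 and L-1 and the tails are swapped; otherwise the parents are
#' returned as-is.
#'
#' @param a,b numeric genomes of equal length.
#' @param rate crossover probability.
#' @return a list of two offspring genomes.
#' @export
single_point_crossover <- function(a, b, rate = 0.90) {
  if (length(a) != length(b)) stop("genome length mismatch")
  L <- length(a)
  if (L >= 2L && stats::runif(1) < rate) {
    cut <- sample.int(L - 1L, 1L)
    tail_idx <- (cut + 1L):L
    tmp <- a[tail_idx]
    a[tail_idx] <- b[tail_idx]
    b[tail_idx] <- tmp
  }
  list(a, b)
}

#' Gene-reset mutation
#'
#' With probability `cfg$mutation_rate` (per offspring), one uniformly
#' chosen gene is replaced by a fresh uniform draw from `cfg$init_range`.
#'
#' @param g numeric genome.
#' @param cfg an `ngn_ga`.
#' @return the (possibly) mutated genome.
#' @export
mutate_genome <- function(g, cfg) {
  if (stats::runif(1) < cfg$mutation_rate) {
    i <- sample.int(length(g), 1L)
    g[i] <- stats::runif(1, cfg$init_range[1], cfg$init_range[2])
  }
  g
}

#' Produce the next generation (Darwinian substitution)
#'
#' Generational replacement: offspring produced by select -> crossover ->
#' mutate fill a population of identical size. With elitism the lowest-MSE
#' individual survives unchanged, carrying its genome and recorded MSE (it
#' is not re-evaluated), which makes the best MSE non-increasing across
#' generations.
#'
#' @param pop an `ngn_population` with all MSEs set.
#' @param cfg an `ngn_ga`.
#' @return the successor `ngn_population` (generation counter incremented);
#'   offspring have unset MSEs.
#' @export
next_generation <- function(pop, cfg) {
  n <- length(pop$individuals)
  new_inds <- vector("list", n)
  filled <- 0L
  if (cfg$elitism) {
    new_inds[[1]] <- best_individual(pop)
    filled <- 1L
  }
  while (filled < n) {
    parents <- montecarlo_select(pop, 2L)
    children <- single_point_crossover(parents[[1]]$genome,
                                       parents[[2]]$genome,
                                       cfg$crossover_rate)
    for (child in children) {
      if (filled < n) {
        filled <- filled + 1L
        new_inds[[filled]] <- new_individual(mutate_genome(child, cfg))
      }
    }
  }
  new_population(new_inds, pop$generation + 1L)
}
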