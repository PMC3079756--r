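#' Glial (astrocyte) configuration
#'
#' Parameters of the artificial astrocyte attached to every non-output
#' neuron. Over a pattern cycle of `cycle_m` iterations a signed activity
#' counter (started at zero) moves +1 when the neuron is active and -1 when
#' it is not, clamped at +/- `sensitivity_n`. Sitting at +n after an active
#' iteration fires an activation event (outgoing weights x (1 +
#' `potentiation_fraction`)); sitting at -n after an inactive iteration
#' fires a depression event (outgoing weights x (1 - `depression_fraction`)).
#' The four reference settings are (n, m) = (2,4), (3,6), (2,6) and (3,8).
#'
#' @param sensitivity_n astrocytic sensitivity n: counter magnitude needed
#'   to stimulate the astrocyte (reference values 2 or 3).
#' @param cycle_m neuron-glia connection power m: iterations per pattern
#'   cycle (reference values 4, 6 or 8); requires `1 <= n <= m`.
#' @param potentiation_fraction fractional weight increase per activation
#'   event (default 0.25).
#' @param depression_fraction fractional weight decrease per depression
#'   event (default 0.50).
#' @param enabled `FALSE` turns the astrocytes off entirely (plain neural
#'   network).
#' @param persistence `"transient"` (default): glial weight changes unfold
#'   within each pattern's cycle and revert before the next pattern, so
#'   training and evaluation are independent of pattern order;
#'   `"cumulative"`: changes persist across the patterns of a sweep.
#'   Cumulative sweeps scale each neuron's outgoing weights by a product of
#'   one factor per pattern, so over long sweeps weights drift by orders of
#'   magnitude and the measured error becomes a property of the sweep
#'   trajectory rather than of the genome; the transient regime keeps the
#'   fitness a pure function of the genome.
#' @return an object of class `ngn_glia`.
#' @export
glial_config <- function(sensitivity_n = 3L, cycle_m = 6L,
                         potentiation_fraction = 0.25,
                         depression_fraction = 0.50,
                         enabled = TRUE,
                         persistence = c("transient", "cumulative")) {
  persistence <- match.arg(persistence)
  sensitivity_n <- as.integer(sensitivity_n)
  cycle_m <- as.integer(cycle_m)
  if (sensitivity_n < 1L || sensitivity_n > cycle_m) {
    stop("need 1 <= sensitivity_n <= cycle_m")
  }
  if (potentiation_fraction < 0 || potentiation_fraction >= 1 ||
      depression_fraction < 0 || depression_fraction >= 1) {
    stop("modulation fractions must lie in [0, 1)")
  }
  structure(list(sensitivity_n = sensitivity_n, cycle_m = cycle_m,
                 potentiation_fraction = potentiation_fraction,
                 depression_fraction = depression_fraction,
                 enabled = isTRUE(enabled), persistence = persistence),
            class = "ngn_glia")
}

#' Parse / format the "n,m" glial notation
#'
#' Configuration files and command lines denote a glial setting as
#' `"n,m"`, e.g. `"3,6"`.
#'
#' @param text a string `"n,m"`.
#' @param ... further arguments passed to [glial_config()].
#' @return `parse_glial_config`: an `ngn_glia`; `format_glial_config`: a
#'   string.
#' @export
parse_glial_config <- function(text, ...) {
  parts <- suppressWarnings(as.integer(strsplit(trimws(text), ",")[[1]]))
  if (length(parts) != 2L || anyNA(parts)) {
    stop("glial configuration must be 'n,m': ", text)
  }
  glial_config(sensitivity_n = parts[1], cycle_m = parts[2], ...)
}

#' @rdname parse_glial_config
#' @param cfg an `ngn_glia`.
#' @export
format_glial_config <- function(cfg) {
  sprintf("%d,%d", cfg$sensitivity_n, cfg$cycle_m)
}

#' Is a neuron active?
#'
#' The activity criterion is the sign of the activation value: strictly
#' positive means active. This applies to tanh outputs of hidden neurons
#' and, for input neurons, to the (normalized, zero-centred) input value.
#'
#' @param activation_value numeric activation value(s).
#' @return logical, `TRUE` where active.
#' @export
is_neuron_active <- function(activation_value) activation_value > 0

#' Fresh astrocyte state for an architecture
#'
#' One zeroed counter per non-output neuron (input and hidden layers), in
#' layer order.
#'
#' @param arch an `ngn_arch`.
#' @return an object of class `ngn_glial_state` with integer `counters` and
#'   logical `activation_events` / `depression_events` for the last update.
#' @export
new_glial_state <- function(arch) {
  s <- arch$layer_sizes
  n <- sum(s[-length(s)])
  structure(list(counters = integer(n),
                 activation_events = logical(n),
                 depression_events = logical(n)),
            class = "ngn_glial_state")
}

#' One iteration of the astrocytic activity counters
#'
#' Active neurons move their counter +1, inactive ones -1, clamped at
#' +/- n. A neuron whose counter sits at +n after an active iteration
#' records an activation event (first arrival and every re-activation at the
#' clamp alike); a counter at -n after an inactive iteration records a
#' depression event.
#'
#' @param state an `ngn_glial_state`.
#' @param active_flags logical vector, one flag per counter.
#' @param cfg an `ngn_glia`.
#' @return the updated `ngn_glial_state`.
#' @export
update_counters <- function(state, active_flags, cfg) {
  if (length(active_flags) != length(state$counters)) {
    stop("one activity flag per counter is required")
  }
  n <- cfg$sensitivity_n
  up <- pmin(state$counters + 1L, n)
  down <- pmax(state$counters - 1L, -n)
  state$counters <- ifelse(active_flags, up, down)
  state$activation_events <- active_flags & state$counters == n
  state$depression_events <- !active_flags & state$counters == -n
  state
}

#' Apply glial weight modulation for the current iteration's events
#'
#' Every outgoing weight of a neuron with an activation event is multiplied
#' by `1 + potentiation_fraction`; with a depression event, by
#' `1 - depression_fraction`. Modulation is multiplicative on the signed
#' weight (sign preserved, magnitude scaled); biases and all other weights
#' are untouched. Output neurons have no outgoing weights and carry no
#' astrocyte.
#'
#' @param genome numeric weight genome.
#' @param arch an `ngn_arch`.
#' @param state an `ngn_glial_state` holding the current iteration's events.
#' @param cfg an `ngn_glia`.
#' @return the modulated genome.
#' @export
apply_glial_modulation <- function(genome, arch, state, cfg) {
  s <- arch$layer_sizes
  L <- length(s)
  if (length(state$counters) != sum(s[-L])) stop("state/architecture mismatch")
  blocks <- genome_blocks(arch)
  pos <- 0L
  up <- 1 + cfg$potentiation_fraction
  dn <- 1 - cfg$depression_fraction
  for (k in seq_len(L - 1L)) {
    a_ev <- state$activation_events[pos + seq_len(s[k])]
    d_ev <- state$depression_events[pos + seq_len(s[k])]
    if (any(a_ev) || any(d_ev)) {
      idx <- blocks$w_off[k] + seq_len(s[k] * s[k + 1L])
      W <- matrix(genome[idx], nrow = s[k])
      if (any(a_ev)) W[a_ev, ] <- W[a_ev, , drop = FALSE] * up
      if (any(d_ev)) W[d_ev, ] <- W[d_ev, , drop = FALSE] * dn
      genome[idx] <- as.numeric(W)
    }
    pos <- pos + s[k]
  }
  genome
}

#' Present one pattern for a full glial cycle
#'
#' Presents the pattern for `cycle_m` consecutive iterations with the
#' astrocyte counters reset to zero at the start. Each iteration runs a
#' forward pass with the current weights, derives activity flags from the
#' activations, updates the counters, and applies the weight modulation —
#' so a weight change takes effect from the next iteration on. The pattern
#' error is the squared difference between the final iteration's binary
#' output and the target, summed over output neurons. The glial rule never
#' reads the target: phase-1 learning is unsupervised.
#'
#' With `cfg$enabled = FALSE` this is exactly one forward pass and the
#' genome is returned unchanged.
#'
#' @param arch an `ngn_arch`.
#' @param genome numeric weight genome.
#' @param pattern input vector.
#' @param target binary/one-hot target vector (length = output layer size).
#' @param cfg an `ngn_glia`.
#' @return a list with `genome` (cycle-end weights), `activations` (final
#'   iteration forward pass), `error`, and per-neuron event tallies
#'   `n_activations` / `n_depressions`.
#' @export
run_pattern_cycle <- function(arch, genome, pattern, target, cfg) {
  n_out <- arch$layer_sizes[length(arch$layer_sizes)]
  if (length(target) != n_out) stop("target length must equal output width")
  if (!cfg$enabled) {
    fp <- forward_pass(arch, genome, pattern)
    return(list(genome = genome, activations = fp,
                error = sum((fp$binary_output - target)^2),
                n_activations = integer(0), n_depressions = integer(0)))
  }
  state <- new_glial_state(arch)
  n_nonout <- length(state$counters)
  tally_a <- integer(n_nonout)
  tally_d <- integer(n_nonout)
  fp <- NULL
  for (it in seq_len(cfg$cycle_m)) {
    fp <- forward_pass(arch, genome, pattern)
    flags <- is_neuron_active(
      unlist(fp$activations[-length(fp$activations)], use.names = FALSE))
    state <- update_counters(state, flags, cfg)
    tally_a <- tally_a + state$activation_events
    tally_d <- tally_d + state$depression_events
    genome <- apply_glial_modulation(genome, arch, state, cfg)
  }
  list(genome = genome, activations = fp,
       error = sum((fp$binary_output - target)^2),
       n_activations = tally_a, n_depressions = tally_d)
}

# activation events produced by one activity sequence on a single counter
count_activation_events <- function(flags, n) {
  counter <- 0L
  events <- 0L
  for (f in flags) {
    counter <- if (f) min(counter + 1L, n) else max(counter - 1L, -n)
    if (f && counter == n) events <- events + 1L
  }
  events
}

#' Maximum astrocytic activations in one pattern cycle
#'
#' The largest number of activation events a single astrocyte can fire
#' within one m-iteration cycle starting from a zero counter. The default
#' method simulates the counter dynamics of a continuously active neuron;
#' `method = "enumerate"` exhaustively simulates all `2^m` activity
#' sequences and maximizes (independent brute-force check, m <= 16).
#' The four reference settings (2,4), (3,6), (2,6), (3,8) allow 3, 4, 5 and
#' 6 activations respectively.
#'
#' @param n astrocytic sensitivity, `1 <= n <= m`.
#' @param m pattern-cycle length.
#' @param method `"simulate"` (always-active neuron) or `"enumerate"`.
#' @return integer activation count.
#' @export
#' @examples
#' max_activations(2, 4)  # 3
#' max_activations(3, 8)  # 6
max_activations <- function(n, m, method = c("simulate", "enumerate")) {
  method <- match.arg(method)
  n <- as.integer(n); m <- as.integer(m)
  if (n < 1L || n > m) stop("need 1 <= n <= m")
  if (method == "simulate") {
    count_activation_events(rep(TRUE, m), n)
  } else {
    if (m > 16L) stop("exhaustive enumeration supported for m <= 16")
    best <- 0L
    for (bits in 0:(2^m - 1L)) {
      flags <- bitwAnd(bits, bitwShiftL(1L, 0:(m - 1L))) != 0L
      best <- max(best, count_activation_events(flags, n))
    }
    best
  }
}
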