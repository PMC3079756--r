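#' Feed-forward network architecture
#'
#' Layer sizes plus the activation scheme: hyperbolic tangent in the hidden
#' layers and a threshold function on the output layer (net input >= 0.5
#' gives a binary 1). Biases, when enabled, add one adjustable threshold per
#' non-input neuron; they take part in the genetic search but are never
#' touched by glial modulation. Disable them for a strict
#' weights-only network.
#'
#' @param layer_sizes integer vector, input layer first, output last; at
#'   least two layers (toy direct input-output nets are allowed
#'   programmatically; the dash notation of [parse_architecture()] requires
#'   a hidden layer).
#' @param use_bias include one bias per non-input neuron (default `TRUE`).
#' @param output_threshold threshold on the output net input (default 0.5).
#' @return an object of class `ngn_arch`.
#' @export
architecture <- function(layer_sizes, use_bias = TRUE, output_threshold = 0.5) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes must be >= 2 positive integers")
  }
  structure(list(layer_sizes = layer_sizes, use_bias = isTRUE(use_bias),
                 output_threshold = output_threshold),
            class = "ngn_arch")
}

#' Parse a dash-notation architecture string
#'
#' Architecture strings such as `"13-4-1"` or `"34-34-18-1"` list the layer
#' sizes from input to output; at least one hidden layer is required.
#'
#' @param text dash-separated positive integers, e.g. `"9-7-1"`.
#' @inheritParams architecture
#' @return an `ngn_arch`.
#' @export
#' @examples
#' neuron_count(parse_architecture("34-34-18-1"))  # 87
parse_architecture <- function(text, use_bias = TRUE, output_threshold = 0.5) {
  parts <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  sizes <- suppressWarnings(as.integer(parts))
  if (length(sizes) < 3L || anyNA(sizes) || any(sizes < 1L) ||
      any(parts != as.character(sizes))) {
    stop("malformed architecture string: ", text)
  }
  architecture(sizes, use_bias = use_bias, output_threshold = output_threshold)
}

#' @export
print.ngn_arch <- function(x, ...) {
  cat(sprintf("<ngn_arch> %s (%d neurons%s)\n",
              paste(x$layer_sizes, collapse = "-"), neuron_count(x),
              if (x$use_bias) ", biased" else ""))
  invisible(x)
}

#' Total neuron count of an architecture
#'
#' @param arch an `ngn_arch`.
#' @return sum of the layer sizes.
#' @export
neuron_count <- function(arch) sum(arch$layer_sizes)

#' Length of the flat weight genome for an architecture
#'
#' The genome stores, for each consecutive layer pair k -> k+1 in order:
#' the weight block (source index varying fastest, destination-major), then
#' — when biases are enabled — one bias per destination neuron. Crossover
#' points therefore have a fixed, reproducible meaning.
#'
#' @param arch an `ngn_arch`.
#' @return integer genome length.
#' @export
genome_length <- function(arch) {
  s <- arch$layer_sizes
  L <- length(s)
  n <- sum(s[-L] * s[-1])
  if (arch$use_bias) n <- n + sum(s[-1])
  as.integer(n)
}

# offsets of the weight/bias blocks for layer pair k (1-based), internal
genome_blocks <- function(arch) {
  s <- arch$layer_sizes
  L <- length(s)
  w_off <- integer(L - 1L); b_off <- integer(L - 1L)
  off <- 0L
  for (k in seq_len(L - 1L)) {
    w_off[k] <- off
    off <- off + s[k] * s[k + 1L]
    if (arch$use_bias) {
      b_off[k] <- off
      off <- off + s[k + 1L]
    } else b_off[k] <- NA_integer_
  }
  list(w_off = w_off, b_off = b_off, total = off)
}

#' Forward pass through the network
#'
#' Propagates one input pattern: the input layer passes values through
#' unchanged, hidden neurons output `tanh(weighted sum + bias)`, and each
#' output neuron's net input is compared against the output threshold
#' (inclusive) to give a binary 0/1. The raw output net inputs are retained
#' for argmax-based multiclass prediction.
#'
#' @param arch an `ngn_arch`.
#' @param genome numeric weight vector of length `genome_length(arch)`.
#' @param pattern numeric input vector, length = input layer size.
#' @return a list with `activations` (per-layer values; the output layer
#'   entry holds the net inputs), `net_output`, and `binary_output`
#'   (integer 0/1 per output neuron).
#' @export
forward_pass <- function(arch, genome, pattern) {
  s <- arch$layer_sizes
  L <- length(s)
  if (length(pattern) != s[1]) stop("pattern length must equal input layer size")
  if (length(genome) != genome_length(arch)) stop("genome length mismatch")
  act <- vector("list", L)
  act[[1]] <- as.numeric(pattern)
  off <- 0L
  for (k in seq_len(L - 1L)) {
    W <- matrix(genome[off + seq_len(s[k] * s[k + 1L])], nrow = s[k])
    off <- off + s[k] * s[k + 1L]
    net <- drop(crossprod(W, act[[k]]))
    if (arch$use_bias) {
      net <- net + genome[off + seq_len(s[k + 1L])]
      off <- off + s[k + 1L]
    }
    act[[k + 1L]] <- if (k < L - 1L) tanh(net) else net
  }
  list(activations = act,
       net_output = act[[L]],
       binary_output = as.integer(act[[L]] >= arch$output_threshold))
}

#' Predict the class of a pattern
#'
#' Single-output networks predict the thresholded binary output; networks
#' with several output neurons predict the argmax of the output net inputs
#' (ties broken towards the lowest index).
#'
#' @inheritParams forward_pass
#' @return a 0-based class index.
#' @export
predict_class <- function(arch, genome, pattern) {
  fp <- forward_pass(arch, genome, pattern)
  if (length(fp$net_output) == 1L) fp$binary_output else
    which.max(fp$net_output) - 1L
}

# target matrix for a dataset given the output layer width: a 0/1 column for
# binary problems, one-hot rows for multiclass
target_matrix <- function(ds, n_outputs) {
  if (n_outputs == 1L) {
    if (ds$n_classes != 2L) {
      stop("a single-output network needs a binary problem")
    }
    matrix(as.numeric(ds$labels), ncol = 1L)
  } else {
    if (n_outputs != ds$n_classes) {
      stop("output layer width must equal the class count")
    }
    Y <- matrix(0, nrow = length(ds$labels), ncol = n_outputs)
    Y[cbind(seq_along(ds$labels), ds$labels + 1L)] <- 1
    Y
  }
}
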