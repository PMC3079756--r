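---
title: "Artificial neuron-glia networks: model, training method and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial neuron-glia networks: model, training method and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliann)
```

## The model

`gliann` implements feed-forward classification networks in which every
non-output neuron carries an *artificial astrocyte*, a unit inspired by the
glial cells that surround biological synapses and modulate transmission on a
slower time scale than neuronal spiking. The network itself is conventional:
hidden neurons apply the hyperbolic tangent to their weighted input (plus an
adjustable bias), and each output neuron compares its raw net input against a
threshold of 0.5 to emit a binary 0/1. Single-output networks read the binary
output as the class; multi-output networks take the argmax of the output net
inputs (ties resolve to the lowest index).

The astrocyte watches its neuron over a *pattern cycle*: each input pattern is
presented for `m` consecutive iterations (`m` in 4, 6, 8). A signed activity
counter starts at 0 and moves +1 on each iteration in which the neuron is
active (activation strictly positive) and −1 otherwise, clamped at ±`n`
(`n` in 2, 3, the *astrocytic sensitivity*). Whenever the counter sits at
+`n` after an active iteration, the astrocyte fires an *activation event* and
multiplies all of the neuron's outgoing weights by 1.25; whenever it sits at
−`n` after an inactive iteration, a *depression event* multiplies them by
0.5. Both events repeat while the counter stays pinned at the clamp, so a
continuously active neuron collects `m − n + 1` activation events per cycle —
3, 4, 5 and 6 for the reference settings (2,4), (3,6), (2,6) and (3,8). The
asymmetry (25% up, 50% down) means only consistently active neurons keep
strengthened connections. Biases are never modulated, and output neurons
carry no astrocyte (they have no outgoing connections). Modulation is
multiplicative on the signed weight, so a weight's sign never changes.

Within an iteration the order is: forward pass, counter update, weight
modulation — a weight change takes effect from the next iteration on, so the
first iteration of every cycle reflects the inherited weights alone.

## Two-phase hybrid training

Training alternates two phases over a population of weight genomes (a genome
is the flat vector of all connection weights and biases, laid out layer pair
by layer pair, destination-major, with each layer's biases after its weight
block — a fixed layout so crossover points are reproducible).

*Phase 1 (unsupervised glial modulation).* Every training pattern is
presented to each candidate network for a full pattern cycle, with the
counters reset at each cycle start. The error of a pattern is the squared
difference between the final iteration's binary output and the target
(summed over output neurons); the MSE of the individual is the mean over
patterns. The glial rule never sees the target — weight changes during the
cycle depend only on activity.

*Phase 2 (genetic algorithm).* Fitness-proportionate ("Montecarlo")
selection with fitness `1/(1 + MSE)`, single-point crossover at rate 0.9,
per-offspring single-gene reset mutation at rate 0.1 drawing from the
initial-weight range, and generational replacement with single-individual
elitism. The elite carries both its genome and its recorded MSE into the
next generation and is not re-evaluated, which makes the best MSE
non-increasing by construction. Reference population sizes are 150 (100 for
the 13-input heart-disease problem); the desk-scale default is 30.

With the glia disabled, phase 1 degenerates to one plain forward pass per
pattern and the identical code path trains an ordinary GA neural network —
the two arms of every comparison share all GA code, and setting both
modulation fractions to zero reproduces the disabled arm bit for bit.

### Glial persistence: a design decision

The reference description of phase 1 can be read in two ways, and the choice
matters enormously.

Under a **cumulative** reading, glial weight changes persist from one
pattern's cycle to the next throughout the sweep. One sweep then multiplies
each neuron's outgoing weights by one factor per pattern (up to 1.25^4 or
0.5^4 at (3,6)), i.e. by an exponential in the number of training patterns:
with 100 patterns, weights drift by tens of orders of magnitude within a
single evaluation. The measured MSE becomes a property of the weight
*trajectory* rather than of the genome: re-running a sweep from the stored
genome does not reproduce it, steady accuracies computed from the stored
genome sit at chance, and the GA can even exploit class-blocked pattern
order by encoding the labels in the drift itself. Writing the swept genome
back into the population (Lamarckian inheritance) compounds the drift across
generations and collapses weights numerically (we measured magnitudes near
1e-80 after 300 generations).

Under the **transient** reading, the modulation unfolds within each
pattern's cycle and reverts before the next pattern: the cycle acts as a
deterministic, activity-dependent reweighting of the network, pattern by
pattern. Fitness is then a pure function of the genome, evaluation is
independent of pattern order, and the training accuracy of a genome is
exactly consistent with its MSE.

`glial_config(persistence =)` implements both; `"transient"` is the default
for the reasons above, `"cumulative"` (with an optional Lamarckian
write-back switch in `training_config()`) is retained for studying the
literal cumulative regime. Evaluation follows the same regime as training:
`evaluate_with_glia()` uses a per-pattern scratch copy under transient glia
("reset" mode) and a cumulative scratch sweep under cumulative glia
("sweep" mode); the stored genome is never altered by evaluation.

## Datasets and the synthetic generator

`load_delimited()` reads delimited text (UCI-style `.data` files work with
the defaults), maps class values to 0-based indices in first-appearance
order, and drops rows containing the missing-value token (the pragmatic
choice for the `?` cells of the Cleveland heart-disease file — dropping
avoids inventing an imputation scheme). `normalize_dataset()` rescales every
feature linearly to [−1, 1]; this matters because the activity criterion is
a sign test, so inputs must be centred around zero. Constant columns map
to 0.

`generate_gaussian_dataset()` provides an offline stand-in for benchmark
data: `n_classes` isotropic unit-variance Gaussians whose means sit on a
scaled simplex of unit vectors, so every pair of class means is exactly
`separation` apart (this requires `n_classes <= n_inputs`). Rows are
emitted in shuffled class order: with class-blocked rows a cumulative glial
sweep can encode the labels in its weight drift, which says nothing about
the inputs. The generator emulates the tabular geometry of the benchmark
problems (balanced classes, moderate overlap) but none of their structure —
correlated features, irrelevant features, label noise, class imbalance — so
tests passing on synthetic data demonstrate the machinery, not real-world
accuracy.

## Evaluation protocol

`run_protocol()` reproduces the paired comparison design: stratified 2-fold
cross-validation repeated `n_cv_repetitions` times (5 by default), crossed
with `n_weight_populations` (10) initial-weight populations — 100 paired
runs at the defaults. For each (split, population) pair the plain network
and the neuron-glia network start from the *same* initial population on the
*same* fold. Per run it records:

* **steady accuracy** — training/test accuracy at the last snapshot;
* **time to 95%** — the first snapshot generation reaching 95% of the
  steady accuracy (resolution limited by `eval_every`, 10 generations by
  default). Times are reported in generations, not minutes: wall-clock stop
  times are hardware-bound and irreproducible, a generation budget is not.

Aggregates report mean ± SEM, the **performance index** (ratio of NGN to NN
mean steady accuracy; > 1 means the astrocytes helped), and two-sided paired
Wilcoxon signed-rank tests (via `stats::wilcox.test`; all-zero difference
vectors return p = 1 by convention, and protocols with fewer than 5 paired
runs report `NA`). Stars render at p < 0.05 / 0.01 / 0.001.

`run_grid()` sweeps problems × architectures × glial settings, writes each
cell's paired records and summary, and pools performance indexes by
hidden-layer count and by problem. `best_glial_config()` selects, per
problem, the glial setting with the highest mean steady test accuracy — the
selection criterion is not fixed by the reference material, and steady test
accuracy is the natural choice when the goal is generalization.

## Numerical and scale choices

* Output threshold comparison is inclusive (net ≥ 0.5 → 1); "active" is
  strictly positive — both fixed conventions so exact tests are possible.
* Initial weights are uniform on [−1, 1]; mutation redraws from the same
  range.
* Training-pattern order is the dataset order; under the default transient
  glia nothing depends on it.
* Desk-scale defaults (population 30, 300 generations, 200-pattern
  synthetic sets, 1 cross-validation repetition) keep a full paired
  comparison in the range of minutes on one core. The reference experiments
  used populations of 100-150 and training periods equivalent to ~5000
  generations on a compute cluster; at desk scale the neuron-glia arm
  converges more slowly than the plain arm and typically only matches it,
  so desk-scale runs demonstrate the protocol, not the published effect
  sizes.
* The phase-1 inner loop (pattern cycles over all patterns and individuals)
  is compiled (Rcpp); the R-level `run_pattern_cycle()` implements the same
  semantics and the test suite asserts the two agree to 1e-12.

## Known limitations

* No astrocyte-astrocyte communication or spatial spread of the glial
  signal; one astrocyte per neuron, acting only on that neuron's outgoing
  connections.
* No gradient-based training, no recurrent connections.
* The binary (thresholded) error makes the fitness landscape piecewise
  constant; GA progress relies on population diversity, and small
  populations can stall.
* Multiclass problems require one output neuron per class; a single-output
  network is binary only.
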