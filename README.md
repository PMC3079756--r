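# gliann — artificial neuron-glia networks

`gliann` is an R package for training and evaluating *neuron-glia networks*
(NGN): feed-forward classification networks in which every non-output neuron
carries an artificial astrocyte, a unit modelled on the glial cells that
sense synaptic activity and modulate transmission on a slower time scale
than neuronal signalling. It is aimed at researchers in bio-inspired machine
learning and computational neuroscience who want to quantify what
activity-dependent glial weight modulation adds to a genetic-algorithm-
trained network under a controlled, paired protocol.

## The model in brief

Networks are ordinary multilayer perceptrons — `tanh` hidden units, a
threshold of 0.5 on each output's net input giving a binary 0/1 — described
by dash notation such as `9-7-1` or `34-34-18-1`. Each input pattern is
presented for a *pattern cycle* of `m` iterations. Every non-output neuron
has a signed activity counter, started at 0, moved +1 when the neuron is
active (activation > 0) and −1 otherwise, and clamped at ±`n`:

* counter at +`n` after an active iteration → *activation event*: all the
  neuron's outgoing weights are multiplied by **1.25**;
* counter at −`n` after an inactive iteration → *depression event*:
  outgoing weights are multiplied by **0.5**.

Events repeat at the clamp, so one cycle permits at most `m − n + 1`
activation events — 3, 4, 5, 6 for the reference settings
(n,m) = (2,4), (3,6), (2,6), (3,8). Training is a two-phase hybrid: phase 1
measures each candidate's mean squared error while the glial modulation
unfolds (unsupervised — the rule never sees the target); phase 2 is one
generation of a real-valued GA (fitness-proportionate selection with fitness
1/(1+MSE), single-point crossover at 0.9, gene-reset mutation at 0.1,
elitist generational replacement). With glia disabled the same code trains
the plain network used as the comparison baseline.

The evaluation protocol pairs the two arms: stratified 5×2 cross-validation
crossed with 10 initial-weight populations gives 100 paired runs per
configuration, summarized by steady accuracies, 95%-of-steady convergence
times (in generations), NGN/NN performance indexes and paired Wilcoxon
signed-rank tests.

## Worked example

```r
library(gliann)

ds <- normalize_dataset(generate_gaussian_dataset(
  n_per_class = 60, n_inputs = 4, n_classes = 2, separation = 3, seed = 42))
ds
#> <ngn_dataset> gaussian_s3: 120 patterns, 4 inputs, 2 classes

cfg <- protocol_config(
  training_config(parse_architecture("4-3-1"),
                  glia = glial_config(3, 6),
                  ga = ga_config(population_size = 20),
                  max_generations = 100, eval_every = 10),
  n_cv_repetitions = 2, n_weight_populations = 3, base_seed = 1)

run_protocol(ds, cfg)
#> <ngn_comparison> gaussian_s3, arch 4-3-1, glia 3,6 (12 paired runs)
#>   steady train acc: NN 0.940+-0.012 vs NGN 0.933+-0.012
#>   steady test acc:  NN 0.886+-0.014 vs NGN 0.878+-0.021
#>   performance index: training 0.993, test 0.991
```

The comparison ran 12 paired trainings (2 repetitions × 2 folds × 3
initial populations): for each pair, the plain network (NN) and the
neuron-glia network (NGN, glial setting n = 3, m = 6) started from the same
initial weight population on the same stratified half-split. Steady
accuracies are the values at the end of the 100-generation budget
(mean ± SEM over the 12 runs); the performance index is the ratio of NGN to
NN mean steady accuracy, so values near 1 mean the astrocytes neither
helped nor hurt on this easy low-dimensional surrogate. At this desk scale
the glial arm typically needs more generations than the plain arm to reach
its plateau; the published effect sizes came from populations of 100–150
run for the equivalent of thousands of generations.

Other entry points: `train_network()` for a single run (returns the
snapshot history), `evaluate_with_glia()` for test-phase accuracy under a
glial setting, `run_grid()` for problems × architectures × glial-settings
sweeps with pooled performance-index tables, and `inst/cli/gliann.R` for a
command-line front end (`train`, `compare`, `grid` subcommands).

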