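---
title: "Searching neural architectures for genomic sequence classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching neural architectures for genomic sequence classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`genarch` automates the design of convolutional and recurrent neural networks
for DNA sequence classification. This vignette explains the model behind the
package: the search space and its conditioning, the deterministic expansion of
a configuration into a network, the surrogate-assisted optimization loop, the
training rules, and the synthetic data the package uses to validate itself —
together with the numerical choices and their limitations.

```{r setup, message = FALSE}
library(genarch)
```

## The template and its search space

Most successful sequence classifiers share a three-stage shape: a trunk of
convolutional layers reading one-hot encoded nucleotides (channels A, C, G,
T), an embedding stage that collapses the position axis — either global
average pooling (GAP) over selected blocks, or a stack of recurrent layers —
and a fully connected classifier. `define_search_space()` parameterizes this
template rather than individual layers: directly parameterizing every layer
would create conditional dimensions (layer 7's kernel size only exists when
there are 7 layers), which substantially complicates surrogate modelling.
Instead only the first and last layers are searched and intermediate layers
are interpolated (see below), so the space has a fixed dimension.

```{r}
sp <- define_search_space(150, "gap", residual = FALSE)
sp
```

Parameters that matter most, with units and defaults:

* `n_conv_layers` (1–20) and `n_conv_blocks` (1–10) jointly set the trunk
  depth; the realized depth is `N_cb * s_cb` (see the block rules below).
* `kernel_size_0/end` (16–2048 positions, log scale) — motif detector width.
* `filters_0/end` (2–64, log scale) — motif detectors per layer. These are
  kept *continuous* in the space and materialized by ceiling in the builder,
  which matches the ceiling in the interpolation formulas and keeps the
  surrogate's input space smooth.
* `dilation_end`, `max_pooling_end` — both length-dependent: their upper
  bound is $2^4$ for read-scale inputs (150 or 250 nt) and $2^7$ for 10 kb
  contigs, because a 150-nt window neither permits nor needs a 128-fold
  reduction of the position axis.
* `skip_ratio` (GAP family only, 0–1): the leading fraction of blocks whose
  outputs are *not* tapped for pooling. Early layers encode low-level motifs
  whose frequencies are often less class-discriminative.
* training parameters: learning rate ($10^{-6}$–$10^{-2}$, log),
  optimizer (Adam/Adagrad/RMSprop/SGD), batch-norm momentum, leaky-ReLU
  slope, dense dropout, and whether the reverse complement is fed as an
  additional input.

Two choices condition the space instead of being searched: the model family
(GAP vs RNN) and the residual flag. Their optima differ enough that each of
the (length × family × residual) combinations is best optimized as an
independent run — a fully crossed design — and keeping them as constants
makes every configuration self-describing. The reference space lists "model
type" as a categorical; we deliberately follow the crossed design instead,
since independent runs parallelize trivially and avoid a mixed-family
surrogate.

## From configuration to network

`build_plan()` expands a configuration deterministically. The block
structure is

$$N_{cb} = \begin{cases} n_c & n_c \le n_{cb} \\ n_{cb} & \text{else}\end{cases},
\qquad s_{cb} = \mathrm{round}(n_c / N_{cb}), \qquad N_c = N_{cb}\, s_{cb},$$

so every block has the same integer number of layers and the realized depth
approximates `n_conv_layers`. `round()` here is *half away from zero* — the
common mathematical convention — and the tests pin this so the behaviour
cannot drift silently (R's own `round()` rounds half to even).

Filters and kernels interpolate exponentially between their first/last
values; under residual blocks the filter count is interpolated block-wise
because a shortcut addition needs equal widths within a block. Dilation
grows exponentially from 1 to `dilation_end` *within* each block and resets
at block boundaries. Degenerate cases are defined explicitly:

* one layer total: `ceil(f_0)` filters, `ceil(k_0)` kernel;
* `s_cb = 1`: the within-block dilation exponent is 0/0; dilation is 1
  (growth "from 1" never starts);
* residual with `N_cb = 1`: the block-wise exponent is 0/0; all layers use
  `ceil(f_0)`.

Max-pooling sites exist after every convolutional layer; the exponent budget
`round(log2 p_end)` is spread as evenly as possible with the remainder
assigned to the *latest* sites, keeping early layers at full resolution
while still reducing length exponentially along the trunk. The GAP head taps
the last $\max(1, \lceil (1-r_s) N_{cb}\rceil)$ block outputs — at least one
block is always pooled.

Every dilated kernel must fit in the sequence length remaining at its layer
(`dilation * (kernel - 1) + 1` positions). Configurations violating this are
not silently clipped: `build_plan()` raises a typed error naming the layer,
and the optimizer records such evaluations with objective 0. This is
deliberate — clipping would make the builder non-faithful to the sampled
configuration and bias the search toward layouts that were never actually
evaluated.

```{r}
cfg <- as_config(sample_configs(sp, 1, seed = 42))
cfg$kernel_size_0 <- 16; cfg$kernel_size_end <- 24
cfg$dilation_end <- 1;   cfg$max_pooling_end <- 4
plan <- build_plan(cfg, sp, n_classes = 3)
count_parameters(plan)$by_stage
```

Further design choices where the template is genuinely open:

* **Residual shortcut path.** When a block changes channel count, the
  shortcut uses a width-1 convolution projection (standard ResNet practice);
  when the block pools internally, the same total pooling is applied on the
  shortcut. Pooling may therefore fall inside residual blocks.
* **Batch normalization** sits after each convolution, before the
  leaky-ReLU, with the searched momentum; running statistics are
  bias-corrected (Adam-style) so early-training predictions are not dominated
  by the zero initialization.
* **RNN head.** All recurrent layers return per-position outputs; the last
  layer's outputs are flattened over positions rather than truncated to the
  final state, preserving positional information for the dense stage.
* **Reverse-complement fusion.** Both strands pass through the *shared*
  trunk and head, and the two embeddings are concatenated before the dense
  stage. This keeps parameter counts stable (only the first dense layer's
  input doubles) and mirrors published reverse-complement architectures; the
  exact fusion point is not fixed by prior work, so this is a package
  decision.
* **Dropout** applies only within the dense stack, where the space defines
  it.

`count_parameters()` gives a closed-form count by stage (convolution, head,
dense, output); `instantiate()` materializes the plan in the package's own
numeric backend, and the two are cross-checked against each other in the
test suite. The backend implements exactly the layer vocabulary of the plans
(same-padding dilated convolution, batch norm, leaky ReLU, max pooling,
residual addition, GAP, LSTM/GRU with one bias set per gate stack,
bidirectionality by concatenation, dense layers with inverted dropout,
softmax with multi-class cross-entropy) and all four optimizers; its
gradients are verified against finite differences in the tests.

## The optimization loop

The objective — validation balanced accuracy of a budget-trained model — is
expensive and noisy, so the search is model-based. Configurations are
encoded into the unit cube (log-scaled numerics affinely, booleans to
\{0,1\}, categoricals one-hot, arg-max decoding with ties to the first
listed value) and a Gaussian process with an isotropic Matérn-3/2 kernel is
fitted to all (encoding, objective) records; kernel length-scale, signal and
noise variances are estimated by marginal likelihood.

Proposals use the upper-confidence-bound rule: score a candidate by
$\mu(x) + \lambda\,\sigma(x)$. For a batch of `q` proposals (default 3,
matching evaluation on a few workers at a time), one $\lambda$ per proposal
is drawn from an exponential distribution — small $\lambda$s exploit, large
ones explore, and the spread makes the batch diverse. The exponential rate
is 1 and configurable; the reference procedure samples $\lambda$
exponentially but does not state the rate. Each acquisition is maximized by
1000 random candidates followed by two coordinate-descent sweeps over the
best 10, a budget that is deterministic under seed and cheap relative to one
objective evaluation. Decoded duplicates are re-drawn.

**Multi-fidelity warm starts.** The search first runs with a short training
budget $t_1$ per evaluation; a second stage at $t_2 > t_1$ then starts with
*no* fresh initial design — the surrogate is fitted to all previous records,
with the log training budget appended to the encoding as one extra
coordinate. Cheap evaluations thus inform the expensive stage without being
conflated with it: the GP can learn both the shared structure and a
fidelity trend. (Pooling records without a fidelity coordinate is the main
alternative; the extra-coordinate form is the minimal mechanism that keeps
the fidelities distinguishable.) The initial design is a Latin hypercube of
size `max(8, 4 × numeric dimensions)` by default — a standard sizing rule;
the reference procedure does not state one.

Objectives are extracted from the validation trace differently per phase:
phase 1 takes the **maximum** balanced accuracy anywhere in the trace (short
runs rarely overfit), phase 2 the **second-highest of the last 20**
validation evaluations, which stops a single noisy spike from promoting an
unstable model. Failed evaluations (unbuildable plans, diverged training)
score 0 and the search continues.

## Training rules

`train_with_budget()` validates every `budget / target_validation_evals`
steps (about 20 evaluations in a short phase, about 100 in a long one, at
reference scale). After each validation:

* the learning rate halves when 3 consecutive evaluations fail to exceed the
  running-best balanced accuracy ("did not increase" is read against the
  running best, the standard plateau semantics; reading it against the
  immediately preceding value would halve on any oscillation). The
  stagnation counter resets after a halving, the running best does not.
* training stops when 10 consecutive evaluations fail to improve — so by the
  time early stopping fires, the schedule has already halved at least twice
  (at counters 3, 6 and 9 within the same stagnation run).

Wall-time budgets are translated to step budgets via one timed warm-up step,
keeping validation cadence hardware-independent; step budgets are exact and
are what the desk-scale tests use, because they make runs bit-reproducible.
`find_max_batch_size()` binary-searches the largest batch a memory probe
accepts and returns 90% of it (floor, minimum 1) as a safety margin.

Batches are class-balanced: with $k$ classes, every batch holds exactly
`batch_size / k` windows per class, so minority classes are oversampled
simply by contributing to every batch. On each file visit a fresh random
start offset is drawn and consecutive non-overlapping windows are emitted —
re-reads of the same genome in later epochs therefore see shifted windows.
Test iteration is the opposite: files in listed order, windows from position
1, tail fragments dropped, no randomness. Ambiguous IUPAC bases one-hot
encode as all-zero columns: they preserve the reading frame while
contributing nothing to convolutions (how ambiguity was handled at reference
scale is unstated; zeroing is the least-informative choice). Windows never
span record boundaries.

All reported accuracies are **class-balanced** (mean per-class recall),
because test collections are typically heavily imbalanced.

## Synthetic fixtures, and what they do and do not show

`generate_genomes()` writes i.i.d.-background genomes with class-specific
k-mers overwritten at Poisson-placed positions (overwriting keeps the genome
length exact; overlapping insertions resolve last-writer-wins, so realized
density is slightly below nominal). `fixture_suite("tiny")` builds 3 classes
× 6 files × 5 kb with one disjoint 8-mer per class at 25 insertions/kb and a
70/20/10 file-level split.

The density default is an analytic choice, fixed before any experiment: a
150-nt window contains at least one motif with probability
$1 - e^{-0.025 \times 150} \approx 0.98$, so a window-level classifier has a
balanced-accuracy ceiling near 0.985 and the end-to-end loop has headroom to
demonstrate learning. At a few insertions per kb, most windows carry no
signal and even a perfect classifier cannot exceed ~0.7 balanced accuracy at
window level — at that density the classes remain separable only at
*genome* level (motif counts over 5 kb), which the test suite demonstrates
with a multinomial logistic oracle.

What passing on these fixtures shows: the search loop, builder, backend and
harness interact correctly end to end, and the optimizer finds
configurations whose trained models approach the fixture's ceiling. What it
does not show: performance on real genomes, where signal is distributed,
compositional biases exist, classes overlap, and models orders of magnitude
larger are required. The fixtures are a correctness instrument, not a
benchmark.

## Desk-scale profile and problem sizes

The package's tests and acceptance script run the full loop on one CPU core,
so they use `desk_profile()` — range overrides shrinking kernels (16–32),
filters (2–12), depth (≤4 layers), dense width (16–64) and learning rate
(3×10⁻⁴–10⁻²) — and a fidelity schedule of 40 then 120 training steps at
batch 24 (the 1:3 budget ratio mirrors the reference 2 h → 6 h schedule),
with 8 initial-design points, 3 proposal batches of 3 per phase, and a
400-step final fit. These sizes are the package's choice of a desk-scale
experiment: large enough for the search to separate good configurations
from bad ones, small enough to iterate on. The override mechanism is the
same one a user would employ to customize the space for real work.

Two further desk-scale safeguards matter enough to state. First, the search's
objective is a noisy, selection-biased estimate (a winner's curse):
`run_architecture_search()` therefore returns the top three distinct
high-fidelity configurations, and `train_final_model()` retrains all of
them, ranks them by deterministic validation-split accuracy, and only then
evaluates the single winner on the test split. Second, the end-to-end smoke
experiment uses the `small` fixture profile rather than `tiny`: with one
validation and one test genome per class, tiny's split-level estimates are
dominated by per-file variance (a model can memorize file backgrounds and
look fine on one held-out file while failing on another), whereas small's
6 validation and 3 test genomes per class make the estimates track true
window-level accuracy.

## Known limitations

* The backend is plain R: it is exact but slow, suitable for desk-scale
  experiments and correctness work, not for training at GPU scale. The plan
  format is backend-independent by design, so a faster backend can
  instantiate the same plans.
* The GP is isotropic; with many encoded dimensions an ARD kernel could
  exploit per-dimension relevance, at the cost of a harder likelihood
  surface.
* The surrogate treats the fidelity coordinate like any other input; strong
  rank *inversions* between fidelities (small models winning short budgets)
  are only captured insofar as the GP can model the interaction.
* Scheduling proposals across workers is the caller's job: the package
  exposes `q`-wide proposal batches, not process orchestration.
* One global max-pooling variant (GMP) is deliberately absent from the head
  vocabulary — average pooling measures motif *frequency*, which the
  literature found superior for these tasks — as are attention layers and
  k-mer-spectrum inputs.
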