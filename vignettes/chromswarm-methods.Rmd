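---
title: "Sequence-free enhancer prediction and swarm-based model interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-free enhancer prediction and swarm-based model interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Enhancers are distal regulatory elements that amplify transcription of their
target genes, largely independent of position and without a universal DNA
sequence code. What they do share is a chromatin signature: active enhancers
carry H3K27ac and H3K4me1, are bound by p300, and sit in open chromatin,
while Polycomb-repressed regions are marked by H3K27me3. `chromswarm`
implements a framework that asks two questions:

1. Can a classifier predict enhancers genome-wide from *binned chromatin
   occupancy alone* — a vector of normalized ChIP-seq signal per 1 kb
   window, with no DNA sequence input?
2. Once a network is trained, which chromatin features does it actually use?
   The package's answer is adversarial particle swarm optimization (APSO): a
   gradient-free attack that synthesizes the input profiles a trained
   network finds maximally (or, with an inverted cost, minimally)
   enhancer-like, requiring nothing from the model beyond a
   vector-in/probability-out interface.

# Training-set construction

Putative enhancers are called as the intersection of STARR-seq peaks
(intrinsic enhancer activity) with ATAC-seq peaks (open chromatin in the
assayed cells), merged and resized to 1 kb about the midpoint
(`intersect_enhancer_calls()`, `resize_midpoint()`). Stringent versus
lenient call sets come from the same intersection applied to peak files
thresholded differently upstream; no peak calling happens in this package.

The genome is tiled into non-overlapping 1 kb windows
(`tile_genome()`), windows overlapping an exclusion list are dropped
(`filter_blacklist()`), and each window is labeled *enhancer* when at least
25% of its bases are covered by enhancer calls (`label_windows()`; overlaps
from multiple calls are summed as a base union, since the fraction is a
property of the window, not of any single call). Because positives are
rare, each positive training window is boosted into 10 copies shifted by
20 bp increments. The direction of the shifts is not inherent in those
counts; `boost_positives()` places them symmetrically (±20 … ±100 bp,
a 200 bp span) so the center distribution of the class is preserved.
Negatives combine windows 10 kb up/downstream of each positive (matched
local chromatin background; dropped when off-chromosome or overlapping any
enhancer call) with an equal-count random sample of enhancer-free windows
(`make_negatives()`), and the row order is shuffled.

Two hold-out schemes are provided: `chromosome_holdout()` (evaluation
windows on chromosomes never used in training, unboosted) and
`cell_line_holdout()` (train on the concatenation of all but one cell line,
evaluate on the one left out, rotating).

# Featurization

Tag positions (e.g. read 5′ ends) are counted in 10 bp bins across each
1 kb window, giving 100 bins per chromatin target (`bin_occupancy()`).
Counts are normalized to `[0,1]` by dividing each target by its global
maximum (`normalize_tensor()`); the scale factors are stored so the map is
invertible. The model-facing representation is a flat, target-major vector
of length `n_targets * 100` (`flatten_for_model()`); the same layout is
used by the attack and by attribution, so any flat coordinate maps back to
a unique (target, bin) pair. Tensors, labels, window coordinates, target
names and scale factors persist in a single seekable binary container
(`save_container()`/`load_container()`) with per-sample random access —
single windows can be read without loading the tensor.

# The classifier zoo

Seven architectures sit behind one contract — flat occupancy vector in,
probability out, differentiable with respect to the input:

| id | architecture |
|----|--------------------------------------------|
| 1  | DNN: three 256-unit ReLU layers, 0.5 dropout after each, sigmoid out |
| 2  | 1D CNN (16/32/64 channels, conv→ReLU→max-pool) → DNN |
| 3  | 3-layer LSTM (hidden 500) → DNN |
| 4  | 1D CNN → LSTM → DNN |
| 5  | 2D CNN (16/32 channels over the targets × bins image) → DNN |
| 6  | 2D CNN → LSTM → DNN |
| 7  | KAN: four Kolmogorov–Arnold layers of width 256, sigmoid out |

Choices the layer counts do not determine were fixed conventionally and
left configurable: convolution kernel 3 (3×3 in 2D), max-pool 2, stride 1,
no padding; 2D inputs are a single-channel (targets × bins) image; the LSTM
runs along the bin (genomic position) axis with targets (or upstream conv
channels) as features; the KAN uses a grid of 5 cubic B-spline segments on
`[-1, 1]` per edge with a SiLU residual branch, following the
efficient-KAN formulation (`kan_edge_activation()` exposes a single edge).
All networks are implemented in a compact in-package engine with explicit
forward/backward passes; input gradients (needed for attribution) are
validated against central finite differences in the test suite for every
architecture.

Training (`train()`) minimizes binary cross-entropy — the canonical loss
for a sigmoid output — with Adam (default learning rate 1e-3, batch 64),
per-epoch seeded shuffling, and dropout active. 20 epochs plateaus the
loss at the problem sizes used here. An optional `weight_decay`
(default 0) adds an L2 penalty; the planted-signature benchmark uses 1e-4
because its networks are heavily over-parameterized relative to 1,500
training windows and an unregularized fit drives training loss to ~0,
leaving a needlessly spiky decision surface.

# Evaluation metrics

`auroc()` is computed from ranks and equals the probability that a random
positive outranks a random negative, with ties counted half. `auprc()` uses
a descending-score sweep with tied scores grouped and step interpolation —
trapezoidal interpolation of precision is deliberately avoided because it
is optimistic exactly in the low-prevalence regime where auPRC is the
informative metric. Both are verified against exhaustive pairwise /
full-sweep oracles in the tests.

# The adversarial swarm

A swarm of `n` particles lives in the model's input space. Each particle
`i` has a location `l_i`, velocity `v_i`, and personal best `h_i`; the
swarm tracks a single global best `g`. Per epoch, every particle is scored,
bests are updated synchronously, and then

```
v_i <- omega * v_i + c1 * r1 * (h_i - l_i) + c2 * r2 * (g - l_i)
l_i <- clip(l_i + v_i, 0, 1)
```

with `r1, r2` fresh uniforms. Defaults and the reasoning behind them:

* **omega = 0.729, c1 = c2 = 1.49445** — the standard constriction
  coefficients, which guarantee convergent (damped oscillatory) particle
  dynamics. Nothing in the problem pins these values; they are the
  conventional choice.
* **`r1`, `r2` per coordinate** (the default) rather than one scalar pair
  per particle. Coordinate-wise draws let a particle mix its personal-best
  support and the global-best support dimension-by-dimension — effectively
  a uniform crossover — which is what standard PSO implementations do and
  what makes 20-epoch convergence possible at input dimensions in the
  hundreds. Scalar draws (`per_coordinate_r = FALSE`) confine each particle
  to the line segment spanned by its anchors and converge far more slowly.
* **Initialization**: locations uniform on `[0,1]` with each coordinate
  independently zeroed with probability `sparsity` (default 0.999),
  emulating the extreme sparsity of binned ChIP tags; velocities start at
  zero; the mask is applied at initialization only (a per-epoch remask is
  available as `remask_each_epoch` for sensitivity analysis).
* **Bounds**: positions are clipped to `[0,1]` — the range of normalized
  occupancy — and the velocity component that caused a clip is zeroed to
  prevent boundary pinning.
* **Objective**: the positive mode maximizes the model's probability, the
  inverted (negative) mode maximizes one minus it, so the same maximizing
  swarm converges to anti-predictive chromatin. Internally, for package
  predictors, the objective is evaluated on the log-odds scale: a confident
  network saturates the sigmoid in double precision (probabilities exactly
  0.0 or 1.0), which collapses the landscape into ties and freezes the
  global best; the log-odds transform is strictly monotone, so the optimum
  is unchanged while full floating-point resolution is retained. Black-box
  callables, which only expose probabilities, use the probability scale.

`attack()` performs `n_runs` independently seeded swarm runs (default 8 ×
500 particles × 20 epochs), returning each run's final global best, the
per-coordinate mean profile across runs, and per-target aggregates (mean
over bins — the profile binned to one value per chromatin feature).
`profile_correlation()` compares the average synthetic profile against
held-out real (or synthetic) occupancy vectors by Pearson correlation, the
frequency-histogram check that the attack reconstructs biologically shaped
chromatin rather than arbitrary adversarial noise.

**Run-to-run variability.** A converged global best is a *sparse* vector:
the swarm stops once the objective saturates, so each run reports one
minimal synthetic profile, not the model's full feature set. Individual
runs therefore differ in which subset of the predictive features they
emphasize, and rankings derived from a single run are noisy; conclusions
should rest on the across-run mean profile and on agreement with the
gradient-based methods. The package's own benchmark (below) measures both
per-run and run-averaged recovery and reports them separately.

# Gradient attribution

`saliency()` is the absolute input gradient. `integrated_gradients()`
approximates the straight-path integral from a baseline (default the zero
vector — "no occupancy") with a midpoint Riemann rule, default 64 steps;
at 1,024 steps the completeness identity (attributions summing to
`f(x) − f(baseline)`) holds to better than 1e-3 on every architecture,
which doubles as an end-to-end check of the backward passes.
`contribution_ranking()` scores each target by the per-coordinate product
of swarm-synthesized occupancy and its attribution, summed per target —
features that the attack reconstructs *and* the network weights.
`binned_visualization()` averages maps to one value per (sample, target)
and orders rows by hierarchical clustering of the occupancy (average
linkage, Euclidean), applied identically to data and attribution so
heatmaps align.

# The synthetic chromatin generator

Every downstream stage is testable without external data through
`generate_dataset()` / `generate_cell_lines()`, which emulate the *shape*
of the real training tensors: per window, `[0,1]` occupancy over 100 bins
for each of 8 targets named after a minimal chromatin panel (H3K4me1,
H3K4me3, H3K27ac, H3K27me3, H3K36me3, CTCF, p300, POLR2A). The design:

* **Positives** carry Gaussian bumps (center bin 50, sd 10 bins) on the
  active-enhancer targets — H3K4me1 (0.8), H3K27ac (0.9), p300 (0.7).
* **Negatives** are a 50/50 mixture of flat background and
  *poised-enhancer-like* windows: high H3K27me3 (0.8) plus weak H3K4me1
  (0.5) and no H3K27ac/p300. The poised component matters: it is what makes
  the repressive mark genuinely *anti-predictive* (the model must use it to
  reject active-looking chromatin) rather than merely absent from
  positives, which is the property the inverted-cost attack probes.
* **Amplitude jitter**: planted signatures are scaled per window by
  `U(0.5, 1)`, the locus-to-locus variability of real ChIP enrichment.
  Without it the classes are degenerately separable and trained scores
  saturate.
* **Decoy peaks**: each non-signature target (H3K4me3, H3K36me3, CTCF,
  POLR2A) carries, with probability 0.3 per window irrespective of label, a
  coherent random-center peak — marks that occur genome-wide at enhancer
  and non-enhancer windows alike and should be learned as uninformative.
* **Background**: independent uniform spikes on `[0,1]` with Bernoulli
  zeroing (sparsity 0.9); per-target max normalization legitimately leaves
  background spikes on the same scale as signal.
* **Cell lines**: each line keeps a Bernoulli-`shared_fraction` subset of
  positive loci in common with all lines (default 0.3), the rest
  line-specific, reproducing the strong cell-type specificity of called
  enhancers; replicates re-noise the same underlying signal.

What the generator does **not** emulate: read-level noise, fragment-length
effects, mappability, inter-target correlation structure beyond the
planted signatures, or genomic autocorrelation between neighboring
windows. Tests passing on this generator demonstrate the machinery —
interval logic, training, metrics, attack dynamics, attribution — not
performance on real chromatin.

# The planted-signature benchmark

`run_planted_benchmark()` is the package's end-to-end verification: 2,000
synthetic windows (1,000 per class), a 25% random hold-out, Model 1
trained 20 epochs (batch 64, lr 1e-3, weight decay 1e-4, training
positives augmented with 4 re-noised copies each — the synthetic analogue
of the pipeline's positive boosting), then 8 positive-mode and 8
negative-mode swarm runs (500 particles, 20 epochs, sparsity 0.999). It
reports held-out auROC/auPRC, per-run and run-averaged planted-feature
recovery, and the correlation of each mode's average profile against
held-out positives. The positive-mode profile correlates positively with
real (held-out) enhancer windows and the negative-mode profile does not —
the qualitative separation expected when the attack reconstructs
biological signal. Per-run exact rankings are substantially noisier than
the run-averaged ones, for the reasons discussed above.

# Downstream statistics

`correlation_cluster()` builds the pairwise Pearson matrix of genome-wide
score tracks and returns an average-linkage clustering order on the
correlation distance. `top_fraction()` takes the top 1% (by default) of
windows with ties at the cutoff broken by coordinate order for
reproducibility, and `multiway_intersection()` decomposes several calls
sets into disjoint elements labeled with their membership pattern (the
Venn decomposition). Enrichment of feature overlaps against size-matched
random controls uses the exact conditional form of the Poisson rate-ratio
test — conditional on the total, the observed count is binomial with
proportion `e/(e+1)` under the null, `e` being the exposure ratio
(default 1, for size-matched control sets) — with Benjamini–Yekutieli
correction (`p.adjust`, valid under arbitrary dependence) at an adjusted
threshold of 0.01. `contact_ratio()` tabulates pairwise-interaction
anchors hitting one enhancer and one promoter (promoters being 1 kb
windows on gene starts) versus random loci, reported as a log2 ratio.

# Numerical and reproducibility notes

* All randomness flows through explicit integer seeds; pipeline stages
  derive independent per-stage seeds from one global seed
  (`stage_seed()`), so each stage is reproducible in isolation. Reruns with
  identical inputs and seeds are byte-identical.
* Problem sizes in the test suite are deliberately small (tensors of
  30–200 windows, reduced layer widths for the slow architectures, 1,024
  integrated-gradient steps only in the completeness checks); the
  benchmark runs at its stated 2,000-window scale once per session.
* Degenerate inputs are defined, not accidental: zero-count targets stay
  zero under normalization; single-class label vectors are errors (not
  NaN) in both metrics; zero-variance profiles make correlations `NA`,
  counted separately; an empty interval list is a valid empty result
  everywhere except where a count match is contractual.
* KAN spline inputs are clamped to the grid range for the spline term
  (the SiLU residual is unclamped); gradients are exact for the clamped
  function.

# Limitations

The engine is CPU-bound, single-threaded R; it is sized for the package's
benchmark and tests, not for genome-scale training. The attack's per-run
output is a minimal adversarial profile, so single-run feature rankings
are noisy by construction. Real-data ingestion stops at BED-like peaks and
point-tag lists: alignment, peak calling, and coverage extraction from BAM
belong to upstream tools.
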