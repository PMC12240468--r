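# chromswarm

Sequence-free enhancer prediction from chromatin occupancy, with
swarm-based interpretation of the trained networks.

## What this is for

Enhancers — distal regulatory elements that amplify gene transcription —
lack a universal DNA sequence code but carry a recognizable chromatin
signature (H3K27ac, H3K4me1, p300 binding, open chromatin; H3K27me3 marks
the repressed opposite). `chromswarm` is for regulatory genomicists who
want to (a) predict enhancers genome-wide using **only** binned ChIP-seq
occupancy — no sequence model, no reference-genome features beyond window
coordinates — and (b) interrogate what a trained predictor actually uses,
including predictors whose internals are inaccessible.

The package implements the full path:

* **Training-set construction** — enhancer calls as STARR-seq ∩ ATAC-seq
  peak intersections, 1 kb genome tiling, blacklist filtering, 25%-overlap
  labeling, positive boosting, flank + random negative controls.
* **Featurization** — tag counts in 10 bp bins (100 bins per target per
  1 kb window), per-target max normalization to [0,1], and a seekable
  binary tensor container with per-sample random access.
* **A seven-architecture classifier zoo** (DNN, 1D/2D CNNs, LSTM hybrids,
  and a Kolmogorov–Arnold network) behind one contract: flat occupancy
  vector in, enhancer probability out. The neural-network engine is
  implemented in-package with hand-written backward passes that the test
  suite verifies against finite differences.
* **APSO** — adversarial particle swarm optimization. A swarm of sparse
  random input vectors is scored by the trained model and iteratively
  pulled toward personal and global bests,

  `v_i ← ω·v_i + c1·r1·(h_i − l_i) + c2·r2·(g − l_i)`,  `l_i ← clip(l_i + v_i, 0, 1)`,

  converging on synthetic chromatin profiles that maximally activate the
  network. Inverting the cost converges on *anti*-predictive profiles
  instead. APSO needs no gradients and no hold-out data, so it applies to
  any scoring function.
* **Gradient attribution** (saliency, integrated gradients with the
  completeness guarantee) to cross-validate swarm findings, plus
  genome-wide score correlation/clustering, top-1% intersection, exact
  Poisson-means enrichment with Benjamini–Yekutieli correction, and
  enhancer–promoter contact ratios.
* **A synthetic chromatin generator** with planted signatures (active
  marks on positives, a poised H3K27me3-like signature on negatives,
  label-independent decoy peaks) so the entire pipeline is testable
  without external data.

## Worked example

```r
library(chromswarm)

# 1. Simulate a small labeled chromatin dataset (8 targets x 100 bins)
cfg <- synthetic_config(n_pos = 300, n_neg = 300, seed = 11)
ds  <- generate_dataset(cfg)
dim(ds$tensor)
#> [1] 600   8 100

# 2. Train the DNN classifier and evaluate on a held-out split
X <- flatten_all(ds$tensor)
set.seed(1); hold <- sample.int(600, 150)
model <- build_model(model_spec(architecture = 1, n_targets = 8), seed = 2)
fit <- train(model, X[-hold, ], ds$labels[-hold],
             training_config(epochs = 10, seed = 3))
round(fit$loss_curve[c(1, 10)], 4)
#> [1] 0.6206 0.0021
report <- evaluate(fit$model, X[hold, ], ds$labels[hold], "random 25% holdout")
c(auROC = report$auroc, auPRC = round(report$auprc, 4))
#> auROC auPRC
#>     1     1

# 3. Attack the trained network: which chromatin features drive prediction?
hp <- swarm_hyperparams(n_particles = 200, epochs = 20, seed = 4)
atk <- attack(fit$model, hp, n_runs = 4, mode = "positive")
sort(round(atk$feature_means, 4), decreasing = TRUE)
#> target3 target7 target1 target2 target8 target5 target4 target6
#>  0.0175  0.0175  0.0025  0.0025  0.0025  0.0024  0.0020  0.0000

# 4. Invert the cost: which features are anti-predictive?
atk_neg <- attack(fit$model, swarm_hyperparams(n_particles = 200, seed = 5),
                  n_runs = 4, mode = "negative")
names(which.max(atk_neg$feature_means))
#> [1] "target4"

# 5. Cross-check with integrated gradients on held-out positives
pos <- intersect(hold, which(ds$labels == 1))[1:20]
ig <- integrated_gradients(fit$model, ds$tensor[pos, , ])
round(colMeans(apply(ig$values, c(1, 2), sum)), 3)
#> [1]  0.198 -0.033  0.386 -0.066 -0.025 -0.041  0.247 -0.050
```

Reading the numbers: training loss drops from 0.62 to ~0.002 in 10 epochs
and the held-out windows are ranked perfectly (the planted signatures make
this an easy dataset). The generator planted its positive signature on
targets 1, 3 and 7 (the H3K4me1-, H3K27ac- and p300-like slots) and a
repressive signature on target 4 (H3K27me3-like): the positive-mode swarm
puts its largest synthetic occupancy on targets 3 and 7 with target 1 just
above background, the inverted-cost swarm converges on target 4, and
integrated gradients independently assign their positive attribution mass
to targets 1, 3 and 7. Swarm feature means are small in absolute terms —
converged adversarial vectors are sparse — and single runs vary; rankings
firm up across runs (see the methods vignette).

A YAML-driven command line covering
`simulate / train / evaluate / score-genome / attack / explain /
make-calls` is installed at `inst/cli/chromswarm.R`.

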