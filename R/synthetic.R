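# Synthetic chromatin occupancy with planted class signatures.
#
# Emulates the shape of real training data: per 1 kb window, one
# [0,1]-normalized occupancy vector of `n_bins` bins per chromatin target.
# Positives carry Gaussian-bump enrichment on designated "active" targets
# (H3K27ac/H3K4me1-like); negatives are a mixture of a repressive signature
# (H3K27me3-like) and sparse flat background.

#' Configuration for the synthetic chromatin generator
#'
#' @param n_targets Number of chromatin targets (default 8, mirroring a
#'   minimal histone-mark/factor panel).
#' @param n_bins Bins per window (default 100, i.e. 10 bp bins over 1 kb).
#' @param n_pos,n_neg Positive / negative window counts.
#' @param positive_signature Per-target amplitude in `[0,1]` planted on
#'   positives. With the default 8-target panel the active-enhancer-like
#'   targets are H3K4me1 (0.8), H3K27ac (0.9) and p300 (0.7); otherwise the
#'   first three targets.
#' @param negative_signature Per-target amplitude in `[0,1]` planted on the
#'   repressive fraction of negatives. Default: the H3K27me3-like target
#'   (slot 4 of the 8-target panel, else the last target) at 0.8.
#' @param peak_center Bin index of the planted bump center (default
#'   `n_bins / 2`).
#' @param peak_width Bump standard deviation in bins (default 10); `Inf`
#'   gives a flat plateau at the full amplitude.
#' @param poised_signature Per-target amplitude planted on the repressive
#'   negatives *in addition to* `negative_signature`, emulating poised
#'   enhancers (H3K4me1-marked, H3K27me3-repressed, H3K27ac-absent).
#'   Default: the H3K4me1-like slot at 0.5 for the 8-target panel, else
#'   zero. This makes the repressive mark genuinely anti-predictive rather
#'   than merely absent from positives.
#' @param amp_jitter Per-sample amplitude variability: every planted
#'   signature is scaled by a uniform draw from `[1 - amp_jitter, 1]`
#'   (default 0.5), emulating locus-to-locus variation in ChIP enrichment.
#' @param decoy_rate Probability, per sample and per *non-signature* target,
#'   of carrying a coherent peak (random center, amplitude `U(0.2, 1)`)
#'   irrespective of the class label (default 0.3). This emulates marks
#'   like CTCF, H3K4me3 or H3K36me3 that occur genome-wide at enhancer and
#'   non-enhancer windows alike and are therefore present in the vector but
#'   uninformative for the label.
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param background_sparsity Probability that a background entry is zeroed
#'   (default 0.9 — ChIP background is mostly empty).
#' @param background_max Upper bound of uniform background signal (default
#'   1: after per-target max normalization, isolated background spikes span
#'   the same `[0,1]` scale as signal).
#' @param neg_repressive_frac Fraction of negatives carrying the repressive
#'   signature rather than flat background (default 0.5).
#' @param n_cell_lines Number of synthetic cell lines (default 1).
#' @param shared_fraction Fraction of positive loci shared across all cell
#'   lines (default 0.3; most synthetic enhancers are line-specific, as in
#'   real cell lines).
#' @param replicates Pseudo-replicates per line, generated by re-noising the
#'   same underlying signal (default 1).
#' @param window_bp Window width in bp used for the synthetic coordinates
#'   (default 1000).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_targets = 8L, n_bins = 100L,
                             n_pos = 1000L, n_neg = 1000L,
                             positive_signature = NULL,
                             negative_signature = NULL,
                             peak_center = NULL, peak_width = 10,
                             poised_signature = NULL, amp_jitter = 0.5,
                             decoy_rate = 0.3, noise_sd = 0.1,
                             background_sparsity = 0.9,
                             background_max = 1,
                             neg_repressive_frac = 0.5,
                             n_cell_lines = 1L, shared_fraction = 0.3,
                             replicates = 1L, window_bp = 1000L, seed = 1L) {
  if (n_bins <= 0) stop("n_bins must be positive", call. = FALSE)
  if (n_targets <= 0) stop("n_targets must be positive", call. = FALSE)
  if (n_pos <= 0 || n_neg <= 0) stop("n_pos and n_neg must be positive", call. = FALSE)
  if (is.null(positive_signature)) {
    positive_signature <- numeric(n_targets)
    if (n_targets >= 8) {
      # H3K4me1 / H3K27ac / p300 slots of the default panel
      positive_signature[c(1L, 3L, 7L)] <- c(0.8, 0.9, 0.7)
    } else {
      positive_signature[seq_len(min(3L, n_targets))] <-
        c(0.9, 0.8, 0.7)[seq_len(min(3L, n_targets))]
    }
  }
  if (is.null(negative_signature)) {
    negative_signature <- numeric(n_targets)
    negative_signature[if (n_targets >= 8) 4L else n_targets] <- 0.8
  }
  if (is.null(poised_signature)) {
    poised_signature <- numeric(n_targets)
    if (n_targets >= 8) poised_signature[1L] <- 0.5
  }
  if (length(positive_signature) != n_targets ||
      length(negative_signature) != n_targets ||
      length(poised_signature) != n_targets) {
    stop("signatures must have one amplitude per target", call. = FALSE)
  }
  if (amp_jitter < 0 || amp_jitter > 1) {
    stop("amp_jitter must be in [0,1]", call. = FALSE)
  }
  if (decoy_rate < 0 || decoy_rate > 1) {
    stop("decoy_rate must be in [0,1]", call. = FALSE)
  }
  amps <- c(positive_signature, negative_signature, poised_signature)
  if (any(amps < 0 | amps > 1)) stop("signature amplitudes must be in [0,1]", call. = FALSE)
  if (background_sparsity < 0 || background_sparsity > 1) {
    stop("background_sparsity must be in [0,1]", call. = FALSE)
  }
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0,1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (is.null(peak_center)) peak_center <- n_bins / 2
  structure(list(
    n_targets = as.integer(n_targets), n_bins = as.integer(n_bins),
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    positive_signature = as.numeric(positive_signature),
    negative_signature = as.numeric(negative_signature),
    poised_signature = as.numeric(poised_signature),
    amp_jitter = amp_jitter, decoy_rate = decoy_rate,
    peak_center = peak_center, peak_width = peak_width,
    noise_sd = noise_sd, background_sparsity = background_sparsity,
    background_max = background_max,
    neg_repressive_frac = neg_repressive_frac,
    n_cell_lines = as.integer(n_cell_lines),
    shared_fraction = shared_fraction,
    replicates = as.integer(replicates),
    window_bp = as.integer(window_bp), seed = as.integer(seed)
  ), class = "synthetic_config")
}

.bump_profile <- function(amp, n_bins, center, width) {
  if (amp == 0) return(numeric(n_bins))
  if (is.infinite(width)) return(rep(amp, n_bins))
  b <- seq_len(n_bins)
  amp * exp(-0.5 * ((b - center) / width)^2)
}

# background + noise for one (targets x bins) window, already seeded
.window_background <- function(cfg) {
  m <- matrix(stats::runif(cfg$n_targets * cfg$n_bins, 0, cfg$background_max),
              nrow = cfg$n_targets)
  if (cfg$background_sparsity > 0) {
    keep <- matrix(stats::runif(length(m)) >= cfg$background_sparsity,
                   nrow = nrow(m))
    m <- m * keep
  }
  m
}

.render_samples <- function(cfg, labels, repressive) {
  n <- length(labels)
  pos_prof <- t(vapply(cfg$positive_signature, .bump_profile,
                       numeric(cfg$n_bins),
                       n_bins = cfg$n_bins, center = cfg$peak_center,
                       width = cfg$peak_width))
  neg_prof <- t(vapply(cfg$negative_signature, .bump_profile,
                       numeric(cfg$n_bins),
                       n_bins = cfg$n_bins, center = cfg$peak_center,
                       width = cfg$peak_width))
  poised_prof <- t(vapply(cfg$poised_signature, .bump_profile,
                          numeric(cfg$n_bins),
                          n_bins = cfg$n_bins, center = cfg$peak_center,
                          width = cfg$peak_width))
  decoy_targets <- which(cfg$positive_signature == 0 &
                         cfg$negative_signature == 0 &
                         cfg$poised_signature == 0)
  tensor <- array(0, dim = c(n, cfg$n_targets, cfg$n_bins))
  for (i in seq_len(n)) {
    base <- .window_background(cfg)
    jit <- stats::runif(1, 1 - cfg$amp_jitter, 1)
    if (labels[i] == 1L) base <- base + jit * pos_prof
    else if (repressive[i]) base <- base + jit * (neg_prof + poised_prof)
    if (cfg$decoy_rate > 0 && length(decoy_targets) > 0) {
      for (t in decoy_targets) {
        if (stats::runif(1) < cfg$decoy_rate) {
          base[t, ] <- base[t, ] + .bump_profile(
            stats::runif(1, 0.2, 1), cfg$n_bins,
            center = stats::runif(1, 1, cfg$n_bins), width = cfg$peak_width)
        }
      }
    }
    if (cfg$noise_sd > 0) {
      base <- base + matrix(stats::rnorm(length(base), 0, cfg$noise_sd),
                            nrow = nrow(base))
    }
    tensor[i, , ] <- pmin(pmax(base, 0), 1)
  }
  tensor
}

#' Generate one labeled synthetic occupancy dataset
#'
#' Positives carry the `positive_signature` bump on their active targets; a
#' `neg_repressive_frac` fraction of negatives carries the
#' `negative_signature` bump (the rest are flat background). Every entry is
#' independently zero-masked background plus Gaussian noise, clipped to
#' `[0,1]`. Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param loci Optional integer vector of window indices (one per sample) on
#'   the synthetic chromosome; defaults to a seeded random draw.
#' @param chrom Synthetic chromosome name.
#' @return A `synthetic_dataset`: list with `tensor`
#'   (samples x targets x bins), `labels` (0/1), `windows` (BED-like
#'   data.frame with `label` and `origin`), `target_names`, and `config`.
#' @export
generate_dataset <- function(config, loci = NULL, chrom = "chrS") {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_pos + cfg$n_neg
  labels <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
  n_rep <- round(cfg$n_neg * cfg$neg_repressive_frac)
  repressive <- c(rep(FALSE, cfg$n_pos),
                  rep(c(TRUE, FALSE), c(n_rep, cfg$n_neg - n_rep)))
  if (is.null(loci)) loci <- sample.int(10L * n, n)
  if (length(loci) != n) stop("loci must have one index per sample", call. = FALSE)
  ord <- sample.int(n)  # shuffle so class blocks are not ordered
  labels <- labels[ord]; repressive <- repressive[ord]; loci <- loci[ord]
  tensor <- .render_samples(cfg, labels, repressive)
  windows <- data.frame(
    chrom = chrom,
    start = (loci - 1L) * cfg$window_bp,
    end = loci * cfg$window_bp,
    label = ifelse(labels == 1L, "enhancer", "non_enhancer"),
    origin = ifelse(labels == 1L, "positive",
                    ifelse(repressive, "repressive_negative", "random_negative")),
    stringsAsFactors = FALSE
  )
  panel <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3", "H3K36me3",
             "CTCF", "p300", "POLR2A")
  target_names <- if (cfg$n_targets == 8L) panel
                  else paste0("target", seq_len(cfg$n_targets))
  structure(list(
    tensor = tensor, labels = labels, windows = windows,
    target_names = target_names,
    config = cfg
  ), class = "synthetic_dataset")
}

#' Generate synthetic datasets for multiple cell lines
#'
#' Each line gets its own positive locus set; a `shared_fraction` of positive
#' loci (Bernoulli per locus) is common to all lines, the rest are
#' line-specific, mirroring the strong cell-type specificity of called
#' enhancers. Negative loci are drawn independently per line.
#'
#' @param config A [synthetic_config()] with `n_cell_lines >= 2`.
#' @return List of `synthetic_dataset`, one per cell line, each with a
#'   `cell_line` field; replicates (if `replicates > 1`) are additional
#'   re-noised datasets appended with the same loci and labels.
#' @export
generate_cell_lines <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (cfg$n_cell_lines < 2) stop("n_cell_lines must be >= 2", call. = FALSE)
  set.seed(cfg$seed)
  k <- cfg$n_cell_lines
  n <- cfg$n_pos + cfg$n_neg
  # carve disjoint locus pools: one shared pool + one per line
  pool_size <- 10L * n
  shared_mask <- stats::runif(cfg$n_pos) < cfg$shared_fraction
  n_shared <- sum(shared_mask)
  shared_loci <- sample.int(pool_size, n_shared)
  out <- vector("list", 0)
  for (line in seq_len(k)) {
    # line-specific loci live in a disjoint coordinate block per line
    block <- pool_size * line
    own <- block + sample.int(pool_size, n - n_shared)
    pos_loci <- integer(cfg$n_pos)
    pos_loci[shared_mask] <- shared_loci
    pos_loci[!shared_mask] <- own[seq_len(cfg$n_pos - n_shared)]
    neg_loci <- own[(cfg$n_pos - n_shared + 1L):(n - n_shared)]
    loci <- c(pos_loci, neg_loci)
    for (rep_i in seq_len(cfg$replicates)) {
      sub <- cfg
      sub$seed <- cfg$seed + 1000L * line + rep_i
      ds <- generate_dataset(sub, loci = loci, chrom = "chrS")
      ds$cell_line <- paste0("line", line)
      ds$replicate <- rep_i
      out[[length(out) + 1L]] <- ds
    }
  }
  out
}

#' Positive locus indices of a synthetic dataset
#'
#' @param dataset A `synthetic_dataset`.
#' @return Integer vector of window start coordinates of the positives.
#' @export
positive_loci <- function(dataset) {
  dataset$windows$start[dataset$labels == 1L]
}
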