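# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (GenomicRanges, rank formulas,
# splineDesign) so agreement is informative.

# ---- interval oracles (per-base set arithmetic) ----------------------------

# set of covered bases (as "chrom:pos" keys) of an interval data.frame
oracle_base_set <- function(df) {
  if (nrow(df) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i) {
    if (df$end[i] <= df$start[i]) return(character(0))
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1L))
  }))
}

# intervals back from a base set, per chromosome (sorted disjoint runs)
oracle_intervals_from_bases <- function(bases) {
  if (length(bases) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(unique(bases), ":", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                   stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df$pos, df$chrom), function(p) {
    p <- sort(unique(p))
    brk <- c(0, which(diff(p) > 1), length(p))
    data.frame(start = p[brk[-length(brk)] + 1L],
               end = p[brk[-1]] + 1L)
  }))
  out$chrom <- sub("\\.[0-9]+$", "", rownames(out))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), c("chrom", "start", "end")]
}

oracle_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  max(0L, min(a_end, b_end) - max(a_start, b_start))
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 5000L,
                             max_len = 400L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- metric oracles --------------------------------------------------------

oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_auprc <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# ---- numeric oracles -------------------------------------------------------

fd_gradient <- function(f, x, i, eps = 1e-5) {
  xp <- x; xm <- x
  xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# Cox-de Boor recursion, independent of splines::splineDesign
oracle_bspline <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  B <- matrix(0, length(x), nb)
  for (i in seq_len(nb)) {
    B[, i] <- .oracle_bspline_one(x, knots, degree, i)
  }
  B
}
.oracle_bspline_one <- function(x, t, k, i) {
  if (k == 0) return(as.numeric(x >= t[i] & x < t[i + 1]))
  d1 <- t[i + k] - t[i]
  d2 <- t[i + k + 1] - t[i + 1]
  a <- if (d1 > 0) (x - t[i]) / d1 * .oracle_bspline_one(x, t, k - 1, i) else 0
  b <- if (d2 > 0) (t[i + k + 1] - x) / d2 * .oracle_bspline_one(x, t, k - 1, i + 1) else 0
  a + b
}

# ---- small model configs ---------------------------------------------------

small_hyperparams <- function() {
  list(dnn_width = 16L, dnn_layers = 2L, dropout = 0.5,
       conv1d_channels = c(4L, 8L), conv2d_channels = c(4L),
       lstm_hidden = 8L, lstm_layers = 2L,
       kan_widths = c(8L, 8L))
}

# small, fast synthetic config for plumbing tests
tiny_config <- function(...) {
  synthetic_config(n_pos = 30L, n_neg = 30L, seed = 7L, ...)
}
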