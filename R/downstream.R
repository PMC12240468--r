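# Cross-model comparison of genome-wide prediction tracks and biological
# enrichment statistics.

#' Correlation matrix and clustering order for score tracks
#'
#' Pairwise Pearson correlation of genome-wide prediction scores on
#' identical windows, with a hierarchical clustering order (average linkage
#' on correlation distance `1 - r`) for heatmap display.
#'
#' @param tracks Named list of score data.frames (from [genome_scores()]),
#'   all on the same windows in the same order.
#' @return List with `correlation` (symmetric matrix, unit diagonal) and
#'   `order` (clustering leaf order).
#' @export
correlation_cluster <- function(tracks) {
  if (length(tracks) < 2) stop("need at least two tracks", call. = FALSE)
  ref <- tracks[[1]][, c("chrom", "start", "end")]
  for (tr in tracks[-1]) {
    if (!identical(tr[, c("chrom", "start", "end")], ref)) {
      stop("tracks are not on identical windows", call. = FALSE)
    }
  }
  m <- vapply(tracks, function(tr) tr$score, numeric(nrow(ref)))
  cmat <- stats::cor(m)
  ord <- seq_len(ncol(cmat))
  if (ncol(cmat) > 2) {
    ord <- stats::hclust(stats::as.dist(1 - cmat), method = "average")$order
  }
  list(correlation = cmat, order = ord)
}

#' Top-scoring fraction of windows
#'
#' The `ceil(frac * n)` highest-scoring windows; ties at the cutoff are
#' broken by coordinate order (chromosome, then start) for reproducibility.
#'
#' @param track Score data.frame (`chrom`, `start`, `end`, `score`).
#' @param frac Fraction to keep (default 0.01, the top 1%).
#' @return The selected rows, highest score first.
#' @export
top_fraction <- function(track, frac = 0.01) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0,1]", call. = FALSE)
  k <- ceiling(frac * nrow(track))
  ord <- order(-track$score, track$chrom, track$start)
  out <- track[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multi-way interval set membership
#'
#' Partitions the union of several interval sets into disjoint elements and
#' labels each with its membership pattern across the named sets (the
#' Venn-diagram decomposition).
#'
#' @param sets Named list of interval data.frames.
#' @return List with `elements` (interval data.frame plus one logical column
#'   per set and a `pattern` string) and `counts` (table of pattern
#'   frequencies).
#' @export
multiway_intersection <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named", call. = FALSE)
  }
  # split the union at every boundary so each element has one pattern
  bounds <- GenomicRanges::disjoin(
    do.call(c, unname(lapply(sets, .df_to_gr))))
  df <- .gr_to_df(bounds)
  member <- vapply(sets, function(s) {
    IRanges::overlapsAny(bounds, .df_to_gr(s))
  }, logical(length(bounds)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  out <- cbind(df, as.data.frame(member), pattern = pattern,
               stringsAsFactors = FALSE)
  list(elements = out, counts = table(pattern))
}

#' Poisson means (rate-ratio) enrichment test
#'
#' Exact conditional test for enrichment of `observed` over `control`
#' counts: conditional on the total `N = observed + control`, the observed
#' count is Binomial(N, e/(e+1)) under the null, where `e` is the exposure
#' ratio (1 when observed and control region sets are size-matched). The
#' one-sided enrichment p-value is the upper binomial tail.
#'
#' @param observed,control Non-negative counts (vectorized).
#' @param exposure_ratio Expected observed/control ratio under the null
#'   (default 1).
#' @return One-sided p-value(s).
#' @export
poisson_enrichment <- function(observed, control, exposure_ratio = 1) {
  if (any(observed < 0) || any(control < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  q <- exposure_ratio / (exposure_ratio + 1)
  stats::pbinom(observed - 1, observed + control, q, lower.tail = FALSE)
}

#' Benjamini-Yekutieli correction
#'
#' Step-up FDR control valid under arbitrary dependence, inflating by the
#' harmonic-sum constant `c(m) = sum_{k<=m} 1/k`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values (same order as input).
#' @export
by_correction <- function(p_values) {
  stats::p.adjust(p_values, method = "BY")
}

#' Enrichment table for many feature sets
#'
#' @param feature_ids Identifier per feature set.
#' @param observed,control Count vectors aligned with `feature_ids`.
#' @param threshold Adjusted-p enrichment threshold (default 0.01).
#' @param exposure_ratio Passed to [poisson_enrichment()].
#' @return Data.frame with raw and BY-adjusted p-values and an `enriched`
#'   flag.
#' @export
enrichment_table <- function(feature_ids, observed, control,
                             threshold = 0.01, exposure_ratio = 1) {
  p <- poisson_enrichment(observed, control, exposure_ratio)
  adj <- by_correction(p)
  data.frame(feature_id = feature_ids, observed_count = observed,
             control_count = control, p_value = p, adjusted_p = adj,
             enriched = adj < threshold, stringsAsFactors = FALSE)
}

#' Enhancer-promoter contact ratio from pairwise interactions
#'
#' Counts interaction pairs with one anchor in an enhancer and the other in
#' a promoter, repeats the count with random loci in place of enhancers,
#' and returns `log2(E-P / R-P)`. A zero denominator yields `Inf` with a
#' flag.
#'
#' @param interactions Data.frame of anchor pairs (`chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`), BEDPE-like.
#' @param enhancers,promoters,random_loci Interval data.frames.
#' @return List with `ep_count`, `rp_count`, `log2_ratio`,
#'   `infinite` (logical).
#' @export
contact_ratio <- function(interactions, enhancers, promoters, random_loci) {
  a1 <- .df_to_gr(data.frame(chrom = interactions$chrom1,
                             start = interactions$start1,
                             end = interactions$end1))
  a2 <- .df_to_gr(data.frame(chrom = interactions$chrom2,
                             start = interactions$start2,
                             end = interactions$end2))
  pgr <- .df_to_gr(promoters)
  # disjoint chromosome sets are a legitimate zero-overlap case; silence
  # the seqlevel-mismatch warning GenomeInfoDb emits for them
  ovl <- function(a, b) suppressWarnings(IRanges::overlapsAny(a, b))
  count_pairs <- function(set_df) {
    sgr <- .df_to_gr(set_df)
    sum((ovl(a1, sgr) & ovl(a2, pgr)) | (ovl(a2, sgr) & ovl(a1, pgr)))
  }
  ep <- count_pairs(enhancers)
  rp <- count_pairs(random_loci)
  ratio <- if (rp == 0) Inf else log2(ep / rp)
  list(ep_count = ep, rp_count = rp, log2_ratio = ratio,
       infinite = rp == 0)
}

#' Define promoters from gene starts
#'
#' A fixed-width window centered on each gene's start coordinate.
#'
#' @param gene_starts Data.frame with `chrom` and `start` (bp of the TSS).
#' @param width Window width (default 1000).
#' @param chrom_sizes Optional clipping bounds.
#' @return Interval data.frame of promoter windows.
#' @export
promoters_from_tss <- function(gene_starts, width = 1000L,
                               chrom_sizes = NULL) {
  df <- data.frame(chrom = gene_starts$chrom,
                   start = gene_starts$start,
                   end = gene_starts$start + 1L,
                   stringsAsFactors = FALSE)
  resize_midpoint(df, width = width, chrom_sizes = chrom_sizes)
}
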