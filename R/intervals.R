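# Interval algebra for enhancer-call and training-window construction.
#
# All user-facing coordinates are 0-based half-open [start, end) in the BED
# convention; GenomicRanges (1-based closed) is used internally.

.check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop(what, " must be a data.frame with columns chrom, start, end", call. = FALSE)
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop("malformed interval at line ", bad[1], ": requires 0 <= start < end",
         call. = FALSE)
  }
  invisible(x)
}

.df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

.sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Read a BED3+ file
#'
#' Reads the first three columns (chrom, start, end) of a BED-like file
#' (plain BED3, BED6, or narrowPeak). Coordinates stay 0-based half-open.
#'
#' @param path Path to a tab-separated BED-like file.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  .check_intervals(out, paste0("BED file ", path))
  out
}

#' Write intervals as BED
#'
#' @param x Interval data.frame (`chrom`, `start`, `end`, plus optional extra
#'   columns which are appended in order).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  .check_intervals(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' @param path Path to a `chrom.sizes`-style file (name, length).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  sizes <- as.integer(df[[2]])
  names(sizes) <- as.character(df[[1]])
  if (anyDuplicated(names(sizes))) stop("duplicate chromosome name in ", path, call. = FALSE)
  if (any(sizes <= 0)) stop("non-positive chromosome size in ", path, call. = FALSE)
  sizes
}

#' Merge overlapping or bookended intervals
#'
#' Collapses a set of intervals into the minimal sorted set of disjoint
#' intervals covering the same bases. Touching intervals (`end == start`)
#' are merged, matching `bedtools merge` defaults.
#'
#' @param peaks Interval data.frame.
#' @return Sorted, pairwise-disjoint interval data.frame.
#' @export
merge_intervals <- function(peaks) {
  .check_intervals(peaks, "peaks")
  if (nrow(peaks) == 0) return(peaks[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(.df_to_gr(peaks), min.gapwidth = 1L)
  .sort_intervals(.gr_to_df(gr))
}

#' Intersect STARR-seq peaks with ATAC-seq peaks to call putative enhancers
#'
#' Putative enhancers are the genomic regions supported by both assays: bases
#' covered by a STARR-seq peak (intrinsic enhancer activity) and an ATAC-seq
#' peak (open chromatin). Stringent vs lenient enhancer sets come from running
#' the same intersection on peak files called at different thresholds.
#'
#' @param starr,atac Interval data.frames (ideally pre-merged).
#' @return Merged interval data.frame of pairwise intersections.
#' @export
intersect_enhancer_calls <- function(starr, atac) {
  .check_intervals(starr, "starr")
  .check_intervals(atac, "atac")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(starr) == 0 || nrow(atac) == 0) return(empty)
  gr <- GenomicRanges::intersect(.df_to_gr(starr), .df_to_gr(atac),
                                 ignore.strand = TRUE)
  if (length(gr) == 0) return(empty)
  .sort_intervals(.gr_to_df(gr))
}

#' Resize a region to a fixed width about its midpoint
#'
#' The midpoint is `floor((start + end) / 2)`; the output spans
#' `[mid - floor(w/2), mid + ceiling(w/2))`. When chromosome sizes are given
#' the result is clipped to `[0, size)`; otherwise a negative start is an
#' error.
#'
#' @param region Interval data.frame (one or more rows).
#' @param width Target width in bp (default 1000, the 1 kb training window).
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return Interval data.frame of resized regions.
#' @export
resize_midpoint <- function(region, width = 1000L, chrom_sizes = NULL) {
  .check_intervals(region, "region")
  if (width <= 0) stop("width must be positive", call. = FALSE)
  mid <- (region$start + region$end) %/% 2L
  start <- mid - width %/% 2L
  end <- start + width
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[region$chrom]
    if (anyNA(sz)) stop("chromosome missing from sizes table", call. = FALSE)
    start <- pmax(start, 0L)
    end <- pmin(end, as.integer(sz))
  } else if (any(start < 0)) {
    stop("resized interval extends below 0; supply chrom_sizes to clip",
         call. = FALSE)
  }
  data.frame(chrom = region$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Tile a genome into non-overlapping fixed-width windows
#'
#' Emits consecutive half-open windows `[k*w, (k+1)*w)` per chromosome,
#' dropping any trailing partial window.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Window width in bp (default 1000).
#' @return Interval data.frame of windows, sorted by chromosome then start.
#' @export
tile_genome <- function(chrom_sizes, window = 1000L) {
  if (anyDuplicated(names(chrom_sizes))) stop("duplicate chromosome name", call. = FALSE)
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive", call. = FALSE)
  pieces <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]] %/% window
    if (n == 0) return(NULL)
    data.frame(chrom = ch,
               start = as.integer((seq_len(n) - 1L) * window),
               end = as.integer(seq_len(n) * window),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Remove windows overlapping a blacklist
#'
#' Drops any window that overlaps an exclusion-list interval by at least
#' one base.
#'
#' @param windows,blacklist Interval data.frames.
#' @return The windows not touching the blacklist.
#' @export
filter_blacklist <- function(windows, blacklist) {
  .check_intervals(windows, "windows")
  if (nrow(blacklist) == 0) return(windows)
  .check_intervals(blacklist, "blacklist")
  hit <- IRanges::overlapsAny(.df_to_gr(windows), .df_to_gr(blacklist))
  windows[!hit, , drop = FALSE]
}

#' Label windows as enhancer / non-enhancer by fractional overlap
#'
#' A window is labeled `enhancer` when the bases it shares with the enhancer
#' call set (union across calls, so multiple overlapping calls sum) amount to
#' at least `min_frac` of the window width; otherwise `non_enhancer`.
#'
#' @param windows Interval data.frame of candidate windows.
#' @param enhancers Interval data.frame of enhancer calls.
#' @param min_frac Minimum overlap fraction (default 0.25).
#' @return `windows` with added `label` column (`"enhancer"`/`"non_enhancer"`)
#'   and `overlap_bp` (total overlapping bases).
#' @export
label_windows <- function(windows, enhancers, min_frac = 0.25) {
  .check_intervals(windows, "windows")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]", call. = FALSE)
  out <- windows
  if (nrow(enhancers) == 0) {
    out$overlap_bp <- 0L
    out$label <- "non_enhancer"
    return(out)
  }
  .check_intervals(enhancers, "enhancers")
  wgr <- .df_to_gr(windows)
  # union first so stacked enhancer calls are not double counted
  egr <- GenomicRanges::reduce(.df_to_gr(enhancers))
  hits <- GenomicRanges::findOverlaps(wgr, egr)
  ov <- IRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                            egr[S4Vectors::subjectHits(hits)])
  bp <- integer(nrow(windows))
  if (length(hits) > 0) {
    agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    bp[as.integer(names(agg))] <- as.integer(agg)
  }
  out$overlap_bp <- bp
  out$label <- ifelse(bp >= min_frac * (windows$end - windows$start),
                      "enhancer", "non_enhancer")
  out
}

#' Boost positive windows by coordinate shifting
#'
#' Duplicates each positive window `n_dup` times at symmetric shifts
#' (`step`, 2*`step`, ... in both directions), spanning `n_dup * step` bp
#' of jitter in total. With the defaults each positive yields 10 copies at
#' offsets -100..-20 and +20..+100 bp, a 200 bp span, augmenting the sparse
#' positive class while preserving each window's center distribution.
#'
#' @param positives Interval data.frame of positive windows.
#' @param n_dup Number of shifted duplicates per window (default 10; must be
#'   even for symmetric placement).
#' @param step Shift increment in bp (default 20).
#' @return Interval data.frame of the shifted duplicates only (originals are
#'   kept separately by the caller), with an `origin` column set to
#'   `"boosted"`.
#' @export
boost_positives <- function(positives, n_dup = 10L, step = 20L) {
  .check_intervals(positives, "positives")
  if (n_dup < 1) stop("n_dup must be >= 1", call. = FALSE)
  if (nrow(positives) == 0) {
    return(cbind(positives[, c("chrom", "start", "end")],
                 origin = character(0)))
  }
  half <- n_dup %/% 2L
  offsets <- step * c(-rev(seq_len(half)), seq_len(n_dup - half))
  out <- do.call(rbind, lapply(offsets, function(o) {
    data.frame(chrom = positives$chrom,
               start = as.integer(positives$start + o),
               end = as.integer(positives$end + o),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$start >= 0, , drop = FALSE]
  out$origin <- "boosted"
  out
}

#' Construct negative-control windows
#'
#' Two negative classes mirror the training design: (i) flank negatives, the
#' windows `offset` bp up- and downstream of every positive (dropped when they
#' run off the chromosome or overlap any enhancer call, so that local
#' chromatin background is sampled without label leakage), and (ii) random
#' negatives, a seeded uniform sample of enhancer-free genome windows with
#' count equal to the number of positives. Output row order is randomized.
#'
#' @param positives Interval data.frame of positive windows.
#' @param genome_windows Interval data.frame of all candidate windows
#'   (typically blacklist-filtered tiles).
#' @param enhancers Interval data.frame of enhancer calls to exclude.
#' @param offset Flank distance in bp (default 10000).
#' @param seed Integer seed for sampling and shuffling.
#' @param chrom_sizes Optional named vector to drop off-chromosome flanks.
#' @return Interval data.frame with an `origin` column
#'   (`"flank_negative"`/`"random_negative"`), shuffled.
#' @export
make_negatives <- function(positives, genome_windows, enhancers,
                           offset = 10000L, seed = 1L, chrom_sizes = NULL) {
  .check_intervals(positives, "positives")
  .check_intervals(genome_windows, "genome_windows")
  if (offset <= 0) stop("offset must be positive", call. = FALSE)
  flanks <- do.call(rbind, lapply(c(-offset, offset), function(o) {
    data.frame(chrom = positives$chrom,
               start = as.integer(positives$start + o),
               end = as.integer(positives$end + o),
               stringsAsFactors = FALSE)
  }))
  keep <- flanks$start >= 0
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[flanks$chrom]
    keep <- keep & !is.na(sz) & flanks$end <= sz
  }
  flanks <- flanks[keep, , drop = FALSE]
  if (nrow(enhancers) > 0 && nrow(flanks) > 0) {
    hit <- IRanges::overlapsAny(.df_to_gr(flanks), .df_to_gr(enhancers))
    flanks <- flanks[!hit, , drop = FALSE]
  }
  if (nrow(flanks) > 0) flanks$origin <- "flank_negative"
  else flanks <- cbind(flanks, origin = character(0))

  pool <- genome_windows
  if (nrow(enhancers) > 0) {
    hit <- IRanges::overlapsAny(.df_to_gr(pool), .df_to_gr(enhancers))
    pool <- pool[!hit, , drop = FALSE]
  }
  n_need <- nrow(positives)
  if (nrow(pool) < n_need) {
    stop("only ", nrow(pool), " enhancer-free windows available for ",
         n_need, " random negatives (short by ", n_need - nrow(pool), ")",
         call. = FALSE)
  }
  set.seed(seed)
  rand <- pool[sample.int(nrow(pool), n_need), c("chrom", "start", "end"),
               drop = FALSE]
  rand$origin <- "random_negative"
  out <- rbind(flanks, rand)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
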