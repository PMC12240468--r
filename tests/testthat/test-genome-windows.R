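# Interval algebra and training-set construction

iv <- function(chrom, start, end) {
  data.frame(chrom = rep(chrom, length.out = length(start)),
             start = start, end = end, stringsAsFactors = FALSE)
}

test_that("merge_intervals merges overlapping and bookended intervals", {
  expect_equal(merge_intervals(iv("chr1", c(10, 15), c(20, 30))),
               iv("chr1", 10, 30), ignore_attr = TRUE)
  # bookended ([10,20) + [20,30)) merge, matching bedtools merge defaults
  expect_equal(merge_intervals(iv("chr1", c(10, 20), c(20, 30))),
               iv("chr1", 10, 30), ignore_attr = TRUE)
  expect_equal(nrow(merge_intervals(iv("chr1", integer(0), integer(0)))), 0)
})

test_that("merge_intervals equals the per-base union oracle on random input", {
  set.seed(11)
  for (rep in 1:25) {
    x <- random_intervals(50)
    got <- merge_intervals(x)
    want <- oracle_intervals_from_bases(oracle_base_set(x))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$chrom, want$chrom)
  }
})

test_that("intersect_enhancer_calls returns STARR/ATAC overlap regions", {
  expect_equal(intersect_enhancer_calls(iv("chr1", 100, 400),
                                        iv("chr1", 300, 600)),
               iv("chr1", 300, 400), ignore_attr = TRUE)
  expect_equal(nrow(intersect_enhancer_calls(iv("chr1", 0, 100),
                                             iv("chr1", 200, 300))), 0)
  expect_equal(nrow(intersect_enhancer_calls(iv("chr1", 0, 100),
                                             iv("chr1", integer(0), integer(0)))), 0)
})

test_that("intersection equals the base-set intersection oracle", {
  set.seed(12)
  for (rep in 1:25) {
    a <- random_intervals(30); b <- random_intervals(30)
    got <- intersect_enhancer_calls(a, b)
    want <- oracle_intervals_from_bases(
      intersect(oracle_base_set(a), oracle_base_set(b)))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("resize_midpoint recenters to the requested width", {
  expect_equal(resize_midpoint(iv("chr1", 0, 1000), 1000),
               iv("chr1", 0, 1000), ignore_attr = TRUE)
  # odd-width input: midpoint by floor
  expect_equal(resize_midpoint(iv("chr1", 10, 15), 4),
               iv("chr1", 10, 14), ignore_attr = TRUE)
  # clipping at chromosome bounds when sizes are given, error otherwise
  expect_equal(resize_midpoint(iv("chr1", 300, 400), 1000,
                               chrom_sizes = c(chr1 = 10000)),
               iv("chr1", 0, 850), ignore_attr = TRUE)
  expect_error(resize_midpoint(iv("chr1", 300, 400), 1000), "chrom_sizes")
})

test_that("tile_genome drops trailing partial windows", {
  expect_equal(nrow(tile_genome(c(chr1 = 1000))), 1)
  expect_equal(nrow(tile_genome(c(chr1 = 2500))), 2)
  expect_equal(nrow(tile_genome(c(chr1 = 3000, chr2 = 1999))), 4)
  w <- tile_genome(c(chr1 = 3000))
  expect_equal(w$start, c(0, 1000, 2000))
  expect_equal(w$end, c(1000, 2000, 3000))
  expect_error(tile_genome(c(chr1 = 1000, chr1 = 2000)), "duplicate")
})

test_that("filter_blacklist removes any window with >= 1 bp overlap", {
  win <- iv("chr1", 0, 1000)
  expect_equal(nrow(filter_blacklist(win, iv("chr1", 999, 1001))), 0)
  expect_equal(filter_blacklist(win, iv("chr1", integer(0), integer(0))), win)
  set.seed(13)
  for (rep in 1:20) {
    w <- random_intervals(40); b <- random_intervals(10)
    got <- filter_blacklist(w, b)
    keep <- vapply(seq_len(nrow(w)), function(i) {
      !any(b$chrom == w$chrom[i] &
             mapply(oracle_overlap_bp, w$start[i], w$end[i],
                    b$start, b$end) > 0)
    }, logical(1))
    expect_equal(got, w[keep, , drop = FALSE], ignore_attr = TRUE)
  }
})

test_that("label_windows applies the 25% overlap rule exactly", {
  win <- iv("chr1", 0, 1000)
  expect_equal(label_windows(win, iv("chr1", 0, 250))$label, "enhancer")
  expect_equal(label_windows(win, iv("chr1", 0, 249))$label, "non_enhancer")
  # overlaps from multiple enhancer calls sum (base union)
  two <- iv("chr1", c(0, 500), c(150, 650))
  expect_equal(label_windows(win, two)$label, "enhancer")
  expect_equal(label_windows(win, two)$overlap_bp, 300L)
  # but stacked calls over the same bases do not double count
  stacked <- iv("chr1", c(0, 0), c(200, 200))
  expect_equal(label_windows(win, stacked)$label, "non_enhancer")
})

test_that("label_windows matches a per-base oracle and is monotone", {
  set.seed(14)
  for (rep in 1:15) {
    w <- random_intervals(25, max_len = 200)
    e1 <- random_intervals(10, max_len = 300)
    e2 <- rbind(e1, random_intervals(5, max_len = 300))
    l1 <- label_windows(w, e1, min_frac = 0.25)
    l2 <- label_windows(w, e2, min_frac = 0.25)
    eb <- oracle_base_set(e1)
    for (i in seq_len(nrow(w))) {
      ov <- length(intersect(oracle_base_set(w[i, ]), eb))
      expect_equal(l1$overlap_bp[i], ov)
      expect_equal(l1$label[i],
                   if (ov >= 0.25 * (w$end[i] - w$start[i])) "enhancer"
                   else "non_enhancer")
    }
    # growing the enhancer set never flips enhancer -> non_enhancer
    expect_true(all(!(l1$label == "enhancer" & l2$label == "non_enhancer")))
  }
})

test_that("boost_positives emits 10 symmetric shifts spanning 200 bp", {
  b <- boost_positives(iv("chr1", 50000, 51000))
  expect_equal(nrow(b), 10)
  offs <- sort(b$start - 50000)
  expect_equal(offs, c(-100, -80, -60, -40, -20, 20, 40, 60, 80, 100))
  expect_equal(max(offs) - min(offs), 200)
  expect_true(all(b$end - b$start == 1000))
  expect_equal(nrow(boost_positives(iv("x", integer(0), integer(0)))), 0)
})

test_that("make_negatives emits flanks and count-matched random negatives", {
  gw <- tile_genome(c(chr1 = 100000))
  pos <- iv("chr1", 50000, 51000)
  enh <- iv("chr1", 50000, 51000)
  neg <- make_negatives(pos, gw, enh, seed = 3)
  flanks <- neg[neg$origin == "flank_negative", ]
  expect_setequal(flanks$start, c(40000, 60000))
  expect_equal(sum(neg$origin == "random_negative"), nrow(pos))
  expect_false(any(neg$start == 50000))
  # upstream flank off-chromosome -> only downstream flank
  neg2 <- make_negatives(iv("chr1", 5000, 6000), gw, enh, seed = 3)
  expect_equal(neg2$start[neg2$origin == "flank_negative"], 15000)
  # insufficient enhancer-free windows is a named error
  expect_error(make_negatives(pos, gw[0, ], enh, seed = 3), "short by")
})

test_that("flank negatives overlapping any enhancer call are dropped", {
  gw <- tile_genome(c(chr1 = 100000))
  pos <- iv("chr1", 50000, 51000)
  enh <- iv("chr1", c(50000, 60500), c(51000, 60600))
  neg <- make_negatives(pos, gw, enh, seed = 5)
  expect_equal(neg$start[neg$origin == "flank_negative"], 40000)
})

test_that("BED round trip preserves intervals and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".bed")
  x <- random_intervals(20)
  write_bed(x, f)
  expect_equal(read_bed(f), x, ignore_attr = TRUE)
  writeLines(c("chr1\t10\t20", "chr1\t30\t25"), f)
  expect_error(read_bed(f), "line 2")
})
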