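# Genome-wide track comparison and enrichment statistics

mk_track <- function(scores, chrom = "chr1") {
  n <- length(scores)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * 1000L,
             end = seq_len(n) * 1000L, score = scores,
             stringsAsFactors = FALSE)
}

test_that("correlation matrix has unit diagonal and matches pairwise cor", {
  set.seed(61)
  s <- runif(50)
  tr <- list(a = mk_track(s), b = mk_track(1 - s), c = mk_track(runif(50)),
             d = mk_track(runif(50)))
  cc <- correlation_cluster(tr)
  expect_equal(unname(diag(cc$correlation)), rep(1, 4))
  expect_equal(cc$correlation["a", "b"], -1)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(cc$correlation[i, j], cor(tr[[i]]$score, tr[[j]]$score))
  }
  expect_setequal(cc$order, 1:4)
  expect_error(correlation_cluster(list(a = mk_track(s))), "two tracks")
  bad <- mk_track(runif(50)); bad$start <- bad$start + 1L
  expect_error(correlation_cluster(list(a = mk_track(s), b = bad)),
               "identical windows")
})

test_that("top_fraction keeps ceil(frac * n) windows with deterministic ties", {
  set.seed(62)
  tr <- mk_track(runif(1000))
  expect_equal(nrow(top_fraction(tr, 0.01)), 10)
  expect_equal(nrow(top_fraction(tr, 1)), 1000)
  expect_true(all(top_fraction(tr, 0.01)$score >= sort(tr$score, TRUE)[10]))
  tied <- mk_track(rep(c(1, 0.5), each = 50))
  expect_identical(top_fraction(tied, 0.6), top_fraction(tied, 0.6))
  expect_equal(top_fraction(tied, 0.6)$start[1:50], tied$start[1:50])
})

test_that("multiway intersection labels membership patterns", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  res_same <- multiway_intersection(list(x = a, y = a))
  expect_equal(unname(res_same$counts["x&y"]), 1L)
  expect_length(res_same$counts, 1)
  b <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  res_dis <- multiway_intersection(list(x = a, y = b))
  expect_setequal(names(res_dis$counts), c("x", "y"))
  # random 3-way instance against a per-base membership oracle
  set.seed(63)
  sets <- list(s1 = random_intervals(10), s2 = random_intervals(10),
               s3 = random_intervals(10))
  res <- multiway_intersection(sets)
  for (i in seq_len(nrow(res$elements))) {
    el <- res$elements[i, c("chrom", "start", "end")]
    bases <- oracle_base_set(el)
    member <- vapply(sets, function(s) {
      length(intersect(bases, oracle_base_set(s))) > 0
    }, logical(1))
    expect_equal(res$elements$pattern[i],
                 paste(names(sets)[member], collapse = "&"))
    # disjoint elements have a single pattern: all bases agree
    expect_true(all(member[strsplit(res$elements$pattern[i], "&")[[1]]]))
  }
  expect_error(multiway_intersection(list(a, b)), "named")
})

test_that("poisson enrichment equals exact binomial tails", {
  expect_equal(poisson_enrichment(0, 0), 1)
  expect_gte(poisson_enrichment(7, 7), 0.5)
  # observed 20 vs control 5: upper tail of Binomial(25, 0.5)
  want <- sum(dbinom(20:25, 25, 0.5))
  expect_equal(poisson_enrichment(20, 5), want, tolerance = 1e-12)
  set.seed(64)
  for (rep in 1:30) {
    o <- rpois(1, 15); ctl <- rpois(1, 10)
    want <- sum(dbinom(o:(o + ctl), o + ctl, 0.5))
    expect_equal(poisson_enrichment(o, ctl), want, tolerance = 1e-12)
  }
  # exposure ratio shifts the null proportion
  e <- 2
  expect_equal(poisson_enrichment(10, 2, exposure_ratio = e),
               sum(dbinom(10:12, 12, e / (e + 1))), tolerance = 1e-12)
  expect_error(poisson_enrichment(-1, 3), "non-negative")
})

test_that("BY correction matches the step-up formula with the harmonic constant", {
  expect_equal(by_correction(0.03), 0.03)
  p <- c(0.01, 0.02)
  cm <- 1 + 1 / 2
  want <- c(min(1, min(2 * cm * 0.01 / 1, 2 * cm * 0.02 / 2)),
            min(1, 2 * cm * 0.02 / 2))
  expect_equal(by_correction(p), want)
  set.seed(65)
  for (m in c(5, 20, 100)) {
    p <- runif(m)^2
    got <- by_correction(p)
    cm <- sum(1 / seq_len(m))
    ord <- order(p)
    stepup <- numeric(m)
    adj <- m * cm * p[ord] / seq_len(m)
    for (i in seq_len(m)) stepup[i] <- min(1, min(adj[i:m]))
    want <- numeric(m); want[ord] <- stepup
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= p))
    expect_true(all(got <= 1))
    # monotone: larger raw p never gets smaller adjusted p
    expect_true(all(diff(got[ord]) >= -1e-12))
  }
})

test_that("enrichment table flags adjusted p below threshold", {
  tab <- enrichment_table(c("f1", "f2", "f3"),
                          observed = c(50, 10, 9),
                          control = c(10, 10, 50))
  expect_true(tab$enriched[1])
  expect_false(tab$enriched[2])
  expect_true(all(tab$adjusted_p >= tab$p_value))
})

test_that("contact ratio counts enhancer-promoter anchor pairs", {
  inter <- data.frame(
    chrom1 = "chr1", start1 = c(0, 0, 500, 900, 100, 0, 200, 950, 0, 400),
    end1 = c(50, 50, 550, 950, 150, 50, 250, 1000, 50, 450),
    chrom2 = "chr1", start2 = c(2000, 100, 2000, 2010, 2020, 600, 2030, 2040,
                                960, 700),
    end2 = c(2050, 150, 2050, 2060, 2070, 650, 2080, 2090, 1000, 750)
  )
  enh <- data.frame(chrom = "chr1", start = c(0, 900), end = c(60, 1000))
  rnd <- data.frame(chrom = "chr1", start = c(400, 500), end = c(460, 560))
  prom <- data.frame(chrom = "chr1", start = 2000, end = 2100)
  # hand count: enhancer-promoter pairs = rows 1, 4, 8; random-promoter
  # pairs = row 3 only
  res <- contact_ratio(inter, enh, prom, rnd)
  expect_equal(res$ep_count, 3)
  expect_equal(res$rp_count, 1)
  expect_equal(res$log2_ratio, log2(3))
  # E-P == R-P -> 0 ; zero denominator flagged infinite
  res0 <- contact_ratio(inter, enh, prom, enh)
  expect_equal(res0$log2_ratio, 0)
  far <- data.frame(chrom = "chr9", start = 0, end = 10)
  resinf <- contact_ratio(inter, enh, prom, far)
  expect_true(resinf$infinite)
  expect_equal(resinf$log2_ratio, Inf)
})

test_that("promoters are fixed windows on gene starts", {
  tss <- data.frame(chrom = "chr1", start = c(5000, 100))
  pr <- promoters_from_tss(tss, width = 1000,
                           chrom_sizes = c(chr1 = 100000))
  expect_equal(pr$start, c(4500, 0))
  expect_equal(pr$end, c(5500, 600))
  expect_equal(pr$end - pr$start, c(1000, 600))
})

test_that("top-1% sharing across synthetic lines rises with shared_fraction", {
  shared_top <- function(s) {
    cfg <- synthetic_config(n_pos = 300, n_neg = 300, n_cell_lines = 2,
                            shared_fraction = s, noise_sd = 0.05, seed = 66)
    lines <- generate_cell_lines(cfg)
    planted <- which(cfg$positive_signature > 0)
    tops <- lapply(lines, function(d) {
      sc <- apply(d$tensor[, planted, , drop = FALSE], 1, mean)
      top_fraction(mk_track_from(d$windows, sc), 0.2)
    })
    ov <- multiway_intersection(list(l1 = tops[[1]][, 1:3],
                                     l2 = tops[[2]][, 1:3]))
    n_both <- sum(ov$elements$pattern == "l1&l2")
    n_both / nrow(ov$elements)
  }
  mk_track_from <- function(w, s) {
    data.frame(chrom = w$chrom, start = w$start, end = w$end, score = s,
               stringsAsFactors = FALSE)
  }
  expect_gt(shared_top(0.9), shared_top(0.05))
})
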