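# Training loop, hold-out schemes, and rank metrics

test_that("auroc handles separation, ties, and matches the 6-sample oracle", {
  expect_equal(auroc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(auroc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  labels <- c(1, 1, 0, 0, 1, 0)
  scores <- c(0.8, 0.4, 0.6, 0.1, 0.9, 0.4)
  expect_equal(auroc(labels, scores), oracle_auroc(labels, scores))
  expect_equal(auroc(labels, scores), 7.5 / 9)  # frozen from the oracle
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("auprc handles degenerate cases and matches the sweep oracle", {
  expect_equal(auprc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auprc(c(1, 1, 1), c(0.5, 0.1, 0.9)), 1.0)
  labels <- c(1, 1, 0, 0, 1, 0)
  scores <- c(0.8, 0.4, 0.6, 0.1, 0.9, 0.4)
  expect_equal(auprc(labels, scores), oracle_auprc(labels, scores),
               tolerance = 1e-14)
  expect_error(auprc(c(0, 0), c(0.2, 0.3)), "positive")
})

test_that("metrics agree with oracles on random tied instances", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    expect_identical(auroc(labels, scores), oracle_auroc(labels, scores))
    expect_lt(abs(auprc(labels, scores) - oracle_auprc(labels, scores)), 1e-12)
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(18)
  labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- runif(40)
  a <- auroc(labels, scores)
  expect_equal(auroc(labels, exp(3 * scores)), a)
  expect_equal(auroc(labels, qlogis(scores)), a)
})

test_that("training reduces loss on separable data and is seed-deterministic", {
  cfg <- tiny_config(noise_sd = 0.02)
  ds <- generate_dataset(cfg)
  spec <- model_spec(1, 8, 100, small_hyperparams())
  m <- build_model(spec, seed = 5)
  fit <- train(m, ds$tensor, ds$labels, training_config(epochs = 8, seed = 6))
  expect_length(fit$loss_curve, 8)
  expect_lt(fit$loss_curve[8], fit$loss_curve[1])
  fit2 <- train(m, ds$tensor, ds$labels, training_config(epochs = 8, seed = 6))
  expect_identical(fit$loss_curve, fit2$loss_curve)
  expect_identical(score(fit$model, ds$tensor), score(fit2$model, ds$tensor))
})

test_that("zero learning rate leaves parameters untouched", {
  ds <- generate_dataset(tiny_config())
  hp <- small_hyperparams(); hp$dropout <- 0
  m <- build_model(model_spec(1, 8, 100, hp), seed = 5)
  fit <- train(m, ds$tensor, ds$labels,
               training_config(epochs = 3, lr = 0, seed = 6))
  expect_identical(fit$model$layers, m$layers)
  expect_equal(diff(range(fit$loss_curve)), 0, tolerance = 1e-12)
})

test_that("labels must be binary", {
  ds <- generate_dataset(tiny_config())
  m <- build_model(model_spec(1, 8, 100, small_hyperparams()), seed = 1)
  expect_error(train(m, ds$tensor, ds$labels + 0.5), "binary")
})

test_that("chromosome holdout is chromosome-disjoint with boosting in train only", {
  win <- rbind(
    data.frame(chrom = "chr1", start = (1:10) * 1000, end = (2:11) * 1000,
               label = rep(c("enhancer", "non_enhancer"), 5)),
    data.frame(chrom = "chr2", start = (1:10) * 1000, end = (2:11) * 1000,
               label = rep(c("enhancer", "non_enhancer"), each = 5)),
    data.frame(chrom = "chr3", start = (1:4) * 1000, end = (2:5) * 1000,
               label = "non_enhancer")
  )
  hs <- chromosome_holdout(win, "chr2")
  expect_setequal(unique(hs$eval$chrom), "chr2")
  expect_false("chr2" %in% hs$train$chrom)
  # boosted rows only in train, 10 per training positive
  expect_equal(sum(hs$train$origin == "boosted"), 10 * 5)
  expect_false("boosted" %in% hs$eval$origin)
  # window conservation: unboosted train rows + eval rows = all rows
  expect_equal(sum(hs$train$origin != "boosted") + nrow(hs$eval), nrow(win))
  expect_error(chromosome_holdout(win, "chrX"), "absent")
})

test_that("cell-line holdout rotates each line out exactly once", {
  cfg <- synthetic_config(n_pos = 15, n_neg = 15, n_cell_lines = 3,
                          shared_fraction = 0.5, seed = 12)
  lines <- generate_cell_lines(cfg)
  rots <- cell_line_holdout(lines, seed = 4)
  expect_length(rots, 3)
  expect_setequal(vapply(rots, `[[`, integer(1), "holdout"), 1:3)
  for (r in rots) {
    expect_equal(nrow(r$train$X), 2 * 30)
    expect_equal(nrow(r$eval$X), 30)
    # eval samples are not rows of the training matrix
    key <- function(M) apply(round(M, 10), 1, paste, collapse = ",")
    expect_length(intersect(key(r$eval$X), key(r$train$X)), 0)
  }
})

test_that("genome_scores joins scores to window coordinates", {
  ds <- generate_dataset(tiny_config())
  m <- build_model(model_spec(1, 8, 100, small_hyperparams()), seed = 2)
  sc <- genome_scores(m, ds$tensor, ds$windows)
  expect_equal(nrow(sc), dim(ds$tensor)[1])
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_identical(sc$start, ds$windows$start)
  expect_identical(sc, genome_scores(m, ds$tensor, ds$windows))
  expect_error(genome_scores(m, ds$tensor, ds$windows[-1, ]), "differ")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(sc, f)
  back <- utils::read.table(f, sep = "\t")
  expect_equal(nrow(back), nrow(sc))
})
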