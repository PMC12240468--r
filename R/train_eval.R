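# Training loop, hold-out schemes, and rank-based evaluation metrics.

#' Training configuration
#'
#' @param epochs Training epochs (default 20, which plateaus the loss on
#'   this problem class).
#' @param batch_size Minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param weight_decay L2 penalty coefficient added to parameter gradients
#'   (default 0; the planted-signature benchmark uses 1e-4 to smooth the
#'   decision surface of heavily over-parameterized fits).
#' @param seed Seed controlling shuffling, dropout, and initialization-free
#'   reproducibility of the loop.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 20L, batch_size = 64L, lr = 1e-3,
                            weight_decay = 0, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (weight_decay < 0) stop("weight_decay must be non-negative", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Chromosome hold-out split
#'
#' Evaluation takes every labeled window on the hold-out chromosomes
#' (unboosted); training takes the remaining windows with positives boosted
#' by coordinate shifting. Train and eval are chromosome-disjoint by
#' construction.
#'
#' @param windows Labeled window data.frame (columns `chrom`, `start`,
#'   `end`, `label`, optional `origin`).
#' @param holdout_chroms Character vector of chromosomes to hold out.
#' @param n_dup,step Boosting parameters passed to [boost_positives()].
#' @return List with `train` (boosted) and `eval` data.frames.
#' @export
chromosome_holdout <- function(windows, holdout_chroms, n_dup = 10L,
                               step = 20L) {
  if (!all(holdout_chroms %in% windows$chrom)) {
    stop("hold-out chromosome absent from windows", call. = FALSE)
  }
  hold <- windows$chrom %in% holdout_chroms
  eval_set <- windows[hold, , drop = FALSE]
  train_set <- windows[!hold, , drop = FALSE]
  if (nrow(eval_set) == 0 || nrow(train_set) == 0) {
    stop("empty train or eval partition", call. = FALSE)
  }
  if (!("origin" %in% names(train_set))) {
    train_set$origin <- ifelse(train_set$label == "enhancer",
                               "positive", "random_negative")
  }
  pos <- train_set[train_set$label == "enhancer", , drop = FALSE]
  if (nrow(pos) > 0) {
    boosted <- boost_positives(pos[, c("chrom", "start", "end")],
                               n_dup = n_dup, step = step)
    boosted$label <- "enhancer"
    train_set <- rbind(train_set[, c("chrom", "start", "end", "origin", "label")],
                       boosted[, c("chrom", "start", "end", "origin", "label")])
  }
  rownames(train_set) <- NULL
  rownames(eval_set) <- NULL
  list(train = train_set, eval = eval_set)
}

#' Cell-line hold-out rotation
#'
#' Every line serves as the evaluation set exactly once; the remaining
#' lines' samples are concatenated (seeded shuffle) for training.
#'
#' @param datasets List of `synthetic_dataset` (or lists with `tensor`,
#'   `labels`), one per cell line.
#' @param seed Shuffle seed.
#' @return List of rotations; each has `train` (list with `X` flat matrix,
#'   `y` labels), `eval` (same shape), and `holdout` (line index).
#' @export
cell_line_holdout <- function(datasets, seed = 1L) {
  k <- length(datasets)
  if (k < 2) stop("need at least two cell lines", call. = FALSE)
  lapply(seq_len(k), function(hold) {
    Xs <- lapply(datasets[-hold], function(d) flatten_all(d$tensor))
    ys <- lapply(datasets[-hold], function(d) d$labels)
    X <- do.call(rbind, Xs)
    y <- unlist(ys, use.names = FALSE)
    set.seed(seed + hold)
    ord <- sample.int(nrow(X))
    list(train = list(X = X[ord, , drop = FALSE], y = y[ord]),
         eval = list(X = flatten_all(datasets[[hold]]$tensor),
                     y = datasets[[hold]]$labels),
         holdout = hold)
  })
}

#' Train a predictor with binary cross-entropy
#'
#' Adam on minibatches with per-epoch seeded shuffling; dropout active.
#' Returns the per-epoch mean training loss alongside the trained model.
#'
#' @param model An untrained (or partially trained) `predictor`.
#' @param X Flat input matrix (samples x input_dim) or occupancy array.
#' @param y 0/1 labels.
#' @param config A [training_config()].
#' @return List with `model` (trained `predictor`) and `loss_curve`
#'   (length = epochs).
#' @export
train <- function(model, X, y, config = training_config()) {
  stopifnot(inherits(model, "predictor"))
  if (!is.null(dim(X)) && length(dim(X)) == 3) X <- flatten_all(X)
  X <- .as_input_matrix(model, X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  n <- nrow(X)
  set.seed(config$seed)
  layers <- model$layers
  opt <- .adam_init(layers)
  tstep <- 0L
  loss_curve <- numeric(config$epochs)
  eps <- 1e-7
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- .net_forward(layers, xb, training = TRUE)
      p <- pmin(pmax(as.vector(fw$out), eps), 1 - eps)
      loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep,
             " (learning rate too high?)", call. = FALSE)
      }
      total <- total + loss * length(idx)
      # dL/dp for BCE; the sigmoid layer backward turns this into (p - y)/n
      gout <- matrix((p - yb) / (p * (1 - p)) / length(idx), ncol = 1)
      bw <- .net_backward(layers, fw$caches, gout)
      if (config$weight_decay > 0) {
        for (i in seq_along(layers)) {
          for (nm in names(bw$grads[[i]])) {
            bw$grads[[i]][[nm]] <- bw$grads[[i]][[nm]] +
              config$weight_decay * layers[[i]]$params[[nm]]
          }
        }
      }
      tstep <- tstep + 1L
      if (config$lr > 0) {
        up <- .adam_update(layers, bw$grads, opt, config$lr, tstep)
        layers <- up$layers
        opt <- up$state
      }
    }
    loss_curve[ep] <- total / n
  }
  model$layers <- layers
  model$epochs_trained <- model$epochs_trained + config$epochs
  list(model = model, loss_curve = loss_curve)
}

#' Area under the ROC curve
#'
#' Computed from ranks, equal to `P(score_pos > score_neg) + 0.5 P(tie)` over
#' all positive/negative pairs (ties get half credit).
#'
#' @param labels 0/1 labels.
#' @param scores Numeric scores.
#' @return auROC in `[0,1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("auroc requires both classes present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated estimator from a descending-score sweep with tied
#' scores grouped: at each distinct threshold the curve gains
#' `(recall_i - recall_{i-1}) * precision_i`. No trapezoid interpolation of
#' precision (which is optimistic at low prevalence).
#'
#' @inheritParams auroc
#' @return auPRC in `[0,1]`.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("auprc requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group ties: cumulative counts at the end of each tie group
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l)[grp_end]
  npred <- grp_end
  precision <- tp / npred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Genome-wide prediction scores
#'
#' Scores every window of a tensor and joins scores to coordinates.
#'
#' @param model A trained `predictor`.
#' @param tensor Occupancy array samples x targets x bins.
#' @param windows Window data.frame aligned with the tensor's samples.
#' @return Data.frame `chrom`, `start`, `end`, `score` (a bedGraph-shaped
#'   table).
#' @export
genome_scores <- function(model, tensor, windows) {
  s <- score(model, tensor)
  if (nrow(windows) != length(s)) {
    stop("windows and tensor sample counts differ", call. = FALSE)
  }
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             score = s, stringsAsFactors = FALSE)
}

#' Write a score table as bedGraph
#'
#' @param scores Data.frame from [genome_scores()].
#' @param path Output path.
#' @export
write_bedgraph <- function(scores, path) {
  utils::write.table(scores[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Evaluate a predictor on labeled data
#'
#' @param model A trained `predictor`.
#' @param X Flat matrix or occupancy array.
#' @param y 0/1 labels.
#' @param holdout_descriptor Free-text description of the hold-out scheme.
#' @param loss_curve Optional per-epoch training loss to carry in the
#'   report (from [train()]).
#' @return An `eval_report` list: `auroc`, `auprc`, `n_pos`, `n_neg`,
#'   `loss_curve`, `holdout_descriptor`.
#' @export
evaluate <- function(model, X, y, holdout_descriptor = "",
                     loss_curve = NULL) {
  s <- score(model, X)
  structure(list(auroc = auroc(y, s), auprc = auprc(y, s),
                 n_pos = sum(y == 1), n_neg = sum(y == 0),
                 loss_curve = loss_curve,
                 holdout_descriptor = holdout_descriptor),
            class = "eval_report")
}
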