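# Gradient-based attribution: saliency and integrated gradients, used to
# cross-validate the swarm attack's feature recovery.

#' Saliency attribution
#'
#' Absolute value of the gradient of the model's score with respect to each
#' input coordinate.
#'
#' @param model A differentiable `predictor`.
#' @param x Flat matrix (samples x input_dim) or occupancy array.
#' @return An `attribution_map`: list with `values` (samples x targets x
#'   bins array), `method`.
#' @export
saliency <- function(model, x) {
  if (is.function(model)) {
    stop("saliency requires a differentiable predictor, not a black-box function",
         call. = FALSE)
  }
  if (!is.null(dim(x)) && length(dim(x)) == 3) x <- flatten_all(x)
  g <- abs(score_gradient(model, x))
  structure(list(values = unflatten(g, model$spec$n_targets,
                                    model$spec$n_bins),
                 method = "saliency"),
            class = "attribution_map")
}

#' Integrated gradients attribution
#'
#' Midpoint-Riemann approximation of the path integral of the input
#' gradient along the straight line from the baseline to the input:
#' `(x - x') * mean_k grad f(x' + (k - 1/2)/m * (x - x'))`. Satisfies the
#' completeness axiom — attributions sum to `f(x) - f(baseline)` — as the
#' step count grows.
#'
#' @param model A differentiable `predictor`.
#' @param x Flat matrix (samples x input_dim) or occupancy array.
#' @param baseline Baseline vector (default zero — the "no occupancy"
#'   state) or matrix matching `x`.
#' @param steps Riemann steps (default 64).
#' @return An `attribution_map` with `values`, `method`, `baseline`,
#'   `steps`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 64L) {
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  if (!is.null(dim(x)) && length(dim(x)) == 3) x <- flatten_all(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(baseline)) baseline <- matrix(0, nrow(x), ncol(x))
  if (is.null(dim(baseline))) {
    if (length(baseline) != ncol(x) && length(baseline) != 1) {
      stop("baseline shape does not match input", call. = FALSE)
    }
    baseline <- matrix(baseline, nrow(x), ncol(x), byrow = TRUE)
  }
  if (!all(dim(baseline) == dim(x))) {
    stop("baseline shape does not match input", call. = FALSE)
  }
  diff_ <- x - baseline
  acc <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    acc <- acc + score_gradient(model, baseline + alpha * diff_)
  }
  attr_flat <- diff_ * acc / steps
  structure(list(values = unflatten(attr_flat, model$spec$n_targets,
                                    model$spec$n_bins),
                 method = "integrated_gradients",
                 baseline = baseline, steps = as.integer(steps)),
            class = "attribution_map")
}

#' Rank chromatin targets by attack x attribution contribution
#'
#' Per coordinate, the product of the swarm-generated synthetic occupancy
#' and its integrated-gradient attribution; summed per target and
#' rank-sorted descending, reported per run. The product scores features the
#' attack both reconstructs and the network actually weights.
#'
#' @param attack_data Matrix (runs x dim) of synthetic vectors — e.g.
#'   `attack_result$runs` — or a single flat vector.
#' @param ig_map Matrix of matching shape with integrated-gradient values
#'   (flat), or an `attribution_map`.
#' @param n_targets,n_bins Tensor shape.
#' @param top_k Targets to report per run (default all).
#' @return List of per-run data.frames (`target`, `contribution`), sorted
#'   descending; ties broken by target order.
#' @export
contribution_ranking <- function(attack_data, ig_map, n_targets, n_bins,
                                 top_k = NULL) {
  if (is.null(dim(attack_data))) attack_data <- matrix(attack_data, nrow = 1)
  if (inherits(ig_map, "attribution_map")) ig_map <- flatten_all(ig_map$values)
  if (is.null(dim(ig_map))) ig_map <- matrix(ig_map, nrow = 1)
  if (!all(dim(ig_map) == dim(attack_data))) {
    stop("attack data and attribution shapes differ", call. = FALSE)
  }
  if (is.null(top_k)) top_k <- n_targets
  lapply(seq_len(nrow(attack_data)), function(r) {
    prod_ <- attack_data[r, ] * ig_map[r, ]
    per_target <- rowSums(matrix(prod_, nrow = n_targets, byrow = TRUE))
    ord <- order(-per_target, seq_len(n_targets))
    data.frame(target = paste0("target", ord),
               contribution = per_target[ord],
               stringsAsFactors = FALSE)[seq_len(min(top_k, n_targets)), ]
  })
}

#' Bin an attribution map to one value per (sample, target)
#'
#' Mean over bins per target for both the attribution map and the occupancy
#' data; the row order comes from hierarchical clustering of the occupancy
#' matrix (average linkage on Euclidean distance) and is applied identically
#' to both matrices, so heatmaps of data and attribution align.
#'
#' @param map An `attribution_map` (or samples x targets x bins array).
#' @param occupancy Occupancy array samples x targets x bins used for
#'   clustering; defaults to the map itself.
#' @return List with `attribution` (samples x targets), `occupancy`
#'   (samples x targets), `row_order`.
#' @export
binned_visualization <- function(map, occupancy = NULL) {
  vals <- if (inherits(map, "attribution_map")) map$values else map
  if (is.null(occupancy)) occupancy <- vals
  attr_m <- apply(vals, c(1, 2), mean)
  occ_m <- apply(occupancy, c(1, 2), mean)
  colnames(attr_m) <- colnames(occ_m) <- paste0("target", seq_len(ncol(occ_m)))
  row_order <- seq_len(nrow(occ_m))
  if (nrow(occ_m) > 2) {
    hc <- stats::hclust(stats::dist(occ_m), method = "average")
    row_order <- hc$order
  }
  list(attribution = attr_m[row_order, , drop = FALSE],
       occupancy = occ_m[row_order, , drop = FALSE],
       row_order = row_order)
}
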