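# Adversarial particle swarm optimization: an architecture-agnostic attack
# that searches the input space of a trained classifier for vectors that
# maximally activate it (positive mode) or maximally deactivate it
# (inverted-cost negative mode). Converged vectors are synthetic chromatin
# profiles reconstructing what the network uses for inference.

#' Swarm hyperparameters
#'
#' @param omega Inertia weight (default 0.729).
#' @param c1 Cognitive weight: attraction to a particle's personal best
#'   (default 1.49445).
#' @param c2 Social weight: attraction to the swarm's global best
#'   (default 1.49445).
#' @param bounds Length-2 vector of per-coordinate bounds (default
#'   `c(0, 1)`, matching the normalized occupancy range).
#' @param sparsity Probability that each coordinate is zeroed at
#'   initialization (default 0.999, emulating the sparse nature of ChIP
#'   data).
#' @param n_particles Swarm size (default 500).
#' @param epochs Swarm iterations (default 20, sufficient for convergence at
#'   this problem size; large networks warrant ~100).
#' @param seed Integer seed.
#' @param per_coordinate_r Draw the r1/r2 uniforms per coordinate (default
#'   TRUE, the standard PSO practice, which mixes personal-best and
#'   global-best support coordinate-wise and is what lets the swarm converge
#'   within 20 epochs at input dimensions in the hundreds); `FALSE` draws
#'   one scalar pair per particle per epoch.
#' @param remask_each_epoch Re-apply the sparsity mask every epoch instead of
#'   only at initialization (default FALSE; provided for sensitivity
#'   analysis).
#' @return A `swarm_hyperparams` list.
#' @export
swarm_hyperparams <- function(omega = 0.729, c1 = 1.49445, c2 = 1.49445,
                              bounds = c(0, 1), sparsity = 0.999,
                              n_particles = 500L, epochs = 20L, seed = 1L,
                              per_coordinate_r = TRUE,
                              remask_each_epoch = FALSE) {
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy lo < hi", call. = FALSE)
  if (sparsity < 0 || sparsity > 1) stop("sparsity must be in [0,1]", call. = FALSE)
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  structure(list(omega = omega, c1 = c1, c2 = c2, bounds = bounds,
                 sparsity = sparsity, n_particles = as.integer(n_particles),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 per_coordinate_r = per_coordinate_r,
                 remask_each_epoch = remask_each_epoch),
            class = "swarm_hyperparams")
}

#' Swarm objective
#'
#' Higher is always better internally: the model's probability in positive
#' mode, one minus it with the inverted cost (negative mode), so the same
#' maximizing swarm converges to anti-predictive features.
#'
#' @param model A `predictor` (or any function mapping an input matrix to
#'   probabilities, for black-box use).
#' @param x Input vector or matrix of row vectors.
#' @param mode `"positive"` or `"negative"`.
#' @return Numeric objective value(s).
#' @export
objective <- function(model, x, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  p <- if (is.function(model)) model(x) else score(model, x)
  if (mode == "positive") p else 1 - p
}

# Internal swarm objective: same ordering as objective(), but evaluated on
# the log-odds scale for predictors so that a saturated sigmoid (p
# numerically 0 or 1) does not collapse the landscape into ties.
.swarm_objective <- function(model, x, mode) {
  if (inherits(model, "predictor")) {
    s <- score_logit(model, x)
    if (mode == "positive") s else -s
  } else {
    objective(model, x, mode)
  }
}

# map an internal objective value back to the probability scale
.objective_to_prob <- function(model, value) {
  if (inherits(model, "predictor")) stats::plogis(value) else value
}

#' Initialize a swarm
#'
#' Particle locations are uniform within bounds with each coordinate
#' independently zeroed with probability `sparsity`; velocities start at
#' zero; personal bests are the initial locations.
#'
#' @param dim Input dimensionality (targets x bins of the attacked model).
#' @param hp A [swarm_hyperparams()].
#' @return A `swarm_state` list: `pos`, `vel`, `pbest` (n_particles x dim
#'   matrices), `pbest_score`, `gbest`, `gbest_score`, `epoch`, `mode`, `hp`.
#' @export
init_swarm <- function(dim, hp) {
  set.seed(hp$seed)
  n <- hp$n_particles
  pos <- matrix(stats::runif(n * dim, hp$bounds[1], hp$bounds[2]), n, dim)
  if (hp$sparsity > 0) {
    keep <- matrix(stats::runif(n * dim) >= hp$sparsity, n, dim)
    pos <- pos * keep
  }
  structure(list(pos = pos, vel = matrix(0, n, dim), pbest = pos,
                 pbest_score = rep(-Inf, n), gbest = pos[1, ],
                 gbest_score = -Inf, epoch = 0L, mode = "positive", hp = hp),
            class = "swarm_state")
}

#' Particle velocity update
#'
#' The three-term rule: inertia times the previous velocity, plus the
#' cognitive pull toward the personal best and the social pull toward the
#' global best, each scaled by its weight and a fresh uniform draw. No
#' velocity clamping.
#'
#' @param velocity,location,pbest,gbest Numeric vectors of equal length.
#' @param hp A [swarm_hyperparams()].
#' @param r1,r2 Optional uniform draws (scalars, or vectors when
#'   `hp$per_coordinate_r`); drawn fresh from `U[0,1]` when missing.
#' @return The new velocity vector.
#' @export
velocity_update <- function(velocity, location, pbest, gbest, hp,
                            r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- if (hp$per_coordinate_r) stats::runif(length(velocity)) else stats::runif(1)
  if (is.null(r2)) r2 <- if (hp$per_coordinate_r) stats::runif(length(velocity)) else stats::runif(1)
  hp$omega * velocity + hp$c1 * r1 * (pbest - location) +
    hp$c2 * r2 * (gbest - location)
}

#' Particle position update
#'
#' New location is the previous location plus the new velocity, clipped
#' coordinate-wise to the bounds.
#'
#' @param location,velocity Numeric vectors.
#' @param bounds Length-2 bounds.
#' @return List with `location` (clipped) and `clipped` (logical vector of
#'   coordinates that hit a bound).
#' @export
position_update <- function(location, velocity, bounds = c(0, 1)) {
  raw <- location + velocity
  newloc <- pmin(pmax(raw, bounds[1]), bounds[2])
  list(location = newloc, clipped = raw != newloc)
}

#' Advance a swarm by one epoch
#'
#' Order per epoch: score all particle locations, update personal bests,
#' update the single (synchronous) global best, then update every particle's
#' velocity and position. Velocity components that caused a bound clip are
#' zeroed to avoid boundary pinning. The global-best score is non-decreasing
#' by construction.
#'
#' @param state A `swarm_state`.
#' @param model Predictor (or scoring function) being attacked.
#' @param mode `"positive"` or `"negative"`.
#' @return The advanced `swarm_state`.
#' @export
swarm_step <- function(state, model, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  hp <- state$hp
  n <- nrow(state$pos); d <- ncol(state$pos)
  scores <- .swarm_objective(model, state$pos, mode)
  improved <- scores > state$pbest_score
  state$pbest[improved, ] <- state$pos[improved, , drop = FALSE]
  state$pbest_score[improved] <- scores[improved]
  best_i <- which.max(state$pbest_score)
  if (state$pbest_score[best_i] > state$gbest_score) {
    state$gbest_score <- state$pbest_score[best_i]
    state$gbest <- state$pbest[best_i, ]
  }
  if (hp$per_coordinate_r) {
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
  } else {
    r1 <- stats::runif(n)
    r2 <- stats::runif(n)
  }
  gmat <- matrix(state$gbest, n, d, byrow = TRUE)
  state$vel <- hp$omega * state$vel +
    hp$c1 * r1 * (state$pbest - state$pos) +
    hp$c2 * r2 * (gmat - state$pos)
  raw <- state$pos + state$vel
  newpos <- pmin(pmax(raw, hp$bounds[1]), hp$bounds[2])
  state$vel[raw != newpos] <- 0
  state$pos <- newpos
  if (hp$remask_each_epoch && hp$sparsity > 0) {
    keep <- matrix(stats::runif(n * d) >= hp$sparsity, n, d)
    state$pos <- state$pos * keep
  }
  state$epoch <- state$epoch + 1L
  state$mode <- mode
  state
}

#' Run the full adversarial swarm attack
#'
#' `n_runs` independently seeded swarms are run to convergence; each run's
#' final global best is one synthetic chromatin vector. The per-coordinate
#' mean over runs is the attack profile, and per-target aggregates (mean
#' over bins, i.e. the profile binned to one value per feature) summarize
#' which chromatin targets drive — or, in negative mode, suppress —
#' prediction.
#'
#' @param model A trained `predictor` or black-box scoring function.
#' @param hp A [swarm_hyperparams()].
#' @param n_runs Independent swarm runs (default 8).
#' @param mode `"positive"` or `"negative"`.
#' @param n_targets,n_bins Tensor shape used to fold flat vectors back to
#'   (target, bin); taken from the model spec when omitted.
#' @return An `attack_result`: `runs` (n_runs x dim matrix of final bests),
#'   `run_scores`, `profile` (targets x bins mean profile),
#'   `feature_summary` (n_runs x targets per-run target means),
#'   `feature_means` (overall per-target means), `mode`, `hp`.
#' @export
attack <- function(model, hp = swarm_hyperparams(), n_runs = 8L,
                   mode = c("positive", "negative"),
                   n_targets = NULL, n_bins = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_targets) && inherits(model, "predictor")) {
    n_targets <- model$spec$n_targets
    n_bins <- model$spec$n_bins
  }
  if (is.null(n_targets) || is.null(n_bins)) {
    stop("n_targets and n_bins required for a black-box model", call. = FALSE)
  }
  dim_ <- n_targets * n_bins
  runs <- matrix(0, n_runs, dim_)
  run_scores <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    hpr <- hp
    hpr$seed <- hp$seed + 7919L * r  # independent seeded runs
    state <- init_swarm(dim_, hpr)
    for (e in seq_len(hp$epochs)) state <- swarm_step(state, model, mode)
    runs[r, ] <- state$gbest
    run_scores[r] <- .objective_to_prob(model, state$gbest_score)
  }
  profile <- apply(unflatten(runs, n_targets, n_bins), c(2, 3), mean)
  per_run <- t(apply(runs, 1, function(v) {
    rowMeans(matrix(v, nrow = n_targets, byrow = TRUE))
  }))
  colnames(per_run) <- paste0("target", seq_len(n_targets))
  structure(list(runs = runs, run_scores = run_scores, profile = profile,
                 feature_summary = per_run,
                 feature_means = colMeans(per_run),
                 mode = mode, hp = hp,
                 n_targets = n_targets, n_bins = n_bins),
            class = "attack_result")
}

#' Correlate an attack profile against reference occupancy vectors
#'
#' Pearson correlation of the flattened average attack profile against each
#' reference sample's flattened occupancy vector, plus histogram counts —
#' the frequency-histogram comparison of synthetic versus held-out chromatin
#' profiles.
#'
#' @param attack_res An `attack_result` (or a targets x bins profile
#'   matrix).
#' @param reference Occupancy array samples x targets x bins (or flat
#'   matrix).
#' @param breaks Histogram breaks over `[-1, 1]` (default 40 bins).
#' @return List with `correlations` (NA where a reference sample has zero
#'   variance), `n_undefined`, `histogram` (counts), `breaks`.
#' @export
profile_correlation <- function(attack_res, reference, breaks = 40L) {
  prof <- if (inherits(attack_res, "attack_result")) {
    as.vector(t(attack_res$profile))
  } else as.vector(t(attack_res))
  if (stats::sd(prof) == 0) {
    stop("attack profile has zero variance; correlation undefined", call. = FALSE)
  }
  refm <- if (length(dim(reference)) == 3) flatten_all(reference) else reference
  cors <- apply(refm, 1, function(v) {
    if (stats::sd(v) == 0) NA_real_ else stats::cor(prof, v)
  })
  br <- seq(-1, 1, length.out = breaks + 1L)
  ok <- cors[!is.na(cors)]
  list(correlations = cors,
       n_undefined = sum(is.na(cors)),
       histogram = graphics::hist(ok, breaks = br, plot = FALSE)$counts,
       breaks = br)
}
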