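# Adversarial particle swarm optimization

# deterministic black-box scorers (gradient-free)
mean_first_target <- function(n_targets, n_bins) {
  function(x) {
    if (is.null(dim(x))) x <- matrix(x, 1)
    rowMeans(x[, seq_len(n_bins), drop = FALSE])
  }
}

test_that("hyperparameter validation", {
  expect_error(swarm_hyperparams(bounds = c(1, 0)), "lo < hi")
  expect_error(swarm_hyperparams(sparsity = 2), "sparsity")
  expect_error(swarm_hyperparams(n_particles = 0), "n_particles")
})

test_that("initialization respects bounds, sparsity, and the seed", {
  hp1 <- swarm_hyperparams(sparsity = 1, n_particles = 20, seed = 1)
  expect_true(all(init_swarm(30, hp1)$pos == 0))
  hp0 <- swarm_hyperparams(sparsity = 0, n_particles = 20, seed = 1)
  st0 <- init_swarm(30, hp0)
  expect_true(all(st0$pos > 0 & st0$pos <= 1))
  expect_true(all(st0$vel == 0))
  expect_identical(st0$pbest, st0$pos)
  expect_identical(init_swarm(30, hp0)$pos, st0$pos)
})

test_that("nonzero count after sparse init is inside the binomial 99.9% band", {
  hp <- swarm_hyperparams(sparsity = 0.999, n_particles = 500, seed = 3)
  st <- init_swarm(800, hp)
  nz <- sum(st$pos > 0)
  bounds <- qbinom(c(0.0005, 0.9995), 500 * 800, 0.001)
  expect_gte(nz, bounds[1])
  expect_lte(nz, bounds[2])
})

test_that("objective follows the mode contract and matches grid search", {
  fake <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, 1)
    rep(0.9, nrow(x))
  }
  expect_equal(objective(fake, runif(4), "positive"), 0.9)
  expect_equal(objective(fake, runif(4), "negative"), 0.1, tolerance = 1e-12)
  # argmax on a 2-d toy model equals brute-force grid search
  toy <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, 1)
    plogis(3 * x[, 1] - 2 * x[, 2])
  }
  grid <- as.matrix(expand.grid(seq(0, 1, 0.05), seq(0, 1, 0.05)))
  best <- grid[which.max(objective(toy, grid, "positive")), ]
  expect_equal(unname(best), c(1, 0))
  bestn <- grid[which.max(objective(toy, grid, "negative")), ]
  expect_equal(unname(bestn), c(0, 1))
})

test_that("velocity update is the exact three-term rule", {
  hp <- swarm_hyperparams(omega = 0.7, c1 = 1.5, c2 = 2.0)
  v <- velocity_update(velocity = c(1, -1), location = c(0, 0),
                       pbest = c(2, 2), gbest = c(4, 0), hp,
                       r1 = 0.5, r2 = 0.25)
  expect_equal(v, c(0.7 * 1 + 1.5 * 0.5 * 2 + 2 * 0.25 * 4,
                    0.7 * -1 + 1.5 * 0.5 * 2 + 2 * 0.25 * 0))
  # inertia only
  hp0 <- swarm_hyperparams(omega = 0.5, c1 = 0, c2 = 0)
  expect_equal(velocity_update(c(1, 0), c(3, 3), c(9, 9), c(-2, 4), hp0,
                               r1 = 0.8, r2 = 0.1), c(0.5, 0))
  # fixed point: l = h = g leaves only the inertia term
  l <- runif(5)
  expect_equal(velocity_update(rep(0.2, 5), l, l, l, hp, r1 = 0.3, r2 = 0.9),
               rep(0.7 * 0.2, 5))
})

test_that("velocity/position updates match direct arithmetic on random cases", {
  set.seed(23)
  hp <- swarm_hyperparams(omega = 0.729, c1 = 1.49445, c2 = 1.49445)
  for (rep in 1:100) {
    d <- sample(1:10, 1)
    v <- runif(d, -1, 1); l <- runif(d); h <- runif(d); g <- runif(d)
    r1 <- runif(1); r2 <- runif(1)
    want_v <- hp$omega * v + hp$c1 * r1 * (h - l) + hp$c2 * r2 * (g - l)
    expect_identical(velocity_update(v, l, h, g, hp, r1, r2), want_v)
    pu <- position_update(l, want_v, c(0, 1))
    expect_identical(pu$location, pmin(pmax(l + want_v, 0), 1))
    expect_identical(pu$clipped, (l + want_v) != pu$location)
  }
})

test_that("position update clips at the bounds", {
  expect_equal(position_update(c(0.9, 0.5), c(0.5, 0))$location, c(1.0, 0.5))
  expect_equal(position_update(0.1, -0.5)$location, 0)
  expect_equal(position_update(0.5, 0)$location, 0.5)
})

test_that("stepping keeps a monotone global best within bounds", {
  f <- mean_first_target(4, 10)
  hp <- swarm_hyperparams(n_particles = 40, sparsity = 0.9, seed = 11,
                          epochs = 15)
  st <- init_swarm(40, hp)
  prev <- -Inf
  for (e in 1:15) {
    st <- swarm_step(st, f, "positive")
    expect_gte(st$gbest_score, prev)
    prev <- st$gbest_score
    expect_gte(min(st$pos), 0)
    expect_lte(max(st$pos), 1)
  }
  expect_equal(st$epoch, 15L)
})

test_that("a constant objective leaves the global best score constant", {
  f <- function(x) rep(0.5, if (is.null(dim(x))) 1 else nrow(x))
  hp <- swarm_hyperparams(n_particles = 10, sparsity = 0.5, seed = 2)
  st <- init_swarm(8, hp)
  st <- swarm_step(st, f, "positive")
  s1 <- st$gbest_score
  for (e in 1:5) st <- swarm_step(st, f, "positive")
  expect_equal(st$gbest_score, s1)
})

test_that("velocity decays geometrically when both attractions are off", {
  hp <- swarm_hyperparams(omega = 0.5, c1 = 0, c2 = 0, n_particles = 5,
                          sparsity = 0, seed = 6)
  st <- init_swarm(6, hp)
  st$vel <- matrix(0.08, 5, 6)  # small so no bound is hit
  st$pos[] <- 0.5
  st$pbest <- st$pos
  f <- function(x) rep(0.5, nrow(x))
  for (e in 1:4) {
    v_before <- st$vel
    st <- swarm_step(st, f, "positive")
    expect_equal(st$vel, 0.5 * v_before, tolerance = 1e-12)
  }
})

test_that("attack concentrates mass on the feature the model rewards", {
  f <- mean_first_target(5, 8)
  hp <- swarm_hyperparams(n_particles = 60, epochs = 25, sparsity = 0.9,
                          seed = 21)
  res <- attack(f, hp, n_runs = 3, mode = "positive", n_targets = 5,
                n_bins = 8)
  expect_equal(unname(which.max(res$feature_means)), 1)
  expect_true(all(res$runs >= 0 & res$runs <= 1))
  # reproducible from seeds
  res2 <- attack(f, hp, n_runs = 3, mode = "positive", n_targets = 5,
                 n_bins = 8)
  expect_identical(res$runs, res2$runs)
})

test_that("inverted cost converges to the feature the model penalizes", {
  pen <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, 1)
    plogis(1 - 4 * rowMeans(x[, 4 * 8 + 1:8, drop = FALSE]))  # target 5 of 5
  }
  hp <- swarm_hyperparams(n_particles = 60, epochs = 25, sparsity = 0.9,
                          seed = 22)
  res <- attack(pen, hp, n_runs = 3, mode = "negative", n_targets = 5,
                n_bins = 8)
  expect_equal(unname(which.max(res$feature_means)), 5)
})

test_that("the attack runs on every architecture and a black-box callable", {
  set.seed(30)
  hp <- swarm_hyperparams(n_particles = 15, epochs = 3, sparsity = 0.9,
                          seed = 31)
  for (a in 1:7) {
    m <- build_model(model_spec(a, 8, 20, small_hyperparams()), seed = 40 + a)
    res <- attack(m, hp, n_runs = 1, mode = "positive")
    expect_equal(dim(res$profile), c(8, 20))
    expect_true(all(res$runs >= 0 & res$runs <= 1))
  }
})

test_that("profile correlations match the direct oracle with NA handling", {
  prof <- matrix(runif(40), 4, 10)
  res <- structure(list(profile = prof), class = "attack_result")
  ref <- array(0, c(3, 4, 10))
  ref[1, , ] <- prof                    # identical -> r = 1
  ref[2, , ] <- 1 - prof                # negated-and-shifted -> r = -1
  ref[3, , ] <- 0.5                     # zero variance -> NA
  pc <- profile_correlation(res, ref)
  expect_equal(unname(pc$correlations[1]), 1)
  expect_equal(unname(pc$correlations[2]), -1)
  expect_true(is.na(pc$correlations[3]))
  expect_equal(pc$n_undefined, 1)
  expect_equal(sum(pc$histogram), 2)
  # random references against stats::cor directly
  set.seed(33)
  ref2 <- array(runif(20 * 40), c(20, 4, 10))
  pc2 <- profile_correlation(res, ref2)
  for (i in 1:20) {
    expect_equal(unname(pc2$correlations[i]),
                 cor(as.vector(t(prof)), flatten_all(ref2)[i, ]))
  }
})
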