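# The seven classifier architectures, all consuming the same flat
# target-major occupancy vector and emitting a probability in [0,1]:
#   1 DNN            2 1D CNN -> DNN      3 LSTM -> DNN
#   4 1D CNN -> LSTM -> DNN               5 2D CNN -> DNN
#   6 2D CNN -> LSTM -> DNN               7 KAN

#' Default per-architecture hyperparameters
#'
#' Widths follow the reference configuration: three 256-node hidden layers
#' with ReLU and 0.5 dropout for the DNN head; 1D conv channels 16/32/64;
#' 2D conv channels 16/32; LSTM hidden size 500 with three layers; KAN with
#' three 256-node hidden transforms. Conv kernel 3, pool 2, stride 1, no
#' padding; KAN grid 5, spline order 3 on `[-1, 1]`.
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(
    dnn_width = 256L, dnn_layers = 3L, dropout = 0.5,
    conv1d_channels = c(16L, 32L, 64L), conv_kernel = 3L, pool = 2L,
    conv2d_channels = c(16L, 32L), conv2d_kernel = c(3L, 3L),
    lstm_hidden = 500L, lstm_layers = 3L,
    kan_widths = c(256L, 256L, 256L), kan_grid = 5L, kan_order = 3L,
    kan_range = c(-1, 1)
  )
}

#' Specify a classifier architecture
#'
#' @param architecture Integer 1-7 selecting the architecture.
#' @param n_targets Number of chromatin targets in the input tensor.
#' @param n_bins Bins per target (default 100).
#' @param hyperparams Named list overriding entries of
#'   [default_hyperparams()].
#' @return A `model_spec` object; flattened input length is
#'   `n_targets * n_bins`.
#' @export
model_spec <- function(architecture, n_targets, n_bins = 100L,
                       hyperparams = list()) {
  if (!architecture %in% 1:7) stop("architecture must be 1..7", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  structure(list(architecture = as.integer(architecture),
                 n_targets = as.integer(n_targets),
                 n_bins = as.integer(n_bins),
                 input_dim = as.integer(n_targets * n_bins),
                 hyperparams = hp),
            class = "model_spec")
}

# DNN head: hidden relu/dropout blocks ending in a 1-unit sigmoid
.dnn_head <- function(d_in, hp) {
  layers <- list()
  d <- d_in
  for (i in seq_len(hp$dnn_layers)) {
    layers <- c(layers, list(.layer_dense(d, hp$dnn_width), .layer_relu(),
                             .layer_dropout(hp$dropout)))
    d <- hp$dnn_width
  }
  c(layers, list(.layer_dense(d, 1L, init_scale = sqrt(1 / d)),
                 .layer_sigmoid()))
}

.conv1d_stack <- function(c_in, length_in, hp) {
  layers <- list()
  C <- c_in; L <- length_in
  for (f in hp$conv1d_channels) {
    if (L < hp$conv_kernel) {
      stop("1D conv stack: sequence length ", L, " below kernel ",
           hp$conv_kernel, " (input bins too few)", call. = FALSE)
    }
    layers <- c(layers, list(.layer_conv1d(C, f, hp$conv_kernel),
                             .layer_relu(), .layer_maxpool1d(hp$pool)))
    L <- (L - hp$conv_kernel + 1L) %/% hp$pool
    if (L == 0) stop("1D conv stack: pooled length reached 0", call. = FALSE)
    C <- f
  }
  list(layers = layers, channels = C, length = L)
}

.conv2d_stack <- function(h_in, w_in, hp) {
  layers <- list()
  C <- 1L; H <- h_in; W <- w_in
  kh <- hp$conv2d_kernel[1]; kw <- hp$conv2d_kernel[2]
  for (f in hp$conv2d_channels) {
    if (H < kh || W < kw) {
      stop("2D conv stack: input ", H, "x", W, " below kernel ", kh, "x", kw,
           call. = FALSE)
    }
    layers <- c(layers, list(.layer_conv2d(C, f, kh, kw), .layer_relu(),
                             .layer_maxpool2d(hp$pool)))
    H <- H - kh + 1L; W <- W - kw + 1L
    sh <- min(hp$pool, H); sw <- min(hp$pool, W)
    H <- H %/% sh; W <- W %/% sw
    if (H == 0 || W == 0) stop("2D conv stack: pooled size reached 0", call. = FALSE)
    C <- f
  }
  list(layers = layers, channels = C, height = H, width = W)
}

.lstm_stack <- function(d_in, hp) {
  layers <- list()
  d <- d_in
  for (i in seq_len(hp$lstm_layers)) {
    layers <- c(layers, list(.layer_lstm(d, hp$lstm_hidden)))
    d <- hp$lstm_hidden
  }
  list(layers = layers, out = d)
}

#' Build an untrained predictor
#'
#' Constructs the architecture named by the spec with seeded parameter
#' initialization. All architectures score a flat occupancy vector to a
#' probability in `[0,1]` (sigmoid output) and are differentiable with
#' respect to their input.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for parameter initialization.
#' @return A `predictor` object.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  hp <- spec$hyperparams
  Tn <- spec$n_targets; Bn <- spec$n_bins
  layers <- switch(as.character(spec$architecture),
    "1" = .dnn_head(spec$input_dim, hp),
    "2" = {
      cs <- .conv1d_stack(Tn, Bn, hp)
      c(list(.layer_reshape("reshape_1d", Tn, Bn)), cs$layers,
        list(.layer_flatten("flatten_conv1d")),
        .dnn_head(cs$channels * cs$length, hp))
    },
    "3" = {
      ls <- .lstm_stack(Tn, hp)
      c(list(.layer_reshape("seq_from_flat", Tn, Bn)), ls$layers,
        list(.layer_take_last()), .dnn_head(ls$out, hp))
    },
    "4" = {
      cs <- .conv1d_stack(Tn, Bn, hp)
      ls <- .lstm_stack(cs$channels, hp)
      c(list(.layer_reshape("reshape_1d", Tn, Bn)), cs$layers,
        list(.layer_seq_adapter("seq_from_conv1d")), ls$layers,
        list(.layer_take_last()), .dnn_head(ls$out, hp))
    },
    "5" = {
      cs <- .conv2d_stack(Tn, Bn, hp)
      c(list(.layer_reshape("reshape_2d", Tn, Bn)), cs$layers,
        list(.layer_flatten("flatten_conv2d")),
        .dnn_head(cs$channels * cs$height * cs$width, hp))
    },
    "6" = {
      cs <- .conv2d_stack(Tn, Bn, hp)
      ls <- .lstm_stack(cs$channels * cs$height, hp)
      c(list(.layer_reshape("reshape_2d", Tn, Bn)), cs$layers,
        list(.layer_seq_adapter("seq_from_conv2d")), ls$layers,
        list(.layer_take_last()), .dnn_head(ls$out, hp))
    },
    "7" = {
      widths <- c(spec$input_dim, hp$kan_widths, 1L)
      layers <- list()
      for (i in seq_len(length(widths) - 1L)) {
        layers <- c(layers, list(
          .layer_kan(widths[i], widths[i + 1L], grid = hp$kan_grid,
                     deg = hp$kan_order, range = hp$kan_range)))
      }
      c(layers, list(.layer_sigmoid()))
    }
  )
  structure(list(layers = layers, spec = spec, seed = as.integer(seed),
                 epochs_trained = 0L),
            class = "predictor")
}

.as_input_matrix <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$spec$input_dim) {
    stop("input length ", ncol(x), " does not match model input dimension ",
         model$spec$input_dim, call. = FALSE)
  }
  x
}

#' Score occupancy vectors with a predictor
#'
#' Deterministic evaluation-mode forward pass (dropout disabled).
#'
#' @param model A `predictor`.
#' @param x Flat occupancy vector, matrix of row vectors, or an occupancy
#'   array samples x targets x bins.
#' @return Numeric vector of probabilities in `[0,1]`, one per sample.
#' @export
score <- function(model, x) {
  stopifnot(inherits(model, "predictor"))
  if (!is.null(dim(x)) && length(dim(x)) == 3) x <- flatten_all(x)
  x <- .as_input_matrix(model, x)
  as.vector(.net_forward(model$layers, x, training = FALSE)$out)
}

#' Score on the log-odds scale
#'
#' The pre-sigmoid network output. Monotone in [score()] but free of the
#' double-precision saturation of the sigmoid near 0 and 1, which matters
#' when ranking inputs a confident network scores (nearly) identically —
#' as the adversarial swarm must.
#'
#' @inheritParams score
#' @return Numeric vector of logits.
#' @export
score_logit <- function(model, x) {
  stopifnot(inherits(model, "predictor"))
  if (!is.null(dim(x)) && length(dim(x)) == 3) x <- flatten_all(x)
  x <- .as_input_matrix(model, x)
  layers <- model$layers
  last <- layers[[length(layers)]]
  if (identical(last$type, "sigmoid")) layers <- layers[-length(layers)]
  as.vector(.net_forward(layers, x, training = FALSE)$out)
}

#' Gradient of the score with respect to the input
#'
#' Evaluation-mode backward pass; used by saliency and integrated gradients.
#'
#' @inheritParams score
#' @return Matrix (samples x input_dim) of per-sample input gradients.
#' @export
score_gradient <- function(model, x) {
  stopifnot(inherits(model, "predictor"))
  if (!is.null(dim(x)) && length(dim(x)) == 3) x <- flatten_all(x)
  x <- .as_input_matrix(model, x)
  fw <- .net_forward(model$layers, x, training = FALSE)
  gout <- matrix(1, nrow(x), 1)
  .net_backward(model$layers, fw$caches, gout)$gin
}

#' Evaluate a single KAN edge activation
#'
#' One learnable edge of a Kolmogorov-Arnold layer: a residual SiLU branch
#' weighted by `w_base` plus a B-spline with coefficients `coef` on a uniform
#' grid over `range` (input clamped to the grid range for the spline term).
#' With all spline coefficients zero this reduces to `w_base * silu(x)`.
#'
#' @param x Numeric vector of inputs.
#' @param edge List with `coef` (length `grid + order`), `w_base`, and
#'   optionally `grid` (default 5), `order` (default 3), `range`
#'   (default `c(-1, 1)`).
#' @return Numeric vector of edge outputs.
#' @export
kan_edge_activation <- function(x, edge) {
  grid <- if (is.null(edge$grid)) 5L else edge$grid
  deg <- if (is.null(edge$order)) 3L else edge$order
  rng <- if (is.null(edge$range)) c(-1, 1) else edge$range
  nb <- grid + deg
  if (length(edge$coef) != nb) {
    stop("edge$coef must have length grid + order = ", nb, call. = FALSE)
  }
  knots <- .kan_knots(grid, deg, rng)
  xc <- pmin(pmax(x, rng[1]), rng[2])
  B <- splines::splineDesign(knots, xc, ord = deg + 1L)
  as.vector(edge$w_base * .silu(x) + B %*% edge$coef)
}

#' Save / load a predictor checkpoint
#'
#' Plain-text JSON checkpoint carrying the spec, seed, epoch count, and all
#' parameters.
#'
#' @param model A `predictor`.
#' @param path File path.
#' @return `path` (save) or the restored `predictor` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "predictor"))
  ser <- list(
    spec = list(architecture = model$spec$architecture,
                n_targets = model$spec$n_targets,
                n_bins = model$spec$n_bins,
                hyperparams = model$spec$hyperparams),
    seed = model$seed,
    epochs_trained = model$epochs_trained,
    params = lapply(model$layers, function(l) {
      lapply(l$params, function(p) {
        if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
        else list(dim = NULL, data = as.vector(p))
      })
    })
  )
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  spec <- model_spec(ser$spec$architecture, ser$spec$n_targets,
                     ser$spec$n_bins, ser$spec$hyperparams)
  model <- build_model(spec, seed = ser$seed)
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      p <- ser$params[[i]][[nm]]
      v <- as.numeric(unlist(p$data))
      if (!is.null(p$dim)) dim(v) <- unlist(p$dim)
      model$layers[[i]]$params[[nm]] <- v
    }
  }
  model$epochs_trained <- ser$epochs_trained
  model
}
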