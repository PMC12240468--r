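# Compact neural-network engine: layer-wise forward/backward passes with
# explicit caches, Adam updates, and input gradients for attribution.
#
# Tensor conventions inside a network:
#   flat   : matrix (n, d)
#   conv1d : array  (n, channels, length)
#   conv2d : array  (n, channels, height, width)
#   seq    : array  (n, time, features)
# The public model input is always the flat target-major occupancy vector.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.silu <- function(x) x * .sigmoid(x)
.silu_grad <- function(x) {
  s <- .sigmoid(x)
  s * (1 + x * (1 - s))
}

# matrix slice of a (n, T, D) array at time t, keeping matrix shape
.slice_t <- function(x, t) {
  m <- x[, t, , drop = FALSE]
  dim(m) <- dim(m)[c(1, 3)]
  m
}

# ---- layer constructors -----------------------------------------------------

.layer_dense <- function(d_in, d_out, init_scale = NULL) {
  if (is.null(init_scale)) init_scale <- sqrt(2 / d_in)
  list(type = "dense",
       params = list(W = matrix(stats::rnorm(d_in * d_out, sd = init_scale),
                                d_in, d_out),
                     b = numeric(d_out)))
}

.layer_relu <- function() list(type = "relu", params = list())
.layer_sigmoid <- function() list(type = "sigmoid", params = list())
.layer_dropout <- function(p) list(type = "dropout", p = p, params = list())

.layer_conv1d <- function(c_in, c_out, kernel) {
  fan_in <- c_in * kernel
  list(type = "conv1d", kernel = kernel, c_in = c_in, c_out = c_out,
       params = list(W = matrix(stats::rnorm(fan_in * c_out,
                                             sd = sqrt(2 / fan_in)),
                                fan_in, c_out),
                     b = numeric(c_out)))
}

.layer_maxpool1d <- function(size = 2L) {
  list(type = "maxpool1d", size = size, params = list())
}

.layer_conv2d <- function(c_in, c_out, kh, kw) {
  fan_in <- c_in * kh * kw
  list(type = "conv2d", kh = kh, kw = kw, c_in = c_in, c_out = c_out,
       params = list(W = matrix(stats::rnorm(fan_in * c_out,
                                             sd = sqrt(2 / fan_in)),
                                fan_in, c_out),
                     b = numeric(c_out)))
}

.layer_maxpool2d <- function(size = 2L) {
  list(type = "maxpool2d", size = size, params = list())
}

.layer_lstm <- function(d_in, hidden) {
  s <- 1 / sqrt(hidden)
  list(type = "lstm", hidden = hidden, d_in = d_in,
       params = list(
         Wx = matrix(stats::runif(d_in * 4 * hidden, -s, s), d_in, 4 * hidden),
         Wh = matrix(stats::runif(hidden * 4 * hidden, -s, s), hidden, 4 * hidden),
         b = numeric(4 * hidden)))
}

.layer_take_last <- function() list(type = "take_last", params = list())

# shape adapters (no parameters)
.layer_reshape <- function(kind, n_targets, n_bins) {
  list(type = kind, n_targets = n_targets, n_bins = n_bins, params = list())
}
.layer_flatten <- function(kind) list(type = kind, params = list())
.layer_seq_adapter <- function(kind) list(type = kind, params = list())

# B-spline knot vector covering [lo, hi] with `grid` intervals, degree `deg`
.kan_knots <- function(grid, deg, range) {
  h <- (range[2] - range[1]) / grid
  seq(range[1] - deg * h, range[2] + deg * h, by = h)
}

.layer_kan <- function(d_in, d_out, grid = 5L, deg = 3L, range = c(-1, 1)) {
  nb <- grid + deg
  s <- sqrt(6 / d_in)
  list(type = "kan", d_in = d_in, d_out = d_out, grid = grid, deg = deg,
       range = range, nb = nb, knots = .kan_knots(grid, deg, range),
       params = list(
         Wbase = matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out),
         Wspline = matrix(stats::rnorm(d_in * nb * d_out,
                                       sd = 0.1 / sqrt(d_in)),
                          d_in * nb, d_out)))
}

# basis matrix (n, nb * d_in) for input matrix x (n, d_in); column order
# (input-major): column (i-1)*nb + j is basis j of input i
.kan_basis <- function(layer, x, derivs = 0L) {
  n <- nrow(x); d_in <- ncol(x); nb <- layer$nb
  xc <- pmin(pmax(as.vector(x), layer$range[1]), layer$range[2])
  D <- splines::splineDesign(layer$knots, xc, ord = layer$deg + 1L,
                             derivs = rep(derivs, length(xc)))
  A <- array(D, dim = c(n, d_in, nb))
  B <- aperm(A, c(1, 3, 2))
  dim(B) <- c(n, nb * d_in)
  B
}

# ---- forward ----------------------------------------------------------------

.layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$params$W
      out <- sweep(out, 2, layer$params$b, "+")
      list(out = out, cache = list(x = x))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    sigmoid = {
      out <- .sigmoid(x)
      list(out = out, cache = list(out = out))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    reshape_1d = {
      # flat target-major (n, T*B) -> (n, C=T, L=B)
      n <- nrow(x)
      a <- x
      dim(a) <- c(n, layer$n_bins, layer$n_targets)
      list(out = aperm(a, c(1, 3, 2)), cache = list(n = n))
    },
    reshape_2d = {
      n <- nrow(x)
      a <- x
      dim(a) <- c(n, layer$n_bins, layer$n_targets)
      a <- aperm(a, c(1, 3, 2))            # (n, T, B)
      dim(a) <- c(n, 1L, layer$n_targets, layer$n_bins)
      list(out = a, cache = list(n = n))
    },
    seq_from_flat = {
      # flat target-major (n, T*B) -> sequence (n, time=B, feat=T)
      n <- nrow(x)
      a <- x
      dim(a) <- c(n, layer$n_bins, layer$n_targets)
      list(out = a, cache = list(n = n))
    },
    conv1d = {
      d <- dim(x); n <- d[1]; C <- d[2]; L <- d[3]; k <- layer$kernel
      if (L < k) stop("conv1d: input length ", L, " smaller than kernel ", k,
                      call. = FALSE)
      L_out <- L - k + 1L
      A <- array(0, c(n, C, k, L_out))
      for (o in seq_len(k)) A[, , o, ] <- x[, , o:(o + L_out - 1L)]
      P <- aperm(A, c(1, 4, 2, 3))
      dim(P) <- c(n * L_out, C * k)
      out_m <- P %*% layer$params$W
      out_m <- sweep(out_m, 2, layer$params$b, "+")
      out <- array(out_m, c(n, L_out, layer$c_out))
      list(out = aperm(out, c(1, 3, 2)),
           cache = list(P = P, n = n, C = C, L = L, L_out = L_out))
    },
    maxpool1d = {
      d <- dim(x); n <- d[1]; C <- d[2]; L <- d[3]; s <- layer$size
      L_out <- L %/% s
      if (L_out == 0) stop("maxpool1d: input length ", L, " below pool size",
                           call. = FALSE)
      xr <- x[, , seq_len(L_out * s), drop = FALSE]
      dim(xr) <- c(n, C, s, L_out)
      out <- xr[, , 1, , drop = FALSE]; dim(out) <- c(n, C, L_out)
      amax <- array(1L, c(n, C, L_out))
      if (s > 1) for (u in 2:s) {
        cand <- xr[, , u, , drop = FALSE]; dim(cand) <- c(n, C, L_out)
        better <- cand > out
        out[better] <- cand[better]
        amax[better] <- u
      }
      list(out = out, cache = list(amax = amax, L = L, s = s))
    },
    conv2d = {
      d <- dim(x); n <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
      kh <- layer$kh; kw <- layer$kw
      if (H < kh || W < kw) {
        stop("conv2d: input ", H, "x", W, " smaller than kernel ",
             kh, "x", kw, call. = FALSE)
      }
      H_out <- H - kh + 1L; W_out <- W - kw + 1L
      A <- array(0, c(n, C, kh, kw, H_out, W_out))
      for (i in seq_len(kh)) for (j in seq_len(kw)) {
        A[, , i, j, , ] <- x[, , i:(i + H_out - 1L), j:(j + W_out - 1L)]
      }
      P <- aperm(A, c(1, 5, 6, 2, 3, 4))
      dim(P) <- c(n * H_out * W_out, C * kh * kw)
      out_m <- P %*% layer$params$W
      out_m <- sweep(out_m, 2, layer$params$b, "+")
      out <- array(out_m, c(n, H_out, W_out, layer$c_out))
      list(out = aperm(out, c(1, 4, 2, 3)),
           cache = list(P = P, n = n, C = C, H = H, W = W,
                        H_out = H_out, W_out = W_out))
    },
    maxpool2d = {
      d <- dim(x); n <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
      sh <- min(layer$size, H); sw <- min(layer$size, W)
      H_out <- H %/% sh; W_out <- W %/% sw
      xr <- x[, , seq_len(H_out * sh), seq_len(W_out * sw), drop = FALSE]
      dim(xr) <- c(n, C, sh, H_out, sw, W_out)
      out <- xr[, , 1, , 1, , drop = FALSE]; dim(out) <- c(n, C, H_out, W_out)
      amax <- array(1L, c(n, C, H_out, W_out))  # combo index (u-1)*sw + v
      for (u in seq_len(sh)) for (v in seq_len(sw)) {
        if (u == 1 && v == 1) next
        cand <- xr[, , u, , v, , drop = FALSE]
        dim(cand) <- c(n, C, H_out, W_out)
        better <- cand > out
        out[better] <- cand[better]
        amax[better] <- (u - 1L) * sw + v
      }
      list(out = out, cache = list(amax = amax, H = H, W = W,
                                   sh = sh, sw = sw))
    },
    seq_from_conv1d = {
      # (n, C, L) -> (n, time=L, feat=C)
      list(out = aperm(x, c(1, 3, 2)), cache = list(d = dim(x)))
    },
    seq_from_conv2d = {
      # (n, C, H, W) -> (n, time=W, feat=C*H)
      d <- dim(x)
      a <- aperm(x, c(1, 4, 2, 3))         # (n, W, C, H)
      dim(a) <- c(d[1], d[4], d[2] * d[3])
      list(out = a, cache = list(d = d))
    },
    lstm = {
      d <- dim(x); n <- d[1]; Tt <- d[2]; H <- layer$hidden
      Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
      h <- matrix(0, n, H); cc <- matrix(0, n, H)
      hs <- array(0, c(n, Tt, H))
      steps <- vector("list", Tt)
      for (t in seq_len(Tt)) {
        xt <- .slice_t(x, t)
        z <- xt %*% Wx + h %*% Wh
        z <- sweep(z, 2, b, "+")
        gi <- .sigmoid(z[, seq_len(H), drop = FALSE])
        gf <- .sigmoid(z[, H + seq_len(H), drop = FALSE])
        gg <- tanh(z[, 2 * H + seq_len(H), drop = FALSE])
        go <- .sigmoid(z[, 3 * H + seq_len(H), drop = FALSE])
        c_new <- gf * cc + gi * gg
        tc <- tanh(c_new)
        h_new <- go * tc
        steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc,
                           gi = gi, gf = gf, gg = gg, go = go, tc = tc)
        h <- h_new; cc <- c_new
        hs[, t, ] <- h
      }
      list(out = hs, cache = list(steps = steps, n = n, Tt = Tt))
    },
    take_last = {
      d <- dim(x)
      list(out = .slice_t(x, d[2]), cache = list(d = d))
    },
    flatten_conv1d = ,
    flatten_conv2d = {
      d <- dim(x)
      out <- x
      dim(out) <- c(d[1], prod(d[-1]))
      list(out = out, cache = list(d = d))
    },
    kan = {
      B <- .kan_basis(layer, x, derivs = 0L)
      sx <- .silu(x)
      out <- sx %*% layer$params$Wbase + B %*% layer$params$Wspline
      list(out = out, cache = list(x = x, B = B, sx = sx))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- backward ---------------------------------------------------------------

.layer_backward <- function(layer, cache, g) {
  switch(layer$type,
    dense = {
      list(gin = g %*% t(layer$params$W),
           grads = list(W = t(cache$x) %*% g, b = colSums(g)))
    },
    relu = list(gin = g * cache$mask, grads = list()),
    sigmoid = {
      o <- cache$out
      list(gin = g * o * (1 - o), grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(gin = g, grads = list())
      else list(gin = g * cache$mask, grads = list())
    },
    reshape_1d = {
      a <- aperm(g, c(1, 3, 2))            # (n, B, T)
      dim(a) <- c(cache$n, prod(dim(g)[-1]))
      list(gin = a, grads = list())
    },
    reshape_2d = {
      d <- dim(g)                          # (n, 1, T, B)
      a <- g
      dim(a) <- c(d[1], d[3], d[4])        # (n, T, B)
      a <- aperm(a, c(1, 3, 2))            # (n, B, T)
      dim(a) <- c(d[1], d[3] * d[4])
      list(gin = a, grads = list())
    },
    seq_from_flat = {
      d <- dim(g)                          # (n, B, T)
      a <- g
      dim(a) <- c(d[1], d[2] * d[3])
      list(gin = a, grads = list())
    },
    conv1d = {
      n <- cache$n; C <- cache$C; L <- cache$L; L_out <- cache$L_out
      k <- layer$kernel
      g2 <- aperm(g, c(1, 3, 2))           # (n, L_out, F)
      dim(g2) <- c(n * L_out, layer$c_out)
      gW <- t(cache$P) %*% g2
      gb <- colSums(g2)
      gP <- g2 %*% t(layer$params$W)       # (n*L_out, C*k)
      dim(gP) <- c(n, L_out, C, k)
      gx <- array(0, c(n, C, L))
      for (o in seq_len(k)) {
        sl <- gP[, , , o, drop = FALSE]
        dim(sl) <- c(n, L_out, C)
        span <- o:(o + L_out - 1L)
        gx[, , span] <- gx[, , span, drop = FALSE] + aperm(sl, c(1, 3, 2))
      }
      list(gin = gx, grads = list(W = gW, b = gb))
    },
    maxpool1d = {
      d <- dim(g); n <- d[1]; C <- d[2]; L_out <- d[3]
      s <- cache$s
      gr <- array(0, c(n, C, s, L_out))
      for (u in seq_len(s)) {
        sel <- cache$amax == u
        tmp <- array(0, c(n, C, L_out)); tmp[sel] <- g[sel]
        gr[, , u, ] <- tmp
      }
      dim(gr) <- c(n, C, s * L_out)
      gx <- array(0, c(n, C, cache$L))
      gx[, , seq_len(s * L_out)] <- gr
      list(gin = gx, grads = list())
    },
    conv2d = {
      n <- cache$n; C <- cache$C; H <- cache$H; W <- cache$W
      H_out <- cache$H_out; W_out <- cache$W_out
      kh <- layer$kh; kw <- layer$kw
      g2 <- aperm(g, c(1, 3, 4, 2))        # (n, H_out, W_out, F)
      dim(g2) <- c(n * H_out * W_out, layer$c_out)
      gW <- t(cache$P) %*% g2
      gb <- colSums(g2)
      gP <- g2 %*% t(layer$params$W)
      dim(gP) <- c(n, H_out, W_out, C, kh, kw)
      gx <- array(0, c(n, C, H, W))
      for (i in seq_len(kh)) for (j in seq_len(kw)) {
        sl <- gP[, , , , i, j, drop = FALSE]
        dim(sl) <- c(n, H_out, W_out, C)
        ih <- i:(i + H_out - 1L); iw <- j:(j + W_out - 1L)
        gx[, , ih, iw] <- gx[, , ih, iw, drop = FALSE] +
          aperm(sl, c(1, 4, 2, 3))
      }
      list(gin = gx, grads = list(W = gW, b = gb))
    },
    maxpool2d = {
      d <- dim(g); n <- d[1]; C <- d[2]; H_out <- d[3]; W_out <- d[4]
      sh <- cache$sh; sw <- cache$sw
      gr <- array(0, c(n, C, sh, H_out, sw, W_out))
      for (u in seq_len(sh)) for (v in seq_len(sw)) {
        sel <- cache$amax == (u - 1L) * sw + v
        tmp <- array(0, c(n, C, H_out, W_out)); tmp[sel] <- g[sel]
        gr[, , u, , v, ] <- tmp
      }
      dim(gr) <- c(n, C, sh * H_out, sw * W_out)
      gx <- array(0, c(n, C, cache$H, cache$W))
      gx[, , seq_len(sh * H_out), seq_len(sw * W_out)] <- gr
      list(gin = gx, grads = list())
    },
    seq_from_conv1d = {
      list(gin = aperm(g, c(1, 3, 2)), grads = list())
    },
    seq_from_conv2d = {
      d <- cache$d                         # (n, C, H, W)
      a <- g                               # (n, W, C*H)
      dim(a) <- c(d[1], d[4], d[2], d[3])
      list(gin = aperm(a, c(1, 3, 4, 2)), grads = list())
    },
    lstm = {
      n <- cache$n; Tt <- cache$Tt; H <- layer$hidden
      Wx <- layer$params$Wx; Wh <- layer$params$Wh
      gWx <- matrix(0, nrow(Wx), ncol(Wx))
      gWh <- matrix(0, nrow(Wh), ncol(Wh))
      gb <- numeric(4 * H)
      d_in <- nrow(Wx)
      gx <- array(0, c(n, Tt, d_in))
      dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
      for (t in rev(seq_len(Tt))) {
        st <- cache$steps[[t]]
        dh <- .slice_t(g, t) + dh_next
        do_ <- dh * st$tc
        dc <- dc_next + dh * st$go * (1 - st$tc^2)
        di <- dc * st$gg
        dg <- dc * st$gi
        df <- dc * st$c_prev
        dc_next <- dc * st$gf
        dz <- cbind(di * st$gi * (1 - st$gi),
                    df * st$gf * (1 - st$gf),
                    dg * (1 - st$gg^2),
                    do_ * st$go * (1 - st$go))
        gWx <- gWx + t(st$xt) %*% dz
        gWh <- gWh + t(st$h_prev) %*% dz
        gb <- gb + colSums(dz)
        gx[, t, ] <- dz %*% t(Wx)
        dh_next <- dz %*% t(Wh)
      }
      list(gin = gx, grads = list(Wx = gWx, Wh = gWh, b = gb))
    },
    take_last = {
      d <- cache$d
      gx <- array(0, d)
      gx[, d[2], ] <- g
      list(gin = gx, grads = list())
    },
    flatten_conv1d = ,
    flatten_conv2d = {
      gx <- g
      dim(gx) <- cache$d
      list(gin = gx, grads = list())
    },
    kan = {
      x <- cache$x
      gWbase <- t(cache$sx) %*% g
      gWspline <- t(cache$B) %*% g
      gsx <- g %*% t(layer$params$Wbase)
      gB <- g %*% t(layer$params$Wspline)  # (n, nb*d_in)
      Bp <- .kan_basis(layer, x, derivs = 1L)
      prod_ <- gB * Bp
      dim(prod_) <- c(nrow(x), layer$nb, ncol(x))
      gx_spline <- colSums(aperm(prod_, c(2, 1, 3)))  # (n, d_in)
      inside <- x > layer$range[1] & x < layer$range[2]
      gx <- gsx * .silu_grad(x) + gx_spline * inside
      list(gin = gx, grads = list(Wbase = gWbase, Wspline = gWspline))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- network drivers --------------------------------------------------------

.net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  out <- X
  for (i in seq_along(layers)) {
    fw <- .layer_forward(layers[[i]], out, training = training)
    out <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = out, caches = caches)
}

# returns list(gin = gradient at input, grads = per-layer parameter grads)
.net_backward <- function(layers, caches, gout) {
  grads <- vector("list", length(layers))
  g <- gout
  for (i in rev(seq_along(layers))) {
    bw <- .layer_backward(layers[[i]], caches[[i]], g)
    g <- bw$gin
    grads[[i]] <- bw$grads
  }
  list(gin = g, grads = grads)
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

.adam_update <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
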