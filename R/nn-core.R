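# Minimal neural-network engine: 1-D conv / transposed conv / LSTM /
# dense layers with hand-written backprop, plus Adam and RMSProp.
# Tensors are base-R arrays, (batch, time, channels) for sequences and
# (batch, features) for flat layers. Every gradient path here is covered
# by finite-difference checks in the test suite.

ACTIVATIONS <- list(
  linear = list(f = function(x) x,
                d = function(x, y) 1),
  lrelu = list(f = function(x) ifelse(x > 0, x, 0.2 * x),
               d = function(x, y) ifelse(x > 0, 1, 0.2)),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 d = function(x, y) y * (1 - y)),
  tanh = list(f = tanh,
              d = function(x, y) 1 - y^2)
)

# Glorot-uniform init with an activation-dependent gain: sigmoid layers
# use gain 4 (the inverse of sigmoid's slope 1/4 at zero) so signal
# variance is preserved through deep sigmoid stacks instead of collapsing
# geometrically.
glorot <- function(n_in, n_out, dims = c(n_in, n_out), gain = 1) {
  lim <- gain * sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

act_gain <- function(act) if (identical(act, "sigmoid")) 4 else 1

# activation codes shared with the compiled kernels
act_code <- function(act) {
  switch(act %||% "linear", linear = 0L, lrelu = 1L, sigmoid = 2L,
         tanh = 3L, stop("unknown activation ", act))
}

flat2 <- function(x) {           # (B, L, C) -> (B*L, C)
  d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x
}
unflat2 <- function(x, B, L) {   # (B*L, C) -> (B, L, C)
  dim(x) <- c(B, L, ncol(x)); x
}
add_bias <- function(z, b) z + rep(b, each = nrow(z))

## ---- layer constructors -------------------------------------------------

nn_conv_k2s2 <- function(n_in, n_filters, act = "lrelu") {
  g <- act_gain(act)
  list(type = "conv_k2s2", act = act,
       par = list(W1 = glorot(2 * n_in, n_filters, c(n_in, n_filters), g),
                  W2 = glorot(2 * n_in, n_filters, c(n_in, n_filters), g),
                  b = numeric(n_filters)))
}

nn_tconv_k2s2 <- function(n_in, n_filters, act = "lrelu") {
  g <- act_gain(act)
  list(type = "tconv_k2s2", act = act,
       par = list(W1 = glorot(n_in, 2 * n_filters, c(n_in, n_filters), g),
                  W2 = glorot(n_in, 2 * n_filters, c(n_in, n_filters), g),
                  b = numeric(n_filters)))
}

nn_conv_k8s1 <- function(n_in, n_filters, act = "sigmoid") {
  W <- lapply(1:8, function(j) glorot(8 * n_in, n_filters,
                                      c(n_in, n_filters), act_gain(act)))
  names(W) <- paste0("W", 1:8)
  list(type = "conv_k8s1", act = act,
       par = c(W, list(b = numeric(n_filters))))
}

# random orthogonal matrix (QR of a Gaussian)
orthogonal_init <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n)))
}

nn_lstm <- function(n_in, n_hidden, act = "tanh") {
  b <- numeric(4 * n_hidden)
  b[(n_hidden + 1):(2 * n_hidden)] <- 1  # unit forget-gate bias init
  g <- act_gain(act)
  # recurrent kernel: per-gate orthogonal blocks (the standard recurrent
  # init), scaled by the activation gain
  Wh <- do.call(cbind, lapply(1:4, function(k) orthogonal_init(n_hidden)))
  list(type = "lstm", act = act, n_hidden = n_hidden,
       par = list(Wx = glorot(n_in + n_hidden, 4 * n_hidden,
                              c(n_in, 4 * n_hidden), g),
                  Wh = Wh * g,
                  b = b))
}

nn_dense <- function(n_in, n_out, act = "sigmoid") {
  list(type = "dense", act = act,
       par = list(W = glorot(n_in, n_out, gain = act_gain(act)),
                  b = numeric(n_out)))
}

# dense layer applied along the time axis, shared across channels:
# (B, L, C) -> (B, L_out, C)
nn_dense_time <- function(L_in, L_out, act = "sigmoid") {
  list(type = "dense_time", act = act,
       par = list(W = glorot(L_in, L_out, gain = act_gain(act)),
                  b = numeric(L_out)))
}

nn_gaussian_noise <- function(sd) {
  list(type = "noise", sd = sd, par = list())
}

## ---- forward ------------------------------------------------------------

layer_forward <- function(layer, X, training = FALSE) {
  a <- ACTIVATIONS[[layer$act %||% "linear"]]
  p <- layer$par
  switch(layer$type,
    conv_k2s2 = {
      d <- dim(X); B <- d[1]; L <- d[2]
      X1 <- flat2(X[, seq(1, L, 2), , drop = FALSE])
      X2 <- flat2(X[, seq(2, L, 2), , drop = FALSE])
      z <- add_bias(X1 %*% p$W1 + X2 %*% p$W2, p$b)
      y <- a$f(z)
      list(out = unflat2(y, B, L / 2),
           cache = list(X1 = X1, X2 = X2, z = z, y = y, B = B, L = L))
    },
    tconv_k2s2 = {
      d <- dim(X); B <- d[1]; L <- d[2]
      Xf <- flat2(X)
      z1 <- add_bias(Xf %*% p$W1, p$b)
      z2 <- add_bias(Xf %*% p$W2, p$b)
      y1 <- a$f(z1); y2 <- a$f(z2)
      out <- array(0, c(B, 2 * L, ncol(z1)))
      out[, seq(1, 2 * L, 2), ] <- unflat2(y1, B, L)
      out[, seq(2, 2 * L, 2), ] <- unflat2(y2, B, L)
      list(out = out,
           cache = list(Xf = Xf, z1 = z1, z2 = z2, y1 = y1, y2 = y2,
                        B = B, L = L))
    },
    conv_k8s1 = {
      d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
      W <- do.call(rbind, p[paste0("W", 1:8)])
      r <- .conv8_fwd(flat2(X), B, L, W, p$b, act_code(layer$act))
      list(out = unflat2(r$y, B, L),
           cache = list(z = r$z, y = r$y, Xcol = r$Xcol, W = W,
                        B = B, L = L, C = C))
    },
    lstm = {
      d <- dim(X); B <- d[1]; L <- d[2]
      Xf <- flat2(X)
      r <- .lstm_fwd(Xf, B, L, p$Wx, p$Wh, p$b, act_code(layer$act))
      list(out = r$h,
           cache = list(r = r, Xf = Xf, B = B, L = L,
                        C = d[3], H = layer$n_hidden))
    },
    dense = {
      z <- add_bias(X %*% p$W, p$b)
      y <- a$f(z)
      list(out = y, cache = list(X = X, z = z, y = y))
    },
    dense_time = {
      d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
      Xp <- aperm(X, c(1, 3, 2))          # (B, C, L)
      dim(Xp) <- c(B * C, L)
      z <- add_bias(Xp %*% p$W, p$b)
      y <- a$f(z)
      out <- array(y, c(B, C, ncol(y)))
      list(out = aperm(out, c(1, 3, 2)),
           cache = list(Xp = Xp, z = z, y = y, B = B, L = L, C = C))
    },
    noise = {
      if (training && layer$sd > 0) {
        X <- X + array(stats::rnorm(length(X), 0, layer$sd), dim(X))
      }
      list(out = X, cache = list())
    },
    stop("unknown layer type ", layer$type))
}

## ---- backward -----------------------------------------------------------

layer_backward <- function(layer, cache, dY) {
  a <- ACTIVATIONS[[layer$act %||% "linear"]]
  p <- layer$par
  switch(layer$type,
    conv_k2s2 = {
      B <- cache$B; L <- cache$L
      dz <- flat2(dY) * a$d(cache$z, cache$y)
      dX <- array(0, c(B, L, nrow(p$W1)))
      dX[, seq(1, L, 2), ] <- unflat2(dz %*% t(p$W1), B, L / 2)
      dX[, seq(2, L, 2), ] <- unflat2(dz %*% t(p$W2), B, L / 2)
      list(dX = dX,
           grads = list(W1 = crossprod(cache$X1, dz),
                        W2 = crossprod(cache$X2, dz),
                        b = colSums(dz)))
    },
    tconv_k2s2 = {
      B <- cache$B; L <- cache$L
      d1 <- flat2(dY[, seq(1, 2 * L, 2), , drop = FALSE])
      d2 <- flat2(dY[, seq(2, 2 * L, 2), , drop = FALSE])
      dz1 <- d1 * a$d(cache$z1, cache$y1)
      dz2 <- d2 * a$d(cache$z2, cache$y2)
      dXf <- dz1 %*% t(p$W1) + dz2 %*% t(p$W2)
      list(dX = unflat2(dXf, B, L),
           grads = list(W1 = crossprod(cache$Xf, dz1),
                        W2 = crossprod(cache$Xf, dz2),
                        b = colSums(dz1) + colSums(dz2)))
    },
    conv_k8s1 = {
      B <- cache$B; L <- cache$L; C <- cache$C
      r <- .conv8_bwd(flat2(dY), cache$z, cache$y, cache$Xcol, cache$W,
                      B, L, act_code(layer$act))
      grads <- lapply(1:8, function(j) {
        r$dW[(j - 1L) * C + seq_len(C), , drop = FALSE]
      })
      names(grads) <- paste0("W", 1:8)
      grads$b <- as.numeric(r$db)
      list(dX = unflat2(r$dX, B, L), grads = grads)
    },
    lstm = {
      B <- cache$B; L <- cache$L
      rc <- cache$r
      r <- .lstm_bwd(dY, cache$Xf, rc$G, rc$Gg, rc$ZG, rc$Cc, rc$ACc,
                     rc$HS, p$Wx, p$Wh, B, L, act_code(layer$act))
      list(dX = unflat2(r$dX, B, L),
           grads = list(Wx = r$dWx, Wh = r$dWh, b = as.numeric(r$db)))
    },
    dense = {
      dz <- dY * a$d(cache$z, cache$y)
      list(dX = dz %*% t(p$W),
           grads = list(W = crossprod(cache$X, dz), b = colSums(dz)))
    },
    dense_time = {
      B <- cache$B; L <- cache$L; C <- cache$C
      dYp <- aperm(dY, c(1, 3, 2))
      dim(dYp) <- c(B * C, dim(dY)[2])
      dz <- dYp * a$d(cache$z, cache$y)
      dXp <- dz %*% t(p$W)
      dX <- array(dXp, c(B, C, L))
      list(dX = aperm(dX, c(1, 3, 2)),
           grads = list(W = crossprod(cache$Xp, dz), b = colSums(dz)))
    },
    noise = list(dX = dY, grads = list()),
    stop("unknown layer type ", layer$type))
}

## ---- sequential model ---------------------------------------------------

nn_sequential <- function(...) {
  structure(list(layers = list(...)), class = "nn_model")
}

nn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], X, training)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

nn_backward <- function(model, caches, dOut) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], dOut)
    dOut <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dOut, grads = grads)
}

nn_n_params <- function(model) {
  sum(vapply(model$layers,
             function(l) sum(vapply(l$par, length, 0L)), 0))
}

## ---- optimizers ---------------------------------------------------------

optimizer <- function(kind = c("adam", "rmsprop"), lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, rho = 0.9, eps = 1e-8) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2,
                 rho = rho, eps = eps, state = NULL, t = 0L),
            class = "nn_optimizer")
}

opt_step <- function(opt, model, grads) {
  if (is.null(opt$state)) {
    opt$state <- lapply(model$layers, function(l) {
      lapply(l$par, function(pp) list(m = 0 * pp, v = 0 * pp))
    })
  }
  opt$t <- opt$t + 1L
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$par)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- opt$state[[i]][[nm]]
      if (opt$kind == "adam") {
        st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
        st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
        mh <- st$m / (1 - opt$beta1^opt$t)
        vh <- st$v / (1 - opt$beta2^opt$t)
        upd <- opt$lr * mh / (sqrt(vh) + opt$eps)
      } else {
        st$v <- opt$rho * st$v + (1 - opt$rho) * g^2
        upd <- opt$lr * g / (sqrt(st$v) + opt$eps)
      }
      model$layers[[i]]$par[[nm]] <- model$layers[[i]]$par[[nm]] - upd
      opt$state[[i]][[nm]] <- st
    }
  }
  list(opt = opt, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
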