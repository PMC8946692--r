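# Minimal neural-network engine used by the two classifiers.
#
# Layers are environments holding parameters, gradients and Adam state;
# convolutions are evaluated as im2col + BLAS matrix products. Internal
# activations are channels-first — [C, H, W, B] for 2D stacks, [C, L, B]
# for 1D stacks, [features, B] for dense stacks — so that im2col,
# col2im and batch-norm statistics are plain reshapes with no array
# permutation; public entry points convert from the channels-last user
# layout once per batch. All randomness (init, dropout) draws from R's
# RNG so a single set.seed() makes runs bit-reproducible.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# user layout -> internal channels-first layout
.to_cf <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) aperm(x, c(3, 1, 2, 4))      # H,W,C,B -> C,H,W,B
  else aperm(x, c(2, 1, 3))                          # L,C,B   -> C,L,B
}

.new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$grads <- list()
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

# ---- layer constructors (parameters drawn from the current RNG) -------

# Glorot-uniform initialization, the convention of the deep-learning
# frameworks this architecture family comes from
.glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

.layer_conv2d <- function(c_in, c_out, k) {
  .new_layer("conv2d", k = k, c_in = c_in, c_out = c_out,
             W = .glorot(c_out, c_in * k * k),
             b = numeric(c_out))
}

.layer_conv1d <- function(c_in, c_out, k) {
  .new_layer("conv1d", k = k, c_in = c_in, c_out = c_out,
             W = .glorot(c_out, c_in * k),
             b = numeric(c_out))
}

.layer_dense <- function(n_in, n_out) {
  .new_layer("dense", W = .glorot(n_out, n_in), b = numeric(n_out))
}

.layer_bn <- function(c_) {
  .new_layer("bn", c_ = c_, gamma = rep(1, c_), beta = numeric(c_),
             rm = numeric(c_), rv = rep(1, c_), momentum = 0.9, eps = 1e-5)
}

.layer_pool2 <- function() .new_layer("pool2")
.layer_pool1 <- function(size) .new_layer("pool1", size = size)
.layer_lrelu <- function(slope = 0.01) .new_layer("lrelu", slope = slope)
.layer_dropout <- function(p) .new_layer("dropout", p = p)
.layer_flatten <- function() .new_layer("flatten")

.layer_lstm <- function(c_in, h) {
  sd_ <- 1 / sqrt(h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1              # forget-gate bias
  .new_layer("lstm", c_in = c_in, h = h,
             Wx = matrix(stats::rnorm(4 * h * c_in, sd = sd_), 4 * h, c_in),
             Wh = matrix(stats::rnorm(4 * h * h, sd = sd_), 4 * h, h),
             b = b)
}

.param_names <- function(ly)
  switch(ly$type,
         conv2d = , conv1d = , dense = c("W", "b"),
         bn = c("gamma", "beta"),
         lstm = c("Wx", "Wh", "b"),
         character(0))

# ---- forward / backward ----------------------------------------------

.fw_conv2d <- function(ly, x) {
  d <- dim(x); C <- d[1]; H <- d[2]; Wd <- d[3]; B <- d[4]
  k <- ly$k; p <- (k - 1L) %/% 2L
  P <- array(0, c(C, H + 2 * p, Wd + 2 * p, B))
  P[, p + seq_len(H), p + seq_len(Wd), ] <- x
  cols <- matrix(0, C * k * k, H * Wd * B)
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    o <- o + 1L
    S <- P[, di + seq_len(H), dj + seq_len(Wd), , drop = FALSE]
    dim(S) <- c(C, H * Wd * B)
    cols[((o - 1L) * C + 1L):(o * C), ] <- S
  }
  Y <- ly$W %*% cols + ly$b
  ly$cache <- list(cols = cols, d = d)
  dim(Y) <- c(ly$c_out, H, Wd, B)
  Y
}

.bw_conv2d <- function(ly, dy) {
  d <- ly$cache$d; C <- d[1]; H <- d[2]; Wd <- d[3]; B <- d[4]
  k <- ly$k; p <- (k - 1L) %/% 2L
  dim(dy) <- c(ly$c_out, H * Wd * B)
  ly$grads$W <- tcrossprod(dy, ly$cache$cols)
  ly$grads$b <- rowSums(dy)
  dcols <- crossprod(ly$W, dy)
  dP <- array(0, c(C, H + 2 * p, Wd + 2 * p, B))
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    o <- o + 1L
    blk <- dcols[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
    dim(blk) <- c(C, H, Wd, B)
    dP[, di + seq_len(H), dj + seq_len(Wd), ] <-
      dP[, di + seq_len(H), dj + seq_len(Wd), , drop = FALSE] + blk
  }
  ly$cache$cols <- NULL
  dP[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
}

.fw_conv1d <- function(ly, x) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- ly$k; p <- (k - 1L) %/% 2L
  P <- array(0, c(C, L + 2 * p, B))
  P[, p + seq_len(L), ] <- x
  cols <- matrix(0, C * k, L * B)
  for (o in seq_len(k)) {
    S <- P[, (o - 1L) + seq_len(L), , drop = FALSE]
    dim(S) <- c(C, L * B)
    cols[((o - 1L) * C + 1L):(o * C), ] <- S
  }
  Y <- ly$W %*% cols + ly$b
  ly$cache <- list(cols = cols, d = d)
  dim(Y) <- c(ly$c_out, L, B)
  Y
}

.bw_conv1d <- function(ly, dy) {
  d <- ly$cache$d; C <- d[1]; L <- d[2]; B <- d[3]
  k <- ly$k; p <- (k - 1L) %/% 2L
  dim(dy) <- c(ly$c_out, L * B)
  ly$grads$W <- tcrossprod(dy, ly$cache$cols)
  ly$grads$b <- rowSums(dy)
  dcols <- crossprod(ly$W, dy)
  dP <- array(0, c(C, L + 2 * p, B))
  for (o in seq_len(k)) {
    blk <- dcols[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
    dim(blk) <- c(C, L, B)
    dP[, (o - 1L) + seq_len(L), ] <-
      dP[, (o - 1L) + seq_len(L), , drop = FALSE] + blk
  }
  ly$cache$cols <- NULL
  dP[, p + seq_len(L), , drop = FALSE]
}

.fw_pool2 <- function(ly, x) {
  d <- dim(x); H <- d[2]; Wd <- d[3]
  r1 <- seq(1L, H, 2L); r2 <- r1 + 1L
  c1 <- seq(1L, Wd, 2L); c2 <- c1 + 1L
  a <- x[, r1, c1, , drop = FALSE]; b <- x[, r2, c1, , drop = FALSE]
  cc <- x[, r1, c2, , drop = FALSE]; dd <- x[, r2, c2, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  m1 <- a == m; m2 <- (b == m) & !m1
  m3 <- (cc == m) & !(m1 | m2); m4 <- !(m1 | m2 | m3)
  ly$cache <- list(d = d, m1 = m1, m2 = m2, m3 = m3, m4 = m4)
  m
}

.bw_pool2 <- function(ly, dy) {
  d <- ly$cache$d
  r1 <- seq(1L, d[2], 2L); c1 <- seq(1L, d[3], 2L)
  dx <- array(0, d)
  dx[, r1, c1, ] <- dy * ly$cache$m1
  dx[, r1 + 1L, c1, ] <- dy * ly$cache$m2
  dx[, r1, c1 + 1L, ] <- dy * ly$cache$m3
  dx[, r1 + 1L, c1 + 1L, ] <- dy * ly$cache$m4
  ly$cache[c("m1", "m2", "m3", "m4")] <- NULL
  dx
}

.fw_pool1 <- function(ly, x) {
  d <- dim(x); L <- d[2]; s <- ly$size
  Lo <- L %/% s
  sl <- lapply(seq_len(s), function(o)
    x[, (seq_len(Lo) - 1L) * s + o, , drop = FALSE])
  m <- do.call(pmax, sl)
  masks <- vector("list", s)
  taken <- array(FALSE, dim(m))
  for (o in seq_len(s)) {
    masks[[o]] <- (sl[[o]] == m) & !taken
    taken <- taken | masks[[o]]
  }
  ly$cache <- list(d = d, Lo = Lo, masks = masks)
  m
}

.bw_pool1 <- function(ly, dy) {
  d <- ly$cache$d; s <- ly$size; Lo <- ly$cache$Lo
  dx <- array(0, d)
  for (o in seq_len(s))
    dx[, (seq_len(Lo) - 1L) * s + o, ] <- dy * ly$cache$masks[[o]]
  ly$cache$masks <- NULL
  dx
}

# batch norm: channels-first activations flatten to a [C, m] matrix by a
# plain reshape, and per-channel statistics recycle down columns
.fw_bn <- function(ly, x, train) {
  d <- dim(x)
  C <- d[1]; m <- prod(d) / C
  M <- x; dim(M) <- c(C, m)
  if (train) {
    mu <- rowMeans(M)
    va <- rowMeans(M * M) - mu^2
    ly$rm <- ly$momentum * ly$rm + (1 - ly$momentum) * mu
    ly$rv <- ly$momentum * ly$rv + (1 - ly$momentum) * va
  } else {
    mu <- ly$rm; va <- ly$rv
  }
  invstd <- 1 / sqrt(va + ly$eps)
  xhat <- (M - mu) * invstd
  Y <- xhat * ly$gamma + ly$beta
  if (train) ly$cache <- list(xhat = xhat, invstd = invstd, m = m, d = d)
  dim(Y) <- d
  Y
}

.bw_bn <- function(ly, dy) {
  cc <- ly$cache; m <- cc$m
  dim(dy) <- c(cc$d[1], m)
  ly$grads$gamma <- rowSums(dy * cc$xhat)
  ly$grads$beta <- rowSums(dy)
  dxhat <- dy * ly$gamma
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cc$xhat)
  dM <- (cc$invstd / m) * (m * dxhat - s1 - cc$xhat * s2)
  dim(dM) <- cc$d
  ly$cache <- NULL
  dM
}

.fw_lrelu <- function(ly, x) {
  mask <- x > 0
  ly$cache <- list(mask = mask)
  pmax(x, 0) + ly$slope * pmin(x, 0)
}

.bw_lrelu <- function(ly, dy) {
  out <- dy * ly$slope + dy * (1 - ly$slope) * ly$cache$mask
  ly$cache <- NULL
  out
}

.fw_dropout <- function(ly, x, train) {
  if (!train || ly$p <= 0) { ly$cache <- NULL; return(x) }
  mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
  dim(mask) <- dim(x)
  ly$cache <- list(mask = mask)
  x * mask
}

.bw_dropout <- function(ly, dy) {
  if (is.null(ly$cache)) return(dy)
  out <- dy * ly$cache$mask
  ly$cache <- NULL
  out
}

.fw_flatten <- function(ly, x) {
  d <- dim(x)
  ly$cache <- list(d = d)
  B <- d[length(d)]
  dim(x) <- c(prod(d) / B, B)
  x
}

.bw_flatten <- function(ly, dy) {
  dim(dy) <- ly$cache$d
  dy
}

.fw_dense <- function(ly, x) {
  ly$cache <- list(x = x)
  ly$W %*% x + ly$b
}

.bw_dense <- function(ly, dy) {
  ly$grads$W <- tcrossprod(dy, ly$cache$x)
  ly$grads$b <- rowSums(dy)
  ly$cache <- NULL
  crossprod(ly$W, dy)
}

.fw_lstm <- function(ly, x) {
  d <- dim(x); C <- d[1]; T_ <- d[2]; B <- d[3]
  h <- ly$h
  # input projection for all timesteps in one gemm; [C,B,T] layout makes
  # per-step column blocks contiguous
  xp <- aperm(x, c(1, 3, 2))
  dim(xp) <- c(C, B * T_)
  Zx <- ly$Wx %*% xp + ly$b
  hs <- matrix(0, h, B); cs <- matrix(0, h, B)
  steps <- vector("list", T_)
  ri <- seq_len(h)
  for (t_ in seq_len(T_)) {
    z <- Zx[, (t_ - 1L) * B + seq_len(B), drop = FALSE] + ly$Wh %*% hs
    ig <- .sigmoid(z[ri, , drop = FALSE])
    fg <- .sigmoid(z[h + ri, , drop = FALSE])
    gg <- tanh(z[2 * h + ri, , drop = FALSE])
    og <- .sigmoid(z[3 * h + ri, , drop = FALSE])
    c_new <- fg * cs + ig * gg
    tc <- tanh(c_new)
    steps[[t_]] <- list(h_prev = hs, c_prev = cs,
                        i = ig, f = fg, g = gg, o = og, tc = tc)
    hs <- og * tc
    cs <- c_new
  }
  ly$cache <- list(steps = steps, d = d, xp = xp)
  hs                       # last hidden state only
}

.bw_lstm <- function(ly, dh) {
  d <- ly$cache$d; C <- d[1]; T_ <- d[2]; B <- d[3]
  h <- ly$h
  dWh <- matrix(0, 4 * h, h)
  dZ <- matrix(0, 4 * h, B * T_)
  dc <- matrix(0, h, B)
  for (t_ in rev(seq_len(T_))) {
    st <- ly$cache$steps[[t_]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dz <- rbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dZ[, (t_ - 1L) * B + seq_len(B)] <- dz
    dWh <- dWh + tcrossprod(dz, st$h_prev)
    dh <- crossprod(ly$Wh, dz)
    dc <- dc * st$f
  }
  ly$grads$Wx <- tcrossprod(dZ, ly$cache$xp)
  ly$grads$Wh <- dWh
  ly$grads$b <- rowSums(dZ)
  dXp <- crossprod(ly$Wx, dZ)
  dim(dXp) <- c(C, B, T_)
  ly$cache <- NULL
  aperm(dXp, c(1, 3, 2))
}

.layer_forward <- function(ly, x, train) {
  switch(ly$type,
         conv2d = .fw_conv2d(ly, x),
         conv1d = .fw_conv1d(ly, x),
         pool2 = .fw_pool2(ly, x),
         pool1 = .fw_pool1(ly, x),
         bn = .fw_bn(ly, x, train),
         lrelu = .fw_lrelu(ly, x),
         dropout = .fw_dropout(ly, x, train),
         flatten = .fw_flatten(ly, x),
         dense = .fw_dense(ly, x),
         lstm = .fw_lstm(ly, x),
         stop("unknown layer type ", ly$type))
}

.layer_backward <- function(ly, dy) {
  switch(ly$type,
         conv2d = .bw_conv2d(ly, dy),
         conv1d = .bw_conv1d(ly, dy),
         pool2 = .bw_pool2(ly, dy),
         pool1 = .bw_pool1(ly, dy),
         bn = .bw_bn(ly, dy),
         lrelu = .bw_lrelu(ly, dy),
         dropout = .bw_dropout(ly, dy),
         flatten = .bw_flatten(ly, dy),
         dense = .bw_dense(ly, dy),
         lstm = .bw_lstm(ly, dy),
         stop("unknown layer type ", ly$type))
}

# x in internal channels-first layout
.net_forward <- function(layers, x, train = FALSE) {
  for (ly in layers) x <- .layer_forward(ly, x, train)
  x
}

.net_backward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- .layer_backward(ly, dy)
  invisible(dy)
}

# softmax cross-entropy on logits [n_class, B] with integer labels 1..n
.softmax <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

.xent_loss_grad <- function(logits, y) {
  B <- ncol(logits)
  P <- .softmax(logits)
  picked <- P[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dZ / B,
       acc = mean(max.col(t(P), ties.method = "first") == y))
}

# ---- parameter utilities ---------------------------------------------

.net_param_list <- function(layers) {
  lapply(layers, function(ly) {
    out <- lapply(.param_names(ly), function(p) get(p, envir = ly))
    names(out) <- .param_names(ly)
    if (ly$type == "bn") { out$rm <- ly$rm; out$rv <- ly$rv }
    out
  })
}

.net_set_params <- function(layers, params) {
  for (i in seq_along(layers))
    for (p in names(params[[i]]))
      assign(p, params[[i]][[p]], envir = layers[[i]])
  invisible(layers)
}

.net_n_params <- function(layers) {
  sum(vapply(layers, function(ly)
    sum(vapply(.param_names(ly), function(p) length(get(p, envir = ly)), 0L)),
    0))
}

# one Adam step over all trainable parameters
.adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in layers) {
    pn <- .param_names(ly)
    if (length(pn) == 0L) next
    if (is.null(ly$adam)) {
      ly$adam <- list(t = 0,
                      m = lapply(pn, function(p) 0 * get(p, envir = ly)),
                      v = lapply(pn, function(p) 0 * get(p, envir = ly)))
      names(ly$adam$m) <- pn; names(ly$adam$v) <- pn
    }
    ly$adam$t <- ly$adam$t + 1
    bc1 <- 1 - beta1^ly$adam$t
    bc2 <- 1 - beta2^ly$adam$t
    for (p in pn) {
      g <- ly$grads[[p]]
      ly$adam$m[[p]] <- beta1 * ly$adam$m[[p]] + (1 - beta1) * g
      ly$adam$v[[p]] <- beta2 * ly$adam$v[[p]] + (1 - beta2) * g * g
      assign(p, get(p, envir = ly) -
               lr * (ly$adam$m[[p]] / bc1) /
               (sqrt(ly$adam$v[[p]] / bc2) + eps),
             envir = ly)
    }
  }
  invisible(layers)
}
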