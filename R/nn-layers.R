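# Differentiable 1-D layer primitives for the breath-segmentation U-Net.
# Tensors are R arrays of dim (batch N, time L, channels C); convolutions
# run as im2col matrix products on the BLAS, which keeps a CPU-only
# training loop tractable at the window sizes used here. Each *_fwd returns
# list(y, cache); the matching *_bwd consumes (dy, cache) and returns the
# input gradient plus parameter gradients. Gradient correctness is pinned
# by finite-difference tests. Hot paths avoid ifelse()/with() and reshape
# via dim<- to keep allocations down.

# ---- convolution ------------------------------------------------------------

# Weights for conv1d are stored as array (k, C_in, C_out); bias length C_out.
# Same-padding with zeros; k odd; dilation supported.
conv1d_fwd <- function(x, W, b, dilation = 1L) {
  d <- dim(x); N <- d[1]; L <- d[2]; C_in <- d[3]
  k <- dim(W)[1]; C_out <- dim(W)[3]
  if (k == 1L) {
    Xcol <- x
    dim(Xcol) <- c(N * L, C_in)
  } else {
    Xcol <- im2col1d(x, N, L, C_in, k, as.integer(dilation))
  }
  Wmat <- aperm(W, c(2, 1, 3))
  dim(Wmat) <- c(k * C_in, C_out)
  Y <- Xcol %*% Wmat
  Y <- Y + rep(b, each = N * L)
  dim(Y) <- c(N, L, C_out)
  list(y = Y, cache = list(Xcol = Xcol, Wmat = Wmat, N = N, L = L,
                           C_in = C_in, C_out = C_out, k = k,
                           dilation = dilation))
}

conv1d_bwd <- function(dy, cache) {
  N <- cache$N; L <- cache$L; C_in <- cache$C_in; C_out <- cache$C_out
  k <- cache$k
  dYmat <- dy
  dim(dYmat) <- c(N * L, C_out)
  db <- colSums(dYmat)
  dWmat <- crossprod(cache$Xcol, dYmat)
  dim(dWmat) <- c(C_in, k, C_out)
  dW <- aperm(dWmat, c(2, 1, 3))
  dXcol <- tcrossprod(dYmat, cache$Wmat)
  if (k == 1L) {
    dim(dXcol) <- c(N, L, C_in)
    return(list(dx = dXcol, dW = dW, db = db))
  }
  dx <- col2im1d(dXcol, N, L, C_in, k, as.integer(cache$dilation))
  list(dx = dx, dW = dW, db = db)
}

# ---- pointwise nonlinearities ----------------------------------------------

leaky_relu_fwd <- function(x, slope = 0.01) {
  mult <- slope + (1 - slope) * (x > 0)
  list(y = x * mult, cache = mult)
}
leaky_relu_bwd <- function(dy, cache) dy * cache

relu_fwd <- function(x) {
  pos <- x > 0
  list(y = x * pos, cache = pos)
}
relu_bwd <- function(dy, cache) dy * cache

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, cache = list(x = x, ph = ph))
}
gelu_bwd <- function(dy, cache)
  dy * (cache$ph + cache$x * stats::dnorm(cache$x))

sigmoid_fwd <- function(x) {
  y <- stats::plogis(x)
  list(y = y, cache = y)
}
sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

# ---- pooling / upsampling ---------------------------------------------------

# Max-pool, window 2, stride 2; L must be even.
maxpool_fwd <- function(x) {
  d <- dim(x); L <- d[2]
  a <- x[, seq(1L, L, 2L), , drop = FALSE]
  b <- x[, seq(2L, L, 2L), , drop = FALSE]
  first <- a >= b # ties to the earlier sample
  list(y = pmax(a, b), cache = list(first = first, L = L))
}
maxpool_bwd <- function(dy, cache) {
  d <- dim(dy); L <- cache$L
  dx <- array(0, c(d[1], L, d[3]))
  dx[, seq(1L, L, 2L), ] <- dy * cache$first
  dx[, seq(2L, L, 2L), ] <- dy * !cache$first
  dx
}

# Transposed convolution, kernel 2, stride 2: doubles the time length.
# W1, W2 are (C_in x C_out); shared bias b.
convtr_fwd <- function(x, W1, W2, b) {
  d <- dim(x); N <- d[1]; L <- d[2]; C_in <- d[3]
  C_out <- ncol(W1)
  Xmat <- x
  dim(Xmat) <- c(N * L, C_in)
  Y1 <- Xmat %*% W1 + rep(b, each = N * L)
  Y2 <- Xmat %*% W2 + rep(b, each = N * L)
  dim(Y1) <- c(N, L, C_out); dim(Y2) <- c(N, L, C_out)
  y <- array(0, c(N, 2L * L, C_out))
  y[, seq(1L, 2L * L, 2L), ] <- Y1
  y[, seq(2L, 2L * L, 2L), ] <- Y2
  list(y = y, cache = list(Xmat = Xmat, W1 = W1, W2 = W2, N = N, L = L,
                           C_in = C_in, C_out = C_out))
}
convtr_bwd <- function(dy, cache) {
  N <- cache$N; L <- cache$L; C_in <- cache$C_in; C_out <- cache$C_out
  dY1 <- dy[, seq(1L, 2L * L, 2L), , drop = FALSE]
  dY2 <- dy[, seq(2L, 2L * L, 2L), , drop = FALSE]
  dim(dY1) <- c(N * L, C_out); dim(dY2) <- c(N * L, C_out)
  db <- colSums(dY1) + colSums(dY2)
  dW1 <- crossprod(cache$Xmat, dY1)
  dW2 <- crossprod(cache$Xmat, dY2)
  dX <- tcrossprod(dY1, cache$W1) + tcrossprod(dY2, cache$W2)
  dim(dX) <- c(N, L, C_in)
  list(dx = dX, dW1 = dW1, dW2 = dW2, db = db)
}

# ---- normalization / regularization ----------------------------------------

# Layer normalization over the channel axis at each (batch, time) position.
layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); M <- d[1] * d[2]; C <- d[3]
  Xm <- x
  dim(Xm) <- c(M, C)
  mu <- rowMeans(Xm)
  xc <- Xm - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Ym <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  dim(Ym) <- d
  list(y = Ym,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d, M = M, C = C))
}
layernorm_bwd <- function(dy, cache) {
  M <- cache$M; C <- cache$C; xhat <- cache$xhat
  dYm <- dy
  dim(dYm) <- c(M, C)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(cache$gamma, each = M)
  dXm <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dXm) <- cache$d
  list(dx = dXm, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; identity when not training or rate 0. Masks are drawn
# from the active RNG stream so training is reproducible from one seed.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, cache = mask)
}
dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- structural ops ---------------------------------------------------------

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  list(y = y, cache = list(Ca = da[3], Cb = db[3]))
}
concat_bwd <- function(dy, cache) {
  list(da = dy[, , seq_len(cache$Ca), drop = FALSE],
       db = dy[, , cache$Ca + seq_len(cache$Cb), drop = FALSE])
}

crop_fwd <- function(x, out_len) {
  d <- dim(x)
  off <- (d[2] - out_len) %/% 2L
  list(y = x[, off + seq_len(out_len), , drop = FALSE],
       cache = list(d = d, off = off, out_len = out_len))
}
crop_bwd <- function(dy, cache) {
  dx <- array(0, cache$d)
  dx[, cache$off + seq_len(cache$out_len), ] <- dy
  dx
}

# Additive attention gate: skip x and gating signal g (same length) each
# pass a 1x1 convolution, are summed, ReLU, projected to one channel,
# sigmoid; the coefficient multiplies the skip channel-wise.
attgate_fwd <- function(x, g, p) {
  th <- conv1d_fwd(x, p$Wt, rep(0, dim(p$Wt)[3]))
  ph <- conv1d_fwd(g, p$Wp, p$bp)
  s <- th$y + ph$y
  r <- relu_fwd(s)
  q <- conv1d_fwd(r$y, p$Wpsi, p$bpsi)
  a <- sigmoid_fwd(q$y)
  d <- dim(x)
  amat <- array(a$y, d) # broadcast single channel over the skip's channels
  list(y = x * amat, coeff = a$y,
       cache = list(x = x, th = th$cache, ph = ph$cache, r = r$cache,
                    q = q$cache, a = a$cache, amat = amat, d = d))
}
attgate_bwd <- function(dy, cache, p) {
  d <- cache$d
  dx1 <- dy * cache$amat
  # gradient into the (broadcast) coefficient: sum over skip channels
  m <- dy * cache$x
  dim(m) <- c(d[1] * d[2], d[3])
  da <- rowSums(m)
  dim(da) <- c(d[1], d[2], 1L)
  dq <- sigmoid_bwd(da, cache$a)
  bq <- conv1d_bwd(dq, cache$q)
  ds <- relu_bwd(bq$dx, cache$r)
  bth <- conv1d_bwd(ds, cache$th)
  bph <- conv1d_bwd(ds, cache$ph)
  list(dx = dx1 + bth$dx, dg = bph$dx,
       dWt = bth$dW, dWp = bph$dW, dbp = bph$db,
       dWpsi = bq$dW, dbpsi = bq$dbpsi %||% bq$db)
}
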