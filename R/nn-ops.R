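# Neural-network primitives with explicit forward/backward passes.
#
# Conventions:
#  * image feature maps are arrays dim c(H, W, C); sequences are matrices L x D
#  * every `*_fw` returns list(out=, cache=); the matching `*_bw(dout, cache)`
#    returns list(dx=, and one gradient per parameter, named like the params)
#  * weights for dense/conv layers are stored input-major: dense W is
#    (in x out); conv W is (K*K*Cin x Cout) so modulation by output channel is
#    a column scaling.

init_mat <- function(nin, nout, gain = sqrt(2)) {
  matrix(rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout)
}

# ---- elementwise activations ----------------------------------------------

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(dout, cache) dout * cache

leaky_relu_fw <- function(x, alpha = 0.01) {
  pos <- x > 0
  scale <- pos + alpha * !pos
  list(out = x * scale, cache = scale)
}
leaky_relu_bw <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense -----------------------------------------------------------------

dense_fw <- function(x, W, b) {
  if (!is.matrix(x)) x <- matrix(x, 1)
  out <- x %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(x = x, W = W))
}
dense_bw <- function(dout, cache) {
  if (!is.matrix(dout)) dout <- matrix(dout, 1)
  list(dx = dout %*% t(cache$W),
       W = crossprod(cache$x, dout),
       b = colSums(dout))
}

# ---- 2-D convolution (stride 1, 'same' zero padding) -----------------------

conv2d_fw <- function(x, W, b, K) {
  d <- dim(x)
  cols <- im2col_same(as.numeric(x), d[1], d[2], d[3], K)
  Cout <- length(b)
  outm <- cols %*% W
  outm <- outm + rep(b, each = nrow(outm))
  list(out = array(outm, c(d[1], d[2], Cout)),
       cache = list(cols = cols, W = W, dims = d, K = K))
}
conv2d_bw <- function(dout, cache) {
  d <- cache$dims
  Cout <- ncol(cache$W)
  dm <- matrix(dout, d[1] * d[2], Cout)
  dcols <- dm %*% t(cache$W)
  list(dx = array(col2im_same(dcols, d[1], d[2], d[3], cache$K), d),
       W = crossprod(cache$cols, dm),
       b = colSums(dm))
}

# ---- 1-D convolution over an L x C sequence (stride 1, 'same' padding) -----

conv1d_fw <- function(x, W, b, K) {
  x <- cbind(x)
  L <- nrow(x); C <- ncol(x); P <- (K - 1) %/% 2
  xp <- rbind(matrix(0, P, C), x, matrix(0, P, C))
  idx <- outer(seq_len(L), 0:(K - 1), `+`)            # L x K rows into xp
  cols <- matrix(0, L, K * C)
  for (c in seq_len(C)) cols[, ((c - 1) * K + 1):(c * K)] <- matrix(xp[idx, c], L, K)
  Cout <- length(b)
  outm <- cols %*% W
  outm <- outm + rep(b, each = L)
  list(out = outm,
       cache = list(cols = cols, W = W, L = L, C = C, K = K, idx = idx))
}
conv1d_bw <- function(dout, cache) {
  L <- cache$L; C <- cache$C; K <- cache$K; P <- (K - 1) %/% 2
  dm <- cbind(dout)
  dcols <- dm %*% t(cache$W)
  dxp <- matrix(0, L + 2 * P, C)
  for (c in seq_len(C)) {
    dc <- matrix(dcols[, ((c - 1) * K + 1):(c * K)], L, K)
    for (k in seq_len(K)) {
      rows <- cache$idx[, k]
      dxp[rows, c] <- dxp[rows, c] + dc[, k]
    }
  }
  list(dx = dxp[(P + 1):(P + L), , drop = FALSE],
       W = crossprod(cache$cols, dm),
       b = colSums(dm))
}

# ---- per-channel normalization with frozen statistics ----------------------
# x is standardized per channel by stored constants (rmean, rsd) and given a
# trainable affine (gamma, beta). The constants default to (0, 1) and can be
# calibrated once from data before training; they are never updated by the
# optimizer, which keeps the layer deterministic, batch-size independent and
# information-preserving across examples.

chan_norm_fw <- function(x, gamma, beta, rmean, rsd) {
  d <- dim(x)
  xm <- if (length(d) == 3) matrix(x, d[1] * d[2], d[3]) else cbind(x)
  N <- nrow(xm)
  xhat <- (xm - rep(rmean, each = N)) * rep(1 / rsd, each = N)
  # clamp keeps the forward pass finite while running statistics are still
  # warming up; with converged statistics xhat stays well inside the bound
  xhat <- pmin(pmax(xhat, -50), 50)
  outm <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  out <- if (length(d) == 3) array(outm, d) else outm
  list(out = out,
       cache = list(xhat = xhat, gamma = gamma, rsd = rsd, d = d))
}
chan_norm_bw <- function(dout, cache) {
  d <- cache$d
  dm <- if (length(d) == 3) matrix(dout, d[1] * d[2], d[3]) else cbind(dout)
  Nr <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxm <- dm * rep(cache$gamma / cache$rsd, each = Nr)
  dx <- if (length(d) == 3) array(dxm, d) else dxm
  list(dx = dx, gamma = dgamma, beta = dbeta,
       rmean = numeric(length(cache$rsd)), rsd = numeric(length(cache$rsd)))
}

# ---- pooling ---------------------------------------------------------------

maxpool_fw <- function(x) {
  d <- dim(x)
  r <- maxpool2x2(as.numeric(x), d[1], d[2], d[3])
  list(out = array(r$out, c(d[1] %/% 2, d[2] %/% 2, d[3])),
       cache = list(idx = r$idx, dims = d))
}
maxpool_bw <- function(dout, cache) {
  dx <- numeric(prod(cache$dims))
  dx[cache$idx] <- as.numeric(dout)
  array(dx, cache$dims)
}

gap_fw <- function(x) {
  d <- dim(x)
  xm <- if (length(d) == 3) matrix(x, d[1] * d[2], d[3]) else cbind(x)
  list(out = colMeans(xm), cache = list(d = d, N = nrow(xm)))
}
gap_bw <- function(dout, cache) {
  d <- cache$d
  dxm <- matrix(dout, cache$N, length(dout), byrow = TRUE) / cache$N
  if (length(d) == 3) array(dxm, d) else dxm
}

# ---- CBAM attention --------------------------------------------------------

#' Channel attention of a convolutional block attention module
#'
#' Scales each channel of a feature map by a sigmoid weight computed from the
#' average- and max-pooled channel descriptors passed through one shared
#' two-layer bottleneck MLP.
#'
#' @param fmap numeric array, dim `c(H, W, C)`.
#' @param params list with `W1` (`C x C/r`), `b1`, `W2` (`C/r x C`), `b2`; if
#'   missing, freshly initialized weights for `reduction` are drawn.
#' @param reduction integer bottleneck reduction ratio (default 8).
#' @return array of the same shape with attribute `"weights"` (the C channel
#'   weights in (0,1)).
#' @export
cbam_channel_attention <- function(fmap, params = NULL, reduction = 8) {
  if (!is_scalar_num(reduction) || reduction <= 0) stopf("reduction must be a positive number")
  C <- dim(fmap)[3]
  if (C < reduction) stopf("channel count (%d) must be >= reduction (%d)", C, reduction)
  if (is.null(params)) params <- init_cbam_channel(C, reduction)
  r <- cbam_channel_fw(fmap, params)
  out <- r$out
  attr(out, "weights") <- r$cache$s
  out
}

init_cbam_channel <- function(C, reduction) {
  Cr <- max(1L, C %/% reduction)
  list(W1 = init_mat(C, Cr), b1 = numeric(Cr),
       W2 = init_mat(Cr, C, gain = 1), b2 = numeric(C))
}

cbam_channel_fw <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  avg <- colMeans(xm)
  mxi <- max.col(t(xm), ties.method = "first")     # argmax position per channel
  mx <- xm[cbind(mxi, seq_len(d[3]))]
  mlp <- function(v) {
    h <- pmax(v %*% p$W1 + p$b1, 0)
    list(h = h, z = h %*% p$W2 + p$b2)
  }
  ma <- mlp(matrix(avg, 1)); mm <- mlp(matrix(mx, 1))
  s <- as.numeric(sigmoid(ma$z + mm$z))
  outm <- xm * rep(s, each = nrow(xm))
  list(out = array(outm, d),
       cache = list(xm = xm, d = d, avg = avg, mx = mx, mxi = mxi,
                    ha = ma$h, hm = mm$h, s = s, p = p))
}

cbam_channel_bw <- function(dout, cache) {
  d <- cache$d; p <- cache$p
  dm <- matrix(dout, d[1] * d[2], d[3])
  dx_direct <- dm * rep(cache$s, each = nrow(dm))
  ds <- colSums(dm * cache$xm)
  dz <- rbind(ds * cache$s * (1 - cache$s))        # 1 x C, shared by branches
  grads <- list(W1 = p$W1 * 0, b1 = numeric(ncol(p$W1)),
                W2 = p$W2 * 0, b2 = numeric(ncol(p$W2)))
  back_branch <- function(v, h) {
    dh <- (dz %*% t(p$W2)) * (h > 0)
    grads$W2 <<- grads$W2 + crossprod(h, dz)
    grads$b2 <<- grads$b2 + as.numeric(dz)
    grads$W1 <<- grads$W1 + crossprod(matrix(v, 1), dh)
    grads$b1 <<- grads$b1 + as.numeric(dh)
    as.numeric(dh %*% t(p$W1))
  }
  davg <- back_branch(cache$avg, cache$ha)
  dmx <- back_branch(cache$mx, cache$hm)
  N <- d[1] * d[2]
  dxm <- dx_direct + matrix(davg, N, d[3], byrow = TRUE) / N
  dxm[cbind(cache$mxi, seq_len(d[3]))] <-
    dxm[cbind(cache$mxi, seq_len(d[3]))] + dmx
  c(list(dx = array(dxm, d)), grads)
}

#' Spatial attention of a convolutional block attention module
#'
#' Scales each spatial position by a sigmoid weight computed by convolving the
#' channel-wise mean and max maps with a single `kernel x kernel` filter.
#'
#' @param fmap numeric array, dim `c(H, W, C)`.
#' @param params list with `W` (`kernel^2*2 x 1`) and `b` (length 1); freshly
#'   initialized if missing.
#' @param kernel odd convolution kernel size (default 7).
#' @return array of the same shape with attribute `"weights"` (H x W map in (0,1)).
#' @export
cbam_spatial_attention <- function(fmap, params = NULL, kernel = 7) {
  if (kernel %% 2 != 1) stopf("spatial attention kernel must be odd, got %d", kernel)
  if (is.null(params)) params <- init_cbam_spatial(kernel)
  r <- cbam_spatial_fw(fmap, params, kernel)
  out <- r$out
  attr(out, "weights") <- matrix(r$cache$s, dim(fmap)[1], dim(fmap)[2])
  out
}

init_cbam_spatial <- function(kernel) {
  list(W = init_mat(kernel * kernel * 2, 1, gain = 1), b = 0)
}

cbam_spatial_fw <- function(x, p, K) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  m <- rowMeans(xm)
  mxi <- max.col(xm, ties.method = "first")        # argmax channel per position
  mx <- xm[cbind(seq_len(nrow(xm)), mxi)]
  stack <- array(c(m, mx), c(d[1], d[2], 2))
  cv <- conv2d_fw(stack, p$W, p$b, K)
  z <- as.numeric(cv$out)
  s <- sigmoid(z)
  outm <- xm * s
  list(out = array(outm, d),
       cache = list(xm = xm, d = d, mxi = mxi, s = s, cv = cv$cache))
}

cbam_spatial_bw <- function(dout, cache) {
  d <- cache$d
  dm <- matrix(dout, d[1] * d[2], d[3])
  dx_direct <- dm * cache$s
  ds <- rowSums(dm * cache$xm)
  dz <- ds * cache$s * (1 - cache$s)
  cb <- conv2d_bw(array(dz, c(d[1], d[2], 1)), cache$cv)
  dstack <- matrix(cb$dx, d[1] * d[2], 2)
  dxm <- dx_direct + dstack[, 1] / d[3]
  dxm[cbind(seq_len(nrow(dxm)), cache$mxi)] <-
    dxm[cbind(seq_len(nrow(dxm)), cache$mxi)] + dstack[, 2]
  list(dx = array(dxm, d), W = cb$W, b = cb$b)
}

# ---- layer norm (per sequence row) -----------------------------------------

layernorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  D <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowSums(xc^2) / D
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma, D = D))
}
layernorm_bw <- function(dout, cache) {
  D <- cache$D
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = nrow(dout))
  dx <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv
  list(dx = dx, gamma = dgamma, beta = dbeta)
}

# ---- softmax over rows -----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- multi-head self-attention ---------------------------------------------
# Weights: Wq, Wk, Wv, Wo all D x D (no biases); heads split columns.

mha_fw <- function(x, p, n_heads) {
  L <- nrow(x); D <- ncol(x)
  dh <- D %/% n_heads
  Q <- x %*% p$Wq; K <- x %*% p$Wk; V <- x %*% p$Wv
  O <- matrix(0, L, D)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    A <- softmax_rows(S)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[h]] <- list(A = A, cols = cols)
  }
  out <- O %*% p$Wo
  list(out = out, cache = list(x = x, Q = Q, K = K, V = V, O = O,
                               heads = heads, p = p, dh = dh))
}

mha_bw <- function(dout, cache) {
  p <- cache$p; x <- cache$x; dh <- cache$dh
  dWo <- crossprod(cache$O, dout)
  dO <- dout %*% t(p$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(x), ncol(x))
  for (hd in cache$heads) {
    cols <- hd$cols; A <- hd$A
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / sqrt(dh)
    dK[, cols] <- (crossprod(dS, cache$Q[, cols, drop = FALSE])) / sqrt(dh)
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx,
       Wq = crossprod(x, dQ), Wk = crossprod(x, dK),
       Wv = crossprod(x, dV), Wo = dWo)
}

# ---- dropout ---------------------------------------------------------------

dropout_fw <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- stats::rbinom(length(x), 1, 1 - p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}
dropout_bw <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- sinusoidal positional encoding ----------------------------------------

positional_encoding <- function(L, D) {
  pos <- seq_len(L) - 1
  pe <- matrix(0, L, D)
  for (i in seq_len(D %/% 2)) {
    w <- 1 / 10000^((2 * (i - 1)) / D)
    pe[, 2 * i - 1] <- sin(pos * w)
    pe[, 2 * i] <- cos(pos * w)
  }
  if (D %% 2 == 1) pe[, D] <- sin(pos / 10000)
  pe
}
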