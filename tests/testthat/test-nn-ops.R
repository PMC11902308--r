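# Neural primitives: hand-computed forward oracles and finite-difference
# gradient checks on tiny shapes.

test_that("channel attention matches a hand-computed sigmoid(MLP(avg)+MLP(max))", {
  # 2-channel 1x1 feature map with hand-set bottleneck weights
  fmap <- array(c(0.5, -1.2), c(1, 1, 2))
  params <- list(W1 = matrix(c(0.3, -0.4), 2, 1), b1 = 0.1,
                 W2 = matrix(c(0.7, -0.2), 1, 2), b2 = c(0, 0.05))
  out <- cbam_channel_attention(fmap, params, reduction = 2)
  v <- c(0.5, -1.2)                      # avg pool = max pool on a 1x1 map
  h <- max(sum(v * c(0.3, -0.4)) + 0.1, 0)
  z <- h * c(0.7, -0.2) + c(0, 0.05)
  s_hand <- 1 / (1 + exp(-(z + z)))      # shared MLP applied to both branches
  expect_equal(as.numeric(attr(out, "weights")), s_hand, tolerance = 1e-12)
  expect_equal(as.numeric(out), v * s_hand, tolerance = 1e-12)
})

test_that("average and max branches coincide for spatially constant channels", {
  # per-channel constant maps make avg-pool == max-pool, so the shared
  # bottleneck sees the same descriptor from both branches
  fmap <- array(rep(c(0.4, -0.9, 1.3), each = 16), c(4, 4, 3))
  params <- mg$init_cbam_channel(3, 1)
  out <- cbam_channel_attention(fmap, params, reduction = 1)
  w <- attr(out, "weights")
  v <- matrix(c(0.4, -0.9, 1.3), 1)
  h <- pmax(v %*% params$W1 + params$b1, 0)
  z <- h %*% params$W2 + params$b2
  expect_equal(as.numeric(w), as.numeric(1 / (1 + exp(-2 * z))),
               tolerance = 1e-12)
  expect_equal(dim(out), dim(fmap))
  expect_true(all(w > 0 & w < 1))
  expect_error(cbam_channel_attention(fmap, params, reduction = 0), "positive")
})

test_that("spatial attention matches a hand computation and keeps shape", {
  # 1-channel 2x2 map; mean map == max map == the map itself
  fmap <- array(c(1, -2, 0.5, 3), c(2, 2, 1))
  K <- 3
  W <- matrix(0, K * K * 2, 1)
  W[5] <- 1          # center tap of the mean-map kernel: identity convolution
  params <- list(W = W, b = 0.2)
  out <- cbam_spatial_attention(fmap, params, kernel = K)
  s_hand <- 1 / (1 + exp(-(as.numeric(fmap) + 0.2)))
  expect_equal(as.numeric(attr(out, "weights")), s_hand, tolerance = 1e-12)
  expect_equal(as.numeric(out), as.numeric(fmap) * s_hand, tolerance = 1e-12)
  expect_equal(dim(out), dim(fmap))
  expect_error(cbam_spatial_attention(fmap, params, kernel = 4), "odd")
})

test_that("spatially constant maps give spatially constant attention", {
  fmap <- array(rep(c(0.7, -0.3), each = 9), c(3, 3, 2))
  out <- cbam_spatial_attention(fmap, mg$init_cbam_spatial(3), kernel = 3)
  w <- attr(out, "weights")
  # interior weight is constant; borders differ only through zero padding
  expect_lt(abs(w[2, 2] - mean(w[2, ])) , 1)
  expect_true(all(w > 0 & w < 1))
})

test_that("single-head attention matches the softmax(QK^T/sqrt(d)) V oracle", {
  set.seed(42)
  L <- 4; D <- 8
  x <- matrix(rnorm(L * D), L, D)
  p <- list(Wq = matrix(rnorm(D * D), D), Wk = matrix(rnorm(D * D), D),
            Wv = matrix(rnorm(D * D), D), Wo = diag(D))
  out <- mg$mha_fw(x, p, n_heads = 1)$out
  Q <- x %*% p$Wq; K <- x %*% p$Wk; V <- x %*% p$Wv
  S <- Q %*% t(K) / sqrt(D)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(out, A %*% V, tolerance = 1e-10)
  expect_equal(rowSums(A), rep(1, L), tolerance = 1e-6)
  expect_true(all(A > 0 & A < 1))
})

test_that("softmax rows sum to one for extreme inputs", {
  z <- rbind(c(1000, 999, 998), c(-1000, 0, 7), c(0, 0, 0))
  p <- mg$softmax_rows(z)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
})

test_that("conv2d gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  W <- matrix(rnorm(9 * 2 * 3, sd = 0.5), 18, 3)
  b <- rnorm(3)
  loss <- function(Wv) {
    sum(mg$conv2d_fw(x, matrix(Wv, 18, 3), b, 3)$out^2) / 2
  }
  fw <- mg$conv2d_fw(x, W, b, 3)
  gr <- mg$conv2d_bw(fw$out, fw$cache)       # dL/dout = out for L = sum(out^2)/2
  idx <- sample(length(W), 6)
  expect_equal(as.numeric(gr$W)[idx], num_grad(loss, as.numeric(W), idx),
               tolerance = 1e-6)
  lx <- function(xv) sum(mg$conv2d_fw(array(xv, dim(x)), W, b, 3)$out^2) / 2
  idx <- sample(length(x), 6)
  expect_equal(as.numeric(gr$dx)[idx], num_grad(lx, as.numeric(x), idx),
               tolerance = 1e-6)
})

test_that("conv1d and channel-norm gradients match finite differences", {
  set.seed(4)
  x <- matrix(rnorm(12 * 2), 12, 2)
  W <- matrix(rnorm(3 * 2 * 4, sd = 0.5), 6, 4)
  b <- rnorm(4)
  gamma <- runif(4, 0.5, 1.5); beta <- rnorm(4)
  rmean <- rnorm(4, sd = 0.1); rsd <- runif(4, 0.8, 1.2)
  f <- function(Wv) {
    cv <- mg$conv1d_fw(x, matrix(Wv, 6, 4), b, 3)
    nm <- mg$chan_norm_fw(cv$out, gamma, beta, rmean, rsd)
    sum(nm$out^2) / 2
  }
  cv <- mg$conv1d_fw(x, W, b, 3)
  nm <- mg$chan_norm_fw(cv$out, gamma, beta, rmean, rsd)
  nb <- mg$chan_norm_bw(nm$out, nm$cache)
  cb <- mg$conv1d_bw(nb$dx, cv$cache)
  idx <- sample(length(W), 6)
  expect_equal(as.numeric(cb$W)[idx], num_grad(f, as.numeric(W), idx),
               tolerance = 1e-6)
  fg <- function(gv) {
    nm <- mg$chan_norm_fw(cv$out, gv, beta, rmean, rsd); sum(nm$out^2) / 2
  }
  expect_equal(nb$gamma, num_grad(fg, gamma, 1:4), tolerance = 1e-6)
})

test_that("transformer-layer gradients match finite differences", {
  set.seed(5)
  cfg <- test_cfg(d_model = 8, n_heads = 2, n_layers = 1, ff_dim = 12)
  p <- local({ set.seed(6); mg$init_seq_encoder(10, cfg) })
  tok <- matrix(rnorm(5 * 10), 5, 10)
  loss_of <- function(pp) sum(mg$seq_encoder_fw(tok, pp, cfg)$out^2) / 2
  fw <- mg$seq_encoder_fw(tok, p, cfg)
  gr <- mg$seq_encoder_bw(fw$out, fw$cache)
  for (leaf in list(c("proj", "W"), c("layer1", "attn", "Wq"),
                    c("layer1", "ff", "W1"), c("layer1", "ln2", "gamma"))) {
    W <- p[[leaf]]
    idx <- sample(length(W), 3)
    num <- num_grad(function(v) {
      p2 <- p; p2[[leaf]] <- array(v, dim(W) %||% length(W)); loss_of(p2)
    }, as.numeric(W), idx)
    expect_equal(as.numeric(gr[[leaf]])[idx], num, tolerance = 1e-5,
                 label = paste(leaf, collapse = "$"))
  }
})

test_that("modulation arithmetic follows (W, b) -> (W*gw, b+gb)", {
  expect_equal(modulate_wb(2, 1, 3, 0.5), list(W = 6, b = 1.5))
  W <- matrix(1:6, 2, 3)
  m <- modulate_wb(W, c(1, 2, 3), gw = c(2, 1, 0.5), gb = 1)
  expect_equal(m$W, W * rep(c(2, 1, 0.5), each = 2))
  expect_equal(m$b, c(2, 3, 4))
})
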