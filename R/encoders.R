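# Per-modality encoders: a CBAM-ResNet12 backbone for the image stream and
# transformer encoders for the sEMG and VIO streams. Each produces one
# fixed-dimension clip-level feature vector r_m.

#' Architecture configuration for the pose-estimation model
#'
#' @param image_size pixel side length the image encoder expects (divisible
#'   by 16: four 2x2 max-pool stages).
#' @param frames_per_clip frames uniformly subsampled from each 10-s clip,
#'   encoded independently and mean-pooled.
#' @param width_mult multiplier on the ResNet-12 stage widths (64,128,256,512).
#' @param reduction,spatial_kernel CBAM channel-attention bottleneck ratio and
#'   spatial-attention kernel size.
#' @param d_model,n_heads,n_layers,ff_dim transformer size for the sequence
#'   encoders.
#' @param emg_downsample,emg_patch sEMG stream: keep every `emg_downsample`-th
#'   sample, then group `emg_patch` consecutive samples into one token.
#' @param vio_downsample,vio_patch same for the VIO stream.
#' @param shared_dim D, the knowledge-sharing target dimension all modality
#'   features are transformed into.
#' @param branch_width channel width of each of the three fusion branches.
#' @param fusion_kernel,decoder_kernel 1-D convolution kernel sizes.
#' @param decoder_channels channels of the decoder convolution block.
#' @param dropout decoder dropout rate (training mode only).
#' @param out_points number of decoded time points (6 joint angles each).
#' @param out_window the decoded window in seconds at the end of the clip:
#'   the model estimates the current pose trajectory over the final
#'   `out_window` seconds, using the whole clip as context.
#' @param modalities character subset of `c("image", "emg", "vio")` used by
#'   the model (the modality-ablation switch); VIO alone is not allowed.
#' @param knowledge_sharing if `FALSE`, the shared-space transforms and the
#'   alignment loss are replaced by plain concatenation of the raw encoder
#'   features (the "nKS" ablation arm).
#' @return list of class `"pose_config"`.
#' @export
pose_model_config <- function(image_size = 64, frames_per_clip = 8,
                              width_mult = 0.25, reduction = 8, spatial_kernel = 7,
                              d_model = 64, n_heads = 4, n_layers = 2, ff_dim = 128,
                              emg_downsample = 10, emg_patch = 50,
                              vio_downsample = 1, vio_patch = 20,
                              shared_dim = 64, branch_width = 32,
                              fusion_kernel = 3, decoder_kernel = 3,
                              decoder_channels = 16, dropout = 0.1,
                              out_points = 10, out_window = 1,
                              modalities = c("image", "emg", "vio"),
                              knowledge_sharing = TRUE) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (identical(modalities, "vio"))
    stopf("a VIO-only model is not supported: VIO lacks spatial context for pose estimation")
  if (image_size %% 16 != 0) stopf("image_size must be divisible by 16")
  if (d_model %% n_heads != 0) stopf("d_model must be divisible by n_heads")
  cfg <- list(image_size = image_size, frames_per_clip = frames_per_clip,
              widths = round(c(64, 128, 256, 512) * width_mult),
              reduction = reduction, spatial_kernel = spatial_kernel,
              d_model = d_model, n_heads = n_heads, n_layers = n_layers,
              ff_dim = ff_dim,
              emg_downsample = emg_downsample, emg_patch = emg_patch,
              vio_downsample = vio_downsample, vio_patch = vio_patch,
              shared_dim = shared_dim, branch_width = branch_width,
              fusion_kernel = fusion_kernel, decoder_kernel = decoder_kernel,
              decoder_channels = decoder_channels, dropout = dropout,
              out_points = out_points, out_window = out_window,
              modalities = modalities,
              knowledge_sharing = knowledge_sharing)
  class(cfg) <- "pose_config"
  cfg
}

#' Reduced desk-scale architecture
#'
#' A small preset of [pose_model_config()] used throughout the package's
#' examples and tests: 32-px frames, 3 frames per clip, narrow ResNet stages
#' and a 1-layer transformer. Pass overrides through `...`.
#' @param ... overrides forwarded to [pose_model_config()].
#' @export
tiny_pose_config <- function(...) {
  defaults <- list(image_size = 32, frames_per_clip = 3, width_mult = 0.125,
                   d_model = 32, n_heads = 4, n_layers = 1, ff_dim = 64,
                   emg_downsample = 20, emg_patch = 10,
                   vio_downsample = 4, vio_patch = 10,
                   shared_dim = 32, branch_width = 16,
                   decoder_channels = 8, out_points = 10)
  args <- utils::modifyList(defaults, list(...))
  do.call(pose_model_config, args)
}

# ---- parameter initialization ----------------------------------------------

init_norm <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                              rmean = rep(0, C), rsd = rep(1, C))

init_res_block <- function(cin, cout, cfg) {
  list(conv1 = list(W = init_mat(9 * cin, cout), b = numeric(cout)),
       n1 = init_norm(cout),
       conv2 = list(W = init_mat(9 * cout, cout), b = numeric(cout)),
       n2 = init_norm(cout),
       conv3 = list(W = init_mat(9 * cout, cout), b = numeric(cout)),
       n3 = init_norm(cout),
       sc = list(W = init_mat(cin, cout, gain = 1), b = numeric(cout)),
       nsc = init_norm(cout),
       ca = init_cbam_channel(cout, cfg$reduction),
       sa = init_cbam_spatial(cfg$spatial_kernel))
}

init_image_encoder <- function(cfg) {
  w <- cfg$widths
  cin <- c(3, w[1], w[2], w[3])
  blocks <- lapply(1:4, function(b) init_res_block(cin[b], w[b], cfg))
  names(blocks) <- paste0("block", 1:4)
  blocks
}

init_ln <- function(C) list(gamma = rep(1, C), beta = rep(0, C))

init_transformer_layer <- function(D, ff) {
  list(attn = list(Wq = init_mat(D, D, gain = 1), Wk = init_mat(D, D, gain = 1),
                   Wv = init_mat(D, D, gain = 1), Wo = init_mat(D, D, gain = 1)),
       ln1 = init_ln(D),
       ff = list(W1 = init_mat(D, ff), b1 = numeric(ff),
                 W2 = init_mat(ff, D, gain = 1), b2 = numeric(D)),
       ln2 = init_ln(D))
}

init_seq_encoder <- function(token_dim, cfg) {
  layers <- lapply(seq_len(cfg$n_layers), function(i)
    init_transformer_layer(cfg$d_model, cfg$ff_dim))
  names(layers) <- paste0("layer", seq_len(cfg$n_layers))
  c(list(proj = list(W = init_mat(token_dim, cfg$d_model, gain = 1),
                     b = numeric(cfg$d_model))),
    layers)
}

encoder_out_dim <- function(cfg, modality) {
  if (modality == "image") cfg$widths[4] else cfg$d_model
}

token_dim_of <- function(cfg, modality) {
  if (modality == "emg") cfg$emg_patch * 6 else cfg$vio_patch * 7
}

# ---- residual CBAM block forward/backward ----------------------------------

res_block_fw <- function(x, p, cfg) {
  c1 <- conv2d_fw(x, p$conv1$W, p$conv1$b, 3)
  n1 <- chan_norm_fw(c1$out, p$n1$gamma, p$n1$beta, p$n1$rmean, p$n1$rsd)
  r1 <- relu_fw(n1$out)
  c2 <- conv2d_fw(r1$out, p$conv2$W, p$conv2$b, 3)
  n2 <- chan_norm_fw(c2$out, p$n2$gamma, p$n2$beta, p$n2$rmean, p$n2$rsd)
  r2 <- relu_fw(n2$out)
  c3 <- conv2d_fw(r2$out, p$conv3$W, p$conv3$b, 3)
  n3 <- chan_norm_fw(c3$out, p$n3$gamma, p$n3$beta, p$n3$rmean, p$n3$rsd)
  sc <- conv2d_fw(x, p$sc$W, p$sc$b, 1)
  nsc <- chan_norm_fw(sc$out, p$nsc$gamma, p$nsc$beta, p$nsc$rmean, p$nsc$rsd)
  ra <- relu_fw(n3$out + nsc$out)
  ca <- cbam_channel_fw(ra$out, p$ca)
  sa <- cbam_spatial_fw(ca$out, p$sa, cfg$spatial_kernel)
  mp <- maxpool_fw(sa$out)
  list(out = mp$out,
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    c2 = c2$cache, n2 = n2$cache, r2 = r2$cache,
                    c3 = c3$cache, n3 = n3$cache,
                    sc = sc$cache, nsc = nsc$cache, ra = ra$cache,
                    ca = ca$cache, sa = sa$cache, mp = mp$cache))
}

res_block_bw <- function(dout, cache) {
  d <- maxpool_bw(dout, cache$mp)
  sa <- cbam_spatial_bw(d, cache$sa)
  ca <- cbam_channel_bw(sa$dx, cache$ca)
  dsum <- relu_bw(ca$dx, cache$ra)
  n3 <- chan_norm_bw(dsum, cache$n3)
  c3 <- conv2d_bw(n3$dx, cache$c3)
  nsc <- chan_norm_bw(dsum, cache$nsc)
  sc <- conv2d_bw(nsc$dx, cache$sc)
  dr2 <- relu_bw(c3$dx, cache$r2)
  n2 <- chan_norm_bw(dr2, cache$n2)
  c2 <- conv2d_bw(n2$dx, cache$c2)
  dr1 <- relu_bw(c2$dx, cache$r1)
  n1 <- chan_norm_bw(dr1, cache$n1)
  c1 <- conv2d_bw(n1$dx, cache$c1)
  list(dx = c1$dx + sc$dx,
       grads = list(conv1 = list(W = c1$W, b = c1$b),
                    n1 = n1[c("gamma", "beta", "rmean", "rsd")],
                    conv2 = list(W = c2$W, b = c2$b),
                    n2 = n2[c("gamma", "beta", "rmean", "rsd")],
                    conv3 = list(W = c3$W, b = c3$b),
                    n3 = n3[c("gamma", "beta", "rmean", "rsd")],
                    sc = list(W = sc$W, b = sc$b),
                    nsc = nsc[c("gamma", "beta", "rmean", "rsd")],
                    ca = list(W1 = ca$W1, b1 = ca$b1, W2 = ca$W2, b2 = ca$b2),
                    sa = list(W = sa$W, b = sa$b)))
}

# ---- image encoder ---------------------------------------------------------

# Uniformly pick frame indices, convert to numeric arrays.
clip_frames <- function(stream, n_frames) {
  Ti <- dim(stream$samples)[4]
  idx <- unique(round(seq(1, Ti, length.out = n_frames)))
  lapply(idx, function(i) frame_as_array(stream, i))
}

image_encoder_fw <- function(frames, p, cfg) {
  Fn <- length(frames)
  per <- vector("list", Fn)
  feat <- numeric(cfg$widths[4])
  for (f in seq_len(Fn)) {
    x <- frames[[f]]
    caches <- vector("list", 4)
    for (b in 1:4) {
      r <- res_block_fw(x, p[[b]], cfg)
      x <- r$out
      caches[[b]] <- r$cache
    }
    g <- gap_fw(x)
    per[[f]] <- list(blocks = caches, gap = g$cache)
    feat <- feat + g$out / Fn
  }
  list(out = feat, cache = list(per = per, Fn = Fn, p = p, cfg = cfg))
}

image_encoder_bw <- function(dfeat, cache) {
  p <- cache$p
  grads <- ptree_zeros_like(p)
  for (f in seq_len(cache$Fn)) {
    pc <- cache$per[[f]]
    d <- gap_bw(dfeat / cache$Fn, pc$gap)
    for (b in 4:1) {
      r <- res_block_bw(d, pc$blocks[[b]])
      d <- r$dx
      grads[[b]] <- ptree_add(grads[[b]], r$grads)
    }
  }
  grads
}

# ---- sequence encoder ------------------------------------------------------

# Downsample and patch a T x D stream into an L x (patch*D) token matrix.
# With `rectify = TRUE` (sEMG) the downsampling computes the average rectified
# value over each window -- the standard surface-EMG envelope estimate --
# instead of decimating, which would alias the 20-450 Hz interference pattern.
patchify <- function(samples, downsample, patch, rectify = FALSE) {
  if (rectify && downsample > 1) {
    Tn <- nrow(samples) %/% downsample
    idx <- rep(seq_len(Tn), each = downsample)
    x <- apply(abs(samples[seq_len(Tn * downsample), , drop = FALSE]), 2,
               function(col) tapply(col, idx, mean))
  } else {
    x <- samples[seq(1, nrow(samples), by = downsample), , drop = FALSE]
  }
  L <- nrow(x) %/% patch
  if (L < 1) stopf("sequence too short to form one token (need %d samples)", patch)
  x <- x[seq_len(L * patch), , drop = FALSE]
  tok <- matrix(0, L, patch * ncol(x))
  for (l in seq_len(L)) {
    tok[l, ] <- as.numeric(x[((l - 1) * patch + 1):(l * patch), ])
  }
  tok
}

seq_encoder_fw <- function(tokens, p, cfg, use_pe = TRUE) {
  pr <- dense_fw(tokens, p$proj$W, p$proj$b)
  x <- pr$out
  if (use_pe) x <- x + positional_encoding(nrow(x), ncol(x))
  layers <- vector("list", cfg$n_layers)
  for (li in seq_len(cfg$n_layers)) {
    lp <- p[[paste0("layer", li)]]
    at <- mha_fw(x, lp$attn, cfg$n_heads)
    u <- x + at$out
    l1 <- layernorm_fw(u, lp$ln1$gamma, lp$ln1$beta)
    h <- pmax(l1$out %*% lp$ff$W1 + matrix(lp$ff$b1, nrow(l1$out), length(lp$ff$b1), byrow = TRUE), 0)
    fo <- h %*% lp$ff$W2 + matrix(lp$ff$b2, nrow(h), length(lp$ff$b2), byrow = TRUE)
    l2 <- layernorm_fw(l1$out + fo, lp$ln2$gamma, lp$ln2$beta)
    layers[[li]] <- list(at = at$cache, l1 = l1$cache, l2 = l2$cache,
                         h = h, l1out = l1$out, lp = lp)
    x <- l2$out
  }
  g <- gap_fw(x)
  list(out = g$out, cache = list(proj = pr$cache, layers = layers, gap = g$cache, cfg = cfg))
}

seq_encoder_bw <- function(dfeat, cache) {
  cfg <- cache$cfg
  d <- gap_bw(dfeat, cache$gap)
  grads <- list()
  for (li in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[li]]
    lp <- lc$lp
    l2 <- layernorm_bw(d, lc$l2)
    dfo <- l2$dx
    dW2 <- crossprod(lc$h, dfo)
    db2 <- colSums(dfo)
    dh <- (dfo %*% t(lp$ff$W2)) * (lc$h > 0)
    dW1 <- crossprod(lc$l1out, dh)
    db1 <- colSums(dh)
    dl1 <- dfo + dh %*% t(lp$ff$W1)
    l1 <- layernorm_bw(dl1, lc$l1)
    du <- l1$dx
    at <- mha_bw(du, lc$at)
    d <- du + at$dx
    grads[[paste0("layer", li)]] <- list(
      attn = list(Wq = at$Wq, Wk = at$Wk, Wv = at$Wv, Wo = at$Wo),
      ln1 = list(gamma = l1$gamma, beta = l1$beta),
      ff = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
      ln2 = list(gamma = l2$gamma, beta = l2$beta))
  }
  pr <- dense_bw(d, cache$proj)
  c(list(proj = list(W = pr$W, b = pr$b)), grads[paste0("layer", seq_len(cfg$n_layers))])
}

# ---- public encoder interface ---------------------------------------------

#' Encode an image stream into a clip-level feature vector
#'
#' Uniformly subsamples `frames_per_clip` frames, passes each through the
#' CBAM-ResNet12 backbone (four residual blocks, each three convolutions, a
#' channel+spatial attention module and a 2x2 max-pool), global-average-pools
#' the last stage and averages over frames. Deterministic in evaluation mode.
#'
#' @param stream an image `modality_stream` (as inside a `multimodal_clip`).
#' @param model a `pose_model` (see [init_pose_model()]).
#' @return numeric feature vector of length `widths[4]`.
#' @export
encode_image <- function(stream, model) {
  stopifnot(inherits(model, "pose_model"))
  if (stream$modality != "image") stopf("encode_image expects an image stream, got '%s'", stream$modality)
  cfg <- model$config
  if (dim(stream$samples)[1] != cfg$image_size)
    stopf("stream is %dpx but the model expects %dpx", dim(stream$samples)[1], cfg$image_size)
  image_encoder_fw(clip_frames(stream, cfg$frames_per_clip),
                   model$params$image, cfg)$out
}

#' Encode an sEMG or VIO stream into a clip-level feature vector
#'
#' Downsamples and patches the stream into tokens, adds sinusoidal positional
#' encodings, applies the transformer encoder and mean-pools the output
#' tokens. Deterministic in evaluation mode.
#'
#' @param stream an `emg` or `vio` `modality_stream`.
#' @param model a `pose_model`.
#' @param positional if `FALSE`, positional encodings are omitted (the
#'   mean-pooled output is then permutation invariant over tokens).
#' @return numeric feature vector of length `d_model`.
#' @export
encode_sequence <- function(stream, model, positional = TRUE) {
  stopifnot(inherits(model, "pose_model"))
  if (!stream$modality %in% c("emg", "vio"))
    stopf("encode_sequence expects an emg or vio stream, got '%s'", stream$modality)
  if (nrow(stream$samples) == 0) stopf("empty sequence")
  cfg <- model$config
  ds <- if (stream$modality == "emg") cfg$emg_downsample else cfg$vio_downsample
  patch <- if (stream$modality == "emg") cfg$emg_patch else cfg$vio_patch
  tokens <- patchify(stream$samples, ds, patch, rectify = stream$modality == "emg")
  seq_encoder_fw(tokens, model$params[[stream$modality]], cfg, use_pe = positional)$out
}
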