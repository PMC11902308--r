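# Knowledge-sharing feature alignment, three-branch fusion, joint-angle
# decoder, and the two-stage pre-training routine.
#
# The pose model maps a 10-s multimodal clip to a 6-joint angle trajectory:
#   r_m = encoder_m(I_m)                  per-modality clip features
#   rt_m = f_m(r_m)                       shared-space transform (affine)
#   L_KS = sum_{k != t} m_k m_t ||rt_k - rt_t||   pairwise alignment loss
#   k = fusion(rt_i, rt_e, rt_v)          three conv branches, GAP, concat
#   yhat = decoder(k)                     conv block + linear head
#   L_PE = mean over samples of (1/6) sum_j (y - yhat)^2

MODALITY_ORDER <- c("image", "emg", "vio")

#' Initialize an untrained pose-estimation model
#'
#' Draws all encoder, transform, fusion and decoder parameters for the given
#' architecture. Deterministic in `(config, seed)`.
#'
#' @param config a [pose_model_config()].
#' @param seed integer RNG seed for the parameter draws.
#' @return list of class `"pose_model"` with elements `config`, `params`,
#'   `log` (NULL until trained).
#' @export
init_pose_model <- function(config = pose_model_config(), seed = 0) {
  stopifnot(inherits(config, "pose_config"))
  local_seed(seed, {
    params <- list()
    for (m in intersect(MODALITY_ORDER, config$modalities)) {
      params[[m]] <- if (m == "image") init_image_encoder(config)
                     else init_seq_encoder(token_dim_of(config, m), config)
    }
    if (config$knowledge_sharing) {
      params$transform <- list()
      params$norms <- list()
      for (m in intersect(MODALITY_ORDER, config$modalities)) {
        din <- encoder_out_dim(config, m)
        params$transform[[m]] <- list(W = init_mat(din, config$shared_dim, gain = 1),
                                      b = numeric(config$shared_dim))
        params$norms[[m]] <- 0  # log-scale; normalizer = exp(0) = 1
      }
    }
    bw <- config$branch_width
    fin <- fusion_in_channels(config)
    params$fusion <- list()
    for (b in 1:3) {
      blocks <- list()
      for (j in seq_len(b)) {
        cin <- if (j == 1) fin else bw
        blocks[[paste0("block", j)]] <- list(
          conv = list(W = init_mat(config$fusion_kernel * cin, bw), b = numeric(bw)),
          norm = init_norm(bw))
      }
      params$fusion[[paste0("branch", b)]] <- blocks
    }
    klen <- 3 * bw
    dc <- config$decoder_channels
    params$decoder <- list(
      conv = list(W = init_mat(config$decoder_kernel, dc), b = numeric(dc)),
      norm = init_norm(dc),
      # frozen standardization: head inputs per element, targets per joint
      stand = list(fmean = numeric(klen * dc), fsd = rep(1, klen * dc),
                   center = numeric(6), scale = rep(1, 6)),
      head = list(W = init_mat(klen * dc, config$out_points * 6, gain = 1),
                  b = numeric(config$out_points * 6)))
    structure(list(config = config, params = params, log = NULL),
              class = "pose_model")
  })
}

# Fusion operates on a sequence with one position per modality and the
# feature dimension as channels; without knowledge sharing the raw encoder
# features are stacked with zero padding up to the widest modality.
fusion_in_channels <- function(cfg) {
  mods <- intersect(MODALITY_ORDER, cfg$modalities)
  if (cfg$knowledge_sharing) cfg$shared_dim
  else max(vapply(mods, function(m) encoder_out_dim(cfg, m), numeric(1)))
}

stack_features <- function(feats, cfg) {
  mods <- intersect(MODALITY_ORDER, names(feats))
  C <- fusion_in_channels(cfg)
  x <- matrix(0, length(mods), C)
  for (i in seq_along(mods)) x[i, seq_along(feats[[mods[i]]])] <- feats[[mods[i]]]
  x
}

# ---- knowledge-sharing transform and loss ----------------------------------

#' Transform an encoder feature into the shared space
#'
#' Applies the modality-specific affine map `rt_m = W r_m + b` taking the
#' encoder feature to the common dimension D. With `W` the identity and
#' `b = 0`, the output equals the input.
#'
#' @param r numeric feature vector.
#' @param model a `pose_model` with knowledge sharing enabled.
#' @param modality one of the model's modalities.
#' @return numeric vector of length `shared_dim`.
#' @export
transform_feature <- function(r, model, modality) {
  stopifnot(inherits(model, "pose_model"))
  tr <- model$params$transform[[modality]]
  if (is.null(tr)) stopf("no shared-space transform for modality '%s'", modality)
  as.numeric(dense_fw(r, tr$W, tr$b)$out)
}

#' Pairwise knowledge-sharing alignment loss
#'
#' `L_KS = sum over unordered modality pairs (k, t) of m_k m_t ||rt_k - rt_t||_2`,
#' where each modality's normalizer `m` is positive (exp-parameterized).
#' Symmetric in the modality order, non-negative, and zero iff all supplied
#' features coincide.
#'
#' @param features named list of equal-length numeric vectors (one per
#'   modality).
#' @param normalizers named numeric vector/list of log-normalizers (one per
#'   modality, defaults to 0, i.e. unit normalizers).
#' @return non-negative scalar.
#' @export
knowledge_sharing_loss <- function(features, normalizers = NULL) {
  mods <- names(features)
  if (length(mods) < 2) {
    warning("knowledge_sharing_loss needs >= 2 modalities; returning 0")
    return(0)
  }
  d <- lengths(features)
  if (length(unique(d)) != 1) stopf("feature dimensions differ: %s", paste(d, collapse = ", "))
  if (is.null(normalizers)) normalizers <- setNames(rep(0, length(mods)), mods)
  total <- 0
  for (a in seq_along(mods)) {
    for (b in seq_along(mods)) {
      if (a < b) {
        w <- exp(normalizers[[mods[a]]] + normalizers[[mods[b]]])
        total <- total + w * sqrt(sum((features[[a]] - features[[b]])^2))
      }
    }
  }
  total
}

# Forward + gradients of L_KS wrt each feature and each log-normalizer.
ks_loss_grad <- function(rt, norms) {
  mods <- names(rt)
  loss <- 0
  dfeat <- lapply(rt, function(v) v * 0)
  dnorm <- setNames(as.list(rep(0, length(mods))), mods)
  eps <- 1e-12
  for (a in seq_along(mods)) {
    for (b in seq_along(mods)) {
      if (a < b) {
        w <- exp(norms[[mods[a]]] + norms[[mods[b]]])
        diff <- rt[[a]] - rt[[b]]
        d2 <- sqrt(sum(diff^2))
        loss <- loss + w * d2
        g <- if (d2 > eps) w * diff / d2 else diff * 0
        dfeat[[a]] <- dfeat[[a]] + g
        dfeat[[b]] <- dfeat[[b]] - g
        dnorm[[mods[a]]] <- dnorm[[mods[a]]] + w * d2
        dnorm[[mods[b]]] <- dnorm[[mods[b]]] + w * d2
      }
    }
  }
  list(loss = loss, dfeat = dfeat, dnorm = dnorm)
}

# ---- fusion ----------------------------------------------------------------

fusion_fw <- function(x0, p, cfg) {
  branches <- vector("list", 3)
  k <- numeric(0)
  for (b in 1:3) {
    x <- x0
    blocks <- vector("list", b)
    for (j in seq_len(b)) {
      bp <- p[[paste0("branch", b)]][[paste0("block", j)]]
      cv <- conv1d_fw(x, bp$conv$W, bp$conv$b, cfg$fusion_kernel)
      nm <- chan_norm_fw(cv$out, bp$norm$gamma, bp$norm$beta, bp$norm$rmean, bp$norm$rsd)
      lr <- leaky_relu_fw(nm$out, 0.01)
      blocks[[j]] <- list(cv = cv$cache, nm = nm$cache, lr = lr$cache)
      x <- lr$out
    }
    g <- gap_fw(x)
    branches[[b]] <- list(blocks = blocks, gap = g$cache)
    k <- c(k, g$out)
  }
  list(out = k, cache = list(branches = branches, cfg = cfg, dims0 = dim(x0)))
}

fusion_bw <- function(dk, cache) {
  cfg <- cache$cfg
  bw <- cfg$branch_width
  grads <- list()
  dx0 <- matrix(0, cache$dims0[1], cache$dims0[2])
  for (b in 1:3) {
    dg <- dk[((b - 1) * bw + 1):(b * bw)]
    d <- gap_bw(dg, cache$branches[[b]]$gap)
    bg <- list()
    for (j in rev(seq_len(b))) {
      bc <- cache$branches[[b]]$blocks[[j]]
      d <- leaky_relu_bw(d, bc$lr)
      nm <- chan_norm_bw(d, bc$nm)
      cv <- conv1d_bw(nm$dx, bc$cv)
      bg[[paste0("block", j)]] <- list(conv = list(W = cv$W, b = cv$b),
                                       norm = nm[c("gamma", "beta", "rmean", "rsd")])
      d <- cv$dx
    }
    grads[[paste0("branch", b)]] <- bg[paste0("block", seq_len(b))]
    dx0 <- dx0 + d
  }
  list(dmat = dx0, grads = grads)
}

#' Fuse aligned modality features
#'
#' Stacks the per-modality (shared-space) features into one sequence-shaped
#' input (one position per modality, feature channels) and passes it through
#' three convolutional branches of 1, 2 and 3 blocks (1-D convolution,
#' frozen-statistics normalization, leaky ReLU). Each branch output is
#' globally average-pooled over positions; the three pooled vectors are
#' concatenated into the fused feature `k`.
#'
#' @param features named list of numeric vectors, in any order; stacked in
#'   the fixed order image, emg, vio.
#' @param model a `pose_model`.
#' @return numeric vector of length `3 * branch_width`.
#' @export
fuse <- function(features, model) {
  stopifnot(inherits(model, "pose_model"))
  if (length(features) == 0) stopf("empty feature map")
  if (max(lengths(features)) > fusion_in_channels(model$config))
    stopf("feature dimension %d exceeds the fusion input width (%d)",
          max(lengths(features)), fusion_in_channels(model$config))
  fusion_fw(stack_features(features, model$config),
            model$params$fusion, model$config)$out
}

# ---- decoder ---------------------------------------------------------------

decoder_fw <- function(k, p, cfg, training = FALSE) {
  kseq <- cbind(k)
  cv <- conv1d_fw(kseq, p$conv$W, p$conv$b, cfg$decoder_kernel)
  nm <- chan_norm_fw(cv$out, p$norm$gamma, p$norm$beta, p$norm$rmean, p$norm$rsd)
  rl <- relu_fw(nm$out)
  fz <- (as.numeric(rl$out) - p$stand$fmean) / p$stand$fsd
  fz <- pmin(pmax(fz, -50), 50)
  dp <- dropout_fw(fz, cfg$dropout, training)
  hd <- dense_fw(matrix(dp$out, 1), p$head$W, p$head$b)
  z <- matrix(hd$out, cfg$out_points, 6)
  out <- z * rep(p$stand$scale, each = cfg$out_points) +
    rep(p$stand$center, each = cfg$out_points)
  list(out = out,
       cache = list(cv = cv$cache, nm = nm$cache, rl = rl$cache, dp = dp$cache,
                    hd = hd$cache, fdim = dim(rl$out), stand = p$stand,
                    z = z, op = cfg$out_points))
}

decoder_bw <- function(dout, cache) {
  st <- cache$stand
  dz <- dout * rep(st$scale, each = cache$op)
  hd <- dense_bw(matrix(as.numeric(dz), 1), cache$hd)
  d <- dropout_bw(as.numeric(hd$dx), cache$dp)
  d <- matrix(d / st$fsd, cache$fdim[1], cache$fdim[2])
  d <- relu_bw(d, cache$rl)
  nm <- chan_norm_bw(d, cache$nm)
  cv <- conv1d_bw(nm$dx, cache$cv)
  zst <- function(v) numeric(length(v))
  list(dk = as.numeric(cv$dx),
       grads = list(conv = list(W = cv$W, b = cv$b),
                    norm = nm[c("gamma", "beta", "rmean", "rsd")],
                    stand = list(fmean = zst(st$fmean), fsd = zst(st$fsd),
                                 center = unname(colSums(dout)),
                                 scale = unname(colSums(dout * cache$z))),
                    head = list(W = hd$W, b = hd$b)))
}

#' Decode a fused feature into a joint-angle trajectory
#'
#' Convolution + normalization + ReLU (+ dropout during training) over the
#' fused feature, then a fully connected regression head. Rows are time
#' points over the 10-s clip; columns the six joint angles in degrees
#' (hip/knee/ankle, left then right). Deterministic in evaluation mode.
#'
#' @param k fused feature vector from [fuse()].
#' @param model a `pose_model`.
#' @return `out_points x 6` numeric matrix of angles in degrees.
#' @export
decode <- function(k, model) {
  stopifnot(inherits(model, "pose_model"))
  if (length(k) != 3 * model$config$branch_width)
    stopf("fused feature length %d does not match the decoder (%d)",
          length(k), 3 * model$config$branch_width)
  out <- decoder_fw(k, model$params$decoder, model$config, training = FALSE)$out
  colnames(out) <- ANGLE_NAMES
  out
}

# ---- losses ----------------------------------------------------------------

#' Mean-squared pose-estimation loss
#'
#' Per time sample, the mean squared error over the `N = 6` joint angles;
#' averaged over samples (optionally weighted, e.g. by a stance/swing mask).
#' `sqrt(pose_loss(pred, truth))` equals the pooled RMSE over the same values.
#'
#' @param pred,truth numeric matrices `n x 6` (degrees).
#' @param weights optional non-negative per-sample weights.
#' @return non-negative scalar.
#' @export
pose_loss <- function(pred, truth, weights = NULL) {
  if (!all(dim(pred) == dim(truth))) stopf("pred and truth shapes differ")
  per_sample <- rowMeans((pred - truth)^2)
  if (is.null(weights)) return(mean(per_sample))
  if (length(weights) != nrow(pred)) stopf("weights length must equal the sample count")
  if (sum(weights) == 0) return(0)
  sum(weights * per_sample) / sum(weights)
}

pose_loss_grad <- function(pred, truth, weights = NULL) {
  n <- nrow(pred)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sum(weights)
  if (sw == 0) return(pred * 0)
  2 * (pred - truth) * weights / (6 * sw)
}

# Ground-truth decoder target for one clip: the angle trajectory over the
# clip's final `out_window` seconds (the estimation instant; the rest of the
# clip is context), sampled at `out_points` points. Also returns the matching
# stance/swing labels.
clip_target <- function(clip, cfg) {
  ang <- clip$angles$samples
  n <- nrow(ang)
  n_win <- max(cfg$out_points, round(cfg$out_window * clip$angles$rate))
  idx <- round(seq(n - n_win + 1, n, length.out = cfg$out_points))
  list(y = ang[idx, , drop = FALSE], phase = clip$phase[idx])
}

phase_weights <- function(target, phase = NULL) {
  if (is.null(phase)) rep(1, nrow(target$y)) else as.numeric(target$phase == phase)
}

# ---- full model forward / backward -----------------------------------------

model_forward <- function(params, cfg, clip, training = FALSE) {
  mods <- intersect(MODALITY_ORDER, cfg$modalities)
  r <- list(); enc_cache <- list()
  for (m in mods) {
    if (m == "image") {
      fr <- clip_frames(clip$streams$image, cfg$frames_per_clip)
      e <- image_encoder_fw(fr, params$image, cfg)
    } else {
      ds <- if (m == "emg") cfg$emg_downsample else cfg$vio_downsample
      patch <- if (m == "emg") cfg$emg_patch else cfg$vio_patch
      tok <- patchify(clip$streams[[m]]$samples, ds, patch, rectify = m == "emg")
      e <- seq_encoder_fw(tok, params[[m]], cfg)
    }
    r[[m]] <- e$out
    enc_cache[[m]] <- e$cache
  }
  tr_cache <- NULL; ks <- NULL
  if (cfg$knowledge_sharing) {
    rt <- list(); tr_cache <- list()
    for (m in mods) {
      tc <- dense_fw(r[[m]], params$transform[[m]]$W, params$transform[[m]]$b)
      rt[[m]] <- as.numeric(tc$out)
      tr_cache[[m]] <- tc$cache
    }
    ks <- ks_loss_grad(rt, params$norms)
  } else {
    rt <- r
  }
  fu <- fusion_fw(stack_features(rt, cfg), params$fusion, cfg)
  dec <- decoder_fw(fu$out, params$decoder, cfg, training)
  list(pred = dec$out, r = r, rt = rt, k = fu$out,
       ks_loss = if (is.null(ks)) 0 else ks$loss, ks = ks,
       cache = list(enc = enc_cache, tr = tr_cache, fu = fu$cache, dec = dec$cache,
                    mods = mods, cfg = cfg))
}

# dpred: gradient of the objective wrt predictions; ks_scale: coefficient of
# L_KS in the objective (0 to skip). Returns a gradient tree matching params.
model_backward <- function(fw, params, dpred, ks_scale = 0) {
  cfg <- fw$cache$cfg
  mods <- fw$cache$mods
  grads <- list()
  dec <- decoder_bw(dpred, fw$cache$dec)
  grads$decoder <- dec$grads
  fu <- fusion_bw(dec$dk, fw$cache$fu)
  grads$fusion <- fu$grads
  drt <- list()
  for (i in seq_along(mods)) {
    drt[[mods[i]]] <- fu$dmat[i, seq_along(fw$rt[[mods[i]]])]
  }
  if (cfg$knowledge_sharing) {
    grads$transform <- list(); grads$norms <- list()
    if (ks_scale != 0) {
      for (m in mods) {
        drt[[m]] <- drt[[m]] + ks_scale * fw$ks$dfeat[[m]]
        grads$norms[[m]] <- ks_scale * fw$ks$dnorm[[m]]
      }
    } else {
      for (m in mods) grads$norms[[m]] <- 0
    }
    dr <- list()
    for (m in mods) {
      tb <- dense_bw(rbind(drt[[m]]), fw$cache$tr[[m]])
      grads$transform[[m]] <- list(W = tb$W, b = tb$b)
      dr[[m]] <- as.numeric(tb$dx)
    }
  } else {
    dr <- drt
  }
  for (m in mods) {
    grads[[m]] <- if (m == "image") image_encoder_bw(dr[[m]], fw$cache$enc[[m]])
                  else seq_encoder_bw(dr[[m]], fw$cache$enc[[m]])
  }
  grads[names(params)]
}

# ---- running normalization statistics --------------------------------------
# Every frozen-statistics normalization layer and the decoder's head-input
# standardization keep running per-channel (or per-element) moments. During
# pre-training stage A each clip's batch statistics update the running values
# (exponential moving average with a short cumulative warm-up); afterwards the
# statistics are frozen, so evaluation, meta-training and adaptation all see
# constant normalizers. Gradients treat the statistics as constants.

ema <- function(old, new, mom) (1 - mom) * old + mom * new

update_norm_leaf <- function(prm, cache, mom, eps = 1e-3) {
  N <- nrow(cache$xhat)
  raw <- cache$xhat * rep(prm$rsd, each = N) + rep(prm$rmean, each = N)
  mu <- colMeans(raw)
  v <- pmax(colMeans(raw^2) - mu^2, 0)
  prm$rmean <- ema(prm$rmean, mu, mom)
  prm$rsd <- sqrt(ema(prm$rsd^2, v + eps, mom))
  prm
}

# One update of all running statistics from a finished forward pass.
update_norm_state <- function(params, fw, mom) {
  mods <- fw$cache$mods
  if ("image" %in% mods) {
    for (f in seq_along(fw$cache$enc$image$per)) {
      pc <- fw$cache$enc$image$per[[f]]
      for (b in 1:4) {
        for (nm in c("n1", "n2", "n3", "nsc")) {
          params$image[[b]][[nm]] <-
            update_norm_leaf(params$image[[b]][[nm]], pc$blocks[[b]][[nm]], mom)
        }
      }
    }
  }
  for (b in 1:3) {
    for (j in seq_len(b)) {
      params$fusion[[b]][[j]]$norm <-
        update_norm_leaf(params$fusion[[b]][[j]]$norm,
                         fw$cache$fu$branches[[b]]$blocks[[j]]$nm, mom)
    }
  }
  params$decoder$norm <- update_norm_leaf(params$decoder$norm, fw$cache$dec$nm, mom)
  # the head input keeps its natural scale (stand$fmean = 0, fsd = 1): the
  # ridge fit of the head shrinks weights on low-variance feature directions,
  # which keeps predictions robust to small upstream parameter perturbations
  # during modulation-based adaptation
  params
}

# Warm up all running statistics before optimization: several sweeps over a
# few calibration clips with cumulative (1/i) averaging per sweep. Successive
# sweeps propagate the normalization down the layer stack (statistics of a
# deep layer are only meaningful once the layers above it are normalized).
warmup_norms <- function(params, cfg, clips, passes = 5) {
  for (p in seq_len(passes)) {
    for (i in seq_along(clips)) {
      fw <- model_forward(params, cfg, clips[[i]], training = FALSE)
      params <- update_norm_state(params, fw, mom = 1 / i)
    }
  }
  params
}

# Per-joint standardization of the regression targets (degrees), set once
# from the training targets before optimization.
target_standardization <- function(params, targets) {
  Y <- do.call(rbind, lapply(targets, `[[`, "y"))
  params$decoder$stand$center <- unname(colMeans(Y))
  params$decoder$stand$scale <- unname(pmax(apply(Y, 2, stats::sd), 1e-3))
  params
}

# ---- pre-training ----------------------------------------------------------

flatten1 <- function(x) do.call(c, x)

# Clip-level feature vector entering the decoder head (standardized).
head_inputs <- function(params, cfg, clips) {
  st <- params$decoder$stand
  t(vapply(clips, function(cl)
    as.numeric(model_forward(params, cfg, cl, training = FALSE)$cache$dec$hd$x),
    numeric(length(st$fmean))))
}

#' Pre-train the pose-estimation model on a cohort
#'
#' Two-stage schedule honoring a separately trained knowledge-transfer module:
#' stage A trains the whole network end to end on `L_KS + lambda_pe * L_PE`
#' (the pose term prevents the alignment loss's all-constant collapse), with
#' Adam, global gradient-norm clipping, and running normalization statistics
#' tracked through the first epoch then frozen. Stage B freezes encoders,
#' transforms and normalizers: optional stochastic fine-tuning of fusion +
#' decoder on `L_PE`, followed by a closed-form ridge fit of the linear
#' regression head (the head is linear in its standardized inputs, so its
#' optimum is a penalized least-squares solution; the penalty is selected on
#' the validation split).
#'
#' When a cohort (or list of trials) is supplied, the train/validation split
#' is at trial level and each training epoch re-cuts the training trials at a
#' random window offset (window jittering), so successive epochs see fresh
#' gait phases; validation always uses the canonical non-overlapping
#' segmentation. A plain clip list disables augmentation and splits at clip
#' level. Fully reproducible from `(cohort, config, seed)`.
#'
#' @param cohort a [make_cohort()] result, a list of `gait_trial`s, or a list
#'   of `multimodal_clip`s.
#' @param config a [pose_model_config()].
#' @param epochs integer vector `c(stage_A, stage_B_sgd)`.
#' @param lr Adam learning rate.
#' @param lambda_pe weight of the pose loss in the stage-A objective.
#' @param clip_norm global gradient-norm clip.
#' @param val_fraction fraction of trials (or clips) held out for the
#'   per-epoch validation RMSE and the ridge-penalty selection (0 disables).
#' @param ridge_lambdas candidate L2 penalties for the head fit.
#' @param augment_rounds extra randomly-offset segmentations of the training
#'   trials added to the ridge design (ignored for clip-list input).
#' @param seed RNG seed covering initialization, shuffling, window offsets
#'   and dropout.
#' @param verbose print per-epoch losses.
#' @return a fitted `"pose_model"`; `$log` holds the per-epoch training log
#'   (stage, L_PE, L_KS, val_RMSE_deg).
#' @export
pretrain <- function(cohort, config = pose_model_config(), epochs = c(8, 0),
                     lr = 1e-3, lambda_pe = 1, clip_norm = 5,
                     val_fraction = 0.2, ridge_lambdas = c(1, 3, 10, 30, 100),
                     augment_rounds = 2, seed = 0, verbose = FALSE) {
  trials <- NULL
  if (inherits(cohort, "gait_cohort")) {
    trials <- cohort_trials(cohort)
  } else if (length(cohort) > 0 && inherits(cohort[[1]], "gait_trial")) {
    trials <- cohort
  }
  if (length(cohort) == 0) stopf("empty dataset")
  model <- init_pose_model(config, seed)
  local_seed(seed + 1L, {
    if (!is.null(trials)) {
      nt <- length(trials)
      n_val <- if (val_fraction > 0 && nt > 1)
        max(1L, floor(val_fraction * nt)) else 0L
      val_tr <- if (n_val > 0) sample.int(nt, n_val) else integer(0)
      train_clips <- flatten1(lapply(trials[setdiff(seq_len(nt), val_tr)],
                                     segment_clips))
      val_clips <- if (n_val > 0) flatten1(lapply(trials[val_tr], segment_clips))
                   else list()
      epoch_clips <- function() {
        flatten1(lapply(trials[setdiff(seq_len(nt), val_tr)], function(tr)
          segment_clips(tr, offset = runif(1, 0, min(10, tr$duration_s / 2)))))
      }
      ridge_rounds <- augment_rounds
    } else {
      clips <- cohort
      n <- length(clips)
      n_val <- if (val_fraction > 0 && n > 1) floor(val_fraction * n) else 0L
      val_i <- if (n_val > 0) sample.int(n, n_val) else integer(0)
      train_clips <- clips[setdiff(seq_len(n), val_i)]
      val_clips <- clips[val_i]
      epoch_clips <- function() train_clips
      ridge_rounds <- 0L
    }
    train_targets <- lapply(train_clips, clip_target, cfg = config)
    val_targets <- lapply(val_clips, clip_target, cfg = config)
    model$params <- target_standardization(model$params, train_targets)
    calib <- train_clips[unique(round(seq(1, length(train_clips),
                                          length.out = min(8, length(train_clips)))))]
    model$params <- warmup_norms(model$params, config, calib)
    params <- model$params
    norm_t <- 50L   # continue from the warm-up with small EMA updates
    log <- NULL

    val_rmse_now <- function(params) {
      if (length(val_clips) == 0) return(NA_real_)
      se <- 0; m <- 0
      for (i in seq_along(val_clips)) {
        fwv <- model_forward(params, config, val_clips[[i]], training = FALSE)
        se <- se + sum((fwv$pred - val_targets[[i]]$y)^2)
        m <- m + length(val_targets[[i]]$y)
      }
      sqrt(se / m)
    }

    # ---- stage A: end-to-end, window-jittered ----
    if (epochs[1] > 0) {
      opt <- adam_init(params, lr = lr)
      for (ep in seq_len(epochs[1])) {
        eclips <- epoch_clips()
        etargets <- lapply(eclips, clip_target, cfg = config)
        ord <- sample(seq_along(eclips))
        pe_sum <- 0; ks_sum <- 0
        for (i in ord) {
          fw <- model_forward(params, config, eclips[[i]], training = TRUE)
          if (ep == 1) {
            # track normalization statistics through the first epoch only,
            # then freeze them for a stationary objective
            norm_t <- norm_t + 1L
            params <- update_norm_state(params, fw, mom = max(1 / norm_t, 0.02))
          }
          y <- etargets[[i]]$y
          pe <- pose_loss(fw$pred, y)
          pe_sum <- pe_sum + pe; ks_sum <- ks_sum + fw$ks_loss
          if (!is.finite(pe) || !is.finite(fw$ks_loss))
            stopf("training diverged (non-finite loss) at stage A epoch %d", ep)
          g <- model_backward(fw, params, pose_loss_grad(fw$pred, y) * lambda_pe,
                              ks_scale = 1)
          # the output calibration constants stay frozen during pretraining
          g$decoder$stand <- ptree_zeros_like(g$decoder$stand)
          g <- clip_global_norm(g, clip_norm)
          st <- adam_step(opt, params, g)
          params <- st$params
          opt <- st$opt
        }
        vr <- val_rmse_now(params)
        log <- rbind(log, data.frame(stage = "A", epoch = ep,
                                     L_PE = pe_sum / length(ord),
                                     L_KS = ks_sum / length(ord),
                                     val_RMSE_deg = vr))
        if (verbose)
          message(sprintf("stage A epoch %d: L_PE %.3f L_KS %.3f val RMSE %.2f",
                          ep, pe_sum / length(ord), ks_sum / length(ord), vr))
      }
    }

    # ---- stage B: frozen encoders/transforms ----
    # The aligned features of the canonical training clips are fixed now, so
    # they are cached and only the fusion + decoder stack iterates.
    rt_of <- function(cl) {
      fw <- model_forward(params, config, cl, training = FALSE)
      stack_features(fw$rt, config)
    }
    if (length(epochs) > 1 && epochs[2] > 0) {
      rt_cache <- lapply(train_clips, rt_of)
      trainable <- intersect(c("fusion", "decoder"), names(params))
      opt <- adam_init(params[trainable], lr = lr)
      for (ep in seq_len(epochs[2])) {
        ord <- sample(seq_along(train_clips))
        pe_sum <- 0
        for (i in ord) {
          fu <- fusion_fw(rt_cache[[i]], params$fusion, config)
          dec <- decoder_fw(fu$out, params$decoder, config, training = TRUE)
          y <- train_targets[[i]]$y
          pe <- pose_loss(dec$out, y)
          pe_sum <- pe_sum + pe
          if (!is.finite(pe))
            stopf("training diverged (non-finite loss) at stage B epoch %d", ep)
          dpred <- pose_loss_grad(dec$out, y)
          db <- decoder_bw(dpred, dec$cache)
          db$grads$stand <- ptree_zeros_like(db$grads$stand)
          fb <- fusion_bw(db$dk, fu$cache)
          g <- clip_global_norm(list(fusion = fb$grads, decoder = db$grads)[trainable],
                                clip_norm)
          st <- adam_step(opt, params[trainable], g)
          params[trainable] <- st$params
          opt <- st$opt
        }
        vr <- val_rmse_now(params)
        log <- rbind(log, data.frame(stage = "B", epoch = ep,
                                     L_PE = pe_sum / length(ord), L_KS = NA_real_,
                                     val_RMSE_deg = vr))
        if (verbose)
          message(sprintf("stage B epoch %d: L_PE %.3f val RMSE %.2f",
                          ep, pe_sum / length(ord), vr))
      }
    }

    # ---- closed-form ridge fit of the linear regression head ----
    pool <- train_clips
    if (ridge_rounds > 0) {
      for (r in seq_len(ridge_rounds)) pool <- c(pool, epoch_clips())
    }
    pool_targets <- lapply(pool, clip_target, cfg = config)
    stn <- params$decoder$stand
    z_of <- function(tgs) t(vapply(tgs, function(tg) as.numeric(
      (tg$y - rep(stn$center, each = nrow(tg$y))) /
        rep(stn$scale, each = nrow(tg$y))), numeric(config$out_points * 6)))
    X <- head_inputs(params, config, pool)
    Z <- z_of(pool_targets)
    fit_head <- function(lambda) {
      Xi <- cbind(1, X)
      pen <- diag(ncol(Xi)); pen[1, 1] <- 0
      B <- solve(crossprod(Xi) + lambda * pen, crossprod(Xi, Z))
      list(W = B[-1, , drop = FALSE], b = as.numeric(B[1, ]))
    }
    if (length(val_clips) > 0) {
      Xv <- cbind(1, head_inputs(params, config, val_clips))
      Yv <- do.call(rbind, lapply(val_targets, `[[`, "y"))
      scores <- vapply(ridge_lambdas, function(lambda) {
        hd <- fit_head(lambda)
        zp <- Xv %*% rbind(hd$b, hd$W)
        pd <- do.call(rbind, lapply(seq_len(nrow(zp)), function(i)
          matrix(zp[i, ], config$out_points, 6) *
            rep(stn$scale, each = config$out_points) +
            rep(stn$center, each = config$out_points)))
        sqrt(mean((pd - Yv)^2))
      }, numeric(1))
      best <- which.min(scores)
      params$decoder$head <- fit_head(ridge_lambdas[best])
      log <- rbind(log, data.frame(stage = "ridge", epoch = best,
                                   L_PE = NA_real_, L_KS = NA_real_,
                                   val_RMSE_deg = scores[best]))
      if (verbose)
        message(sprintf("ridge head: lambda %.3g, val RMSE %.2f",
                        ridge_lambdas[best], scores[best]))
    } else {
      params$decoder$head <- fit_head(stats::median(ridge_lambdas))
    }
    model$params <- params
    model$log <- log
    model$seed <- seed
    model
  })
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.pose_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(ptree_leaves(x$params), length, numeric(1)))
  cat(sprintf("<pose_model> modalities: %s | knowledge sharing: %s\n",
              paste(cfg$modalities, collapse = "+"),
              if (cfg$knowledge_sharing) "on" else "off"))
  cat(sprintf("  %s px frames x%d, transformer d=%d, shared D=%d, %d parameters\n",
              cfg$image_size, cfg$frames_per_clip, cfg$d_model, cfg$shared_dim, np))
  if (!is.null(x$log)) {
    n_ep <- sum(x$log$stage %in% c("A", "B"))
    pe <- tail(stats::na.omit(x$log$L_PE), 1)
    cat(sprintf("  trained: %d epochs + ridge head, final L_PE %.2f\n", n_ep, pe))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.pose_model <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("training log (last rows):\n")
    print(tail(object$log, 4), row.names = FALSE)
  }
  invisible(object$log)
}

#' @export
coef.pose_model <- function(object, ...) object$params

#' Predict joint-angle trajectories for multimodal clips
#'
#' @param object a fitted `pose_model`.
#' @param clips a `multimodal_clip` or list of them.
#' @param ... unused.
#' @return a list of `out_points x 6` trajectory matrices (degrees), one per
#'   clip.
#' @export
predict.pose_model <- function(object, clips, ...) {
  if (inherits(clips, "multimodal_clip")) clips <- list(clips)
  lapply(clips, function(cl) {
    out <- model_forward(object$params, object$config, cl, training = FALSE)$pred
    colnames(out) <- ANGLE_NAMES
    out
  })
}

#' @export
residuals.pose_model <- function(object, clips, ...) {
  if (inherits(clips, "multimodal_clip")) clips <- list(clips)
  preds <- predict(object, clips)
  lapply(seq_along(clips), function(i)
    preds[[i]] - clip_target(clips[[i]], object$config)$y)
}
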