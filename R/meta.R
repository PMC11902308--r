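# Meta-transfer learning: scale/shift parameter modulation of a frozen
# pre-trained model, episodic (support/query) training of the modulation
# initialization, and few-shot intra-subject adaptation.

# "scale"/"center" are the decoder's per-joint output calibration: treating
# them as a weight/bias pair puts Eq.-4-style scale/shift modulation on the
# output layer, whose channels are the six joints.
WEIGHT_NAMES <- c("W", "W1", "W2", "Wq", "Wk", "Wv", "Wo", "scale")
BIAS_NAMES <- c("b", "b1", "b2", "center")
MODULATED_GROUPS <- function(params) intersect(c("image", "emg", "vio", "fusion"), names(params))

#' Scale/shift modulation of one weight/bias pair
#'
#' The elementary modulation `(W, b) -> (W * gw, b + gb)`: multiplicative
#' scaling of the weights (per output channel when `W` is a matrix and `gw` a
#' vector) and an additive shift of the biases.
#'
#' @param W weight scalar or matrix (columns are output channels).
#' @param b bias scalar or vector (may be `NULL` for bias-free weights).
#' @param gw scale: scalar or one value per output channel.
#' @param gb shift: scalar or one value per bias element.
#' @return list with modulated `W` and `b`.
#' @export
modulate_wb <- function(W, b = NULL, gw = 1, gb = 0) {
  Wm <- if (is.matrix(W)) sweep(W, 2, gw, `*`) else W * gw
  bm <- if (is.null(b)) NULL else b + gb
  list(W = Wm, b = bm)
}

# A modulation tree mirrors the weight/bias leaves of the modulated parameter
# groups: scales initialized to 1, shifts to 0 (the identity modulation).
mod_like <- function(x) {
  if (!is.list(x)) return(NULL)
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm %in% WEIGHT_NAMES && is.matrix(v)) out[[nm]] <- rep(1, ncol(v))
    else if (nm %in% BIAS_NAMES && is.numeric(v) && !is.list(v)) out[[nm]] <- rep(0, length(v))
    else if (is.list(v)) {
      sub <- mod_like(v)
      if (length(sub)) out[[nm]] <- sub
    }
  }
  out
}

apply_mod <- function(p, m) {
  for (nm in names(m)) {
    if (is.list(m[[nm]])) p[[nm]] <- apply_mod(p[[nm]], m[[nm]])
    else if (nm %in% WEIGHT_NAMES) {
      p[[nm]] <- if (is.matrix(p[[nm]]))
        p[[nm]] * rep(m[[nm]], each = nrow(p[[nm]])) else p[[nm]] * m[[nm]]
    }
    else p[[nm]] <- p[[nm]] + m[[nm]]
  }
  p
}

# Chain parameter gradients (wrt modulated tensors) to modulation gradients:
# d/dgw_c = sum_rows dW'[, c] * W_base[, c]; d/dgb = db'.
mod_grads <- function(dp, base, m) {
  out <- list()
  for (nm in names(m)) {
    if (is.list(m[[nm]])) out[[nm]] <- mod_grads(dp[[nm]], base[[nm]], m[[nm]])
    else if (nm %in% WEIGHT_NAMES) {
      out[[nm]] <- if (is.matrix(base[[nm]]))
        colSums(dp[[nm]] * base[[nm]]) else dp[[nm]] * base[[nm]]
    }
    else out[[nm]] <- dp[[nm]]
  }
  out
}

#' Identity modulation parameters for a pose model
#'
#' Scales (`gw`, per output channel of every encoder and fusion weight) set
#' to 1 and shifts (`gb`, per bias element) set to 0, so that
#' [modulate()] with this object reproduces the base model exactly.
#'
#' @param model a `pose_model`.
#' @return list of class `"modulation_params"`.
#' @export
modulation_init <- function(model) {
  stopifnot(inherits(model, "pose_model"))
  groups <- MODULATED_GROUPS(model$params)
  mod <- lapply(setNames(groups, groups),
                function(g) mod_like(model$params[[g]]))
  # per-joint scale/shift on the decoder's output calibration layer
  mod$decoder <- list(stand = list(scale = rep(1, 6), center = rep(0, 6)))
  structure(list(mod = mod), class = "modulation_params")
}

#' Apply parameter modulation to a pre-trained model
#'
#' Returns a copy of the model whose encoder and fusion weights are scaled by
#' `gw` and biases shifted by `gb`; the base model is unchanged. With the
#' identity modulation the returned model's predictions are bit-identical to
#' the base model's.
#'
#' @param model a `pose_model`.
#' @param mod a `modulation_params` (see [modulation_init()]).
#' @return a modulated `pose_model`.
#' @export
modulate <- function(model, mod) {
  stopifnot(inherits(model, "pose_model"), inherits(mod, "modulation_params"))
  for (g in names(mod$mod)) {
    if (is.null(model$params[[g]])) stopf("modulation group '%s' not in model", g)
    model$params[[g]] <- apply_mod(model$params[[g]], mod$mod[[g]])
  }
  model
}

# ---- tasks and episodes ----------------------------------------------------

#' Define a meta-learning task
#'
#' A task is one level of one axis: a subject (intra-subject adaptation), a
#' walking-speed class, or a walking phase. Phase tasks restrict the loss and
#' evaluation to samples of that phase via the clips' stance/swing mask.
#'
#' @param axis `"subject"`, `"speed"` or `"phase"`.
#' @param level the task value: a subject id, one of slow/moderate/fast, or
#'   one of stance/swing. A vector of levels defines an N-way task.
#' @export
task_definition <- function(axis = c("subject", "speed", "phase"), level) {
  axis <- match.arg(axis)
  ok <- switch(axis,
               subject = is.character(level),
               speed = all(level %in% c("slow", "moderate", "fast")),
               phase = all(level %in% c("stance", "swing")))
  if (!ok) stopf("invalid level for axis '%s'", axis)
  structure(list(axis = axis, level = level), class = "task_definition")
}

clip_matches_task <- function(clip, axis, level) {
  switch(axis,
         subject = clip$subject_id == level,
         speed = clip$speed_class == level,
         phase = TRUE)
}

#' Sample an N-way K-shot episode
#'
#' Draws disjoint support (`N x K` clips) and query (`N x Q` clips) sets
#' uniformly without replacement from the clips matching each task level.
#'
#' @param clips a list of `multimodal_clip`s or a `gait_cohort`.
#' @param task a [task_definition()]; its `level` vector defines the N ways.
#' @param K,Q support and query shots per way (`K >= 1`, `Q >= 1`).
#' @param seed RNG seed; identical arguments give identical membership.
#' @return list of class `"episode"` with `support`, `query`, `task`,
#'   `way` labels and sizes.
#' @export
sample_episode <- function(clips, task, K, Q, seed = 0) {
  stopifnot(inherits(task, "task_definition"), K >= 1, Q >= 1)
  if (inherits(clips, "gait_cohort")) clips <- cohort_clips(clips)
  support <- list(); query <- list(); sway <- character(0); qway <- character(0)
  local_seed(seed, {
    for (lv in task$level) {
      idx <- which(vapply(clips, clip_matches_task, logical(1), task$axis, lv))
      if (length(idx) < K + Q)
        stopf("task %s='%s' has %d clips, need K+Q = %d",
              task$axis, lv, length(idx), K + Q)
      pick <- sample(idx, K + Q)
      support <- c(support, clips[pick[seq_len(K)]])
      query <- c(query, clips[pick[K + seq_len(Q)]])
      sway <- c(sway, rep(lv, K)); qway <- c(qway, rep(lv, Q))
    }
  })
  structure(list(task = task, support = support, query = query,
                 support_way = sway, query_way = qway,
                 N = length(task$level), K = K, Q = Q, seed = seed),
            class = "episode")
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode> %d-way %d-shot (%d queries/way), task %s = %s\n",
              x$N, x$K, x$Q, x$task$axis, paste(x$task$level, collapse = "/")))
  invisible(x)
}

#' Episodic support loss
#'
#' The mean over the `N x K` support clips of the per-clip pose loss (each
#' clip's MSE over its decoded samples and six angles); for phase tasks the
#' per-clip loss is restricted to samples of that phase.
#'
#' @param model a `pose_model`.
#' @param support list of `multimodal_clip`s.
#' @param task optional [task_definition()] (used for phase masking).
#' @return non-negative scalar.
#' @export
episode_loss <- function(model, support, task = NULL) {
  if (length(support) == 0) stopf("empty support set")
  cfg <- model$config
  ph <- if (!is.null(task) && task$axis == "phase") task$level[1] else NULL
  losses <- vapply(support, function(cl) {
    tg <- clip_target(cl, cfg)
    fw <- model_forward(model$params, cfg, cl, training = FALSE)
    pose_loss(fw$pred, tg$y, phase_weights(tg, ph))
  }, numeric(1))
  mean(losses)
}

# ---- inner loop ------------------------------------------------------------

# How much of the decoder is task-adapted: "full" fine-tunes every decoder
# tensor, "bias" only the bias vectors (the low-capacity setting that is
# robust in the 1-shot regime), "none" freezes the decoder (only the
# modulation parameters adapt). TRUE/FALSE are accepted as full/none.
head_grad_mask <- function(mode) {
  zero_stand <- function(g) {
    # the output calibration (stand) adapts only through the modulation
    # parameters, never through direct head gradients
    g$stand <- ptree_zeros_like(g$stand)
    g
  }
  if (identical(mode, "none")) return(function(gh) ptree_zeros_like(gh))
  if (identical(mode, "bias")) {
    zero_w <- function(g) {
      for (nm in names(g)) {
        if (is.list(g[[nm]])) g[[nm]] <- zero_w(g[[nm]])
        else if (nm %in% WEIGHT_NAMES) g[[nm]] <- g[[nm]] * 0
      }
      g
    }
    return(function(gh) zero_stand(zero_w(gh)))
  }
  zero_stand
}

norm_adapt_mode <- function(x) {
  if (isTRUE(x)) "full" else if (isFALSE(x)) "none" else
    match.arg(x, c("full", "bias", "none"))
}

# Gradient-based fine-tuning of (modulation, decoder) on a support set:
# full-batch plain gradient steps with a global norm clip. Plain SGD (rather
# than an adaptive optimizer) keeps the update proportional to the gradient,
# so parameters with negligible support gradient stay put -- important when a
# few shots must not perturb thousands of modulation scales.
# Returns the adapted values plus the per-step mean support loss.
inner_adapt <- function(base_params, cfg, mod, head, support, task,
                        steps, lr, adapt_decoder = TRUE, clip_norm = 10) {
  ph <- if (!is.null(task) && task$axis == "phase") task$level[1] else NULL
  targets <- lapply(support, clip_target, cfg = cfg)
  loss_path <- numeric(steps)
  state <- list(mod = mod, head = head)
  mask_head <- head_grad_mask(adapt_decoder)
  for (s in seq_len(steps)) {
    mod <- state$mod; head <- state$head
    eff <- base_params
    if (!identical(adapt_decoder, "none")) eff$decoder <- head
    p <- eff
    for (g in names(mod)) p[[g]] <- apply_mod(p[[g]], mod[[g]])
    gm <- ptree_zeros_like(mod)
    gh <- ptree_zeros_like(head)
    tot <- 0
    for (i in seq_along(support)) {
      fw <- model_forward(p, cfg, support[[i]], training = FALSE)
      w <- phase_weights(targets[[i]], ph)
      tot <- tot + pose_loss(fw$pred, targets[[i]]$y, w)
      dpred <- pose_loss_grad(fw$pred, targets[[i]]$y, w) / length(support)
      g <- model_backward(fw, p, dpred, ks_scale = 0)
      for (gr in names(mod))
        gm[[gr]] <- ptree_add(gm[[gr]], mod_grads(g[[gr]], eff[[gr]], mod[[gr]]))
      gh <- ptree_add(gh, g$decoder)
    }
    loss_path[s] <- tot / length(support)
    g <- clip_global_norm(list(mod = gm, head = mask_head(gh)), clip_norm)
    state <- list(mod = sgd_step(state$mod, g$mod, lr),
                  head = sgd_step(state$head, g$head, lr))
  }
  list(mod = state$mod, head = state$head, loss_path = loss_path)
}

# Gradient of the query loss wrt (modulation, decoder head), evaluated at the
# adapted parameters (first-order meta-gradient).
query_grad <- function(base_params, cfg, mod, head, query, task, adapt_decoder = TRUE) {
  ph <- if (!is.null(task) && task$axis == "phase") task$level[1] else NULL
  mask_head <- head_grad_mask(adapt_decoder)
  eff <- base_params
  if (!identical(adapt_decoder, "none")) eff$decoder <- head
  p <- eff
  for (g in names(mod)) p[[g]] <- apply_mod(p[[g]], mod[[g]])
  gm <- ptree_zeros_like(mod)
  gh <- ptree_zeros_like(head)
  se <- 0; nn <- 0
  for (cl in query) {
    tg <- clip_target(cl, cfg)
    w <- phase_weights(tg, ph)
    fw <- model_forward(p, cfg, cl, training = FALSE)
    dpred <- pose_loss_grad(fw$pred, tg$y, w) / length(query)
    g <- model_backward(fw, p, dpred, ks_scale = 0)
    for (gr in names(mod))
      gm[[gr]] <- ptree_add(gm[[gr]], mod_grads(g[[gr]], eff[[gr]], mod[[gr]]))
    gh <- ptree_add(gh, g$decoder)
    if (sum(w) > 0) {
      keep <- w > 0
      se <- se + sum((fw$pred[keep, , drop = FALSE] - tg$y[keep, , drop = FALSE])^2)
      nn <- nn + sum(keep) * 6
    }
  }
  list(gm = gm, gh = mask_head(gh), rmse = if (nn > 0) sqrt(se / nn) else NA_real_)
}

# ---- meta-training ---------------------------------------------------------

#' Meta-train the modulation initialization on episodic tasks
#'
#' The pre-trained weights stay frozen; only the shared initialization of the
#' scale/shift modulation parameters (and, by default, the decoder head) is
#' learned. Per episode: sample a task and a support/query split, run
#' `inner_steps` gradient steps on the support loss starting from the shared
#' initialization, then update the initialization with the first-order
#' gradient of the query loss at the adapted parameters (Adam).
#'
#' @param pretrained a fitted `pose_model`.
#' @param cohort a `gait_cohort` or list of clips (the meta-training pool).
#' @param tasks list of [task_definition()]s; default: one subject task per
#'   subject present in the pool.
#' @param episodes number of episodes.
#' @param K,Q support/query shots per episode.
#' @param inner_steps,inner_lr inner-loop gradient steps and learning rate.
#' @param outer_lr Adam learning rate for the initialization update.
#' @param adapt_decoder `"full"`, `"bias"` (default; only decoder bias
#'   vectors adapt, which is robust in the 1-shot regime) or `"none"`: how
#'   much of the decoder is fine-tuned in the inner loop alongside the
#'   modulation parameters.
#' @param clip_norm global gradient-norm clip for the outer update.
#' @param seed RNG seed (episode sampling is derived from it).
#' @param verbose print per-episode progress.
#' @return list of class `"meta_learner"`: frozen `base` model, learned
#'   `mod` initialization, `head`, and an episode `log`.
#' @export
meta_train <- function(pretrained, cohort, tasks = NULL, episodes = 30,
                       K = 5, Q = 5, inner_steps = 10, inner_lr = 1e-2,
                       outer_lr = 1e-3, adapt_decoder = "bias", clip_norm = 5,
                       seed = 0, verbose = FALSE) {
  stopifnot(inherits(pretrained, "pose_model"))
  clips <- if (inherits(cohort, "gait_cohort")) cohort_clips(cohort) else cohort
  if (is.null(tasks)) {
    ids <- unique(vapply(clips, `[[`, character(1), "subject_id"))
    tasks <- lapply(ids, function(s) task_definition("subject", s))
  }
  if (length(tasks) == 0) stopf("no meta-training tasks")
  adapt_decoder <- norm_adapt_mode(adapt_decoder)
  cfg <- pretrained$config
  mod <- modulation_init(pretrained)$mod
  head_p <- pretrained$params$decoder
  state <- list(mod = mod, head = head_p)
  opt <- adam_init(state, lr = outer_lr)
  seeds <- derive_seeds(seed, 2L * episodes)
  log <- NULL
  for (e in seq_len(episodes)) {
    task <- tasks[[local_seed(seeds[2 * e - 1], sample.int(length(tasks), 1))]]
    ep <- sample_episode(clips, task, K = K, Q = Q, seed = seeds[2 * e])
    ad <- inner_adapt(pretrained$params, cfg, state$mod, state$head,
                      ep$support, task, inner_steps, inner_lr, adapt_decoder)
    qg <- query_grad(pretrained$params, cfg, ad$mod, ad$head,
                     ep$query, task, adapt_decoder)
    g <- clip_global_norm(list(mod = qg$gm, head = qg$gh), clip_norm)
    if (!all(vapply(ptree_leaves(g), function(v) all(is.finite(v)), logical(1))))
      stopf("meta-training diverged (non-finite gradient) at episode %d", e)
    st <- adam_step(opt, state, g)
    state <- st$params
    opt <- st$opt
    log <- rbind(log, data.frame(
      episode = e, axis = task$axis, level = paste(task$level, collapse = "/"),
      support_loss = tail(ad$loss_path, 1) %||% NA_real_,
      query_rmse_deg = qg$rmse))
    if (verbose)
      message(sprintf("episode %d (%s=%s): query RMSE %.2f deg",
                      e, task$axis, paste(task$level, collapse = "/"), qg$rmse))
  }
  structure(list(base = pretrained, mod = state$mod, head = state$head,
                 config = list(K = K, Q = Q, inner_steps = inner_steps,
                               inner_lr = inner_lr, outer_lr = outer_lr,
                               adapt_decoder = adapt_decoder, seed = seed),
                 log = log),
            class = "meta_learner")
}

#' @export
print.meta_learner <- function(x, ...) {
  cat(sprintf("<meta_learner> %d episodes, inner %d steps @ %.3g, outer Adam @ %.3g\n",
              NROW(x$log), x$config$inner_steps, x$config$inner_lr, x$config$outer_lr))
  if (NROW(x$log) > 0)
    cat(sprintf("  query RMSE: first %.2f -> last %.2f deg\n",
                x$log$query_rmse_deg[1], tail(x$log$query_rmse_deg, 1)))
  invisible(x)
}

# Build the task-specific pose model from a modulation/head state.
assemble_task_model <- function(meta, mod, head) {
  m <- meta$base
  if (!identical(meta$config$adapt_decoder, "none")) m$params$decoder <- head
  for (g in names(mod)) m$params[[g]] <- apply_mod(m$params[[g]], mod[[g]])
  m$lineage <- list(from = "meta_learner", inner_steps = meta$config$inner_steps)
  m
}

#' Adapt the meta-learner to a new task from a few shots
#'
#' Runs the inner-loop fine-tuning on the new task's support set only,
#' starting from the meta-learned modulation initialization; the pre-trained
#' base weights stay frozen. With `inner_steps = 0` the returned model
#' reproduces the initialization's behavior.
#'
#' @param meta a [meta_train()] result.
#' @param support list of `multimodal_clip`s (the K shots).
#' @param inner_steps,inner_lr override the meta-learner's inner-loop
#'   settings (defaults: as meta-trained).
#' @param task optional [task_definition()] for phase-restricted adaptation.
#' @return the adapted task-specific `pose_model`.
#' @export
meta_adapt <- function(meta, support, inner_steps = NULL, inner_lr = NULL,
                       task = NULL) {
  stopifnot(inherits(meta, "meta_learner"))
  if (length(support) == 0) stopf("empty support set")
  steps <- inner_steps %||% meta$config$inner_steps
  lr <- inner_lr %||% meta$config$inner_lr
  if (steps == 0) return(assemble_task_model(meta, meta$mod, meta$head))
  ad <- inner_adapt(meta$base$params, meta$base$config, meta$mod, meta$head,
                    support, task, steps, lr, meta$config$adapt_decoder)
  m <- assemble_task_model(meta, ad$mod, ad$head)
  m$adapt_loss_path <- ad$loss_path
  m
}
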