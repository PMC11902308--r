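# RMSE metrics in degrees, model comparison reports, and the ablation harness.

#' Root-mean-square error of joint-angle trajectories, in degrees
#'
#' Per-joint RMSE is the square root of the mean squared error over samples;
#' the overall RMSE pools all joints and samples (it is not the mean of the
#' per-joint RMSEs).
#'
#' @param pred,truth numeric matrices `n x 6`, or lists of such matrices
#'   (stacked row-wise).
#' @return list with `overall` (scalar) and `per_joint` (length 6).
#' @export
rmse_degrees <- function(pred, truth) {
  if (is.list(pred)) pred <- do.call(rbind, pred)
  if (is.list(truth)) truth <- do.call(rbind, truth)
  if (!all(dim(pred) == dim(truth))) stopf("pred and truth shapes differ")
  sq <- (pred - truth)^2
  list(overall = sqrt(mean(sq)),
       per_joint = setNames(sqrt(colMeans(sq)), ANGLE_NAMES[seq_len(ncol(sq))]))
}

#' Evaluate a pose model on a set of clips
#'
#' Predicts every clip, compares against the ground-truth trajectories on the
#' decoder grid and aggregates: pooled overall RMSE, per-joint RMSE, and
#' breakdowns by walking-speed class and by stance/swing phase. Residual sums
#' of squares are stored so the pooled RMSE is recomputable from the report.
#'
#' @param model a fitted `pose_model`.
#' @param clips list of `multimodal_clip`s.
#' @param label optional condition label carried into the report.
#' @return list of class `"evaluation_report"`.
#' @export
evaluate_model <- function(model, clips, label = "model") {
  stopifnot(inherits(model, "pose_model"))
  if (inherits(clips, "multimodal_clip")) clips <- list(clips)
  cfg <- model$config
  sse_j <- numeric(6); n <- 0
  sse_speed <- c(slow = 0, moderate = 0, fast = 0)
  n_speed <- c(slow = 0, moderate = 0, fast = 0)
  sse_phase <- c(stance = 0, swing = 0)
  n_phase <- c(stance = 0, swing = 0)
  for (cl in clips) {
    tg <- clip_target(cl, cfg)
    pred <- model_forward(model$params, cfg, cl, training = FALSE)$pred
    sq <- (pred - tg$y)^2
    sse_j <- sse_j + colSums(sq)
    n <- n + nrow(sq)
    sc <- cl$speed_class
    sse_speed[sc] <- sse_speed[sc] + sum(sq)
    n_speed[sc] <- n_speed[sc] + length(sq)
    for (ph in c("stance", "swing")) {
      keep <- tg$phase == ph
      sse_phase[ph] <- sse_phase[ph] + sum(sq[keep, , drop = FALSE])
      n_phase[ph] <- n_phase[ph] + sum(keep) * 6
    }
  }
  structure(list(
    label = label,
    overall_rmse_deg = sqrt(sum(sse_j) / (n * 6)),
    per_joint_rmse_deg = setNames(sqrt(sse_j / n), ANGLE_NAMES),
    per_speed_rmse_deg = ifelse(n_speed > 0, sqrt(sse_speed / n_speed), NA_real_),
    per_phase_rmse_deg = ifelse(n_phase > 0, sqrt(sse_phase / n_phase), NA_real_),
    sse = sum(sse_j), sse_per_joint = sse_j,
    sse_per_phase = sse_phase, n_per_phase = n_phase,
    n_clips = length(clips), n_samples = n),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: overall RMSE %.3f deg (%d clips, %d samples)\n",
              x$label, x$overall_rmse_deg, x$n_clips, x$n_samples))
  cat("  per joint:", paste(sprintf("%s %.2f", names(x$per_joint_rmse_deg),
                                    x$per_joint_rmse_deg), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' Round-trips losslessly through JSON.
#' @param report an `evaluation_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in grep("rmse|sse|^n_", names(x), value = TRUE))
    if (is.list(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  structure(x, class = "evaluation_report")
}

#' Compare models on a shared query set
#'
#' Evaluates every model on the same clips and tabulates all pairwise
#' relative error reductions `(RMSE_a - RMSE_b) / RMSE_a`.
#'
#' @param models named list of fitted `pose_model`s.
#' @param clips shared evaluation clips.
#' @return list with `reports` (one per model) and `reduction` (data frame of
#'   pairwise relative reductions).
#' @export
compare_models <- function(models, clips) {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  reports <- lapply(names(models), function(nm)
    evaluate_model(models[[nm]], clips, label = nm))
  names(reports) <- names(models)
  rmse <- vapply(reports, `[[`, numeric(1), "overall_rmse_deg")
  grid <- expand.grid(a = names(models), b = names(models),
                      stringsAsFactors = FALSE)
  red <- data.frame(model_a = grid$a, model_b = grid$b,
                    rmse_a = rmse[grid$a], rmse_b = rmse[grid$b],
                    relative_reduction = (rmse[grid$a] - rmse[grid$b]) / rmse[grid$a],
                    row.names = NULL)
  list(reports = reports, reduction = red)
}

#' Few-shot evaluation of a meta-learner on held-out tasks
#'
#' For each held-out subject: draw a disjoint support/query split, evaluate
#' the pre-trained model and each `shots`-shot adapted model on the same
#' query clips. Shot 0 denotes the unadapted pre-trained model.
#'
#' @param pretrained the pre-trained `pose_model`.
#' @param meta the `meta_learner` (may be NULL to evaluate pretraining only).
#' @param heldout_clips clips of the held-out (adaptation-target) subjects.
#' @param shots integer vector of shot counts (0 = pretrained).
#' @param Q query clips per subject.
#' @param seed episode-sampling seed.
#' @return data frame: subject, shots, rmse_deg.
#' @export
few_shot_eval <- function(pretrained, meta, heldout_clips, shots = c(0, 1, 5),
                          Q = 5, seed = 0) {
  ids <- unique(vapply(heldout_clips, `[[`, character(1), "subject_id"))
  maxK <- max(c(shots, 1))
  out <- NULL
  seeds <- derive_seeds(seed, length(ids))
  for (i in seq_along(ids)) {
    task <- task_definition("subject", ids[i])
    ep <- sample_episode(heldout_clips, task, K = maxK, Q = Q, seed = seeds[i])
    targets <- lapply(ep$query, clip_target, cfg = pretrained$config)
    truth <- lapply(targets, `[[`, "y")
    for (s in shots) {
      m <- if (s == 0) pretrained
           else meta_adapt(meta, ep$support[seq_len(s)], task = NULL)
      pred <- predict(m, ep$query)
      out <- rbind(out, data.frame(subject = ids[i], shots = s,
                                   rmse_deg = rmse_degrees(pred, truth)$overall))
    }
  }
  out
}

#' Modality and knowledge-sharing ablation harness
#'
#' Trains and evaluates one arm per configuration (a modality subset and/or
#' knowledge sharing on/off) with shared data splits, episode seeds and
#' query sets, and reports pre-trained, 1-shot and 5-shot RMSE per arm.
#' A VIO-only arm is rejected (VIO lacks spatial context on its own).
#'
#' @param cohort a `gait_cohort`.
#' @param arms list of arms; each a list with elements `name`, `modalities`
#'   and `knowledge_sharing`. `default_modality_arms()` and `ks_arms()` build
#'   the standard sets.
#' @param holdout number of adaptation-target subjects held out of training.
#' @param base_config a [pose_model_config()] whose `modalities` /
#'   `knowledge_sharing` fields are overridden per arm.
#' @param epochs,episodes,K,Q,inner_steps,inner_lr,outer_lr training settings
#'   shared by all arms.
#' @param shots shot counts evaluated (0 = pretrained).
#' @param seeds integer vector; every arm is run once per seed and RMSEs are
#'   averaged.
#' @return data frame: one row per arm, RMSE columns per shot count.
#' @export
run_ablation <- function(cohort, arms = default_modality_arms(), holdout = 1,
                         base_config = tiny_pose_config(),
                         epochs = c(6, 0), episodes = 10, K = 5, Q = 5,
                         inner_steps = 10, inner_lr = 1e-2, outer_lr = 1e-3,
                         shots = c(0, 1, 5), seeds = 1) {
  stopifnot(inherits(cohort, "gait_cohort"))
  for (arm in arms) {
    if (identical(sort(arm$modalities), "vio"))
      stopf("arm '%s': a VIO-only model is rejected (VIO lacks spatial context)", arm$name)
  }
  rows <- NULL
  for (arm in arms) {
    acc <- matrix(0, length(seeds), length(shots))
    for (si in seq_along(seeds)) {
      sd <- seeds[si]
      cfg <- base_config
      cfg$modalities <- arm$modalities
      cfg$knowledge_sharing <- arm$knowledge_sharing %||% TRUE
      split <- split_cohort(cohort, holdout = holdout, seed = sd)
      pm <- pretrain(split$pretrain_trials, cfg, epochs = epochs, seed = sd)
      mt <- meta_train(pm, split$train_clips, episodes = episodes, K = K, Q = Q,
                       inner_steps = inner_steps, inner_lr = inner_lr,
                       outer_lr = outer_lr, seed = sd)
      fe <- few_shot_eval(pm, mt, split$holdout_clips, shots = shots,
                          Q = Q, seed = sd)
      acc[si, ] <- vapply(shots, function(s)
        mean(fe$rmse_deg[fe$shots == s]), numeric(1))
    }
    row <- data.frame(arm = arm$name,
                      modalities = paste(arm$modalities, collapse = "+"),
                      knowledge_sharing = arm$knowledge_sharing %||% TRUE)
    for (j in seq_along(shots)) {
      row[[if (shots[j] == 0) "rmse_pretrained" else sprintf("rmse_%dshot", shots[j])]] <-
        mean(acc[, j])
    }
    rows <- rbind(rows, row)
  }
  rows
}

#' @rdname run_ablation
#' @export
default_modality_arms <- function() {
  list(list(name = "vision", modalities = "image"),
       list(name = "semg", modalities = "emg"),
       list(name = "vision+semg", modalities = c("image", "emg")),
       list(name = "vision+vio", modalities = c("image", "vio")),
       list(name = "semg+vio", modalities = c("emg", "vio")),
       list(name = "all", modalities = c("image", "emg", "vio")))
}

#' @rdname run_ablation
#' @export
ks_arms <- function() {
  list(list(name = "KS", modalities = c("image", "emg", "vio"), knowledge_sharing = TRUE),
       list(name = "nKS", modalities = c("image", "emg", "vio"), knowledge_sharing = FALSE))
}
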