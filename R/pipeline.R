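# End-to-end orchestration: leave-subjects-out experiment runner, cohort
# validation, and configuration handling shared with the command-line script.

#' Split a cohort into training and held-out (adaptation-target) subjects
#'
#' @param cohort a `gait_cohort`.
#' @param holdout number of subjects reserved for adaptation (never seen in
#'   pretraining or meta-training).
#' @param pretrain_fraction fraction of the training subjects' clips used for
#'   pretraining (0.5 / 0.75 / 1.0 mirror small/middle/large-scale models).
#' @param seed seed for the subject draw and clip subsampling.
#' @return list with `train_trials`, `pretrain_trials` (the
#'   `pretrain_fraction` subsample), `train_clips`, `pretrain_clips`,
#'   `holdout_clips`, `train_ids`, `holdout_ids`.
#' @export
split_cohort <- function(cohort, holdout = 2, pretrain_fraction = 1.0, seed = 1) {
  stopifnot(inherits(cohort, "gait_cohort"))
  ids <- vapply(cohort$subjects, function(s) s$profile$subject_id, character(1))
  if (holdout >= length(ids)) stopf("holdout (%d) must be < n_subjects (%d)", holdout, length(ids))
  hold_ids <- local_seed(seed, sample(ids, holdout))
  train_ids <- setdiff(ids, hold_ids)
  trials <- cohort_trials(cohort)
  tid <- vapply(trials, `[[`, character(1), "subject_id")
  train_trials <- trials[tid %in% train_ids]
  pre_trials <- train_trials
  if (pretrain_fraction < 1) {
    keep <- local_seed(seed + 1L,
                       sample.int(length(train_trials),
                                  max(1L, round(pretrain_fraction * length(train_trials)))))
    pre_trials <- train_trials[keep]
  }
  clips <- cohort_clips(cohort)
  sid <- vapply(clips, `[[`, character(1), "subject_id")
  list(train_trials = train_trials, pretrain_trials = pre_trials,
       train_clips = clips[sid %in% train_ids],
       pretrain_clips = do.call(c, lapply(pre_trials, segment_clips)),
       holdout_clips = clips[sid %in% hold_ids],
       train_ids = train_ids, holdout_ids = hold_ids)
}

#' Configuration of a full meta-transfer experiment
#'
#' @param n_subjects,trials_per_speed,duration_s cohort size and protocol.
#' @param holdout adaptation-target subjects held out of all training.
#' @param pretrain_fraction 0.5 / 0.75 / 1.0 pretraining-scale flag.
#' @param generator a [gait_config()].
#' @param model a [pose_model_config()] (image sizes must agree).
#' @param epochs pretraining epochs `c(stage_A, stage_B)`.
#' @param episodes,K,Q,inner_steps,inner_lr,outer_lr meta-training settings.
#' @param shots shot counts evaluated on the held-out subjects.
#' @param task_axis `"subject"`, `"speed"` or `"phase"` meta-training tasks.
#' @param seed master seed for the whole run.
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_subjects = 8, trials_per_speed = 1, duration_s = 60,
                              holdout = 2, pretrain_fraction = 1.0,
                              generator = gait_config(image_size = 32),
                              model = tiny_pose_config(),
                              epochs = c(10, 0), episodes = 15, K = 5, Q = 5,
                              inner_steps = 10, inner_lr = 1e-2, outer_lr = 1e-3,
                              shots = c(0, 1, 5), task_axis = "subject", seed = 1) {
  if (generator$image_size != model$image_size)
    stopf("generator renders %dpx frames but the model expects %dpx",
          generator$image_size, model$image_size)
  if (!pretrain_fraction %in% c(0.5, 0.75, 1.0))
    stopf("pretrain_fraction must be one of 0.5, 0.75, 1.0")
  structure(as.list(environment()), class = "experiment_config")
}

#' Run a full simulate / pretrain / meta-train / adapt / evaluate experiment
#'
#' Leave-subjects-out protocol: the adaptation-target subjects never appear
#' in the pretraining or meta-training pools (verified before training). All
#' stages derive their seeds from the config's master seed, so reruns with an
#' identical config reproduce the reports exactly.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the resolved config (YAML),
#'   training logs (CSV) and the final report (CSV + JSON) are written there.
#' @param verbose print stage progress.
#' @return list of class `"metagait_experiment"`: the cohort split ids, the
#'   fitted models, the per-subject few-shot table and summary RMSEs.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, 5)
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating cohort (%d subjects)...", config$n_subjects)
  cohort <- make_cohort(config$n_subjects, config$trials_per_speed,
                        seed = seeds[1], config = config$generator,
                        duration_s = config$duration_s)
  split <- split_cohort(cohort, holdout = config$holdout,
                        pretrain_fraction = config$pretrain_fraction,
                        seed = seeds[2])
  pre_ids <- unique(vapply(split$pretrain_clips, `[[`, character(1), "subject_id"))
  if (length(intersect(pre_ids, split$holdout_ids)) > 0)
    stopf("split integrity violated: adaptation targets present in the pretraining set")
  say("pretraining on %d clips from %d subjects...",
      length(split$pretrain_clips), length(split$train_ids))
  pm <- pretrain(split$pretrain_trials, config$model, epochs = config$epochs,
                 seed = seeds[3], verbose = verbose)
  tasks <- NULL
  if (config$task_axis == "speed")
    tasks <- lapply(c("slow", "moderate", "fast"), function(l) task_definition("speed", l))
  if (config$task_axis == "phase")
    tasks <- lapply(c("stance", "swing"), function(l) task_definition("phase", l))
  say("meta-training (%d episodes)...", config$episodes)
  mt <- meta_train(pm, split$pretrain_clips, tasks = tasks,
                   episodes = config$episodes, K = config$K, Q = config$Q,
                   inner_steps = config$inner_steps, inner_lr = config$inner_lr,
                   outer_lr = config$outer_lr, seed = seeds[4], verbose = verbose)
  say("adapting to %d held-out subjects...", length(split$holdout_ids))
  fs <- few_shot_eval(pm, mt, split$holdout_clips, shots = config$shots,
                      Q = config$Q, seed = seeds[5])
  mean_rmse <- tapply(fs$rmse_deg, fs$shots, mean)
  base <- mean_rmse[as.character(0)]
  summary_df <- data.frame(shots = as.integer(names(mean_rmse)),
                           rmse_deg = as.numeric(mean_rmse),
                           relative_reduction =
                             as.numeric((base - mean_rmse) / base))
  result <- structure(list(config = config, train_ids = split$train_ids,
                           holdout_ids = split$holdout_ids,
                           pretrained = pm, meta = mt,
                           few_shot = fs, summary = summary_df),
                      class = "metagait_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(yaml::as.yaml(serialize_config(config)), file.path(out_dir, "config.yaml"))
    write.csv(pm$log, file.path(out_dir, "pretrain_log.csv"), row.names = FALSE)
    write.csv(mt$log, file.path(out_dir, "meta_log.csv"), row.names = FALSE)
    write.csv(fs, file.path(out_dir, "few_shot.csv"), row.names = FALSE)
    jsonlite::write_json(list(summary = summary_df,
                              holdout = split$holdout_ids),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  x$model <- unclass(x$model)
  x
}

#' @export
print.metagait_experiment <- function(x, ...) {
  cat(sprintf("<metagait_experiment> %d train / %d held-out subjects, task axis '%s'\n",
              length(x$train_ids), length(x$holdout_ids), x$config$task_axis))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Validate the structural invariants of a cohort
#'
#' Checks, for every trial: sample counts equal `round(rate * duration)`,
#' channel counts (6 sEMG, 6 angles, 7 VIO columns), unit-norm VIO
#' quaternions (within 1e-6), image dimensions, stance-fraction band and the
#' stance/swing alternation of the phase mask.
#'
#' @param x a `gait_cohort` or a path to one written by [write_cohort()].
#' @param stance_band allowed stance fraction range per trial.
#' @return data frame of checks with an `ok` column; attribute `"valid"` is
#'   `TRUE` iff all checks passed.
#' @export
validate_cohort <- function(x, stance_band = c(0.55, 0.65)) {
  if (is.character(x)) x <- read_cohort(x)
  stopifnot(inherits(x, "gait_cohort"))
  rows <- NULL
  add <- function(subject, trial, check, ok, detail = "") {
    rows <<- rbind(rows, data.frame(subject = subject, trial = trial,
                                    check = check, ok = ok, detail = detail))
  }
  for (s in x$subjects) {
    sid <- s$profile$subject_id
    for (ti in seq_along(s$trials)) {
      tr <- s$trials[[ti]]
      dur <- tr$duration_s
      for (nm in names(tr$streams)) {
        st <- tr$streams[[nm]]
        n_obs <- if (length(dim(st$samples)) == 4) dim(st$samples)[4] else nrow(st$samples)
        n_exp <- n_samples_for(st$rate, dur)
        add(sid, ti, paste0(nm, "_count"), n_obs == n_exp,
            sprintf("%d vs %d", n_obs, n_exp))
      }
      add(sid, ti, "angles_count",
          nrow(tr$angles$samples) == n_samples_for(tr$angles$rate, dur))
      add(sid, ti, "emg_channels", ncol(tr$streams$emg$samples) == 6)
      add(sid, ti, "angle_channels", ncol(tr$angles$samples) == 6)
      add(sid, ti, "vio_channels", ncol(tr$streams$vio$samples) >= 7)
      qn <- sqrt(rowSums(tr$streams$vio$samples[, 4:7]^2))
      add(sid, ti, "quaternion_norm", max(abs(qn - 1)) <= 1e-6,
          sprintf("max dev %.2e", max(abs(qn - 1))))
      sf <- mean(tr$phase == "stance")
      add(sid, ti, "stance_fraction",
          sf >= stance_band[1] & sf <= stance_band[2], sprintf("%.3f", sf))
      r <- rle(tr$phase)
      add(sid, ti, "phase_alternation", all(r$values[-1] != head(r$values, -1)))
    }
  }
  attr(rows, "valid") <- all(rows$ok)
  rows
}
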