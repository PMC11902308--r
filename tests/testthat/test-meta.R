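# Parameter modulation, episodes, meta-training and few-shot adaptation.

make_meta0 <- function(model, inner_steps = 2, inner_lr = 1e-3,
                       adapt_decoder = "bias") {
  structure(list(base = model, mod = modulation_init(model)$mod,
                 head = model$params$decoder,
                 config = list(K = 2, Q = 2, inner_steps = inner_steps,
                               inner_lr = inner_lr, outer_lr = 0,
                               adapt_decoder = adapt_decoder, seed = 0),
                 log = NULL),
            class = "meta_learner")
}

test_that("identity modulation reproduces the base model bit for bit", {
  model <- fx_model()
  clip <- fx_clip()
  m2 <- modulate(model, modulation_init(model))
  expect_identical(predict(model, clip), predict(m2, clip))
})

test_that("random modulation equals a model rebuilt with substituted tensors", {
  model <- fx_model()
  clip <- fx_clip()
  mod <- modulation_init(model)
  set.seed(20)
  mod$mod$emg$proj$W <- runif(length(mod$mod$emg$proj$W), 0.8, 1.2)
  mod$mod$emg$proj$b <- rnorm(length(mod$mod$emg$proj$b), sd = 0.05)
  mod$mod$fusion$branch2$block1$conv$W <-
    runif(length(mod$mod$fusion$branch2$block1$conv$W), 0.9, 1.1)
  mod$mod$decoder$stand$scale <- runif(6, 0.9, 1.1)
  mod$mod$decoder$stand$center <- rnorm(6)
  modulated <- modulate(model, mod)
  rebuilt <- model
  rebuilt$params$emg$proj$W <-
    sweep(model$params$emg$proj$W, 2, mod$mod$emg$proj$W, `*`)
  rebuilt$params$emg$proj$b <-
    model$params$emg$proj$b + mod$mod$emg$proj$b
  rebuilt$params$fusion$branch2$block1$conv$W <-
    sweep(model$params$fusion$branch2$block1$conv$W, 2,
          mod$mod$fusion$branch2$block1$conv$W, `*`)
  rebuilt$params$decoder$stand$scale <-
    model$params$decoder$stand$scale * mod$mod$decoder$stand$scale
  rebuilt$params$decoder$stand$center <-
    model$params$decoder$stand$center + mod$mod$decoder$stand$center
  expect_equal(predict(modulated, clip), predict(rebuilt, clip),
               tolerance = 1e-12)
  # the base model is untouched
  expect_identical(model$params, fx_model()$params)
})

test_that("episodes are disjoint, seeded and validated", {
  clips <- fx_clips()
  id <- clips[[1]]$subject_id
  task <- task_definition("subject", id)
  ep <- sample_episode(clips, task, K = 3, Q = 4, seed = 11)
  expect_length(ep$support, 3)
  expect_length(ep$query, 4)
  key <- function(cl) paste(cl$subject_id, cl$speed_kmh, cl$t0)
  expect_length(intersect(sapply(ep$support, key), sapply(ep$query, key)), 0)
  expect_true(all(sapply(c(ep$support, ep$query), `[[`, "subject_id") == id))
  ep2 <- sample_episode(clips, task, K = 3, Q = 4, seed = 11)
  expect_identical(sapply(ep$support, key), sapply(ep2$support, key))
  # exhaustive partition at the boundary K + Q = available clips
  n_avail <- sum(sapply(clips, `[[`, "subject_id") == id)
  ep3 <- sample_episode(clips, task, K = 4, Q = n_avail - 4, seed = 2)
  expect_length(c(ep3$support, ep3$query), n_avail)
  expect_error(sample_episode(clips, task, K = n_avail, Q = 1, seed = 2),
               "need K\\+Q")
})

test_that("speed and phase tasks are validated and filter as documented", {
  expect_error(task_definition("speed", "sprint"), "invalid level")
  expect_error(task_definition("phase", "flight"), "invalid level")
  clips <- fx_clips()
  ep <- sample_episode(clips, task_definition("speed", "slow"), K = 1, Q = 1,
                       seed = 1)
  expect_true(all(sapply(c(ep$support, ep$query), `[[`, "speed_class") == "slow"))
})

test_that("the episodic loss is the mean per-clip pose loss", {
  model <- fx_model()
  clips <- fx_clips()[1:2]
  l1 <- episode_loss(model, clips[1])
  tg <- mg$clip_target(clips[[1]], model$config)
  fw <- mg$model_forward(model$params, model$config, clips[[1]], FALSE)
  expect_equal(l1, pose_loss(fw$pred, tg$y), tolerance = 1e-12)  # K = 1
  l2 <- episode_loss(model, clips[2])
  expect_equal(episode_loss(model, clips), (l1 + l2) / 2, tolerance = 1e-12)
  expect_error(episode_loss(model, list()), "empty")
})

test_that("zero-step adaptation returns the initialization's behavior", {
  model <- fx_model()
  meta0 <- make_meta0(model, inner_steps = 0)
  adapted <- meta_adapt(meta0, fx_clips()[1])
  expect_identical(predict(adapted, fx_clip()), predict(model, fx_clip()))
  expect_error(meta_adapt(meta0, list()), "empty")
})

test_that("adaptation is deterministic and freezes the base weights", {
  model <- fx_model()
  meta0 <- make_meta0(model, inner_steps = 2)
  support <- fx_clips()[1:2]
  a1 <- meta_adapt(meta0, support)
  a2 <- meta_adapt(meta0, support)
  expect_identical(a1$params, a2$params)
  # adapted parameters moved, but only in modulated/fine-tuned leaves;
  # the meta-learner's stored base model is untouched
  expect_identical(meta0$base$params, model$params)
  expect_gt(max(abs(a1$params$decoder$stand$center -
                    model$params$decoder$stand$center)), 0)
})

test_that("meta-training runs episodically, logs per episode, and freezes the base", {
  clips <- fx_clips()
  cfg <- test_cfg()
  pm <- pretrain(clips[1:6], cfg, epochs = c(1, 0), seed = 8, val_fraction = 0)
  base_snapshot <- pm$params
  mt <- meta_train(pm, clips, episodes = 2, K = 2, Q = 2, inner_steps = 1,
                   seed = 5)
  expect_s3_class(mt, "meta_learner")
  expect_equal(nrow(mt$log), 2)                 # episode log length = episodes
  expect_true(all(is.finite(mt$log$query_rmse_deg)))
  expect_identical(mt$base$params, base_snapshot)
  expect_error(meta_train(pm, clips, tasks = list(), episodes = 1), "tasks")
})

test_that("zero learning rates leave the modulation at its initialization", {
  clips <- fx_clips()
  cfg <- test_cfg()
  pm <- pretrain(clips[1:6], cfg, epochs = c(1, 0), seed = 8, val_fraction = 0)
  mt <- meta_train(pm, clips, episodes = 1, K = 2, Q = 2, inner_steps = 1,
                   inner_lr = 0, outer_lr = 0, seed = 5)
  init <- modulation_init(pm)$mod
  expect_equal(mt$mod, init, tolerance = 1e-12)
})
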