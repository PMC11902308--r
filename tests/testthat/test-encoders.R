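# Per-modality encoders: determinism, symmetry properties, shapes.

test_that("encoders are deterministic and batch-independent in evaluation mode", {
  model <- fx_model()
  clip <- fx_clip()
  f1 <- encode_image(clip$streams$image, model)
  f2 <- encode_image(clip$streams$image, model)
  expect_identical(f1, f2)
  expect_length(f1, model$config$widths[4])
  e1 <- encode_sequence(clip$streams$emg, model)
  e2 <- encode_sequence(clip$streams$emg, model)
  expect_identical(e1, e2)
  expect_length(e1, model$config$d_model)
  v1 <- encode_sequence(clip$streams$vio, model)
  expect_true(all(is.finite(c(f1, e1, v1))))
})

test_that("encoders reject wrong modalities and empty sequences", {
  model <- fx_model()
  clip <- fx_clip()
  expect_error(encode_image(clip$streams$emg, model), "image")
  expect_error(encode_sequence(clip$streams$image, model), "emg or vio")
  empty <- mg$modality_stream("vio", matrix(numeric(0), 0, 7), 200)
  expect_error(encode_sequence(empty, model), "empty|short")
})

test_that("mean pooling without positional encoding is token-permutation invariant", {
  model <- fx_model()
  clip <- fx_clip()
  vio <- clip$streams$vio
  f_plain <- encode_sequence(vio, model, positional = FALSE)
  # circularly shift the underlying samples by a whole number of patches
  shift <- model$config$vio_patch * model$config$vio_downsample * 3
  n <- nrow(vio$samples)
  vio_perm <- vio
  vio_perm$samples <- vio$samples[c((shift + 1):n, 1:shift), , drop = FALSE]
  f_perm <- encode_sequence(vio_perm, model, positional = FALSE)
  expect_equal(f_plain, f_perm, tolerance = 1e-8)
  # with positional encoding the same shift must change the output
  g_plain <- encode_sequence(vio, model, positional = TRUE)
  g_perm <- encode_sequence(vio_perm, model, positional = TRUE)
  expect_gt(max(abs(g_plain - g_perm)), 1e-6)
})

test_that("image encoding reduces to the configured feature dimension for any frame count", {
  cfg <- test_cfg(frames_per_clip = 5)
  model <- init_pose_model(cfg, seed = 2)
  f <- encode_image(fx_clip()$streams$image, model)
  expect_length(f, cfg$widths[4])
})

test_that("architecture validation catches impossible configurations", {
  expect_error(pose_model_config(image_size = 20), "divisible by 16")
  expect_error(pose_model_config(d_model = 30, n_heads = 4), "divisible by n_heads")
  expect_error(pose_model_config(modalities = "vio"), "VIO")
  m <- fx_model()
  big <- gait_config(image_size = 64)
  tr <- simulate_trial(make_subject(1, big), 4.5, 10, seed = 1, config = big)
  expect_error(encode_image(segment_clips(tr)[[1]]$streams$image, m), "64px")
})

test_that("every trainable tensor receives a nonzero pose-loss gradient", {
  cfg <- test_cfg()
  model <- init_pose_model(cfg, seed = 4)
  clip <- fx_clip()
  fw <- mg$model_forward(model$params, cfg, clip, training = FALSE)
  tgt <- mg$clip_target(clip, cfg)
  g <- mg$model_backward(fw, model$params,
                         mg$pose_loss_grad(fw$pred, tgt$y), ks_scale = 1)
  walk <- function(g, path = "") {
    if (!is.list(g)) {
      # frozen normalization statistics legitimately have zero gradients
      if (!grepl("rmean|rsd|fmean|fsd|center|scale", path))
        expect_gt(max(abs(g)), 0, label = path)
      return(invisible())
    }
    for (nm in names(g)) walk(g[[nm]], paste(path, nm, sep = "$"))
  }
  walk(g)
})
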