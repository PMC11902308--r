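# Knowledge-sharing transforms, alignment loss, fusion, decoder, pose loss.

test_that("the shared-space transform is the documented affine map", {
  cfg <- test_cfg()
  model <- init_pose_model(cfg, seed = 3)
  D <- cfg$shared_dim
  # identity-initialized transform with matching dimension reproduces input
  model$params$transform$emg <- list(W = diag(D), b = numeric(D))
  r <- rnorm(D)
  expect_equal(transform_feature(r, model, "emg"), r)
  # zero input through a zero-bias transform gives zero
  model$params$transform$vio$b <- numeric(D)
  expect_equal(transform_feature(numeric(D), model, "vio"), numeric(D))
  # fixed random parameters match the hand-computed matrix product
  W <- matrix(rnorm(D * D), D); b <- rnorm(D)
  model$params$transform$image <- list(W = W, b = b)
  x <- rnorm(D)
  expect_equal(transform_feature(x, model, "image"),
               as.numeric(x %*% W + b), tolerance = 1e-12)
  expect_error(transform_feature(r, model, "radar"), "modality")
})

test_that("the alignment loss is the normalized pairwise Euclidean distance", {
  # two modalities, features (0,0) and (3,4), unit normalizer -> 5
  expect_equal(knowledge_sharing_loss(list(a = c(0, 0), b = c(3, 4))), 5)
  # coincident features give exactly zero
  f <- rnorm(8)
  expect_equal(knowledge_sharing_loss(list(i = f, e = f, v = f)), 0)
  # three modalities: equals the brute-force sum over unordered pairs
  set.seed(9)
  fs <- list(i = rnorm(4), e = rnorm(4), v = rnorm(4))
  brute <- 0
  nm <- names(fs)
  for (a in 1:2) for (b in (a + 1):3)
    brute <- brute + sqrt(sum((fs[[a]] - fs[[b]])^2))
  expect_equal(knowledge_sharing_loss(fs), brute, tolerance = 1e-12)
  # invariant to the order the modalities are supplied
  expect_equal(knowledge_sharing_loss(fs[c(3, 1, 2)]), brute, tolerance = 1e-12)
  # exp-parameterized normalizers multiply pairwise
  expect_equal(knowledge_sharing_loss(list(a = c(0, 0), b = c(3, 4)),
                                      normalizers = c(a = log(2), b = 0)), 10)
  expect_warning(out <- knowledge_sharing_loss(list(a = 1:3)), "2 modalities")
  expect_equal(out, 0)
  expect_error(knowledge_sharing_loss(list(a = 1:3, b = 1:4)), "dimensions differ")
})

test_that("alignment-loss gradients match finite differences", {
  set.seed(10)
  rt <- list(image = rnorm(5), emg = rnorm(5), vio = rnorm(5))
  norms <- list(image = 0.2, emg = -0.1, vio = 0)
  gr <- mg$ks_loss_grad(rt, norms)
  f <- function(v) {
    rt2 <- rt; rt2$emg <- v
    mg$ks_loss_grad(rt2, norms)$loss
  }
  expect_equal(gr$dfeat$emg, num_grad(f, rt$emg, 1:5), tolerance = 1e-6)
  fn <- function(v) {
    n2 <- norms; n2$image <- v
    mg$ks_loss_grad(rt, n2)$loss
  }
  expect_equal(gr$dnorm$image, num_grad(fn, norms$image, 1), tolerance = 1e-6)
})

test_that("fusion concatenates three pooled branch outputs", {
  cfg <- test_cfg()
  model <- init_pose_model(cfg, seed = 5)
  D <- cfg$shared_dim
  feats <- list(image = rnorm(D), emg = rnorm(D), vio = rnorm(D))
  k <- fuse(feats, model)
  expect_length(k, 3 * cfg$branch_width)       # F = w1 + w2 + w3
  expect_true(all(is.finite(k)))
  expect_error(fuse(list(), model), "empty")
  # single-block branch against a hand computation (identity statistics)
  p1 <- model$params$fusion$branch1$block1
  x0 <- mg$stack_features(feats, cfg)
  cv <- mg$conv1d_fw(x0, p1$conv$W, p1$conv$b, cfg$fusion_kernel)
  xh <- sweep(sweep(cv$out, 2, p1$norm$rmean), 2, p1$norm$rsd, `/`)
  nm <- sweep(sweep(xh, 2, p1$norm$gamma, `*`), 2, p1$norm$beta, `+`)
  lr <- ifelse(nm > 0, nm, 0.01 * nm)
  expect_equal(k[seq_len(cfg$branch_width)], colMeans(lr), tolerance = 1e-10)
})

test_that("the decoder is deterministic in evaluation mode and shape-checked", {
  cfg <- test_cfg()
  model <- init_pose_model(cfg, seed = 6)
  k <- rnorm(3 * cfg$branch_width)
  y1 <- decode(k, model)
  y2 <- decode(k, model)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(cfg$out_points, 6))
  expect_error(decode(rnorm(5), model), "length")
})

test_that("pose loss is the per-sample MSE over six angles", {
  expect_equal(pose_loss(matrix(1, 1, 6), matrix(0, 1, 6)), 1)   # (1/6)*6
  y <- matrix(rnorm(30), 5, 6)
  expect_equal(pose_loss(y, y), 0)
  # equals the naive two-loop computation on a random batch
  p <- matrix(rnorm(30), 5, 6)
  brute <- 0
  for (i in 1:5) {
    s <- 0
    for (j in 1:6) s <- s + (p[i, j] - y[i, j])^2
    brute <- brute + s / 6
  }
  expect_equal(pose_loss(p, y), brute / 5, tolerance = 1e-12)
  # weighted variant restricts to the masked samples
  w <- c(1, 0, 1, 0, 0)
  expect_equal(pose_loss(p, y, w),
               (rowMeans((p - y)^2)[1] + rowMeans((p - y)^2)[3]) / 2)
  expect_error(pose_loss(p, y[1:3, ]), "shapes")
})

test_that("RMSE equals the square root of the pooled pose loss", {
  set.seed(12)
  p <- matrix(rnorm(60), 10, 6); y <- matrix(rnorm(60), 10, 6)
  expect_equal(rmse_degrees(p, y)$overall, sqrt(pose_loss(p, y)),
               tolerance = 1e-9)
})

test_that("a short pretraining run is reproducible and properly logged", {
  clips <- fx_clips()[1:6]
  cfg <- test_cfg()
  m1 <- pretrain(clips, cfg, epochs = c(1, 1), seed = 3, val_fraction = 0)
  expect_s3_class(m1, "pose_model")
  expect_equal(nrow(m1$log), 2)                  # one entry per epoch
  expect_true(all(is.finite(m1$log$L_PE)))
  expect_true(all(is.finite(m1$log$L_KS[m1$log$stage == "A"])))
  m2 <- pretrain(clips, cfg, epochs = c(1, 1), seed = 3, val_fraction = 0)
  expect_equal(tail(m1$log$L_PE, 1), tail(m2$log$L_PE, 1), tolerance = 1e-6)
  expect_error(pretrain(list(), cfg), "empty")
})

test_that("modality-ablated models train and evaluate without structural failure", {
  clips <- fx_clips()[1:4]
  for (mods in list("image", "emg", c("emg", "vio"))) {
    cfg <- test_cfg(modalities = mods)
    m <- pretrain(clips, cfg, epochs = c(1, 0), seed = 1, val_fraction = 0)
    ev <- evaluate_model(m, clips[1:2])
    expect_true(is.finite(ev$overall_rmse_deg))
  }
})
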