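# Synthetic multimodal gait generator: determinism, rates, protocol
# bookkeeping, stream invariants and lossless interchange.

test_that("subject profiles are deterministic in the seed and distinct across seeds", {
  gen <- test_gen()
  p0 <- make_subject(0, gen)
  p0b <- make_subject(0, gen)
  expect_identical(p0, p0b)
  p1 <- make_subject(1, gen)
  fields <- c("baseline_offsets", "fourier_amps", "fourier_phases",
              "cadence_scale", "emg_gain", "marker_offsets")
  differs <- vapply(fields, function(f) !isTRUE(all.equal(p0[[f]], p1[[f]])),
                    logical(1))
  expect_true(any(differs))
  expect_true(all(is.finite(p0$fourier_amps)) && all(p0$fourier_amps >= 0))
  expect_gt(p0$cadence_scale, 0)
  expect_true(all(p0$noise_levels >= 0))
})

test_that("zero-width config ranges give the range midpoints", {
  gen <- test_gen(offset_jitter = c(2, 2), amp_scale = c(1, 1),
                  phase_jitter = c(0, 0), cadence_scale = c(1.05, 1.05),
                  emg_gain = c(0.9, 0.9), marker_offset = c(-1, -1))
  p <- make_subject(7, gen)
  expect_equal(unname(p$baseline_offsets),
               unname(gen$offset_template[rep(1:3, 2)] + 2))
  expect_equal(unname(p$fourier_amps), unname(gen$amp_template[rep(1:3, 2), ]))
  expect_equal(p$cadence_scale, 1.05)
  expect_equal(unname(p$emg_gain), rep(0.9, 6))
  expect_equal(unname(p$marker_offsets), rep(-1, 6))
})

test_that("invalid config ranges are rejected", {
  expect_error(test_gen(amp_scale = c(1.2, 0.8)), "min <= max")
  expect_error(gait_config(noise = list(image = -0.1, emg = 0, vio = 0, angle = 0)),
               ">= 0")
})

test_that("stream sample counts follow the acquisition rates exactly", {
  # 1-minute trial at the nominal rates: 30 / 1111.111 / 200 / 100 Hz
  gen <- test_gen()
  tr <- simulate_trial(make_subject(11, gen), 3.5, duration_s = 60,
                       seed = 2, config = gen)
  expect_equal(dim(tr$streams$image$samples)[4], 1800)
  expect_equal(nrow(tr$streams$emg$samples), 66667)
  expect_equal(nrow(tr$streams$vio$samples), 12000)
  expect_equal(nrow(tr$angles$samples), 6000)
  expect_equal(ncol(tr$streams$emg$samples), 6)
  expect_equal(ncol(tr$angles$samples), 6)
  expect_gte(ncol(tr$streams$vio$samples), 7)
})

test_that("simulation is bit-identical under a fixed seed and rejects bad arguments", {
  gen <- test_gen()
  pr <- make_subject(3, gen)
  t1 <- simulate_trial(pr, 4.5, 20, seed = 9, config = gen)
  t2 <- simulate_trial(pr, 4.5, 20, seed = 9, config = gen)
  expect_identical(t1$streams$emg$samples, t2$streams$emg$samples)
  expect_identical(t1$streams$image$samples, t2$streams$image$samples)
  expect_identical(t1$streams$vio$samples, t2$streams$vio$samples)
  expect_error(simulate_trial(pr, -1, 20, seed = 1, config = gen), "speed")
  expect_error(simulate_trial(pr, 4.5, 0, seed = 1, config = gen), "duration")
})

test_that("VIO quaternions have unit norm within 1e-6", {
  q <- fx_trial()$streams$vio$samples[, 4:7]
  expect_lt(max(abs(sqrt(rowSums(q^2)) - 1)), 1e-6)
})

test_that("the sEMG activation envelope is exactly periodic at the stride period", {
  gen <- test_gen(noiseless = TRUE)
  pr <- make_subject(5, gen)
  f <- stride_hz(pr, 4.5, gen)
  t <- seq(0, 2, by = 1e-3)
  e1 <- emg_envelope(pr, 4.5, t, gen)
  e2 <- emg_envelope(pr, 4.5, t + 1 / f, gen)
  expect_lt(max(abs(e1 - e2)), 1e-9)
})

test_that("noiseless reference angles are a deterministic function of (profile, speed, t)", {
  gen <- test_gen(noiseless = TRUE)
  pr <- make_subject(5, gen)
  tr <- simulate_trial(pr, 6, 10, seed = 31, config = gen)
  ta <- (seq_len(nrow(tr$angles$samples)) - 1) / tr$angles$rate
  expected <- gait_angles(pr, 6, ta + tr$phase0 / tr$stride_hz, gen) +
    rep(pr$marker_offsets, each = length(ta))
  expect_equal(tr$angles$samples, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("clip segmentation follows the shot protocol", {
  gen <- test_gen()
  pr <- make_subject(13, gen)
  tr60 <- simulate_trial(pr, 4.5, 60, seed = 1, config = gen)
  clips <- segment_clips(tr60)
  expect_length(clips, 6)                      # 1-min trial -> 6 ten-second shots
  expect_equal(dim(clips[[1]]$streams$image$samples)[4], 300)
  expect_equal(nrow(clips[[1]]$streams$emg$samples), 11111)
  expect_equal(nrow(clips[[1]]$angles$samples), 1000)
  expect_length(clips[[1]]$phase, 1000)
  tr_short <- simulate_trial(pr, 4.5, 9.5, seed = 1, config = gen)
  expect_warning(out <- segment_clips(tr_short), "shorter")
  expect_length(out, 0)
})

test_that("cohort bookkeeping matches the acquisition protocol arithmetic", {
  co <- fx_cohort()                            # 2 subjects x 3 trials (1/speed)
  trials <- cohort_trials(co)
  expect_length(trials, 6)
  speeds <- table(vapply(trials, `[[`, character(1), "speed_class"))
  expect_equal(unname(speeds[c("slow", "moderate", "fast")]), rep(2L, 3),
               ignore_attr = TRUE)
  dirs <- vapply(trials, `[[`, character(1), "direction")
  expect_true(all(c("cw", "ccw") %in% dirs))   # alternating direction
  clips <- fx_clips()
  expect_length(clips, 6 * 3)                  # 30-s trials -> 3 clips each
})

test_that("identical cohort seeds reproduce the cohort array-wise", {
  gen <- test_gen()
  c1 <- make_cohort(1, 1, seed = 21, config = gen, duration_s = 20)
  c2 <- make_cohort(1, 1, seed = 21, config = gen, duration_s = 20)
  expect_identical(c1$subjects[[1]]$trials[[2]]$streams$emg$samples,
                   c2$subjects[[1]]$trials[[2]]$streams$emg$samples)
  expect_identical(c1$subjects[[1]]$profile, c2$subjects[[1]]$profile)
})

test_that("cohorts round-trip losslessly through the interchange format", {
  co <- fx_cohort()
  path <- withr::local_tempfile(fileext = ".rds")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(cohort_clips(back)[[4]]$streams$emg$samples,
                   fx_clips()[[4]]$streams$emg$samples)
  expect_identical(back$config$rates, co$config$rates)
  expect_true(nzchar(attr(back, "config_yaml")))
})

test_that("tidy CSV export has the documented grammar", {
  gen <- test_gen()
  co <- make_cohort(1, 1, seed = 33, config = gen, duration_s = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  export_angles_csv(co, path)
  df <- read.csv(path)
  expect_named(df, c("subject", "trial", "speed_kmh", "time_s", "joint",
                     "side", "angle_deg"))
  expect_setequal(unique(df$joint), c("hip", "knee", "ankle"))
  expect_setequal(unique(df$side), c("L", "R"))
  expect_equal(nrow(df), 3 * 1000 * 6)         # 3 trials x 1000 samples x 6 angles
})

test_that("stance fraction sits in the physiological band and decreases with speed", {
  gen <- test_gen()
  pr <- make_subject(17, gen)
  fr <- vapply(c(3.5, 4.5, 6), function(v) {
    tr <- simulate_trial(pr, v, 30, seed = 3, config = gen)
    mean(tr$phase == "stance")
  }, numeric(1))
  expect_true(all(fr >= 0.55 & fr <= 0.65))
  expect_true(all(diff(fr) < 0))
})

test_that("phase mask alternates stance and swing once per cycle", {
  tr <- fx_trial()
  r <- rle(tr$phase)
  expect_true(all(r$values[-1] != head(r$values, -1)))
  # number of stance intervals ~ number of gait cycles in the trial
  n_cycles <- tr$duration_s * tr$stride_hz
  expect_lt(abs(sum(r$values == "stance") - n_cycles), 2)
})

test_that("subjects are separable: inter-subject exceeds intra-subject distance", {
  # trials start at random gait phases, so trajectories are compared through
  # phase-insensitive summaries: per-joint time mean and time sd
  gen <- test_gen(noiseless = TRUE)
  summ <- function(tr) {
    a <- tr$angles$samples
    c(colMeans(a), apply(a, 2, sd))
  }
  feats <- lapply(1:4, function(i) {
    p <- make_subject(i, gen)
    lapply(1:2, function(k)
      summ(simulate_trial(p, 4.5, 20, seed = 100 * i + k, config = gen)))
  })
  d <- function(a, b) sqrt(mean((a - b)^2))
  intra <- mean(vapply(feats, function(f) d(f[[1]], f[[2]]), numeric(1)))
  inter <- mean(apply(utils::combn(4, 2), 2, function(ij)
    d(feats[[ij[1]]][[1]], feats[[ij[2]]][[1]])))
  expect_gt(inter, intra)
})
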