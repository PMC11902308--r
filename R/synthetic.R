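# Synthetic multimodal gait generator.
#
# Emulates a treadmill-familiarized overground walking protocol: subjects walk
# a circular path at slow / moderate / fast speeds (3.5, 4.5, 6 km/h) for
# 1-minute trials while four synchronized streams are recorded on one clock:
# an RGB image stream (30 Hz), six-channel surface EMG (1111.111 Hz),
# visual-inertial odometry of the pelvis (200 Hz) and ground-truth joint
# angles (100 Hz). Joint-angle trajectories follow a subject-specific
# truncated Fourier series over the gait cycle; sEMG is a phase-locked
# activation envelope multiplying band-limited carrier noise; VIO advances
# along the circular path with step-frequency vertical bobbing; image frames
# are a sagittal stick-figure render driven by the same angles.

SPEEDS_KMH <- c(slow = 3.5, moderate = 4.5, fast = 6)
ANGLE_NAMES <- c("hip_L", "knee_L", "ankle_L", "hip_R", "knee_R", "ankle_R")
EMG_NAMES <- c("RF_L", "BF_L", "GA_L", "RF_R", "BF_R", "GA_R")

#' Generator configuration for the synthetic gait simulator
#'
#' Collects every distribution range, rate and noise level used by
#' [make_subject()], [simulate_trial()] and [make_cohort()]. Defaults emulate
#' the acquisition protocol the package targets: 30 Hz RGB, 1111.111 Hz
#' six-channel sEMG, 200 Hz pelvis VIO and 100 Hz reference joint angles,
#' 1-minute trials at 3.5/4.5/6 km/h on a circular path.
#'
#' @param image_size side length in pixels of the square RGB frames.
#' @param rates named list of sampling rates in Hz (image, emg, vio, angles).
#' @param offset_jitter,amp_scale,phase_jitter,cadence_scale,emg_gain
#'   two-element `c(min, max)` ranges for the subject-profile draws.
#' @param marker_offset range of the per-joint reference (marker-placement)
#'   offset in degrees: the motion-capture reference angles differ from the
#'   visually observable pose by a subject-specific constant per joint,
#'   emulating inter-session marker placement variability.
#' @param noise named list of noise SDs: `image` (pixel intensity, 0-1 scale),
#'   `emg` (additive sensor noise, envelope units), `vio` (position, metres;
#'   also yaw jitter in radians), `angle` (degrees).
#' @param stride_base,stride_slope gait-cycle (stride) frequency model:
#'   `stride_hz = cadence_scale * (stride_base + stride_slope * speed_kmh)`.
#' @param duty_base,duty_slope stance duty factor model:
#'   `duty = duty_base + duty_slope * speed_kmh` (fraction of the cycle).
#' @param path_radius_m radius of the circular walking path.
#' @param pelvis_height_m,pelvis_bob_m mean pelvis height and vertical
#'   oscillation amplitude (at step frequency, twice the stride frequency).
#' @param emg_band carrier band in Hz for the band-limited EMG noise.
#' @return a list of class `"gait_config"`.
#' @export
gait_config <- function(image_size = 64,
                        rates = list(image = 30, emg = 1111.111, vio = 200, angles = 100),
                        offset_jitter = c(-5, 5),
                        amp_scale = c(0.85, 1.15),
                        phase_jitter = c(-0.25, 0.25),
                        cadence_scale = c(0.9, 1.1),
                        emg_gain = c(0.7, 1.3),
                        marker_offset = c(-5, 5),
                        noise = list(image = 0.02, emg = 0.05, vio = 0.005, angle = 0),
                        stride_base = 0.55, stride_slope = 0.085,
                        duty_base = 0.68, duty_slope = -0.02,
                        path_radius_m = 2, pelvis_height_m = 1.0, pelvis_bob_m = 0.02,
                        emg_band = c(20, 450)) {
  cfg <- list(image_size = as.integer(image_size), rates = rates,
              offset_jitter = offset_jitter, amp_scale = amp_scale,
              phase_jitter = phase_jitter, cadence_scale = cadence_scale,
              emg_gain = emg_gain, marker_offset = marker_offset, noise = noise,
              stride_base = stride_base, stride_slope = stride_slope,
              duty_base = duty_base, duty_slope = duty_slope,
              path_radius_m = path_radius_m, pelvis_height_m = pelvis_height_m,
              pelvis_bob_m = pelvis_bob_m, emg_band = emg_band,
              # per-joint Fourier templates: rows hip/knee/ankle, 3 harmonics
              amp_template = rbind(hip = c(20, 4, 1),
                                   knee = c(15, 12, 4),
                                   ankle = c(8, 6, 2)),
              phase_template = rbind(hip = c(0.2, 1.0, 0),
                                     knee = c(-1.2, 0.5, 1.5),
                                     ankle = c(2.0, -0.8, 0.5)),
              offset_template = c(hip = 10, knee = 25, ankle = -5),
              # EMG activation template: cycle-phase centres/widths, left leg
              emg_centers = c(RF = 0.98, BF = 0.88, GA = 0.45),
              emg_widths = c(RF = 0.08, BF = 0.07, GA = 0.09),
              emg_base = 0.05)
  for (rg in list(cfg$offset_jitter, cfg$amp_scale, cfg$phase_jitter,
                  cfg$cadence_scale, cfg$emg_gain, cfg$marker_offset)) {
    if (length(rg) != 2 || rg[1] > rg[2]) stopf("config range must be c(min, max) with min <= max")
  }
  if (any(unlist(cfg$noise) < 0)) stopf("noise SDs must be >= 0")
  if (cfg$image_size %% 16 != 0) stopf("image_size must be divisible by 16")
  class(cfg) <- "gait_config"
  cfg
}

#' Draw a subject profile
#'
#' Deterministically samples one subject's gait characteristics from the
#' configured ranges: per-angle baseline offsets, per-joint Fourier harmonic
#' amplitudes and phases, a cadence multiplier and per-muscle EMG gains.
#'
#' @param seed non-negative integer; the same `(seed, config)` always returns
#'   a field-identical profile.
#' @param config a [gait_config()].
#' @return list of class `"subject_profile"`.
#' @export
make_subject <- function(seed, config = gait_config()) {
  if (!is_scalar_num(seed) || seed < 0) stopf("seed must be a non-negative number")
  stopifnot(inherits(config, "gait_config"))
  local_seed(seed, {
    runif2 <- function(n, rg) runif(n, rg[1], rg[2])
    tmpl_a <- config$amp_template[rep(1:3, 2), ]     # 6 angles x 3 harmonics
    tmpl_p <- config$phase_template[rep(1:3, 2), ]
    prof <- list(
      subject_id = sprintf("S%06d", as.integer(seed)),
      baseline_offsets = config$offset_template[rep(1:3, 2)] +
        runif2(6, config$offset_jitter),
      fourier_amps = tmpl_a * matrix(runif2(18, config$amp_scale), 6, 3),
      fourier_phases = tmpl_p + matrix(runif2(18, config$phase_jitter), 6, 3),
      cadence_scale = runif2(1, config$cadence_scale),
      emg_gain = runif2(6, config$emg_gain),
      marker_offsets = runif2(6, config$marker_offset),
      noise_levels = unlist(config$noise))
    names(prof$baseline_offsets) <- names(prof$marker_offsets) <- ANGLE_NAMES
    rownames(prof$fourier_amps) <- rownames(prof$fourier_phases) <- ANGLE_NAMES
    names(prof$emg_gain) <- EMG_NAMES
    stopifnot(all(is.finite(prof$fourier_amps)), all(prof$fourier_amps >= 0),
              prof$cadence_scale > 0)
    class(prof) <- "subject_profile"
    prof
  })
}

#' Stride (gait-cycle) frequency in Hz for a subject at a walking speed
#' @param profile a [make_subject()] profile.
#' @param speed_kmh walking speed in km/h.
#' @param config a [gait_config()].
#' @export
stride_hz <- function(profile, speed_kmh, config = gait_config()) {
  profile$cadence_scale * (config$stride_base + config$stride_slope * speed_kmh)
}

# Stance duty factor (fraction of the gait cycle in stance) at a given speed.
duty_factor <- function(speed_kmh, config) {
  config$duty_base + config$duty_slope * speed_kmh
}

#' Noiseless joint-angle trajectories of the Fourier gait model
#'
#' `theta_j(t) = offset_j + sum_h a_jh cos(2 pi h f t + phi_jh [+ h pi])`,
#' with the `h pi` term applied to right-side angles (half-cycle shift) and
#' `f` the subject's stride frequency at the given speed. This is the exact
#' deterministic decoder target in the noiseless limit.
#'
#' @inheritParams stride_hz
#' @param t numeric vector of times in seconds.
#' @return `length(t) x 6` matrix of angles in degrees
#'   (hip/knee/ankle, left then right).
#' @export
gait_angles <- function(profile, speed_kmh, t, config = gait_config()) {
  f <- stride_hz(profile, speed_kmh, config)
  out <- matrix(0, length(t), 6, dimnames = list(NULL, ANGLE_NAMES))
  for (j in 1:6) {
    th <- rep(profile$baseline_offsets[j], length(t))
    side_shift <- if (j > 3) pi else 0
    for (h in 1:3) {
      th <- th + profile$fourier_amps[j, h] *
        cos(2 * pi * h * f * t + profile$fourier_phases[j, h] + h * side_shift)
    }
    out[, j] <- th
  }
  out
}

#' Phase-locked sEMG activation envelope
#'
#' Deterministic per-muscle activation over the gait cycle: a baseline plus a
#' Gaussian bump at a muscle-specific cycle phase (RF near terminal
#' swing/loading, BF near late swing, GA near late stance), right leg shifted
#' by half a cycle, scaled by the subject's per-channel gain. Exactly periodic
#' with period `1 / stride_hz()`.
#'
#' @inheritParams gait_angles
#' @return `length(t) x 6` matrix (RF/BF/GA, left then right).
#' @export
emg_envelope <- function(profile, speed_kmh, t, config = gait_config()) {
  f <- stride_hz(profile, speed_kmh, config)
  phi <- (f * t) %% 1
  out <- matrix(0, length(t), 6, dimnames = list(NULL, EMG_NAMES))
  for (c in 1:6) {
    m <- ((c - 1) %% 3) + 1
    ph <- if (c > 3) (phi + 0.5) %% 1 else phi
    d <- abs(ph - config$emg_centers[m])
    d <- pmin(d, 1 - d)                      # circular distance on the cycle
    out[, c] <- profile$emg_gain[c] *
      (config$emg_base + exp(-0.5 * (d / config$emg_widths[m])^2))
  }
  out
}

# One modality's samples for a window, with rate and channel metadata.
modality_stream <- function(modality, samples, rate, t0 = 0) {
  structure(list(modality = modality, samples = samples, rate = rate, t0 = t0),
            class = "modality_stream")
}

#' @export
print.modality_stream <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<modality_stream '%s'> %s @ %.3f Hz, t0 = %.1f s\n",
              x$modality, paste(d, collapse = "x"), x$rate, x$t0))
  invisible(x)
}

n_samples_for <- function(rate, duration_s) round(rate * duration_s)

speed_class_of <- function(speed_kmh) {
  if (speed_kmh < 4) "slow" else if (speed_kmh < 5) "moderate" else "fast"
}

# Rasterize one sagittal stick-figure frame into an S x S x 3 intensity array
# (values 0-1): left leg in the red channel, right leg in green, pelvis marker
# in blue. Points sampled along each limb segment are splatted with a small
# Gaussian brush, so limb positions are encoded with sub-pixel (anti-aliased)
# intensity rather than binary lines.
render_frame <- function(chains, S) {
  img <- array(0, c(S, S, 3))
  npts <- S
  sgrid <- seq(0, 1, length.out = npts)
  offs_r <- rep(-1:1, times = 3)
  offs_c <- rep(-1:1, each = 3)
  splat <- function(pr, pc) {
    n <- length(pr)
    rr <- round(pr); cc <- round(pc)
    r0 <- rep(rr, 9) + rep(offs_r, each = n)
    c0 <- rep(cc, 9) + rep(offs_c, each = n)
    w <- exp(-((r0 - pr)^2 + (c0 - pc)^2) / (2 * 0.7^2))
    keep <- r0 >= 1 & r0 <= S & c0 >= 1 & c0 <= S
    idx <- r0[keep] + (c0[keep] - 1L) * S
    w <- w[keep]
    ord <- order(w)                # ascending: the final write is the max
    m <- matrix(0, S, S)
    m[idx[ord]] <- w[ord]
    m
  }
  for (leg in 1:2) {
    ch <- chains[[leg]]                       # 4 x 2: hip, knee, ankle, toe
    px <- numeric(3 * npts); py <- numeric(3 * npts)
    for (seg in 1:3) {
      a <- ch[seg, ]; b <- ch[seg + 1, ]
      i <- ((seg - 1) * npts + 1):(seg * npts)
      px[i] <- a[1] + sgrid * (b[1] - a[1])
      py[i] <- a[2] + sgrid * (b[2] - a[2])
    }
    img[, , leg] <- splat((1.6 - py) / 1.6 * (S - 1) + 1,
                          (px + 0.8) / 1.6 * (S - 1) + 1)
  }
  hp <- chains[[1]][1, ]
  img[, , 3] <- splat((1.6 - hp[2]) / 1.6 * (S - 1) + 1,
                      (hp[1] + 0.8) / 1.6 * (S - 1) + 1)
  img
}

# Leg-chain joint coordinates (hip, knee, ankle, toe) from the three sagittal
# angles in degrees; hip pinned at (0, hip_y).
leg_chain <- function(hip_deg, knee_deg, ankle_deg, hip_y) {
  d2r <- pi / 180
  lt <- 0.42; ls <- 0.43; lf <- 0.15
  a_th <- hip_deg * d2r
  a_sh <- (hip_deg - knee_deg) * d2r
  a_ft <- (hip_deg - knee_deg + 90 + ankle_deg) * d2r
  hip <- c(0, hip_y)
  knee <- hip + lt * c(sin(a_th), -cos(a_th))
  ankle <- knee + ls * c(sin(a_sh), -cos(a_sh))
  toe <- ankle + lf * c(sin(a_ft), -cos(a_ft))
  rbind(hip, knee, ankle, toe)
}

#' Simulate one synchronized multimodal walking trial
#'
#' All four streams are generated from one clock and one subject-specific
#' Fourier gait model: ground-truth angles at 100 Hz, sEMG as activation
#' envelope x band-limited carrier noise plus sensor noise at 1111.111 Hz,
#' pelvis VIO (3-D position + unit yaw quaternion) along a circular path at
#' 200 Hz, and 30 Hz stick-figure RGB frames driven by the same angles.
#' Each trial starts at a random point of the gait cycle (recordings are not
#' synchronized to heel strike); the stance/swing mask still references heel
#' strike at cycle phase 0. The reference angle stream includes the subject's
#' constant marker-placement offsets, the other streams do not -- adapting a
#' model to a new subject therefore has an irreducible subject-specific
#' component, as in real motion-capture references.
#'
#' @param profile a [make_subject()] profile.
#' @param speed_kmh walking speed in km/h (> 0).
#' @param duration_s trial duration in seconds (> 0), nominally 60.
#' @param direction `"ccw"` or `"cw"` around the circular path.
#' @param seed integer; identical arguments reproduce bit-identical streams.
#' @param config a [gait_config()].
#' @return list of class `"gait_trial"` with `$streams` (image, emg, vio),
#'   `$angles` (the ground-truth stream), `$phase` (per-angle-sample
#'   stance/swing mask) and trial metadata.
#' @export
simulate_trial <- function(profile, speed_kmh, duration_s = 60,
                           direction = c("ccw", "cw"), seed = 0,
                           config = gait_config()) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "gait_config"))
  if (!is_scalar_num(speed_kmh) || speed_kmh <= 0) stopf("speed_kmh must be > 0")
  if (!is_scalar_num(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  direction <- match.arg(direction)
  rs <- config$rates
  nz <- profile$noise_levels
  f <- stride_hz(profile, speed_kmh, config)
  local_seed(seed, {
    # recording starts at an arbitrary point of the gait cycle
    phase0 <- runif(1)
    tshift <- phase0 / f

    # reference angles (100 Hz): the motion-capture ground truth carries the
    # subject's constant per-joint marker-placement offset, which is not
    # observable in the image / sEMG / VIO streams
    Ta <- n_samples_for(rs$angles, duration_s)
    ta <- (seq_len(Ta) - 1) / rs$angles
    ang <- gait_angles(profile, speed_kmh, ta + tshift, config)
    ang <- ang + rep(profile$marker_offsets, each = Ta)
    if (nz["angle"] > 0) ang <- ang + matrix(rnorm(length(ang), sd = nz["angle"]), nrow(ang))
    phase <- ifelse((f * ta + phase0) %% 1 < duty_factor(speed_kmh, config), "stance", "swing")

    # sEMG (1111.111 Hz): envelope x band-limited carrier + sensor noise
    Te <- n_samples_for(rs$emg, duration_s)
    te <- (seq_len(Te) - 1) / rs$emg
    env <- emg_envelope(profile, speed_kmh, te + tshift, config)
    bf <- signal::butter(4, config$emg_band / (rs$emg / 2), type = "pass")
    carrier <- apply(matrix(rnorm(Te * 6), Te, 6), 2,
                     function(w) as.numeric(signal::filter(bf, w)))
    emg <- env * carrier
    if (nz["emg"] > 0) emg <- emg + matrix(rnorm(Te * 6, sd = nz["emg"]), Te, 6)
    colnames(emg) <- EMG_NAMES

    # VIO (200 Hz): circular path, step-frequency bob, tangent-aligned yaw
    Tv <- n_samples_for(rs$vio, duration_s)
    tv <- (seq_len(Tv) - 1) / rs$vio
    v_ms <- speed_kmh / 3.6
    om <- (v_ms / config$path_radius_m) * if (direction == "ccw") 1 else -1
    alpha <- om * tv
    z <- config$pelvis_height_m + config$pelvis_bob_m * sin(2 * pi * 2 * f * (tv + tshift))
    pos <- cbind(config$path_radius_m * cos(alpha),
                 config$path_radius_m * sin(alpha), z)
    if (nz["vio"] > 0) pos <- pos + matrix(rnorm(Tv * 3, sd = nz["vio"]), Tv, 3)
    yaw <- alpha + (pi / 2) * sign(om)
    if (nz["vio"] > 0) yaw <- yaw + rnorm(Tv, sd = nz["vio"])
    vio <- cbind(pos, cos(yaw / 2), 0, 0, sin(yaw / 2))
    colnames(vio) <- c("x", "y", "z", "qw", "qx", "qy", "qz")

    # image stream (30 Hz): sagittal stick-figure render of the same angles
    Ti <- n_samples_for(rs$image, duration_s)
    ti <- (seq_len(Ti) - 1) / rs$image
    ang_i <- gait_angles(profile, speed_kmh, ti + tshift, config)
    hip_y <- 0.9 + config$pelvis_bob_m * sin(2 * pi * 2 * f * (ti + tshift))
    S <- config$image_size
    frames <- array(as.raw(0), c(S, S, 3, Ti))
    img_noise <- nz["image"]
    for (k in seq_len(Ti)) {
      chains <- list(leg_chain(ang_i[k, 1], ang_i[k, 2], ang_i[k, 3], hip_y[k]),
                     leg_chain(ang_i[k, 4], ang_i[k, 5], ang_i[k, 6], hip_y[k]))
      fr <- render_frame(chains, S)
      if (img_noise > 0) fr <- fr + array(rnorm(length(fr), sd = img_noise), dim(fr))
      frames[, , , k] <- as.raw(pmin(pmax(round(fr * 255), 0), 255))
    }

    trial <- list(
      streams = list(image = modality_stream("image", frames, rs$image),
                     emg = modality_stream("emg", emg, rs$emg),
                     vio = modality_stream("vio", vio, rs$vio)),
      angles = modality_stream("angles", ang, rs$angles),
      phase = phase,
      subject_id = profile$subject_id,
      speed_kmh = speed_kmh, speed_class = speed_class_of(speed_kmh),
      direction = direction, duration_s = duration_s, seed = seed,
      stride_hz = f, phase0 = phase0)
    class(trial) <- "gait_trial"
    trial
  })
}

#' Convert one stored image frame to a numeric array
#' @param stream an image `modality_stream`.
#' @param i frame index.
#' @return `H x W x 3` numeric array on the 0-1 scale.
#' @export
frame_as_array <- function(stream, i) {
  fr <- stream$samples[, , , i]
  array(as.integer(fr), dim(fr)) / 255
}

#' Cut a trial into fixed-length multimodal clips
#'
#' Non-overlapping consecutive 10-s windows by default; a trailing remainder
#' shorter than `clip_s` is dropped. Each clip carries every modality over the
#' same wall-clock window (exactly `round(rate * clip_s)` samples per stream),
#' the ground-truth angles, the stance/swing phase mask, and its task labels
#' (subject, speed class, direction). A trial shorter than `clip_s` yields an
#' empty list with a warning.
#'
#' @param trial a [simulate_trial()] result.
#' @param clip_s clip length in seconds (default 10; one clip = one "shot").
#' @param offset start of the first window in seconds from the trial start
#'   (default 0; used for window-jittered training augmentation).
#' @return list of `"multimodal_clip"` objects.
#' @export
segment_clips <- function(trial, clip_s = 10, offset = 0) {
  stopifnot(inherits(trial, "gait_trial"))
  if (!is_scalar_num(clip_s) || clip_s <= 0) stopf("clip_s must be > 0")
  n <- floor((trial$duration_s - offset) / clip_s)
  if (n < 1) {
    warning("trial shorter than clip_s; returning no clips")
    return(list())
  }
  take <- function(stream, k) {
    ns <- n_samples_for(stream$rate, clip_s)
    i0 <- round(((k - 1) * clip_s + offset) * stream$rate)
    idx <- i0 + seq_len(ns)
    s <- stream$samples
    sub <- if (length(dim(s)) == 4) s[, , , idx, drop = FALSE] else s[idx, , drop = FALSE]
    modality_stream(stream$modality, sub, stream$rate, t0 = (k - 1) * clip_s + offset)
  }
  lapply(seq_len(n), function(k) {
    na <- n_samples_for(trial$angles$rate, clip_s)
    ia <- round(((k - 1) * clip_s + offset) * trial$angles$rate) + seq_len(na)
    clip <- list(
      streams = list(image = take(trial$streams$image, k),
                     emg = take(trial$streams$emg, k),
                     vio = take(trial$streams$vio, k)),
      angles = take(trial$angles, k),
      phase = trial$phase[ia],
      subject_id = trial$subject_id,
      speed_kmh = trial$speed_kmh, speed_class = trial$speed_class,
      direction = trial$direction, clip_s = clip_s,
      t0 = (k - 1) * clip_s + offset)
    class(clip) <- "multimodal_clip"
    clip
  })
}

#' @export
print.multimodal_clip <- function(x, ...) {
  cat(sprintf("<multimodal_clip> subject %s, %s (%.1f km/h), t0 = %.0f s, %.0f s\n",
              x$subject_id, x$speed_class, x$speed_kmh, x$t0, x$clip_s))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Per subject: `trials_per_speed` trials at each of the three walking speeds
#' (3.5, 4.5, 6 km/h), alternating path direction, each lasting `duration_s`.
#' The default protocol (4 trials per speed, 1-minute trials) gives 12 trials
#' and 72 ten-second clips per subject.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_speed trials at each speed (default 4).
#' @param seed cohort master seed; all subject and trial seeds derive from it.
#' @param config a [gait_config()].
#' @param duration_s trial duration in seconds (default 60).
#' @return list of class `"gait_cohort"`.
#' @export
make_cohort <- function(n_subjects, trials_per_speed = 4, seed = 1,
                        config = gait_config(), duration_s = 60) {
  if (!is_scalar_num(n_subjects) || n_subjects < 1) stopf("n_subjects must be >= 1")
  subj_seeds <- derive_seeds(seed, n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    profile <- make_subject(subj_seeds[i], config)
    tseeds <- derive_seeds(subj_seeds[i] + 1L, 3L * trials_per_speed)
    trials <- vector("list", 3L * trials_per_speed)
    k <- 0L
    for (sp in SPEEDS_KMH) {
      for (r in seq_len(trials_per_speed)) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(profile, sp, duration_s,
                                      direction = if (k %% 2 == 1) "ccw" else "cw",
                                      seed = tseeds[k], config = config)
      }
    }
    subjects[[i]] <- list(profile = profile, trials = trials)
  }
  structure(list(config = config, seed = seed, n_subjects = n_subjects,
                 trials_per_speed = trials_per_speed, duration_s = duration_s,
                 subjects = subjects),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  nt <- sum(vapply(x$subjects, function(s) length(s$trials), integer(1)))
  cat(sprintf("<gait_cohort> %d subjects, %d trials (%d per speed x 3 speeds), %.0f-s trials, seed %d\n",
              x$n_subjects, nt, x$trials_per_speed, x$duration_s, x$seed))
  invisible(x)
}

#' All clips of a cohort
#' @param cohort a [make_cohort()] result.
#' @param clip_s clip length in seconds.
#' @return flat list of `multimodal_clip`s across all subjects and trials.
#' @export
cohort_clips <- function(cohort, clip_s = 10) {
  stopifnot(inherits(cohort, "gait_cohort"))
  per_trial <- unlist(lapply(cohort$subjects, function(s)
    lapply(s$trials, segment_clips, clip_s = clip_s)), recursive = FALSE)
  do.call(c, per_trial)
}

#' All trials of a cohort (flat list)
#' @param cohort a [make_cohort()] result.
#' @export
cohort_trials <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  unlist(lapply(cohort$subjects, `[[`, "trials"), recursive = FALSE)
}

#' Write / read a cohort losslessly
#'
#' The cohort is serialized to a single RDS file with the generator
#' configuration embedded as YAML for provenance; [read_cohort()] restores a
#' clip-wise identical object.
#' @param cohort a `gait_cohort`.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "gait_cohort"))
  attr(cohort, "config_yaml") <- yaml::as.yaml(unclass(cohort$config))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "gait_cohort")) stopf("'%s' does not contain a gait_cohort", path)
  x
}

#' Export ground-truth angles as a tidy CSV
#'
#' One row per (time, angle): columns subject, trial, speed_kmh, time_s,
#' joint, side, angle_deg.
#' @param cohort a `gait_cohort`.
#' @param path output CSV path.
#' @export
export_angles_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- list()
  for (s in cohort$subjects) {
    for (ti in seq_along(s$trials)) {
      tr <- s$trials[[ti]]
      ang <- tr$angles$samples
      t_s <- (seq_len(nrow(ang)) - 1) / tr$angles$rate
      for (j in seq_len(ncol(ang))) {
        parts <- strsplit(colnames(ang)[j], "_")[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = tr$subject_id, trial = ti, speed_kmh = tr$speed_kmh,
          time_s = t_s, joint = parts[1], side = parts[2], angle_deg = ang[, j])
      }
    }
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
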