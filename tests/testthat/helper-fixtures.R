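# Shared fixtures, built once per test run. Everything is generated in code
# at desk scale (32-px frames, short trials) so the whole suite stays fast.

mg <- asNamespace("metagait")

test_gen <- function(noiseless = FALSE, ...) {
  if (noiseless)
    gait_config(image_size = 32,
                noise = list(image = 0, emg = 0, vio = 0, angle = 0), ...)
  else gait_config(image_size = 32, ...)
}

test_cfg <- function(...) tiny_pose_config(...)

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# One 30-s trial at moderate speed (shared by many tests).
fx_trial <- function() fixture("trial", function() {
  simulate_trial(make_subject(3, test_gen()), 4.5, duration_s = 30,
                 seed = 5, config = test_gen())
})

# A tiny 2-subject cohort: 1 trial per speed, 30-s trials.
fx_cohort <- function() fixture("cohort", function() {
  make_cohort(2, trials_per_speed = 1, seed = 7, config = test_gen(),
              duration_s = 30)
})

fx_clips <- function() fixture("clips", function() cohort_clips(fx_cohort()))

# An untrained model matching the fixtures.
fx_model <- function() fixture("model", function() init_pose_model(test_cfg(), seed = 1))

# One 10-s clip.
fx_clip <- function() fixture("clip", function() segment_clips(fx_trial())[[1]])

# Central-difference gradient of f at x[idx].
num_grad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
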