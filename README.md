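# metagait

Meta-transfer learning for lower-limb joint-angle estimation from
synchronized multimodal gait recordings, with a built-in synthetic
multimodal gait simulator.

## The problem

Wearable interaction systems (exoskeletons, rehabilitation monitors,
cooperative robots) need continuous estimates of the six lower-limb joint
angles — hip, knee and ankle of both legs — from the sensors a person can
actually wear: a camera, surface EMG electrodes and a pelvis-mounted
visual-inertial odometry (VIO) unit. A model pre-trained on a cohort
degrades on a new person, because motion patterns, muscle gains and the
motion-capture reference itself (marker placement) are subject-specific.
`metagait` implements a three-stage remedy:

1. **Pre-training.** Per-modality encoders — a CBAM-ResNet12 backbone for
   the 30 Hz image stream (four residual blocks, each three convolutions, a
   channel+spatial attention module and a max-pool), transformer encoders
   for the ~1111 Hz six-channel sEMG and the 200 Hz VIO stream — produce
   clip-level features `r_m = X*(I_m)`. Knowledge-sharing transforms
   `r~_m = f_m(r_m)` map them into one space, trained with the pairwise
   alignment loss `L_KS = sum_(k!=t) m_k m_t ||r~_k − r~_t||_2` (trainable
   positive normalizers `m`). A three-branch convolutional fusion network
   produces the fused feature `k`, and a decoder regresses the joint-angle
   trajectory; the pose loss is the mean squared error
   `L_PE = (1/N) sum_i (y_i − y^_i)^2` over the `N = 6` angles.
2. **Meta-transfer.** The pre-trained weights are frozen; scale/shift
   modulation parameters `ML(W, b) = (W*γw, b + γb)` are trained
   episodically: per N-way K-shot episode, an inner loop fine-tunes the
   modulation on the support set with `L_T = (1/(N·K)) Σ L_MSE`, and the
   shared initialization is updated from the query loss (first order).
3. **Meta-adaptation.** For a new subject, the same inner loop runs on K
   ten-second support clips ("shots"); the adapted task model is evaluated
   by RMSE in degrees on disjoint query clips.

Because the dataset the method targets is not public, the package ships a
**synthetic gait generator**: subject-specific truncated-Fourier joint
trajectories, phase-locked sEMG envelopes on band-limited carrier noise,
circular-path pelvis VIO with unit quaternions, stick-figure image frames —
all hard-synchronized, multi-rate (30/1111.111/200/100 Hz), with
per-subject marker-placement offsets in the reference angles so that
intra-subject adaptation has something real to correct.

## Worked example

```r
library(metagait)

gen <- gait_config(image_size = 32)            # desk-scale rendering
cohort <- make_cohort(n_subjects = 8, trials_per_speed = 1, seed = 1,
                      config = gen)
split <- split_cohort(cohort, holdout = 2, seed = 2)

model <- pretrain(split$pretrain_trials, tiny_pose_config(),
                  epochs = c(8, 0), seed = 3)
model
#> <pose_model> modalities: image+emg+vio | knowledge sharing: on
#>   32 px frames x3, transformer d=32, shared D=32, 185918 parameters
#>   trained: 8 epochs + ridge head, final L_PE 175.71

meta <- meta_train(model, split$pretrain_clips, episodes = 5,
                   K = 5, Q = 5, seed = 4)

fs <- few_shot_eval(model, meta, split$holdout_clips,
                    shots = c(0, 1, 5), seed = 5)
aggregate(rmse_deg ~ shots, fs, mean)
#>   shots  rmse_deg
#> 1     0  9.524033
#> 2     1 11.650111
#> 3     5 11.533901
```

The table reports pooled RMSE in degrees over the six joint angles on the
held-out subjects' query clips: row `0` is the unadapted pre-trained model,
rows `1` and `5` the model after 1-shot and 5-shot adaptation (each shot is
one 10-second clip). At this desk scale the pre-trained model tracks a new
subject's pose to ~10°, and few-shot adaptation does not improve on it:
the subject-systematic part of the error (the ±5° marker-placement
offsets) is a minor share of the desk-scale tracking error, so the support
gradient is dominated by phase noise — see the methods vignette for the
quantitative analysis and for why this reverses at realistic (1–2°)
operating accuracy.

`evaluate_model()` breaks an evaluation down by joint, walking speed and
stance/swing phase; `run_ablation()` reproduces the modality-subset and
knowledge-sharing-versus-concatenation comparisons; `run_experiment()` runs
the whole simulate → pretrain → meta-train → adapt → evaluate pipeline from
one seeded config. A command-line wrapper with `simulate`, `validate`,
`pretrain`, `metatrain`, `adapt`, `evaluate` and `experiment` subcommands is
installed at `inst/cli/metagait.R`.

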