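---
title: "Models and methods behind metagait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metagait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metagait` estimates the six lower-limb joint angles (hip, knee, ankle of
both legs, in degrees) from three synchronized wearable-sensor streams and
adapts that estimator to a new person from a handful of 10-second clips.
This vignette explains the synthetic data model, the network, the losses,
the meta-learning procedure, the numerical choices, and — importantly —
what the desk-scale experiments in the test suite do and do not demonstrate.

## 1. The synthetic multimodal gait model

No public dataset combines RGB video, six-channel surface EMG and pelvis
VIO with motion-capture reference angles, so the package generates its own
cohorts with known ground truth. The generator emulates a standard gait-lab
protocol: each subject walks a circular path (radius 2 m) at 3.5, 4.5 and
6 km/h, several 1-minute trials per speed, all streams on one clock.

**Joint angles.** Each angle follows a truncated Fourier series over the
gait cycle,

$$\theta_j(t) = o_j + \sum_{h=1}^{3} a_{jh}\cos(2\pi h f t + \phi_{jh}),$$

with right-side angles shifted by half a cycle. Three harmonics suffice to
produce the characteristic biphasic knee and ankle patterns. The stride
frequency is `f = cadence_scale * (0.55 + 0.085 * speed_kmh)` Hz, giving
0.85–1.06 Hz over the speed range, and the stance fraction of the cycle
decreases linearly with speed (0.61 at 3.5 km/h to 0.56 at 6 km/h), inside
the physiological 0.55–0.65 band. A subject is a draw of per-angle baseline
offsets (template ± 5°), harmonic amplitude scales (±15%), harmonic phase
jitter (±0.25 rad), a cadence multiplier (±10%) and per-muscle EMG gains
(±30%). Every trial starts at a uniformly random point of the gait cycle —
recordings are not synchronized to heel strike — which matters: without it
a cohort exposes only a handful of distinct clip phases and phase
generalization cannot be assessed at all.

**Marker-placement offsets.** The reference (motion-capture) angles carry a
per-subject, per-joint constant offset drawn from U(−5°, 5°), *not*
reflected in the image, sEMG or VIO streams. This emulates inter-session
marker placement variability, whose reported magnitude in gait analysis is
a few degrees per joint. It is what makes intra-subject adaptation a
well-posed problem in the simulator: a model that reads the inputs
perfectly still carries an irreducible subject-specific bias against the
reference until it has seen a few labelled clips of that subject. (In an
earlier version of the generator without this term, a well-trained model
generalized essentially perfectly to unseen subjects and few-shot
adaptation had nothing systematic left to correct.)

**sEMG.** Each of the six channels (rectus femoris, biceps femoris,
gastrocnemius, both legs) is a phase-locked activation envelope — a
baseline plus a Gaussian bump at a muscle-specific cycle phase (RF near
terminal swing/loading, BF near late swing, GA near late stance), the right
leg shifted half a cycle — multiplied by zero-mean Gaussian carrier noise
band-limited to 20–450 Hz at the 1111.111 Hz sampling rate, plus additive
sensor noise. The envelope, not the interference pattern, carries the
information; physiological fidelity beyond the timing template is a
non-goal.

**VIO.** Pelvis position advances along the circular path at the walking
speed with a 2 cm vertical oscillation at step frequency (twice the stride
frequency); the orientation quaternion follows the path tangent. Position
and yaw carry small Gaussian noise; quaternions stay exactly unit-norm.

**Images.** 30 Hz RGB frames render a sagittal stick figure (thigh, shank,
foot of both legs, fixed camera) driven by the same angle trajectories,
left leg in the red channel, right leg in green, a pelvis marker in blue.
Points along each limb are splatted with a small Gaussian brush, so limb
positions are encoded with sub-pixel intensity rather than binary lines —
at 32–64 px this roughly doubles how well a linear probe can read the pose
from convolutional features. Frames are stored as 8-bit rasters to keep a
full cohort in memory.

What the generator deliberately does *not* model: soft-tissue artifact
dynamics, camera perspective and occlusion, EMG crosstalk between muscles,
non-steady gait (turns, stops), or treadmill familiarization. Conclusions
from the test suite therefore speak to the pipeline's mechanics — losses,
training, adaptation protocol, reproducibility — not to clinical accuracy.

## 2. The estimation model

The unit of processing is a 10-second multimodal clip (one "shot"). The
model output is the pose trajectory over the final second of the clip
(default 10 time points × 6 angles): the clip is context and the estimate
refers to the current instant, matching the real-time framing of the
method. An earlier whole-clip formulation (predict all 10 s on an absolute
grid) was abandoned: a 10-s absolute-time trajectory depends on
`cos(2π h f t)` with `t` up to 10, so predictions become hypersensitive to
the subject's exact stride frequency, and accuracy cannot transfer across
cadences even in principle.

**Encoders.** The image stream is uniformly subsampled to a few frames
(default 8, desk preset 3) which pass independently through the
CBAM-ResNet12 backbone — four residual blocks of three 3×3 convolutions
each, a 1×1 shortcut, channel attention (sigmoid of a shared two-layer
bottleneck applied to average- and max-pooled channel descriptors,
reduction 8), spatial attention (7×7 convolution of the channel-wise mean
and max maps), 2×2 max-pooling — then global average pooling; frame
features are averaged. The sEMG stream is converted to its average
rectified value (rectify, window-mean) before tokenization — decimating raw
EMG would alias the 20–450 Hz band into noise — and the VIO stream is
decimated; both are cut into fixed-length tokens, linearly projected,
given sinusoidal positional encodings, and passed through a post-norm
transformer (desk preset: 1 layer, 4 heads, d_model 32) whose output tokens
are mean-pooled.

**Knowledge sharing.** Per-modality affine transforms map the encoder
features to a shared dimension D (default 64, desk 32). The alignment loss
is the pairwise Euclidean distance between transformed features, each pair
weighted by the product of two per-modality trainable positive normalizers
(exp-parameterized). The transform is affine (no nonlinearity): identity
initialization then reproduces its input exactly, and the encoders already
supply the nonlinearity.

**Fusion.** The aligned features are stacked as a *sequence of one position
per modality* with D channels; three branches of 1, 2 and 3 blocks (1-D
convolution, normalization, leaky ReLU) process it and are globally
average-pooled over positions; the three pooled vectors concatenate into
`k`. The alternative reading — one long single-channel sequence — was
measured to be degenerate: global average pooling after a stride-1
convolution collapses it to (almost) the sequence mean, and the fused
feature carried no clip information. In the concatenation ("nKS") ablation
the raw encoder features are stacked zero-padded instead and the alignment
loss is dropped.

**Decoder.** A 1-D convolution block over `k`, ReLU, dropout, then a fully
connected regression head. The head works against per-joint standardized
targets: frozen center/scale constants (the training targets' per-joint
mean and SD in degrees) form an output calibration layer,
`out = z * scale + center`. Predictions are always in degrees.

**Normalization.** All convolutional-block normalizations use frozen
running statistics: warm-up sweeps over a few clips propagate sensible
per-channel moments down the layer stack, the first training epoch tracks
them with a small EMA, then they freeze. Per-example (instance) statistics
were measurably destructive here — training is clip-at-a-time, and
normalizing each clip by its own statistics removed exactly the
cross-clip differences the decoder needs. Transformer LayerNorm is
standard. Standardized activations are clamped at ±50, which only ever
binds while the statistics are warming up.

## 3. Training

**Stage A** trains everything end to end on `L_KS + λ·L_PE` with λ = 1,
Adam at 1e-3, global gradient-norm clip 5, one clip per step. The pose term
is the anti-collapse counterweight to the alignment loss (whose global
minimum is all-constant features); because the pose loss is in squared
degrees (~150 at initialization) while the alignment loss is order 5, a
small λ lets the alignment gradient dominate and collapse the transforms —
observed directly — so λ = 1. Each epoch re-cuts the training trials at a
random window offset ("window jittering"), so successive epochs see fresh
gait phases; validation always uses the canonical non-overlapping
segmentation of held-out *trials*.

**Stage B** freezes encoders, transforms and normalizers. The fusion and
decoder convolutions may take further SGD epochs (cached aligned features
make these cheap; default 0), and the linear regression head is then fitted
in closed form: it is linear in its inputs, so its optimum is a ridge
solution, with the penalty chosen on the validation split from
{1, 3, 10, 30, 100}. Clip-at-a-time Adam cannot reach that optimum in any
reasonable step budget (its per-step movement is bounded by the learning
rate), which is why the head is estimated rather than iterated. The ridge
design matrix includes extra jittered segmentations of the training trials.

**Meta-transfer.** The modulation set is: a scale per output channel and a
shift per bias element of every encoder and fusion weight, plus a per-joint
scale/shift on the decoder's output calibration layer (the output layer's
"channels" are the six joints, so this is the same scale/shift rule applied
at the natural output granularity). The inner loop is full-batch plain
gradient descent (10 steps, 1e-2, global clip) on the support loss; plain
SGD matters because an adaptive inner optimizer moves *every* modulation
scale by roughly the learning rate regardless of its gradient, which
measurably damaged the model for K ≤ 5. By default the decoder's bias
vectors are fine-tuned alongside the modulation ("bias" mode); fully
fine-tuning the 10⁴–10⁵ head weights on 1–5 clips overfits badly and is
available as the "full" switch. The outer loop updates the shared
initialization with the first-order query gradient (Adam, 1e-3).

**Meta-adaptation** runs the same inner loop on a new task's support set
only; the pre-trained weights are never touched (verified element-wise in
the tests).

## 4. What the desk-scale experiments show — and what they cannot

The acceptance suite runs the full pipeline at a reduced scale: 32 px
frames, 3 frames per clip, d_model 32, 6 training + 2 held-out subjects,
one trial per speed, a few epochs and episodes (sizes chosen so the whole
suite runs in minutes on one CPU; the vignette states them as the package's
choices). At this scale:

* **Learnability** is comfortably demonstrated: on a noiseless
  single-subject cohort, pretraining halves the validation RMSE relative to
  the untrained model (typically ~20° → ~8–10°).
* **Cross-subject transfer** works: the pre-trained model tracks unseen
  subjects' pose at roughly the same RMSE as held-out trials of training
  subjects.
* **Few-shot adaptation effect sizes do not survive the scale-down.** The
  adaptable, subject-systematic error is the marker-offset RMS (~2.9°).
  With a desk-scale base RMSE of 6–11°, the phase-tracking noise in a
  5-shot support estimate caps the attainable relative reduction at a few
  percent (support residuals within a clip are strongly correlated, so the
  effective sample size is the number of clips, not samples). A ≥10%
  reduction would need a base RMSE around 4°, outside the tiny
  architecture's reach. The corresponding acceptance checks are asserted at
  their stated thresholds and are expected to fail at desk scale; they
  document the gap rather than hiding it. At the method's intended
  operating point (base RMSE 1–2°, where the subject-systematic component
  dominates), the same machinery is exactly what removes it.
* The **knowledge-sharing vs concatenation** comparison is likewise a
  small-effect contrast at this scale and is reported as measured.

## 5. Numerical and design choices

* Weight initialization: He-scaled Gaussians for convolutions and ReLU
  layers, unit-gain for linear maps; all draws seeded.
* Determinism: every public entry point takes a seed; seeds for sub-steps
  are derived from it; a private RNG scope leaves the caller's stream
  untouched. Single-device reproducibility is the contract.
* Degenerate inputs: trials shorter than a clip yield an empty clip list
  with a warning; a VIO-only model is rejected (no spatial context);
  episode sampling names the shortfall when a task has too few clips;
  non-finite losses abort training with a diagnostic.
* Tie-breaks: max-pooling and attention argmaxes take the first maximum;
  the alignment-loss gradient at exactly coincident features is defined
  as zero.
* The cohort interchange format is a single RDS file with the generator
  configuration embedded as YAML, plus a tidy CSV export for the reference
  angles. Image frames are stored as raw 8-bit arrays.
* Evaluation pools squared errors over joints and samples before taking
  the root; per-joint, per-speed and per-phase breakdowns come from the
  same residual sums, so the pooled value is exactly recomputable from a
  report.

## 6. Known limitations

Hand-written gradients restrict the architecture to the implemented layer
set; there is no GPU path; second-order meta-gradients are not implemented
(first-order updates only); the generator's subject space is a parametric
family, so "new subject" means new parameters of a known family — a much
easier transfer problem than a new human; and the desk-scale adaptation
results above should not be read as a measurement of the method's few-shot
benefit at realistic accuracy levels.
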