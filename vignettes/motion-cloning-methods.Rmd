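---
title: "Synthetic motion cloning and shoulder-elbow synergy decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic motion cloning and shoulder-elbow synergy decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

People with an amputation above the elbow lose voluntary elbow flexion and
forearm pronation. One control strategy for a powered prosthetic elbow is to
exploit the inter-joint synergy of natural reaching: shoulder and elbow
motion are tightly coordinated, so a regression model can predict the elbow
angles a person *would* have used from the shoulder angles they still
produce. Training such a decoder needs many repetitions of reaching
movements from many people — data that are expensive to record.

This package implements a motion-cloning alternative: a simulated 7-DOF arm
learns the same reaching task by reinforcement learning, synthetic
joint-angle data are extracted from the trained policy, and the decoder is
trained on cloned, human, or mixed data. Because no public motion-capture
dataset accompanies the protocol, the package also contains a fully
specified surrogate-subject generator that emulates a panel of six
participants, so every experiment in the package is reproducible from code
alone.

## The arm model

`arm_model()` builds a three-segment chain — upper arm 0.30 m, forearm
0.25 m, hand 0.18 m (typical adult anthropometry; all configurable) — with a
3-DOF shoulder (flexion, abduction, internal rotation), a 2-DOF elbow
(flexion, pronation) and a 2-DOF wrist (flexion, abduction). The endpoint is
the fingertip; the palm normal is the hand's flat-side normal.

Frames are right-handed: x forward, y left, z up; the zero pose is the arm
extended along +x with the palm down. Two conventions deserve comment
because they were forced by the geometry of desk-height reaching:

* **Shoulder decomposition order.** The shoulder composes flexion (about y)
  first, then abduction, then internal rotation. An abduction-first
  decomposition has its gimbal singularity where the upper arm points
  straight down — exactly the dominant direction when reaching on a
  horizontal plane below the shoulder — and produces ±360° jumps in the
  recorded channels. With flexion first the singular directions are straight
  left/right, far outside the workspace, and all channels are smooth.
* **Angle branches and limits.** Internal rotation and pronation are
  reported on the continuous [0°, 360°) branch: palm-down desk reaching
  lives around 130–270° in these coordinates, and the principal (±180°)
  branch would cut the workspace in half. Joint limits default to
  S_abd ± 90°, S_flex [−60°, 180°], S_rot and E_pron [0°, 360°],
  E_flex [0°, 150°], wrist ± 70°; these were chosen by scanning the task
  workspace (all eight targets, swivel styles 5–50°) so that every palm-down
  reach is feasible with margin.

`forward_kinematics()` composes the seven rotations; it is verified in the
test suite against an independent Rodrigues-formula oracle on 10^4 random
configurations.

### Redundancy and the swivel angle

A 7-DOF arm placing a fingertip has four redundant degrees of freedom. The
package resolves them with the standard *swivel angle*: the rotation of the
elbow about the shoulder–fingertip axis, measured from the vertical plane
(0° = elbow directly below the axis). `inverse_kinematics_swivel()` places
the fingertip exactly (closed-form two-link solve plus a fixed-point
correction, converged to 10^-10 m) with the elbow at the requested swivel.

Palm orientation is handled the way tabletop reaching does it
biomechanically: forearm pronation follows the *task* — the pronation
profile that levels the palm at a fixed reference elevation (reference
swivel 27°, the panel midpoint) for the current fingertip position — while
wrist flexion absorbs the residual tilt caused by the subject's actual elbow
elevation. Pronation is therefore a function of the fingertip position
alone, identical across swivel styles, and the individual differences
between subjects appear where they belong: in the shoulder channels and the
(unrecorded) wrist. An earlier design that forced the palm level with a
straight wrist pushed 20–25° of swivel-dependent variation into the recorded
pronation channel, which is neither anatomical (a straight-wrist palm
constraint over this workspace demands pronation excursions a real forearm
cannot make) nor consistent with the small inter-subject variations the
recorded-channel correlations are meant to show.

## The task protocol

`target_grid()` places eight targets on a 0.5 m-diameter circle in a
horizontal plane; the default center, (0.35, 0, −0.25) m from the shoulder,
is a comfortable desk-height position (the protocol does not fix the
circle's position relative to the body — this is the package's choice).
Target 1 is the far point; numbering runs clockwise seen from above.

One *center-out-center* trial is: reach from the center to the target
(2.0 s, matching the protocol's go cue), touch (0.5 s), return (2.0 s), and
wait at the center (1.0 s), sampled at 50 Hz. The moving-point reference of
the learning task interpolates the same path linearly. The 2/0.5/2/1 split
of the 5 s return-and-wait interval is a package decision; all durations are
configurable through `phase_timing()`.

## The reaching environment and the policy

`reach_env()` is a velocity-controlled kinematic simulator: the action is a
normalized joint-velocity command in [−1, 1]^7, integrated at dt = 0.02 s
with a maximum speed of 180 deg/s and clipped to the joint limits. There is
no contact and no gravity; this backend is self-contained and fast, and the
`step_dynamics()` contract allows a physics engine to be slotted in.

The reward is

r(s, a) = − b · error_p − c · ‖a‖² − d · error_o,

with error_p the fingertip-to-moving-point distance (m), ‖a‖² the squared
norm of the normalized command (an energy surrogate), and
error_o = 1 − palm_normal · down ∈ [0, 2]. Defaults b = 2, c = 0.05,
d = 0.5 make the position term dominate at typical errors (~0.1 m) while
the action term discourages bang-bang control. The reward is never positive
and vanishes exactly when all three terms do.

`train_policy()` is a soft actor–critic implementation written in base-R
matrix code (no RL library exists in this stack): a tanh-squashed Gaussian
actor, twin Q critics with target networks, a replay buffer, and automatic
entropy-coefficient tuning towards a target entropy of −7. The observation
is the minimal sufficient set: the 7 joint angles scaled by their limits,
the fingertip, the moving point, and their difference. One episode is one
trial; episodes cycle through the eight targets; the arm resets to the
neutral pose (fingertip at the grid center, swivel 27°). All gradients are
hand-derived and checked against finite differences in the test suite.
Episodes end on the trial clock, so target values always bootstrap
(time-limit termination is not treated as absorbing).

`clone_dataset()` rolls out the deterministic (mean) policy over the
standard schedule — four repetitions per target by default — and records the
five dataset channels at 50 Hz under subject id `"DRL"`.

## The surrogate-subject panel

`synthesize_trial()` builds one trial: the fingertip follows the
center–target–center lines under minimum-jerk time scaling
(s(τ) = 10τ³ − 15τ⁴ + 6τ⁵), the joint angles come from the swivel IK at the
subject's personal swivel angle, and smooth zero-mean Ornstein–Uhlenbeck
noise (exact discretization) is added per recorded channel. Phase durations
are jittered per trial. Everything is deterministic given the subject seed
and the trial keys.

The default panel spreads six subjects over swivel 12°–42° in 6° steps with
2° noise, 0.3 s noise correlation time and 10% timing jitter: enough spread
that cross-subject transfer is nontrivial but learnable. What the generator
emulates: per-subject redundancy style, trial-to-trial kinematic noise,
timing variability, session structure (session 1 for training, session 2
for testing). What it does not emulate: trunk compensation, sensor
(IMU-drift) artifacts, fatigue, target-dependent style changes, or any
specific human's actual trajectories — so passing the package's experiments
shows the pipeline recovers structure *of this kind*, not that it would
reach the same accuracy on any particular human cohort.

`average_subjects()` implements the cross-subject average used by the
gold-standard decoder: every trial is resampled phase-by-phase onto the
nominal phase timeline at the dataset's sampling period (reach 100 samples,
touch 25, return 100, wait 50 at 50 Hz — per-phase alignment while keeping
the uniform sampling the decoder requires), then averaged pointwise.

## The decoder

`train_predictor()` fits the CNN-LSTM regressor: one 1-D convolution layer
(64 filters, kernel 3 by default), two LSTM layers of 256 units, and a dense
head mapping the final hidden state to the two elbow angles, trained with
Adam on mean squared error. The input is a sliding window (default 50
samples = 1 s) of the three shoulder channels; the target is the elbow pair
at the window's last sample — a causal decoder, matching the online
prediction a prosthesis needs. Windows never span trial boundaries.
Normalization (per-channel z-scores for inputs and outputs) is fitted on the
training split only; validation is split by whole trials, never by window,
to avoid leakage; early stopping uses patience 15. The network and its
backpropagation (through the LSTM stack and convolution) are implemented in
base-R matrix code and finite-difference-checked in the tests.

`predict_elbow()` emits one prediction per input sample from the first full
window onward and edge-pads the warm-up samples with the first prediction,
so outputs align sample-by-sample with inputs.

## Evaluation

* `pearson_r()` / `interpret_r()`: product-moment correlation with the
  conventional seven descriptive bands; band endpoints are assigned to the
  stronger band (0.7 is "strong"), since the published band edges overlap.
* `rmse_deg()`: root-mean-squared error in degrees. The *overall* RMSE of a
  test set concatenates all samples of both elbow channels before applying
  the formula — concatenation weights every sample equally, which is the
  transparent choice when trials have unequal lengths.
* `correlation_matrix()`: per-channel correlations of each dataset's
  time-normalized mean trial against a reference (the cross-subject
  average), per target.
* `reaching_error_cm()`: both the actual trial and the predicted-elbow
  variant are replayed through the forward kinematics with the wrist held
  neutral (only shoulder and elbow channels are recorded); the error is the
  fingertip discrepancy at the actual trial's apex sample — the sample
  farthest from the grid center — in cm. The apex is the task-relevant
  instant (the touch); since elbow pronation is collinear with the straight
  hand, this metric isolates elbow-flexion accuracy.

## The two experiment scenarios

`scenario_sufficient_data()`: for each held-out subject, a `Human-Avg-Model`
is trained on the cross-subject average of the five remaining subjects'
training sessions, and a `DRL-Model` is trained once on the cloned dataset
alone; both are evaluated on the held-out subject's test session. No
test-subject trial ever enters a training set (asserted by key
intersection).

`scenario_limited_data()`: for each subject, a `Human-Sparse-Model` is
trained on one repetition of targets {1, 3, 5, 7} from the training session,
and a `Hybrid-Model` on that plus one cloned repetition of targets
{2, 4, 6, 8}; both are evaluated cross-subject on every other subject's test
session over all eight targets. The report carries the mean cross-subject
RMSE per training subject and the percentage improvement
(sparse − hybrid) / sparse × 100.

Session 1 trains, session 2 tests; one policy is shared across all
evaluations; replicate seeds regenerate the noise realizations and decoder
initializations.

## Problem sizes used by the shipped evaluations

The package's own end-to-end checks (test suite and `scripts/acceptance.R`)
run at reduced problem sizes chosen to keep a complete replication on a
single CPU: 5 × 10^4 soft actor–critic steps (the module's acceptance bar
for this scale is a mean tracking error below 0.05 m over a full eight-target
schedule), a 2 × 32-unit decoder on 0.5 s windows with stride 4 and at most
25 training epochs, and one test repetition per target in the cross-subject
evaluations. The full-scale defaults (2 × 10^5 steps, 2 × 256 LSTM units,
1 s windows, stride 1) remain the function defaults.

## Numerical choices and degenerate inputs

* IK fixed point: converged when every fingertip component moves < 10^-10 m;
  at most 25 sweeps (typically 4–6); unreachable targets and
  vertically-aligned swivel references raise typed errors.
* Correlation of a constant series is a typed error, never silently zero.
* Correlation-band endpoints break ties toward the stronger band.
* Reaching-error apexes outside the reach/touch phases trigger a warning and
  are used anyway.
* The reward clips actions before measuring ‖a‖², so the reported energy
  term always refers to the command actually applied.
* Every stochastic component (surrogate noise, jitter, SAC exploration and
  replay sampling, decoder initialization, shuffling, validation split)
  derives from explicit integer seeds; per-trial seeds are mixed with a
  modular hash kept exact in double arithmetic.

## Known limitations

* The kinematic backend has no gravity, inertia or contact. Nothing anchors
  the policy's redundancy resolution beyond the energy and palm terms, and
  the residual freedom is real: a trained policy tracks the fingertip
  accurately yet may resolve redundancy — and split palm orientation between
  pronation and wrist — differently from the surrogate convention. Decoders
  trained on cloned data alone therefore transfer to surrogate subjects less
  accurately than decoders trained on (averaged) surrogate data; the hybrid
  augmentation result is robust to this because sparse and hybrid models
  share the human-style training subject.
* Cross-subject transfer degrades toward the extremes of the swivel panel
  (12° and 42°), where the held-out style lies outside the convex hull of
  the training styles. This is a property of the emulated population, fixed
  by the generator defaults.
* The decoder predicts only the two elbow channels; wrist prediction and
  EMG-informed decoding are out of scope.
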