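# reachclone

Synthetic arm-reaching motion cloning and shoulder–elbow synergy decoding.

## What this is for

Controlling a powered prosthetic elbow from residual shoulder motion relies
on the inter-joint synergy of natural reaching: during a reach, elbow
flexion–extension and forearm pronation–supination are tightly coordinated
with the shoulder angles, so a regression model can predict the elbow
angles a person would have used from the shoulder kinematics they still
produce. Training such a decoder normally requires large motion-capture
datasets from many participants.

`reachclone` implements a motion-cloning alternative for the
center-out-center reaching task (eight targets on a 0.5 m circle in a
horizontal plane): a simulated 7-DOF arm — 3-DOF shoulder, 2-DOF elbow,
2-DOF wrist — learns to track the task's moving reference point by
reinforcement learning, and synthetic joint-angle datasets extracted from
the trained policy supplement or replace human training data. The package
is aimed at motor-control and prosthetics researchers who want a fully
reproducible, code-only testbed for synthetic-data augmentation of
kinematic decoders.

## The models at the core

**Reaching policy.** A soft actor–critic (SAC) agent controls normalized
joint velocities of the arm; the reward per step is

    r(s, a) = −b · error_p − c · ‖a‖² − d · error_o

with `error_p` the fingertip–to–moving-point distance, `‖a‖²` the action
energy, and `error_o = 1 − palm_normal · down` keeping the palm facing the
table (defaults b = 2, c = 0.05, d = 0.5). Deterministic rollouts of the
trained policy yield the cloned dataset (subject `"DRL"`): per-sample
shoulder angles (Sθx rotation, Sθy flexion, Sθz abduction) and elbow angles
(Eθx pronation, Eθy flexion) at 50 Hz.

**Surrogate subjects.** Six simulated participants replace the undeposited
human cohort: straight-line minimum-jerk fingertip paths, per-subject elbow
*swivel* style (12°–42°), smooth Ornstein–Uhlenbeck angle noise (2°), and
10% trial-timing jitter, all seeded and exactly reproducible.

**Decoder.** A CNN-LSTM (one 1-D convolution layer, two LSTM layers of 256
units, dense head; Adam) maps sliding windows of the three shoulder
channels to the two elbow angles at the window's last sample.

**Evaluation.** Pearson correlation with the conventional descriptive
bands, RMSE in degrees `sqrt(mean((x̂_t − x_t)²))`, and a forward-kinematic
target-reaching error: the predicted-elbow trial is replayed through the
arm model and compared with the actual replay at the reach apex, in cm.

All numerical kernels (the SAC trainer and the CNN-LSTM with hand-derived
backpropagation) are implemented in base-R matrix code and verified against
finite-difference oracles in the test suite.

## Worked example

Synthesize one surrogate subject (two sessions), train a compact decoder on
session 1 and evaluate it on session 2:

```r
library(reachclone)

arm    <- arm_model()
grid   <- target_grid()
timing <- phase_timing()

subject <- subject_profile("S1", swivel_deg = 18, seed = 101)
data <- synthesize_subject(subject, arm, grid, timing,
                           repetitions = 2, sessions = 2)

model <- train_predictor(
  data[data$session == 1, ],
  predictor_config(conv_filters = 16, lstm_units = 32, max_epochs = 20,
                   patience = 5, seed = 1),
  window_config(window_len = 25, stride = 4))
glance(model)
#> # A tibble: 1 × 5
#>   epochs final_train_loss best_val_loss lstm_units window_len
#>    <int>            <dbl>         <dbl>      <int>      <int>
#> 1     17            0.163         0.121         32         25

preds  <- predict_dataset(model, data[data$session == 2, ])
report <- metrics_report(preds, data[data$session == 2, ], arm, grid)
report
#> <metrics_report> 1 subject(s); overall RMSE: S1 2.85 deg
#>   mean reaching error: 2.62 cm

head(report$per_channel, 4)
#> # A tibble: 4 × 5
#>   subject_id target_id channel pearson_r rmse_deg
#>   <chr>          <int> <chr>       <dbl>    <dbl>
#> 1 S1                 1 E_flex      0.989     3.88
#> 2 S1                 1 E_pron      0.474     2.18
#> 3 S1                 2 E_flex      0.990     4.30
#> 4 S1                 2 E_pron      0.508     2.02
```

The decoder reaches 2.85° overall elbow RMSE on the held-out session and
its reconstructed fingertip lands within 2.6 cm of the actual one at the
reach apex; elbow flexion tracks almost perfectly (r ≈ 0.99, a "strong
positive" relationship in the conventional bands), while the pronation
channel — whose variation is mostly the injected noise — correlates more
weakly.

The full experiments are one call each: `train_policy()` +
`clone_dataset()` produce the synthetic dataset, and
`scenario_sufficient_data()` / `scenario_limited_data()` run the
leave-one-subject-out comparison of synthetic-only vs averaged-human
decoders and the sparse-vs-hybrid cross-subject augmentation study.
`autoplot()`, `tidy()` and `glance()` methods summarise every fitted
object. A thin command-line wrapper (`inst/cli/reachclone`, or `run_cli()`)
exposes the pipeline as subcommands (`synth-subjects`, `train-policy`,
`clone`, `train-predictor`, `predict`, `evaluate`, `experiment`).

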