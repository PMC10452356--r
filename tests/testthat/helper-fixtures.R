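# Shared fixtures and an independent forward-kinematics oracle.

# Rodrigues rotation formula: rotation of `theta` radians about unit `axis`.
# Written independently of the package's elementary-rotation composition.
rodrigues <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Independent FK: accumulate the chain with Rodrigues matrices, walking the
# segments explicitly. Mirrors the documented joint semantics only.
oracle_fk <- function(arm, q_deg) {
  q <- as.numeric(q_deg) * pi / 180
  names(q) <- joint_order()
  R <- rodrigues(c(0, 1, 0), q[["S_flex"]]) %*%
    rodrigues(c(0, 0, 1), q[["S_abd"]]) %*%
    rodrigues(c(1, 0, 0), q[["S_rot"]])
  elbow <- arm$shoulder_origin + R %*% c(arm$upper_arm_len, 0, 0)
  R <- R %*% rodrigues(c(0, 1, 0), q[["E_flex"]]) %*%
    rodrigues(c(1, 0, 0), q[["E_pron"]])
  wrist <- elbow + R %*% c(arm$forearm_len, 0, 0)
  R <- R %*% rodrigues(c(0, 1, 0), q[["W_flex"]]) %*%
    rodrigues(c(0, 0, 1), q[["W_abd"]])
  fingertip <- wrist + R %*% c(arm$hand_len, 0, 0)
  list(fingertip = as.numeric(fingertip), elbow_point = as.numeric(elbow),
       palm_normal = as.numeric(R %*% c(0, 0, -1)))
}

random_joint_vectors <- function(arm, n, seed = 1) {
  lim <- arm$joint_limits
  set.seed(seed)
  sapply(seq_len(7), function(j) runif(n, lim[j, 1], lim[j, 2]))
}

test_arm <- function() arm_model()
test_grid <- function() target_grid()
test_timing <- function() phase_timing()

# A fast timing for unit tests: short trial, coarse sampling.
fast_timing <- function() phase_timing(reach_s = 0.6, touch_hold_s = 0.2,
                                       return_s = 0.6, center_wait_s = 0.2,
                                       dt = 0.05)

# Noiseless, jitter-free surrogate profile.
clean_profile <- function(id = "S1", swivel = 24, seed = 101) {
  subject_profile(id, swivel_deg = swivel, angle_noise_sd = 0,
                  timing_jitter_frac = 0, seed = seed)
}

# Tiny hand-built motion tibble with a perfectly learnable shoulder-elbow
# synergy (elbow angles are fixed linear maps of the shoulder channels).
# Avoids the IK machinery entirely.
toy_dataset <- function(n_trials = 4, len = 60, dt = 0.02, subject = "T1",
                        elbow_constant = NULL, session = 1) {
  purrr::map_dfr(seq_len(n_trials), function(k) {
    t <- (seq_len(len) - 1) * dt
    s_rot <- 180 + 20 * sin(2 * pi * t / (len * dt) + k / 3)
    s_flex <- 90 + 15 * cos(2 * pi * t / (len * dt) + k / 5)
    s_abd <- 10 * sin(4 * pi * t / (len * dt) + k / 7)
    e_pron <- if (is.null(elbow_constant)) {
      0.4 * s_rot + 0.2 * s_flex
    } else rep(elbow_constant[1], len)
    e_flex <- if (is.null(elbow_constant)) {
      0.5 * s_flex - 0.3 * s_abd + 40
    } else rep(elbow_constant[2], len)
    tibble::tibble(subject_id = subject, target_id = ((k - 1L) %% 8L) + 1L,
                   repetition = ((k - 1L) %/% 8L) + 1L,
                   session = as.integer(session), t = t,
                   S_rot = s_rot, S_flex = s_flex, S_abd = s_abd,
                   E_pron = e_pron, E_flex = e_flex)
  })
}

# Small decoder configuration for fast unit-test training runs.
tiny_predictor_cfg <- function(seed = 1, epochs = 15) {
  predictor_config(conv_filters = 8, conv_kernel = 3, lstm_units = 8,
                   lstm_layers = 2, learning_rate = 5e-3, max_epochs = epochs,
                   batch_size = 32, patience = epochs, val_fraction = 0,
                   seed = seed)
}

# Scenario-scale decoder for fast_timing fixtures: a short window keeps the
# warm-up padding inside the near-static reach onset.
scenario_test_cfg <- function(seed = 1) {
  predictor_config(conv_filters = 8, conv_kernel = 3, lstm_units = 16,
                   lstm_layers = 2, learning_rate = 5e-3, max_epochs = 50,
                   batch_size = 16, patience = 50, val_fraction = 0,
                   seed = seed)
}
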