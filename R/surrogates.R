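#' Minimum-jerk time-scaling profile
#'
#' The classic smooth point-to-point profile `s = 10 tau^3 - 15 tau^4 + 6 tau^5`,
#' with zero velocity and acceleration at both ends and peak normalized speed
#' 1.875 at `tau = 0.5`.
#'
#' @param tau Normalized time in `[0, 1]` (vectorized).
#' @return Normalized displacement in `[0, 1]`.
#' @export
minimum_jerk_profile <- function(tau) {
  if (any(!is.finite(tau)) || any(tau < -1e-12) || any(tau > 1 + 1e-12)) {
    abort_reachclone("tau must lie in [0, 1]", "reachclone_range")
  }
  tau <- clamp(tau, 0, 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Surrogate subject profile
#'
#' One simulated participant: a constant elbow swivel angle (the subject's
#' redundancy-resolution style), smooth kinematic noise, and per-trial timing
#' jitter.
#'
#' @param subject_id Character label, e.g. `"S1"`.
#' @param swivel_deg Elbow swivel in degrees, constant for the subject.
#' @param angle_noise_sd Stationary standard deviation of the added
#'   Ornstein-Uhlenbeck angle noise, degrees.
#' @param noise_corr_time_s Correlation time of the noise process, seconds.
#' @param timing_jitter_frac Fractional uniform jitter applied independently to
#'   each phase duration (must be in `[0, 0.5)`).
#' @param seed Integer seed; all trials of the subject derive from it.
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(subject_id, swivel_deg, angle_noise_sd = 2,
                            noise_corr_time_s = 0.3, timing_jitter_frac = 0.1,
                            seed = 1L) {
  if (angle_noise_sd < 0) {
    abort_reachclone("angle_noise_sd must be >= 0", "reachclone_invalid_config")
  }
  if (timing_jitter_frac < 0 || timing_jitter_frac >= 0.5) {
    abort_reachclone("timing_jitter_frac must be in [0, 0.5)",
                     "reachclone_invalid_config")
  }
  structure(list(subject_id = as.character(subject_id),
                 swivel_deg = swivel_deg,
                 angle_noise_sd = angle_noise_sd,
                 noise_corr_time_s = noise_corr_time_s,
                 timing_jitter_frac = timing_jitter_frac,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

#' Default panel of six surrogate subjects
#'
#' Swivel angles spread over a plausible human range (12 to 42 degrees in 6
#' degree steps) so that cross-subject transfer is nontrivial but learnable;
#' 2 degrees of smooth angle noise and 10% timing jitter.
#'
#' @return List of six `subject_profile` objects, ids `S1`..`S6`.
#' @export
default_subject_profiles <- function() {
  swivels <- seq(12, 42, by = 6)
  purrr::map(seq_along(swivels), function(i) {
    subject_profile(paste0("S", i), swivel_deg = swivels[i],
                    seed = 100L + i)
  })
}

# Angle columns of the motion CSV schema, in recorded order.
angle_columns <- function() c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")

dataset_key_columns <- function() c("subject_id", "target_id", "repetition", "session")

motion_schema_columns <- function() c(dataset_key_columns(), "t", angle_columns())

# Map the 5 recorded angles (+ neutral wrist) onto the 7-joint vector.
joint_vector_from_angles <- function(s_rot, s_flex, s_abd, e_pron, e_flex) {
  c(S_abd = s_abd, S_flex = s_flex, S_rot = s_rot,
    E_flex = e_flex, E_pron = e_pron, W_flex = 0, W_abd = 0)
}

# Deterministic per-trial seed below 2^31, mixing the subject seed and keys.
# The multiplier keeps every intermediate product below 2^53 so the modular
# arithmetic stays exact in doubles.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 104729
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 65521) * 2654435 + 12345) %% 2147483647
  }
  as.integer(h)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stationary Ornstein-Uhlenbeck sample path (exact discretization).
ou_noise <- function(n, dt, sd, corr_time) {
  if (sd == 0) return(rep(0, n))
  a <- exp(-dt / corr_time)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - a^2))
  for (k in seq_len(n - 1)) x[k + 1] <- a * x[k] + innov[k]
  x
}

jittered_timing <- function(timing, frac) {
  if (frac == 0) return(timing)
  jit <- function(d) {
    dj <- d * (1 + stats::runif(1, -frac, frac))
    max(timing$dt, round(dj / timing$dt) * timing$dt)
  }
  phase_timing(reach_s = jit(timing$reach_s),
               touch_hold_s = jit(timing$touch_hold_s),
               return_s = jit(timing$return_s),
               center_wait_s = jit(timing$center_wait_s),
               dt = timing$dt)
}

#' Synthesize one surrogate reaching trial
#'
#' The fingertip follows straight center-to-target-to-center lines with
#' minimum-jerk time scaling; joint angles come from
#' [inverse_kinematics_swivel()] at the subject's swivel angle; zero-mean
#' Ornstein-Uhlenbeck noise is added per recorded angle. Deterministic given
#' the profile seed and the trial keys.
#'
#' @param profile A `subject_profile`.
#' @param arm An `arm_model`.
#' @param grid A `target_grid`.
#' @param timing A `phase_timing` (nominal; per-trial jitter is applied).
#' @param target_id,repetition,session Trial keys.
#' @return Tibble with columns
#'   `subject_id, target_id, repetition, session, t, S_rot, S_flex, S_abd,
#'   E_pron, E_flex, phase`.
#' @export
synthesize_trial <- function(profile, arm, grid, timing, target_id,
                             repetition = 1, session = 1) {
  trial_seed <- derive_seed(profile$seed, target_id, repetition, session)
  with_local_seed(trial_seed, {
    tj <- jittered_timing(timing, profile$timing_jitter_frac)
    traj <- fingertip_reference_path(grid, tj, target_id)
    qq <- ik_path(arm, as.matrix(traj[, c("x", "y", "z")]),
                  swivel_deg = profile$swivel_deg)
    q5 <- qq[, c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")]
    colnames(q5) <- angle_columns()
    for (j in seq_len(5)) {
      q5[, j] <- q5[, j] + ou_noise(nrow(q5), tj$dt, profile$angle_noise_sd,
                                    profile$noise_corr_time_s)
    }
    tibble::tibble(
      subject_id = profile$subject_id,
      target_id = as.integer(target_id),
      repetition = as.integer(repetition),
      session = as.integer(session),
      t = traj$t,
      S_rot = q5[, 1], S_flex = q5[, 2], S_abd = q5[, 3],
      E_pron = q5[, 4], E_flex = q5[, 5],
      phase = traj$phase
    )
  })
}

# Ideal fingertip path for a trial: straight lines + minimum-jerk time scaling.
fingertip_reference_path <- function(grid, timing, target_id) {
  n <- round(trial_duration(timing) / timing$dt)
  times <- (seq_len(n) - 1) * timing$dt
  tgt <- target_position(grid, target_id)
  ctr <- grid$center
  t1 <- timing$reach_s
  t2 <- t1 + timing$touch_hold_s
  t3 <- t2 + timing$return_s
  pos <- matrix(0, n, 3)
  phase <- character(n)
  for (i in seq_len(n)) {
    t <- times[i]
    if (t < t1) {
      s <- minimum_jerk_profile(t / t1)
      pos[i, ] <- ctr + s * (tgt - ctr); phase[i] <- "reach"
    } else if (t < t2) {
      pos[i, ] <- tgt; phase[i] <- "touch"
    } else if (t < t3) {
      s <- minimum_jerk_profile((t - t2) / timing$return_s)
      pos[i, ] <- tgt + s * (ctr - tgt); phase[i] <- "return"
    } else {
      pos[i, ] <- ctr; phase[i] <- "wait"
    }
  }
  tibble::tibble(t = times, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 phase = phase)
}

#' Synthesize a full surrogate-subject dataset
#'
#' @inheritParams synthesize_trial
#' @param repetitions Repetitions per target per session (default 4).
#' @param sessions Number of recording sessions (default 2: one for training,
#'   one for testing).
#' @return Motion tibble with `repetitions * n_targets * sessions` trials.
#' @export
synthesize_subject <- function(profile, arm, grid, timing, repetitions = 4,
                               sessions = 2) {
  if (repetitions < 1) {
    abort_reachclone("repetitions must be >= 1", "reachclone_invalid_config")
  }
  keys <- tidyr::expand_grid(session = seq_len(sessions),
                             repetition = seq_len(repetitions),
                             target_id = grid$targets$target_id)
  purrr::pmap_dfr(keys, function(session, repetition, target_id) {
    synthesize_trial(profile, arm, grid, timing, target_id, repetition, session)
  })
}

#' Synthesize datasets for a panel of surrogate subjects
#'
#' @param profiles List of `subject_profile`s (default the six-subject panel).
#' @inheritParams synthesize_subject
#' @return One motion tibble containing all subjects.
#' @export
synthesize_subjects <- function(profiles = default_subject_profiles(), arm,
                                grid, timing, repetitions = 4, sessions = 2) {
  purrr::map_dfr(profiles, synthesize_subject, arm = arm, grid = grid,
                 timing = timing, repetitions = repetitions, sessions = sessions)
}

# Assign nominal phase labels to a trial lacking them, by scaling the nominal
# phase proportions to the trial's duration.
assign_phases_nominal <- function(times, timing) {
  dur <- max(times) + timing$dt
  fracs <- c(timing$reach_s, timing$touch_hold_s, timing$return_s,
             timing$center_wait_s) / trial_duration(timing)
  b <- cumsum(fracs) * dur
  eps <- 1e-9
  ifelse(times < b[1] - eps, "reach",
         ifelse(times < b[2] - eps, "touch",
                ifelse(times < b[3] - eps, "return", "wait")))
}

# Resample one trial onto the nominal per-phase timeline at dt, phase by phase.
resample_trial_nominal <- function(trial, timing) {
  if (!"phase" %in% names(trial)) {
    trial$phase <- assign_phases_nominal(trial$t, timing)
  }
  dt <- timing$dt
  phases <- list(reach = timing$reach_s, touch = timing$touch_hold_s,
                 return = timing$return_s, wait = timing$center_wait_s)
  offset <- 0
  out <- vector("list", length(phases))
  for (k in seq_along(phases)) {
    ph <- names(phases)[k]
    dur <- phases[[k]]
    n_out <- round(dur / dt)
    rows <- trial[trial$phase == ph, ]
    if (nrow(rows) == 0) {
      abort_reachclone(sprintf("trial has no samples in phase '%s'", ph),
                       "reachclone_incompatible_datasets")
    }
    tau_in <- if (nrow(rows) > 1) {
      (rows$t - rows$t[1]) / (rows$t[nrow(rows)] - rows$t[1])
    } else 0
    tau_out <- if (n_out > 1) seq(0, 1, length.out = n_out) else 0
    res <- tibble::tibble(t = offset + (seq_len(n_out) - 1) * dt, phase = ph)
    for (col in angle_columns()) {
      res[[col]] <- if (nrow(rows) > 1) {
        stats::approx(tau_in, rows[[col]], xout = tau_out, rule = 2)$y
      } else rep(rows[[col]], n_out)
    }
    out[[k]] <- res
    offset <- offset + dur
  }
  dplyr::bind_rows(out)
}

#' Average motion data across subjects
#'
#' For every `(target_id, repetition, session)` cell, each subject's trial is
#' resampled phase-by-phase onto the nominal phase timeline (linear
#' interpolation at the dataset's sampling period), and the angles are averaged
#' pointwise across subjects. The result carries subject id `"AVG"`.
#'
#' @param data Motion tibble containing two or more subjects with identical
#'   trial structure.
#' @param timing The nominal `phase_timing`.
#' @return Motion tibble with one averaged trial per cell.
#' @export
average_subjects <- function(data, timing) {
  validate_motion_dataset(data, dt = timing$dt)
  cells <- dplyr::distinct(data, .data$target_id, .data$repetition, .data$session)
  subjects <- unique(data$subject_id)
  per_subject_cells <- dplyr::count(data, .data$subject_id,
                                    .data$target_id, .data$repetition,
                                    .data$session)
  if (nrow(per_subject_cells) != length(subjects) * nrow(cells)) {
    abort_reachclone("subjects do not share an identical trial structure",
                     "reachclone_incompatible_datasets")
  }
  purrr::pmap_dfr(cells, function(target_id, repetition, session) {
    trials <- purrr::map(subjects, function(s) {
      tr <- data[data$subject_id == s & data$target_id == target_id &
                   data$repetition == repetition & data$session == session, ]
      resample_trial_nominal(tr, timing)
    })
    base <- trials[[1]]
    for (col in angle_columns()) {
      base[[col]] <- rowMeans(do.call(cbind, purrr::map(trials, col)))
    }
    tibble::tibble(subject_id = "AVG", target_id = as.integer(target_id),
                   repetition = as.integer(repetition),
                   session = as.integer(session),
                   t = base$t,
                   S_rot = base$S_rot, S_flex = base$S_flex,
                   S_abd = base$S_abd, E_pron = base$E_pron,
                   E_flex = base$E_flex, phase = base$phase)
  })
}

#' Validate a motion dataset against the package schema
#'
#' Checks column presence, key uniqueness, finite angles and per-trial uniform
#' sampling.
#'
#' @param data Motion tibble.
#' @param dt Expected sample period in seconds (optional).
#' @return `data`, invisibly, if valid; otherwise a schema error naming the
#'   offending trial or row.
#' @export
validate_motion_dataset <- function(data, dt = NULL) {
  missing <- setdiff(motion_schema_columns(), names(data))
  if (length(missing) > 0) {
    abort_reachclone(sprintf("motion data is missing column(s): %s",
                             paste(missing, collapse = ", ")),
                     "reachclone_schema")
  }
  for (col in angle_columns()) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad) > 0) {
      abort_reachclone(sprintf("non-finite %s at row %d", col, bad[1]),
                       "reachclone_schema")
    }
  }
  keyed <- dplyr::group_by(data, .data$subject_id, .data$target_id,
                           .data$repetition, .data$session)
  info <- dplyr::summarise(
    keyed,
    dup_t = anyDuplicated(.data$t) > 0,
    ok_dt = {
      dts <- diff(.data$t)
      length(dts) == 0 || max(abs(dts - dts[1])) < 1e-9
    },
    dt1 = if (dplyr::n() > 1) .data$t[2] - .data$t[1] else NA_real_,
    .groups = "drop")
  if (any(info$dup_t)) {
    r <- info[info$dup_t, ][1, ]
    abort_reachclone(sprintf("duplicate trial rows for (%s, target %d, rep %d, session %d)",
                             r$subject_id, r$target_id, r$repetition, r$session),
                     "reachclone_schema")
  }
  if (any(!info$ok_dt)) {
    r <- info[!info$ok_dt, ][1, ]
    abort_reachclone(sprintf("non-uniform sampling in trial (%s, target %d, rep %d, session %d)",
                             r$subject_id, r$target_id, r$repetition, r$session),
                     "reachclone_schema")
  }
  if (!is.null(dt)) {
    bad <- which(is.finite(info$dt1) & abs(info$dt1 - dt) > 1e-9)
    if (length(bad) > 0) {
      r <- info[bad[1], ]
      abort_reachclone(sprintf("trial (%s, target %d, rep %d, session %d) is not sampled at dt = %g",
                               r$subject_id, r$target_id, r$repetition, r$session, dt),
                       "reachclone_schema")
    }
  }
  invisible(data)
}

#' Read and write motion datasets as CSV
#'
#' The on-disk schema is exactly
#' `subject_id,target_id,repetition,session,t,S_rot,S_flex,S_abd,E_pron,E_flex`
#' (angles in degrees, `t` in seconds). `read_dataset()` optionally
#' reconstructs phase labels from a nominal `phase_timing`.
#'
#' @param data Motion tibble.
#' @param path CSV file path.
#' @param timing Optional `phase_timing` used to re-attach phase labels on read.
#' @return `write_dataset()`: `path` invisibly. `read_dataset()`: motion tibble.
#' @export
write_dataset <- function(data, path) {
  validate_motion_dataset(data)
  readr::write_csv(data[, motion_schema_columns()], path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, timing = NULL) {
  if (!file.exists(path)) {
    abort_reachclone(sprintf("no such file: %s", path), "reachclone_schema")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(header, motion_schema_columns())) {
    abort_reachclone(
      sprintf("malformed header: expected '%s', found '%s'",
              paste(motion_schema_columns(), collapse = ","),
              paste(header, collapse = ",")),
      "reachclone_schema")
  }
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            subject_id = readr::col_character(),
                            target_id = readr::col_integer(),
                            repetition = readr::col_integer(),
                            session = readr::col_integer(),
                            .default = readr::col_double()))
  validate_motion_dataset(data)
  if (!is.null(timing)) {
    data <- dplyr::mutate(
      dplyr::group_by(data, .data$subject_id, .data$target_id,
                      .data$repetition, .data$session),
      phase = assign_phases_nominal(.data$t, timing))
    data <- dplyr::ungroup(data)
  }
  data
}
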