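#' Target grid for the center-out-center reaching task
#'
#' Places `n_targets` points evenly on a horizontal circle. Target 1 lies in
#' the +x (far-from-body) direction; numbering proceeds clockwise when viewed
#' from above.
#'
#' @param center 3-vector, metres; circle center, default a comfortable
#'   desk-height plane in front of the shoulder.
#' @param diameter Circle diameter in metres (default 0.5).
#' @param n_targets Number of targets (default 8).
#' @return A `target_grid` object; `$targets` is a tibble with columns
#'   `target_id, x, y, z`.
#' @export
target_grid <- function(center = c(0.35, 0, -0.25), diameter = 0.5,
                        n_targets = 8) {
  if (!is.finite(diameter) || diameter <= 0) {
    abort_reachclone("grid diameter must be positive", "reachclone_invalid_config")
  }
  if (n_targets < 1) {
    abort_reachclone("need at least one target", "reachclone_invalid_config")
  }
  center <- as.numeric(center)
  r <- diameter / 2
  theta <- -(seq_len(n_targets) - 1) * 2 * pi / n_targets
  targets <- tibble::tibble(
    target_id = seq_len(n_targets),
    x = center[1] + r * cos(theta),
    y = center[2] + r * sin(theta),
    z = center[3]
  )
  structure(list(center = center, diameter = diameter, targets = targets),
            class = "target_grid")
}

#' @export
print.target_grid <- function(x, ...) {
  cat("<target_grid>", nrow(x$targets), "targets, diameter", x$diameter,
      "m, center (", paste(format(x$center, digits = 3), collapse = ", "), ")\n")
  invisible(x)
}

target_position <- function(grid, target_id) {
  row <- grid$targets[grid$targets$target_id == target_id, ]
  if (nrow(row) != 1) {
    abort_reachclone(sprintf("unknown target id %s", target_id),
                     "reachclone_missing_data")
  }
  c(row$x, row$y, row$z)
}

#' Phase timing of one center-out-center trial
#'
#' Defaults mirror the cueing used for the human protocol: a 2 s outward
#' reach (the green interval), a short touch hold, a 2 s return and a 1 s
#' center wait (together the red interval), sampled at 50 Hz.
#'
#' @param reach_s,touch_hold_s,return_s,center_wait_s Phase durations, seconds.
#' @param dt Sample period in seconds; must divide every phase duration.
#' @return A `phase_timing` object.
#' @export
phase_timing <- function(reach_s = 2.0, touch_hold_s = 0.5, return_s = 2.0,
                         center_wait_s = 1.0, dt = 0.02) {
  durs <- c(reach = reach_s, touch = touch_hold_s, ret = return_s,
            wait = center_wait_s, dt = dt)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort_reachclone("all phase durations and dt must be positive",
                     "reachclone_invalid_config")
  }
  for (d in durs[1:4]) {
    k <- d / dt
    if (abs(k - round(k)) > 1e-9) {
      abort_reachclone("dt must divide every phase duration",
                       "reachclone_invalid_config")
    }
  }
  structure(list(reach_s = reach_s, touch_hold_s = touch_hold_s,
                 return_s = return_s, center_wait_s = center_wait_s, dt = dt),
            class = "phase_timing")
}

#' Duration of one trial in seconds
#' @param timing A `phase_timing`.
#' @export
trial_duration <- function(timing) {
  timing$reach_s + timing$touch_hold_s + timing$return_s + timing$center_wait_s
}

#' Position of the moving point at time `t` within a trial
#'
#' Linear center-to-target motion during the reach phase, hold at the target,
#' linear return, then hold at the center.
#'
#' @param grid A `target_grid`.
#' @param timing A `phase_timing`.
#' @param target_id Target number.
#' @param t Time in seconds from trial start, `0 <= t <= trial_duration`.
#' @return List with `position` (3-vector) and `phase`
#'   (one of `"reach"`, `"touch"`, `"return"`, `"wait"`).
#' @export
moving_point_position <- function(grid, timing, target_id, t) {
  dur <- trial_duration(timing)
  if (!is.finite(t) || t < -1e-9 || t > dur + 1e-9) {
    abort_reachclone(sprintf("t = %.3f s is outside the trial [0, %.3f]", t, dur),
                     "reachclone_range")
  }
  tgt <- target_position(grid, target_id)
  ctr <- grid$center
  t1 <- timing$reach_s
  t2 <- t1 + timing$touch_hold_s
  t3 <- t2 + timing$return_s
  if (t < t1) {
    list(position = ctr + (t / t1) * (tgt - ctr), phase = "reach")
  } else if (t < t2) {
    list(position = tgt, phase = "touch")
  } else if (t < t3) {
    s <- (t - t2) / timing$return_s
    list(position = tgt + s * (ctr - tgt), phase = "return")
  } else {
    list(position = ctr, phase = "wait")
  }
}

#' Reference trajectory of the moving point over one full trial
#'
#' @inheritParams moving_point_position
#' @return Tibble with columns `t, x, y, z, phase`, sampled at `timing$dt`
#'   from 0 to just under the trial duration.
#' @export
moving_point_trajectory <- function(grid, timing, target_id) {
  n <- round(trial_duration(timing) / timing$dt)
  times <- (seq_len(n) - 1) * timing$dt
  out <- purrr::map(times, function(t) moving_point_position(grid, timing, target_id, t))
  pos <- do.call(rbind, purrr::map(out, "position"))
  tibble::tibble(t = times, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 phase = purrr::map_chr(out, "phase"))
}

#' Back-to-back schedule of center-out-center trials
#'
#' @param grid A `target_grid`.
#' @param timing A `phase_timing`.
#' @param repetitions Number of passes over `order`.
#' @param order Target ids visited within one pass (default all, in order).
#' @return Tibble with columns `trial, repetition, target_id, start_s`.
#' @export
trial_schedule <- function(grid, timing, repetitions = 4,
                           order = grid$targets$target_id) {
  if (repetitions < 1) {
    abort_reachclone("repetitions must be >= 1", "reachclone_invalid_config")
  }
  if (length(order) == 0) {
    abort_reachclone("target order must not be empty", "reachclone_invalid_config")
  }
  dur <- trial_duration(timing)
  sched <- tidyr::expand_grid(repetition = seq_len(repetitions),
                              target_id = as.integer(order))
  sched$trial <- seq_len(nrow(sched))
  sched$start_s <- (sched$trial - 1) * dur
  sched[, c("trial", "repetition", "target_id", "start_s")]
}
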