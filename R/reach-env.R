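#' Reward weights for the reaching environment
#'
#' The scalar reward is `-b * error_p - c * ||a||^2 - d * error_o`: a position
#' error term (metres), an action-energy term on the normalized joint-velocity
#' command, and a palm-orientation term `1 - palm_normal . down` in `[0, 2]`.
#' Defaults make the position term dominate at typical tracking errors while
#' the action term discourages bang-bang control.
#'
#' @param b,c,d Nonnegative coefficients; `b` must be positive.
#' @return A `reward_weights` object.
#' @export
reward_weights <- function(b = 2.0, c = 0.05, d = 0.5) {
  if (b <= 0 || c < 0 || d < 0) {
    abort_reachclone("require b > 0 and c, d >= 0", "reachclone_invalid_config")
  }
  structure(list(b = b, c = c, d = d), class = "reward_weights")
}

#' Velocity-controlled reaching environment
#'
#' A kinematic simulator of the 7-DOF arm tracking the moving point of the
#' center-out-center task: actions are normalized joint-velocity commands in
#' `[-1, 1]`, integrated at `timing$dt` and clipped to the joint limits. One
#' episode is one trial towards one target; the arm resets to the neutral
#' pose (fingertip at the grid center).
#'
#' @param arm An `arm_model`.
#' @param grid A `target_grid`.
#' @param timing A `phase_timing`.
#' @param weights A `reward_weights`.
#' @param max_speed Maximum joint speed in deg/s mapped to action 1.
#' @param neutral_swivel_deg Swivel of the neutral (reset) pose.
#' @return A `reach_env` object.
#' @export
reach_env <- function(arm, grid, timing, weights = reward_weights(),
                      max_speed = 180, neutral_swivel_deg = 27) {
  q0 <- inverse_kinematics_swivel(arm, grid$center,
                                  swivel_deg = neutral_swivel_deg,
                                  palm_down = TRUE)
  structure(list(arm = arm, grid = grid, timing = timing, weights = weights,
                 max_speed = max_speed, q_neutral = q0,
                 n_steps = round(trial_duration(timing) / timing$dt)),
            class = "reach_env")
}

#' @export
print.reach_env <- function(x, ...) {
  cat("<reach_env>", x$n_steps, "steps/episode, dt", x$timing$dt,
      "s, max speed", x$max_speed, "deg/s\n")
  invisible(x)
}

#' Reset the environment to the start of a trial
#'
#' @param env A `reach_env`.
#' @param target_id Target for this episode.
#' @return An environment state: list with `q` (deg), `q_dot` (deg/s),
#'   `moving_point`, `phase`, `t`, `target_id`.
#' @export
env_reset <- function(env, target_id) {
  mp <- moving_point_position(env$grid, env$timing, target_id, 0)
  list(q = env$q_neutral, q_dot = rep(0, 7), moving_point = mp$position,
       phase = mp$phase, t = 0, target_id = as.integer(target_id),
       pose = forward_kinematics(env$arm, env$q_neutral))
}

#' Advance the environment by one control step
#'
#' `q' = clip(q + action * max_speed * dt, joint_limits)`; the moving point
#' advances along the task-protocol reference. Deterministic: identical
#' inputs give identical next states.
#'
#' @param state Environment state (see [env_reset()]).
#' @param action Numeric 7-vector, clipped to `[-1, 1]`.
#' @param env A `reach_env`.
#' @return The next environment state.
#' @export
step_dynamics <- function(state, action, env) {
  a <- clamp(as.numeric(action), -1, 1)
  lim <- env$arm$joint_limits
  dt <- env$timing$dt
  q_new <- clamp(state$q + a * env$max_speed * dt, lim[, "min"], lim[, "max"])
  names(q_new) <- joint_order()
  t_new <- state$t + dt
  t_query <- min(t_new, trial_duration(env$timing))
  mp <- moving_point_position(env$grid, env$timing, state$target_id, t_query)
  list(q = q_new, q_dot = (q_new - state$q) / dt, moving_point = mp$position,
       phase = mp$phase, t = t_new, target_id = state$target_id,
       pose = forward_kinematics(env$arm, q_new))
}

#' Reward of a state-action pair
#'
#' @param state Environment state.
#' @param action Numeric 7-vector (normalized command).
#' @param env A `reach_env` (supplies the arm and weights).
#' @return List with `reward` (scalar, always `<= 0`) and `terms`
#'   (`error_p` metres, `action_sq`, `error_o`).
#' @export
env_reward <- function(state, action, env) {
  a <- clamp(as.numeric(action), -1, 1)
  pose <- state$pose %||% forward_kinematics(env$arm, state$q)
  error_p <- vec_norm(pose$fingertip - state$moving_point)
  action_sq <- sum(a * a)
  error_o <- 1 - sum(pose$palm_normal * c(0, 0, -1))
  w <- env$weights
  r <- -w$b * error_p - w$c * action_sq - w$d * error_o
  list(reward = r,
       terms = list(error_p = error_p, action_sq = action_sq,
                    error_o = error_o))
}

# Observation vector fed to the policy: joint angles scaled to [-1, 1] by
# their limits, fingertip xyz, moving-point xyz, error vector xyz.
env_observe <- function(state, env) {
  lim <- env$arm$joint_limits
  q_s <- 2 * (state$q - lim[, "min"]) / (lim[, "max"] - lim[, "min"]) - 1
  pose <- state$pose %||% forward_kinematics(env$arm, state$q)
  c(q_s, pose$fingertip, state$moving_point,
    state$moving_point - pose$fingertip)
}

env_obs_dim <- function() 16L
env_act_dim <- function() 7L
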