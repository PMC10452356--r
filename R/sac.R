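# Soft actor-critic trainer for the reaching environment, in base-R matrix
# code: a squashed-Gaussian actor, twin Q critics with target networks, a
# replay buffer and automatic entropy-coefficient tuning. Gradients are
# hand-derived (reparameterized actor path, MSE critic path) and checked
# against finite differences in the test suite.

mlp_init <- function(sizes) {
  params <- list()
  for (i in seq_len(length(sizes) - 1)) {
    params[[paste0("W", i)]] <- glorot(sizes[i], sizes[i + 1])
    params[[paste0("b", i)]] <- numeric(sizes[i + 1])
  }
  params
}

# ReLU MLP forward; linear output layer. X: [B, in]. Returns caches.
mlp_forward <- function(params, X) {
  n_layers <- length(params) / 2
  hs <- list(X)
  zs <- list()
  h <- X
  for (i in seq_len(n_layers)) {
    z <- h %*% params[[paste0("W", i)]]
    z <- z + rep(params[[paste0("b", i)]], each = nrow(z))
    zs[[i]] <- z
    h <- if (i < n_layers) z * (z > 0) else z
    hs[[i + 1]] <- h
  }
  list(out = h, hs = hs, zs = zs)
}

# Backward through the MLP. dout: [B, out]. Returns grads and dX.
mlp_backward <- function(params, fwd, dout) {
  n_layers <- length(params) / 2
  grads <- list()
  d <- dout
  for (i in rev(seq_len(n_layers))) {
    if (i < n_layers) d <- d * (fwd$zs[[i]] > 0)
    grads[[paste0("W", i)]] <- crossprod(fwd$hs[[i]], d)
    grads[[paste0("b", i)]] <- colSums(d)
    d <- tcrossprod(d, params[[paste0("W", i)]])
  }
  list(grads = grads, dX = d)
}

LOGSTD_MIN <- -8
LOGSTD_MAX <- 2

# Actor head: MLP output is [mu (7) | logstd (7)], logstd clipped.
actor_sample <- function(params, obs, eps = NULL, deterministic = FALSE) {
  fwd <- mlp_forward(params, obs)
  n_a <- ncol(fwd$out) / 2
  mu <- fwd$out[, seq_len(n_a), drop = FALSE]
  logstd <- clamp(fwd$out[, n_a + seq_len(n_a), drop = FALSE],
                  LOGSTD_MIN, LOGSTD_MAX)
  if (deterministic) {
    return(list(action = tanh(mu), mu = mu, fwd = fwd))
  }
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  sigma <- exp(logstd)
  u <- mu + sigma * eps
  a <- tanh(u)
  # log-density of the tanh-squashed Gaussian
  logp <- rowSums(-0.5 * eps^2 - logstd - 0.5 * log(2 * pi) -
                    log(1 - a^2 + 1e-6))
  list(action = a, mu = mu, logstd = logstd, sigma = sigma, eps = eps,
       u = u, logp = logp, fwd = fwd)
}

# Gradients of (alpha * logp - q_min) wrt actor parameters, given per-sample
# upstream weight 1/B. dq_da: [B, n_a] gradient of q_min wrt the action.
actor_backward <- function(params, smp, dq_da, alpha, B) {
  a <- smp$action
  n_a <- ncol(a)
  sech2 <- 1 - a^2                       # da/du
  corr <- 2 * a * sech2 / (1 - a^2 + 1e-6)  # dlogp/du (squash correction)
  # loss per sample: alpha * logp - q_min; gradient wrt u
  dL_du <- (alpha * corr - dq_da * sech2) / B
  dmu <- dL_du
  # logstd path: u = mu + exp(logstd) * eps; plus the -logstd term in logp
  dlogstd <- dL_du * smp$sigma * smp$eps - (alpha / B)
  active <- (smp$logstd > LOGSTD_MIN) & (smp$logstd < LOGSTD_MAX)
  dlogstd <- dlogstd * active
  dout <- cbind(dmu, dlogstd)
  mlp_backward(params, smp$fwd, dout)$grads
}

soft_update <- function(target, source, tau) {
  for (k in names(source)) {
    target[[k]] <- (1 - tau) * target[[k]] + tau * source[[k]]
  }
  target
}

#' Train a reaching policy with soft actor-critic
#'
#' Learns a stochastic tracking policy for the center-out-center task by
#' maximizing reward plus policy entropy, with twin Q critics, target
#' networks and automatic tuning of the entropy coefficient towards a target
#' entropy of `-7` (minus the action dimension). Episodes cycle through the
#' eight targets; one episode is one full trial.
#'
#' @param arm An `arm_model`.
#' @param grid A `target_grid`.
#' @param timing A `phase_timing`.
#' @param weights A `reward_weights`.
#' @param steps Total environment steps (default 2e5).
#' @param seed Integer seed for all training randomness.
#' @param hidden Hidden-layer width of actor and critics.
#' @param batch_size Replay minibatch size.
#' @param lr Adam learning rate for actor, critics and entropy coefficient.
#' @param gamma Discount factor.
#' @param tau Target-network soft-update coefficient.
#' @param warmup Uniform-random exploration steps before learning starts.
#' @param update_every Gradient updates are performed every this many steps.
#' @param max_speed Maximum joint speed in deg/s.
#' @return A `policy_handle` with the trained actor, the per-episode return
#'   log, and the training configuration.
#' @export
train_policy <- function(arm, grid, timing, weights = reward_weights(),
                         steps = 2e5, seed = 1L, hidden = 64,
                         batch_size = 64, lr = 1e-3, gamma = 0.99,
                         tau = 0.005, warmup = 1000, update_every = 1,
                         max_speed = 180) {
  if (steps <= 0) {
    abort_reachclone("steps must be positive", "reachclone_invalid_config")
  }
  env <- reach_env(arm, grid, timing, weights, max_speed = max_speed)
  n_obs <- env_obs_dim(); n_act <- env_act_dim()
  with_local_seed(as.integer(seed), {
    actor <- mlp_init(c(n_obs, hidden, hidden, 2 * n_act))
    q1 <- mlp_init(c(n_obs + n_act, hidden, hidden, 1))
    q2 <- mlp_init(c(n_obs + n_act, hidden, hidden, 1))
    q1_t <- q1; q2_t <- q2
    opt_a <- adam_init(actor); opt_1 <- adam_init(q1); opt_2 <- adam_init(q2)
    log_alpha <- log(0.1)
    opt_alpha <- list(m = 0, v = 0, t = 0)
    target_entropy <- -n_act
    cap <- min(steps, 200000L)
    buf <- list(obs = matrix(0, cap, n_obs), act = matrix(0, cap, n_act),
                rew = numeric(cap), obs2 = matrix(0, cap, n_obs))
    buf_n <- 0L; buf_at <- 0L
    episode_log <- list()
    target_cycle <- grid$targets$target_id
    ep_i <- 0L
    state <- NULL; obs <- NULL
    ep_return <- 0; ep_err <- 0; ep_steps <- 0L
    begin_episode <- function() {
      ep_i <<- ep_i + 1L
      tid <- target_cycle[((ep_i - 1L) %% length(target_cycle)) + 1L]
      state <<- env_reset(env, tid)
      obs <<- env_observe(state, env)
      ep_return <<- 0; ep_err <<- 0; ep_steps <<- 0L
    }
    begin_episode()
    for (step_i in seq_len(steps)) {
      if (step_i <= warmup) {
        action <- stats::runif(n_act, -1, 1)
      } else {
        smp <- actor_sample(actor, matrix(obs, 1, n_obs))
        action <- as.numeric(smp$action)
      }
      nxt <- step_dynamics(state, action, env)
      rw <- env_reward(nxt, action, env)
      obs2 <- env_observe(nxt, env)
      buf_at <- (buf_at %% cap) + 1L
      buf$obs[buf_at, ] <- obs
      buf$act[buf_at, ] <- action
      buf$rew[buf_at] <- rw$reward
      buf$obs2[buf_at, ] <- obs2
      buf_n <- min(buf_n + 1L, cap)
      ep_return <- ep_return + rw$reward
      ep_err <- ep_err + rw$terms$error_p
      ep_steps <- ep_steps + 1L
      done <- nxt$t >= trial_duration(timing) - 1e-9
      if (done) {
        episode_log[[length(episode_log) + 1]] <- tibble::tibble(
          episode = ep_i, target_id = state$target_id,
          return_ = ep_return, mean_error_p = ep_err / ep_steps)
        begin_episode()
      } else {
        state <- nxt; obs <- obs2
      }
      if (step_i > warmup && step_i %% update_every == 0) {
        ix <- sample.int(buf_n, batch_size, replace = buf_n < batch_size)
        ob <- buf$obs[ix, , drop = FALSE]
        ac <- buf$act[ix, , drop = FALSE]
        re <- buf$rew[ix]
        ob2 <- buf$obs2[ix, , drop = FALSE]
        alpha <- exp(log_alpha)
        # --- critic update (time-limit episodes: always bootstrap) ---
        smp2 <- actor_sample(actor, ob2)
        in2 <- cbind(ob2, smp2$action)
        qt1 <- mlp_forward(q1_t, in2)$out
        qt2 <- mlp_forward(q2_t, in2)$out
        y <- re + gamma * (pmin(qt1, qt2) - alpha * smp2$logp)
        in1 <- cbind(ob, ac)
        f1 <- mlp_forward(q1, in1)
        f2 <- mlp_forward(q2, in1)
        if (!all(is.finite(f1$out)) || !all(is.finite(f2$out))) {
          abort_reachclone("non-finite critic values: training diverged",
                           "reachclone_training_failure")
        }
        d1 <- 2 * (f1$out - y) / batch_size
        d2 <- 2 * (f2$out - y) / batch_size
        g1 <- mlp_backward(q1, f1, d1)$grads
        g2 <- mlp_backward(q2, f2, d2)$grads
        u1 <- adam_step(opt_1, q1, g1, lr); opt_1 <- u1$state; q1 <- u1$params
        u2 <- adam_step(opt_2, q2, g2, lr); opt_2 <- u2$state; q2 <- u2$params
        # --- actor update ---
        smp <- actor_sample(actor, ob)
        in_pi <- cbind(ob, smp$action)
        fq1 <- mlp_forward(q1, in_pi)
        fq2 <- mlp_forward(q2, in_pi)
        use1 <- fq1$out <= fq2$out
        ones <- matrix(1, batch_size, 1)
        dqa1 <- mlp_backward(q1, fq1, ones)$dX[, n_obs + seq_len(n_act),
                                               drop = FALSE]
        dqa2 <- mlp_backward(q2, fq2, ones)$dX[, n_obs + seq_len(n_act),
                                               drop = FALSE]
        dq_da <- dqa1 * as.numeric(use1) + dqa2 * as.numeric(!use1)
        ga <- actor_backward(actor, smp, dq_da, alpha, batch_size)
        ua <- adam_step(opt_a, actor, ga, lr); opt_a <- ua$state
        actor <- ua$params
        # --- entropy coefficient ---
        dla <- -mean(smp$logp + target_entropy) * alpha
        opt_alpha$t <- opt_alpha$t + 1
        opt_alpha$m <- 0.9 * opt_alpha$m + 0.1 * dla
        opt_alpha$v <- 0.999 * opt_alpha$v + 0.001 * dla^2
        log_alpha <- log_alpha -
          lr * (opt_alpha$m / (1 - 0.9^opt_alpha$t)) /
          (sqrt(opt_alpha$v / (1 - 0.999^opt_alpha$t)) + 1e-8)
        q1_t <- soft_update(q1_t, q1, tau)
        q2_t <- soft_update(q2_t, q2, tau)
      }
    }
    structure(list(actor = actor, env_config = list(
      weights = weights, max_speed = max_speed,
      neutral_swivel_deg = 27),
      training_seed = as.integer(seed), steps_trained = steps,
      entropy_weight = exp(log_alpha),
      episode_log = dplyr::bind_rows(episode_log)),
      class = "policy_handle")
  })
}

#' @export
print.policy_handle <- function(x, ...) {
  cat("<policy_handle> SAC,", x$steps_trained, "steps,",
      nrow(x$episode_log), "episodes, entropy weight",
      format(x$entropy_weight, digits = 3), "\n")
  invisible(x)
}

#' @method tidy policy_handle
#' @export
tidy.policy_handle <- function(x, ...) x$episode_log

#' @method glance policy_handle
#' @export
glance.policy_handle <- function(x, ...) {
  log <- x$episode_log
  n <- nrow(log)
  q <- max(1L, floor(n / 4))
  tibble::tibble(
    steps_trained = x$steps_trained,
    episodes = n,
    first_quartile_return = mean(log$return_[seq_len(q)]),
    final_quartile_return = mean(log$return_[(n - q + 1):n]),
    final_mean_error_p = mean(log$mean_error_p[(n - q + 1):n]),
    entropy_weight = x$entropy_weight
  )
}

#' Learning curve of a trained policy
#'
#' @param object A `policy_handle`.
#' @param ... Unused.
#' @return A ggplot object of episode return against episode number.
#' @method autoplot policy_handle
#' @export
autoplot.policy_handle <- function(object, ...) {
  ggplot2::ggplot(object$episode_log,
                  ggplot2::aes(x = .data$episode, y = .data$return_)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::labs(x = "episode", y = "episode return")
}

# Deterministic (mean-action) policy rollout over one trial.
rollout_trial <- function(policy, env, target_id) {
  state <- env_reset(env, target_id)
  n <- env$n_steps
  q5 <- matrix(0, n, 5)
  phases <- character(n)
  err <- numeric(n)
  times <- numeric(n)
  for (k in seq_len(n)) {
    q5[k, ] <- state$q[c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")]
    phases[k] <- state$phase
    times[k] <- state$t
    pose <- forward_kinematics(env$arm, state$q)
    err[k] <- vec_norm(pose$fingertip - state$moving_point)
    obs <- env_observe(state, env)
    act <- actor_sample(policy$actor, matrix(obs, 1, env_obs_dim()),
                        deterministic = TRUE)$action
    state <- step_dynamics(state, as.numeric(act), env)
  }
  colnames(q5) <- angle_columns()
  list(t = times, angles = q5, phase = phases, error_p = err)
}

#' Evaluate a policy's tracking error over a full schedule
#'
#' Deterministic rollouts over one pass of every target; returns the mean
#' position error per trial.
#'
#' @param policy A `policy_handle`.
#' @param arm,grid,timing Environment definition (must match training).
#' @return Tibble with `target_id` and `mean_error_p` (metres).
#' @export
evaluate_policy <- function(policy, arm, grid, timing) {
  env <- reach_env(arm, grid, timing, policy$env_config$weights,
                   max_speed = policy$env_config$max_speed,
                   neutral_swivel_deg = policy$env_config$neutral_swivel_deg)
  purrr::map_dfr(grid$targets$target_id, function(tid) {
    ro <- rollout_trial(policy, env, tid)
    tibble::tibble(target_id = tid, mean_error_p = mean(ro$error_p))
  })
}

#' Extract a synthetic motion dataset from a trained policy
#'
#' Deterministic-mode rollouts over `trial_schedule(grid, timing,
#' repetitions)`; records the five dataset angles per sample at the protocol
#' sampling rate under subject id `"DRL"`.
#'
#' @param policy A `policy_handle`.
#' @param arm,grid,timing Environment definition.
#' @param repetitions Repetitions per target (default 4).
#' @param session Session number recorded in the dataset (default 1).
#' @return Motion tibble with `repetitions * n_targets` trials.
#' @export
clone_dataset <- function(policy, arm, grid, timing, repetitions = 4,
                          session = 1) {
  if (!inherits(policy, "policy_handle") || policy$steps_trained <= 0) {
    abort_reachclone("policy has not been trained", "reachclone_invalid_state")
  }
  env <- reach_env(arm, grid, timing, policy$env_config$weights,
                   max_speed = policy$env_config$max_speed,
                   neutral_swivel_deg = policy$env_config$neutral_swivel_deg)
  sched <- trial_schedule(grid, timing, repetitions)
  purrr::pmap_dfr(sched, function(trial, repetition, target_id, start_s) {
    ro <- rollout_trial(policy, env, target_id)
    tibble::tibble(subject_id = "DRL", target_id = as.integer(target_id),
                   repetition = as.integer(repetition),
                   session = as.integer(session),
                   t = ro$t,
                   S_rot = ro$angles[, 1], S_flex = ro$angles[, 2],
                   S_abd = ro$angles[, 3], E_pron = ro$angles[, 4],
                   E_flex = ro$angles[, 5],
                   phase = ro$phase)
  })
}
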