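make_env <- function(weights = reward_weights()) {
  reach_env(test_arm(), test_grid(), test_timing(), weights)
}

# hand-built state at the reference pose (arm straight forward, palm down)
straight_state <- function(env, moving_point, e_pron_deg = 0) {
  q <- stats::setNames(rep(0, 7), joint_order())
  q["E_pron"] <- e_pron_deg
  list(q = q, q_dot = rep(0, 7), moving_point = moving_point,
       phase = "reach", t = 0, target_id = 1L,
       pose = forward_kinematics(env$arm, q))
}

test_that("step_dynamics integrates, clips and advances the moving point", {
  env <- make_env()
  s0 <- env_reset(env, 1)
  s1 <- step_dynamics(s0, rep(0, 7), env)
  expect_equal(s1$q, s0$q)
  expect_equal(s1$t, s0$t + env$timing$dt)

  # +1 elbow flexion at 180 deg/s for 0.02 s adds exactly 3.6 degrees
  a <- rep(0, 7); a[4] <- 1
  s2 <- step_dynamics(s0, a, env)
  expect_equal(unname(s2$q["E_flex"] - s0$q["E_flex"]), 3.6, tolerance = 1e-12)

  # clipping at the joint limit
  s_lim <- s0
  s_lim$q["E_flex"] <- env$arm$joint_limits["E_flex", "max"]
  s3 <- step_dynamics(s_lim, a, env)
  expect_equal(unname(s3$q["E_flex"]),
               unname(env$arm$joint_limits["E_flex", "max"]))

  # determinism
  s4 <- step_dynamics(s0, a, env)
  expect_identical(s2$q, s4$q)
})

test_that("reward matches hand arithmetic on constructed states", {
  env <- make_env(reward_weights(b = 2, c = 0.05, d = 0.5))
  tip <- c(0.73, 0, 0)

  # fingertip on the moving point, zero action, palm exactly down: reward 0
  r0 <- env_reward(straight_state(env, tip), rep(0, 7), env)
  expect_equal(r0$reward, 0, tolerance = 1e-12)
  expect_equal(r0$terms$error_p, 0, tolerance = 1e-12)
  expect_equal(r0$terms$error_o, 0, tolerance = 1e-12)

  # error_p = 0.1, ||a||^2 = 1, error_o = 0.2  ->  -(0.2 + 0.05 + 0.1)
  st <- straight_state(env, c(0.63, 0, 0),
                       e_pron_deg = acos(0.8) * 180 / pi)
  a <- c(1, rep(0, 6))
  r1 <- env_reward(st, a, env)
  expect_equal(r1$terms$error_p, 0.1, tolerance = 1e-9)
  expect_equal(r1$terms$action_sq, 1)
  expect_equal(r1$terms$error_o, 0.2, tolerance = 1e-9)
  expect_equal(r1$reward, -0.35, tolerance = 1e-9)

  # doubling the position error strictly decreases the reward
  far <- env_reward(straight_state(env, c(0.53, 0, 0)), a, env)
  expect_lt(far$reward, r1$reward)
})

test_that("reward is never positive and vanishes only with all terms", {
  env <- make_env()
  set.seed(11)
  for (i in 1:200) {
    q <- sapply(seq_len(7), function(j)
      runif(1, env$arm$joint_limits[j, 1], env$arm$joint_limits[j, 2]))
    st <- list(q = stats::setNames(q, joint_order()),
               moving_point = c(runif(1, 0.1, 0.6), runif(1, -0.3, 0.3),
                                runif(1, -0.3, 0)),
               phase = "reach", t = 0, target_id = 1L)
    a <- runif(7, -1, 1)
    r <- env_reward(st, a, env)
    expect_lte(r$reward, 0)
    if (r$reward == 0) {
      expect_equal(r$terms$error_p + r$terms$action_sq + r$terms$error_o, 0)
    }
  }
})

test_that("invalid reward weights and training budgets are rejected", {
  expect_error(reward_weights(b = 0), class = "reachclone_invalid_config")
  expect_error(reward_weights(c = -1), class = "reachclone_invalid_config")
  expect_error(train_policy(test_arm(), test_grid(), test_timing(), steps = 0),
               class = "reachclone_invalid_config")
})

test_that("actor and critic gradients agree with finite differences", {
  set.seed(21)
  n_obs <- 3; n_act <- 2; B <- 5
  actor <- reachclone:::mlp_init(c(n_obs, 6, 2 * n_act))
  q1 <- reachclone:::mlp_init(c(n_obs + n_act, 6, 1))
  q2 <- reachclone:::mlp_init(c(n_obs + n_act, 6, 1))
  obs <- matrix(rnorm(B * n_obs), B, n_obs)
  eps <- matrix(rnorm(B * n_act), B, n_act)
  alpha <- 0.3

  actor_loss <- function(params) {
    smp <- reachclone:::actor_sample(params, obs, eps = eps)
    qin <- cbind(obs, smp$action)
    qv <- pmin(reachclone:::mlp_forward(q1, qin)$out,
               reachclone:::mlp_forward(q2, qin)$out)
    mean(alpha * smp$logp - qv)
  }
  smp <- reachclone:::actor_sample(actor, obs, eps = eps)
  qin <- cbind(obs, smp$action)
  f1 <- reachclone:::mlp_forward(q1, qin)
  f2 <- reachclone:::mlp_forward(q2, qin)
  use1 <- f1$out <= f2$out
  ones <- matrix(1, B, 1)
  d1 <- reachclone:::mlp_backward(q1, f1, ones)$dX[, n_obs + seq_len(n_act)]
  d2 <- reachclone:::mlp_backward(q2, f2, ones)$dX[, n_obs + seq_len(n_act)]
  dq_da <- d1 * as.numeric(use1) + d2 * as.numeric(!use1)
  ga <- reachclone:::actor_backward(actor, smp, dq_da, alpha, B)
  for (k in names(actor)) {
    idx <- sample(length(actor[[k]]), min(4, length(actor[[k]])))
    for (i in idx) {
      h <- 1e-6
      pp <- actor; pp[[k]][i] <- pp[[k]][i] + h
      pm <- actor; pm[[k]][i] <- pm[[k]][i] - h
      num <- (actor_loss(pp) - actor_loss(pm)) / (2 * h)
      expect_equal(ga[[k]][i], num, tolerance = 1e-3)
    }
  }

  # critic MSE path
  target <- matrix(rnorm(B), B, 1)
  critic_loss <- function(params) {
    mean((reachclone:::mlp_forward(params, qin)$out - target)^2)
  }
  fc <- reachclone:::mlp_forward(q1, qin)
  gc <- reachclone:::mlp_backward(q1, fc, 2 * (fc$out - target) / B)$grads
  for (k in names(q1)) {
    i <- sample(length(q1[[k]]), 1)
    h <- 1e-6
    pp <- q1; pp[[k]][i] <- pp[[k]][i] + h
    pm <- q1; pm[[k]][i] <- pm[[k]][i] - h
    num <- (critic_loss(pp) - critic_loss(pm)) / (2 * h)
    expect_equal(gc[[k]][i], num, tolerance = 1e-3)
  }
})

test_that("environment observation encodes scaled joints and task geometry", {
  env <- make_env()
  s <- env_reset(env, 2)
  obs <- reachclone:::env_observe(s, env)
  expect_length(obs, 16)
  expect_true(all(obs[1:7] >= -1 & obs[1:7] <= 1))
  # at reset the fingertip sits on the moving point (the grid center)
  expect_equal(unname(obs[8:10]), unname(obs[11:13]), tolerance = 1e-6)
  expect_equal(unname(obs[14:16]), rep(0, 3), tolerance = 1e-6)
})
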