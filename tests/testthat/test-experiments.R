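# Scenario machinery is exercised on a small noiseless panel with equal
# swivel styles, where cross-subject transfer is exact and decoders must
# reach sub-degree accuracy. A noiseless surrogate relabelled "DRL" stands in
# for the cloned dataset so that the orchestration can be tested without a
# reinforcement-learning run (the cloning path itself is covered elsewhere).

small_panel <- function(n = 3, swivel = 24, sessions = 2, reps = 1) {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  profiles <- lapply(seq_len(n), function(i)
    subject_profile(paste0("S", i), swivel_deg = swivel, angle_noise_sd = 0,
                    timing_jitter_frac = 0, seed = 200 + i))
  synthesize_subjects(profiles, arm, grid, tm, repetitions = reps,
                      sessions = sessions)
}

fake_drl <- function(reps = 1) {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  ds <- synthesize_subject(subject_profile("X", 24, 0, 0.3, 0, seed = 999),
                           arm, grid, tm, repetitions = reps, sessions = 1)
  dplyr::mutate(ds, subject_id = "DRL")
}

small_cfg <- function(scenario, seed = 1) {
  scenario_config(scenario, arm = test_arm(), grid = test_grid(),
                  timing = fast_timing(),
                  predictor_cfg = scenario_test_cfg(seed = seed),
                  wc = window_config(window_len = 4, stride = 1),
                  seed = seed)
}

test_that("sufficient-data scenario evaluates both decoders per held-out subject", {
  surr <- small_panel()
  drl <- fake_drl()
  rep1 <- scenario_sufficient_data(surr, drl, small_cfg("sufficient"))
  expect_s3_class(rep1, "experiment_report")
  expect_equal(nrow(rep1$per_subject), 3 * 2)
  expect_setequal(unique(rep1$per_subject$model),
                  c("DRL-Model", "Human-Avg-Model"))
  # noiseless panel with a single shared swivel: transfer is exact, so both
  # decoders must be accurate to within a degree
  expect_lt(max(rep1$per_subject$overall_rmse_deg), 1.0)
  # aggregate means equal recomputation from the per-subject rows
  g <- glance(rep1)
  for (m in g$model) {
    expect_equal(g$mean_rmse_deg[g$model == m],
                 mean(rep1$per_subject$overall_rmse_deg[
                   rep1$per_subject$model == m]), tolerance = 1e-9)
  }
})

test_that("the cloned training set must not contain surrogate subjects", {
  surr <- small_panel(2)
  bad <- dplyr::mutate(fake_drl(), subject_id = "S1")
  expect_error(scenario_sufficient_data(surr, bad, small_cfg("sufficient")),
               class = "reachclone_invalid_state")
})

test_that("limited-data scenario: hybrid coverage helps and the report is consistent", {
  surr <- small_panel(2)
  drl <- fake_drl()
  cfg <- small_cfg("limited")
  rep2 <- scenario_limited_data(surr, drl, cfg)
  expect_s3_class(rep2, "experiment_report")
  # 2 training subjects x 1 test subject x 2 models
  expect_equal(nrow(rep2$per_pair), 4)
  imp <- rep2$improvement
  expect_equal(imp$improvement_pct,
               (imp$sparse_rmse_deg - imp$hybrid_rmse_deg) /
                 imp$sparse_rmse_deg * 100, tolerance = 1e-9)
  # in the noiseless shared-swivel limit, added target coverage cannot hurt
  expect_lte(mean(imp$hybrid_rmse_deg), mean(imp$sparse_rmse_deg) + 0.1)
})

test_that("training sets never contain test-subject trials", {
  surr <- small_panel(2)
  train <- surr[surr$subject_id == "S1" & surr$session == 1, ]
  test <- surr[surr$subject_id == "S2" & surr$session == 2, ]
  expect_silent(reachclone:::assert_disjoint_trials(train, test))
  expect_error(reachclone:::assert_disjoint_trials(surr, test),
               class = "reachclone_invalid_state")
})

test_that("scenario configuration enforces the sparse/fill split", {
  expect_error(small_cfg("nonsense"))
  expect_error(scenario_config("limited", sparse_human_targets = c(1, 2),
                               drl_fill_targets = c(2, 3)),
               class = "reachclone_invalid_config")
  expect_error(scenario_config("limited", sparse_human_targets = c(0, 1)),
               class = "reachclone_invalid_config")
})

test_that("the command line refuses unknown commands and missing inputs", {
  expect_equal(run_cli(character(0)), 1L)
  expect_equal(run_cli("frobnicate"), 1L)
  expect_equal(suppressMessages(run_cli(c("train-predictor", "--out", tempdir()))), 1L)
  expect_equal(suppressMessages(
    run_cli(c("synth-subjects", "--config", "/no/such/file.yaml",
              "--out", tempdir()))), 1L)
})

test_that("the command line generates targets and surrogate data with a manifest", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "cfg.yaml")
  yaml::write_yaml(list(
    timing = list(reach_s = 0.6, touch_hold_s = 0.2, return_s = 0.6,
                  center_wait_s = 0.2, dt = 0.05),
    subjects = list(s1 = list(id = "S1", swivel_deg = 20, seed = 11,
                              angle_noise_sd = 0, timing_jitter_frac = 0),
                    s2 = list(id = "S2", swivel_deg = 30, seed = 12,
                              angle_noise_sd = 0, timing_jitter_frac = 0))),
    cfgfile)

  expect_equal(run_cli(c("generate-targets", "--config", cfgfile,
                         "--out", file.path(out, "g"))), 0L)
  targets <- readr::read_csv(file.path(out, "g", "targets.csv"),
                             show_col_types = FALSE)
  expect_equal(nrow(targets), 8)
  expect_true(file.exists(file.path(out, "g", "manifest.json")))

  expect_equal(run_cli(c("synth-subjects", "--config", cfgfile,
                         "--reps", "1", "--sessions", "1",
                         "--out", file.path(out, "s"))), 0L)
  ds <- read_dataset(file.path(out, "s", "surrogate_data.csv"))
  expect_setequal(unique(ds$subject_id), c("S1", "S2"))
  manifest <- jsonlite::read_json(file.path(out, "s", "manifest.json"))
  expect_equal(manifest$package, "reachclone")
  expect_true(nchar(manifest$input_md5$config) == 32)
})
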