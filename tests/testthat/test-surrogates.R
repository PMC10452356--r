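test_that("minimum-jerk profile satisfies its boundary conditions", {
  expect_equal(minimum_jerk_profile(0), 0)
  expect_equal(minimum_jerk_profile(1), 1)
  expect_equal(minimum_jerk_profile(0.5), 0.5)
  # endpoint derivatives vanish
  h <- 1e-6
  expect_lt(abs(minimum_jerk_profile(h) - minimum_jerk_profile(0)) / h, 1e-4)
  expect_lt(abs(minimum_jerk_profile(1) - minimum_jerk_profile(1 - h)) / h, 1e-4)
  # peak normalized speed 1.875 at tau = 0.5 (analytic maximum of the quintic)
  tau <- seq(0, 1, by = 1e-4)
  speed <- diff(minimum_jerk_profile(tau)) / 1e-4
  expect_equal(max(speed), 1.875, tolerance = 1e-3)
  expect_error(minimum_jerk_profile(1.2), class = "reachclone_range")
})

test_that("noiseless surrogate trials follow the ideal minimum-jerk path", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  prof <- clean_profile()
  tr <- synthesize_trial(prof, arm, grid, tm, target_id = 4)
  ang <- as.matrix(tr[, c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")])
  # reconstruct the fingertip with the subject's wrist flexion (the recorded
  # channels omit the wrist, so recompute the full IK pose)
  ref <- reachclone:::fingertip_reference_path(grid, tm, 4)
  for (i in seq_len(nrow(tr))) {
    q <- inverse_kinematics_swivel(arm, c(ref$x[i], ref$y[i], ref$z[i]),
                                   prof$swivel_deg)
    fp <- forward_kinematics(arm, q)$fingertip
    expect_lt(sqrt(sum((fp - c(ref$x[i], ref$y[i], ref$z[i]))^2)), 1e-4)
    expect_equal(unname(ang[i, ]),
                 unname(q[c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")]),
                 tolerance = 1e-9)
  }
})

test_that("trial synthesis is deterministic and seed-separated", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  prof <- subject_profile("S1", 24, seed = 101)
  t1 <- synthesize_trial(prof, arm, grid, tm, 2, 1, 1)
  t2 <- synthesize_trial(prof, arm, grid, tm, 2, 1, 1)
  expect_identical(t1, t2)
  t3 <- synthesize_trial(prof, arm, grid, tm, 2, 2, 1)
  expect_false(identical(t1$E_flex, t3$E_flex))
  prof2 <- subject_profile("S1", 24, seed = 102)
  t4 <- synthesize_trial(prof2, arm, grid, tm, 2, 1, 1)
  expect_false(identical(t1$E_flex, t4$E_flex))
})

test_that("injected angle noise has the configured magnitude", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  noisy <- subject_profile("S1", 24, angle_noise_sd = 2,
                           timing_jitter_frac = 0, seed = 77)
  clean <- subject_profile("S1", 24, angle_noise_sd = 0,
                           timing_jitter_frac = 0, seed = 77)
  devs <- c()
  for (tid in 1:8) for (rep_i in 1:4) {
    a <- synthesize_trial(noisy, arm, grid, tm, tid, rep_i, 1)
    b <- synthesize_trial(clean, arm, grid, tm, tid, rep_i, 1)
    for (col in c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")) {
      devs <- c(devs, a[[col]] - b[[col]])
    }
  }
  expect_gt(sd(devs), 1.5)
  expect_lt(sd(devs), 2.5)
})

test_that("subject synthesis produces the session x repetition x target grid", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  ds <- synthesize_subject(clean_profile(), arm, grid, tm,
                           repetitions = 4, sessions = 2)
  keys <- dplyr::distinct(ds, target_id, repetition, session)
  expect_equal(nrow(keys), 64)
  ds1 <- synthesize_subject(clean_profile(), arm, grid, tm,
                            repetitions = 1, sessions = 1)
  expect_equal(nrow(dplyr::distinct(ds1, target_id, repetition, session)), 8)
  expect_error(synthesize_subject(clean_profile(), arm, grid, tm,
                                  repetitions = 0),
               class = "reachclone_invalid_config")
})

test_that("cross-subject averaging is an identity for one subject and linear", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  ds <- synthesize_subject(clean_profile(), arm, grid, tm,
                           repetitions = 1, sessions = 1)
  avg1 <- average_subjects(ds, tm)
  # identity modulo resampling: the noiseless jitter-free trial is already on
  # the nominal timeline
  tr <- ds[ds$target_id == 1, ]
  av <- avg1[avg1$target_id == 1, ]
  expect_equal(av$E_flex, tr$E_flex, tolerance = 1e-9)
  expect_equal(unique(avg1$subject_id), "AVG")

  shifted <- dplyr::mutate(ds, subject_id = "S9",
                           dplyr::across(dplyr::all_of(
                             c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")),
                             function(x) x + 2))
  avg2 <- average_subjects(dplyr::bind_rows(ds, shifted), tm)
  expect_equal(avg2$E_flex[avg2$target_id == 1], tr$E_flex + 1,
               tolerance = 1e-9)
  # averaged angles stay inside the pointwise envelope of the inputs
  expect_true(all(avg2$E_pron >= pmin(ds$E_pron, shifted$E_pron) - 1e-9))
  expect_true(all(avg2$E_pron <= pmax(ds$E_pron, shifted$E_pron) + 1e-9))
})

test_that("averaging rejects mismatched trial structures", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  ds <- synthesize_subject(clean_profile(), arm, grid, tm, 1, 1)
  partial <- dplyr::mutate(ds[ds$target_id <= 4, ], subject_id = "S2")
  expect_error(average_subjects(dplyr::bind_rows(ds, partial), tm),
               class = "reachclone_incompatible_datasets")
})

test_that("CSV round-trip preserves the dataset and validates the schema", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  ds <- synthesize_subject(subject_profile("S1", 24, seed = 5,
                                           timing_jitter_frac = 0),
                           arm, grid, tm, repetitions = 2, sessions = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path, tm)
  for (col in c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex", "t")) {
    expect_equal(back[[col]], ds[[col]], tolerance = 1e-9)
  }
  # expected row count: trials x samples per trial (jitter-free)
  expect_equal(nrow(back), 16 * round(trial_duration(tm) / tm$dt))
  # phase labels are reconstructed from the nominal proportions
  expect_equal(back$phase, ds$phase)

  txt <- readLines(path)
  txt[1] <- sub(",E_flex", ",E_bend", txt[1])
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, bad)
  expect_error(read_dataset(bad), class = "reachclone_schema")
})

test_that("schema validation names duplicated and irregular trials", {
  ds <- toy_dataset(n_trials = 2)
  expect_silent(validate_motion_dataset(ds))
  expect_error(validate_motion_dataset(dplyr::bind_rows(ds, ds[1:5, ])),
               class = "reachclone_schema")
  jitter <- ds
  jitter$t[3] <- jitter$t[3] + 0.003
  expect_error(validate_motion_dataset(jitter), class = "reachclone_schema")
  nofin <- ds
  nofin$E_flex[2] <- NaN
  expect_error(validate_motion_dataset(nofin), class = "reachclone_schema")
})
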