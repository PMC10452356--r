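test_that("pearson_r matches closed forms and rejects degenerate input", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_r(a, 2 * a + 1), 1, tolerance = 1e-12)
  expect_equal(pearson_r(a, -a), -1, tolerance = 1e-12)
  expect_equal(pearson_r(a, c(1, 3, 2, 4)), 0.8, tolerance = 1e-9)
  expect_error(pearson_r(a, c(1, 2, 3)), class = "reachclone_shape")
  expect_error(pearson_r(a, rep(1, 4)),
               class = "reachclone_undefined_correlation")
})

test_that("pearson_r is invariant under positive affine maps", {
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    r0 <- pearson_r(a, b)
    expect_equal(pearson_r(3.2 * a + 7, b), r0, tolerance = 1e-12)
    expect_equal(pearson_r(a, 0.05 * b - 2), r0, tolerance = 1e-12)
    expect_equal(pearson_r(a, -b), -r0, tolerance = 1e-12)
  }
})

test_that("interpret_r reproduces every correlation band with tie-breaks", {
  cases <- list(
    list(0.85, "strong positive"), list(0.7, "strong positive"),
    list(0.5, "distinct positive"), list(0.3, "distinct positive"),
    list(0.2, "weak positive"), list(0.1, "weak positive"),
    list(0.0, "not linear"), list(0.05, "not linear"),
    list(-0.05, "not linear"), list(-0.1, "weak negative"),
    list(-0.2, "weak negative"), list(-0.3, "distinct negative"),
    list(-0.5, "distinct negative"), list(-0.7, "strong negative"),
    list(-1, "strong negative"), list(1, "strong positive"))
  for (cs in cases) expect_equal(interpret_r(cs[[1]]), cs[[2]])
  expect_error(interpret_r(1.5), class = "reachclone_range")
})

test_that("rmse_deg matches hand arithmetic and a brute-force loop", {
  x <- c(10, 20, 30)
  expect_equal(rmse_deg(x, x), 0)
  expect_equal(rmse_deg(x + 2, x), 2, tolerance = 1e-12)
  expect_equal(rmse_deg(x + c(0, 3, 4), x), sqrt(25 / 3), tolerance = 1e-9)
  expect_error(rmse_deg(x, c(1, 2)), class = "reachclone_shape")
  set.seed(9)
  for (i in 1:10) {
    p <- rnorm(40); a <- rnorm(40)
    brute <- 0
    for (k in seq_along(p)) brute <- brute + (p[k] - a[k])^2
    expect_equal(rmse_deg(p, a), sqrt(brute / 40), tolerance = 1e-12)
  }
})

test_that("correlation matrix is 1 against itself and flips sign with a channel", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  ds <- synthesize_subject(clean_profile(), arm, grid, tm, 1, 1)
  self_cm <- correlation_matrix(ds, ds, target_id = 3, timing = tm)
  expect_equal(nrow(self_cm), 5)
  expect_equal(self_cm$r, rep(1, 5), tolerance = 1e-9)

  flipped <- dplyr::mutate(ds, subject_id = "F1",
                           S_flex = -.data$S_flex)
  both <- dplyr::bind_rows(ds, flipped)
  cm <- correlation_matrix(both, ds, target_id = 3, timing = tm)
  expect_equal(nrow(cm), 10)
  r_orig <- cm$r[cm$subject_id == "S1" & cm$channel == "S_flex"]
  r_flip <- cm$r[cm$subject_id == "F1" & cm$channel == "S_flex"]
  expect_equal(r_flip, -r_orig, tolerance = 1e-9)
  expect_error(correlation_matrix(ds, ds, target_id = 99, timing = tm),
               class = "reachclone_missing_data")
})

test_that("reaching error is zero for exact elbow predictions", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  tr <- synthesize_trial(clean_profile(), arm, grid, tm, 1)
  expect_equal(reaching_error_cm(tr, tr, arm, grid), 0, tolerance = 1e-12)
})

test_that("reaching error measures the apex fingertip displacement", {
  arm <- test_arm(); grid <- test_grid(); tm <- fast_timing()
  tr <- synthesize_trial(clean_profile(), arm, grid, tm, 1)
  # apex of the actual trial (via wrist-neutral FK, as the metric defines it)
  ang <- as.matrix(tr[, c("S_rot", "S_flex", "S_abd", "E_pron", "E_flex")])
  fp <- reachclone:::fk_fingertips(arm, ang)
  apex <- which.max(rowSums(sweep(fp, 2, grid$center)^2))
  # oracle: solve for the constant elbow-flexion offset that moves the apex
  # fingertip exactly 3 cm
  shift_at <- function(delta) {
    q <- ang[apex, ]; q["E_flex"] <- q["E_flex"] + delta
    sqrt(sum((reachclone:::fk_fingertips(arm, t(as.matrix(q)))[1, ] -
                fp[apex, ])^2)) - 0.03
  }
  delta <- uniroot(shift_at, c(0, 20), tol = 1e-10)$root
  pred <- dplyr::mutate(tr, E_flex = .data$E_flex + delta)
  expect_equal(reaching_error_cm(pred, tr, arm, grid), 3.0, tolerance = 1e-6)
  # samples away from the apex do not matter
  pred2 <- pred
  pred2$E_flex[-apex] <- pred2$E_flex[-apex] + 25
  expect_equal(reaching_error_cm(pred2, tr, arm, grid),
               reaching_error_cm(pred, tr, arm, grid), tolerance = 1e-12)
})

test_that("metrics_report aggregates per subject, target and channel", {
  ds <- toy_dataset(n_trials = 4, len = 50)
  preds <- dplyr::transmute(ds, subject_id = .data$subject_id,
                            target_id = .data$target_id,
                            repetition = .data$repetition,
                            session = .data$session, t = .data$t,
                            E_pron_pred = .data$E_pron + 1,
                            E_flex_pred = .data$E_flex)
  rep_m <- metrics_report(preds, ds)
  expect_s3_class(rep_m, "metrics_report")
  expect_equal(nrow(rep_m$per_channel), 4 * 2)
  expect_equal(rep_m$per_subject$overall_rmse_deg, sqrt(1 / 2),
               tolerance = 1e-9)
  pron_rows <- rep_m$per_channel[rep_m$per_channel$channel == "E_pron", ]
  expect_equal(pron_rows$rmse_deg, rep(1, 4), tolerance = 1e-9)
})
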