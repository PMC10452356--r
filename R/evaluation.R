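#' Pearson product-moment correlation
#'
#' @param a,b Numeric series of equal length (>= 2), neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) {
    abort_reachclone("series lengths differ", "reachclone_shape")
  }
  if (length(a) < 2) {
    abort_reachclone("need at least 2 samples", "reachclone_shape")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_reachclone("correlation is undefined for a constant series",
                     "reachclone_undefined_correlation")
  }
  stats::cor(a, b)
}

#' Interpret a Pearson correlation coefficient
#'
#' Maps `r` to the conventional descriptive band. Band endpoints are assigned
#' to the stronger band (e.g. `r = 0.7` is "strong positive").
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @return Character label: one of `"strong positive"`, `"distinct positive"`,
#'   `"weak positive"`, `"not linear"`, `"weak negative"`,
#'   `"distinct negative"`, `"strong negative"`.
#' @export
interpret_r <- function(r) {
  if (!is.finite(r) || abs(r) > 1 + 1e-12) {
    abort_reachclone("r must lie in [-1, 1]", "reachclone_range")
  }
  a <- abs(r)
  strength <- if (a >= 0.7) "strong" else if (a >= 0.3) "distinct" else
    if (a >= 0.1) "weak" else return("not linear")
  paste(strength, if (r > 0) "positive" else "negative")
}

#' Root mean squared error in degrees
#'
#' `sqrt(mean((pred - actual)^2))` over all samples.
#'
#' @param pred,actual Numeric series of equal length.
#' @return RMSE in the units of the inputs (degrees for joint angles).
#' @export
rmse_deg <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    abort_reachclone("series lengths differ", "reachclone_shape")
  }
  if (length(pred) < 1) {
    abort_reachclone("need at least 1 sample", "reachclone_shape")
  }
  sqrt(mean((pred - actual)^2))
}

# Fingertip positions for a matrix of recorded 5-angle samples, wrist neutral.
fk_fingertips <- function(arm, angles) {
  n <- nrow(angles)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    q <- joint_vector_from_angles(angles[i, "S_rot"], angles[i, "S_flex"],
                                  angles[i, "S_abd"], angles[i, "E_pron"],
                                  angles[i, "E_flex"])
    out[i, ] <- forward_kinematics(arm, q)$fingertip
  }
  out
}

# Time-normalized mean trial of one subject for one target: every matching
# trial resampled onto the nominal timeline, then averaged pointwise.
mean_trial_for_target <- function(data, subject, target_id, timing) {
  rows <- data[data$subject_id == subject & data$target_id == target_id, ]
  if (nrow(rows) == 0) {
    abort_reachclone(sprintf("subject %s has no trials for target %d",
                             subject, target_id),
                     "reachclone_missing_data")
  }
  keys <- dplyr::distinct(rows, .data$repetition, .data$session)
  trials <- purrr::pmap(keys, function(repetition, session) {
    resample_trial_nominal(
      rows[rows$repetition == repetition & rows$session == session, ], timing)
  })
  base <- trials[[1]]
  for (col in angle_columns()) {
    base[[col]] <- rowMeans(do.call(cbind, purrr::map(trials, col)))
  }
  base
}

#' Correlation matrix of motion datasets against a reference
#'
#' For each subject in `data` and each of the five recorded angle channels,
#' computes the Pearson correlation between that subject's time-normalized
#' mean trial and the reference's, for one target.
#'
#' @param data Motion tibble (one or more subjects, e.g. all surrogates plus
#'   the cloned dataset).
#' @param reference Motion tibble used as the benchmark (typically the
#'   cross-subject average).
#' @param target_id Target to compare.
#' @param timing Nominal `phase_timing` used for time normalization.
#' @return Tibble with columns `subject_id, target_id, channel, r`.
#' @export
correlation_matrix <- function(data, reference, target_id, timing) {
  if (!any(reference$target_id == target_id) ||
      !any(data$target_id == target_id)) {
    abort_reachclone(sprintf("target %d missing from a dataset", target_id),
                     "reachclone_missing_data")
  }
  ref_subject <- unique(reference$subject_id)[1]
  ref_trial <- mean_trial_for_target(reference, ref_subject, target_id, timing)
  purrr::map_dfr(unique(data$subject_id), function(s) {
    mt <- mean_trial_for_target(data, s, target_id, timing)
    tibble::tibble(
      subject_id = s,
      target_id = as.integer(target_id),
      channel = angle_columns(),
      r = purrr::map_dbl(angle_columns(),
                         function(col) pearson_r(mt[[col]], ref_trial[[col]]))
    )
  })
}

#' Forward-kinematic target-reaching error
#'
#' Replays two versions of the same trial through the arm's forward
#' kinematics with the wrist held neutral: the actual motion, and the actual
#' shoulder motion combined with predicted elbow angles. The reaching error is
#' the Euclidean distance between the two fingertip positions at the actual
#' motion's apex sample (maximum fingertip distance from the grid center),
#' in centimetres.
#'
#' @param pred_motion Trial tibble whose `E_pron`/`E_flex` are predictions
#'   (shoulder columns must equal `actual_motion`'s).
#' @param actual_motion The subject's actual trial tibble.
#' @param arm An `arm_model`.
#' @param grid The `target_grid` (for the center point).
#' @return Reaching error in cm.
#' @export
reaching_error_cm <- function(pred_motion, actual_motion, arm, grid) {
  if (nrow(pred_motion) != nrow(actual_motion)) {
    abort_reachclone("trials have different lengths", "reachclone_shape")
  }
  act <- as.matrix(actual_motion[, angle_columns()])
  prd <- act
  prd[, "E_pron"] <- pred_motion$E_pron
  prd[, "E_flex"] <- pred_motion$E_flex
  fp_act <- fk_fingertips(arm, act)
  d2 <- rowSums(sweep(fp_act, 2, grid$center)^2)
  apex <- which.max(d2)
  if ("phase" %in% names(actual_motion) &&
      !actual_motion$phase[apex] %in% c("reach", "touch")) {
    warning("apex sample falls outside the reach/touch phases; using it anyway",
            call. = FALSE)
  }
  q_pred <- joint_vector_from_angles(prd[apex, "S_rot"], prd[apex, "S_flex"],
                                     prd[apex, "S_abd"], prd[apex, "E_pron"],
                                     prd[apex, "E_flex"])
  fp_pred <- forward_kinematics(arm, q_pred)$fingertip
  100 * vec_norm(fp_pred - fp_act[apex, ])
}

#' Per-subject prediction metrics report
#'
#' Joins predicted elbow angles with the actual motion and computes, per
#' subject: Pearson correlation and RMSE per (target, elbow channel), the
#' overall RMSE (all test samples of both elbow channels concatenated), and
#' the per-target forward-kinematic reaching error.
#'
#' @param predictions Tibble with trial keys, `t`, and `E_pron_pred`,
#'   `E_flex_pred` columns (as returned by [predict_dataset()]).
#' @param actual Motion tibble with the same trials.
#' @param arm An `arm_model`; with `grid`, enables the reaching-error block
#'   (both may be `NULL` to skip it).
#' @param grid A `target_grid` or `NULL`.
#' @return A `metrics_report` object with tibbles `per_channel`,
#'   `per_subject`, and `reaching`.
#' @export
metrics_report <- function(predictions, actual, arm = NULL, grid = NULL) {
  joined <- dplyr::inner_join(
    predictions[, c(dataset_key_columns(), "t", "E_pron_pred", "E_flex_pred")],
    actual,
    by = c(dataset_key_columns(), "t"))
  if (nrow(joined) == 0) {
    abort_reachclone("predictions and actual data share no samples",
                     "reachclone_missing_data")
  }
  long <- tidyr::pivot_longer(
    dplyr::transmute(joined,
                     subject_id = .data$subject_id,
                     target_id = .data$target_id,
                     repetition = .data$repetition,
                     session = .data$session,
                     E_pron_err = .data$E_pron_pred - .data$E_pron,
                     E_flex_err = .data$E_flex_pred - .data$E_flex,
                     E_pron_pred = .data$E_pron_pred,
                     E_flex_pred = .data$E_flex_pred,
                     E_pron = .data$E_pron, E_flex = .data$E_flex),
    cols = c("E_pron", "E_flex"),
    names_to = "channel", values_to = "actual_angle")
  long$pred_angle <- ifelse(long$channel == "E_pron",
                            long$E_pron_pred, long$E_flex_pred)
  per_channel <- dplyr::summarise(
    dplyr::group_by(long, .data$subject_id, .data$target_id, .data$channel),
    pearson_r = pearson_r(.data$pred_angle, .data$actual_angle),
    rmse_deg = rmse_deg(.data$pred_angle, .data$actual_angle),
    .groups = "drop")
  per_subject <- dplyr::summarise(
    dplyr::group_by(long, .data$subject_id),
    overall_rmse_deg = rmse_deg(.data$pred_angle, .data$actual_angle),
    .groups = "drop")
  reaching <- NULL
  if (!is.null(arm) && !is.null(grid)) {
    trials <- dplyr::distinct(joined, .data$subject_id, .data$target_id,
                              .data$repetition, .data$session)
    reaching <- purrr::pmap_dfr(trials, function(subject_id, target_id,
                                                 repetition, session) {
      tr <- joined[joined$subject_id == subject_id &
                     joined$target_id == target_id &
                     joined$repetition == repetition &
                     joined$session == session, ]
      pred_tr <- dplyr::transmute(tr, E_pron = .data$E_pron_pred,
                                  E_flex = .data$E_flex_pred)
      err <- reaching_error_cm(pred_tr, tr, arm, grid)
      tibble::tibble(subject_id = subject_id, target_id = target_id,
                     repetition = repetition, session = session,
                     reaching_error_cm = err)
    })
  }
  structure(list(per_channel = per_channel, per_subject = per_subject,
                 reaching = reaching),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", nrow(x$per_subject), "subject(s); overall RMSE:",
      paste(sprintf("%s %.2f deg", x$per_subject$subject_id,
                    x$per_subject$overall_rmse_deg), collapse = ", "), "\n")
  if (!is.null(x$reaching)) {
    cat("  mean reaching error:",
        sprintf("%.2f cm", mean(x$reaching$reaching_error_cm)), "\n")
  }
  invisible(x)
}
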