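#' Scenario configuration
#'
#' Bundles everything the two evaluation scenarios need: the surrogate panel,
#' task geometry and timing, reward weights and training budgets, decoder
#' configuration and the sparse/fill target split used by the limited-data
#' scenario.
#'
#' @param scenario `"sufficient"` or `"limited"`.
#' @param profiles List of `subject_profile`s.
#' @param arm,grid,timing,weights Task definition objects.
#' @param sac_steps SAC training steps.
#' @param predictor_cfg A `predictor_config`.
#' @param wc A `window_config`.
#' @param sparse_human_targets Targets covered by the sparse human data.
#' @param drl_fill_targets Targets filled in from the cloned dataset; must be
#'   disjoint from `sparse_human_targets`.
#' @param test_repetitions Repetitions per target used from each test
#'   subject's held-out session (`NULL` = all).
#' @param seed Master seed.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario = c("sufficient", "limited"),
                            profiles = default_subject_profiles(),
                            arm = arm_model(), grid = target_grid(),
                            timing = phase_timing(),
                            weights = reward_weights(),
                            sac_steps = 2e5,
                            predictor_cfg = predictor_config(),
                            wc = window_config(),
                            sparse_human_targets = c(1, 3, 5, 7),
                            drl_fill_targets = c(2, 4, 6, 8),
                            test_repetitions = NULL,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (length(intersect(sparse_human_targets, drl_fill_targets)) > 0) {
    abort_reachclone("sparse and fill target sets must be disjoint",
                     "reachclone_invalid_config")
  }
  all_ids <- grid$targets$target_id
  if (!all(c(sparse_human_targets, drl_fill_targets) %in% all_ids)) {
    abort_reachclone("sparse/fill targets must be existing target ids",
                     "reachclone_invalid_config")
  }
  structure(list(scenario = scenario, profiles = profiles, arm = arm,
                 grid = grid, timing = timing, weights = weights,
                 sac_steps = sac_steps, predictor_cfg = predictor_cfg,
                 wc = wc, sparse_human_targets = sparse_human_targets,
                 drl_fill_targets = drl_fill_targets,
                 test_repetitions = test_repetitions,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

assert_disjoint_trials <- function(train, test) {
  key <- function(d) paste(d$subject_id, d$target_id, d$repetition, d$session)
  if (length(intersect(unique(key(train)), unique(key(test)))) > 0) {
    abort_reachclone("test-subject trials leaked into a training set",
                     "reachclone_invalid_state")
  }
  invisible(TRUE)
}

subset_session <- function(data, session) data[data$session == session, ]

limit_repetitions <- function(data, reps) {
  if (is.null(reps)) return(data)
  data[data$repetition <= reps, ]
}

predictor_cfg_with_seed <- function(cfg, seed) {
  cfg$seed <- as.integer(seed)
  cfg
}

#' Sufficient-data scenario: synthetic-only vs averaged-human decoders
#'
#' Builds (or reuses) the cloned dataset, then for every held-out subject
#' trains a decoder on the cross-subject average of the remaining subjects'
#' training sessions (the `Human-Avg-Model`) and evaluates both it and the
#' decoder trained purely on the cloned data (the `DRL-Model`) on the held-out
#' subject's test session.
#'
#' @param surrogate_data Motion tibble for the full surrogate panel
#'   (2 sessions).
#' @param drl_data Cloned motion tibble (subject `"DRL"`).
#' @param cfg A `scenario_config`.
#' @return An `experiment_report`.
#' @export
scenario_sufficient_data <- function(surrogate_data, drl_data, cfg) {
  subjects <- setdiff(unique(surrogate_data$subject_id), "DRL")
  if (length(subjects) < 2) {
    abort_reachclone("need at least two surrogate subjects",
                     "reachclone_invalid_config")
  }
  if (any(drl_data$subject_id != "DRL")) {
    abort_reachclone("the cloned dataset must contain only subject 'DRL'",
                     "reachclone_invalid_state")
  }
  drl_model <- train_predictor(drl_data,
                               predictor_cfg_with_seed(cfg$predictor_cfg,
                                                       derive_seed(cfg$seed, 999)),
                               cfg$wc)
  per_subject <- list(); per_channel <- list(); reaching <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test <- limit_repetitions(
      subset_session(surrogate_data[surrogate_data$subject_id == s, ], 2),
      cfg$test_repetitions)
    train_pool <- subset_session(
      surrogate_data[surrogate_data$subject_id != s, ], 1)
    assert_disjoint_trials(train_pool, test)
    avg_data <- average_subjects(train_pool, cfg$timing)
    avg_model <- train_predictor(avg_data,
                                 predictor_cfg_with_seed(cfg$predictor_cfg,
                                                         derive_seed(cfg$seed, i)),
                                 cfg$wc)
    for (m in c("DRL-Model", "Human-Avg-Model")) {
      model <- if (m == "DRL-Model") drl_model else avg_model
      preds <- predict_dataset(model, test)
      rep_m <- metrics_report(preds, test, cfg$arm, cfg$grid)
      per_subject[[length(per_subject) + 1]] <- tibble::tibble(
        model = m, subject_id = s,
        overall_rmse_deg = rep_m$per_subject$overall_rmse_deg,
        mean_reaching_error_cm = mean(rep_m$reaching$reaching_error_cm))
      per_channel[[length(per_channel) + 1]] <-
        dplyr::mutate(rep_m$per_channel, model = m)
      reaching[[length(reaching) + 1]] <-
        dplyr::mutate(rep_m$reaching, model = m)
    }
  }
  structure(list(scenario = "sufficient",
                 per_subject = dplyr::bind_rows(per_subject),
                 per_channel = dplyr::bind_rows(per_channel),
                 reaching = dplyr::bind_rows(reaching)),
            class = "experiment_report")
}

#' Limited-data scenario: sparse vs hybrid decoders, cross-subject
#'
#' For every training subject, a `Human-Sparse-Model` is trained on one
#' repetition of that subject's training session restricted to the sparse
#' targets, and a `Hybrid-Model` on that plus one cloned repetition of the
#' complementary fill targets. Both are evaluated on every other subject's
#' test session over all targets; the report carries mean cross-subject RMSE
#' per training subject and the percentage improvement
#' `(sparse - hybrid) / sparse * 100`.
#'
#' @inheritParams scenario_sufficient_data
#' @return An `experiment_report`.
#' @export
scenario_limited_data <- function(surrogate_data, drl_data, cfg) {
  subjects <- setdiff(unique(surrogate_data$subject_id), "DRL")
  if (length(subjects) < 2) {
    abort_reachclone("need at least two surrogate subjects",
                     "reachclone_invalid_config")
  }
  drl_fill <- drl_data[drl_data$repetition == 1 &
                         drl_data$target_id %in% cfg$drl_fill_targets, ]
  per_pair <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    own <- surrogate_data[surrogate_data$subject_id == s, ]
    sparse_train <- own[own$session == 1 & own$repetition == 1 &
                          own$target_id %in% cfg$sparse_human_targets, ]
    hybrid_train <- dplyr::bind_rows(sparse_train, drl_fill)
    sparse_model <- train_predictor(
      sparse_train,
      predictor_cfg_with_seed(cfg$predictor_cfg, derive_seed(cfg$seed, i, 1)),
      cfg$wc)
    hybrid_model <- train_predictor(
      hybrid_train,
      predictor_cfg_with_seed(cfg$predictor_cfg, derive_seed(cfg$seed, i, 2)),
      cfg$wc)
    for (s2 in setdiff(subjects, s)) {
      test <- limit_repetitions(
        subset_session(surrogate_data[surrogate_data$subject_id == s2, ], 2),
        cfg$test_repetitions)
      assert_disjoint_trials(sparse_train, test)
      for (m in c("Human-Sparse-Model", "Hybrid-Model")) {
        model <- if (m == "Human-Sparse-Model") sparse_model else hybrid_model
        preds <- predict_dataset(model, test)
        rep_m <- metrics_report(preds, test)
        per_pair[[length(per_pair) + 1]] <- tibble::tibble(
          train_subject = s, test_subject = s2, model = m,
          overall_rmse_deg = rep_m$per_subject$overall_rmse_deg)
      }
    }
  }
  per_pair <- dplyr::bind_rows(per_pair)
  means <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(per_pair, .data$train_subject, .data$model),
      mean_rmse_deg = mean(.data$overall_rmse_deg), .groups = "drop"),
    names_from = "model", values_from = "mean_rmse_deg")
  improvement <- dplyr::transmute(
    means,
    train_subject = .data$train_subject,
    sparse_rmse_deg = .data$`Human-Sparse-Model`,
    hybrid_rmse_deg = .data$`Hybrid-Model`,
    improvement_pct = (.data$`Human-Sparse-Model` - .data$`Hybrid-Model`) /
      .data$`Human-Sparse-Model` * 100)
  structure(list(scenario = "limited", per_pair = per_pair,
                 improvement = improvement),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", x$scenario, "scenario\n")
  print(glance(x))
  invisible(x)
}

#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) {
  if (x$scenario == "sufficient") x$per_subject else x$improvement
}

#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  if (x$scenario == "sufficient") {
    out <- dplyr::summarise(
      dplyr::group_by(x$per_subject, .data$model),
      mean_rmse_deg = mean(.data$overall_rmse_deg),
      mean_reaching_error_cm = mean(.data$mean_reaching_error_cm),
      .groups = "drop")
  } else {
    out <- tibble::tibble(
      sparse_mean_rmse_deg = mean(x$improvement$sparse_rmse_deg),
      hybrid_mean_rmse_deg = mean(x$improvement$hybrid_rmse_deg),
      mean_improvement_pct = mean(x$improvement$improvement_pct))
  }
  out
}

#' Comparison plot for an experiment report
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-subject RMSE by model.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  if (object$scenario == "sufficient") {
    ggplot2::ggplot(object$per_subject,
                    ggplot2::aes(x = .data$subject_id,
                                 y = .data$overall_rmse_deg,
                                 fill = .data$model)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "held-out subject", y = "overall RMSE (deg)",
                    fill = NULL)
  } else {
    ggplot2::ggplot(object$per_pair,
                    ggplot2::aes(x = .data$train_subject,
                                 y = .data$overall_rmse_deg,
                                 fill = .data$model)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "training subject",
                    y = "cross-subject RMSE (deg)", fill = NULL)
  }
}
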