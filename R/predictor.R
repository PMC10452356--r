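#' Sliding-window configuration for the decoder
#'
#' @param window_len Window length in samples (default 50, i.e. 1 s at 50 Hz).
#' @param stride Step between consecutive training windows, samples.
#' @return A `window_config` object.
#' @export
window_config <- function(window_len = 50, stride = 1) {
  if (window_len < 1 || stride < 1) {
    abort_reachclone("window_len and stride must be >= 1",
                     "reachclone_invalid_config")
  }
  structure(list(window_len = as.integer(window_len),
                 stride = as.integer(stride)),
            class = "window_config")
}

#' CNN-LSTM decoder configuration
#'
#' One 1-D convolution layer feeding a two-layer LSTM (256 units each by
#' default) and a dense output head, trained with Adam on mean squared error.
#'
#' @param conv_filters,conv_kernel Convolution width and kernel (samples).
#' @param lstm_units Units per LSTM layer.
#' @param lstm_layers Number of stacked LSTM layers.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Training epoch cap.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience, epochs without validation
#'   improvement.
#' @param val_fraction Fraction of trials held out for validation (split by
#'   whole trials, never by window).
#' @param seed Integer seed controlling initialisation, the trial split and
#'   minibatch shuffling.
#' @return A `predictor_config` object.
#' @export
predictor_config <- function(conv_filters = 64, conv_kernel = 3,
                             lstm_units = 256, lstm_layers = 2,
                             learning_rate = 1e-3, max_epochs = 200,
                             batch_size = 64, patience = 15,
                             val_fraction = 0.1, seed = 1L) {
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 lstm_units = as.integer(lstm_units),
                 lstm_layers = as.integer(lstm_layers),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "predictor_config")
}

shoulder_columns <- function() c("S_rot", "S_flex", "S_abd")
elbow_columns <- function() c("E_pron", "E_flex")

split_trials <- function(data) {
  keys <- dplyr::distinct(data, .data$subject_id, .data$target_id,
                          .data$repetition, .data$session)
  purrr::pmap(keys, function(subject_id, target_id, repetition, session) {
    data[data$subject_id == subject_id & data$target_id == target_id &
           data$repetition == repetition & data$session == session, ]
  })
}

#' Build supervised (shoulder window, elbow target) pairs
#'
#' Sliding windows of the three shoulder channels over each trial; the target
#' is the pair of elbow angles at the window's final sample. Windows never
#' span trial boundaries; trials shorter than the window are skipped with a
#' warning.
#'
#' @param data Motion tibble.
#' @param wc A `window_config`.
#' @return List with `X` (array `n x window_len x 3`), `Y`
#'   (matrix `n x 2`, columns `E_pron`, `E_flex`) and `trial_index`
#'   (integer trial id per window).
#' @export
make_windows <- function(data, wc) {
  trials <- split_trials(data)
  W <- wc$window_len
  xs <- list(); ys <- list(); idx <- list()
  skipped <- 0
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    n <- nrow(tr)
    if (n < W) { skipped <- skipped + 1; next }
    starts <- seq(1, n - W + 1, by = wc$stride)
    S <- as.matrix(tr[, shoulder_columns()])
    E <- as.matrix(tr[, elbow_columns()])
    Xk <- array(0, c(length(starts), W, 3))
    for (i in seq_along(starts)) {
      Xk[i, , ] <- S[starts[i]:(starts[i] + W - 1), ]
    }
    xs[[length(xs) + 1]] <- Xk
    ys[[length(ys) + 1]] <- E[starts + W - 1, , drop = FALSE]
    idx[[length(idx) + 1]] <- rep(k, length(starts))
  }
  if (skipped > 0) {
    warning(sprintf("%d trial(s) shorter than the window were skipped", skipped),
            call. = FALSE)
  }
  if (length(xs) == 0) {
    abort_reachclone("no trial is long enough for the requested window",
                     "reachclone_invalid_input")
  }
  n_tot <- sum(purrr::map_int(xs, function(x) dim(x)[1]))
  X <- array(0, c(n_tot, W, 3))
  at <- 1
  for (x in xs) {
    nk <- dim(x)[1]
    X[at:(at + nk - 1), , ] <- x
    at <- at + nk
  }
  list(X = X, Y = do.call(rbind, ys), trial_index = unlist(idx))
}

normalize_windows <- function(X, mu, sd) {
  for (j in 1:3) X[, , j] <- (X[, , j] - mu[j]) / sd[j]
  X
}

predictor_loss <- function(params, X, Y, cfg, batch = 1024) {
  n <- dim(X)[1]
  tot <- 0
  at <- 1
  while (at <= n) {
    ix <- at:min(n, at + batch - 1)
    fwd <- cnn_lstm_forward(params, X[ix, , , drop = FALSE], cfg$conv_kernel,
                            cfg$lstm_units, cfg$lstm_layers, keep_cache = FALSE)
    tot <- tot + sum((fwd$yhat - Y[ix, , drop = FALSE])^2)
    at <- at + batch
  }
  tot / (n * ncol(Y))
}

#' Train the CNN-LSTM shoulder-to-elbow decoder
#'
#' Fits the decoder by minibatch Adam on mean squared error over the pairs
#' from [make_windows()], with per-channel z-normalization fitted on the
#' training data only, a by-trial validation split and early stopping.
#' Deterministic given `cfg$seed`.
#'
#' @param train Motion tibble used for training.
#' @param cfg A `predictor_config`.
#' @param wc A `window_config`.
#' @return A `trained_predictor` object.
#' @export
train_predictor <- function(train, cfg = predictor_config(),
                            wc = window_config()) {
  validate_motion_dataset(train)
  with_local_seed(cfg$seed, {
    wins <- make_windows(train, wc)
    n <- dim(wins$X)[1]
    # split by whole trials
    trial_ids <- unique(wins$trial_index)
    n_val_trials <- floor(cfg$val_fraction * length(trial_ids))
    val_trials <- if (n_val_trials > 0) {
      sample(trial_ids, n_val_trials)
    } else integer(0)
    is_val <- wins$trial_index %in% val_trials
    x_mu <- purrr::map_dbl(1:3, function(j) mean(wins$X[!is_val, , j]))
    x_sd <- purrr::map_dbl(1:3, function(j) {
      s <- stats::sd(as.numeric(wins$X[!is_val, , j])); max(s, 1e-8)
    })
    y_mu <- colMeans(wins$Y[!is_val, , drop = FALSE])
    y_sd <- pmax(apply(wins$Y[!is_val, , drop = FALSE], 2, stats::sd), 1e-8)
    X <- normalize_windows(wins$X, x_mu, x_sd)
    Y <- sweep(sweep(wins$Y, 2, y_mu), 2, y_sd, "/")
    Xtr <- X[!is_val, , , drop = FALSE]; Ytr <- Y[!is_val, , drop = FALSE]
    Xva <- X[is_val, , , drop = FALSE]; Yva <- Y[is_val, , drop = FALSE]
    params <- cnn_lstm_init(3, cfg$conv_filters, cfg$conv_kernel,
                            cfg$lstm_units, cfg$lstm_layers, 2)
    opt <- adam_init(params)
    ntr <- dim(Xtr)[1]
    history <- list()
    best_val <- Inf; best_params <- params; bad_epochs <- 0
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(ntr)
      ep_loss <- 0; nb <- 0
      at <- 1
      while (at <= ntr) {
        ix <- ord[at:min(ntr, at + cfg$batch_size - 1)]
        Xb <- Xtr[ix, , , drop = FALSE]
        Yb <- Ytr[ix, , drop = FALSE]
        fwd <- cnn_lstm_forward(params, Xb, cfg$conv_kernel, cfg$lstm_units,
                                cfg$lstm_layers)
        resid <- fwd$yhat - Yb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort_reachclone("non-finite training loss", "reachclone_training_failure")
        }
        dy <- 2 * resid / length(resid)
        grads <- cnn_lstm_backward(params, fwd, dy, cfg$conv_kernel,
                                   cfg$lstm_units, cfg$lstm_layers)
        upd <- adam_step(opt, params, grads, cfg$learning_rate)
        opt <- upd$state; params <- upd$params
        ep_loss <- ep_loss + loss; nb <- nb + 1
        at <- at + cfg$batch_size
      }
      val_loss <- if (dim(Xva)[1] > 0) {
        predictor_loss(params, Xva, Yva, cfg)
      } else ep_loss / nb
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_loss = val_loss)
      if (val_loss < best_val - 1e-7) {
        best_val <- val_loss; best_params <- params; bad_epochs <- 0
      } else {
        bad_epochs <- bad_epochs + 1
        if (bad_epochs >= cfg$patience) break
      }
    }
    structure(list(params = best_params, config = cfg, window = wc,
                   norm = list(x_mu = x_mu, x_sd = x_sd,
                               y_mu = y_mu, y_sd = y_sd),
                   history = dplyr::bind_rows(history)),
              class = "trained_predictor")
  })
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat("<trained_predictor> CNN-LSTM,", x$config$lstm_layers, "LSTM layer(s) x",
      x$config$lstm_units, "units;", nrow(x$history), "epoch(s) trained\n")
  invisible(x)
}

#' Predict elbow angles from a shoulder-angle series
#'
#' Produces one `(E_pron, E_flex)` prediction per input sample from index
#' `window_len` onward; earlier samples are filled by edge-padding the first
#' prediction, so the output has the same length as the input.
#'
#' @param model A `trained_predictor`.
#' @param shoulder Matrix or data frame with columns `S_rot, S_flex, S_abd`
#'   (degrees), one row per sample.
#' @return Matrix `n x 2` with columns `E_pron`, `E_flex` (degrees).
#' @export
predict_elbow <- function(model, shoulder) {
  S <- as.matrix(as.data.frame(shoulder)[, shoulder_columns()])
  n <- nrow(S)
  W <- model$window$window_len
  if (n < W) {
    abort_reachclone(sprintf("series of %d samples is shorter than the %d-sample window",
                             n, W),
                     "reachclone_input_too_short")
  }
  starts <- seq_len(n - W + 1)
  X <- array(0, c(length(starts), W, 3))
  for (i in starts) X[i, , ] <- S[i:(i + W - 1), ]
  X <- normalize_windows(X, model$norm$x_mu, model$norm$x_sd)
  cfg <- model$config
  preds <- matrix(0, length(starts), 2)
  at <- 1
  while (at <= length(starts)) {
    ix <- at:min(length(starts), at + 511)
    fwd <- cnn_lstm_forward(model$params, X[ix, , , drop = FALSE],
                            cfg$conv_kernel, cfg$lstm_units, cfg$lstm_layers,
                            keep_cache = FALSE)
    preds[ix, ] <- fwd$yhat
    at <- at + 512
  }
  preds <- sweep(sweep(preds, 2, model$norm$y_sd, "*"), 2, model$norm$y_mu, "+")
  out <- rbind(matrix(preds[1, ], W - 1, 2, byrow = TRUE), preds)
  colnames(out) <- elbow_columns()
  out
}

#' Predict elbow angles for every trial of a motion dataset
#'
#' @param model A `trained_predictor`.
#' @param data Motion tibble (its shoulder columns are the decoder input).
#' @return Tibble with the trial keys, `t`, and `E_pron_pred`, `E_flex_pred`.
#' @export
predict_dataset <- function(model, data) {
  validate_motion_dataset(data)
  trials <- split_trials(data)
  purrr::map_dfr(trials, function(tr) {
    p <- predict_elbow(model, tr)
    tibble::tibble(subject_id = tr$subject_id, target_id = tr$target_id,
                   repetition = tr$repetition, session = tr$session,
                   t = tr$t, E_pron_pred = p[, 1], E_flex_pred = p[, 2])
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy trained_predictor
#' @export
tidy.trained_predictor <- function(x, ...) x$history

#' @method glance trained_predictor
#' @export
glance.trained_predictor <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    best_val_loss = min(x$history$val_loss),
    lstm_units = x$config$lstm_units,
    window_len = x$window$window_len
  )
}

#' Learning-curve plot for a trained decoder
#'
#' @param object A `trained_predictor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trained_predictor
#' @export
autoplot.trained_predictor <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, cols = c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE (normalized)", color = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
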