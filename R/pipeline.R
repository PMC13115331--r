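#' Experiment configuration
#'
#' Bundles every knob of the end-to-end study: geometry, protocol
#' emulation, dataset sizing, classifiers and training controls. Defaults
#' reproduce the package's reference study: two emulated participants
#' (seeds), three interference-free training sessions each, all six
#' confounder blocks, four classifiers.
#'
#' @param refinement Mesh refinement for the simulator (6 -> 576
#'   elements).
#' @param seeds Integer vector of participant seeds (each seed stands in
#'   for one participant: jittered anatomy plus independent noise).
#' @param n_sessions Interference-free training sessions per participant.
#' @param reps_train,reps_conf Repetitions per gesture in training /
#'   confounder blocks.
#' @param windows_per_class Balanced cap on training windows per class
#'   (sets the training problem size).
#' @param eval_windows_per_class Balanced cap on evaluation windows per
#'   class per condition.
#' @param noise_snr_db Measurement noise level (dB).
#' @param models Classifiers to fit.
#' @param nn_epochs,nn_batch_size,nn_patience Training-loop controls for
#'   the sequence models.
#' @param out_dir Optional directory for JSON/CSV artifacts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(refinement = 6L, seeds = c(1L, 2L),
                              n_sessions = 3L, reps_train = 10L,
                              reps_conf = 5L, windows_per_class = 50L,
                              eval_windows_per_class = 30L,
                              noise_snr_db = 40,
                              models = c("faspp_gru", "cnn_lstm", "knn",
                                         "svm"),
                              nn_epochs = 25L, nn_batch_size = 1L,
                              nn_patience = 6L, out_dir = NULL) {
  structure(list(refinement = refinement, seeds = seeds,
                 n_sessions = n_sessions, reps_train = reps_train,
                 reps_conf = reps_conf,
                 windows_per_class = windows_per_class,
                 eval_windows_per_class = eval_windows_per_class,
                 noise_snr_db = noise_snr_db, models = models,
                 nn_epochs = nn_epochs, nn_batch_size = nn_batch_size,
                 nn_patience = nn_patience, out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full gesture-recognition experiment
#'
#' For each participant seed: simulates the interference-free training
#' sessions, windows and splits them (70-15-15), fits every classifier on
#' the training split only, then evaluates on the held-out test split
#' (condition `none`) and on freshly simulated confounder blocks
#' (limb position L/R/U/D, time drift, contact rotation). Confusion
#' matrices are pooled across participants per model and condition; a
#' Friedman test over the paired (participant x condition) accuracy blocks
#' compares the models.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return An object of class `eit_experiment`: list with `metrics`
#'   (pooled per model x condition), `per_seed` (accuracy per seed, model,
#'   condition), `confusions` (nested list), `friedman` (tibble),
#'   `glances` (per-model fit summaries), `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  protocol <- adjacent_protocol()
  mesh <- build_disk_mesh(config$refinement)
  base <- base_conductivity(mesh)
  gain <- session_gain(mesh, base, protocol)
  conds <- list(
    limb_L = confounder("limb_position", direction = "L"),
    limb_R = confounder("limb_position", direction = "R"),
    limb_U = confounder("limb_position", direction = "U"),
    limb_D = confounder("limb_position", direction = "D"),
    time_drift = confounder("time_drift"),
    contact_rotation = confounder("contact_rotation")
  )

  per_seed <- list()
  confusions <- list()
  glances <- list()
  curves <- list()
  for (seed in config$seeds) {
    say("participant seed ", seed)
    tpl <- gesture_templates(participant_seed = seed)
    train_windows <- dplyr::bind_rows(lapply(seq_len(config$n_sessions),
                                             function(i) {
      s <- simulate_session(
        session_spec(reps = config$reps_train,
                     noise_snr_db = config$noise_snr_db,
                     seed = seed * 1000L + i),
        tpl, confounder("none"), mesh, protocol, base, gain = gain)
      # cap per session before pooling so the pooled window table stays
      # small in memory; the pooled cap below balances across sessions
      subsample_windows(window_sequences(s), config$windows_per_class,
                        seed = seed * 1000L + 50L + i)
    }))
    train_windows <- subsample_windows(train_windows,
                                       config$windows_per_class,
                                       seed = seed * 1000L + 77L)
    gc(verbose = FALSE)
    splits <- split_dataset(train_windows, seed = seed * 1000L + 88L)
    say("  train/val/test windows: ", nrow(splits$train), "/",
        nrow(splits$val), "/", nrow(splits$test))

    eval_sets <- list(none = splits$test)
    for (j in seq_along(conds)) {
      s <- simulate_session(
        session_spec(reps = config$reps_conf,
                     noise_snr_db = config$noise_snr_db,
                     seed = seed * 1000L + 100L + j),
        tpl, conds[[j]], mesh, protocol, base, gain = gain)
      w <- window_sequences(s)
      eval_sets[[names(conds)[j]]] <-
        subsample_windows(w, config$eval_windows_per_class,
                          seed = seed * 1000L + 200L + j)
    }
    rm(s, w)
    gc(verbose = FALSE)

    for (m in config$models) {
      say("  fitting ", m)
      fit <- switch(
        m,
        faspp_gru = nn_train(
          nn_init(faspp_gru_config(batch_size = config$nn_batch_size,
                                   max_epochs = config$nn_epochs,
                                   patience = config$nn_patience),
                  seed = seed * 10L + 1L),
          splits$train, splits$val, seed = seed * 10L + 2L),
        cnn_lstm = nn_train(
          nn_init(cnn_lstm_config(batch_size = config$nn_batch_size,
                                  max_epochs = config$nn_epochs,
                                  patience = config$nn_patience),
                  seed = seed * 10L + 3L),
          splits$train, splits$val, seed = seed * 10L + 4L),
        knn = fit_knn(splits$train, splits$val),
        svm = fit_svm(splits$train, splits$val)
      )
      ev <- evaluate_under_conditions(fit, eval_sets, model_name = m)
      ev$metrics$seed <- seed
      per_seed[[paste(seed, m)]] <- ev$metrics
      confusions[[as.character(seed)]][[m]] <- ev$confusions
      if (inherits(fit, "eit_nn")) {
        gl <- glance(fit); gl$seed <- seed
        glances[[paste(seed, m)]] <- gl
        cv <- tidy(fit); cv$model <- m; cv$seed <- seed
        curves[[paste(seed, m)]] <- cv
      }
    }
  }

  per_seed <- dplyr::bind_rows(per_seed)

  # pool confusion matrices across participants
  pool <- list()
  metrics <- list()
  for (m in config$models) {
    pool[[m]] <- list()
    for (cond in c("none", names(conds))) {
      cms <- lapply(config$seeds, function(s) {
        confusions[[as.character(s)]][[m]][[cond]]
      })
      cm <- Reduce(`+`, lapply(cms, unclass))
      class(cm) <- c("eit_confusion", class(cm))
      pool[[m]][[cond]] <- cm
      met <- compute_metrics(cm)
      metrics[[paste(m, cond)]] <-
        tibble::tibble(model = m, condition = cond,
                       accuracy = met$accuracy, macro_f1 = met$macro_f1,
                       n = sum(cm))
    }
  }
  metrics <- dplyr::bind_rows(metrics)

  friedman <- if (length(config$models) >= 2L) {
    acc <- per_seed |>
      dplyr::select("seed", "condition", "model", "accuracy") |>
      tidyr::pivot_wider(names_from = "model", values_from = "accuracy")
    compare_models(as.matrix(acc[, config$models]))
  }

  out <- structure(
    list(metrics = metrics, per_seed = per_seed, confusions = pool,
         friedman = friedman,
         glances = if (length(glances)) dplyr::bind_rows(glances),
         curves = if (length(curves)) dplyr::bind_rows(curves),
         config = config),
    class = "eit_experiment"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(metrics = metrics, per_seed = per_seed,
           friedman = out$friedman),
      file.path(config$out_dir, "metrics.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.eit_experiment <- function(x, ...) {
  cat("<eit_experiment> ", length(x$config$seeds), " participants, ",
      length(x$config$models), " models\n", sep = "")
  print(tidyr::pivot_wider(x$metrics[, c("model", "condition",
                                         "accuracy")],
                           names_from = "condition",
                           values_from = "accuracy"))
  invisible(x)
}

#' @method tidy eit_experiment
#' @export
tidy.eit_experiment <- function(x, ...) x$metrics

#' Accuracy-by-condition plot for an experiment
#'
#' @param object An `eit_experiment`.
#' @param ... Unused.
#' @return A ggplot bar chart of pooled accuracy per model and condition,
#'   with per-participant points overlaid.
#' @method autoplot eit_experiment
#' @export
autoplot.eit_experiment <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(.data$condition, .data$accuracy,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = object$per_seed,
      ggplot2::aes(.data$condition, .data$accuracy,
                   group = .data$model),
      position = ggplot2::position_dodge(width = 0.9), size = 0.8,
      show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}
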