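#' Train a sequence classifier with Adam and early stopping
#'
#' Minimizes the mean cross-entropy of one-hot gesture targets with the Adam
#' optimizer at the configured learning rate, recording per-epoch training
#' and validation loss and accuracy. Training stops when the validation loss
#' has not improved for `patience` epochs or at `max_epochs`; the parameters
#' of the best validation epoch are kept. Deterministic given `seed`.
#'
#' @param model An untrained `eit_nn` from [nn_init()].
#' @param train,val Window tibbles (disjoint) from [window_sequences()] /
#'   [split_dataset()].
#' @param seed Integer seed controlling batch shuffling.
#' @param verbose Print per-epoch progress.
#' @return The trained `eit_nn`, with `curves` (a tibble of learning
#'   curves) attached.
#' @export
nn_train <- function(model, train, val, seed = 1L, verbose = FALSE) {
  if (nrow(train) == 0L || nrow(val) == 0L) {
    stop("training and validation sets must be non-empty")
  }
  cfg <- model$cfg
  classes <- model$classes
  Xtr <- window_array(train)
  if (isTRUE(cfg$standardize)) model$scaler <- fit_scaler(Xtr)
  tr_inp <- nn_prepare(model$arch, Xtr, model$scaler)
  ytr <- match(train$label, classes)
  va_inp <- nn_prepare(model$arch, window_array(val), model$scaler)
  yva <- match(val$label, classes)
  if (anyNA(ytr) || anyNA(yva)) stop("labels outside the known classes")

  n <- tr_inp$Bw
  # deep-copy parameters: the optimizer updates them in place
  model$params <- lapply(model$params, function(p) p + 0)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  curves <- vector("list", cfg$max_epochs)
  wait <- 0L

  withr::with_seed(seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      tr_loss <- 0; tr_hits <- 0L
      for (start in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        yb <- ytr[idx]
        fw <- nn_forward_prepared(model, nn_slice(tr_inp, idx),
                                  keep_cache = TRUE)
        P <- fw$probs
        tr_loss <- tr_loss + cross_entropy(P, yb) * length(idx)
        tr_hits <- tr_hits + sum(max.col(t(P)) == yb)
        dZ <- P
        dZ[cbind(yb, seq_along(yb))] <- dZ[cbind(yb, seq_along(yb))] - 1
        dZ <- dZ / length(idx)
        grads <- nn_backward(model, fw$cache, dZ)
        state$t <- state$t + 1L
        adam_update(model$params, grads, state$m, state$v, cfg$lr,
                    0.9, 0.999, 1e-8, state$t)
      }
      va <- nn_evaluate_loss(model, va_inp, yva)
      curves[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = tr_loss / n, train_acc = tr_hits / n,
        val_loss = va$loss, val_acc = va$acc
      )
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                        epoch, tr_loss / n, tr_hits / n, va$loss, va$acc))
      }
      if (va$loss < best$loss - 1e-6) {
        best <- list(loss = va$loss,
                     params = lapply(model$params, function(p) p + 0),
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$curves <- dplyr::bind_rows(curves)
  model
}

# loss/accuracy on a prepared input, evaluated in inference batches
nn_evaluate_loss <- function(model, inp, y, batch = 256L) {
  n <- inp$Bw
  loss <- 0; hits <- 0L
  for (start in seq.int(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    P <- nn_forward_prepared(model, nn_slice(inp, idx))$probs
    loss <- loss + cross_entropy(P, y[idx]) * length(idx)
    hits <- hits + sum(max.col(t(P)) == y[idx])
  }
  list(loss = loss / n, acc = hits / n)
}

#' Predict gesture classes for windows
#'
#' @param object A trained `eit_nn`.
#' @param windows Window tibble.
#' @param ... Unused.
#' @return A tibble with predicted class `.pred`, the true `label`, and one
#'   probability column per class.
#' @export
predict.eit_nn <- function(object, windows, ...) {
  inp <- nn_prepare(object$arch, window_array(windows), object$scaler)
  n <- inp$Bw
  probs <- matrix(0, n, length(object$classes))
  for (start in seq.int(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    probs[idx, ] <- t(nn_forward_prepared(object, nn_slice(inp, idx))$probs)
  }
  colnames(probs) <- object$classes
  out <- tibble::tibble(
    .pred = object$classes[max.col(probs, ties.method = "first")],
    label = windows$label
  )
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' Learning curves of a fitted classifier
#'
#' @param x A trained `eit_nn`.
#' @param ... Unused.
#' @return Tibble of per-epoch train/validation loss and accuracy.
#' @method tidy eit_nn
#' @export
tidy.eit_nn <- function(x, ...) {
  if (is.null(x$curves)) stop("model is untrained")
  x$curves
}

#' One-row summary of a fitted classifier
#'
#' @param x A trained `eit_nn`.
#' @param ... Unused.
#' @return One-row tibble: architecture, parameter count, epochs run, best
#'   epoch, final validation loss and accuracy.
#' @method glance eit_nn
#' @export
glance.eit_nn <- function(x, ...) {
  tibble::tibble(
    arch = x$arch,
    n_parameters = n_params(x$params),
    epochs = if (is.null(x$curves)) 0L else max(x$curves$epoch),
    best_epoch = x$best_epoch %||% NA_integer_,
    val_loss = if (is.null(x$curves)) NA_real_ else
      x$curves$val_loss[which.min(x$curves$val_loss)],
    val_acc = if (is.null(x$curves)) NA_real_ else
      x$curves$val_acc[which.min(x$curves$val_loss)]
  )
}

#' Plot learning curves
#'
#' @param object A trained `eit_nn`.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy panels over epochs.
#' @method autoplot eit_nn
#' @export
autoplot.eit_nn <- function(object, ...) {
  cv <- tidy(object)
  long <- tidyr::pivot_longer(cv, -"epoch", names_to = c("split", "metric"),
                              names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
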