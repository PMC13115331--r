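# Conventional classifiers on flattened windows (11 frames x 208 channels
# -> 2288 features), sharing the window/split interface of the sequence
# models so comparisons are paired.

flatten_windows <- function(windows) {
  t(vapply(windows$v, as.numeric, numeric(length(windows$v[[1]]))))
}

#' K-nearest-neighbour gesture classifier
#'
#' Euclidean KNN on flattened, per-feature standardized windows with a
#' deterministic tie-break: among tied vote counts the class earliest in
#' the canonical class order wins. `k` is tuned on the validation split by
#' accuracy (grid 1, 3, 5, 7, 9) unless given explicitly.
#'
#' @param train,val Window tibbles; `val` is used for tuning `k`.
#' @param k Neighbour count; `NULL` (default) tunes on `val`.
#' @return An object of class `eit_knn` with a [predict()] method.
#' @export
fit_knn <- function(train, val = NULL, k = NULL) {
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain at least two classes")
  }
  X <- flatten_windows(train)
  mu <- colMeans(X)
  sd <- pmax(apply(X, 2, stats::sd), 1e-8)
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  obj <- structure(list(Z = Z, labels = train$label, mu = mu, sd = sd,
                        k = k %||% 1L, classes = gesture_classes()),
                   class = "eit_knn")
  if (is.null(k)) {
    if (is.null(val)) stop("supply either k or a validation set")
    accs <- vapply(c(1L, 3L, 5L, 7L, 9L), function(kk) {
      obj$k <- kk
      mean(predict(obj, val)$.pred == val$label)
    }, numeric(1))
    obj$k <- c(1L, 3L, 5L, 7L, 9L)[which.max(accs)]
  }
  obj
}

#' @export
print.eit_knn <- function(x, ...) {
  cat("<eit_knn> k =", x$k, "on", nrow(x$Z), "training windows\n")
  invisible(x)
}

#' @export
predict.eit_knn <- function(object, windows, ...) {
  Q <- sweep(sweep(flatten_windows(windows), 2, object$mu), 2, object$sd,
             "/")
  d2 <- outer(rowSums(Q^2), rowSums(object$Z^2), "+") -
    2 * tcrossprod(Q, object$Z)
  k <- object$k
  classes <- object$classes
  pred <- apply(d2, 1, function(dr) {
    nb <- object$labels[order(dr)[seq_len(k)]]
    votes <- table(factor(nb, levels = classes))
    classes[which.max(votes)]  # which.max takes the earliest tie
  })
  tibble::tibble(.pred = unname(pred), label = windows$label)
}

#' Support-vector-machine gesture classifier
#'
#' RBF-kernel SVM (libsvm via e1071, pairwise multiclass) on flattened
#' windows; features are standardized internally by the backend. Cost and
#' gamma are tuned on the validation split over small log-grids unless
#' given.
#'
#' @param train,val Window tibbles.
#' @param cost,gamma Hyperparameters; `NULL` tunes on `val`.
#' @return An object of class `eit_svm` with a [predict()] method.
#' @export
fit_svm <- function(train, val = NULL, cost = NULL, gamma = NULL) {
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain at least two classes")
  }
  X <- flatten_windows(train)
  y <- factor(train$label, levels = gesture_classes())
  g0 <- 1 / ncol(X)
  grid <- if (is.null(cost) || is.null(gamma)) {
    expand.grid(cost = c(1, 10, 100), gamma = g0 * c(0.1, 1))
  } else {
    data.frame(cost = cost, gamma = gamma)
  }
  best <- NULL; best_acc <- -1
  for (i in seq_len(nrow(grid))) {
    fit <- e1071::svm(X, y, kernel = "radial", cost = grid$cost[i],
                      gamma = grid$gamma[i])
    acc <- if (nrow(grid) == 1L) 1 else {
      if (is.null(val)) stop("supply cost and gamma, or a validation set")
      mean(as.character(
        stats::predict(fit, flatten_windows(val))) == val$label)
    }
    if (acc > best_acc) {
      best_acc <- acc
      best <- list(fit = fit, cost = grid$cost[i], gamma = grid$gamma[i])
    }
  }
  structure(best, class = "eit_svm")
}

#' @export
print.eit_svm <- function(x, ...) {
  cat("<eit_svm> RBF, cost =", x$cost, ", gamma =", signif(x$gamma, 3),
      "\n")
  invisible(x)
}

#' @export
predict.eit_svm <- function(object, windows, ...) {
  p <- stats::predict(object$fit, flatten_windows(windows))
  tibble::tibble(.pred = as.character(p), label = windows$label)
}

#' Fit any of the four gesture classifiers under one interface
#'
#' @param method One of `"faspp_gru"`, `"cnn_lstm"`, `"knn"`, `"svm"`.
#' @param train,val Window tibbles.
#' @param seed Seed for initialization and shuffling (sequence models).
#' @param ... Extra arguments passed to the model's config or fitter.
#' @return A fitted classifier with a [predict()] method returning a
#'   tibble with `.pred` and `label`.
#' @export
fit_classifier <- function(method = c("faspp_gru", "cnn_lstm", "knn",
                                      "svm"),
                           train, val, seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
         knn = fit_knn(train, val, ...),
         svm = fit_svm(train, val, ...),
         faspp_gru = nn_train(nn_init(faspp_gru_config(...), seed = seed),
                              train, val, seed = seed + 1L),
         cnn_lstm = nn_train(nn_init(cnn_lstm_config(...), seed = seed),
                             train, val, seed = seed + 1L))
}
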