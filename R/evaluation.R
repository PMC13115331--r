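#' Confusion matrix of predictions
#'
#' @param truth,pred Character vectors of true and predicted classes, or a
#'   prediction tibble (with columns `label`, `.pred`) as `truth`.
#' @param classes Class order (rows = truth, columns = predicted).
#' @return An integer matrix of class `eit_confusion`.
#' @export
confusion_matrix <- function(truth, pred = NULL,
                             classes = gesture_classes()) {
  if (is.data.frame(truth)) {
    pred <- truth$.pred
    truth <- truth$label
  }
  cm <- table(factor(truth, levels = classes),
              factor(pred, levels = classes))
  out <- matrix(as.integer(cm), length(classes), length(classes),
                dimnames = list(truth = classes, predicted = classes))
  class(out) <- c("eit_confusion", class(out))
  out
}

#' Classification metrics from a confusion matrix
#'
#' Multiclass accuracy is the trace over the total. Per-class precision,
#' recall and F1 use the one-vs-rest reduction of the matrix into TP, TN,
#' FP, FN counts; a zero denominator yields 0 by convention. F1 is
#' aggregated as the macro average over classes (classes are balanced by
#' design of the protocol).
#'
#' @param cm An `eit_confusion` (or plain square count matrix).
#' @return An object of class `eit_metrics`: list with `accuracy`,
#'   `macro_f1`, and `per_class` (tibble of class, precision, recall, f1).
#' @examples
#' cm <- matrix(c(8, 2, 2, 8), 2, 2)
#' compute_metrics(cm)$accuracy # 0.8
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(cm)
  if (length(cm) == 0L || sum(cm) == 0) stop("empty confusion matrix")
  total <- sum(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  structure(
    list(accuracy = sum(tp) / total,
         macro_f1 = mean(f1),
         per_class = tibble::tibble(class = classes, precision = precision,
                                    recall = recall, f1 = f1,
                                    support = rowSums(cm))),
    class = "eit_metrics"
  )
}

#' @export
print.eit_metrics <- function(x, ...) {
  cat("<eit_metrics> accuracy ", round(x$accuracy, 4), ", macro-F1 ",
      round(x$macro_f1, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy eit_metrics
#' @export
tidy.eit_metrics <- function(x, ...) x$per_class

#' @method glance eit_metrics
#' @export
glance.eit_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1)
}

#' Plot a confusion matrix
#'
#' @param object An `eit_confusion`.
#' @param ... Unused.
#' @return A ggplot heat map with counts annotated.
#' @method autoplot eit_confusion
#' @export
autoplot.eit_confusion <- function(object, ...) {
  df <- tibble::tibble(
    truth = rep(rownames(object), times = ncol(object)),
    predicted = rep(colnames(object), each = nrow(object)),
    n = as.integer(object)
  )
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  df$predicted <- factor(df$predicted, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted classifier across experimental conditions
#'
#' Applies the classifier (trained on interference-free data only) to one
#' held-out window set per condition and reports a metric row and a
#' confusion matrix for each.
#'
#' @param model A fitted classifier with a `predict` method.
#' @param datasets Named list of window tibbles keyed by condition (e.g.
#'   `none`, `limb_L`, ..., `time_drift`, `contact_rotation`).
#' @param model_name Label recorded in the report.
#' @return A list: `metrics` (tibble with condition, model, accuracy,
#'   macro_f1, n) and `confusions` (named list of `eit_confusion`).
#' @export
evaluate_under_conditions <- function(model, datasets,
                                      model_name = class(model)[1]) {
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be a named list keyed by condition")
  }
  rows <- list()
  cms <- list()
  for (cond in names(datasets)) {
    pr <- stats::predict(model, datasets[[cond]])
    cm <- confusion_matrix(pr)
    met <- compute_metrics(cm)
    cms[[cond]] <- cm
    rows[[cond]] <- tibble::tibble(condition = cond, model = model_name,
                                   accuracy = met$accuracy,
                                   macro_f1 = met$macro_f1,
                                   n = nrow(datasets[[cond]]))
  }
  list(metrics = dplyr::bind_rows(rows), confusions = cms)
}

#' Friedman test comparing paired model accuracies
#'
#' Nonparametric rank test over paired blocks (participants/seeds,
#' optionally crossed with conditions): are the models' accuracy
#' distributions distinguishable? Wraps the chi-square approximation of
#' the Friedman rank statistic.
#'
#' @param acc A blocks x models numeric matrix (or data frame) of paired
#'   accuracies; column names are model names.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `n_blocks`.
#' @export
compare_models <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) < 2L) stop("need at least two models to compare")
  if (nrow(acc) < 3L) stop("need at least three paired blocks")
  if (anyNA(acc)) stop("accuracies must be complete (paired blocks)")
  ft <- stats::friedman.test(acc)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # every block fully tied: no evidence of any difference
    stat <- 0
    p <- 1
  }
  tibble::tibble(statistic = stat, df = unname(ft$parameter),
                 p.value = p, n_blocks = nrow(acc))
}

#' Two-dimensional embedding of window features
#'
#' Projects high-dimensional features (flattened windows or classifier
#' frame embeddings) to 2-D for cluster visualization with Barnes-Hut
#' t-SNE, a standard nonlinear neighbour-embedding method. Deterministic
#' given `seed`; duplicate rows are collapsed before embedding and
#' restored afterwards so duplicated inputs map to identical coordinates.
#'
#' @param features Numeric matrix (rows = observations) or a window tibble
#'   (flattened internally).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; default adapts to the sample size.
#' @return A tibble with `x`, `y` (one row per input observation).
#' @export
embed_features <- function(features, seed = 1L, perplexity = NULL) {
  if (is.data.frame(features)) features <- flatten_windows(features)
  n <- nrow(features)
  if (n < 50L) stop("need at least 50 observations to embed")
  key <- apply(features, 1, function(r) paste(signif(r, 12),
                                              collapse = ","))
  uniq <- !duplicated(key)
  Xu <- features[uniq, , drop = FALSE]
  perplexity <- perplexity %||% max(5, min(30, floor((nrow(Xu) - 1) / 3)))
  emb <- withr::with_seed(seed, {
    Rtsne::Rtsne(Xu, perplexity = perplexity, check_duplicates = FALSE,
                 pca = TRUE, theta = 0.5, verbose = FALSE)$Y
  })
  full <- emb[match(key, key[uniq]), , drop = FALSE]
  tibble::tibble(x = full[, 1], y = full[, 2])
}

#' Extract classifier frame-sequence embeddings
#'
#' Returns the recurrent layer's final hidden state for each window — the
#' feature representation the MLP head classifies.
#'
#' @param model A trained `eit_nn`.
#' @param windows Window tibble.
#' @return Numeric matrix (windows x hidden units).
#' @export
nn_embed <- function(model, windows) {
  inp <- nn_prepare(model$arch, window_array(windows), model$scaler)
  n <- inp$Bw
  h_dim <- if (model$arch == "faspp_gru") model$cfg$gru_hidden else
    model$cfg$lstm_hidden
  H <- matrix(0, n, h_dim)
  for (start in seq.int(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    fw <- nn_forward_prepared(model, nn_slice(inp, idx), keep_cache = TRUE)
    H[idx, ] <- t(fw$cache$h)
  }
  H
}

#' Plot a 2-D embedding with nearest-centroid decision regions
#'
#' Scatter of embedded points coloured by label over a background of
#' decision regions obtained by classifying a grid of 2-D points with a
#' nearest-centroid rule in the embedded space (a visualization
#' approximation: the true classifier operates in the original feature
#' space).
#'
#' @param embedding Tibble from [embed_features()].
#' @param labels Class labels, one per row.
#' @param grid_n Background grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels, grid_n = 120L) {
  df <- dplyr::mutate(embedding, label = labels)
  cent <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     .groups = "drop")
  gx <- seq(min(df$x), max(df$x), length.out = grid_n)
  gy <- seq(min(df$y), max(df$y), length.out = grid_n)
  grid <- tidyr::expand_grid(x = gx, y = gy)
  d2 <- outer(grid$x, cent$cx, "-")^2 + outer(grid$y, cent$cy, "-")^2
  grid$region <- cent$label[max.col(-d2)]
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = grid,
                         ggplot2::aes(.data$x, .data$y,
                                      fill = .data$region),
                         alpha = 0.25) +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$label), size = 0.8) +
    ggplot2::labs(x = NULL, y = NULL, fill = "region", colour = "label") +
    ggplot2::theme_minimal()
}
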