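test_that("perfect and hand-computed confusion matrices score correctly", {
  cm <- diag(5L) * 10L
  rownames(cm) <- colnames(cm) <- letters[1:5]
  class(cm) <- c("eit_confusion", class(cm))
  met <- compute_metrics(cm)
  expect_equal(met$accuracy, 1)
  expect_equal(met$macro_f1, 1)
  # binary counts TP=8, FP=2, FN=2, TN=8 (Eq. oracle by hand)
  cm2 <- matrix(c(8, 2, 2, 8), 2, 2,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  met2 <- compute_metrics(cm2)
  expect_equal(met2$accuracy, 0.8)
  expect_equal(met2$per_class$precision[1], 0.8)
  expect_equal(met2$per_class$recall[1], 0.8)
  expect_equal(met2$per_class$f1[1], 0.8)
  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")
})

test_that("a class never predicted nor present scores zero F1", {
  cm <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cm[1, 1] <- 5L; cm[2, 2] <- 5L
  met <- compute_metrics(cm)
  expect_equal(met$per_class$f1[3], 0)
  expect_equal(met$accuracy, 1)
})

test_that("metrics agree with a brute-force counting oracle", {
  withr::with_seed(14, {
    for (i in 1:100) {
      n <- sample(20:60, 1)
      truth <- sample(gesture_classes(), n, replace = TRUE)
      pred <- truth
      flip <- runif(n) < 0.3
      pred[flip] <- sample(gesture_classes(), sum(flip), replace = TRUE)
      met <- compute_metrics(confusion_matrix(truth, pred))
      # oracle: direct counting per class
      accs <- mean(truth == pred)
      f1s <- vapply(gesture_classes(), function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fp <- sum(truth != cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        prec <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec <- if (tp + fn > 0) tp / (tp + fn) else 0
        if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      }, numeric(1))
      expect_equal(met$accuracy, accs)
      expect_equal(met$macro_f1, mean(f1s))
    }
  })
})

test_that("one-vs-rest micro accuracy equals the multiclass trace rate", {
  withr::with_seed(15, {
    for (i in 1:20) {
      cm <- matrix(rpois(81, 4), 9, 9)
      tp <- diag(cm)
      fp <- colSums(cm) - tp
      micro <- sum(tp) / (sum(tp) + sum(fp))   # pooled one-vs-rest rate
      expect_equal(micro, sum(diag(cm)) / sum(cm))
    }
  })
})

test_that("confusion totals are conserved through evaluation", {
  w <- random_window_tbl(54, seed = 16)
  fit <- fit_knn(w, k = 1L)
  sets <- list(none = w[1:30, ], shifted = w[31:54, ])
  ev <- evaluate_under_conditions(fit, sets)
  expect_equal(sum(ev$confusions$none), 30L)
  expect_equal(sum(ev$confusions$shifted), 24L)
  expect_equal(ev$metrics$n, c(30L, 24L))
  expect_error(evaluate_under_conditions(fit, list(w)), "named")
})

test_that("Friedman comparison matches the direct rank formula", {
  # identical accuracies for all models: no evidence of difference
  same <- matrix(0.9, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- compare_models(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # hand-built blocks: compare against the textbook statistic
  acc <- matrix(c(0.9, 0.8, 0.7,
                  0.85, 0.8, 0.6,
                  0.95, 0.7, 0.65,
                  0.9, 0.85, 0.8), 4, 3, byrow = TRUE,
                dimnames = list(NULL, c("m1", "m2", "m3")))
  res2 <- compare_models(acc)
  R <- t(apply(acc, 1, rank))
  n <- nrow(acc); k <- ncol(acc)
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  expect_equal(res2$statistic, stat)
  expect_equal(res2$df, k - 1)
  expect_equal(res2$p.value, stats::pchisq(stat, k - 1,
                                           lower.tail = FALSE))
  # strict dominance with two models reaches the design's minimal p
  dom <- matrix(c(0.9, 0.5, 0.8, 0.4, 0.85, 0.45, 0.9, 0.6), 4, 2,
                byrow = TRUE, dimnames = list(NULL, c("m1", "m2")))
  res3 <- compare_models(dom)
  expect_equal(res3$statistic, 4)  # n * (k^2 - 1) / ... : all ranks equal
  expect_equal(res3$p.value, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_error(compare_models(same[, 1, drop = FALSE]), "two models")
  expect_error(compare_models(same[1:2, ]), "three")
})

test_that("2-D embedding maps points, duplicates and clusters sensibly", {
  withr::with_seed(17, {
    centers <- matrix(rnorm(3 * 20, sd = 10), 3)
    X <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 20, sd = 0.3),
                                                 60)
    labels <- rep(c("a", "b", "c"), each = 20)
  })
  X[2, ] <- X[1, ]  # exact duplicate
  emb <- embed_features(X, seed = 5)
  expect_equal(nrow(emb), 60L)
  expect_identical(unlist(emb[1, ]), unlist(emb[2, ]))
  expect_gt(silhouette_mean(as.matrix(emb), labels), 0)
  expect_error(embed_features(X[1:10, ], seed = 1), "at least 50")
})
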