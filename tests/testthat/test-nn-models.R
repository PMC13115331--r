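test_that("default configurations hit the printed parameter budgets", {
  expect_equal(n_params(nn_init(faspp_gru_config(), seed = 1)$params),
               650000, tolerance = 10000 / 650000)
  expect_equal(n_params(nn_init(cnn_lstm_config(), seed = 1)$params),
               880000, tolerance = 10000 / 880000)
})

test_that("forward pass emits a probability simplex", {
  withr::with_seed(5, {
    for (cfg in list(tiny_faspp(), tiny_cnn_lstm())) {
      model <- nn_init(cfg, seed = 2)
      X <- array(rnorm(cfg$window * 208 * 4, 100, 100),
                 dim = c(cfg$window, 208, 4))
      P <- nn_forward(model, X)$probs
      expect_identical(dim(P), c(9L, 4L))
      expect_true(all(P >= 0))
      expect_equal(colSums(P), rep(1, 4), tolerance = 1e-6)
    }
  })
})

test_that("analytic gradients match finite differences", {
  for (cfg in list(tiny_faspp(), tiny_cnn_lstm())) {
    model <- nn_init(cfg, seed = 3)
    withr::with_seed(42, {
      # nudge all parameters (incl. biases) off zero so no activation sits
      # exactly on a ReLU kink
      model$params <- lapply(model$params,
                             function(p) p + rnorm(length(p), sd = 0.05))
      B <- 3L
      X <- array(rnorm(cfg$window * 208 * B, 100, 100),
                 dim = c(cfg$window, 208, B))
      y <- c(1L, 2L, 3L)
      lossfn <- function(params) {
        model$params <- params
        cross_entropy(nn_forward(model, X)$probs, y)
      }
      fw <- nn_forward(model, X, keep_cache = TRUE)
      dZ <- fw$probs
      dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
      dZ <- dZ / B
      g <- nn_backward(model, fw$cache, dZ)
      worst <- 0
      for (k in names(model$params)) {
        for (ii in sample(length(model$params[[k]]),
                          min(5, length(model$params[[k]])))) {
          eps <- 1e-5 * max(1, abs(model$params[[k]][ii]))
          p1 <- model$params; p1[[k]][ii] <- p1[[k]][ii] + eps
          p2 <- model$params; p2[[k]][ii] <- p2[[k]][ii] - eps
          fd <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
          worst <- max(worst, abs(fd - g[[k]][ii]) /
                         max(1e-6, abs(fd), abs(g[[k]][ii])))
        }
      }
      expect_lt(worst, 0.02)
    })
  }
})

test_that("identical sequences in a batch get identical predictions", {
  cfg <- tiny_faspp()
  model <- nn_init(cfg, seed = 4)
  one <- withr::with_seed(6, array(rnorm(cfg$window * 208, 100, 100),
                                   dim = c(cfg$window, 208, 1)))
  X <- array(one, dim = c(cfg$window, 208, 3))
  P <- nn_forward(model, X)$probs
  expect_equal(P[, 1], P[, 2], tolerance = 1e-12)
  expect_equal(P[, 1], P[, 3], tolerance = 1e-12)
})

test_that("grid gather maps channels to drive-major rows with zero pads", {
  X <- array(rep(1:208, each = 1), dim = c(1, 208, 1))
  F256 <- frames_from_windows(X)
  m <- matrix(F256[, 1], 16, 16)
  expect_equal(m[, 14:16], matrix(0, 16, 3))
  expect_equal(m[4, 6] * 1000, (4 - 1) * 13 + 6)  # volts scaling
})
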