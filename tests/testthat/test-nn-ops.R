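test_that("fold and unfold are mutually inverse bijections", {
  withr::with_seed(1, {
    for (i in 1:100) {
      C <- sample(1:6, 1)
      B <- sample(1:3, 1)
      X <- matrix(rnorm(C * 8 * 8 * B), C)
      Y <- fold_op(X, 8L, 8L, B)
      expect_identical(dim(Y), c(4L * C, 16L * B))
      expect_identical(unfold_op(Y, 8L, 8L, B), X)   # bit-exact
      expect_identical(fold_op(unfold_op(Y, 8L, 8L, B), 8L, 8L, B), Y)
      expect_identical(sort(as.numeric(Y)), sort(as.numeric(X)))
    }
  })
  # shape contract at network scale: 32x32x8 <-> 16x16x32
  X <- matrix(rnorm(8 * 32 * 32), 8)
  expect_identical(dim(fold_op(X, 32L, 32L, 1L)), c(32L, 256L))
  # constant map stays constant (pure rearrangement)
  expect_true(all(fold_op(matrix(2, 3, 64), 8L, 8L, 1L) == 2))
  expect_error(fold_op(matrix(1, 2, 15), 5L, 3L, 1L), "even")
  expect_error(unfold_op(matrix(1, 6, 16), 8L, 8L, 1L), "divisible by 4")
})

test_that("dilated convolutions preserve spatial size", {
  withr::with_seed(2, {
    X <- matrix(rnorm(4 * 16 * 16 * 2), 4)
    for (d in c(1L, 2L, 4L)) {
      Wt <- array(rnorm(6 * 4 * 9), dim = c(6, 4, 9))
      out <- conv2d_fwd(X, Wt, rnorm(6), 16L, 16L, 2L, d)
      expect_identical(dim(out$Y), c(6L, 16L * 16L * 2L))
    }
  })
})

test_that("impulse probe recovers the dilated receptive field", {
  for (d in c(1L, 2L, 4L)) {
    # gradient support at one output position spans the 3x3 dilated taps
    Wt <- array(1, dim = c(1, 1, 9))
    G <- matrix(0, 1, 16 * 16)
    center <- (8 - 1) * 16 + 8  # (row 8, col 8), column-major
    G[1, center] <- 1
    Xcol <- im2col_3x3(matrix(0, 1, 256), 16L, 16L, 1L, d)
    gX <- conv2d_bwd(G, Wt, Xcol, 16L, 16L, 1L, d)$gX
    on <- which(gX[1, ] != 0)
    rows <- (on - 1) %% 16 + 1
    cols <- (on - 1) %/% 16 + 1
    expect_length(on, 9L)                       # 3x3 taps
    expect_equal(max(rows) - min(rows), 2L * d) # (2d+1) bounding box
    expect_equal(max(cols) - min(cols), 2L * d)
  }
})

test_that("zero input with zero bias maps to zero through the encoder", {
  Wt <- array(rnorm(5 * 3 * 9), dim = c(5, 3, 9))
  out <- conv2d_fwd(matrix(0, 3, 16 * 16), Wt, numeric(5), 16L, 16L, 1L)
  expect_true(all(out$Y == 0))
})

test_that("softmax and cross-entropy closed forms hold", {
  P <- softmax_cols(matrix(rnorm(45), 9))
  expect_true(all(P >= 0))
  expect_equal(colSums(P), rep(1, 5), tolerance = 1e-12)
  # uniform prediction over 9 classes costs ln 9 per sample
  unif <- matrix(1 / 9, 9, 7)
  expect_equal(cross_entropy(unif, sample(9, 7, replace = TRUE)), log(9))
  # a certain correct prediction costs zero
  sure <- matrix(0, 9, 1); sure[4, 1] <- 1
  expect_equal(cross_entropy(sure, 4L), 0)
})

test_that("im2col/col2im are adjoint", {
  withr::with_seed(3, {
    X <- matrix(rnorm(3 * 64), 3)
    G <- matrix(rnorm(27 * 64), 27)
    Xc <- im2col_3x3(X, 8L, 8L, 1L, 2L)
    # <im2col(X), G> == <X, col2im(G)>
    expect_equal(sum(Xc * G), sum(X * col2im_3x3(G, 8L, 8L, 1L, 2L, 3L)))
  })
})
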