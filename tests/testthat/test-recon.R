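test_that("difference voltages subtract channel-wise", {
  v <- rnorm(208)
  expect_equal(difference_voltages(v, v), rep(0, 208))
  r <- rnorm(208)
  expect_equal(difference_voltages(v, r), v - r)
  expect_error(difference_voltages(v, rnorm(100)), "same number")
})

test_that("identity system reduces to the data at alpha zero", {
  dv <- rnorm(5)
  img <- tikhonov_reconstruct(diag(5), dv, alpha = 0)
  expect_equal(img$delta_sigma, dv, tolerance = 1e-10)
})

test_that("heavy regularization shrinks the image to zero", {
  mesh <- fixture_mesh(3L)
  J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
  dv <- withr::with_seed(2, rnorm(208) * 1e-5)
  lam <- max(eigen(J$J %*% t(J$J), symmetric = TRUE,
                   only.values = TRUE)$values)
  img <- tikhonov_reconstruct(J, dv, alpha = 1e8 * lam)
  ref <- tikhonov_reconstruct(J, dv, alpha = 0.01 * lam)
  expect_lt(sqrt(sum(img$delta_sigma^2)),
            1e-6 * sqrt(sum(ref$delta_sigma^2)))
})

test_that("small dense system matches brute-force normal equations", {
  J <- matrix(c(1, 2, 0, -1, 3, 1), 3, 2)
  dv <- c(1, 0.5, -2)
  for (alpha in c(0.1, 1, 10)) {
    oracle <- solve(t(J) %*% J + alpha * diag(2), t(J) %*% dv)
    img <- tikhonov_reconstruct(J, dv, alpha = alpha)
    expect_equal(img$delta_sigma, as.numeric(oracle), tolerance = 1e-10)
  }
})

test_that("normal-equation residual is tiny at the default alpha", {
  mesh <- fixture_mesh(3L)
  J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
  dv <- withr::with_seed(3, rnorm(208) * 1e-5)
  img <- tikhonov_reconstruct(J, dv)
  A <- crossprod(J$J)
  diag(A) <- diag(A) + img$alpha
  res <- A %*% img$delta_sigma - crossprod(J$J, dv)
  expect_lt(sqrt(sum(res^2)) / sqrt(sum(crossprod(J$J, dv)^2)), 1e-8)
})

test_that("image norm is nonincreasing in alpha and zero maps to zero", {
  mesh <- fixture_mesh(3L)
  J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
  dv <- withr::with_seed(5, rnorm(208) * 1e-5)
  lam <- max(eigen(J$J %*% t(J$J), symmetric = TRUE,
                   only.values = TRUE)$values)
  norms <- vapply(lam * 10^seq(-6, 2), function(a) {
    sqrt(sum(tikhonov_reconstruct(J, dv, alpha = a)$delta_sigma^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  z <- tikhonov_reconstruct(J, rep(0, 208), alpha = lam * 0.01)
  expect_equal(z$delta_sigma, rep(0, ncol(J$J)))
})

test_that("rank-deficient system without regularization errors", {
  mesh <- fixture_mesh(3L)
  J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
  # 208 equations, 144 unknowns is overdetermined but J'J is near-singular
  # for an underdetermined wide block; force the degenerate case directly
  Jw <- cbind(J$J, J$J)  # duplicated columns: exactly rank deficient
  expect_error(tikhonov_reconstruct(Jw, rnorm(208), alpha = 0),
               "singular")
})

test_that("single-inclusion reconstruction localizes the target", {
  mesh <- fixture_mesh(6L)
  p <- adjacent_protocol()
  base <- rep(1, nrow(mesh$elements))
  tpl <- structure(list(
    gesture = "probe",
    inclusions = data.frame(muscle = "x", x = 0.45, y = 0.3,
                            radius = 0.16, contrast = 0.4, lag = 0)),
    class = "gesture_template")
  sigma <- make_gesture_field(tpl, 1, base, mesh)
  v0 <- solve_forward(mesh, base, p)
  v1 <- solve_forward(mesh, sigma, p)
  J <- compute_jacobian(mesh, base, p)
  img <- tikhonov_reconstruct(J, difference_voltages(v1, v0), mesh = mesh)
  peak <- which.max(abs(img$delta_sigma))
  d <- sqrt((mesh$centroids[peak, 1] - 0.45)^2 +
              (mesh$centroids[peak, 2] - 0.3)^2)
  expect_lt(d, 1.5 * 0.16)
  # reconstructed change has the sign of the true contrast at the peak
  expect_gt(img$delta_sigma[peak], 0)
})

test_that("rest-interval reference frame averages rest frames", {
  stream <- tibble::tibble(
    t = c(0, 1, 2, 3), gesture = c(NA, "pointer", NA, "pointer"),
    condition = "none", phase = c("interval", "instructed", "interval",
                                  "instructed"))
  stream$v <- matrix(rep(c(1, 3, 5, 7), 208), 4)
  expect_equal(reference_frame(stream), rep(3, 208))
  expect_equal(reference_frame(stream, "first_frame"), rep(1, 208))
})
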