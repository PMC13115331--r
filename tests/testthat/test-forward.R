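test_that("homogeneous-disk voltages match the analytic series solution", {
  mesh <- fixture_mesh(7L)
  p <- adjacent_protocol()
  v <- solve_forward(mesh, rep(1, nrow(mesh$elements)), p)
  va <- disk_analytic_voltages(mesh, p)
  expect_lt(max(abs(v - va) / abs(va)), 0.02)
})

test_that("voltages scale as 1/sigma and linearly with current", {
  mesh <- fixture_mesh(3L)
  p <- adjacent_protocol()
  sigma <- rep(1, nrow(mesh$elements))
  v1 <- solve_forward(mesh, sigma, p)
  expect_equal(solve_forward(mesh, 2 * sigma, p), v1 / 2,
               tolerance = 1e-12)
  expect_equal(solve_forward(mesh, 0.25 * sigma, p), 4 * v1,
               tolerance = 1e-12)
  p2 <- adjacent_protocol(current_mA = 3)
  expect_equal(solve_forward(mesh, sigma, p2), 3 * v1, tolerance = 1e-12)
})

test_that("reciprocity holds: swapping drive and measurement pairs", {
  mesh <- fixture_mesh(7L)
  p <- adjacent_protocol()
  sigma <- withr::with_seed(4, rep(1, nrow(mesh$elements)) *
                              runif(nrow(mesh$elements), 0.5, 2))
  v <- solve_forward(mesh, sigma, p)
  chs <- p$channels
  vmax <- max(abs(v))
  worst <- 0
  for (r in seq_len(nrow(chs))) {
    r2 <- which(chs$drive == chs$mpos[r] & chs$mpos == chs$drive[r])
    if (length(r2) == 1L) {
      worst <- max(worst, abs(v[r] - v[r2]) / vmax)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("forward solver validates inputs", {
  mesh <- fixture_mesh(3L)
  p <- adjacent_protocol()
  expect_error(solve_forward(mesh, rep(-1, nrow(mesh$elements)), p),
               "positive")
  expect_error(solve_forward(mesh, rep(1, 5), p), "per mesh element")
  expect_error(solve_forward(mesh, rep(1, nrow(mesh$elements)),
                             adjacent_protocol(n_electrodes = 12L)),
               "electrode count")
})

test_that("homogeneous voltages converge between refinement levels", {
  p <- adjacent_protocol()
  v8 <- solve_forward(fixture_mesh(8L), rep(1, 16 * 64), p)
  v9 <- solve_forward(build_disk_mesh(9), rep(1, 16 * 81), p)
  expect_lt(max(abs(v9 - v8) / abs(v8)), 0.01)
})

test_that("adjoint Jacobian matches central finite differences", {
  mesh <- fixture_mesh(6L)
  p <- adjacent_protocol()
  m <- nrow(mesh$elements)
  sigma <- rep(1, m)
  J <- compute_jacobian(mesh, sigma, p)
  expect_equal(dim(J$J), c(208L, m))
  expect_true(all(is.finite(J$J)))
  els <- withr::with_seed(9, sample(m, 22))
  delta <- 1e-4
  for (e in els) {
    s1 <- sigma; s1[e] <- s1[e] + delta
    s2 <- sigma; s2[e] <- s2[e] - delta
    fd <- (solve_forward(mesh, s1, p) - solve_forward(mesh, s2, p)) /
      (2 * delta)
    expect_lt(max(abs(fd - J$J[, e])) / max(abs(fd)), 0.01)
  }
})

test_that("zero conductivity change predicts zero voltage change", {
  mesh <- fixture_mesh(3L)
  J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
  expect_equal(as.numeric(J$J %*% numeric(nrow(mesh$elements))),
               rep(0, 208))
})

test_that("belt rotation by one full pitch leaves voltages unchanged", {
  p <- adjacent_protocol()
  mesh0 <- fixture_mesh(6L)
  sigma0 <- rep(1, nrow(mesh0$elements))
  v0 <- solve_forward(mesh0, sigma0, p)
  meshr <- build_disk_mesh(6, rotation = 2 * pi / 16)
  vr <- solve_forward(meshr, rep(1, nrow(meshr$elements)), p)
  expect_lt(max(abs(vr - v0)) / max(abs(v0)), 1e-10)
})
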