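test_that("gesture templates are valid and deliberately structured", {
  tpl <- gesture_templates()
  expect_length(tpl, 9L)
  expect_setequal(names(tpl), gesture_classes())
  expect_equal(nrow(tpl$rest$inclusions), 0L)
  for (t in tpl) {
    inc <- t$inclusions
    if (nrow(inc)) {
      expect_true(all(sqrt(inc$x^2 + inc$y^2) + inc$radius <= 1))
    }
  }
  # power and thumb share 3 of 4 inclusions (similar steady patterns)
  expect_equal(length(intersect(tpl$power$inclusions$muscle,
                                tpl$thumb$inclusions$muscle)), 3L)
  expect_equal(nrow(tpl$power$inclusions), 4L)
  # participant seeds jitter geometry deterministically
  a <- gesture_templates(participant_seed = 5)
  b <- gesture_templates(participant_seed = 5)
  c <- gesture_templates(participant_seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$power$inclusions$x, c$power$inclusions$x))
  expect_true(all(a$power$inclusions$lag >= 0 &
                    a$power$inclusions$lag <= 0.3))
})

test_that("gesture fields scale inclusions by activation", {
  mesh <- fixture_mesh(6L)
  base <- rep(0.3, nrow(mesh$elements))
  tpl <- gesture_templates()
  expect_equal(make_gesture_field(tpl$rest, 1, base, mesh), base)
  expect_equal(make_gesture_field(tpl$pointer, 0, base, mesh), base)
  # element count with modified sigma equals brute-force point-in-circle
  f1 <- make_gesture_field(tpl$pointer, 1, base, mesh)
  changed <- which(f1 != base)
  inc <- tpl$pointer$inclusions
  expected <- which(Reduce(`|`, lapply(seq_len(nrow(inc)), function(i) {
    (mesh$centroids[, 1] - inc$x[i])^2 +
      (mesh$centroids[, 2] - inc$y[i])^2 <= inc$radius[i]^2
  })))
  expect_setequal(changed, expected)
  expect_error(make_gesture_field(tpl$pointer, 2, base, mesh), "0, 1")
  bad <- tpl$pointer
  bad$inclusions$x[1] <- 0.99
  expect_error(make_gesture_field(bad, 1, base, mesh), "outside")
})

test_that("confounder constructors validate and 'none' is the identity", {
  expect_error(confounder("limb_position", direction = "Q"), "L, R, U, D")
  expect_error(confounder("wobble"))
  setup <- list(mesh = fixture_mesh(3L), base = rep(1, 144),
                templates = gesture_templates())
  expect_identical(apply_confounder(setup, confounder("none")), setup)
  stream <- tibble::tibble(t = 0, gesture = NA_character_,
                           condition = "none", phase = "interval")
  stream$v <- matrix(1, 1, 208)
  expect_identical(apply_confounder(stream, confounder("none")), stream)
})

test_that("limb position perturbs rest frames without any gesture", {
  mesh <- fixture_mesh(6L)
  base <- base_conductivity(mesh)
  p <- adjacent_protocol()
  setup <- list(mesh = mesh, base = base,
                templates = gesture_templates())
  conf <- confounder("limb_position", direction = "U")
  moved <- apply_confounder(setup, conf)
  v0 <- solve_forward(mesh, base, p)
  v1 <- solve_forward(moved$mesh, moved$base, p)
  expect_gt(max(abs(v1 - v0) / max(abs(v0))), 1e-4)
  # inclusion centres shifted upward by the configured amount
  expect_equal(moved$templates$pointer$inclusions$y,
               setup$templates$pointer$inclusions$y + conf$shift)
})

test_that("whole-pitch belt rotation with channel relabelling is identity", {
  mesh <- fixture_mesh(6L)
  base <- base_conductivity(mesh)
  p <- adjacent_protocol()
  setup <- list(mesh = mesh, base = base,
                templates = gesture_templates())
  rot <- apply_confounder(setup, confounder("contact_rotation",
                                            rotation_frac = 1))
  v0 <- solve_forward(mesh, base, p)
  v1 <- solve_forward(rot$mesh, base, p)
  # the anatomy is anchored, so rotating the belt by one full pitch maps
  # drive d of the rotated belt onto drive d+1 of the original
  chs <- p$channels
  relabel <- vapply(seq_len(208), function(r) {
    which(chs$drive == (chs$drive[r] + 1L) %% 16L &
            chs$mpos == (chs$mpos[r] + 1L) %% 16L)
  }, integer(1))
  expect_lt(max(abs(v1 - v0[relabel])) / max(abs(v0)), 1e-8)
  # half-pitch rotation is a genuine perturbation
  half <- apply_confounder(setup, confounder("contact_rotation"))
  vh <- solve_forward(half$mesh, base, p)
  expect_gt(max(abs(vh - v0) / max(abs(v0))), 1e-4)
})

test_that("simulated sessions honour the protocol arithmetic", {
  mesh <- fixture_mesh(6L)
  base <- base_conductivity(mesh)
  p <- adjacent_protocol()
  tpl <- gesture_templates(participant_seed = 1)
  gain <- session_gain(mesh, base, p)
  s <- simulate_session(session_spec(reps = 10, seed = 3), tpl,
                        confounder("none"), mesh, p, base, gain = gain)
  # 9 gestures x 10 reps x 3 s x 23 fps
  expect_equal(sum(!is.na(s$gesture)), 6210L)
  expect_equal(nrow(s), 9L * 10L * (3L + 5L) * 23L)
  sc <- simulate_session(session_spec(reps = 5, seed = 4), tpl,
                         confounder("contact_rotation"), mesh, p, base,
                         gain = gain)
  expect_equal(sum(!is.na(sc$gesture)), 3105L)
  # same seed twice: bit-identical streams
  s2 <- simulate_session(session_spec(reps = 10, seed = 3), tpl,
                         confounder("none"), mesh, p, base, gain = gain)
  expect_identical(s$v, s2$v)
  # baseline voltages land in the instrument's working range (the largest
  # channel is calibrated to 800 mV; measurement noise adds ~1%)
  v_rest <- s$v[s$phase == "interval", ][1, ]
  expect_lt(max(abs(v_rest)), 800 * 1.05)
  expect_gt(min(abs(v_rest)), 20)
})

test_that("infinite SNR makes repeated steady-state frames identical", {
  mesh <- fixture_mesh(6L)
  base <- base_conductivity(mesh)
  p <- adjacent_protocol()
  tpl <- gesture_templates(participant_seed = 2)
  s <- simulate_session(
    session_spec(gestures = c("power", "rest"), reps = 2,
                 noise_snr_db = Inf, seed = 9),
    tpl, confounder("none"), mesh, p, base)
  # late instructed frames of the same rep are past the ramp: identical
  pow <- which(s$gesture == "power")
  last_two <- s$v[pow[c(68, 69)], ]
  expect_identical(last_two[1, ], last_two[2, ])
})

test_that("distinct gestures are separable against measurement noise", {
  mesh <- fixture_mesh(6L)
  base <- base_conductivity(mesh)
  p <- adjacent_protocol()
  tpl <- gesture_templates(participant_seed = 3)
  gain <- session_gain(mesh, base, p)
  s <- simulate_session(session_spec(reps = 2, seed = 10), tpl,
                        confounder("none"), mesh, p, base, gain = gain)
  # steady-state frame per (gesture, rep): last instructed frame
  idx <- which(!is.na(s$gesture))
  steady <- s[idx[seq_along(idx) %% 69 == 0], ]
  within <- c(); between <- c()
  for (g1 in unique(steady$gesture)) {
    rows <- which(steady$gesture == g1)
    within <- c(within, dist(steady$v[rows, ]))
    others <- which(steady$gesture != g1)
    between <- c(between,
                 sqrt(rowSums((steady$v[others, , drop = FALSE] -
                                 rep(steady$v[rows[1], ],
                                     each = length(others)))^2)))
  }
  expect_gt(min(between), max(within))
})

test_that("time drift scales channels slowly and multiplicatively", {
  mesh <- fixture_mesh(6L)
  base <- base_conductivity(mesh)
  p <- adjacent_protocol()
  tpl <- gesture_templates(participant_seed = 4)
  s <- simulate_session(
    session_spec(gestures = c("rest"), reps = 3, noise_snr_db = Inf,
                 seed = 12),
    tpl, confounder("time_drift"), mesh, p, base)
  first <- s$v[1, ]
  last <- s$v[nrow(s), ]
  ratio <- last / first
  expect_true(all(is.finite(ratio)))
  expect_gt(stats::sd(ratio), 0)          # per-channel amplitudes differ
  expect_lt(max(abs(ratio - 1)), 0.10)    # drift is slow and small
})
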