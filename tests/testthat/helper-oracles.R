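# Shared fixtures and independent oracles.

# memoized meshes so expensive geometry is built once per run
.fixtures <- new.env()
fixture_mesh <- function(L) {
  key <- paste0("mesh", L)
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build_disk_mesh(L)
  .fixtures[[key]]
}

# Closed-form potential on the homogeneous unit disk with point current
# sources on the boundary (image method: a boundary source has itself as
# image, doubling the free-space log kernel; the sum of source and sink
# terms has zero normal flux on the rest of the boundary). Currents are
# spread uniformly over each electrode's boundary nodes, matching the
# solver's discrete gap-electrode model.
disk_analytic_voltages <- function(mesh, protocol, sigma0 = 1) {
  angle_of <- function(nodes) atan2(mesh$nodes[nodes, 2],
                                    mesh$nodes[nodes, 1])
  u_at <- function(th_eval, th_src, th_snk) {
    vapply(th_eval, function(t) {
      da <- mean(log(2 * abs(sin((t - th_src) / 2))))
      db <- mean(log(2 * abs(sin((t - th_snk) / 2))))
      (db - da) / (pi * sigma0)
    }, numeric(1))
  }
  chs <- protocol$channels
  ne <- protocol$n_electrodes
  I_amp <- protocol$current_mA * 1e-3
  vapply(seq_len(nrow(chs)), function(r) {
    src <- angle_of(mesh$electrodes[[chs$drive[r] + 1L]])
    snk <- angle_of(mesh$electrodes[[(chs$drive[r] + 1L) %% ne + 1L]])
    mp <- angle_of(mesh$electrodes[[chs$mpos[r] + 1L]])
    mn <- angle_of(mesh$electrodes[[chs$mneg[r] + 1L]])
    I_amp * (mean(u_at(mp, src, snk)) - mean(u_at(mn, src, snk)))
  }, numeric(1))
}

# tiny network configs for gradient checks and fast training tests
tiny_faspp <- function(..., window = 4L) {
  faspp_gru_config(aspp_channels = 3L, proj_channels = 8L, embed_dim = 6L,
                   gru_hidden = 7L, mlp_hidden = 5L, window = window, ...)
}
tiny_cnn_lstm <- function(..., window = 4L) {
  cnn_lstm_config(conv_channels = c(3L, 4L), embed_dim = 6L,
                  lstm_hidden = 7L, mlp_hidden = 5L, window = window, ...)
}

random_window_tbl <- function(n, win = 11L, classes = gesture_classes(),
                              seed = 1L, centers = NULL) {
  withr::with_seed(seed, {
    labels <- rep_len(classes, n)
    centers <- centers %||%
      matrix(rnorm(length(classes) * 208, sd = 50), length(classes))
    v <- lapply(seq_len(n), function(i) {
      ci <- match(labels[i], classes)
      matrix(rep(centers[ci, ], each = win), win) +
        matrix(rnorm(win * 208, sd = 2), win)
    })
    tibble::tibble(start = seq_len(n), label = labels,
                   condition = "none", v = v)
  })
}

# mean silhouette width from scratch (Euclidean)
silhouette_mean <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
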