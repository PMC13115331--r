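test_that("frame-to-matrix layout is canonical and invertible", {
  f <- as.numeric(1:208)
  m <- frame_to_matrix(f)
  expect_equal(dim(m), c(16L, 16L))
  expect_equal(sum(m[, 14:16]), 0)           # zero padding
  expect_equal(m[4, 6], (4 - 1) * 13 + 6)    # drive-major rows
  expect_equal(matrix_to_frame(m), f)
  ones <- frame_to_matrix(rep(1, 208))
  expect_equal(sum(ones == 1), 208L)
  expect_equal(sum(ones == 0), 48L)
  expect_error(frame_to_matrix(1:100), "208")
})

make_stream <- function(labels, fps = 23) {
  n <- length(labels)
  out <- tibble::tibble(t = (seq_len(n) - 1) / fps, gesture = labels,
                        condition = "none", phase = "instructed")
  out$v <- matrix(rnorm(n * 208), n)
  attr(out, "frame_rate") <- fps
  out
}

test_that("windowing enumerates uniform-label windows with stride 1", {
  expect_equal(nrow(window_sequences(make_stream(rep("power", 11)))), 1L)
  w <- window_sequences(make_stream(rep("power", 69)))
  expect_equal(nrow(w), 59L)  # floor((69 - 11) / 1) + 1
  expect_true(all(vapply(w$v, nrow, integer(1)) == 11L))
  # label change mid-window discards the straddling windows
  mixed <- make_stream(c(rep("power", 30), rep("open", 30)))
  wm <- window_sequences(mixed)
  expect_equal(nrow(wm), (30 - 11 + 1) * 2)
  expect_false(any(wm$start > 20 & wm$start < 31))
  # unlabelled frames produce no windows
  expect_equal(nrow(window_sequences(make_stream(rep(NA_character_, 30)))),
               0L)
  # shorter than one window: empty result, not an error
  expect_equal(nrow(window_sequences(make_stream(rep("power", 5)))), 0L)
})

test_that("split is a deterministic 70-15-15 partition", {
  w <- window_sequences(make_stream(rep("power", 110)))
  sp <- split_dataset(w, seed = 4)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$val), 15L)
  expect_equal(nrow(sp$test), 15L)
  all_starts <- sort(c(sp$train$start, sp$val$start, sp$test$start))
  expect_equal(all_starts, sort(w$start))          # exhaustive
  expect_equal(anyDuplicated(all_starts), 0L)      # disjoint
  sp2 <- split_dataset(w, seed = 4)
  expect_identical(sp$train$start, sp2$train$start)
  sp3 <- split_dataset(w, seed = 5)
  expect_false(identical(sp$train$start, sp3$train$start))
  expect_error(split_dataset(w[1:5, ]), "at least 10")
})

test_that("balanced subsampling caps windows per class", {
  w <- random_window_tbl(90, seed = 2)
  sub <- subsample_windows(w, 5, seed = 1)
  expect_true(all(table(sub$label) == 5))
  expect_identical(subsample_windows(w, 5, seed = 1)$start, sub$start)
})

test_that("frame stream CSV round-trips bit-identically", {
  stream <- make_stream(c(rep("power", 10), rep(NA_character_, 5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_frames(stream, path, meta = list(note = "fixture"))
  back <- read_frames(path)
  expect_identical(frame_matrix(back), frame_matrix(stream))
  expect_identical(back$gesture, stream$gesture)
  expect_equal(attr(back, "frame_rate"), 23)
  expect_true(file.exists(paste0(path, ".meta.json")))
})
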