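#' Extract the frame-by-channel voltage matrix from a frame stream
#'
#' @param stream A frame tibble with a matrix column `v` (frames x channels),
#'   as produced by [simulate_session()].
#' @return The numeric matrix of voltages (mV).
#' @export
frame_matrix <- function(stream) {
  v <- stream$v
  if (is.null(v)) stop("stream has no voltage column `v`")
  as.matrix(v)
}

#' Reshape a 208-channel frame into a padded 16 x 16 matrix
#'
#' Row `d` (1..16) holds the 13 measurements of drive `d` in columns 1..13;
#' columns 14..16 are zero padding. The layout keeps the channels of one
#' current drive contiguous along a row, preserving drive locality for the
#' spatial encoder, and is exactly invertible on the 208 true channels.
#'
#' @param frame Numeric vector of 208 voltages in canonical channel order.
#' @return A 16 x 16 numeric matrix.
#' @examples
#' m <- frame_to_matrix(1:208)
#' m[4, 6] # drive 4, measurement 6 -> channel (4-1)*13 + 6
#' @export
frame_to_matrix <- function(frame) {
  if (length(frame) != 208L) stop("frame must have exactly 208 channels")
  m <- matrix(0, 16, 16)
  m[, 1:13] <- matrix(frame, nrow = 16, byrow = TRUE)
  m
}

#' @rdname frame_to_matrix
#' @param grid A 16 x 16 matrix from [frame_to_matrix()].
#' @return `matrix_to_frame` returns the 208-channel vector.
#' @export
matrix_to_frame <- function(grid) {
  stopifnot(identical(dim(grid), c(16L, 16L)))
  as.numeric(t(grid[, 1:13]))
}

#' Segment a frame stream into fixed-length labelled sequences
#'
#' Slides a window of `window_ms` milliseconds (11 frames at 23 frames/s)
#' over the stream with stride `max(1, round(window * (1 - overlap)))`
#' frames. A window is kept only when all of its frames carry the same
#' non-missing gesture label, so supervision is unambiguous; windows inside
#' the instructed period retain transition frames (the instructed label
#' covers the transient state).
#'
#' @param stream Frame tibble from [simulate_session()] (needs columns
#'   `gesture`, `condition` and matrix column `v`, plus a `frame_rate`
#'   attribute or 23 frames/s is assumed).
#' @param window_ms Window length in milliseconds (480 by default).
#' @param overlap Fractional overlap between consecutive windows (0.875 by
#'   default; with an 11-frame window this gives stride 1).
#' @return A tibble with one row per retained window: `start` (frame index),
#'   `label`, `condition`, and list-column `v` of window matrices
#'   (window x 208).
#' @export
window_sequences <- function(stream, window_ms = 480, overlap = 0.875) {
  fps <- attr(stream, "frame_rate") %||% 23
  w <- max(1L, round(window_ms / 1000 * fps))
  stride <- max(1L, round(w * (1 - overlap)))
  v <- frame_matrix(stream)
  n <- nrow(v)
  if (n < w) {
    return(tibble::tibble(start = integer(0), label = character(0),
                          condition = character(0), v = list()))
  }
  starts <- seq.int(1L, n - w + 1L, by = stride)
  lab <- stream$gesture
  cond <- stream$condition
  # a window is uniform when the label run containing its first frame
  # extends past its last frame
  runs <- rle(ifelse(is.na(lab), "<na>", lab))
  run_id <- rep.int(seq_along(runs$lengths), runs$lengths)
  keep <- !is.na(lab[starts]) & run_id[starts] == run_id[starts + w - 1L]
  starts <- starts[keep]
  tibble::tibble(
    start = starts,
    label = lab[starts],
    condition = cond[starts],
    v = lapply(starts, function(s) v[s:(s + w - 1L), , drop = FALSE])
  )
}

#' Randomized train/validation/test split
#'
#' Permutes the windows with a seeded RNG and partitions them 70-15-15 (by
#' default) into disjoint, exhaustive subsets.
#'
#' @param windows A window tibble from [window_sequences()].
#' @param fractions Length-3 numeric summing to 1.
#' @param seed Integer seed for the permutation.
#' @return A named list of three tibbles: `train`, `val`, `test`.
#' @export
split_dataset <- function(windows, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(windows)
  if (n < 10L) stop("need at least 10 sequences to split")
  perm <- withr::with_seed(seed, sample.int(n))
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  list(train = windows[sort(perm[seq_len(n1)]), ],
       val = windows[sort(perm[n1 + seq_len(n2)]), ],
       test = windows[sort(perm[(n1 + n2 + 1):n]), ])
}

#' Balanced subsampling of windows by class
#'
#' Keeps at most `per_class` windows of each label, sampled uniformly with a
#' seeded RNG. Used to set the problem size of training runs while keeping
#' class balance.
#'
#' @param windows Window tibble.
#' @param per_class Maximum windows per label.
#' @param seed Integer seed.
#' @return The subsampled window tibble (original order preserved).
#' @export
subsample_windows <- function(windows, per_class, seed = 1L) {
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(windows)), windows$label), function(i) {
      if (length(i) > per_class) sample(i, per_class) else i
    }), use.names = FALSE)
  })
  windows[sort(idx), ]
}

#' Write / read a frame stream as CSV with a JSON sidecar
#'
#' The on-disk schema is a plain CSV table (`t`, `gesture`, `condition`,
#' `phase`, `v1` ... `v208`) written losslessly (shortest round-tripping
#' decimal representation of each 64-bit float) plus a `.meta.json` sidecar
#' carrying the frame rate and a configuration echo.
#'
#' @param stream Frame tibble.
#' @param path CSV file path; the sidecar is `<path>.meta.json`.
#' @param meta Optional named list merged into the sidecar.
#' @return `write_frames` returns `path` invisibly; `read_frames` the
#'   stream tibble with its `frame_rate` attribute restored.
#' @export
write_frames <- function(stream, path, meta = list()) {
  v <- frame_matrix(stream)
  # decimal text with 17 significant digits round-trips IEEE doubles
  vc <- matrix(sprintf("%.17g", v), nrow(v))
  colnames(vc) <- paste0("v", seq_len(ncol(v)))
  flat <- data.frame(t = sprintf("%.17g", stream$t),
                     gesture = stream$gesture,
                     condition = stream$condition, phase = stream$phase, vc,
                     check.names = FALSE)
  data.table::fwrite(flat, path, quote = FALSE)
  meta$frame_rate <- attr(stream, "frame_rate") %||% 23
  meta$n_channels <- ncol(v)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  flat <- data.table::fread(path, data.table = FALSE)
  vcols <- grep("^v[0-9]+$", names(flat))
  v <- as.matrix(flat[, vcols])
  dimnames(v) <- NULL
  out <- tibble::tibble(t = flat$t,
                        gesture = ifelse(flat$gesture == "", NA_character_,
                                         flat$gesture),
                        condition = flat$condition, phase = flat$phase)
  out$v <- v
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "frame_rate") <- meta$frame_rate
  }
  out
}

#' Stack a window tibble into a dense array
#'
#' @param windows Window tibble.
#' @return A `window x channels x n_windows` numeric array.
#' @export
window_array <- function(windows) {
  arr <- array(0, dim = c(dim(windows$v[[1]]), nrow(windows)))
  for (i in seq_len(nrow(windows))) arr[, , i] <- windows$v[[i]]
  arr
}
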