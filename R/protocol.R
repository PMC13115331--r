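#' Adjacent current-drive measurement protocol
#'
#' Builds the canonical adjacent ("neighbouring") drive protocol used by
#' 16-electrode armband EIT: current is injected in turn through each pair of
#' neighbouring electrodes and the differential voltage is read from every
#' adjacent electrode pair not involved in the injection. With 16 electrodes
#' this yields 16 drives x 13 measurements = 208 channels per frame.
#'
#' Channel order is canonical and documented: drive-major (drive `d` injects
#' from electrode `d` into electrode `d + 1`, 0-based, counter-clockwise),
#' measurement-minor with measurement pairs `(m, m + 1)` for
#' `m = d + 2, ..., d + 14` (mod 16), i.e. ascending from two electrodes
#' past the source. The voltage sign convention is `V = u(m) - u(m + 1)`.
#'
#' @param n_electrodes Electrode count (16 for the armband).
#' @param current_mA Drive current amplitude in milliamperes. Boundary
#'   voltages scale linearly in it.
#' @return An object of class `eit_protocol`: list with `n_electrodes`,
#'   `current_mA`, `drive_pairs` (n x 2, 0-based), and `channels`, a tibble
#'   with one row per measurement channel (`channel`, `drive`, `src`, `snk`,
#'   `mpos`, `mneg`; electrodes 0-based).
#' @examples
#' p <- adjacent_protocol()
#' nrow(p$channels) # 208
#' @export
adjacent_protocol <- function(n_electrodes = 16L, current_mA = 1) {
  ne <- as.integer(n_electrodes)
  stopifnot(ne >= 8L, current_mA > 0)
  drives <- cbind(src = 0:(ne - 1L), snk = (1:ne) %% ne)
  rows <- lapply(0:(ne - 1L), function(d) {
    m <- (d + 1L + seq_len(ne - 3L)) %% ne    # d+2 .. d+14, mod ne
    tibble::tibble(drive = d, src = d, snk = (d + 1L) %% ne,
                   mpos = m, mneg = (m + 1L) %% ne)
  })
  channels <- dplyr::bind_rows(rows)
  channels$channel <- seq_len(nrow(channels))
  structure(
    list(n_electrodes = ne, current_mA = current_mA, drive_pairs = drives,
         channels = channels[, c("channel", "drive", "src", "snk",
                                 "mpos", "mneg")]),
    class = "eit_protocol"
  )
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("<eit_protocol> adjacent drive, ", x$n_electrodes, " electrodes, ",
      nrow(x$channels), " channels, ", x$current_mA, " mA\n", sep = "")
  invisible(x)
}
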