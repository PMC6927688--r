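#' DeltaHeight/time trace of a tracked molecule
#'
#' The per-frame observable is DeltaHeight = max - min height inside the
#' `window` x `window` nm box centered on the tracked molecule center (an
#' axis-aligned box rounded to whole pixels; 10 x 10 px at 0.5 nm/px). The
#' max-min difference cancels any constant height offset exactly. Frames in
#' which the molecule was not tracked, or whose window would leave the frame,
#' are skipped (no interpolation).
#'
#' @param movie an [afm_movie()].
#' @param track rows of a `particle_tracks` data.frame for one molecule.
#' @param window box side, nm (default 5).
#' @param follow if `TRUE` (default) the box follows the per-frame tracked
#'   center; if `FALSE` it stays at the molecule's first position.
#' @return data.frame (molecule_id, frame, time_s, delta_height_nm); class
#'   `height_trace`.
#' @export
delta_height_trace <- function(movie, track, window = 5, follow = TRUE) {
  stop_if(nrow(track) < 1, "track has no frames")
  half <- round(window / movie$pixel_size / 2)
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  rows <- list()
  r_fix <- round(track$row[1]); c_fix <- round(track$col[1])
  for (i in seq_len(nrow(track))) {
    f <- track$frame[i]
    r <- if (follow) round(track$row[i]) else r_fix
    c0 <- if (follow) round(track$col[i]) else c_fix
    ri <- (r - half + 1):(r + half); ci <- (c0 - half + 1):(c0 + half)
    if (min(ri) < 0 || min(ci) < 0 || max(ri) > nr - 1 || max(ci) > nc - 1)
      next  # window exceeds frame bounds: flagged by omission
    win <- movie$frames[ri + 1, ci + 1, f]
    tline <- movie$frame_times[f] +
      if (movie$line_time > 0) r * movie$line_time else 0
    rows[[length(rows) + 1]] <- data.frame(
      molecule_id = track$molecule_id[1], frame = f, time_s = tline,
      delta_height_nm = max(win) - min(win))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = integer(0), frame = integer(0),
               time_s = numeric(0), delta_height_nm = numeric(0))
  class(out) <- c("height_trace", "data.frame")
  out
}

#' Section kymograph of a tracked molecule
#'
#' Extracts a fixed-length line section through the per-frame molecule center
#' at a given angle; one kymograph row per frame.
#'
#' @param movie an [afm_movie()].
#' @param track track rows for one molecule.
#' @param angle section direction, degrees (0 = along columns).
#' @param length_nm section length, nm (default 15).
#' @return list(image = frames x positions matrix (nm), distance_nm,
#'   frame, time_s); class `kymograph`.
#' @export
kymograph <- function(movie, track, angle = 0, length_nm = 15) {
  stop_if(nrow(track) < 1, "track has no frames")
  n <- ceiling(length_nm / movie$pixel_size)
  tt <- seq(-0.5, 0.5, length.out = n) * length_nm / movie$pixel_size
  th <- angle * pi / 180
  img <- matrix(NA_real_, nrow(track), n)
  for (i in seq_len(nrow(track))) {
    f <- track$frame[i]
    rows <- track$row[i] + tt * sin(th)
    cols <- track$col[i] + tt * cos(th)
    img[i, ] <- bilinear_sample(movie$frames[, , f], rows, cols)
  }
  structure(list(image = img,
                 distance_nm = tt * movie$pixel_size,
                 frame = track$frame,
                 time_s = movie$frame_times[track$frame]),
            class = "kymograph")
}

#' Write / read DeltaHeight traces as CSV
#' @param trace a `height_trace` (or several row-bound); @param path file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("height_trace", "data.frame")
  out
}
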