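#' Simulate an imaging condition and run the full classification pipeline
#'
#' End-to-end convenience wrapper used for condition-level analyses:
#' draws per-frame gating states for each molecule from a condition preset's
#' jump chain, renders the tip-convolved movie with drift and noise, then
#' runs the analysis chain — per-frame plane flattening, drift correction,
#' particle detection on the median frame, tracking, snapshot classification —
#' and summarizes occupancy and the frame-to-frame transition matrix.
#'
#' @param preset a [condition_preset()] (or the name of one).
#' @param n_molecules molecules in the patch (default 20).
#' @param n_frames frames (default 100).
#' @param grid an [imaging_config()]; the default uses a field sized for the
#'   requested molecule count.
#' @param flatten,drift run those preprocessing steps (default TRUE).
#' @return list: `occupancy` (classified, with s.e.m.), `transitions`
#'   ([transition_matrix()]), `labels`, `truth_labels`, `truth_occupancy`,
#'   `movie`, `tracks`, `preset`.
#' @export
run_condition <- function(preset, n_molecules = 20, n_frames = 100,
                          grid = NULL, flatten = TRUE, drift = TRUE) {
  if (is.character(preset)) preset <- condition_preset(preset)
  patch <- membrane_patch(n_molecules, field_nm = field_for(n_molecules))
  if (is.null(grid)) {
    px <- 0.5
    grid <- imaging_config(pixel_size = px,
                           frame_shape = as.integer(field_for(n_molecules) / px))
  }
  chains <- lapply(seq_len(n_molecules), function(i)
    sample_chain(preset$P, n_frames, grid$frame_interval))
  sim <- simulate_movie(lapply(chains, `[[`, "path"), patch, grid, n_frames)
  movie <- sim$movie
  if (flatten) {
    for (f in seq_len(n_frames))
      movie$frames[, , f] <- plane_flatten(movie$frames[, , f]) +
        stats::median(movie$frames[, , f])
  }
  shifts <- NULL
  if (drift) {
    dc <- drift_correct(movie)
    movie <- dc$movie; shifts <- dc$shifts
  }
  dets <- lapply(seq_len(n_frames), function(f)
    detect_particles(movie$frames[, , f], grid$pixel_size, min_height = 3,
                     min_separation = 0.8 * 10.9))
  tracks <- track_particles(dets, grid$pixel_size)
  # molecules are laterally static once drift-corrected: keep persistent
  # tracks and classify every frame at the molecule's median position
  lens <- table(tracks$molecule_id)
  keep <- as.integer(names(lens)[lens >= 0.5 * n_frames])
  full <- do.call(rbind, lapply(seq_along(keep), function(i) {
    tr <- tracks[tracks$molecule_id == keep[i], ]
    data.frame(molecule_id = i, frame = seq_len(n_frames),
               row = stats::median(tr$row), col = stats::median(tr$col))
  }))
  class(full) <- c("particle_tracks", "data.frame")
  labels <- classify_movie(movie, full)
  tracks <- full
  occ <- occupancy(labels, condition = preset$condition)
  tm <- transition_matrix(labels)
  truth_labels <- data.frame(
    molecule_id = rep(seq_len(n_molecules), each = n_frames),
    frame = rep(seq_len(n_frames), n_molecules),
    class = unlist(lapply(chains, `[[`, "labels")))
  class(truth_labels) <- c("class_labels", "data.frame")
  list(occupancy = occ, transitions = tm, labels = labels,
       truth_labels = truth_labels,
       truth_occupancy = occupancy(truth_labels, preset$condition),
       movie = movie, tracks = tracks, shifts = shifts, preset = preset,
       patch = patch, grid = grid)
}

# patch field (nm) comfortably holding n molecules at ~14 nm spacing,
# with margins wide enough for the classification patch around every center
field_for <- function(n) {
  side <- ceiling(sqrt(n))
  len <- max(60, (side - 1) * 14 + 22 + 14)
  c(len, len)
}
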