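#' HS-AFM movie container
#'
#' @param frames 3D numeric array (rows, cols, frames) of heights in nm, or a
#'   list of matrices.
#' @param pixel_size nm per pixel.
#' @param frame_times acquisition start time of each frame, s.
#' @param line_time s per scan line (0 = instantaneous frames).
#' @param t0 experiment time of the first frame, s.
#' @return object of class `afm_movie`.
#' @export
afm_movie <- function(frames, pixel_size, frame_times, line_time = 0, t0 = 0) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stop_if(length(dim(frames)) != 3, "frames must be a rows x cols x n array")
  stop_if(length(frame_times) != dim(frames)[3],
          "need one frame time per frame")
  stop_if(any(diff(frame_times) <= 0), "frame_times must be strictly increasing")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_times = frame_times, line_time = line_time, t0 = t0),
            class = "afm_movie")
}

#' @export
print.afm_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("HS-AFM movie: %d frames of %d x %d px (%.2g nm/px), %.3g-%.3g s\n",
              d[3], d[1], d[2], x$pixel_size,
              x$frame_times[1], x$frame_times[d[3]]))
  invisible(x)
}

#' @export
`[.afm_movie` <- function(x, i) {
  afm_movie(x$frames[, , i, drop = FALSE], x$pixel_size,
            x$frame_times[i], x$line_time, x$t0)
}

#' Number of frames in a movie
#' @param movie an `afm_movie`.
#' @export
nframes <- function(movie) dim(movie$frames)[3]

#' Simulate a raster-scanned HS-AFM movie with ground truth
#'
#' Renders each molecule's gating path into frames line by line: scan line i
#' of frame f images the conformation the molecule had at time
#' `f * frame_interval + i * line_time`, so state changes faster than the
#' frame time produce intra-frame mixtures (the top and bottom of a frame can
#' show different conformations). Each composed true surface is then passed
#' through the tip-convolution model, linear scanner drift is applied to the
#' particle centers, and Gaussian vertical noise is added.
#'
#' @param paths list (one per molecule) of state-interval data.frames as
#'   returned by [sample_gating()] or [sample_chain()]`$path`.
#' @param patch a [membrane_patch()] with one center per molecule.
#' @param grid an [imaging_config()].
#' @param n_frames number of frames to render.
#' @param geometry_args named list of arguments forwarded to
#'   [particle_geometry()] (shared dimensional parameters).
#' @return list with `movie` (an [afm_movie()]) and `truth` (data.frame of
#'   molecule_id, t_start, t_end, class — the ground-truth state log).
#' @export
simulate_movie <- function(paths, patch, grid, n_frames,
                           geometry_args = list()) {
  n_mol <- length(paths)
  stop_if(nrow(patch$centers) != n_mol, "need one path per particle center")
  nr <- grid$frame_shape[1]; nc <- grid$frame_shape[2]
  frames <- array(0, c(nr, nc, n_frames))
  geom_cache <- new.env(parent = emptyenv())
  geom_for <- function(cls, offsets) {
    if (cls != "openplus") {
      key <- cls
      if (is.null(geom_cache[[key]]))
        geom_cache[[key]] <- do.call(particle_geometry,
                                     c(list(class_label = cls), geometry_args))
      geom_cache[[key]]
    } else {
      do.call(particle_geometry,
              c(list(class_label = "openplus", offsets = offsets),
                geometry_args))
    }
  }
  for (f in seq_len(n_frames)) {
    t_f <- (f - 1) * grid$frame_interval
    line_t <- t_f + (0:(nr - 1)) * grid$line_time
    # drift: particle centers move with the scanner offset accumulated to t_f
    drift <- grid$drift_velocity * t_f
    img <- matrix(patch$membrane_top_height, nr, nc)
    for (m in seq_len(n_mol)) {
      p <- paths[[m]]
      idx <- pmin(pmax(findInterval(line_t, p$t_start), 1L), nrow(p))
      runs <- rle(idx)
      row0 <- 0L
      for (j in seq_along(runs$lengths)) {
        rows <- (row0 + 1L):(row0 + runs$lengths[j])
        row0 <- row0 + runs$lengths[j]
        iv <- runs$values[j]
        gm <- geom_for(p$class[iv],
                       if ("offsets" %in% names(p)) p$offsets[[iv]] else NULL)
        ctr <- patch$centers[m, ] + drift
        img[rows, ] <- render_height_map(gm, matrix(ctr, 1), grid,
                                         membrane_top_height = patch$membrane_top_height,
                                         rows = rows,
                                         base = img[rows, , drop = FALSE])
      }
    }
    img <- tip_dilate(img, grid$tip_radius, grid$pixel_size)
    if (grid$vertical_noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, grid$vertical_noise_sd),
                          nr, nc)
    frames[, , f] <- img
  }
  truth <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    p <- paths[[m]]
    data.frame(molecule_id = m, t_start = p$t_start, t_end = p$t_end,
               class = p$class, stringsAsFactors = FALSE)
  }))
  list(movie = afm_movie(frames, grid$pixel_size,
                         frame_times = (seq_len(n_frames) - 1) * grid$frame_interval,
                         line_time = grid$line_time),
       truth = truth)
}

#' Write / read a movie as multi-page TIFF + JSON sidecar
#'
#' Heights are stored as 32-bit float TIFF pages normalized by
#' `height_scale_nm` (recorded in the sidecar along with pixel size and
#' timing), so round-tripping preserves nm values to float precision.
#'
#' @param movie an [afm_movie()].
#' @param prefix output path prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return invisibly, the two file paths.
#' @export
write_movie <- function(movie, prefix) {
  hmax <- max(movie$frames, 1e-9)
  hmin <- min(movie$frames, 0)
  scale <- hmax - hmin
  pages <- lapply(seq_len(nframes(movie)), function(i)
    (movie$frames[, , i] - hmin) / scale)
  tif <- paste0(prefix, ".tif"); js <- paste0(prefix, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_nm = movie$pixel_size,
                            frame_interval_s = if (nframes(movie) > 1)
                              diff(movie$frame_times)[1] else NA,
                            frame_times_s = movie$frame_times,
                            line_time_s = movie$line_time,
                            t0_s = movie$t0,
                            height_offset_nm = hmin,
                            height_scale_nm = scale),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}

#' @rdname write_movie
#' @export
read_movie <- function(prefix) {
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  frames <- simplify2array(pages) * meta$height_scale_nm + meta$height_offset_nm
  afm_movie(frames, meta$pixel_size_nm, meta$frame_times_s,
            meta$line_time_s, meta$t0_s)
}

#' Write / read a ground-truth state log as JSON lines
#' @param truth data.frame (molecule_id, t_start, t_end, class).
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(truth)))
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rows <- lapply(readLines(path), jsonlite::fromJSON)
  do.call(rbind, lapply(rows, as.data.frame))
}
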