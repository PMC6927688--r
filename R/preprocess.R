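#' First-order plane flattening
#'
#' Fits a least-squares plane `a + b*col + c*row` over the unmasked pixels
#' and subtracts it from the whole frame. By default, bright (particle)
#' pixels are excluded from the fit with an Otsu threshold so the membrane
#' and support define the plane; flattening is idempotent.
#'
#' @param frame height image, nm.
#' @param mask optional logical matrix, `TRUE` = exclude from the plane fit
#'   (the plane is still subtracted everywhere).
#' @param auto_mask if `TRUE` and `mask` is `NULL`, exclude pixels above the
#'   Otsu threshold.
#' @return flattened frame (nm).
#' @export
plane_flatten <- function(frame, mask = NULL, auto_mask = TRUE) {
  stop_if(!all(is.finite(frame)), "frame must be finite")
  if (is.null(mask) && auto_mask) mask <- frame > otsu_threshold(frame)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(frame), ncol(frame))
  keep <- !mask
  stop_if(!any(keep), "all pixels masked")
  nr <- nrow(frame); nc <- ncol(frame)
  cc <- matrix(rep(0:(nc - 1), each = nr), nr)
  rr <- matrix(rep(0:(nr - 1), nc), nr)
  fit <- stats::lm.fit(cbind(1, cc[keep], rr[keep]), frame[keep])
  frame - (fit$coefficients[1] + fit$coefficients[2] * cc +
             fit$coefficients[3] * rr)
}

#' Otsu threshold of a height image
#' @param img numeric matrix; @param n_bins histogram bins.
#' @return threshold (nm) maximizing between-class variance.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.numeric(img)
  br <- seq(min(v), max(v), length.out = n_bins + 1)
  if (br[1] == br[n_bins + 1]) return(br[1])
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(n_bins + 1)]) / 2
  w0 <- cumsum(p); mu <- cumsum(p * mids); mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# cross-correlation shift of b relative to a, with parabolic subpixel peak
xcorr_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  nr <- nrow(a); nc <- ncol(a)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  refine <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (den == 0) 0 else 0.5 * (cm1 - cp1) / den
  }
  pr <- peak[1]; pc <- peak[2]
  rm1 <- cc[(pr - 2) %% nr + 1, pc]; rp1 <- cc[pr %% nr + 1, pc]
  cm1 <- cc[pr, (pc - 2) %% nc + 1]; cp1 <- cc[pr, pc %% nc + 1]
  dr <- wrap(pr, nr) + refine(rm1, cc[pr, pc], rp1)
  dc <- wrap(pc, nc) + refine(cm1, cc[pr, pc], cp1)
  c(dr = -dr, dc = -dc, peak = max(cc) / (stats::sd(a) * stats::sd(b) * nr * nc))
}

#' Drift correction by cross-correlation registration
#'
#' Estimates the (dy, dx) shift of each frame relative to the reference by
#' the cross-correlation peak with parabolic subpixel refinement, accumulates
#' shifts along the movie when registering to the previous frame, and
#' resamples every frame so the static background is stationary. Frames whose
#' normalized correlation peak falls below `min_peak` are flagged and inherit
#' the interpolated shift of their neighbors.
#'
#' @param movie an [afm_movie()].
#' @param reference `"previous"` (accumulated frame-to-frame shifts) or
#'   `"first"`.
#' @param min_peak normalized correlation acceptance threshold.
#' @return list with `movie` (registered), `shifts` (n x 2 matrix, px,
#'   (dr, dc) applied), and `flagged` (logical).
#' @export
drift_correct <- function(movie, reference = c("previous", "first"),
                          min_peak = 0.2) {
  reference <- match.arg(reference)
  nf <- nframes(movie)
  stop_if(nf < 2, "drift correction needs at least 2 frames")
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dr", "dc")))
  flagged <- logical(nf)
  for (i in 2:nf) {
    ref <- if (reference == "previous") movie$frames[, , i - 1]
           else movie$frames[, , 1]
    s <- xcorr_shift(ref, movie$frames[, , i])
    if (is.finite(s["peak"]) && s["peak"] < min_peak) {
      flagged[i] <- TRUE
      s[c("dr", "dc")] <- 0
    }
    shifts[i, ] <- if (reference == "previous")
      shifts[i - 1, ] + s[c("dr", "dc")] else s[c("dr", "dc")]
  }
  if (any(flagged)) {
    ok <- which(!flagged)
    for (j in 1:2)
      shifts[flagged, j] <- stats::approx(ok, shifts[ok, j], xout = which(flagged),
                                          rule = 2)$y
  }
  out <- movie$frames
  for (i in 2:nf)
    out[, , i] <- shift_image(movie$frames[, , i], -shifts[i, 1], -shifts[i, 2],
                              fill = stats::median(movie$frames[, , i]))
  list(movie = afm_movie(out, movie$pixel_size, movie$frame_times,
                         movie$line_time, movie$t0),
       shifts = shifts, flagged = flagged)
}

#' Detect particle centers in a flattened frame
#'
#' Local maxima of a Gaussian-smoothed frame above `min_height`, with
#' non-maximum suppression at `min_separation` and intensity-weighted
#' subpixel centroids.
#'
#' @param frame flattened height image, nm.
#' @param pixel_size nm per px.
#' @param min_height detection threshold above the frame median, nm.
#' @param min_separation suppression radius, nm.
#' @param smooth_nm Gaussian smoothing SD, nm.
#' @param centroid_nm half-width of the iterated centroid window, nm.
#' @return data.frame (row, col) of 0-based subpixel centers (px).
#' @export
detect_particles <- function(frame, pixel_size = 0.5, min_height = 3,
                             min_separation = 8, smooth_nm = 1,
                             centroid_nm = 7) {
  sm <- gaussian_smooth(frame, smooth_nm / pixel_size)
  # background reference: low quantile, robust to dense particle coverage
  bg <- stats::quantile(sm, 0.25, names = FALSE)
  nr <- nrow(sm); nc <- ncol(sm)
  inner <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner >= sm[1:(nr - 2), 2:(nc - 1)] &
    inner >= sm[3:nr, 2:(nc - 1)] &
    inner >= sm[2:(nr - 1), 1:(nc - 2)] &
    inner >= sm[2:(nr - 1), 3:nc] &
    inner > bg + min_height
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(row = numeric(0), col = numeric(0)))
  cand <- data.frame(row = idx[, 1], col = idx[, 2],   # 1-based inner -> 0-based full
                     val = inner[idx])
  cand <- cand[order(-cand$val), ]
  sep_px <- min_separation / pixel_size
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d2 <- (cand$row[later] - cand$row[i])^2 + (cand$col[later] - cand$col[i])^2
      keep[later][d2 < sep_px^2] <- FALSE
    }
  }
  cand <- cand[keep, ]
  # iterated subpixel centroid over a disk around the peak (peaks are
  # plateau-like after tip convolution, so the raw maximum is biased by up to
  # half the plateau; a square window would also clip neighboring particles
  # at its corners in crowded patches, hence disk weights with a height gate).
  # the disk must extend past the pedestal edge: on the plateau itself the
  # gated weights are nearly uniform and carry no centring gradient
  ctr <- t(apply(cand, 1, function(p)
    refine_center(sm, p[1], p[2], centroid_nm / pixel_size, bg + min_height / 2)))
  data.frame(row = ctr[, 1], col = ctr[, 2])
}

#' Link detections across frames into particle tracks
#'
#' Greedy nearest-neighbor frame-to-frame linking: each track is extended to
#' its closest detection in the next frame if within `max_link_distance`;
#' unlinked detections start new tracks. Gaps up to `max_gap` frames are
#' allowed before a track is closed.
#'
#' @param detections list (per frame) of data.frames (row, col) in px.
#' @param pixel_size nm per px.
#' @param max_link_distance nm.
#' @param max_gap frames a track may go undetected and still be linked.
#' @return data.frame (molecule_id, frame, row, col); class `particle_tracks`.
#' @export
track_particles <- function(detections, pixel_size = 0.5,
                            max_link_distance = 5, max_gap = 2) {
  max_px <- max_link_distance / pixel_size
  tracks <- list()   # each: list(rows, cols, frames, last_seen)
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    used <- rep(FALSE, nrow(det))
    if (length(tracks)) {
      open_idx <- which(vapply(tracks, function(tr) f - tr$last_seen <= max_gap + 1,
                               logical(1)))
      # greedy: closest (track, detection) pairs first
      if (length(open_idx) && nrow(det)) {
        last_pos <- t(vapply(tracks[open_idx], function(tr)
          c(tr$rows[length(tr$rows)], tr$cols[length(tr$cols)]), numeric(2)))
        dmat <- outer(last_pos[, 1], det$row, "-")^2 +
          outer(last_pos[, 2], det$col, "-")^2
        repeat {
          m <- which.min(dmat)
          if (!length(m) || dmat[m] > max_px^2) break
          ij <- arrayInd(m, dim(dmat))
          ti <- open_idx[ij[1]]; di <- ij[2]
          tr <- tracks[[ti]]
          tr$rows <- c(tr$rows, det$row[di]); tr$cols <- c(tr$cols, det$col[di])
          tr$frames <- c(tr$frames, f); tr$last_seen <- f
          tracks[[ti]] <- tr
          used[di] <- TRUE
          dmat[ij[1], ] <- Inf; dmat[, ij[2]] <- Inf
        }
      }
    }
    for (di in which(!used)) {
      tracks[[length(tracks) + 1]] <- list(rows = det$row[di], cols = det$col[di],
                                           frames = f, last_seen = f)
    }
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(molecule_id = i, frame = tr$frames, row = tr$rows, col = tr$cols)
  }))
  class(out) <- c("particle_tracks", "data.frame")
  out
}

#' n-fold rotational average of a particle patch
#'
#' Mean of the patch rotated by k*360/n degrees (k = 0..n-1) about the given
#' subpixel center with bilinear interpolation; pixels that leave the patch
#' under any rotation are dropped from the average (NA).
#'
#' @param patch height image, nm.
#' @param n fold symmetry (>= 1).
#' @param center 0-based (row, col) subpixel rotation center (default patch
#'   center).
#' @return averaged patch (nm) with NA outside the common support.
#' @export
nfold_average <- function(patch, n = 5, center = NULL) {
  stop_if(n < 1, "n must be >= 1")
  if (is.null(center)) center <- (dim(patch) - 1) / 2
  stop_if(center[1] < 0 || center[2] < 0 ||
            center[1] > nrow(patch) - 1 || center[2] > ncol(patch) - 1,
          "center outside patch")
  if (n == 1) return(patch)
  acc <- patch
  for (k in 1:(n - 1)) acc <- acc + rotate_about(patch, 360 * k / n, center)
  acc / n
}

#' Cross-section profile with peak-to-peak height and periodicity
#'
#' Bilinear samples along the segment from `p0` to `p1` at `pixel_size`
#' steps. Periodicity is the first off-zero maximum of the autocorrelation of
#' the mean-subtracted profile (suited to short profiles); it is `NA` when
#' the profile is flat.
#'
#' @param frame height image, nm.
#' @param p0,p1 0-based (row, col) endpoints, px.
#' @param pixel_size nm per px.
#' @return list(distance_nm, height_nm, peak_to_peak, periodicity_nm).
#' @export
cross_section <- function(frame, p0, p1, pixel_size = 0.5) {
  len_px <- sqrt(sum((p1 - p0)^2))
  stop_if(len_px == 0, "degenerate segment")
  n <- max(2L, ceiling(len_px))
  tt <- seq(0, 1, length.out = n + 1)
  rows <- p0[1] + tt * (p1[1] - p0[1])
  cols <- p0[2] + tt * (p1[2] - p0[2])
  h <- bilinear_sample(frame, rows, cols)
  d <- tt * len_px * pixel_size
  v <- h - mean(h, na.rm = TRUE)
  per <- NA_real_
  if (stats::sd(h, na.rm = TRUE) > 1e-12) {
    ac <- stats::acf(v[!is.na(v)], lag.max = length(v) - 2, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    # first local max after the initial decay
    lm_idx <- which(diff(sign(diff(ac))) == -2) + 1
    lm_idx <- lm_idx[ac[lm_idx] > 0]
    if (length(lm_idx)) per <- (lm_idx[1] - 1) * (d[2] - d[1])
  }
  list(distance_nm = d, height_nm = h,
       peak_to_peak = max(h, na.rm = TRUE) - min(h, na.rm = TRUE),
       periodicity_nm = per)
}

#' Height histogram with mode detection
#'
#' Histogram of all pixel heights with modes found by local-maximum detection
#' on a smoothed density; reports pairwise mode separations (e.g. the
#' support-to-protein peak-to-peak distance).
#'
#' @param x an [afm_movie()] or a height matrix.
#' @param bin_width nm (default 0.25).
#' @param smooth_bins SD (in bins) of the Gaussian used to smooth counts.
#' @param min_frac modes must exceed this fraction of the tallest mode.
#' @return list(breaks, counts, modes_nm, mode_separations_nm).
#' @export
height_histogram <- function(x, bin_width = 0.25, smooth_bins = 2,
                             min_frac = 0.05) {
  v <- if (inherits(x, "afm_movie")) as.numeric(x$frames) else as.numeric(x)
  stop_if(length(v) < 1000, "need at least 1000 pixels")
  rng <- range(v)
  if (diff(rng) < bin_width)
    return(list(breaks = rng, counts = length(v), modes_nm = mean(rng),
                mode_separations_nm = numeric(0)))
  br <- seq(rng[1], rng[2] + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  cnt <- h$counts
  if (smooth_bins > 0) {
    half <- ceiling(3 * smooth_bins)
    k <- dnorm(-half:half, sd = smooth_bins); k <- k / sum(k)
    cnt <- as.numeric(stats::filter(c(rep(cnt[1], half), cnt,
                                      rep(cnt[length(cnt)], half)),
                                    k, sides = 2))[(half + 1):(half + length(cnt))]
  }
  n <- length(cnt)
  is_mode <- c(FALSE, cnt[2:(n - 1)] > cnt[1:(n - 2)] &
                 cnt[2:(n - 1)] >= cnt[3:n], FALSE)
  is_mode <- is_mode & cnt >= min_frac * max(cnt)
  # endpoints can also be modes
  if (cnt[1] > cnt[2] && cnt[1] >= min_frac * max(cnt)) is_mode[1] <- TRUE
  if (cnt[n] > cnt[n - 1] && cnt[n] >= min_frac * max(cnt)) is_mode[n] <- TRUE
  modes <- h$mids[is_mode]
  seps <- if (length(modes) > 1) as.numeric(stats::dist(modes)) else numeric(0)
  list(breaks = h$breaks, counts = h$counts, modes_nm = modes,
       mode_separations_nm = seps)
}

#' Write particle tracks to CSV
#' @param tracks a `particle_tracks` data.frame; @param path file.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("particle_tracks", "data.frame")
  out
}
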