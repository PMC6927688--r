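#' Snapshot features of a particle patch
#'
#' Computes the feature set used by the conformational decision list:
#' \describe{
#'   \item{S5}{5-fold rotational correlation: mean Pearson correlation
#'     between the mean-subtracted patch and its 72, 144, 216, 288 degree
#'     rotations about the particle center, evaluated over a centered disk of
#'     radius `s5_radius` nm (the particle body, so the symmetric membrane
#'     background does not inflate the correlation).}
#'   \item{apex}{maximum height above the local membrane within the particle
#'     footprint (disk of radius 0.45 * outer_diameter).}
#'   \item{apex_offset}{distance (nm) of that maximum from the center.}
#'   \item{n_lobes}{number of suppressed local maxima of the smoothed patch
#'     higher than `base_protrusion - 1` nm above the local membrane.}
#'   \item{eccentricity}{second-moment eccentricity of the super-threshold
#'     footprint (pixels above the elevated-apex threshold).}
#' }
#' The local membrane reference is a low quantile of the heights in an
#' annulus at 1.2-1.5 x the particle outer radius (robust to neighboring
#' particles clipping the annulus in crowded patches).
#'
#' @param patch height image (nm) at least `outer_diameter` wide.
#' @param center 0-based (row, col) subpixel particle center in the patch.
#' @param pixel_size nm per px.
#' @param outer_diameter nm (default 10.9).
#' @param base_protrusion nm (default 7).
#' @param apex_extra nm (default 1.5); the elevated threshold is
#'   `base_protrusion + apex_extra / 2`.
#' @param s5_radius radius of the S5 correlation disk, nm (default
#'   `ring_diameter` = 5).
#' @param recenter refine the center on the particle body's center of mass
#'   before computing features (default TRUE; the S5 rotation axis must sit
#'   within about half a pixel of the true symmetry axis).
#' @return list of features (class `snapshot_features`); `S5` is `NA` and
#'   `flat` is `TRUE` for featureless patches.
#' @export
extract_features <- function(patch, center = NULL, pixel_size = 0.5,
                             outer_diameter = 10.9, base_protrusion = 7,
                             apex_extra = 1.5, s5_radius = 5,
                             recenter = TRUE) {
  if (is.null(center)) center <- (dim(patch) - 1) / 2
  stop_if(min(dim(patch)) * pixel_size < outer_diameter,
          "patch smaller than the particle outer diameter")
  nr <- nrow(patch); nc <- ncol(patch)
  # all features are computed on a lightly smoothed patch: the rotational
  # correlation and the footprint should reflect structure, not pixel noise
  sm <- gaussian_smooth(patch, 0.75 / pixel_size)
  if (recenter && stats::sd(sm) > 1e-9) {
    # symmetry features need the rotation axis within ~half a pixel; refine
    # the supplied center on the particle body's center of mass
    floor_h <- stats::quantile(sm, 0.2, names = FALSE) + 2
    ctr2 <- refine_center(sm, center[1], center[2],
                          0.5 * outer_diameter / pixel_size, floor_h)
    # accept only a small correction; a strongly asymmetric molecule can
    # legitimately have its mass off-axis
    if (sqrt(sum((ctr2 - center)^2)) <= 2.5 / pixel_size) center <- ctr2
  }
  rr <- matrix(rep(0:(nr - 1), nc), nr) - center[1]
  cc <- matrix(rep(0:(nc - 1), each = nr), nr) - center[2]
  d_nm <- sqrt(rr^2 + cc^2) * pixel_size
  r_out <- outer_diameter / 2
  annulus <- d_nm >= 1.2 * r_out & d_nm <= 1.5 * r_out
  # low quantile rather than median: in crowded patches the annulus clips the
  # flanks of neighboring particles, whereas the true membrane fills the gaps
  membrane <- if (any(annulus))
    stats::quantile(sm[annulus], 0.2, names = FALSE)
  else stats::quantile(sm, 0.2, names = FALSE)
  if (stats::sd(patch) < 1e-9) {
    return(structure(list(S5 = NA_real_, apex = 0, apex_offset = NA_real_,
                          n_lobes = 0L, eccentricity = NA_real_,
                          membrane = membrane, flat = TRUE),
                     class = "snapshot_features"))
  }
  # S5 over the particle-body disk
  disk <- d_nm <= s5_radius
  cors <- numeric(4)
  for (k in 1:4) {
    rot <- rotate_about(sm, 72 * k, center)
    ok <- disk & !is.na(rot)
    cors[k] <- suppressWarnings(stats::cor(sm[ok], rot[ok]))
  }
  s5 <- mean(cors)
  # apex within the footprint
  foot <- d_nm <= 0.45 * outer_diameter
  rel <- sm - membrane
  apex <- max(rel[foot])
  w <- which(foot & rel == apex, arr.ind = TRUE)[1, ]
  apex_offset <- unname(sqrt((w[1] - 1 - center[1])^2 +
                               (w[2] - 1 - center[2])^2) * pixel_size)
  # prominent lobes: suppressed local maxima of the smoothed patch
  thr_lobe <- membrane + base_protrusion - 1
  inner <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner >= sm[1:(nr - 2), 2:(nc - 1)] & inner >= sm[3:nr, 2:(nc - 1)] &
    inner >= sm[2:(nr - 1), 1:(nc - 2)] & inner >= sm[2:(nr - 1), 3:nc] &
    inner > thr_lobe & foot[2:(nr - 1), 2:(nc - 1)]
  pk <- which(is_max, arr.ind = TRUE)
  n_lobes <- 0L
  if (nrow(pk)) {
    vals <- inner[pk]
    o <- order(-vals); pk <- pk[o, , drop = FALSE]
    sep_px <- 2 / pixel_size
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))) {
      if (!keep[i] || i == nrow(pk)) next
      later <- (i + 1):nrow(pk)
      d2 <- (pk[later, 1] - pk[i, 1])^2 + (pk[later, 2] - pk[i, 2])^2
      keep[later][d2 < sep_px^2] <- FALSE
    }
    n_lobes <- sum(keep)
  }
  # eccentricity of the elevated footprint
  thr_elev <- membrane + base_protrusion + apex_extra / 2
  sel <- sm > thr_elev & d_nm <= 0.6 * outer_diameter
  ecc <- NA_real_
  if (sum(sel) >= 3) {
    yr <- rr[sel]; xc <- cc[sel]
    covm <- stats::cov(cbind(yr, xc))
    ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] > 0) ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  }
  structure(list(S5 = s5, apex = apex, apex_offset = apex_offset,
                 n_lobes = n_lobes, eccentricity = ecc,
                 membrane = membrane, flat = FALSE),
            class = "snapshot_features")
}

#' Classification thresholds for the conformational decision list
#'
#' All defaults are calibrated on simulator renders of the four parametric
#' classes under the default imaging noise (see the methods vignette):
#' measured apex heights sit below their geometric values because features
#' are computed on a lightly smoothed patch against a local-membrane
#' reference, so the elevated-apex threshold is the midpoint of the measured
#' (not geometric) closed and raised apex distributions.
#'
#' @param s_thr minimum S5 for the symmetric (closed) class.
#' @param h_thr elevated-apex threshold above the local membrane, nm.
#' @param r_core maximum apex offset for the dome (open-II) class, nm.
#' @param e_thr minimum footprint eccentricity for open-I.
#' @return named list of thresholds.
#' @export
classify_thresholds <- function(s_thr = 0.88, h_thr = 7.3, r_core = 0.9,
                                e_thr = 0.6) {
  list(s_thr = s_thr, h_thr = h_thr, r_core = r_core, e_thr = e_thr)
}

#' Classify a snapshot into the four conformational classes
#'
#' Ordered decision list:
#' closed if `S5 >= s_thr` and `apex < h_thr` (5-fold symmetric, no elevated
#' subunit); open-II if `apex >= h_thr` and `apex_offset <= r_core` (elevated
#' center dome); open-I if `apex >= h_thr`, `n_lobes <= 3` and
#' `eccentricity >= e_thr` (few, asymmetrically placed elevated protrusions);
#' open-+ otherwise (asymmetric molecules of all kinds, including those
#' without increased height).
#'
#' @param features a `snapshot_features`.
#' @param thresholds a [classify_thresholds()] list.
#' @return one of [gating_classes()].
#' @export
classify_snapshot <- function(features, thresholds = classify_thresholds()) {
  th <- thresholds
  if (isTRUE(features$flat)) return("openplus")
  if (!is.na(features$S5) && features$S5 >= th$s_thr &&
      features$apex < th$h_thr) return("closed")
  if (features$apex >= th$h_thr && !is.na(features$apex_offset) &&
      features$apex_offset <= th$r_core) return("open2")
  if (features$apex >= th$h_thr && features$n_lobes <= 3 &&
      !is.na(features$eccentricity) && features$eccentricity >= th$e_thr)
    return("open1")
  "openplus"
}

#' Classify every tracked molecule in every frame of a movie
#'
#' Extracts a patch around each tracked center, computes features and applies
#' the decision list; the standard entry point from tracking into occupancy
#' and transition analyses.
#'
#' @param movie an [afm_movie()] (flattened / drift-corrected).
#' @param tracks `particle_tracks` data.frame.
#' @param patch_nm patch half-width, nm (default 8.5, covering the membrane
#'   annulus).
#' @param thresholds [classify_thresholds()].
#' @param geometry_args list with optional `outer_diameter`,
#'   `base_protrusion`, `apex_extra` overrides.
#' @return data.frame (molecule_id, frame, class); class `class_labels`.
#' @export
classify_movie <- function(movie, tracks, patch_nm = 8.5,
                           thresholds = classify_thresholds(),
                           geometry_args = list()) {
  half <- ceiling(patch_nm / movie$pixel_size)
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  fa <- function(nm, def) if (!is.null(geometry_args[[nm]])) geometry_args[[nm]] else def
  out <- vector("list", nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    r <- round(tracks$row[i]); c0 <- round(tracks$col[i])
    ri <- (r - half):(r + half); ci <- (c0 - half):(c0 + half)
    if (min(ri) < 0 || min(ci) < 0 || max(ri) > nr - 1 || max(ci) > nc - 1)
      next
    patch <- movie$frames[ri + 1, ci + 1, tracks$frame[i]]
    ctr <- c(tracks$row[i] - ri[1], tracks$col[i] - ci[1])
    ft <- extract_features(patch, ctr, movie$pixel_size,
                           outer_diameter = fa("outer_diameter", 10.9),
                           base_protrusion = fa("base_protrusion", 7),
                           apex_extra = fa("apex_extra", 1.5))
    out[[i]] <- data.frame(molecule_id = tracks$molecule_id[i],
                           frame = tracks$frame[i],
                           class = classify_snapshot(ft, thresholds))
  }
  res <- do.call(rbind, out)
  class(res) <- c("class_labels", "data.frame")
  res
}

#' Per-condition class occupancy with s.e.m. across molecules
#'
#' Class fractions are computed per molecule first, then averaged across
#' molecules; the error is the standard error of the mean across molecules
#' (matching error bars computed across molecules, not pooled frames).
#'
#' @param labels `class_labels` data.frame (molecule_id, frame, class).
#' @param condition label recorded in the output.
#' @return data.frame (condition, class, mean_percent, sem_percent,
#'   n_molecules, n_frames).
#' @export
occupancy <- function(labels, condition = NA) {
  mols <- unique(labels$molecule_id)
  stop_if(length(mols) < 2, "occupancy needs >= 2 molecules")
  cls <- gating_classes()
  frac <- t(vapply(mols, function(m) {
    x <- labels$class[labels$molecule_id == m]
    vapply(cls, function(cl) mean(x == cl), 0)
  }, numeric(4)))
  data.frame(condition = condition, class = cls,
             mean_percent = 100 * colMeans(frac),
             sem_percent = 100 * apply(frac, 2, stats::sd) / sqrt(length(mols)),
             n_molecules = length(mols), n_frames = nrow(labels),
             row.names = NULL)
}

#' Frame-to-frame 4x4 transition matrix
#'
#' Counts transitions between consecutive frames of the same molecule,
#' row-normalizes to percentages (conditional on the origin state), and sums
#' the elevated block (open2/open1 x open2/open1) and elongated block
#' (open1/open+ x open1/open+).
#'
#' @param labels `class_labels` data.frame.
#' @return list (class `transition_matrix`): `counts`, `percent` (rows sum
#'   to 100; NA rows flagged), `block_sums`, `n_pairs`.
#' @export
transition_matrix <- function(labels) {
  cls <- gating_classes()
  counts <- matrix(0, 4, 4, dimnames = list(cls, cls))
  for (m in unique(labels$molecule_id)) {
    x <- labels[labels$molecule_id == m, ]
    x <- x[order(x$frame), ]
    consec <- which(diff(x$frame) == 1)
    if (!length(consec)) next
    a <- factor(x$class[consec], cls); b <- factor(x$class[consec + 1], cls)
    counts <- counts + table(a, b)
  }
  stop_if(sum(counts) < 1, "need at least 2 consecutive frames")
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs > 0, rs, NA)
  elevated <- c("open2", "open1"); elongated <- c("open1", "openplus")
  blocks <- c(elevated = sum(counts[elevated, elevated]),
              elongated = sum(counts[elongated, elongated]))
  structure(list(counts = counts, percent = percent, block_sums = blocks,
                 n_pairs = sum(counts),
                 empty_rows = rownames(counts)[rs == 0]),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Frame-to-frame transitions (%d pairs), row percentages:\n",
              x$n_pairs))
  print(round(x$percent, 1))
  cat("block sums (counts): elevated =", x$block_sums["elevated"],
      ", elongated =", x$block_sums["elongated"], "\n")
  invisible(x)
}

#' Aggregate probability of returning to the symmetric (closed) class
#'
#' Conditional percentage, over all frame pairs whose origin state is any
#' open class, of landing in the closed class at the next frame.
#'
#' @param tm a [transition_matrix()].
#' @return percentage (NA with a warning if no open-origin pairs exist).
#' @export
return_to_closed_probability <- function(tm) {
  open_rows <- gating_classes()[-1]
  tot <- sum(tm$counts[open_rows, ])
  if (tot == 0) {
    warning("no transitions out of open classes; return probability undefined")
    return(NA_real_)
  }
  100 * sum(tm$counts[open_rows, "closed"]) / tot
}

#' Two-sample test of class occupancy between conditions
#'
#' Welch two-sided t test on per-molecule class fractions.
#'
#' @param frac_a,frac_b numeric vectors of per-molecule fractions.
#' @return `htest` object; p is `NA` (flagged by warning) when both samples
#'   have zero variance and identical means cannot be tested.
#' @export
occupancy_test <- function(frac_a, frac_b) {
  stop_if(length(frac_a) < 2 || length(frac_b) < 2,
          "need >= 2 molecules per condition")
  if (stats::sd(frac_a) == 0 && stats::sd(frac_b) == 0) {
    if (isTRUE(all.equal(mean(frac_a), mean(frac_b)))) {
      res <- list(statistic = c(t = 0), p.value = 1,
                  method = "Welch Two Sample t-test (degenerate: equal constants)")
      class(res) <- "htest"
      return(res)
    }
    warning("zero variance in both samples; p undefined")
    res <- list(statistic = c(t = NA_real_), p.value = NA_real_,
                method = "Welch Two Sample t-test (degenerate)")
    class(res) <- "htest"
    return(res)
  }
  stats::t.test(frac_a, frac_b, var.equal = FALSE)
}
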