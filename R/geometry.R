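#' Parametric pentamer geometry
#'
#' Builds the parametric surface model of one membrane-embedded pentameric
#' channel in one of the four conformational classes used throughout the
#' package: `closed` (5-fold symmetric flower), `open1` (reduced lateral
#' extent, three elevated protrusions), `open2` (dome: one subunit displaced
#' onto the axis and raised), `openplus` (irregular asymmetric forms with
#' random per-subunit elevations).
#'
#' Each subunit is drawn as a smooth super-Gaussian cap
#' \eqn{h_k(d) = (H + o_k)\exp(-(d/w)^4)} centered on the subunit position;
#' the particle surface is the pointwise maximum over the five caps, sitting
#' on the membrane plane. The cap width `w` is tied to the outer diameter so
#' that the half-maximum footprint of a closed particle matches
#' `outer_diameter`. For the closed class the surface maximum above the
#' membrane is exactly `base_protrusion`.
#'
#' @param class_label one of `"closed"`, `"open1"`, `"open2"`, `"openplus"`.
#' @param outer_diameter particle outer diameter, nm (default 10.9).
#' @param ring_diameter top-ring (subunit circle) diameter, nm (default 5.0).
#' @param base_protrusion protrusion height above the membrane, nm (default 7).
#' @param apex_extra extra elevation of raised subunits for the open classes,
#'   nm (default 1.5; forced to 0 for `closed`).
#' @param offsets optional numeric(5) per-subunit elevation offsets (nm);
#'   defaults depend on the class (`openplus` draws random offsets, see
#'   [sample_openplus_offsets()]).
#' @param phase rotation of the subunit ring, degrees.
#' @param center_dip_depth depth of the axial pore dip carved into the
#'   subunit surface, nm. Defaults to 1.2 except for `open2`, where the
#'   displaced subunit occupies the axis and no pore is visible (0). The
#'   default is calibrated so the tip-convolved closed particle shows the
#'   ~1 nm max-min relief over its 5 x 5 nm center window that is the
#'   closed-state DeltaHeight signature.
#' @param dip_sigma lateral scale of the pore dip (super-Gaussian), nm.
#' @return object of class `particle_geometry`: list with the fields above
#'   plus `subunit_xy` (5 x 2 matrix of subunit positions, nm, relative to
#'   the particle center) and `subunit_width` (nm).
#' @export
particle_geometry <- function(class_label = c("closed", "open1", "open2", "openplus"),
                              outer_diameter = 10.9,
                              ring_diameter = 5.0,
                              base_protrusion = 7.0,
                              apex_extra = 1.5,
                              offsets = NULL,
                              phase = 90,
                              center_dip_depth = NULL,
                              dip_sigma = 1.4) {
  class_label <- match.arg(class_label)
  stop_if(ring_diameter >= outer_diameter, "ring_diameter must be < outer_diameter")
  stop_if(base_protrusion <= 0, "base_protrusion must be > 0")
  r_ring <- ring_diameter / 2
  # half-max footprint of a closed particle = outer_diameter
  w <- (outer_diameter / 2 - r_ring) / log(2)^0.25
  ang <- (phase + 72 * (0:4)) * pi / 180
  xy <- cbind(x = r_ring * cos(ang), y = r_ring * sin(ang))
  widths <- rep(w, 5)
  if (class_label == "closed") {
    apex_extra <- 0
    if (is.null(offsets)) offsets <- rep(0, 5)
    stop_if(length(unique(round(offsets, 12))) != 1,
            "closed geometry must have all subunit offsets equal")
  } else if (class_label == "open2") {
    # one subunit displaced onto the 5-fold axis and raised
    xy[1, ] <- c(0, 0)
    if (is.null(offsets)) offsets <- c(apex_extra, rep(0, 4))
  } else if (class_label == "open1") {
    # reduced lateral extent; three adjacent elevated subunits, two lowered
    r_red <- 0.8 * r_ring
    xy <- cbind(x = r_red * cos(ang), y = r_red * sin(ang))
    widths <- w * c(0.75, 0.75, 0.75, 0.6, 0.6)
    if (is.null(offsets)) offsets <- c(rep(apex_extra, 3), rep(-1.5, 2))
  } else { # openplus
    if (is.null(offsets)) offsets <- sample_openplus_offsets()
  }
  stop_if(length(offsets) != 5, "offsets must have length 5")
  if (is.null(center_dip_depth))
    center_dip_depth <- if (class_label == "open2") 0 else 1.2
  structure(list(class_label = class_label,
                 outer_diameter = outer_diameter,
                 ring_diameter = ring_diameter,
                 base_protrusion = base_protrusion,
                 apex_extra = apex_extra,
                 offsets = as.numeric(offsets),
                 subunit_xy = xy,
                 subunit_width = widths,
                 center_dip_depth = center_dip_depth,
                 dip_sigma = dip_sigma,
                 subunit_count = 5L),
            class = "particle_geometry")
}

#' Random per-subunit elevations for the open-+ class
#'
#' The open-+ class pools "asymmetric molecules of all kinds", operationalized
#' as independent per-subunit elevation offsets: subunits sag away from the
#' quaternary assembly (down to -2.5 nm) or rise moderately (up to +0.5 nm,
#' i.e. below the elevated-class apex), breaking the 5-fold symmetry without
#' necessarily increasing height.
#'
#' @param n number of subunits (5).
#' @param lo,hi uniform range of offsets, nm.
#' @return numeric(n) offsets in nm.
#' @export
sample_openplus_offsets <- function(n = 5, lo = -2.5, hi = 0.5) {
  stats::runif(n, lo, hi)
}

#' Imaging grid / scan configuration
#'
#' @param pixel_size sampling, nm per pixel (default 0.5).
#' @param frame_shape integer(2) image shape (rows, cols) in pixels.
#' @param frame_interval frame acquisition time, s (default 0.55).
#' @param vertical_noise_sd additive Gaussian vertical noise SD, nm.
#' @param drift_velocity numeric(2) lateral drift (vx, vy) in nm/s applied to
#'   particle centers (x = columns, y = rows).
#' @param tip_radius AFM tip apex radius, nm (default 2).
#' @return object of class `imaging_config`; `line_time` is
#'   `frame_interval / frame_shape[1]`.
#' @export
imaging_config <- function(pixel_size = 0.5,
                           frame_shape = c(128L, 128L),
                           frame_interval = 0.55,
                           vertical_noise_sd = 0.1,
                           drift_velocity = c(0.05, 0.03),
                           tip_radius = 2.0) {
  stop_if(pixel_size <= 0, "pixel_size must be > 0")
  stop_if(frame_interval <= 0, "frame_interval must be > 0")
  stop_if(vertical_noise_sd < 0, "vertical_noise_sd must be >= 0")
  stop_if(tip_radius < 0, "tip_radius must be >= 0")
  structure(list(pixel_size = pixel_size,
                 frame_shape = as.integer(frame_shape),
                 frame_interval = frame_interval,
                 line_time = frame_interval / frame_shape[1],
                 vertical_noise_sd = vertical_noise_sd,
                 drift_velocity = drift_velocity,
                 tip_radius = tip_radius),
            class = "imaging_config")
}

#' Membrane patch layout
#'
#' Places particle centers on a jittered triangular-ish lattice with the
#' observed ~14 nm center-to-center periodicity, inside a rectangular field.
#'
#' @param n_particles number of particles to place.
#' @param field_nm numeric(2) field size (width x, height y) in nm.
#' @param lattice_spacing center-to-center spacing, nm (default 14).
#' @param membrane_top_height membrane surface height above the support, nm
#'   (default 5).
#' @param jitter_nm uniform positional jitter per particle, nm.
#' @param margin_nm empty border kept around the patch, nm.
#' @return object of class `membrane_patch`: list(centers = n x 2 matrix of
#'   (x, y) nm, membrane_top_height, lattice_spacing, field_nm).
#' @export
membrane_patch <- function(n_particles = 20,
                           field_nm = c(64, 64),
                           lattice_spacing = 14,
                           membrane_top_height = 5,
                           jitter_nm = 0.5,
                           margin_nm = 11) {
  xs <- seq(margin_nm, field_nm[1] - margin_nm, by = lattice_spacing)
  ys <- seq(margin_nm, field_nm[2] - margin_nm, by = lattice_spacing)
  g <- expand.grid(x = xs, y = ys)
  # offset alternate rows for a denser, honeycomb-like packing
  odd <- (match(g$y, ys) %% 2) == 1
  g$x <- g$x + ifelse(odd, 0, lattice_spacing / 2)
  g <- g[g$x <= field_nm[1] - margin_nm, ]
  stop_if(nrow(g) < n_particles,
          "field too small for requested particle count at this spacing")
  g <- g[seq_len(n_particles), ]
  ctr <- as.matrix(g) + matrix(stats::runif(2 * n_particles, -jitter_nm, jitter_nm),
                               ncol = 2)
  structure(list(centers = ctr,
                 membrane_top_height = membrane_top_height,
                 lattice_spacing = lattice_spacing,
                 field_nm = field_nm),
            class = "membrane_patch")
}

#' Render the true (un-convolved) surface of a set of particles
#'
#' Draws each particle's five subunit caps on the membrane plane and combines
#' everything (membrane, all subunits, all particles) by pointwise maximum.
#' Heights are nm above the support; the membrane occupies the whole field.
#'
#' @param geometries a `particle_geometry` or list of them (one per particle).
#' @param centers n x 2 matrix of particle centers (x, y) in nm (a single
#'   center may be given as numeric(2)).
#' @param grid an [imaging_config()].
#' @param membrane_top_height membrane height above support, nm.
#' @param rows optional integer vector of 1-based image rows to render
#'   (default all rows); used for line-by-line scan composition.
#' @param base optional existing image to draw onto (matching `rows` subset).
#' @return matrix `frame_shape` (or `length(rows)` x cols) of heights in nm.
#' @export
render_height_map <- function(geometries, centers, grid,
                              membrane_top_height = 5,
                              rows = NULL, base = NULL) {
  if (inherits(geometries, "particle_geometry")) geometries <- list(geometries)
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  stop_if(length(geometries) != nrow(centers),
          "need one geometry per particle center")
  nr <- grid$frame_shape[1]; nc <- grid$frame_shape[2]
  if (is.null(rows)) rows <- seq_len(nr)
  px <- grid$pixel_size
  ys <- (rows - 1) * px           # nm, row direction
  xs <- (0:(nc - 1)) * px         # nm, col direction
  if (is.null(base)) base <- matrix(membrane_top_height, length(rows), nc)
  img <- base
  for (i in seq_along(geometries)) {
    gm <- geometries[[i]]
    cx <- centers[i, 1]; cy <- centers[i, 2]
    ext <- gm$outer_diameter  # render window half-width, nm
    ri <- which(ys >= cy - ext & ys <= cy + ext)
    ci <- which(xs >= cx - ext & xs <= cx + ext)
    if (!length(ri) || !length(ci)) next
    dx <- outer(rep(1, length(ri)), xs[ci] - cx)
    dy <- outer(ys[ri] - cy, rep(1, length(ci)))
    part <- matrix(0, length(ri), length(ci))
    for (k in 1:5) {
      d2 <- (dx - gm$subunit_xy[k, 1])^2 + (dy - gm$subunit_xy[k, 2])^2
      hk <- (gm$base_protrusion + gm$offsets[k]) *
        exp(-(d2 / gm$subunit_width[k]^2)^2)
      part <- pmax(part, hk)
    }
    if (gm$center_dip_depth > 0) {
      r2 <- dx^2 + dy^2
      part <- part - gm$center_dip_depth * exp(-(r2 / gm$dip_sigma^2)^2)
    }
    img[ri, ci] <- pmax(img[ri, ci], membrane_top_height + pmax(part, 0))
  }
  img
}

#' Spherical-cap tip kernel
#'
#' Height deficit profile of a spherical tip apex of radius `tip_radius`:
#' `c(d) = R - sqrt(R^2 - d^2)` for lateral distance `d <= R`. Pixels beyond
#' the cap support are excluded from the dilation.
#'
#' @param tip_radius nm; @param pixel_size nm per px.
#' @return matrix of deficits (nm) with `NA` outside the support; odd size,
#'   apex at the center.
#' @export
tip_kernel <- function(tip_radius, pixel_size) {
  if (tip_radius <= 0) return(matrix(0, 1, 1))
  half <- floor(tip_radius / pixel_size)
  d <- (-half:half) * pixel_size
  dd <- sqrt(outer(d^2, d^2, "+"))
  k <- tip_radius - sqrt(pmax(tip_radius^2 - dd^2, 0))
  k[dd > tip_radius] <- NA
  k
}

#' Tip convolution (grayscale dilation with a spherical-cap tip)
#'
#' Models AFM image formation: the imaged height at each pixel is the highest
#' position at which the tip apex can sit without the tip cap intersecting the
#' surface, i.e. a grayscale dilation
#' `out(x) = max_u [ surface(x + u) - c(u) ]` over the cap support.
#' The output is everywhere >= the input and equals it where the apex touches
#' the true surface; `tip_radius = 0` is the identity.
#'
#' @param surface height image, nm.
#' @param tip_radius tip apex radius, nm.
#' @param pixel_size nm per pixel.
#' @return imaged topograph, nm (same shape).
#' @export
tip_dilate <- function(surface, tip_radius, pixel_size) {
  stop_if(tip_radius < 0, "tip_radius must be >= 0")
  if (tip_radius == 0) return(surface)
  k <- tip_kernel(tip_radius, pixel_size)
  half <- (nrow(k) - 1L) / 2L
  nr <- nrow(surface); nc <- ncol(surface)
  # pad with -Inf so borders only see real surface
  pad <- matrix(-Inf, nr + 2 * half, nc + 2 * half)
  pad[(half + 1):(half + nr), (half + 1):(half + nc)] <- surface
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (is.na(k[i, j])) next
      out <- pmax(out, pad[(i):(i + nr - 1), (j):(j + nc - 1)] - k[i, j])
    }
  }
  out
}
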