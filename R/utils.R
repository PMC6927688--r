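# Shared image utilities. Convention used throughout the package:
# images are numeric matrices of heights in nm above the support plane,
# indexed [row, col], 0-based pixel coordinates with origin at the top-left
# pixel *center*; physical position (nm) = pixel index * pixel_size.

#' Bilinear sampling of an image at fractional pixel coordinates
#'
#' Samples a height image at arbitrary (row, col) positions with bilinear
#' interpolation. Positions outside the image return `fill`.
#'
#' @param img numeric matrix (nm heights).
#' @param row,col numeric vectors of 0-based fractional pixel coordinates.
#' @param fill value for out-of-bounds samples (default `NA`).
#' @return numeric vector of sampled heights.
#' @keywords internal
bilinear_sample <- function(img, row, col, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 0 & c0 >= 0 & r0 <= nr - 1 & c0 <= nc - 1 &
    (r0 + ifelse(fr > 0, 1, 0)) <= nr - 1 & (c0 + ifelse(fc > 0, 1, 0)) <= nc - 1
  out <- rep(fill, length(row))
  if (!any(ok)) return(out)
  r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
  r1k <- pmin(r0k + 1, nr - 1); c1k <- pmin(c0k + 1, nc - 1)
  i00 <- img[cbind(r0k + 1, c0k + 1)]
  i01 <- img[cbind(r0k + 1, c1k + 1)]
  i10 <- img[cbind(r1k + 1, c0k + 1)]
  i11 <- img[cbind(r1k + 1, c1k + 1)]
  out[ok] <- i00 * (1 - frk) * (1 - fck) + i01 * (1 - frk) * fck +
    i10 * frk * (1 - fck) + i11 * frk * fck
  out
}

#' Rotate an image about an arbitrary subpixel center
#'
#' @param img numeric matrix.
#' @param angle rotation angle in degrees (counter-clockwise in row/col space).
#' @param center length-2 numeric, 0-based (row, col) center of rotation.
#' @param fill out-of-bounds fill value.
#' @return rotated matrix, same shape.
#' @keywords internal
rotate_about <- function(img, angle, center, fill = NA_real_) {
  th <- angle * pi / 180
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
  dr <- g$row - center[1]; dc <- g$col - center[2]
  # inverse map: sample the source at the back-rotated position
  sr <- center[1] + cos(th) * dr + sin(th) * dc
  sc <- center[2] - sin(th) * dr + cos(th) * dc
  matrix(bilinear_sample(img, sr, sc, fill = fill), nr, nc)
}

#' Shift an image by a subpixel offset (bilinear)
#' @param img matrix; @param dr,dc shift in pixels applied to content
#'   (positive = content moves down/right); @param fill fill value.
#' @keywords internal
shift_image <- function(img, dr, dc, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  g <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
  matrix(bilinear_sample(img, g$row - dr, g$col - dc, fill = fill), nr, nc)
}

#' Separable Gaussian smoothing
#' @param img matrix; @param sigma SD in pixels (0 returns input).
#' @keywords internal
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(t(tmp), 2, pad_conv))
}

# iterated center-of-mass refinement within a disk of radius `rad_px`,
# weighting pixels above `floor_h`; returns 0-based (row, col)
refine_center <- function(img, r, c0, rad_px, floor_h, n_iter = 4) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(rad_px)
  for (it in seq_len(n_iter)) {
    ri <- max(1, round(r) + 1 - half):min(nr, round(r) + 1 + half)
    ci <- max(1, round(c0) + 1 - half):min(nc, round(c0) + 1 + half)
    rr <- outer(ri - 1, rep(1, length(ci)))
    cc <- outer(rep(1, length(ri)), ci - 1)
    w <- pmax(img[ri, ci] - floor_h, 0)
    w[(rr - r)^2 + (cc - c0)^2 > rad_px^2] <- 0
    sw <- sum(w)
    if (sw == 0) break
    r <- sum(rr * w) / sw
    c0 <- sum(cc * w) / sw
  }
  c(r, c0)
}

# internal argument checks
stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
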