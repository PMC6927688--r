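test_that("plane flattening removes a known plane and is idempotent", {
  set.seed(31)
  nr <- 60; nc <- 60
  cc <- matrix(rep(0:(nc - 1), each = nr), nr)
  rr <- matrix(rep(0:(nr - 1), nc), nr)
  field <- matrix(0, nr, nc)
  field[20:30, 25:35] <- 6  # a particle-like plateau
  plane <- 1.5 + 0.02 * cc - 0.013 * rr
  flat <- plane_flatten(field + plane, mask = field > 0)
  # recovers the particle field exactly (up to the fitted intercept)
  expect_equal(flat - min(flat), field, tolerance = 1e-8)
  # residual tilt of the output over the fitted (unmasked) pixels is zero
  keep <- !(field > 0)
  refit <- stats::lm.fit(cbind(1, cc[keep], rr[keep]), flat[keep])
  expect_lt(max(abs(refit$coefficients[2:3])), 1e-12)
  # idempotence with the automatic Otsu mask
  f1 <- plane_flatten(field + plane)
  expect_equal(plane_flatten(f1), f1, tolerance = 1e-8)
  # pure plane maps to zeros
  expect_equal(plane_flatten(plane, auto_mask = FALSE),
               matrix(0, nr, nc), tolerance = 1e-8)
  expect_error(plane_flatten(field, mask = matrix(TRUE, nr, nc)), "masked")
})

test_that("drift correction recovers synthetic drift within 0.25 px", {
  grid <- quiet_grid(c(96L, 96L), noise = 0, drift = c(0.2 / 0.55, 0.12 / 0.55))
  set.seed(32)
  patch <- membrane_patch(4, field_nm = c(48, 48), jitter_nm = 0.3)
  paths <- replicate(4, {
    p <- data.frame(t_start = 0, t_end = 1e6, class = "closed")
    p$offsets <- list(NULL); p
  }, simplify = FALSE)
  nf <- 12
  sim <- simulate_movie(paths, patch, grid, nf)
  dc <- drift_correct(sim$movie)
  # true drift in px per frame: (vy, vx) * dt / px
  true_pf <- c(0.12, 0.2) / 0.55 * grid$frame_interval / grid$pixel_size
  true_shift <- outer(0:(nf - 1), true_pf)
  expect_lt(max(abs(dc$shifts - true_shift)), 0.25)
  # recovered velocity within 10%
  v_est <- (dc$shifts[nf, ] - dc$shifts[1, ]) / (nf - 1)
  expect_equal(unname(v_est), true_pf, tolerance = 0.1)
  # zero-drift movie gives zero shifts
  grid0 <- quiet_grid(c(96L, 96L))
  sim0 <- simulate_movie(paths, patch, grid0, 3)
  dc0 <- drift_correct(sim0$movie)
  expect_lt(max(abs(dc0$shifts)), 0.05)
  expect_error(drift_correct(sim0$movie[1]), "2 frames")
})

test_that("particle detection finds every particle within 1 px, no noise", {
  set.seed(33)
  grid <- quiet_grid(c(184L, 184L))
  patch <- membrane_patch(20, field_nm = c(92, 92))
  paths <- replicate(20, {
    p <- data.frame(t_start = 0, t_end = 1e6, class = "closed")
    p$offsets <- list(NULL); p
  }, simplify = FALSE)
  sim <- simulate_movie(paths, patch, grid, 1)
  det <- detect_particles(sim$movie$frames[, , 1], 0.5, min_height = 3,
                          min_separation = 0.8 * 10.9)
  expect_equal(nrow(det), 20)
  true_px <- patch$centers[, c(2, 1)] / 0.5
  err <- apply(det, 1, function(p)
    min(sqrt((true_px[, 1] - p[1])^2 + (true_px[, 2] - p[2])^2)))
  expect_lt(max(err), 1)
  # flat frame: nothing detected
  expect_equal(nrow(detect_particles(matrix(5, 64, 64))), 0)
})

test_that("non-maximum suppression merges close detections", {
  grid <- quiet_grid(c(60L, 60L))
  # two particles 5 nm apart with 8 nm suppression: one detection
  g <- particle_geometry("closed")
  s <- render_height_map(list(g, g), rbind(c(12, 15), c(17, 15)), grid)
  det <- detect_particles(s, 0.5, min_height = 3, min_separation = 8)
  expect_equal(nrow(det), 1)
})

test_that("greedy tracking keeps identities and handles disappearance", {
  # static particles: one full-length track each
  det_static <- replicate(6, data.frame(row = c(10, 40), col = c(10, 40)),
                          simplify = FALSE)
  tr <- track_particles(det_static, pixel_size = 0.5, max_link_distance = 5)
  expect_equal(length(unique(tr$molecule_id)), 2)
  expect_true(all(table(tr$molecule_id) == 6))
  # disappearance mid-movie: track ends without spurious links
  det_gap <- c(replicate(3, data.frame(row = c(10, 40), col = c(10, 40)),
                         simplify = FALSE),
               replicate(3, data.frame(row = 40, col = 40),
                         simplify = FALSE))
  tr2 <- track_particles(det_gap, 0.5, max_link_distance = 5, max_gap = 1)
  lens <- table(tr2$molecule_id)
  expect_equal(sort(as.integer(lens)), c(3, 6))
  # particles jumping farther than max_link_distance per frame are not
  # linked (each new position starts a new track instead of swapping ids)
  det_cross <- list(data.frame(row = c(10, 40), col = c(10, 40)),
                    data.frame(row = c(26, 24), col = c(26, 24)))
  tr3 <- track_particles(det_cross, 0.5, max_link_distance = 5)
  expect_equal(length(unique(tr3$molecule_id)), 4)
})

test_that("nfold average is a projection onto n-fold symmetry", {
  img <- render_one("closed", tip = 0)
  ctr <- c(24, 24)
  avg1 <- nfold_average(img, 5, ctr)
  # symmetric input is unchanged inside the common support up to the
  # bilinear interpolation error at the steep pedestal edge
  ok <- !is.na(avg1)
  expect_lt(max(abs(avg1[ok] - img[ok])), 0.3)
  # applying twice equals applying once (projection, interpolation tolerance)
  avg2 <- nfold_average(avg1, 5, ctr)
  ok2 <- !is.na(avg2)
  expect_lt(max(abs(avg2[ok2] - avg1[ok2])), 0.15)
  # n = 1 is the identity; bad center errors
  expect_identical(nfold_average(img, 1, ctr), img)
  expect_error(nfold_average(img, 5, c(-3, 2)), "center")
  # asymmetric render becomes 5-fold symmetric: correlation of the output
  # with its own 72-degree rotation
  img_a <- render_one("open2", tip = 0)
  avg_a <- nfold_average(img_a, 5, ctr)
  rot <- afmgating:::rotate_about(avg_a, 72, ctr)
  ok3 <- !is.na(avg_a) & !is.na(rot)
  expect_gt(stats::cor(avg_a[ok3], rot[ok3]), 0.999)
})

test_that("cross sections read out step height and lattice periodicity", {
  # membrane edge: support at 0, membrane+protein at 12
  frame <- matrix(0, 60, 60)
  frame[, 31:60] <- 12
  cs <- cross_section(frame, c(30, 5), c(30, 55), pixel_size = 0.5)
  expect_equal(cs$peak_to_peak, 12)
  # synthetic row of particles at exact 14-nm spacing
  grid <- quiet_grid(c(80L, 160L))
  centers <- cbind(x = seq(12, 68, by = 14), y = 20)
  geoms <- replicate(nrow(centers), particle_geometry("closed"),
                     simplify = FALSE)
  s <- render_height_map(geoms, centers, grid)
  cs2 <- cross_section(s, c(40, 4), c(40, 156), pixel_size = 0.5)
  expect_equal(cs2$periodicity_nm, 14, tolerance = 0.5 / 14)
  # constant frame: flat profile, periodicity undefined
  cs3 <- cross_section(matrix(5, 40, 40), c(10, 2), c(10, 38))
  expect_true(is.na(cs3$periodicity_nm))
  expect_equal(cs3$peak_to_peak, 0)
  expect_error(cross_section(frame, c(10, 10), c(10, 10)), "degenerate")
})

test_that("height histograms separate support and protein surfaces", {
  set.seed(35)
  # half support (0 nm), half protein surface (12 nm), mild roughness
  img <- cbind(matrix(rnorm(60 * 30, 0, 0.3), 60),
               matrix(rnorm(60 * 30, 12, 0.3), 60))
  hh <- height_histogram(img, bin_width = 0.25)
  expect_equal(length(hh$modes_nm), 2)
  expect_equal(max(hh$mode_separations_nm), 12, tolerance = 0.4 / 12)
  # stacked double membrane: modes at ~12 and ~17 nm
  img2 <- cbind(matrix(rnorm(60 * 20, 0, 0.3), 60),
                matrix(rnorm(60 * 20, 12, 0.3), 60),
                matrix(rnorm(60 * 20, 17, 0.3), 60))
  hh2 <- height_histogram(img2, bin_width = 0.25)
  expect_equal(sort(round(hh2$modes_nm))[2:3], c(12, 17), tolerance = 0.05)
  # constant image: single mode
  hh3 <- height_histogram(matrix(5, 40, 40))
  expect_equal(length(hh3$modes_nm), 1)
})
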