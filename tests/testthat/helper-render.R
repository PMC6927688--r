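# Shared fixtures: small noiseless renders and tiny movies, built in code.

quiet_grid <- function(shape = c(48L, 48L), noise = 0, drift = c(0, 0),
                       frame_interval = 0.55) {
  imaging_config(frame_shape = as.integer(shape), vertical_noise_sd = noise,
                 drift_velocity = drift, frame_interval = frame_interval)
}

# tip-convolved single-particle render centered at (12, 12) nm on a 24x24 nm
# field; returns the image (48 x 48 px at 0.5 nm/px)
render_one <- function(class_label, grid = quiet_grid(), tip = 2, ...) {
  gm <- particle_geometry(class_label, ...)
  s <- render_height_map(gm, c(12, 12), grid)
  tip_dilate(s, tip, grid$pixel_size)
}

# 5x5 nm center window (10x10 px) around the pixel center (24, 24)
center_window <- function(img, half_px = 5, ctr = 24) {
  idx <- (ctr - half_px + 1):(ctr + half_px)
  img[idx, idx]
}

# features of a render at its true center, with a 33-px patch
features_of <- function(img, ctr = c(24, 24), half = 16, ...) {
  ri <- (ctr[1] - half):(ctr[1] + half)
  ci <- (ctr[2] - half):(ctr[2] + half)
  extract_features(img[ri + 1, ci + 1], c(ctr[1] - ri[1], ctr[2] - ci[1]), ...)
}

# two-state discrete path (frame labels 1/2) from exponential dwell rates,
# sampled at dt; used by dynamics recovery tests
sample_two_state <- function(rate_low, rate_high, n_frames, dt) {
  t_tot <- n_frames * dt
  t <- 0; state <- 1L
  times <- numeric(0); states <- integer(0)
  while (t < t_tot) {
    times <- c(times, t); states <- c(states, state)
    t <- t + stats::rexp(1, if (state == 1L) rate_low else rate_high)
    state <- 3L - state
  }
  tf <- (seq_len(n_frames) - 1) * dt
  states[findInterval(tf, times)]
}
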