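# exhaustive-enumeration oracle: best RSS over all segmentations of x with
# exactly m change points (piecewise-constant fit by segment means)
best_rss_oracle <- function(x, m) {
  n <- length(x)
  seg_rss <- function(i, j) {
    v <- x[i:j]
    sum((v - mean(v))^2)
  }
  best <- Inf
  cps <- utils::combn(seq_len(n - 1), m)
  for (k in seq_len(ncol(cps))) {
    b <- c(0, cps[, k], n)
    rss <- sum(vapply(seq_len(length(b) - 1),
                      function(i) seg_rss(b[i] + 1, b[i + 1]), 0))
    best <- min(best, rss)
  }
  best
}

fit_rss <- function(x, fit) {
  segs <- fit$segments
  sum(vapply(seq_len(nrow(segs)), function(i) {
    v <- x[segs$start[i]:segs$end[i]]
    sum((v - mean(v))^2)
  }, 0))
}

test_that("noise estimator is robust to steps", {
  set.seed(41)
  # pure Gaussian noise
  sig <- replicate(30, estimate_noise(rnorm(1000, sd = 0.2)))
  expect_equal(mean(sig), 0.2, tolerance = 0.1)
  # square wave + noise: tracks the noise, not the 1.5 nm step size
  sq <- rep(c(0, 1.5), each = 50, times = 10) + rnorm(1000, sd = 0.2)
  expect_equal(estimate_noise(sq), 0.2, tolerance = 0.15)
  # constant trace
  expect_equal(estimate_noise(rep(1, 10)), 0)
  expect_error(estimate_noise(c(1, 2)), "short")
})

test_that("step detection is exact on clean steps and silent on constants", {
  x <- c(rep(0, 50), rep(1.5, 50))
  fit <- detect_steps(x, noise_sd = 0.01)
  expect_identical(fit$change_points, 50L)
  expect_equal(fit$segments$mean, c(0, 1.5))
  expect_identical(detect_steps(rep(2, 30), noise_sd = 0.1)$change_points,
                   integer(0))
})

test_that("segmentation RSS matches the exhaustive oracle on short traces", {
  set.seed(42)
  for (rep_i in 1:8) {
    n <- sample(8:12, 1)
    x <- c(rnorm(ceiling(n / 2), 0, 0.2), rnorm(floor(n / 2), 1.5, 0.2))
    fit <- detect_steps(x, t_critical = 3, min_segment = 2)
    m <- length(fit$change_points)
    if (m == 0) next
    expect_equal(fit_rss(x, fit), best_rss_oracle(x, m),
                 tolerance = 1e-8 + 0.05 * abs(best_rss_oracle(x, m)))
  }
})

test_that("state grouping matches the exhaustive 2-partition oracle", {
  # hand-built step fit with means {0.9, 1.0, 2.4, 2.5}, equal durations
  x <- rep(c(0.9, 1.0, 2.4, 2.5), each = 10)
  fit <- detect_steps(x, noise_sd = 0.01)
  expect_equal(nrow(fit$segments), 4)
  g2 <- group_states(fit, 2)
  expect_equal(g2$levels, c(0.95, 2.45), tolerance = 1e-10)
  expect_equal(g2$segment_state, c(1, 1, 2, 2))
  # oracle: all 2-partitions of segments minimizing within-group SS
  segs <- fit$segments
  best <- Inf; best_assign <- NULL
  for (code in 1:(2^4 - 2)) {
    a <- as.integer(intToBits(code))[1:4] + 1L
    if (length(unique(a)) != 2) next
    ss <- 0
    for (s in 1:2) {
      idx <- a == s
      if (!any(idx)) next
      mu <- sum(segs$mean[idx] * segs$n[idx]) / sum(segs$n[idx])
      ss <- ss + sum(segs$n[idx] * (segs$mean[idx] - mu)^2)
    }
    if (ss < best) { best <- ss; best_assign <- a }
  }
  expect_true(all(g2$segment_state == best_assign) ||
                all(g2$segment_state == 3L - best_assign))
  # identity grouping and global-mean grouping
  expect_equal(group_states(fit, 4)$levels, sort(segs$mean))
  expect_equal(group_states(fit, 1)$levels,
               sum(segs$mean * segs$n) / sum(segs$n))
  expect_error(group_states(fit, 5), "out of range")
})

test_that("MDL selects two states for two-level traces and one for noise", {
  set.seed(43)
  ok2 <- 0; ok1 <- 0; n_rep <- 25
  for (i in seq_len(n_rep)) {
    lev <- rep(rep(c(1, 2.5), length.out = 10), each = 50)
    x2 <- lev + rnorm(500, sd = 0.2)
    if (idealize(x2)$chosen_k == 2) ok2 <- ok2 + 1
    x1 <- rnorm(500, sd = 0.2)
    if (idealize(x1)$chosen_k == 1) ok1 <- ok1 + 1
  }
  expect_gte(ok2, n_rep - 1)
  expect_gte(ok1, n_rep - 1)
})

test_that("description length prefers two states and RSS decreases in k", {
  set.seed(44)
  x <- rep(c(1, 2.5), each = 100) + rnorm(200, sd = 0.2)
  dls <- idealize(x, K_max = 5)$dl_curve
  expect_equal(which.min(dls$dl), 2)
  expect_true(all(diff(dls$rss) <= 1e-9))  # RSS non-increasing in k
})

test_that("idealization recovers simulated gating levels and supports force_k", {
  set.seed(45)
  lev <- rep(rep(c(1, 2.5), length.out = 12), each = 40)
  x <- lev + rnorm(480, sd = 0.2)
  fit <- idealize(x)
  expect_equal(fit$chosen_k, 2)
  expect_equal(fit$levels, c(1, 2.5), tolerance = 0.1 / 2.5)
  # force_k = 2 on a 3-level trace gives the best 2-level merge: the two
  # nearest levels (2.2, 2.5) merge, far level 0.5 stays
  lev3 <- rep(c(0.5, 2.2, 2.5, 0.5, 2.2), each = 60)
  x3 <- lev3 + rnorm(300, sd = 0.1)
  f3 <- idealize(x3, force_k = 2)
  expect_equal(f3$chosen_k, 2)
  expect_equal(f3$levels[1], 0.5, tolerance = 0.1)
  expect_equal(f3$levels[2], mean(c(2.2, 2.5, 2.2)), tolerance = 0.12)
  # monotone ramp with K_max = 1
  expect_equal(idealize(seq(0, 1, length.out = 50), K_max = 1)$chosen_k, 1)
})

test_that("idealization is scale- and offset-equivariant", {
  set.seed(46)
  x <- rep(c(1, 2.5), each = 100) + rnorm(200, sd = 0.2)
  f1 <- idealize(x)
  f2 <- idealize(2.5 * x + 3)
  expect_identical(f2$change_points, f1$change_points)
  expect_equal(f2$levels, 2.5 * f1$levels + 3, tolerance = 1e-8)
  expect_identical(f2$labels, f1$labels)
})

test_that("false-step rate on pure noise is below one step per trace", {
  set.seed(47)
  n_steps <- vapply(1:40, function(i)
    length(detect_steps(rnorm(1000, sd = 0.2), t_critical = 5)$change_points),
    0L)
  expect_lt(mean(n_steps), 1)
})

test_that("idealization writes CSV + JSON summaries", {
  set.seed(48)
  x <- rep(c(1, 2.5), each = 50) + rnorm(100, sd = 0.2)
  fit <- idealize(x)
  pref <- file.path(withr::local_tempdir(), "ideal")
  write_idealization(fit, pref)
  df <- utils::read.csv(paste0(pref, ".csv"))
  expect_equal(nrow(df), 100)
  js <- jsonlite::read_json(paste0(pref, ".json"), simplifyVector = TRUE)
  expect_equal(js$chosen_k, 2)
})
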