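#' Robust noise estimate of a time trace
#'
#' `sigma = median(|x[i+1] - x[i]|) / (0.6745 * sqrt(2))` — the median
#' absolute successive difference scaled to the Gaussian SD. Insensitive to a
#' small number of steps because steps contribute only one difference each.
#'
#' @param x numeric trace (length >= 4).
#' @return estimated noise SD (same units as `x`).
#' @export
estimate_noise <- function(x) {
  stop_if(length(x) < 4, "trace too short for noise estimation")
  stats::median(abs(diff(x))) / (0.6745 * sqrt(2))
}

#' Step detection by recursive t-statistic segmentation
#'
#' Recursive binary segmentation: within each segment the split point c
#' maximizing the two-sample statistic
#' `t(c) = |mean_L - mean_R| / (sigma * sqrt(1/n_L + 1/n_R))`
#' is accepted while `t > t_critical` and both children have at least
#' `min_segment` points. Deterministic for fixed inputs.
#'
#' @param x numeric trace.
#' @param noise_sd noise SD (default [estimate_noise()]).
#' @param t_critical acceptance threshold (default 5).
#' @param min_segment minimum child segment length (default 2).
#' @return list (class `step_fit`): `change_points` (indices i such that a
#'   step occurs between x[i] and x[i+1]), `segments` (data.frame start, end,
#'   mean, n), `noise_sd`.
#' @export
detect_steps <- function(x, noise_sd = NULL, t_critical = 5, min_segment = 2) {
  stop_if(length(x) < 2 * min_segment, "trace shorter than 2*min_segment")
  if (is.null(noise_sd)) noise_sd <- estimate_noise(x)
  cps <- integer(0)
  split_rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_segment) return()
    seg <- x[lo:hi]
    cs <- cumsum(seg)
    tot <- cs[n]
    cand <- min_segment:(n - min_segment)
    nl <- cand; nr <- n - cand
    ml <- cs[cand] / nl; mr <- (tot - cs[cand]) / nr
    sd_use <- if (noise_sd > 0) noise_sd else .Machine$double.eps
    tstat <- abs(ml - mr) / (sd_use * sqrt(1 / nl + 1 / nr))
    best <- which.max(tstat)
    if (tstat[best] > t_critical) {
      c_abs <- as.integer(lo + cand[best] - 1)
      cps <<- c(cps, c_abs)
      split_rec(lo, c_abs)
      split_rec(c_abs + 1, hi)
    }
  }
  split_rec(1, length(x))
  cps <- sort(as.integer(cps))
  bounds <- c(0, cps, length(x))
  segs <- data.frame(start = bounds[-length(bounds)] + 1, end = bounds[-1])
  segs$n <- segs$end - segs$start + 1
  segs$mean <- vapply(seq_len(nrow(segs)),
                      function(i) mean(x[segs$start[i]:segs$end[i]]), 0)
  structure(list(change_points = cps, segments = segs, noise_sd = noise_sd),
            class = "step_fit")
}

#' Agglomerative grouping of segment means into k states
#'
#' Repeatedly merges the pair of levels with the closest means, replacing
#' them by their duration-weighted centroid, until `k` levels remain.
#'
#' @param fit a `step_fit` from [detect_steps()].
#' @param k target number of states (1..number of segments).
#' @return list: `levels` (duration-weighted state means, sorted increasing),
#'   `segment_state` (state index per segment, 1..k).
#' @export
group_states <- function(fit, k) {
  segs <- fit$segments
  n_seg <- nrow(segs)
  stop_if(k < 1 || k > n_seg, "k out of range")
  means <- segs$mean; wts <- as.numeric(segs$n)
  group <- as.list(seq_len(n_seg))
  while (length(means) > k) {
    o <- order(means)
    dm <- diff(means[o])
    j <- which.min(dm)
    a <- o[j]; b <- o[j + 1]
    new_mean <- (means[a] * wts[a] + means[b] * wts[b]) / (wts[a] + wts[b])
    means[a] <- new_mean; wts[a] <- wts[a] + wts[b]
    group[[a]] <- c(group[[a]], group[[b]])
    means <- means[-b]; wts <- wts[-b]; group <- group[-b]
  }
  ord <- order(means)
  seg_state <- integer(n_seg)
  for (s in seq_along(ord)) seg_state[group[[ord[s]]]] <- s
  list(levels = means[ord], segment_state = seg_state)
}

#' Minimum description length of a k-state fit
#'
#' `DL(k) = (N/2) log(RSS_k / N) + ((m + level_cost * k)/2) log N` where N is
#' the trace length, m the number of retained change points and RSS_k the
#' residual sum of squares of the trace about its assigned state levels — a
#' BIC-style code length: goodness of fit plus a parameter cost for each
#' change point and each level. The per-level cost is weighted by
#' `level_cost` (default 2, i.e. `log N` per level): with the plain 1/2
#' weight the criterion is near-indifferent between a true level and the
#' same level split into two clusters a fraction of the noise SD apart, and
#' model-order recovery on two-level traces becomes seed-dependent.
#'
#' @param x numeric trace.
#' @param fit `step_fit`; @param grouping result of [group_states()].
#' @param level_cost weight of the per-level parameter cost.
#' @return list(dl, rss, k, m).
#' @export
description_length <- function(x, fit, grouping, level_cost = 2) {
  n <- length(x)
  levels_per_point <- state_labels_per_point(fit, grouping)
  rss <- sum((x - grouping$levels[levels_per_point])^2)
  rss_floor <- max(rss, .Machine$double.eps)
  m <- length(fit$change_points)
  k <- length(grouping$levels)
  list(dl = (n / 2) * log(rss_floor / n) + ((m + level_cost * k) / 2) * log(n),
       rss = rss, k = k, m = m, rss_floored = rss < .Machine$double.eps)
}

state_labels_per_point <- function(fit, grouping) {
  segs <- fit$segments
  rep(grouping$segment_state, segs$n)
}

#' Idealize a DeltaHeight/time trace into discrete states
#'
#' Full pipeline: noise estimation, recursive t-test step detection,
#' agglomerative grouping to k = 1..K_max levels, and minimum-description-
#' length selection of the state count. `force_k` overrides the MDL choice
#' (the standard analysis mode forces two DeltaHeight states: low =
#' symmetric/closed-like, high = any conformation with elevated subunits).
#'
#' @param x numeric trace (length >= 10), or a `height_trace` data.frame.
#' @param K_max largest state count considered (default 5).
#' @param force_k optional forced state count.
#' @param t_critical,min_segment passed to [detect_steps()].
#' @return object of class `stasi_fit`: list with `levels`, `labels`
#'   (per-point state index, 1 = lowest level), `idealized` (per-point level,
#'   nm), `chosen_k`, `dl_curve` (data.frame k, dl, rss), `change_points`,
#'   `noise_sd`, `x`, `times`.
#' @export
idealize <- function(x, K_max = 5, force_k = NULL, t_critical = 5,
                     min_segment = 2) {
  times <- NULL
  if (is.data.frame(x)) {
    times <- x$time_s
    x <- x$delta_height_nm
  }
  stop_if(length(x) < 10, "trace too short to idealize")
  noise_sd <- estimate_noise(x)
  fit <- detect_steps(x, noise_sd, t_critical, min_segment)
  kmax_eff <- min(K_max, nrow(fit$segments))
  dl <- data.frame(k = seq_len(kmax_eff), dl = NA_real_, rss = NA_real_)
  groupings <- vector("list", kmax_eff)
  for (k in seq_len(kmax_eff)) {
    groupings[[k]] <- group_states(fit, k)
    d <- description_length(x, fit, groupings[[k]])
    dl$dl[k] <- d$dl; dl$rss[k] <- d$rss
  }
  chosen_k <- if (!is.null(force_k)) min(force_k, kmax_eff)
  else dl$k[which.min(dl$dl)]
  g <- groupings[[chosen_k]]
  labels <- state_labels_per_point(fit, g)
  structure(list(levels = g$levels, labels = labels,
                 idealized = g$levels[labels],
                 chosen_k = chosen_k, dl_curve = dl,
                 change_points = fit$change_points,
                 noise_sd = noise_sd, x = x, times = times),
            class = "stasi_fit")
}

#' @export
print.stasi_fit <- function(x, ...) {
  cat(sprintf("State idealization: %d points, k = %d state(s), noise sd = %.3g nm\n",
              length(x$x), x$chosen_k, x$noise_sd))
  cat("  levels (nm):", paste(sprintf("%.3g", x$levels), collapse = ", "), "\n")
  cat(sprintf("  %d change point(s)\n", length(x$change_points)))
  invisible(x)
}

#' @export
plot.stasi_fit <- function(x, ...) {
  t <- if (!is.null(x$times)) x$times else seq_along(x$x)
  graphics::plot(t, x$x, type = "l", col = "grey50",
                 xlab = if (!is.null(x$times)) "time (s)" else "frame",
                 ylab = expression(Delta * "Height (nm)"), ...)
  graphics::lines(t, x$idealized, col = "red", lwd = 2)
  invisible(x)
}

#' Write an idealization to CSV (+ JSON model summary)
#' @param fit `stasi_fit`; @param prefix writes `<prefix>.csv`, `<prefix>.json`.
#' @export
write_idealization <- function(fit, prefix) {
  df <- data.frame(time_s = if (!is.null(fit$times)) fit$times else NA,
                   delta_height_nm = fit$x,
                   state_label = fit$labels,
                   state_level_nm = fit$idealized)
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(chosen_k = fit$chosen_k, levels_nm = fit$levels,
                            noise_sd_nm = fit$noise_sd,
                            n_change_points = length(fit$change_points),
                            dl_curve = fit$dl_curve),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
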