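#' Dwell times of a two-state idealization
#'
#' Maximal constant-label runs of the idealized trace. The first and last
#' dwell of each molecule are right/left-censored (entry or exit was not
#' observed) and flagged; durations sum to the trace span. One-frame dwells
#' are kept but flagged as blips (no missed-event correction is applied).
#'
#' @param fit a `stasi_fit` (2-state) or an integer label vector.
#' @param times per-point times, s (default taken from the fit; else frame
#'   index).
#' @param molecule_id id recorded in the output.
#' @return data.frame (molecule_id, state = "low"/"high", entry_time_s,
#'   duration_s, censored, blip).
#' @export
extract_dwells <- function(fit, times = NULL, molecule_id = 1L) {
  labels <- if (inherits(fit, "stasi_fit")) fit$labels else as.integer(fit)
  if (is.null(times))
    times <- if (inherits(fit, "stasi_fit") && !is.null(fit$times)) fit$times
  else seq_along(labels) - 1
  stop_if(length(unique(labels)) > 2, "dwell analysis expects a 2-state idealization")
  n <- length(labels)
  dt_end <- c(diff(times), if (n > 1) diff(times)[n - 1] else 1)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  entry <- times[starts]
  # a dwell lasts from entry of its first frame to entry of the next dwell
  # (last dwell extends one frame interval past its last point)
  exit <- c(entry[-1], times[n] + dt_end[n])
  data.frame(molecule_id = molecule_id,
             state = c("low", "high")[r$values],
             entry_time_s = entry,
             duration_s = exit - entry,
             censored = seq_along(r$values) %in% c(1, length(r$values)),
             blip = r$lengths == 1)
}

#' Transition events of a two-state idealization
#'
#' @param fit `stasi_fit` or label vector; @param times,molecule_id as in
#'   [extract_dwells()].
#' @return data.frame (molecule_id, time_s, direction = "up"/"down").
#' @export
transition_events <- function(fit, times = NULL, molecule_id = 1L) {
  labels <- if (inherits(fit, "stasi_fit")) fit$labels else as.integer(fit)
  if (is.null(times))
    times <- if (inherits(fit, "stasi_fit") && !is.null(fit$times)) fit$times
  else seq_along(labels) - 1
  d <- diff(labels)
  idx <- which(d != 0)
  data.frame(molecule_id = molecule_id,
             time_s = times[idx + 1],
             direction = ifelse(d[idx] > 0, "up", "down"))
}

#' Bin up/down transition events over time
#'
#' Half-open bins `[t0 + i*w, t0 + (i+1)*w)`; total counts are conserved
#' (events at or beyond `t1` fall in the last bin only if within range).
#'
#' @param events data.frame (time_s, direction) from [transition_events()].
#' @param t0,t1 analysis window, s.
#' @param bin_width s (default 30).
#' @return data.frame (t_mid, up, down).
#' @export
bin_transitions <- function(events, t0, t1, bin_width = 30) {
  stop_if(t0 >= t1, "t0 must be < t1")
  edges <- seq(t0, t1, by = bin_width)
  if (edges[length(edges)] < t1)
    edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1
  out <- data.frame(t_mid = edges[-length(edges)] + bin_width / 2,
                    up = 0L, down = 0L)
  keep <- events$time_s >= t0 & events$time_s < edges[length(edges)]
  ev <- events[keep, ]
  if (nrow(ev)) {
    b <- findInterval(ev$time_s, edges, rightmost.closed = FALSE)
    for (dir in c("up", "down")) {
      tb <- tabulate(b[ev$direction == dir], nb)
      out[[dir]] <- tb
    }
  }
  out
}

#' Sliding event-window average dwell time
#'
#' Mean dwell duration over a sliding window of `window_events` dwells
#' ordered by entry time, per state, plotted at the window's mean entry time.
#' Censored dwells are excluded. With fewer than `window_events` dwells a
#' single global mean is returned and flagged.
#'
#' @param dwells data.frame from [extract_dwells()] (possibly row-bound over
#'   molecules).
#' @param window_events window size (default 20).
#' @return data.frame (state, time_s, mean_dwell_s, flagged_global).
#' @export
sliding_dwell_average <- function(dwells, window_events = 20) {
  dw <- dwells[!dwells$censored, ]
  out <- list()
  for (st in unique(dw$state)) {
    d <- dw[dw$state == st, ]
    d <- d[order(d$entry_time_s), ]
    n <- nrow(d)
    if (n == 0) next
    if (n < window_events) {
      out[[st]] <- data.frame(state = st, time_s = mean(d$entry_time_s),
                              mean_dwell_s = mean(d$duration_s),
                              flagged_global = TRUE)
      next
    }
    cs_d <- cumsum(d$duration_s); cs_t <- cumsum(d$entry_time_s)
    i <- window_events:n
    means <- (cs_d[i] - c(0, cs_d)[i - window_events + 1]) / window_events
    tmid <- (cs_t[i] - c(0, cs_t)[i - window_events + 1]) / window_events
    out[[st]] <- data.frame(state = st, time_s = tmid, mean_dwell_s = means,
                            flagged_global = FALSE)
  }
  do.call(rbind, out)
}

#' Percentage of molecules in the high state over time
#'
#' @param fits list of `stasi_fit` (one per molecule; 2-state) or a list of
#'   label vectors.
#' @param frames optional frame indices to evaluate (default all frames of
#'   the first fit).
#' @return data.frame (frame, n_tracked, n_high, percent_high).
#' @export
fraction_open_vs_time <- function(fits, frames = NULL) {
  stop_if(length(fits) < 1, "need at least one molecule")
  lab <- lapply(fits, function(f)
    if (inherits(f, "stasi_fit")) f$labels else as.integer(f))
  if (is.null(frames)) frames <- seq_along(lab[[1]])
  n_high <- n_tr <- integer(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    vals <- vapply(lab, function(l) if (f <= length(l)) l[f] else NA_integer_,
                   integer(1))
    n_tr[i] <- sum(!is.na(vals))
    n_high[i] <- sum(vals == 2, na.rm = TRUE)
  }
  data.frame(frame = frames, n_tracked = n_tr, n_high = n_high,
             percent_high = 100 * n_high / pmax(n_tr, 1))
}

#' Equilibrium free-energy difference from mean dwell times
#'
#' `dG = -ln(tau_low / tau_high)` in units of kBT: negative values favor the
#' low (ligand-bound, closed-like) state. Antisymmetric under swapping the
#' arguments.
#'
#' @param mean_dwell_low,mean_dwell_high mean dwell times, s (> 0).
#' @return energy difference in kBT.
#' @export
energy_difference <- function(mean_dwell_low, mean_dwell_high) {
  stop_if(mean_dwell_low <= 0 || mean_dwell_high <= 0,
          "dwell times must be > 0")
  -log(mean_dwell_low / mean_dwell_high)
}
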