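#' Gating class labels
#' @return character(4): closed, open1, open2, openplus.
#' @export
gating_classes <- function() c("closed", "open1", "open2", "openplus")

#' Mg2+-dependent four-state gating model
#'
#' Continuous-time Markov model over \{closed, open-I, open-II, open-+\}.
#' The channel leaves the closed state at rate `k_off` (Mg2+ unbinding from
#' the intracellular sensor sites) and any open class returns to closed at
#' rate `k_on * [Mg2+]_free`, so the stationary closed occupancy at constant
#' free concentration c is `c / (c + K_d)` with `K_d = k_off / k_on`.
#' `Q_open` exchanges the three open classes among themselves.
#'
#' @param K_d apparent dissociation constant, mM (default 2).
#' @param k_off closed -> open rate, 1/s.
#' @param k_on open -> closed rate constant per mM, 1/(mM s); defaults to
#'   `k_off / K_d`.
#' @param Q_open 3x3 rate matrix among (open1, open2, openplus); off-diagonal
#'   >= 0, rows sum to 0.
#' @param open_entry_weights probabilities of entering each open class on a
#'   closed -> open transition; must sum to 1.
#' @param subunit_flicker_rate rate of resampling the open-+ per-subunit
#'   elevations, 1/s (sub-frame-time subunit fluctuations).
#' @param subunit_flicker_amp scale of those elevations, nm (passed to the
#'   renderer via [sample_openplus_offsets()] limits).
#' @return object of class `gating_model`.
#' @export
gating_model <- function(K_d = 2.0,
                         k_off = 1 / 30,
                         k_on = k_off / K_d,
                         Q_open = default_q_open(),
                         open_entry_weights = c(0.25, 0.25, 0.5),
                         subunit_flicker_rate = 2,
                         subunit_flicker_amp = 2.5) {
  stop_if(k_on <= 0 || k_off <= 0, "rates must be > 0")
  stop_if(abs(sum(open_entry_weights) - 1) > 1e-9,
          "open_entry_weights must sum to 1")
  stop_if(any(Q_open - diag(diag(Q_open)) < 0) ||
            any(abs(rowSums(Q_open)) > 1e-9),
          "Q_open must have non-negative off-diagonals and zero row sums")
  structure(list(K_d = k_off / k_on, k_off = k_off, k_on = k_on,
                 Q_open = Q_open,
                 open_entry_weights = open_entry_weights,
                 subunit_flicker_rate = subunit_flicker_rate,
                 subunit_flicker_amp = subunit_flicker_amp),
            class = "gating_model")
}

#' @rdname gating_model
#' @export
default_q_open <- function() {
  q <- matrix(c(-0.2, 0.1, 0.1,
                0.1, -0.2, 0.1,
                0.1, 0.1, -0.2), 3, 3, byrow = TRUE)
  dimnames(q) <- list(gating_classes()[2:4], gating_classes()[2:4])
  q
}

#' Ligand concentration schedule
#'
#' Time-stamped total Mg2+ / EDTA additions; the free Mg2+ concentration in
#' each epoch follows 1:1 chelation mass balance via [free_mg()].
#'
#' @param times event times, s (strictly increasing, first usually 0).
#' @param mg_total total Mg2+ after each event, mM.
#' @param edta_total total EDTA after each event, mM.
#' @param kd_edta conditional Mg-EDTA dissociation constant, mM (default 0.1,
#'   appropriate near pH 6).
#' @return object of class `concentration_schedule` with a `free_mg` column.
#' @export
concentration_schedule <- function(times = 0, mg_total = 10, edta_total = 0,
                                   kd_edta = 0.1) {
  stop_if(any(diff(times) <= 0), "event times must be strictly increasing")
  stop_if(any(c(mg_total, edta_total, kd_edta) < 0),
          "concentrations must be >= 0")
  n <- max(length(times), length(mg_total), length(edta_total))
  df <- data.frame(time = rep_len(times, n),
                   mg_total = rep_len(mg_total, n),
                   edta_total = rep_len(edta_total, n))
  df$free_mg <- mapply(free_mg, df$mg_total, df$edta_total,
                       MoreArgs = list(kd_edta = kd_edta))
  attr(df, "kd_edta") <- kd_edta
  class(df) <- c("concentration_schedule", "data.frame")
  df
}

#' Free Mg2+ under 1:1 EDTA chelation
#'
#' Solves the mass-balance quadratic
#' `x^2 + (EDTA - Mg + Kd) x - Kd * Mg = 0` for the free ion concentration x
#' (the positive root), where Kd is the conditional Mg-EDTA dissociation
#' constant.
#'
#' @param mg_total total Mg2+, mM.
#' @param edta_total total EDTA, mM.
#' @param kd_edta conditional dissociation constant, mM.
#' @return free Mg2+ concentration, mM, in `[0, mg_total]`.
#' @export
free_mg <- function(mg_total, edta_total, kd_edta = 0.1) {
  stop_if(mg_total < 0 || edta_total < 0 || kd_edta < 0,
          "concentrations must be >= 0")
  b <- edta_total - mg_total + kd_edta
  c0 <- -kd_edta * mg_total
  x <- (-b + sqrt(b^2 - 4 * c0)) / 2
  min(max(x, 0), mg_total)
}

#' Stationary closed occupancy at constant free Mg2+
#' @param conc free Mg2+, mM; @param K_d mM.
#' @return c / (c + K_d).
#' @export
stationary_closed_fraction <- function(conc, K_d = 2) conc / (conc + K_d)

free_mg_at <- function(schedule, t) {
  i <- findInterval(t, schedule$time)
  ifelse(i < 1, schedule$free_mg[1], schedule$free_mg[pmax(i, 1)])
}

#' Sample a continuous-time gating path (Gillespie)
#'
#' Simulates the four-state gating chain under a piecewise-constant free-Mg2+
#' concentration (from the schedule). Within each concentration epoch all
#' rates are constant and exact Gillespie sampling is used; jumps are capped
#' at epoch boundaries. Open-+ sojourns are subdivided at
#' `subunit_flicker_rate` with freshly drawn per-subunit elevations, so the
#' returned intervals are directly renderable.
#'
#' @param model a [gating_model()].
#' @param schedule a [concentration_schedule()].
#' @param duration path length, s.
#' @param init initial state (default drawn from the stationary law at the
#'   initial concentration).
#' @return data.frame of intervals: `t_start`, `t_end`, `class`, plus an
#'   `offsets` list-column of per-subunit elevations (NULL except open-+).
#' @export
sample_gating <- function(model, schedule, duration, init = NULL) {
  stop_if(duration <= 0, "duration must be > 0")
  cls <- gating_classes()
  epochs <- c(schedule$time, Inf)
  if (is.null(init)) {
    c0 <- free_mg_at(schedule, 0)
    p_closed <- stationary_closed_fraction(c0, model$K_d)
    init <- if (stats::runif(1) < p_closed) 1L else
      1L + sample.int(3, 1, prob = model$open_entry_weights)
  }
  state <- init
  t <- 0
  out_t0 <- numeric(0); out_t1 <- numeric(0); out_s <- integer(0)
  seg_start <- 0
  while (t < duration) {
    ep <- findInterval(t, schedule$time)
    ep <- max(ep, 1)
    t_ep_end <- min(epochs[ep + 1], duration)
    conc <- schedule$free_mg[ep]
    if (state == 1L) {
      rate <- model$k_off
      rates_to <- model$open_entry_weights * model$k_off
      targets <- 2:4
    } else {
      qrow <- model$Q_open[state - 1L, ]
      r_back <- model$k_on * conc
      rates_to <- c(r_back, qrow[-(state - 1L)])
      targets <- c(1L, setdiff(2:4, state))
      rate <- sum(rates_to)
    }
    dt <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (t + dt >= t_ep_end) {
      t <- t_ep_end
      if (t >= duration) break
      next  # concentration change, same state
    }
    t <- t + dt
    new_state <- targets[sample.int(length(targets), 1, prob = rates_to)]
    if (new_state != state) {
      out_t0 <- c(out_t0, seg_start); out_t1 <- c(out_t1, t)
      out_s <- c(out_s, state)
      seg_start <- t
      state <- new_state
    }
  }
  out_t0 <- c(out_t0, seg_start); out_t1 <- c(out_t1, duration)
  out_s <- c(out_s, state)
  path <- data.frame(t_start = out_t0, t_end = out_t1,
                     class = cls[out_s], stringsAsFactors = FALSE)
  subdivide_flicker(path, model)
}

# split open-+ sojourns at the flicker rate and attach per-subunit offsets
subdivide_flicker <- function(path, model) {
  rows <- vector("list", nrow(path))
  amp <- model$subunit_flicker_amp
  for (i in seq_len(nrow(path))) {
    r <- path[i, ]
    if (r$class != "openplus" || model$subunit_flicker_rate <= 0) {
      rows[[i]] <- data.frame(t_start = r$t_start, t_end = r$t_end,
                              class = r$class)
      rows[[i]]$offsets <- list(NULL)
      next
    }
    cuts <- r$t_start
    while (TRUE) {
      nxt <- cuts[length(cuts)] + stats::rexp(1, model$subunit_flicker_rate)
      if (nxt >= r$t_end) break
      cuts <- c(cuts, nxt)
    }
    seg <- data.frame(t_start = cuts, t_end = c(cuts[-1], r$t_end),
                      class = r$class)
    seg$offsets <- replicate(nrow(seg),
                             sample_openplus_offsets(lo = -amp, hi = 0.5),
                             simplify = FALSE)
    rows[[i]] <- seg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discrete-time per-frame gating presets for the imaging conditions
#'
#' Frame-to-frame jump chains for the four experimental conditions
#' (saturating 10 mM, intermediate 3 mM, depleted 0 mM, and re-addition of
#' 25 mM Mg2+). Each chain is constructed from two inputs: the stationary
#' class occupancies pi and the aggregate conditional probability rho that a
#' molecule in any open class returns to closed on the next frame. With
#' P(open_i -> closed) = rho, P(open_i -> open_j) = (1 - rho) q_j and
#' P(closed -> open_j) = alpha q_j where q is the open-conditional occupancy
#' and `alpha = rho (1 - pi_closed) / pi_closed` (global balance), the chain's
#' stationary law is exactly pi and its open -> closed return probability is
#' exactly rho.
#'
#' @param condition one of `"10mM"`, `"3mM"`, `"0mM"`, `"readd25mM"`.
#' @return list with `condition`, `conc_mM`, `occupancy` (named numeric(4),
#'   fractions), `return_prob`, and `P` (4x4 row-stochastic matrix).
#' @export
condition_preset <- function(condition = c("10mM", "3mM", "0mM", "readd25mM")) {
  condition <- match.arg(condition)
  tab <- list(
    "10mM"      = list(conc = 10, pi = c(0.91, 0.03, 0.03, 0.03), rho = 0.50),
    "3mM"       = list(conc = 3,  pi = c(0.20, 0.15, 0.15, 0.50), rho = 0.14),
    "0mM"       = list(conc = 0,  pi = c(0.08, 0.25, 0.25, 0.42), rho = 0.07),
    "readd25mM" = list(conc = 25, pi = c(0.35, 0.15, 0.15, 0.35), rho = 0.20)
  )[[condition]]
  pi <- tab$pi; rho <- tab$rho
  names(pi) <- gating_classes()
  q <- pi[2:4] / sum(pi[2:4])
  alpha <- rho * (1 - pi[1]) / pi[1]
  stop_if(alpha > 1, "infeasible preset: closed exit probability > 1")
  P <- matrix(0, 4, 4, dimnames = list(gating_classes(), gating_classes()))
  P[1, ] <- c(1 - alpha, alpha * q)
  for (i in 2:4) P[i, ] <- c(rho, (1 - rho) * q)
  list(condition = condition, conc_mM = tab$conc, occupancy = pi,
       return_prob = rho, P = P)
}

#' Sample a per-frame state path from a discrete jump chain
#'
#' Draws frame labels from a row-stochastic matrix starting at the stationary
#' law, and expands them into renderable state intervals aligned to frame
#' times (open-+ frames get fresh per-subunit elevations each frame).
#'
#' @param P 4x4 row-stochastic matrix over [gating_classes()].
#' @param n_frames number of frames.
#' @param frame_interval s per frame.
#' @param flicker_amp open-+ per-subunit elevation range, nm.
#' @return list(labels = character(n_frames), path = interval data.frame as
#'   in [sample_gating()]).
#' @export
sample_chain <- function(P, n_frames, frame_interval = 0.55,
                         flicker_amp = 2.5) {
  stop_if(any(abs(rowSums(P) - 1) > 1e-9), "P rows must sum to 1")
  pi <- stationary_law(P)
  s <- integer(n_frames)
  s[1] <- sample.int(4, 1, prob = pi)
  for (i in seq_len(n_frames - 1)) {
    s[i + 1] <- sample.int(4, 1, prob = P[s[i], ])
  }
  cls <- gating_classes()[s]
  path <- data.frame(t_start = (seq_len(n_frames) - 1) * frame_interval,
                     t_end = seq_len(n_frames) * frame_interval,
                     class = cls, stringsAsFactors = FALSE)
  path$offsets <- lapply(cls, function(cl)
    if (cl == "openplus") sample_openplus_offsets(lo = -flicker_amp, hi = 0.5)
    else NULL)
  # merge is not needed: renderer takes per-interval geometry as-is
  list(labels = cls, path = path)
}

#' Stationary law of a finite row-stochastic matrix
#' @param P row-stochastic matrix.
#' @return stationary probability vector.
#' @export
stationary_law <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}
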