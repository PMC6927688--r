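#' Asymmetric-particle fraction for one titration condition
#'
#' A particle snapshot counts as "dynamically asymmetric" when its class is
#' any non-closed class; a molecule is asymmetric when it is non-closed in at
#' least `window_frac` of a `window` consecutive-frame window (default: half
#' of a 10-frame window).
#'
#' @param labels `class_labels` data.frame for one condition, or a logical
#'   vector (`TRUE` = asymmetric particle).
#' @param conc_mM free Mg2+ of the condition.
#' @param window,window_frac windowed definition of a dynamically asymmetric
#'   molecule (used with frame-resolved labels).
#' @return data.frame row (conc_mM, n, n_asym, fraction, se) with the
#'   binomial standard error `sqrt(p(1-p)/n)`.
#' @export
asymmetric_fraction <- function(labels, conc_mM = NA, window = 10,
                                window_frac = 0.5) {
  if (is.logical(labels)) {
    asym <- labels
  } else {
    stop_if(nrow(labels) == 0, "no labels")
    asym <- vapply(split(labels$class != "closed", labels$molecule_id),
                   function(x) {
                     if (length(x) < window) return(mean(x) >= window_frac)
                     # any window with enough non-closed frames
                     cs <- cumsum(c(0, x))
                     any((cs[(window + 1):length(cs)] -
                            cs[1:(length(cs) - window)]) / window >= window_frac)
                   }, logical(1))
  }
  n <- length(asym)
  stop_if(n == 0, "no particles")
  p <- mean(asym)
  data.frame(conc_mM = conc_mM, n = n, n_asym = sum(asym), fraction = p,
             se = sqrt(p * (1 - p) / n))
}

#' Simulate a binomial titration series from the gating stationary law
#'
#' Draws `n_particles` Bernoulli asymmetric/symmetric outcomes per
#' concentration from the stationary open probability
#' `1 - c/(c + K_d)` of the gating model.
#'
#' @param concentrations free Mg2+ values, mM.
#' @param K_d true dissociation constant, mM.
#' @param n_particles particles scored per condition.
#' @return titration series data.frame (rows of [asymmetric_fraction()]).
#' @export
simulate_titration <- function(concentrations = c(0.2, 0.5, 1, 2, 4, 7, 10),
                               K_d = 2, n_particles = 100) {
  do.call(rbind, lapply(concentrations, function(cc) {
    p_open <- 1 - stationary_closed_fraction(cc, K_d)
    asym <- stats::runif(n_particles) < p_open
    asymmetric_fraction(asym, conc_mM = cc)
  }))
}

#' Fit an apparent K_d to a titration series
#'
#' Weighted least squares of the binding curve
#' `f(c) = 1 - c^n / (c^n + K_d^n)` (Hill coefficient n fixed to 1 by
#' default) to asymmetric fractions, weights 1/SE^2 (zero-SE points get the
#' largest finite weight). Confidence interval by parametric bootstrap over
#' particles.
#'
#' @param series data.frame (conc_mM, n, n_asym, fraction, se).
#' @param fix_hill if `TRUE` (default) n = 1; otherwise n is free.
#' @param n_boot bootstrap replicates for the CI (0 disables).
#' @param conf CI level.
#' @return object of class `kd_fit`: list(K_d, hill, ci, fitted, series).
#' @export
fit_kd <- function(series, fix_hill = TRUE, n_boot = 200, conf = 0.95) {
  stop_if(nrow(series) < 4, "need >= 4 concentrations")
  rng <- range(series$conc_mM)
  spans <- any(series$fraction > 0.6) && any(series$fraction < 0.4)
  if (!spans)
    warning("series does not span the transition; K_d poorly constrained")
  w <- 1 / pmax(series$se, 1e-3)^2
  fit1 <- function(s, wts) {
    start <- list(K = max(stats::median(s$conc_mM), 1e-3))
    if (fix_hill) {
      f <- minpack.lm::nlsLM(fraction ~ 1 - conc_mM / (conc_mM + K),
                             data = s, start = start, weights = wts,
                             lower = c(K = 1e-6))
      c(K = stats::coef(f)[["K"]], n = 1)
    } else {
      f <- minpack.lm::nlsLM(fraction ~ 1 - conc_mM^n / (conc_mM^n + K^n),
                             data = s, start = c(start, n = 1), weights = wts,
                             lower = c(K = 1e-6, n = 0.1))
      c(K = stats::coef(f)[["K"]], n = stats::coef(f)[["n"]])
    }
  }
  est <- fit1(series, w)
  ci <- c(NA, NA)
  if (n_boot > 0) {
    ks <- replicate(n_boot, {
      s2 <- series
      s2$n_asym <- stats::rbinom(nrow(s2), s2$n, pmin(pmax(s2$fraction, 0), 1))
      s2$fraction <- s2$n_asym / s2$n
      s2$se <- sqrt(pmax(s2$fraction * (1 - s2$fraction), 1e-6) / s2$n)
      tryCatch(fit1(s2, 1 / s2$se^2)[["K"]], error = function(e) NA_real_)
    })
    ci <- stats::quantile(ks, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE)
  }
  fitted <- 1 - series$conc_mM^est[["n"]] /
    (series$conc_mM^est[["n"]] + est[["K"]]^est[["n"]])
  structure(list(K_d = est[["K"]], hill = est[["n"]], ci = ci,
                 fitted = fitted, series = series,
                 spans_transition = spans),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Apparent K_d = %.3g mM (Hill n = %.3g)\n", x$K_d, x$hill))
  if (!all(is.na(x$ci)))
    cat(sprintf("  bootstrap CI: [%.3g, %.3g] mM\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
plot.kd_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(s$conc_mM, s$fraction, log = "x", pch = 19,
                 xlab = "free Mg2+ (mM)", ylab = "asymmetric fraction",
                 ylim = c(0, 1), ...)
  graphics::arrows(s$conc_mM, s$fraction - s$se, s$conc_mM, s$fraction + s$se,
                   angle = 90, code = 3, length = 0.03)
  cgrid <- exp(seq(log(min(s$conc_mM)), log(max(s$conc_mM)), length.out = 100))
  graphics::lines(cgrid, 1 - cgrid^x$hill / (cgrid^x$hill + x$K_d^x$hill),
                  col = "red")
  invisible(x)
}
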