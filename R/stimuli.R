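# Looming-stimulus geometry, the luminance-matched dimming control, and
# logistic psychometric fits of contrast-dependent escape probability.

#' Define a looming stimulus
#'
#' A dark disc simulating an object of half-size L approaching at constant
#' speed V subtends the visual angle `theta(t) = 2 * atan((L/V) /
#' (t_collision - t))`; the stimulus expands from `start_angle` to
#' `end_angle` and is parameterized by the ratio `l_over_v` (s).
#'
#' @param l_over_v L/V ratio (s), e.g. 0.255 or 0.490.
#' @param start_angle,end_angle angular sizes (deg) at stimulus onset/offset.
#' @param contrast nominal contrast fraction in [0, 1].
#' @param lux optional measured luminance metadata (spot and background lux).
#' @return object of class `loom_stimulus` with `t_collision` and
#'   `t_end` (s, relative to the time the spot subtends `start_angle`).
#' @export
loom_stimulus <- function(l_over_v, start_angle = 10, end_angle = 70,
                          contrast = 1, lux = NULL) {
  stopifnot(l_over_v > 0, end_angle > start_angle, start_angle > 0,
            end_angle < 180)
  t_collision <- l_over_v / tan(deg2rad(start_angle / 2))
  t_end <- t_collision - l_over_v / tan(deg2rad(end_angle / 2))
  structure(list(l_over_v = l_over_v, start_angle = start_angle,
                 end_angle = end_angle, contrast = contrast, lux = lux,
                 t_collision = t_collision, t_end = t_end),
            class = "loom_stimulus")
}

#' @export
print.loom_stimulus <- function(x, ...) {
  cat(sprintf(
    "loom_stimulus: %g-%g deg, L/V = %g s, contrast %g (expansion %.3f s)\n",
    x$start_angle, x$end_angle, x$l_over_v, x$contrast, x$t_end))
  invisible(x)
}

#' Angular size of a looming stimulus over time
#'
#' @param stim a [loom_stimulus()].
#' @param t time (s) from stimulus onset (the moment the spot subtends
#'   `start_angle`); values beyond the expansion interval are clipped to the
#'   start/end angles.
#' @return angular size(s) in degrees.
#' @export
loom_angle_profile <- function(stim, t) {
  tt <- stim$t_collision - t
  th <- ifelse(tt > 0, 2 * rad2deg(atan(stim$l_over_v / tt)),
               stim$end_angle)
  pmin(pmax(th, stim$start_angle), stim$end_angle)
}

#' Time at which a looming stimulus reaches a given angular size
#'
#' Closed-form inversion of the angular-size formula.
#'
#' @param stim a [loom_stimulus()].
#' @param theta angular size(s), deg, within `[start_angle, end_angle]`.
#' @return time(s) in s from stimulus onset.
#' @export
loom_time_of_angle <- function(stim, theta) {
  stopifnot(all(theta >= stim$start_angle - 1e-9),
            all(theta <= stim$end_angle + 1e-9))
  stim$t_collision - stim$l_over_v / tan(deg2rad(theta / 2))
}

# solid angle (sr) of a disc of angular diameter theta (deg)
disc_solid_angle <- function(theta) 2 * pi * (1 - cos(deg2rad(theta / 2)))

#' Luminance-matched dimming control profile
#'
#' The control stimulus is a disc of fixed angular size equal to the loom's
#' final size whose intensity dims so that its whole-field luminance change
#' equals the expanding loom's (solid-angle-weighted) change at every
#' instant: `deficit(t) = contrast * Omega(theta(t)) / Omega(end_angle)`.
#'
#' @param stim a [loom_stimulus()].
#' @param t times (s) from stimulus onset.
#' @return data.frame with `time`, `angle` (the loom's angular size),
#'   `deficit` (the dimming disc's contrast deficit in [0, contrast]).
#' @export
dimming_profile <- function(stim, t) {
  th <- loom_angle_profile(stim, t)
  data.frame(time = t, angle = th,
             deficit = stim$contrast * disc_solid_angle(th) /
               disc_solid_angle(stim$end_angle))
}

#' Fit a logistic psychometric function to escape-probability data
#'
#' Maximum-likelihood Bernoulli fit of
#' `P(escape | c) = (1 - lambda) / (1 + exp(-beta * (c - alpha)))` with the
#' lower asymptote fixed at zero and, by default, the lapse rate `lambda`
#' fixed at zero. `alpha` is the contrast threshold (the curve's midpoint)
#' and `beta > 0` the slope. Goodness of fit and parameter confidence
#' intervals come from a parametric bootstrap.
#'
#' @param contrast contrast levels (fractions).
#' @param n_escape escapes observed per level.
#' @param n_trials trials per level.
#' @param free_lapse estimate the lapse rate instead of fixing it at 0.
#' @param n_boot parametric bootstrap resamples (0 to skip).
#' @param seed seed for the bootstrap.
#' @return object of class `psychometric_fit`: `alpha`, `beta`, `lambda`,
#'   `loglik`, `deviance`, `gof_p` (bootstrap goodness-of-fit p-value),
#'   `ci_alpha`, `ci_beta` (95% bootstrap CIs), `data`.
#' @export
fit_psychometric <- function(contrast, n_escape, n_trials,
                             free_lapse = FALSE, n_boot = 1000, seed = 1L) {
  stopifnot(length(contrast) >= 3L, length(n_escape) == length(contrast),
            length(n_trials) == length(contrast), all(n_trials > 0),
            all(n_escape >= 0), all(n_escape <= n_trials))
  if (sum(n_escape) == 0L || all(n_escape == n_trials))
    stop("non-identifiable fit: responses are all-zero or all-one")
  nll <- function(par) {
    a <- par[1]; b <- exp(par[2])
    lam <- if (free_lapse) stats::plogis(par[3]) * 0.2 else 0
    p <- (1 - lam) * stats::plogis(b * (contrast - a))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(n_escape * log(p) + (n_trials - n_escape) * log(1 - p))
  }
  # moment-style initialization from the empirical curve
  pe <- n_escape / n_trials
  a0 <- stats::approx(c(0, pe[order(contrast)], 1),
                      c(min(contrast), contrast[order(contrast)],
                        max(contrast)), xout = 0.5, ties = "ordered")$y
  if (!is.finite(a0)) a0 <- stats::median(contrast)
  init <- c(a0, log(5 / max(diff(range(contrast)), 0.1)))
  if (free_lapse) init <- c(init, stats::qlogis(0.05))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  a <- opt$par[1]; b <- exp(opt$par[2])
  lam <- if (free_lapse) stats::plogis(opt$par[3]) * 0.2 else 0
  phat <- (1 - lam) * stats::plogis(b * (contrast - a))
  dev <- binom_deviance(n_escape, n_trials, phat)
  gof_p <- NA_real_
  ca <- cb <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    with_seed(seed, {
      devs <- alphas <- betas <- rep(NA_real_, n_boot)
      for (i in seq_len(n_boot)) {
        yb <- stats::rbinom(length(contrast), n_trials, phat)
        if (sum(yb) == 0L || all(yb == n_trials)) next
        ob <- stats::optim(opt$par, function(par) {
          aa <- par[1]; bb <- exp(par[2])
          ll <- if (free_lapse) stats::plogis(par[3]) * 0.2 else 0
          p <- (1 - ll) * stats::plogis(bb * (contrast - aa))
          p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
          -sum(yb * log(p) + (n_trials - yb) * log(1 - p))
        }, method = "Nelder-Mead", control = list(maxit = 1000))
        ll <- if (free_lapse) stats::plogis(ob$par[3]) * 0.2 else 0
        pb <- (1 - ll) * stats::plogis(exp(ob$par[2]) *
                                         (contrast - ob$par[1]))
        devs[i] <- binom_deviance(yb, n_trials, pb)
        alphas[i] <- ob$par[1]; betas[i] <- exp(ob$par[2])
      }
      gof_p <- mean(devs >= dev, na.rm = TRUE)
      ca <- stats::quantile(alphas, c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE)
      cb <- stats::quantile(betas, c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE)
    })
  }
  structure(list(alpha = a, beta = b, lambda = lam, loglik = -opt$value,
                 deviance = dev, gof_p = gof_p, ci_alpha = ca, ci_beta = cb,
                 data = data.frame(contrast = contrast, n_escape = n_escape,
                                   n_trials = n_trials)),
            class = "psychometric_fit")
}

binom_deviance <- function(y, n, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ps <- pmin(pmax(y / n, 1e-12), 1 - 1e-12)
  2 * sum(y * log(ps / p) + (n - y) * log((1 - ps) / (1 - p)))
}

#' Predicted escape probability from a psychometric fit
#'
#' @param object a `psychometric_fit`.
#' @param newdata optional vector of contrast values (defaults to the
#'   fitted levels).
#' @param ... unused.
#' @return predicted probabilities.
#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$contrast else newdata
  (1 - object$lambda) * stats::plogis(object$beta * (cc - object$alpha))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "psychometric_fit: alpha = %.3f, beta = %.2f, lambda = %.3f\n",
    x$alpha, x$beta, x$lambda))
  if (!is.na(x$gof_p))
    cat(sprintf("  deviance %.2f (bootstrap GOF p = %.3f)\n",
                x$deviance, x$gof_p))
  invisible(x)
}
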