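# Kinematic segmentation: per-fish vergence threshold from a two-Gaussian
# mixture, hunting-epoch extraction, tail-velocity bout detection and
# centroid-speed escape detection.

#' Fit the per-fish vergence threshold
#'
#' Fits a two-component Gaussian mixture to the vergence-angle distribution
#' by maximum likelihood (EM, via mclust) and sets the hunting threshold one
#' standard deviation below the mean of the higher-angle component.
#'
#' @param vergence vergence series (deg; left minus right eye angle).
#' @param min_weight minimum mixing weight of either component; below this
#'   the fit is declared degenerate (unimodal input).
#' @param min_separation minimum distance between component means (deg) for a
#'   valid bimodal fit.
#' @return object of class `vergence_threshold`: list with `threshold`,
#'   `mu` (low, high), `sigma`, `weight`, `loglik`, `bic_two`, `bic_one`.
#' @seealso [segment_hunting_epochs()]
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_vergence_threshold <- function(vergence, min_weight = 0.02,
                                   min_separation = 8) {
  vergence <- vergence[is.finite(vergence)]
  if (length(vergence) < 200)
    stop("vergence series too short to populate both modes")
  fit <- mclust::Mclust(vergence, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("degenerate fit: mixture estimation failed")
  mu <- as.numeric(fit$parameters$mean)
  sg <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sg) == 1L) sg <- rep(sg, 2L)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; w <- w[o]
  one <- mclust::Mclust(vergence, G = 1, modelNames = "V", verbose = FALSE)
  if (min(w) < min_weight || diff(mu) < min_separation)
    stop("degenerate fit: vergence distribution appears unimodal")
  structure(list(threshold = mu[2] - sg[2], mu = mu, sigma = sg, weight = w,
                 loglik = fit$loglik, bic_two = fit$bic, bic_one = one$bic),
            class = "vergence_threshold")
}

#' @export
print.vergence_threshold <- function(x, ...) {
  cat(sprintf(
    "vergence_threshold: %.2f deg  (modes %.1f +/- %.1f, %.1f +/- %.1f)\n",
    x$threshold, x$mu[1], x$sigma[1], x$mu[2], x$sigma[2]))
  invisible(x)
}

#' Segment hunting epochs from the vergence series
#'
#' A fish is considered hunting while vergence exceeds the fitted threshold.
#' Maximal above-threshold runs are extracted, runs separated by gaps of at
#' most `merge_gap` are merged, and epochs shorter than `min_duration` are
#' discarded. The epoch onset marks the convergent saccade; the dominant eye
#' is the one showing the greater nasal rotation relative to its pre-epoch
#' baseline.
#'
#' @param session a [behavior_session], or a list with `time`, `vergence`,
#'   `left_eye`, `right_eye`, `sampling_rate`.
#' @param threshold numeric threshold (deg) or a [fit_vergence_threshold()]
#'   result.
#' @param merge_gap maximum sub-threshold gap merged into an epoch (s).
#' @param min_duration minimum epoch duration (s).
#' @return data.frame with `epoch_id`, `onset`, `offset`, `duration`,
#'   `dominant_eye`.
#' @export
segment_hunting_epochs <- function(session, threshold, merge_gap = 0.07,
                                   min_duration = 0.1) {
  thr <- if (inherits(threshold, "vergence_threshold")) threshold$threshold
         else as.numeric(threshold)
  rate <- session$sampling_rate
  v <- session$vergence
  runs <- find_runs(v >= thr,
                    merge_gap = as.integer(round(merge_gap * rate)),
                    min_len = as.integer(round(min_duration * rate)))
  if (nrow(runs) == 0L) {
    return(data.frame(epoch_id = integer(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      dominant_eye = character(0)))
  }
  t <- session$time
  dom <- character(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    base <- max(1L, i0 - as.integer(round(0.3 * rate))):max(1L, i0 - 1L)
    ep <- i0:min(i1, i0 + as.integer(round(0.3 * rate)))
    dL <- mean(session$left_eye[ep]) - mean(session$left_eye[base])
    dR <- mean(session$right_eye[ep]) - mean(session$right_eye[base])
    # nasal rotation: clockwise (+) for the left eye, counter-clockwise (-)
    # for the right eye
    dom[k] <- if (dL >= -dR) "left" else "right"
  }
  data.frame(epoch_id = seq_len(nrow(runs)), onset = t[runs$start],
             offset = t[runs$end], duration = t[runs$end] - t[runs$start],
             dominant_eye = dom)
}

#' Detect swim bouts from tail kinematics
#'
#' The cumulative tail angle (sum of the 8 inter-segment angles) is smoothed
#' with a Savitzky-Golay filter and bouts are detected as runs where the
#' absolute angular velocity exceeds `velocity_threshold` (default
#' 500 deg/s), with gap merging and minimum-duration pruning.
#'
#' @param tail_angles matrix (n x 8) of inter-segment angles (deg), or a
#'   [behavior_session].
#' @param rate sampling rate (Hz); taken from the session if one is given.
#' @param velocity_threshold deg/s.
#' @param sg_window Savitzky-Golay window length (samples, odd).
#' @param merge_gap maximum sub-threshold gap merged into a bout (s).
#' @param min_duration minimum bout duration (s).
#' @return data.frame with `bout_id`, `onset`, `offset`, `duration`,
#'   `peak_velocity` (deg/s).
#' @export
detect_bouts <- function(tail_angles, rate = NULL, velocity_threshold = 500,
                         sg_window = 21L, merge_gap = 0.03,
                         min_duration = 0.02) {
  if (inherits(tail_angles, "behavior_session")) {
    rate <- tail_angles$sampling_rate
    tail_angles <- tail_angles$tail_angles
  }
  stopifnot(!is.null(rate), ncol(tail_angles) == 8L)
  cum <- rowSums(tail_angles)
  n <- length(cum)
  win <- min(sg_window, if (n %% 2L == 0L) n - 1L else n)
  if (win %% 2L == 0L) win <- win - 1L
  sm <- if (win >= 5L) signal::sgolayfilt(cum, p = 3, n = win) else cum
  vel <- c(0, diff(sm)) * rate
  runs <- find_runs(abs(vel) > velocity_threshold,
                    merge_gap = as.integer(round(merge_gap * rate)),
                    min_len = as.integer(round(min_duration * rate)))
  if (nrow(runs) == 0L) {
    return(data.frame(bout_id = integer(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      peak_velocity = numeric(0)))
  }
  t <- (seq_len(n) - 1L) / rate
  peak <- vapply(seq_len(nrow(runs)), function(k)
    max(abs(vel[runs$start[k]:runs$end[k]])), 1)
  data.frame(bout_id = seq_len(nrow(runs)), onset = t[runs$start],
             offset = t[runs$end], duration = t[runs$end] - t[runs$start],
             peak_velocity = peak)
}

#' Detect escape events from body-centroid speed
#'
#' Escapes are detected where the instantaneous frame-to-frame speed of the
#' body centroid exceeds `speed_threshold` (default 75 mm/s); one event is
#' reported per supra-threshold run. When a stimulus log is supplied, the
#' latency from the most recent stimulus onset is reported.
#'
#' @param time sample times (s) of the centroid series.
#' @param x,y body centroid (mm).
#' @param speed_threshold mm/s.
#' @param stimulus_onsets optional vector of stimulus onset times (s).
#' @return data.frame with `event_id`, `onset`, `offset`, `peak_speed`,
#'   `latency` (NA without a stimulus log).
#' @export
detect_escapes <- function(time, x, y, speed_threshold = 75,
                           stimulus_onsets = NULL) {
  stopifnot(length(time) == length(x), length(x) == length(y))
  if (length(time) < 2L) {
    return(data.frame(event_id = integer(0), onset = numeric(0),
                      offset = numeric(0), peak_speed = numeric(0),
                      latency = numeric(0)))
  }
  sp <- c(0, sqrt(diff(x)^2 + diff(y)^2) / diff(time))
  runs <- find_runs(sp > speed_threshold)
  if (nrow(runs) == 0L) {
    return(data.frame(event_id = integer(0), onset = numeric(0),
                      offset = numeric(0), peak_speed = numeric(0),
                      latency = numeric(0)))
  }
  onset <- time[runs$start]
  lat <- rep(NA_real_, length(onset))
  if (!is.null(stimulus_onsets) && length(stimulus_onsets)) {
    for (k in seq_along(onset)) {
      prev <- stimulus_onsets[stimulus_onsets <= onset[k]]
      if (length(prev)) lat[k] <- onset[k] - max(prev)
    }
  }
  data.frame(event_id = seq_len(nrow(runs)), onset = onset,
             offset = time[runs$end],
             peak_speed = vapply(seq_len(nrow(runs)), function(k)
               max(sp[runs$start[k]:runs$end[k]]), 1),
             latency = lat)
}
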