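# Per-bout pursuit scoring, target assignment, outcome classification and
# ethogram statistics for hunting routines.
#
# Distance-gain and orientation-gain of a bout are the fractions of
# fish-target distance and azimuth eliminated by that bout: positive gains
# mean the larva oriented toward and approached the prey; a bout with
# negative distance- AND orientation-gain marks abandonment of pursuit.

# fish-target geometry at a given time: distance from the eyes' midpoint to
# the target, and signed azimuth (deg, positive to the fish's right) between
# the eyes-center-to-target vector and the heading
target_geometry <- function(session, target_xy, t) {
  i <- which.min(abs(session$time - t))
  E <- eyes_center(session, i)[1, ]
  d <- sqrt(sum((target_xy - E)^2))
  az <- wrap180(vec_angle(target_xy[1] - E[1], target_xy[2] - E[2]) -
                  session$heading[i])
  list(distance = d, azimuth = az)
}

# prey position (mm) of one track at time t, linearly interpolated; NA when
# the track does not cover t
track_position <- function(track_xy, track_t, t) {
  if (t < min(track_t) || t > max(track_t)) return(c(NA_real_, NA_real_))
  c(stats::approx(track_t, track_xy[, 1], t)$y,
    stats::approx(track_t, track_xy[, 2], t)$y)
}

#' Compute distance- and orientation-gain of one bout
#'
#' Gains are the fraction of fish-target distance / azimuth eliminated by
#' the bout: `gain = (pre - post) / pre` evaluated at the bout onset and
#' offset, with the target position linearly interpolated from its low-rate
#' track. Distance is measured from the midpoint of the eye centroids;
#' azimuth is the angle between the eyes-center-to-target vector and the
#' heading (only its magnitude enters the gain).
#'
#' @param session a [behavior_session].
#' @param target_track data.frame or matrix with columns time, x, y (mm) for
#'   the target prey.
#' @param bout list or one-row data.frame with `onset` and `offset` (s).
#' @return object of class `bout_gain`: list with `distance_gain`,
#'   `orientation_gain`, `pre_distance`, `post_distance`, `pre_azimuth`,
#'   `post_azimuth`, `defined`.
#' @export
compute_gains <- function(session, target_track, bout) {
  tt <- as.matrix(target_track)
  pos_on <- track_position(tt[, 2:3, drop = FALSE], tt[, 1], bout$onset)
  pos_off <- track_position(tt[, 2:3, drop = FALSE], tt[, 1], bout$offset)
  if (any(is.na(pos_on)) || any(is.na(pos_off))) {
    return(structure(list(distance_gain = NA_real_,
                          orientation_gain = NA_real_,
                          pre_distance = NA_real_, post_distance = NA_real_,
                          pre_azimuth = NA_real_, post_azimuth = NA_real_,
                          defined = FALSE), class = "bout_gain"))
  }
  pre <- target_geometry(session, pos_on, bout$onset)
  post <- target_geometry(session, pos_off, bout$offset)
  gd <- if (pre$distance > 0)
    (pre$distance - post$distance) / pre$distance else NA_real_
  go <- if (abs(pre$azimuth) > 0)
    (abs(pre$azimuth) - abs(post$azimuth)) / abs(pre$azimuth) else NA_real_
  structure(list(distance_gain = gd, orientation_gain = go,
                 pre_distance = pre$distance, post_distance = post$distance,
                 pre_azimuth = pre$azimuth, post_azimuth = post$azimuth,
                 defined = TRUE), class = "bout_gain")
}

#' @export
print.bout_gain <- function(x, ...) {
  if (!x$defined) cat("bout_gain: undefined (target lost)\n")
  else cat(sprintf("bout_gain: distance %.3f, orientation %.3f\n",
                   x$distance_gain, x$orientation_gain))
  invisible(x)
}

#' Convert prey tracks or prey ground truth to per-track tables
#'
#' Splits a [link_tracks()] result (or the generator's `prey_truth`) into a
#' list of per-track matrices with columns time (s), x, y (mm) — the form
#' consumed by [compute_gains()] and [assign_target()].
#'
#' @param prey_tracks a `prey_tracks` or `prey_truth` object.
#' @param px_per_mm image scale (required for `prey_tracks`).
#' @param frame_times frame times in s (required for `prey_tracks`).
#' @return list of numeric matrices (time, x, y).
#' @export
as_track_list <- function(prey_tracks, px_per_mm = NULL, frame_times = NULL) {
  if (inherits(prey_tracks, "prey_truth")) {
    n <- ncol(prey_tracks$x)
    return(lapply(seq_len(n), function(p)
      cbind(time = prey_tracks$time, x = prey_tracks$x[, p],
            y = prey_tracks$y[, p])))
  }
  stopifnot(inherits(prey_tracks, "prey_tracks"), !is.null(px_per_mm),
            !is.null(frame_times))
  pts <- prey_tracks$points
  lapply(split(pts, pts$track_id), function(d)
    cbind(time = frame_times[d$frame], x = d$x / px_per_mm,
          y = d$y / px_per_mm))
}

#' Assign the target prey of a hunting routine
#'
#' Among prey located within the reactive perceptive field at routine onset
#' (distance <= `max_distance` from the eyes' center, |azimuth| <=
#' `max_azimuth` from the heading), the target is the prey for which both
#' distance- and orientation-gain of the first two bouts are positive. Ties
#' (several prey satisfying the full criterion, common when prey lie in the
#' pursuit cone) are resolved toward the candidate with the most
#' positive-gain bouts over the whole routine, then the smallest
#' fish-target distance after the final bout, and flagged ambiguous.
#'
#' @param routine list/row with `onset`, `offset` (s).
#' @param tracks list of per-track matrices (time, x, y in mm), e.g. from a
#'   `prey_truth` via the generator, or [link_tracks()] output converted to
#'   mm; a `prey_truth` object is also accepted.
#' @param session a [behavior_session].
#' @param bouts data.frame of bouts (onset, offset) within the routine, in
#'   time order; at least 2 are required.
#' @param max_distance,max_azimuth reactive-field constants (mm, deg).
#' @return list with `target` (track index or `NA`), `ambiguous`,
#'   `candidates` (indices in the field), `gains` (first-two-bout gain sums
#'   for candidates).
#' @export
assign_target <- function(routine, tracks, session, bouts,
                          max_distance = 6, max_azimuth = 120) {
  if (inherits(tracks, "prey_truth")) tracks <- as_track_list(tracks)
  if (nrow(bouts) < 2L)
    return(list(target = NA_integer_, ambiguous = FALSE,
                candidates = integer(0), gains = numeric(0)))
  t0 <- routine$onset
  in_field <- logical(length(tracks))
  for (p in seq_along(tracks)) {
    pos <- track_position(tracks[[p]][, 2:3, drop = FALSE],
                          tracks[[p]][, 1], t0)
    if (any(is.na(pos))) next
    g <- target_geometry(session, pos, t0)
    in_field[p] <- g$distance <= max_distance && abs(g$azimuth) <= max_azimuth
  }
  cand <- which(in_field)
  if (length(cand) == 0L)
    return(list(target = NA_integer_, ambiguous = FALSE,
                candidates = integer(0), gains = numeric(0)))
  bo <- bouts[order(bouts$onset), ]
  score <- n_pos <- final_d <- rep(NA_real_, length(cand))
  okpos <- logical(length(cand))
  for (j in seq_along(cand)) {
    gl <- lapply(seq_len(nrow(bo)), function(b)
      compute_gains(session, tracks[[cand[j]]], bo[b, ]))
    if (!gl[[1]]$defined || !gl[[2]]$defined) next
    gg <- c(gl[[1]]$distance_gain, gl[[1]]$orientation_gain,
            gl[[2]]$distance_gain, gl[[2]]$orientation_gain)
    okpos[j] <- all(is.finite(gg)) && all(gg > 0)
    score[j] <- sum(gg)
    n_pos[j] <- sum(vapply(gl, function(g)
      isTRUE(g$distance_gain > 0 && g$orientation_gain > 0), TRUE))
    final_d[j] <- gl[[length(gl)]]$post_distance
  }
  hits <- which(okpos)
  if (length(hits) == 0L)
    return(list(target = NA_integer_, ambiguous = FALSE, candidates = cand,
                gains = score))
  best <- hits[order(-n_pos[hits], final_d[hits])][1]
  list(target = cand[best], ambiguous = length(hits) > 1L,
       candidates = cand, gains = score)
}

#' Classify the outcome of a hunting routine from event annotations
#'
#' A routine is an abort iff no capture event (ram or suction) falls within
#' its epoch; otherwise it is an attempt whose type is the capture event's
#' and whose success flag is set by an ingestion event. Capture-type scoring
#' is consumed as annotation (generator ground truth or a manual-annotation
#' file), never inferred from kinematics.
#'
#' @param routine list/row with `onset`, `offset` and optionally
#'   `routine_id`.
#' @param events data.frame with `routine_id` (optional), `type`
#'   (`ram`/`suction`/`ingestion`), `time`.
#' @return list with `outcome` ("abort"/"attempt"), `attempt_type`
#'   ("ram"/"suction"/NA), `success` (logical or NA), `label`.
#' @export
classify_outcome <- function(routine, events) {
  ev <- events
  if (!is.null(routine$routine_id) && "routine_id" %in% names(ev) &&
      nrow(ev) > 0)
    ev <- ev[!is.na(ev$routine_id) & ev$routine_id == routine$routine_id, ,
             drop = FALSE]
  if (nrow(ev) > 0)
    ev <- ev[ev$time >= routine$onset - 1e-9 &
               ev$time <= routine$offset + 1e-9, , drop = FALSE]
  cap <- ev[ev$type %in% c("ram", "suction"), , drop = FALSE]
  ing <- ev[ev$type == "ingestion", , drop = FALSE]
  if (nrow(cap) == 0L) {
    if (nrow(ing) > 0L)
      stop("inconsistent annotation: ingestion event without a capture event")
    return(list(outcome = "abort", attempt_type = NA_character_,
                success = NA, label = "abort"))
  }
  typ <- cap$type[which.min(cap$time)]
  suc <- nrow(ing) > 0L
  list(outcome = "attempt", attempt_type = typ, success = suc,
       label = paste0("attempt-", typ, "-", if (suc) "success" else "fail"))
}

#' Build an ethogram from classified routines
#'
#' Branch probabilities of the routine-outcome tree (abort vs attempt; ram
#' vs suction given attempt; success given attempt type), per fish and
#' pooled, with per-fish medians for group comparison.
#'
#' @param routines data.frame with columns `fish`, `outcome`
#'   ("abort"/"attempt"), `attempt_type`, `success` (may contain NAs for
#'   aborts).
#' @return object of class `ethogram`: list with `per_fish` (data.frame of
#'   per-fish branch probabilities and counts), `pooled` (named vector),
#'   `medians` (per-fish medians of each branch probability).
#' @export
build_ethogram <- function(routines) {
  stopifnot(all(c("fish", "outcome") %in% names(routines)))
  empty <- routines$fish[!routines$fish %in%
                           routines$fish[!is.na(routines$outcome)]]
  split_f <- split(routines, routines$fish)
  rows <- lapply(names(split_f), function(f) {
    d <- split_f[[f]]
    n <- nrow(d)
    if (n == 0L) {
      warning("fish ", f, " has zero routines; omitted")
      return(NULL)
    }
    na <- sum(d$outcome == "abort")
    att <- d[d$outcome == "attempt", , drop = FALSE]
    nat <- nrow(att)
    nram <- sum(att$attempt_type == "ram", na.rm = TRUE)
    nsuc <- sum(att$success, na.rm = TRUE)
    data.frame(fish = f, n_routines = n, n_abort = na, n_attempt = nat,
               p_abort = na / n, p_attempt = nat / n,
               p_ram_given_attempt = if (nat) nram / nat else NA_real_,
               p_suction_given_attempt = if (nat) 1 - nram / nat else
                 NA_real_,
               p_success_given_attempt = if (nat) nsuc / nat else NA_real_)
  })
  per_fish <- do.call(rbind, rows)
  n <- nrow(routines)
  na <- sum(routines$outcome == "abort")
  att <- routines[routines$outcome == "attempt", , drop = FALSE]
  nat <- nrow(att)
  nram <- sum(att$attempt_type == "ram", na.rm = TRUE)
  nsuc <- sum(att$success, na.rm = TRUE)
  pooled <- c(n_routines = n, p_abort = na / n, p_attempt = nat / n,
              p_ram_given_attempt = if (nat) nram / nat else NA_real_,
              p_suction_given_attempt = if (nat) 1 - nram / nat else
                NA_real_,
              p_success_given_attempt = if (nat) nsuc / nat else NA_real_)
  med <- vapply(per_fish[, grep("^p_", names(per_fish))],
                stats::median, 1, na.rm = TRUE)
  structure(list(per_fish = per_fish, pooled = pooled, medians = med),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat("ethogram:", x$pooled["n_routines"], "routines,",
      nrow(x$per_fish), "fish\n")
  cat(sprintf("  P(abort) = %.3f   P(attempt) = %.3f\n",
              x$pooled["p_abort"], x$pooled["p_attempt"]))
  cat(sprintf("  P(ram|attempt) = %.3f   P(suction|attempt) = %.3f\n",
              x$pooled["p_ram_given_attempt"],
              x$pooled["p_suction_given_attempt"]))
  cat(sprintf("  P(success|attempt) = %.3f\n",
              x$pooled["p_success_given_attempt"]))
  invisible(x)
}

#' Compare a branch probability between two cohorts
#'
#' Wilcoxon rank-sum test on per-fish branch probabilities of two ethograms
#' (the per-fish median values are the test observations).
#'
#' @param etho_a,etho_b [build_ethogram()] results.
#' @param branch column name, e.g. `"p_abort"`.
#' @return the `htest` object from [stats::wilcox.test()].
#' @export
compare_ethograms <- function(etho_a, etho_b, branch = "p_abort") {
  stats::wilcox.test(etho_a$per_fish[[branch]], etho_b$per_fish[[branch]],
                     exact = FALSE)
}

#' Summary statistics over classified routines
#'
#' Computes the fraction of routines containing a negative-gain bout
#' (negative distance- AND orientation-gain), split by outcome, plus routine
#' durations, bout counts, target geometry at onset, and the hunt initiation
#' rate.
#'
#' @param routines data.frame with `outcome`, `neg_gain_bout` (logical),
#'   `onset`, `offset` and optionally `n_bouts`, `onset_distance`,
#'   `onset_azimuth`.
#' @param session_minutes total observation time (min) for the initiation
#'   rate (NA to skip).
#' @return list with `neg_gain_fraction` (named: abort, attempt),
#'   `durations`, `bout_counts`, `onset_distance`, `onset_azimuth`,
#'   `hunt_rate_per_min`.
#' @export
summarize_routines <- function(routines, session_minutes = NA_real_) {
  ab <- routines$outcome == "abort"
  frac <- c(abort = if (any(ab)) mean(routines$neg_gain_bout[ab]) else
              NA_real_,
            attempt = if (any(!ab)) mean(routines$neg_gain_bout[!ab]) else
              NA_real_)
  list(neg_gain_fraction = frac,
       durations = routines$offset - routines$onset,
       bout_counts = routines$n_bouts,
       onset_distance = routines$onset_distance,
       onset_azimuth = routines$onset_azimuth,
       hunt_rate_per_min = if (is.na(session_minutes)) NA_real_ else
         nrow(routines) / session_minutes)
}
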