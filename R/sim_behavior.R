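# Synthetic free-swimming behavior generator.
#
# Emulates the statistical structure of a prey-capture assay: a single larva
# in a 35 mm dish performing discrete swim bouts, bimodal ocular vergence with
# convergence episodes marking hunting routines, ~80 prey particles with
# Ornstein-Uhlenbeck motion, and routines with configurable
# abort/attempt/success outcomes and per-bout pursuit gains. Every generated
# event is recorded in a ground-truth log against which the tracking and
# segmentation operators can be validated.

#' Configuration for the behavioral simulator
#'
#' Defaults describe the standard assay: a 35 mm Petri dish imaged at
#' 24.8 px/mm, fish kinematics at 700 Hz, full-frame prey video at 17.5 Hz
#' and around 80 prey particles.
#'
#' @param duration_s session length (s).
#' @param arena_diameter dish diameter (mm).
#' @param px_per_mm image scale (px/mm).
#' @param rate_hi kinematics sampling rate (Hz).
#' @param rate_lo prey-frame rate (Hz).
#' @param n_prey number of prey particles.
#' @param hunt_rate hunting-routine initiations per minute.
#' @param p_abort probability a routine is aborted before any capture attempt.
#' @param p_ram_given_attempt probability an attempt is a ram-like capture
#'   swim (otherwise suction).
#' @param p_success_given_attempt probability an attempt ingests the target.
#' @param neg_gain_rate_abort probability an aborted routine ends with a bout
#'   having negative distance- and orientation-gain.
#' @param neg_gain_rate_attempt same, for routines ending in an attempt.
#' @param vergence_baseline_deg,vergence_baseline_sd mean and SD (deg) of the
#'   non-hunting vergence mode.
#' @param vergence_hunting_deg,vergence_hunting_sd mean and SD (deg) of the
#'   hunting vergence mode.
#' @param bout_rate spontaneous bout rate outside hunts (bouts/s).
#' @param hunt_bout_interval interval between bout onsets within a routine (s).
#' @param bout_duration bout duration (s).
#' @param tail_peak_velocity peak cumulative tail angular velocity within a
#'   bout (deg/s).
#' @param prey_speed typical prey swimming speed (mm/s).
#' @param prey_tau velocity correlation time of prey motion (s).
#' @param escape_rate escape events per minute (outside hunts).
#' @param escape_displacement displacement of an escape event (mm).
#' @param eye_offset_mm distance from body centroid to the eyes' midpoint
#'   along the heading (mm).
#' @param seed integer seed; fanned out to independent per-subsystem streams.
#' @return object of class `behavior_sim_config` (a validated list).
#' @export
behavior_sim_config <- function(duration_s = 60,
                                arena_diameter = 35,
                                px_per_mm = 24.8,
                                rate_hi = 700,
                                rate_lo = 17.5,
                                n_prey = 80,
                                hunt_rate = 3,
                                p_abort = 0.6,
                                p_ram_given_attempt = 0.25,
                                p_success_given_attempt = 0.5,
                                neg_gain_rate_abort = 0.37,
                                neg_gain_rate_attempt = 0.09,
                                vergence_baseline_deg = 16,
                                vergence_baseline_sd = 3,
                                vergence_hunting_deg = 52,
                                vergence_hunting_sd = 4,
                                bout_rate = 1,
                                hunt_bout_interval = 0.45,
                                bout_duration = 0.15,
                                tail_peak_velocity = 3000,
                                prey_speed = 1,
                                prey_tau = 1,
                                escape_rate = 0,
                                escape_displacement = 10,
                                eye_offset_mm = 0.25,
                                seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_abort, p_ram_given_attempt, p_success_given_attempt,
             neg_gain_rate_abort, neg_gain_rate_attempt)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (arena_diameter <= 0) stop("arena_diameter must be > 0")
  if (rate_hi <= 0 || rate_lo <= 0 || duration_s <= 0)
    stop("rates and duration must be > 0")
  if (n_prey == 0 && hunt_rate > 0)
    stop("n_prey = 0 with hunt_rate > 0: no targets to hunt")
  if (vergence_hunting_deg <= vergence_baseline_deg)
    stop("hunting vergence mode must exceed the baseline mode")
  structure(cfg, class = "behavior_sim_config")
}

#' @export
print.behavior_sim_config <- function(x, ...) {
  cat("behavior_sim_config:", x$duration_s, "s,", x$n_prey, "prey,",
      x$hunt_rate, "hunts/min, p_abort =", x$p_abort, "\n")
  invisible(x)
}

#' Synchronized kinematic time series of one session
#'
#' Constructor for the `behavior_session` container holding body centroid
#' (mm), heading and eye angles (deg, clockwise-positive), the 8 tail
#' inter-segment angles and the derived vergence channel (left minus right
#' eye angle), all uniformly sampled.
#'
#' @param time sample times (s).
#' @param body_x,body_y body centroid (mm, arena coordinates).
#' @param heading heading (deg).
#' @param left_eye,right_eye eye angles relative to heading (deg).
#' @param tail_angles matrix (n x 8) of inter-segment angles (deg).
#' @param sampling_rate Hz.
#' @param px_per_mm image scale.
#' @param eye_offset_mm body-centroid-to-eyes-center distance (mm).
#' @param arena_diameter mm.
#' @return object of class `behavior_session`.
#' @export
behavior_session <- function(time, body_x, body_y, heading, left_eye,
                             right_eye, tail_angles, sampling_rate,
                             px_per_mm = 24.8, eye_offset_mm = 0.25,
                             arena_diameter = 35) {
  n <- length(time)
  stopifnot(length(body_x) == n, length(body_y) == n, length(heading) == n,
            length(left_eye) == n, length(right_eye) == n,
            nrow(tail_angles) == n, ncol(tail_angles) == 8L)
  structure(list(time = time, body_x = body_x, body_y = body_y,
                 heading = heading, left_eye = left_eye,
                 right_eye = right_eye, vergence = left_eye - right_eye,
                 tail_angles = tail_angles, sampling_rate = sampling_rate,
                 px_per_mm = px_per_mm, eye_offset_mm = eye_offset_mm,
                 arena_diameter = arena_diameter),
            class = "behavior_session")
}

#' @export
print.behavior_session <- function(x, ...) {
  cat("behavior_session:", length(x$time), "samples at", x$sampling_rate,
      "Hz (", round(max(x$time), 1), "s )\n")
  invisible(x)
}

# eyes-center position (mm) for every sample of a session
eyes_center <- function(session, idx = seq_along(session$time)) {
  u <- ang_unit(session$heading[idx])
  cbind(session$body_x[idx] + session$eye_offset_mm * u[, 1],
        session$body_y[idx] + session$eye_offset_mm * u[, 2])
}

# --- prey motion -----------------------------------------------------------

# Ornstein-Uhlenbeck velocity, reflecting boundary at arena radius - margin.
sim_prey_paths <- function(n_prey, t_lo, radius, speed, tau, seed) {
  n <- length(t_lo)
  px <- matrix(0, n, max(n_prey, 1L))
  py <- matrix(0, n, max(n_prey, 1L))
  if (n_prey == 0L) {
    return(list(x = px[, 0, drop = FALSE], y = py[, 0, drop = FALSE]))
  }
  with_seed(seed, {
    dt <- diff(t_lo[1:2])
    sig <- speed / sqrt(2)              # per-component stationary velocity SD
    a <- exp(-dt / tau)
    b <- sig * sqrt(1 - a^2)
    r0 <- radius * sqrt(stats::runif(n_prey))
    th <- stats::runif(n_prey, 0, 360)
    x <- r0 * cos(deg2rad(th)); y <- r0 * sin(deg2rad(th))
    vx <- stats::rnorm(n_prey, 0, sig); vy <- stats::rnorm(n_prey, 0, sig)
    for (k in seq_len(n)) {
      px[k, ] <- x; py[k, ] <- y
      x <- x + vx * dt; y <- y + vy * dt
      rr <- sqrt(x^2 + y^2)
      out <- rr > radius
      if (any(out)) {                    # reflect position and velocity
        nx <- x[out] / rr[out]; ny <- y[out] / rr[out]
        over <- rr[out] - radius
        x[out] <- x[out] - 2 * over * nx
        y[out] <- y[out] - 2 * over * ny
        dot <- vx[out] * nx + vy[out] * ny
        vx[out] <- vx[out] - 2 * dot * nx
        vy[out] <- vy[out] - 2 * dot * ny
      }
      vx <- a * vx + b * stats::rnorm(n_prey)
      vy <- a * vy + b * stats::rnorm(n_prey)
    }
  })
  list(x = px, y = py)
}

# smooth windowed translation of one prey path so that it passes through
# `target_pos` at time `t0`; ramps of `ramp` seconds on each side of
# [t0 - lead, t_end + lag].
shift_prey_path <- function(prey, t_lo, p, t0, t_end, target_pos,
                            lead = 1, lag = 1, ramp = 1) {
  cur <- c(stats::approx(t_lo, prey$x[, p], t0, rule = 2)$y,
           stats::approx(t_lo, prey$y[, p], t0, rule = 2)$y)
  delta <- target_pos - cur
  w <- rep(0, length(t_lo))
  a <- t0 - lead; b <- t_end + lag
  w[t_lo >= a & t_lo <= b] <- 1
  rise <- t_lo >= a - ramp & t_lo < a
  w[rise] <- (1 - cos(pi * (t_lo[rise] - (a - ramp)) / ramp)) / 2
  fall <- t_lo > b & t_lo <= b + ramp
  w[fall] <- (1 + cos(pi * (t_lo[fall] - b) / ramp)) / 2
  prey$x[, p] <- prey$x[, p] + delta[1] * w
  prey$y[, p] <- prey$y[, p] + delta[2] * w
  prey
}

prey_at <- function(prey, t_lo, p, t) {
  c(stats::approx(t_lo, prey$x[, p], t, rule = 2)$y,
    stats::approx(t_lo, prey$y[, p], t, rule = 2)$y)
}

# --- main generator --------------------------------------------------------

#' Simulate a free-swimming behavioral session
#'
#' Generates a ground-truthed session: bout-structured locomotion, bimodal
#' vergence with convergence episodes, Brownian-like prey, and hunting
#' routines whose targets satisfy the reactive-perceptive-field criterion
#' (initial range <= 6 mm, |azimuth| <= 120 deg, positive gains on the first
#' two bouts) by construction. Aborted routines end, with configurable
#' probability, in a bout with negative distance- and orientation-gain
#' followed by vergence relaxation.
#'
#' @param config a [behavior_sim_config()].
#' @return list with components `session` ([behavior_session]), `prey`
#'   (class `prey_truth`: `time`, `x`, `y` matrices of true prey positions in
#'   mm) and `log` (class `ground_truth_log`: data.frames `routines`,
#'   `bouts`, `events`, `escapes`, plus the generator's own vergence
#'   threshold `vergence_threshold`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  cfg <- config
  dt_hi <- 1 / cfg$rate_hi
  t_hi <- seq(0, cfg$duration_s, by = dt_hi)
  n_hi <- length(t_hi)
  t_lo <- seq(0, cfg$duration_s, by = 1 / cfg$rate_lo)
  radius <- cfg$arena_diameter / 2 - 1    # 1 mm wall margin for prey
  prey <- sim_prey_paths(cfg$n_prey, t_lo, radius, cfg$prey_speed,
                         cfg$prey_tau, fanout_seed(cfg$seed, "prey"))
  thr_gen <- cfg$vergence_hunting_deg - cfg$vergence_hunting_sd

  routines <- list(); bouts <- list(); events <- list(); escapes <- list()
  # event segments used to build the position/heading series
  seg <- list()
  with_seed(fanout_seed(cfg$seed, "routines"), {
    E <- c(stats::runif(1, -3, 3), stats::runif(1, -3, 3))
    heading <- stats::runif(1, 0, 360)
    t_cur <- 0.5
    rid <- 0L; bid <- 0L
    prey_free_at <- rep(-Inf, max(cfg$n_prey, 1L))
    fish_max_r <- cfg$arena_diameter / 2 - 3

    add_bout <- function(t_on, E0, h0, E1, h1, routine_id = NA_integer_,
                         gain_d = NA_real_, gain_o = NA_real_,
                         kind = "swim") {
      bid <<- bid + 1L
      bouts[[bid]] <<- data.frame(
        bout_id = bid, routine_id = routine_id, onset = t_on,
        offset = t_on + cfg$bout_duration,
        displacement = sqrt(sum((E1 - E0)^2)),
        turn = wrap180(h1 - h0), gain_d = gain_d, gain_o = gain_o,
        kind = kind)
      seg[[length(seg) + 1L]] <<- list(t_on = t_on,
                                       t_off = t_on + cfg$bout_duration,
                                       E0 = E0, E1 = E1, h0 = h0, h1 = h1)
    }

    next_hunt <- if (cfg$hunt_rate > 0)
      t_cur + stats::rexp(1, cfg$hunt_rate / 60) else Inf
    next_escape <- if (cfg$escape_rate > 0)
      t_cur + stats::rexp(1, cfg$escape_rate / 60) else Inf

    while (t_cur < cfg$duration_s - 2) {
      next_spont <- if (cfg$bout_rate > 0)
        t_cur + stats::rexp(1, cfg$bout_rate) else Inf
      t_next <- min(next_hunt, next_escape, next_spont)
      if (t_next > cfg$duration_s - 2) break

      if (t_next == next_hunt) {
        # ----- hunting routine -----
        rid <- rid + 1L
        t0 <- t_next
        outcome <- if (stats::runif(1) < cfg$p_abort) "abort" else "attempt"
        att_type <- if (outcome == "attempt") {
          if (stats::runif(1) < cfg$p_ram_given_attempt) "ram" else "suction"
        } else NA_character_
        success <- if (outcome == "attempt")
          stats::runif(1) < cfg$p_success_given_attempt else NA
        neg_rate <- if (outcome == "abort") cfg$neg_gain_rate_abort
                    else cfg$neg_gain_rate_attempt
        inject_neg <- stats::runif(1) < neg_rate
        n_bouts <- 3L + stats::rpois(1, if (outcome == "abort") 1 else 2)

        # place a target prey within the reactive perceptive field
        side <- sample(c(-1, 1), 1)
        az0 <- side * stats::runif(1, 25, 95)
        r0 <- stats::runif(1, 2.5, 5.5)
        P0 <- E + r0 * c(cos(deg2rad(heading + az0)),
                         sin(deg2rad(heading + az0)))
        if (sqrt(sum(P0^2)) > radius - 0.5) {   # keep target inside the dish
          P0 <- P0 * (radius - 0.5) / sqrt(sum(P0^2))
          r0 <- sqrt(sum((P0 - E)^2))
          az0 <- wrap180(vec_angle(P0[1] - E[1], P0[2] - E[2]) - heading)
        }
        # bout schedule
        b_on <- t0 + 0.12 + (seq_len(n_bouts) - 1L) * cfg$hunt_bout_interval +
          stats::runif(n_bouts, -0.04, 0.04)
        t_end <- max(b_on) + cfg$bout_duration + 0.25
        p_tgt <- if (cfg$n_prey > 0) {
          free <- which(prey_free_at < t0 - 2)
          if (length(free) == 0) which.min(prey_free_at) else free[1]
        } else NA_integer_
        prey <- shift_prey_path(prey, t_lo, p_tgt, t0, t_end, P0)
        prey_free_at[p_tgt] <- t_end + 3

        gains_d <- stats::runif(n_bouts, 0.2, 0.5)
        gains_o <- stats::runif(n_bouts, 0.25, 0.6)
        if (inject_neg) {                 # pursuit-abandoning final bout
          gains_d[n_bouts] <- -stats::runif(1, 0.2, 0.6)
          gains_o[n_bouts] <- -stats::runif(1, 0.3, 1.0)
        }
        Eb <- E; hb <- heading
        for (b in seq_len(n_bouts)) {
          ton <- b_on[b]; toff <- ton + cfg$bout_duration
          Pa <- prey_at(prey, t_lo, p_tgt, ton)
          Pb <- prey_at(prey, t_lo, p_tgt, toff)
          pre_d <- sqrt(sum((Pa - Eb)^2))
          pre_az <- wrap180(vec_angle(Pa[1] - Eb[1], Pa[2] - Eb[2]) - hb)
          post_d <- max(pre_d * (1 - gains_d[b]), 0.25)
          post_az <- pre_az * (1 - gains_o[b])
          dirv <- Pb - Eb
          dirv <- dirv / sqrt(sum(dirv^2))
          E1 <- Pb - post_d * dirv
          h1 <- wrap180(vec_angle(Pb[1] - E1[1], Pb[2] - E1[2]) - post_az)
          add_bout(ton, Eb, hb, E1, h1, routine_id = rid,
                   gain_d = gains_d[b], gain_o = gains_o[b], kind = "hunt")
          Eb <- E1; hb <- h1
        }
        E <- Eb; heading <- hb
        # capture events for attempts (final bout is the capture swim)
        if (outcome == "attempt") {
          events[[length(events) + 1L]] <- data.frame(
            routine_id = rid, type = att_type, time = b_on[n_bouts])
          if (isTRUE(success)) {
            events[[length(events) + 1L]] <- data.frame(
              routine_id = rid, type = "ingestion",
              time = b_on[n_bouts] + cfg$bout_duration + 0.02)
          }
        }
        label <- if (outcome == "abort") "abort" else
          paste0("attempt-", att_type, "-", if (success) "success" else "fail")
        # true onset/offset: crossings of the generator's hunting threshold
        ramp_up <- 0.015; ramp_dn <- 0.08
        fr <- (thr_gen - cfg$vergence_baseline_deg) /
          (cfg$vergence_hunting_deg - cfg$vergence_baseline_deg)
        up_frac <- acos(1 - 2 * fr) / pi
        onset_true <- t0 + up_frac * ramp_up
        offset_true <- t_end + (1 - up_frac) * ramp_dn
        routines[[rid]] <- data.frame(
          routine_id = rid, t_ramp_start = t0, onset = onset_true,
          offset = offset_true, plateau_end = t_end,
          target = p_tgt, outcome = outcome, attempt_type = att_type,
          success = success, label = label, side = side,
          dominant_eye = if (side > 0) "left" else "right",
          n_bouts = n_bouts, neg_gain_bout = inject_neg,
          onset_distance = r0, onset_azimuth = az0)
        t_cur <- t_end + 1.5
        next_hunt <- t_cur + stats::rexp(1, cfg$hunt_rate / 60)
        if (next_escape < t_cur)
          next_escape <- t_cur + stats::rexp(1, cfg$escape_rate / 60)
      } else if (t_next == next_escape) {
        # ----- escape event: fast, large displacement -----
        h1 <- wrap180(heading + stats::runif(1, 120, 240))
        to_center <- vec_angle(-E[1], -E[2])
        if (sqrt(sum(E^2)) > fish_max_r - cfg$escape_displacement)
          h1 <- to_center
        E1 <- E + cfg$escape_displacement * c(cos(deg2rad(h1)),
                                              sin(deg2rad(h1)))
        if (sqrt(sum(E1^2)) > fish_max_r)
          E1 <- E1 * fish_max_r / sqrt(sum(E1^2))
        seg[[length(seg) + 1L]] <- list(t_on = t_next, t_off = t_next + 0.1,
                                        E0 = E, E1 = E1, h0 = heading,
                                        h1 = h1)
        escapes[[length(escapes) + 1L]] <- data.frame(
          onset = t_next, offset = t_next + 0.1,
          displacement = sqrt(sum((E1 - E)^2)))
        E <- E1; heading <- h1
        t_cur <- t_next + 0.3
        next_escape <- t_cur + stats::rexp(1, cfg$escape_rate / 60)
      } else {
        # ----- spontaneous bout -----
        turn <- stats::rnorm(1, 0, 30)
        if (sqrt(sum(E^2)) > fish_max_r) {
          to_center <- vec_angle(-E[1], -E[2])
          turn <- wrap180(to_center - heading)
        }
        h1 <- wrap180(heading + turn)
        disp <- stats::runif(1, 0.5, 1.2)
        E1 <- E + disp * c(cos(deg2rad(h1)), sin(deg2rad(h1)))
        if (sqrt(sum(E1^2)) > fish_max_r)
          E1 <- E1 * fish_max_r / sqrt(sum(E1^2))
        add_bout(t_next, E, heading, E1, h1)
        E <- E1; heading <- h1
        t_cur <- t_next + cfg$bout_duration + 0.05
      }
    }
  })

  routines <- if (length(routines)) do.call(rbind, routines) else
    data.frame(routine_id = integer(0), t_ramp_start = numeric(0),
               onset = numeric(0), offset = numeric(0),
               plateau_end = numeric(0), target = integer(0),
               outcome = character(0), attempt_type = character(0),
               success = logical(0), label = character(0), side = numeric(0),
               dominant_eye = character(0), n_bouts = integer(0),
               neg_gain_bout = logical(0), onset_distance = numeric(0),
               onset_azimuth = numeric(0))
  bouts <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(bout_id = integer(0), routine_id = integer(0),
               onset = numeric(0), offset = numeric(0),
               displacement = numeric(0), turn = numeric(0),
               gain_d = numeric(0), gain_o = numeric(0), kind = character(0))
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(routine_id = integer(0), type = character(0),
               time = numeric(0))
  escapes <- if (length(escapes)) do.call(rbind, escapes) else
    data.frame(onset = numeric(0), offset = numeric(0),
               displacement = numeric(0))

  # ----- assemble the high-rate kinematic series -----
  pos_x <- numeric(n_hi); pos_y <- numeric(n_hi); hdg <- numeric(n_hi)
  segs <- seg[order(vapply(seg, function(s) s$t_on, 1))]
  # piecewise fill: constant between movement segments, raised-cosine within
  E_cur <- if (length(segs)) segs[[1]]$E0 else c(0, 0)
  h_cur <- if (length(segs)) segs[[1]]$h0 else 0
  i_cur <- 1L
  for (s in segs) {
    i_on <- min(max(1L, floor(s$t_on / dt_hi) + 1L), n_hi)
    i_off <- min(max(i_on, ceiling(s$t_off / dt_hi) + 1L), n_hi)
    if (i_on > i_cur) {
      pos_x[i_cur:(i_on - 1L)] <- E_cur[1]
      pos_y[i_cur:(i_on - 1L)] <- E_cur[2]
      hdg[i_cur:(i_on - 1L)] <- h_cur
    }
    ii <- i_on:i_off
    u <- (t_hi[ii] - s$t_on) / (s$t_off - s$t_on)
    u <- pmin(pmax(u, 0), 1)
    w <- (1 - cos(pi * u)) / 2
    pos_x[ii] <- s$E0[1] + w * (s$E1[1] - s$E0[1])
    pos_y[ii] <- s$E0[2] + w * (s$E1[2] - s$E0[2])
    hdg[ii] <- s$h0 + w * wrap180(s$h1 - s$h0)
    E_cur <- s$E1; h_cur <- s$h1
    i_cur <- i_off + 1L
  }
  if (i_cur <= n_hi) {
    pos_x[i_cur:n_hi] <- E_cur[1]
    pos_y[i_cur:n_hi] <- E_cur[2]
    hdg[i_cur:n_hi] <- h_cur
  }
  hdg <- hdg %% 360

  # ----- vergence / eye channels -----
  v0 <- rep(cfg$vergence_baseline_deg, n_hi)     # noiseless profile
  sd_v <- rep(cfg$vergence_baseline_sd, n_hi)
  fdom <- rep(0.5, n_hi)                          # left-eye share of vergence
  amp <- cfg$vergence_hunting_deg - cfg$vergence_baseline_deg
  ramp_up <- 0.015; ramp_dn <- 0.08
  if (nrow(routines) > 0) {
    for (r in seq_len(nrow(routines))) {
      t0 <- routines$t_ramp_start[r]; t1 <- routines$plateau_end[r]
      ii <- which(t_hi >= t0 & t_hi <= t1 + ramp_dn)
      tt <- t_hi[ii]
      w <- rep(1, length(ii))
      wu <- tt < t0 + ramp_up
      w[wu] <- (1 - cos(pi * (tt[wu] - t0) / ramp_up)) / 2
      wd <- tt > t1
      w[wd] <- (1 + cos(pi * (tt[wd] - t1) / ramp_dn)) / 2
      v0[ii] <- cfg$vergence_baseline_deg + amp * w
      sd_v[ii] <- cfg$vergence_baseline_sd +
        (cfg$vergence_hunting_sd - cfg$vergence_baseline_sd) * w
      fL <- if (routines$side[r] > 0) 0.68 else 0.32
      fdom[ii] <- 0.5 + (fL - 0.5) * w
    }
  }
  verg <- with_seed(fanout_seed(cfg$seed, "vergence"),
                    v0 + stats::rnorm(n_hi) * sd_v)
  gaze <- with_seed(fanout_seed(cfg$seed, "gaze"), {
    g <- stats::rnorm(n_hi, 0, 1)
    as.numeric(stats::filter(g, 0.99, method = "recursive")) * sqrt(1 - 0.99^2)
  })
  left_eye <- fdom * verg + gaze
  right_eye <- gaze - (1 - fdom) * verg

  # ----- tail channels -----
  tail <- with_seed(fanout_seed(cfg$seed, "tail"), {
    m <- matrix(stats::rnorm(n_hi * 8L), n_hi, 8L)
    for (j in 1:8) m[, j] <-
      as.numeric(stats::filter(m[, j], 0.97, method = "recursive")) *
      sqrt(1 - 0.97^2) * 0.3
    m
  })
  f_tb <- 22                                   # tail-beat frequency (Hz)
  amp_seg <- cfg$tail_peak_velocity / (2 * pi * f_tb) / sum((1:8) / 8)
  edge <- 0.02                                 # sharp 20 ms on/off ramps
  if (nrow(bouts) > 0) {
    sgn <- with_seed(fanout_seed(cfg$seed, "tailsign"),
                     sample(c(-1, 1), nrow(bouts), replace = TRUE))
    for (b in seq_len(nrow(bouts))) {
      ii <- which(t_hi >= bouts$onset[b] & t_hi <= bouts$offset[b])
      if (!length(ii)) next
      tau <- t_hi[ii] - bouts$onset[b]
      Tb <- bouts$offset[b] - bouts$onset[b]
      w <- rep(1, length(ii))                  # Tukey window
      e1 <- tau < edge
      w[e1] <- (1 - cos(pi * tau[e1] / edge)) / 2
      e2 <- tau > Tb - edge
      w[e2] <- (1 + cos(pi * (tau[e2] - (Tb - edge)) / edge)) / 2
      osc <- sin(2 * pi * f_tb * tau) * w * sgn[b]
      for (j in 1:8) tail[ii, j] <- tail[ii, j] + amp_seg * (j / 8) * osc
    }
  }

  body_x <- pos_x - cfg$eye_offset_mm * cos(deg2rad(hdg))
  body_y <- pos_y - cfg$eye_offset_mm * sin(deg2rad(hdg))
  session <- behavior_session(t_hi, body_x, body_y, hdg, left_eye, right_eye,
                              tail, cfg$rate_hi, cfg$px_per_mm,
                              cfg$eye_offset_mm, cfg$arena_diameter)
  prey_truth <- structure(list(time = t_lo, x = prey$x, y = prey$y,
                               px_per_mm = cfg$px_per_mm,
                               arena_diameter = cfg$arena_diameter),
                          class = "prey_truth")
  log <- structure(list(routines = routines, bouts = bouts, events = events,
                        escapes = escapes, vergence_threshold = thr_gen,
                        merge_events = 0L, config = cfg),
                   class = "ground_truth_log")
  list(session = session, prey = prey_truth, log = log)
}

#' @export
print.ground_truth_log <- function(x, ...) {
  cat("ground_truth_log:", nrow(x$routines), "routines,", nrow(x$bouts),
      "bouts,", nrow(x$escapes), "escapes\n")
  if (nrow(x$routines)) print(table(x$routines$label))
  invisible(x)
}

#' Simulate classified routine outcomes for a cohort of fish
#'
#' Outcome-level generator used for ethogram statistics at cohort scale: it
#' emits, per fish, hunting-routine records with capture-event annotation
#' rows drawn from the branch probabilities, without simulating kinematics.
#' The annotations feed [classify_outcome()] and [build_ethogram()].
#'
#' @param n_fish number of fish.
#' @param routines_per_fish routines per fish (recycled).
#' @param p_abort,p_ram_given_attempt,p_success_given_attempt branch
#'   probabilities.
#' @param neg_gain_rate_abort,neg_gain_rate_attempt probability that a
#'   routine of the given outcome contains a negative-gain bout.
#' @param seed integer seed.
#' @return list with `epochs` (data.frame: `fish`, `routine_id`, `onset`,
#'   `offset`, `neg_gain_bout`, true `label`) and `events` (data.frame:
#'   `routine_id`, `type`, `time`).
#' @export
simulate_outcome_cohort <- function(n_fish, routines_per_fish,
                                    p_abort = 0.6,
                                    p_ram_given_attempt = 0.25,
                                    p_success_given_attempt = 0.5,
                                    neg_gain_rate_abort = 0.37,
                                    neg_gain_rate_attempt = 0.09,
                                    seed = 1L) {
  stopifnot(all(c(p_abort, p_ram_given_attempt, p_success_given_attempt,
                  neg_gain_rate_abort, neg_gain_rate_attempt) >= 0))
  nr <- rep_len(routines_per_fish, n_fish)
  with_seed(seed, {
    rows <- list(); evs <- list(); rid <- 0L
    for (f in seq_len(n_fish)) {
      for (k in seq_len(nr[f])) {
        rid <- rid + 1L
        onset <- (rid - 1L) * 10
        offset <- onset + stats::runif(1, 1.5, 4)
        abort <- stats::runif(1) < p_abort
        if (abort) {
          neg <- stats::runif(1) < neg_gain_rate_abort
          rows[[rid]] <- data.frame(fish = f, routine_id = rid,
                                    onset = onset, offset = offset,
                                    neg_gain_bout = neg, label = "abort")
        } else {
          typ <- if (stats::runif(1) < p_ram_given_attempt) "ram" else
            "suction"
          suc <- stats::runif(1) < p_success_given_attempt
          neg <- stats::runif(1) < neg_gain_rate_attempt
          rows[[rid]] <- data.frame(
            fish = f, routine_id = rid, onset = onset, offset = offset,
            neg_gain_bout = neg,
            label = paste0("attempt-", typ, "-",
                           if (suc) "success" else "fail"))
          evs[[length(evs) + 1L]] <- data.frame(
            routine_id = rid, type = typ,
            time = offset - stats::runif(1, 0.2, 0.6))
          if (suc) evs[[length(evs) + 1L]] <- data.frame(
            routine_id = rid, type = "ingestion", time = offset - 0.05)
        }
      }
    }
    list(epochs = do.call(rbind, rows),
         events = if (length(evs)) do.call(rbind, evs) else
           data.frame(routine_id = integer(0), type = character(0),
                      time = numeric(0)))
  })
}
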