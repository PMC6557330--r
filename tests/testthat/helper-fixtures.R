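# Shared fixtures, generated in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# short free-swimming session with frequent hunts
fixture_session <- function() {
  memo("session", simulate_session(
    behavior_sim_config(duration_s = 8, hunt_rate = 20, seed = 7)))
}

# compact calcium recording (fewer cells/repeats than the defaults)
fixture_calcium <- function() {
  memo("calcium", simulate_calcium(calcium_sim_config(
    n_cells = c("aCh-A" = 25, "pCh-A" = 15, "OT" = 30, "other" = 10),
    n_repeats = 12, seed = 11)))
}

# hand-built session: stationary fish at a fixed pose, n samples
pose_session <- function(heading = 30, left = 18, right = -18,
                         tail = rep(0, 8), n = 2, body = c(0, 0),
                         rate = 700) {
  behavior_session(time = (seq_len(n) - 1) / rate,
                   body_x = rep(body[1], n), body_y = rep(body[2], n),
                   heading = rep(heading, n),
                   left_eye = rep(left, n), right_eye = rep(right, n),
                   tail_angles = matrix(rep(tail, each = n), n, 8),
                   sampling_rate = rate)
}

# clean background matching the renderer for a given frame stack element
stack_background <- function(stack, k) {
  arena_px <- 2 * (stack$frame_center[1] - 0.5)
  render_background(nrow(stack$frames[[k]]), ncol(stack$frames[[k]]),
                    stack$frame_center, arena_px / 2, stack$origin[k, ])
}

# brute-force minimum-cost assignment by permutation enumeration (<= 6 rows)
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 6)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  best <- Inf
  for (p in perms(seq_len(m)))
    best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
  best
}

assignment_cost <- function(cost, a) {
  sum(cost[cbind(which(a > 0), a[a > 0])])
}

wrap180_t <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# minimal hand-built recording: 1 Hz frames, one GO prey-spot epoch with a
# convergence at t = 12, three NO-GO epochs whose matched windows hold known
# values
hand_cmi_setup <- function(go_val = 3, nogo_vals = c(0, 1, 2)) {
  ft <- seq(0.5, 99.5, by = 1)
  Fz <- matrix(0, 1, length(ft))
  Fz[1, 11:14] <- go_val               # [10, 14] s window around t = 12
  Fz[1, 31:34] <- nogo_vals[1]         # epoch-relative windows in NO-GO
  Fz[1, 51:54] <- nogo_vals[2]
  Fz[1, 71:74] <- nogo_vals[3]
  activity <- structure(list(F = Fz, time = ft, rois = NULL, flat = FALSE),
                        class = "activity_matrix")
  stim <- data.frame(trial_id = 1:4, type = "spot_cw",
                     onset = c(10, 30, 50, 70),
                     offset = c(15, 35, 55, 75),
                     go = c(TRUE, FALSE, FALSE, FALSE),
                     conv_time = c(12, NA, NA, NA),
                     conv_side = c("left", NA, NA, NA))
  trials <- structure(list(
    stimuli = stim,
    convergences = data.frame(time = 12, side = "left",
                              spontaneous = FALSE)),
    class = "trial_table")
  list(activity = activity, trials = trials)
}


# builds a session whose eyes-center moves from the (pre_d, pre_az) to the
# (post_d, post_az) geometry relative to a fixed target at `target`,
# heading 0 throughout; returns the session, target track and one bout
two_pose_scene <- function(pre_d, pre_az, post_d, post_az,
                           target = c(6, 1)) {
  rate <- 700
  n <- 200
  E_pre <- target - pre_d * c(cos(pre_az * pi / 180),
                              sin(pre_az * pi / 180))
  E_post <- target - post_d * c(cos(post_az * pi / 180),
                                sin(post_az * pi / 180))
  half <- n / 2
  ex <- c(rep(E_pre[1], half), rep(E_post[1], half))
  ey <- c(rep(E_pre[2], half), rep(E_post[2], half))
  ses <- behavior_session(time = (seq_len(n) - 1) / rate,
                          body_x = ex - 0.25, body_y = ey,
                          heading = rep(0, n),
                          left_eye = rep(8, n), right_eye = rep(-8, n),
                          tail_angles = matrix(0, n, 8),
                          sampling_rate = rate)
  list(session = ses,
       track = cbind(time = c(0, 1), x = rep(target[1], 2),
                     y = rep(target[2], 2)),
       bout = list(onset = 0.02, offset = (n - 2) / rate))
}

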