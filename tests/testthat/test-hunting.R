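test_that("gain arithmetic matches the fraction-eliminated definition", {
  s <- two_pose_scene(4, 30, 4, 30)
  g <- compute_gains(s$session, s$track, s$bout)
  expect_equal(g$distance_gain, 0, tolerance = 1e-9)
  expect_equal(g$orientation_gain, 0, tolerance = 1e-9)

  s <- two_pose_scene(4, 30, 2, 15)
  g <- compute_gains(s$session, s$track, s$bout)
  expect_equal(g$distance_gain, 0.5, tolerance = 1e-9)
  expect_equal(g$orientation_gain, 0.5, tolerance = 1e-9)

  s <- two_pose_scene(3, 20, 4.5, 40)
  g <- compute_gains(s$session, s$track, s$bout)
  expect_equal(g$distance_gain, -0.5, tolerance = 1e-9)
  expect_equal(g$orientation_gain, -1, tolerance = 1e-9)
  expect_true(g$distance_gain < 0 && g$orientation_gain < 0)
})

test_that("a dead target track yields an undefined, flagged gain", {
  s <- two_pose_scene(4, 30, 2, 15)
  dead <- cbind(time = c(5, 6), x = c(1, 1), y = c(1, 1))
  g <- compute_gains(s$session, dead, s$bout)
  expect_false(g$defined)
  expect_true(is.na(g$distance_gain))
})

test_that("gains are invariant under rigid scene transforms", {
  set.seed(21)
  for (r in 1:200) {
    pre_d <- runif(1, 1, 6); pre_az <- runif(1, -110, 110)
    post_d <- runif(1, 0.5, 6); post_az <- pre_az * runif(1, -1, 1)
    s <- two_pose_scene(pre_d, pre_az, post_d, post_az)
    g0 <- compute_gains(s$session, s$track, s$bout)
    th <- runif(1, 0, 360); dx <- runif(1, -5, 5); dy <- runif(1, -5, 5)
    R <- matrix(c(cos(th * pi / 180), sin(th * pi / 180),
                  -sin(th * pi / 180), cos(th * pi / 180)), 2, 2)
    ses <- s$session
    p <- cbind(ses$body_x, ses$body_y) %*% t(R)
    ses$body_x <- p[, 1] + dx
    ses$body_y <- p[, 2] + dy
    ses$heading <- (ses$heading + th) %% 360
    tt <- s$track
    q <- tt[, 2:3] %*% t(R)
    tt[, 2] <- q[, 1] + dx
    tt[, 3] <- q[, 2] + dy
    g1 <- compute_gains(ses, tt, s$bout)
    expect_equal(g1$distance_gain, g0$distance_gain, tolerance = 1e-9)
    expect_equal(g1$orientation_gain, g0$orientation_gain,
                 tolerance = 1e-9)
  }
})

test_that("target assignment: empty field, unique candidate, id permutation", {
  sim <- fixture_session()
  tr <- sim$log$routines[1, ]
  tb <- sim$log$bouts
  eb <- tb[!is.na(tb$routine_id) & tb$routine_id == tr$routine_id, ]
  # all prey far outside the field -> none
  far <- lapply(1:5, function(p)
    cbind(time = c(0, 100), x = c(20 + p, 20 + p), y = c(20, 20)))
  res <- assign_target(tr, far, sim$session, eb)
  expect_true(is.na(res$target))
  # fewer than 2 bouts -> no target
  res1 <- assign_target(tr, as_track_list(sim$prey), sim$session, eb[1, ])
  expect_true(is.na(res1$target))
  # full track set: recovers the intended target
  res2 <- assign_target(tr, as_track_list(sim$prey), sim$session, eb)
  expect_identical(res2$target, tr$target)
  # permutation of track ids maps the assignment accordingly
  tracks <- as_track_list(sim$prey)
  perm <- rev(seq_along(tracks))
  res3 <- assign_target(tr, tracks[perm], sim$session, eb)
  expect_identical(perm[res3$target], tr$target)
})

test_that("only the candidate with positive first-two-bout gains is chosen", {
  # fish advances along +x and turns toward A, so A's distance and azimuth
  # both shrink each bout; B sits laterally and recedes
  rate <- 700; n <- 350
  ex <- c(rep(0, 100), rep(1, 100), rep(2, 150))
  hd <- c(rep(20, 100), rep(12, 100), rep(10, 150))
  u <- cbind(cos(hd * pi / 180), sin(hd * pi / 180))
  ses <- behavior_session(time = (seq_len(n) - 1) / rate,
                          body_x = ex - 0.25 * u[, 1],
                          body_y = -0.25 * u[, 2],
                          heading = hd,
                          left_eye = rep(8, n), right_eye = rep(-8, n),
                          tail_angles = matrix(0, n, 8),
                          sampling_rate = rate)
  tracks <- list(
    A = cbind(time = c(0, 1), x = c(5, 5), y = c(0.3, 0.3)),
    B = cbind(time = c(0, 1), x = c(-1, -1), y = c(1.732, 1.732)))
  bouts <- data.frame(onset = c(0.05, 0.2),
                      offset = c(0.18, 0.33))
  routine <- list(onset = 0.01, offset = 0.45)
  res <- assign_target(routine, tracks, ses, bouts)
  expect_identical(res$target, 1L)
  expect_false(res$ambiguous)
})

test_that("outcome classification follows the event annotations", {
  r <- list(routine_id = 1, onset = 0, offset = 2)
  none <- data.frame(routine_id = integer(0), type = character(0),
                     time = numeric(0))
  expect_identical(classify_outcome(r, none)$outcome, "abort")
  ev <- data.frame(routine_id = 1, type = c("ram", "ingestion"),
                   time = c(1.5, 1.8))
  oc <- classify_outcome(r, ev)
  expect_identical(oc$outcome, "attempt")
  expect_identical(oc$attempt_type, "ram")
  expect_true(oc$success)
  expect_identical(oc$label, "attempt-ram-success")
  # suction without ingestion
  oc2 <- classify_outcome(r, data.frame(routine_id = 1, type = "suction",
                                        time = 1))
  expect_identical(oc2$label, "attempt-suction-fail")
  # events outside the epoch do not count
  oc3 <- classify_outcome(r, data.frame(routine_id = 1, type = "ram",
                                        time = 5))
  expect_identical(oc3$outcome, "abort")
  # ingestion without capture is inconsistent
  expect_error(classify_outcome(r, data.frame(routine_id = 1,
                                              type = "ingestion",
                                              time = 1)),
               "inconsistent")
})

test_that("ethogram branch probabilities and conservation", {
  mk_routines <- function(nab, nram, nsuc_ram, nsuction, nsuc_suc) {
    data.frame(
      fish = 1,
      outcome = c(rep("abort", nab), rep("attempt", nram + nsuction)),
      attempt_type = c(rep(NA, nab), rep("ram", nram),
                       rep("suction", nsuction)),
      success = c(rep(NA, nab), rep(c(TRUE, FALSE),
                                    c(nsuc_ram, nram - nsuc_ram)),
                  rep(c(TRUE, FALSE), c(nsuc_suc, nsuction - nsuc_suc))))
  }
  etho <- build_ethogram(mk_routines(60, 10, 5, 30, 15))
  expect_equal(unname(etho$pooled["p_abort"]), 0.6)
  expect_equal(unname(etho$pooled["p_suction_given_attempt"]), 0.75)
  expect_equal(unname(etho$pooled["p_success_given_attempt"]), 0.5)
  # sibling branches sum to one, counts conserve routines
  expect_equal(unname(etho$pooled["p_abort"] + etho$pooled["p_attempt"]), 1)
  expect_identical(etho$per_fish$n_abort + etho$per_fish$n_attempt,
                   etho$per_fish$n_routines)
  # all-abort cohort
  allab <- build_ethogram(data.frame(fish = 1, outcome = rep("abort", 5),
                                     attempt_type = NA, success = NA))
  expect_equal(unname(allab$pooled["p_abort"]), 1)
  expect_true(is.na(allab$pooled["p_ram_given_attempt"]))
})

test_that("two cohorts with different abort rates separate by rank-sum", {
  co_a <- simulate_outcome_cohort(7, 112, p_abort = 0.60, seed = 5)
  co_b <- simulate_outcome_cohort(8, 112, p_abort = 0.80, seed = 6)
  cls <- function(co) {
    lab <- vapply(seq_len(nrow(co$epochs)), function(k)
      classify_outcome(co$epochs[k, ], co$events)$outcome, "")
    data.frame(fish = co$epochs$fish, outcome = lab,
               attempt_type = NA, success = NA)
  }
  w <- compare_ethograms(build_ethogram(cls(co_a)),
                         build_ethogram(cls(co_b)))
  expect_lt(w$p.value, 0.05)
})

test_that("negative-gain fractions split by outcome", {
  r <- data.frame(outcome = c(rep("abort", 4), rep("attempt", 6)),
                  neg_gain_bout = c(TRUE, TRUE, FALSE, FALSE,
                                    rep(FALSE, 6)),
                  onset = 1:10, offset = 2:11, n_bouts = 3)
  s <- summarize_routines(r, session_minutes = 5)
  expect_equal(unname(s$neg_gain_fraction["abort"]), 0.5)
  expect_equal(unname(s$neg_gain_fraction["attempt"]), 0)
  expect_equal(s$hunt_rate_per_min, 2)
  # no negative-gain bouts anywhere -> both fractions zero
  r$neg_gain_bout <- FALSE
  s0 <- summarize_routines(r)
  expect_true(all(s0$neg_gain_fraction == 0))
})
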