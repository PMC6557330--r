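test_that("config validation rejects impossible study conditions", {
  expect_error(behavior_sim_config(p_abort = 1.2), "probabilities")
  expect_error(behavior_sim_config(arena_diameter = -1), "arena")
  expect_error(behavior_sim_config(n_prey = 0, hunt_rate = 2), "no targets")
  expect_s3_class(behavior_sim_config(), "behavior_sim_config")
})

test_that("probability-zero branches never occur", {
  sim <- simulate_session(behavior_sim_config(
    duration_s = 40, hunt_rate = 20, rate_hi = 200, p_abort = 0, seed = 3))
  expect_gt(nrow(sim$log$routines), 3)
  expect_false(any(sim$log$routines$outcome == "abort"))
})

test_that("hunt_rate = 0 yields zero routines and no threshold crossings", {
  sim <- simulate_session(behavior_sim_config(
    duration_s = 20, hunt_rate = 0, rate_hi = 200, seed = 5))
  expect_identical(nrow(sim$log$routines), 0L)
  expect_true(all(sim$session$vergence < sim$log$vergence_threshold))
})

test_that("abort fraction recovers the generator parameter", {
  p <- 0.6
  sims <- lapply(1:4, function(s) simulate_session(behavior_sim_config(
    duration_s = 500, hunt_rate = 15, rate_hi = 100, p_abort = p,
    seed = s)))
  lab <- unlist(lapply(sims, function(x) x$log$routines$outcome))
  n <- length(lab)
  expect_gt(n, 150)
  expect_lt(abs(mean(lab == "abort") - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("session invariants hold", {
  sim <- fixture_session()
  ses <- sim$session
  # vergence is exactly left minus right eye angle
  expect_equal(ses$vergence, ses$left_eye - ses$right_eye)
  # uniform sampling
  expect_equal(diff(range(diff(ses$time))), 0, tolerance = 1e-9)
  # every routine's bouts lie within its epoch
  rb <- sim$log$bouts[!is.na(sim$log$bouts$routine_id), ]
  for (r in unique(rb$routine_id)) {
    ep <- sim$log$routines[sim$log$routines$routine_id == r, ]
    expect_true(all(rb$onset[rb$routine_id == r] >= ep$t_ramp_start))
    expect_true(all(rb$offset[rb$routine_id == r] <= ep$offset))
  }
  # outcome taxonomy
  expect_true(all(sim$log$routines$label %in%
                    c("abort", "attempt-ram-success", "attempt-ram-fail",
                      "attempt-suction-success", "attempt-suction-fail")))
  # targets satisfy the reactive-field criterion at onset by construction
  expect_true(all(sim$log$routines$onset_distance <= 6))
  expect_true(all(abs(sim$log$routines$onset_azimuth) <= 120))
})

test_that("vergence distribution is bimodal when hunting occurs", {
  sim <- simulate_session(behavior_sim_config(
    duration_s = 60, hunt_rate = 15, rate_hi = 350, seed = 2))
  v <- sim$session$vergence
  two <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  one <- mclust::Mclust(v, G = 1, modelNames = "V", verbose = FALSE)
  expect_gt(two$bic, one$bic)   # two-mode fit improvement
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- behavior_sim_config(duration_s = 5, hunt_rate = 20, seed = 42)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$session, b$session)
  expect_identical(a$prey, b$prey)
  expect_identical(a$log$routines, b$log$routines)
})

test_that("escape events reach the escape-speed regime at the prey frame rate", {
  sim <- simulate_session(behavior_sim_config(
    duration_s = 60, hunt_rate = 0, bout_rate = 0.3, escape_rate = 6,
    rate_hi = 350, seed = 9))
  expect_gt(nrow(sim$log$escapes), 1)
  lo <- seq(0, 60, by = 1 / 17.5)
  x <- approx(sim$session$time, sim$session$body_x, lo, rule = 2)$y
  y <- approx(sim$session$time, sim$session$body_y, lo, rule = 2)$y
  ev <- detect_escapes(lo, x, y)
  expect_gte(nrow(ev), nrow(sim$log$escapes))
})

test_that("outcome-level cohort generator hits its branch probabilities", {
  co <- simulate_outcome_cohort(6, 150, p_abort = 0.5,
                                p_ram_given_attempt = 0.3, seed = 2)
  lab <- co$epochs$label
  expect_identical(length(lab), 900L)
  expect_lt(abs(mean(lab == "abort") - 0.5), 3 * sqrt(0.25 / 900))
  # every attempt epoch has a capture event inside it
  att <- co$epochs[co$epochs$label != "abort", ]
  for (k in seq_len(nrow(att))) {
    ev <- co$events[co$events$routine_id == att$routine_id[k], ]
    expect_true(any(ev$type %in% c("ram", "suction") &
                      ev$time >= att$onset[k] & ev$time <= att$offset[k]))
  }
})
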