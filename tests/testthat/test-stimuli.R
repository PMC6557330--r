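test_that("loom angular profile: clipping, inversion, scale covariance", {
  st <- loom_stimulus(0.255, 10, 100)
  # analytic collision time from the start angle
  expect_equal(st$t_collision, 0.255 / tan(5 * pi / 180), tolerance = 1e-12)
  # theta = 10 deg at t = 0 by construction
  expect_equal(loom_angle_profile(st, 0), 10, tolerance = 1e-9)
  # clipped at the end angle beyond the expansion
  expect_equal(loom_angle_profile(st, st$t_end + 1), 100)
  expect_equal(loom_angle_profile(st, st$t_collision + 1), 100)
  # strictly increasing before clipping
  tt <- seq(0, st$t_end - 1e-6, length.out = 500)
  expect_true(all(diff(loom_angle_profile(st, tt)) > 0))
  # inversion round-trip exact to 1e-9
  th <- seq(10, 100, length.out = 200)
  expect_lt(max(abs(loom_angle_profile(st, loom_time_of_angle(st, th)) -
                      th)), 1e-9)
  # doubling L/V doubles every time-to-collision at fixed theta
  st2 <- loom_stimulus(0.510, 10, 100)
  expect_equal(st2$t_collision - loom_time_of_angle(st2, th),
               2 * (st$t_collision - loom_time_of_angle(st, th)),
               tolerance = 1e-9)
})

test_that("dimming control matches the loom's solid-angle change", {
  st <- loom_stimulus(0.49, 10, 70, contrast = 0.8)
  tt <- seq(0, st$t_end, length.out = 50)
  dp <- dimming_profile(st, tt)
  # numerical-integration oracle for the disc solid angle
  omega <- function(theta_deg) {
    integrate(function(phi) 2 * pi * sin(phi), 0,
              theta_deg / 2 * pi / 180)$value
  }
  om70 <- omega(70)
  for (k in c(1, 10, 25, 40, 50)) {
    expect_equal(dp$deficit[k],
                 0.8 * omega(loom_angle_profile(st, tt[k])) / om70,
                 tolerance = 1e-8)
  }
  # at the end time the dimming deficit equals the full contrast
  expect_equal(dp$deficit[50], 0.8, tolerance = 1e-9)
  # zero-contrast loom -> constant (zero) dimming profile
  st0 <- loom_stimulus(0.49, 10, 70, contrast = 0)
  expect_true(all(dimming_profile(st0, tt)$deficit == 0))
})

test_that("psychometric fit is identifiable, monotone, and localizes steps", {
  lv <- seq(0.2, 1, by = 0.2)
  expect_error(fit_psychometric(lv, rep(0, 5), rep(20, 5), n_boot = 0),
               "non-identifiable")
  expect_error(fit_psychometric(lv, rep(20, 5), rep(20, 5), n_boot = 0),
               "non-identifiable")
  # perfect step: alpha between the bracketing levels
  f <- fit_psychometric(lv, c(0, 0, 0, 20, 20), rep(20, 5), n_boot = 0)
  expect_gt(f$alpha, 0.6)
  expect_lt(f$alpha, 0.8)
  expect_gt(f$beta, 0)
  # fitted curve monotone non-decreasing
  p <- predict(f, seq(0, 1, by = 0.01))
  expect_true(all(diff(p) >= 0))
})

test_that("psychometric fit reduces deviance against the flat model", {
  set.seed(9)
  lv <- seq(0.2, 1, by = 0.2)
  y <- rbinom(5, 40, plogis(8 * (lv - 0.5)))
  f <- fit_psychometric(lv, y, rep(40, 5), n_boot = 0)
  pbar <- sum(y) / 200
  dev_flat <- -2 * sum(y * log(pbar) + (40 - y) * log(1 - pbar))
  dev_fit <- -2 * f$loglik
  expect_lt(dev_fit, dev_flat)
})

test_that("parametric bootstrap GOF p-values are roughly uniform", {
  set.seed(4)
  lv <- seq(0.2, 1, by = 0.2)
  ps <- replicate(200, {
    y <- rbinom(5, 30, plogis(9 * (lv - 0.55)))
    if (sum(y) == 0 || all(y == 30)) return(NA_real_)
    fit_psychometric(lv, y, rep(30, 5), n_boot = 99, seed = 1)$gof_p
  })
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
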