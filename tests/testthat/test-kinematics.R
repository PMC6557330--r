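test_that("vergence threshold is mu_high - sigma_high on a known mixture", {
  set.seed(1)
  v <- c(rnorm(7e4, 15, 3), rnorm(3e4, 55, 5))
  fit <- fit_vergence_threshold(v)
  expect_equal(fit$threshold, 50, tolerance = 1)
  expect_gt(fit$mu[2], fit$mu[1])
  # data order does not matter
  fit2 <- fit_vergence_threshold(rev(v))
  expect_equal(fit$threshold, fit2$threshold, tolerance = 0.2)
})

test_that("a unimodal vergence distribution is a degenerate fit", {
  set.seed(2)
  expect_error(fit_vergence_threshold(rnorm(5e3, 15, 3)), "degenerate")
  expect_error(fit_vergence_threshold(rnorm(50, 15, 3)), "too short")
})

test_that("epoch segmentation: empty, merge and pruning rules", {
  rate <- 700
  mk <- function(v) list(time = (seq_along(v) - 1) / rate, vergence = v,
                         left_eye = v / 2, right_eye = -v / 2,
                         sampling_rate = rate)
  # constant baseline -> zero epochs
  ep <- segment_hunting_epochs(mk(rep(15, 2000)), 48)
  expect_identical(nrow(ep), 0L)
  # square pulse with a 50 ms sub-threshold dip inside -> one merged epoch
  v <- rep(15, 3000)
  v[1000:1800] <- 55
  v[1400:1434] <- 40               # 50 ms dip
  ep <- segment_hunting_epochs(mk(v), 48)
  expect_identical(nrow(ep), 1L)
  # a dip longer than the merge gap splits the epoch
  v[1400:1470] <- 40               # ~100 ms dip
  ep <- segment_hunting_epochs(mk(v), 48)
  expect_identical(nrow(ep), 2L)
})

test_that("epochs match the generator log, onsets within 10 ms", {
  sim <- fixture_session()
  thr <- fit_vergence_threshold(sim$session$vergence)
  ep <- segment_hunting_epochs(sim$session, thr)
  tr <- sim$log$routines
  expect_identical(nrow(ep), nrow(tr))
  expect_lt(max(abs(ep$onset - tr$onset)), 0.010)
  expect_identical(ep$dominant_eye, tr$dominant_eye)
})

test_that("bout detection: flat trace, single burst, generator recall", {
  rate <- 700
  # flat trace -> no bouts
  expect_identical(nrow(detect_bouts(matrix(0, 2000, 8), rate)), 0L)
  # one 150 ms raised-cosine velocity burst peaking at 800 deg/s
  t <- (0:(2000 - 1)) / rate
  vel <- ifelse(t >= 1 & t <= 1.15,
                800 * (1 - cos(2 * pi * (t - 1) / 0.15)) / 2, 0)
  cum <- cumsum(vel) / rate
  b <- detect_bouts(matrix(cum / 8, 2000, 8), rate)
  expect_identical(nrow(b), 1L)
  expect_equal(b$peak_velocity, 800, tolerance = 40)
  # generator recall and onset accuracy
  sim <- fixture_session()
  det <- detect_bouts(sim$session)
  tru <- sim$log$bouts
  err <- vapply(tru$onset, function(o) min(abs(det$onset - o)), 1)
  expect_gte(mean(err <= 0.010), 0.95)
})

test_that("bout detection is amplitude-scale covariant", {
  sim <- fixture_session()
  n1 <- nrow(detect_bouts(sim$session$tail_angles, 700))
  n2 <- nrow(detect_bouts(2 * sim$session$tail_angles, 700))
  expect_gte(n2, n1)
})

test_that("escape detection thresholds at 75 mm/s", {
  t <- seq(0, 10, by = 1 / 17.5)
  # stationary fish
  expect_identical(nrow(detect_escapes(t, rep(1, length(t)),
                                       rep(2, length(t)))), 0L)
  # routine swimming capped at 30 mm/s
  x <- cumsum(rep(30 / 17.5, length(t)))
  expect_identical(nrow(detect_escapes(t, x, x * 0)), 0L)
  # one escape at 120 mm/s peak
  x2 <- rep(0, length(t))
  x2[t >= 5] <- 120 / 17.5
  ev <- detect_escapes(t, cumsum(x2), x2 * 0,
                       stimulus_onsets = c(1, 4.8))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$latency, ev$onset - 4.8)
})

test_that("threshold recovery holds over randomized mixtures", {
  set.seed(10)
  errs <- replicate(12, {
    mu1 <- runif(1, 10, 20); s1 <- runif(1, 2, 4)
    mu2 <- runif(1, 45, 60); s2 <- runif(1, 3, 6)
    w <- runif(1, 0.15, 0.4)
    n <- 2e4
    v <- c(rnorm(round(n * (1 - w)), mu1, s1), rnorm(round(n * w), mu2, s2))
    abs(fit_vergence_threshold(v)$threshold - (mu2 - s2))
  })
  expect_lte(median(errs), 1)
})
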