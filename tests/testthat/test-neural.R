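test_that("z-scoring: standardization, flat guard, affine invariance", {
  x <- matrix(as.numeric(0:9), 1, 10)
  z <- zscore(x)
  expect_equal(mean(z$F), 0, tolerance = 1e-12)
  expect_equal(sd(z$F), 1, tolerance = 1e-12)
  zc <- zscore(matrix(5, 1, 10))
  expect_true(zc$flat)
  expect_true(all(zc$F == 0))
  z2 <- zscore(3 * x + 7)
  expect_equal(z$F, z2$F, tolerance = 1e-12)
  expect_error(zscore(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("the hand-worked CMI example gives d1 = 2 exactly", {
  h <- hand_cmi_setup()
  res <- compute_cmi(h$activity, h$trials, "left")
  expect_equal(as.numeric(res$d), 2, tolerance = 1e-12)
  expect_equal(res$cmi, 2, tolerance = 1e-12)
  expect_identical(res$n_events, 1L)
  # GO mean equal to the NO-GO mean gives CMI = 0
  h0 <- hand_cmi_setup(go_val = 1)
  expect_equal(compute_cmi(h0$activity, h0$trials, "left")$cmi, 0,
               tolerance = 1e-12)
  # degenerate reference SD drops the event
  hd <- hand_cmi_setup(nogo_vals = c(1, 1, 1))
  expect_warning(rd <- compute_cmi(hd$activity, hd$trials, "left"), NA)
  expect_true(is.nan(rd$cmi) || is.na(rd$cmi))
})

test_that("CMI is invariant to affine rescaling of the raw trace", {
  sim <- fixture_calcium()
  a1 <- compute_cmi(sim$activity, sim$trials, "left")
  resc <- zscore(2.5 * sim$raw + 11, frame_times = sim$activity$time,
                 rois = sim$activity$rois)
  a2 <- compute_cmi(resc, sim$trials, "left")
  expect_equal(a1$cmi, a2$cmi, tolerance = 1e-9)
})

test_that("circular-shuffle null reproduces observed CMI at each shift", {
  h <- hand_cmi_setup()
  obs <- compute_cmi(h$activity, h$trials, "left")$cmi
  nul <- shuffle_null(h$activity, h$trials, "left", n_perm = 8, seed = 3)
  Tn <- ncol(h$activity$F)
  for (p in seq_along(nul$shifts)) {
    s <- nul$shifts[p]
    rolled <- h$activity
    rolled$F <- h$activity$F[, ((seq_len(Tn) - 1 - s) %% Tn) + 1,
                             drop = FALSE]
    expect_equal(nul$null[, p], compute_cmi(rolled, h$trials, "left")$cmi,
                 tolerance = 1e-12)
    if (s == 0L) expect_equal(nul$null[, p], obs, tolerance = 1e-12)
  }
  # determinism under a fixed seed
  nul2 <- shuffle_null(h$activity, h$trials, "left", n_perm = 8, seed = 3)
  expect_identical(nul$null, nul2$null)
})

test_that("stationary-noise cells have a centered shuffle null", {
  sim <- fixture_calcium()
  noise <- sim$activity
  set.seed(77)
  noise$F <- matrix(rnorm(20 * ncol(sim$activity$F)), 20)
  nul <- shuffle_null(noise, sim$trials, "left", n_perm = 600, seed = 5)
  expect_lt(max(abs(nul$null_mean)), 0.15)
  expect_lt(mean(abs(nul$null_mean)), 0.1)
})

test_that("VRV construction: single and repeated epochs, segment bookkeeping", {
  ft <- seq(0.5, 59.5, by = 1)
  g <- function(tau) sin(tau)          # epoch-relative response shape
  Fz <- matrix(0, 1, length(ft))
  for (on in c(10, 40))
    Fz[1, ft >= on & ft <= on + 5] <- g(ft[ft >= on & ft <= on + 5] - on)
  act <- structure(list(F = Fz, time = ft, rois = NULL, flat = FALSE),
                   class = "activity_matrix")
  one <- data.frame(type = "flash_light", onset = 10, offset = 15)
  v1 <- build_vrvs(act, one)
  manual <- approx(ft, Fz[1, ], xout = 10 + seq(0, 5, by = 1))$y
  expect_equal(as.numeric(v1$vrv), manual, tolerance = 1e-9)
  # two identical repetitions equal either one
  two <- rbind(one, data.frame(type = "flash_light", onset = 40,
                               offset = 45))
  v2 <- build_vrvs(act, two)
  expect_equal(as.numeric(v2$vrv), as.numeric(v1$vrv), tolerance = 1e-9)
  # zero-repetition type excluded with a warning
  expect_warning(build_vrvs(act, one, stim_order = c("flash_light",
                                                     "loom")),
                 "zero repetitions")
  # segment bookkeeping on the calcium fixture
  sim <- fixture_calcium()
  vr <- build_vrvs(sim$activity, sim$trials)
  expect_identical(sum(vr$segments$end - vr$segments$start + 1L),
                   ncol(vr$vrv))
  # noiseless spot-CW cells peak in the CW segment
  nf <- simulate_calcium(calcium_sim_config(
    n_cells = c("OT" = 6), noise_sd = 0, n_repeats = 4,
    mixture = c(spot_cw = 1), conv_region = NULL, go_fraction = 0,
    spont_conv_per_min = 0, seed = 8))
  vv <- build_vrvs(nf$activity, nf$trials)
  cw <- vv$segments[vv$segments$type == "spot_cw", ]
  ccw <- vv$segments[vv$segments$type == "spot_ccw", ]
  for (i in 1:6) {
    expect_identical(which.max(vv$vrv[i, ]) >= cw$start &&
                       which.max(vv$vrv[i, ]) <= cw$end, TRUE)
    expect_lt(max(abs(vv$vrv[i, ccw$start:ccw$end])),
              0.2 * max(vv$vrv[i, cw$start:cw$end]))
  }
})

test_that("clustering: identical, two-template, and pure-noise inputs", {
  # 20 identical VRVs -> one archetype, everyone assigned
  v <- matrix(rep(sin(seq(0, 6, length.out = 50)), each = 20), 20)
  cl <- cluster_vrvs(v)
  expect_identical(cl$n_archetypes, 1L)
  expect_true(all(cl$assignment == 1L))
  # two orthogonal templates with noisy copies
  set.seed(12)
  t1 <- rnorm(120); t2 <- rnorm(120)
  mk <- function(tpl, n) t(replicate(n, tpl + rnorm(120, 0, 0.23)))
  V <- rbind(mk(t1, 50), mk(t2, 50))
  truth <- rep(1:2, each = 50)
  cl2 <- cluster_vrvs(V)
  expect_identical(cl2$n_archetypes, 2L)
  agree <- max(mean(cl2$assignment == truth, na.rm = TRUE),
               mean(cl2$assignment == 3 - truth, na.rm = TRUE))
  expect_gte(agree, 0.95)
  # pure-noise VRVs: pairwise correlations verified low, no archetypes
  set.seed(13)
  N <- matrix(rnorm(30 * 400), 30)
  cm <- cor(t(N))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.3)
  cl3 <- cluster_vrvs(N)
  expect_identical(cl3$n_archetypes, 0L)
  expect_true(all(is.na(cl3$assignment)))
})

test_that("clustering is invariant to ROI input order", {
  set.seed(14)
  t1 <- rnorm(80); t2 <- rnorm(80)
  V <- rbind(t(replicate(20, t1 + rnorm(80, 0, 0.2))),
             t(replicate(20, t2 + rnorm(80, 0, 0.2))))
  cl <- cluster_vrvs(V)
  perm <- sample(nrow(V))
  clp <- cluster_vrvs(V[perm, ])
  # same partition up to archetype relabeling
  expect_identical(is.na(clp$assignment), is.na(cl$assignment[perm]))
  tab <- table(cl$assignment[perm], clp$assignment)
  expect_identical(sum(apply(tab, 1, max)), sum(tab))
})

test_that("every assigned ROI is within 0.5 correlation distance of its archetype", {
  sim <- fixture_calcium()
  vr <- build_vrvs(sim$activity, sim$trials)
  cl <- cluster_vrvs(vr)
  for (a in seq_len(cl$n_archetypes)) {
    members <- which(!is.na(cl$assignment) & cl$assignment == a)
    if (!length(members)) next
    d <- 1 - as.numeric(cor(t(vr$vrv[members, , drop = FALSE]),
                            cl$archetypes[a, ]))
    expect_true(all(d <= 0.5 + 1e-9))
  }
})

test_that("region summaries: localization, conservation, degenerate input", {
  sim <- fixture_calcium()
  cl <- compute_cmi(sim$activity, sim$trials, "left")
  cr <- compute_cmi(sim$activity, sim$trials, "right")
  vr <- build_vrvs(sim$activity, sim$trials)
  cls <- cluster_vrvs(vr)
  rs <- region_summaries(cl, cr, sim$activity$rois, clusters = cls)
  # convergence-modulated cells are confined to aCh-A by construction
  best <- rs$regions$region[which.max(rs$regions$mean_cmi_ipsi)]
  expect_identical(best, "aCh-A")
  # cross-tab rows conserve per-cluster cell counts
  expect_identical(sum(rs$cluster_cross), length(cl$cmi))
  tab <- table(ifelse(is.na(cls$assignment), "unclustered",
                      paste0("cluster_", cls$assignment)))
  expect_identical(unname(rowSums(rs$cluster_cross)[names(tab)]),
                   as.numeric(tab))
  # all-zero CMI gives zero means and fractions
  z <- structure(list(cmi = rep(0, nrow(sim$activity$rois)),
                      positive = rep(FALSE, nrow(sim$activity$rois))),
                 class = "cmi_result")
  rz <- region_summaries(z, z, sim$activity$rois)
  expect_true(all(rz$regions$mean_cmi_ipsi == 0))
  expect_true(all(rz$regions$frac_pos_ipsi == 0))
})
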