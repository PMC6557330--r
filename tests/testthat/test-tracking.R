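test_that("background model updates as an exponential moving average", {
  f0 <- matrix(0, 10, 10)
  m <- background_model(f0, update_rate = 1)
  m <- update_background(m, matrix(7, 10, 10))
  expect_equal(m$background, matrix(7, 10, 10))
  m <- background_model(matrix(0, 4, 4), update_rate = 0.5)
  m <- update_background(m, matrix(100, 4, 4))
  expect_equal(m$background, matrix(50, 4, 4))
  # fixed point under constant frames
  m <- background_model(matrix(0, 4, 4), update_rate = 0.2)
  for (i in 1:200) m <- update_background(m, matrix(3, 4, 4))
  expect_lt(max(abs(m$background - 3)), 1e-6)
  expect_error(update_background(m, matrix(0, 5, 5)), "shape")
})

test_that("a blank frame yields an invalid pose, not an error", {
  bg <- matrix(0.9, 120, 120)
  pose <- detect_fish(bg, bg)
  expect_false(pose$valid)
  expect_true(is.na(pose$heading))
})

test_that("fish pose is recovered at a known rendered pose", {
  ses <- pose_session(heading = 30, left = 18, right = -18)
  st <- render_frames(ses, NULL, times = 0, view = "crop",
                      include_prey = FALSE)
  pose <- detect_fish(st$frames[[1]], stack_background(st, 1))
  tr <- st$truth[[1]]
  expect_true(pose$valid)
  expect_lt(sqrt(sum((pose$body - tr$body)^2)), 0.5)
  expect_lt(abs(wrap180_t(pose$heading - 30)), 2)
  expect_lt(abs(pose$left_eye_angle - 18), 2)
  expect_lt(abs(pose$right_eye_angle - (-18)), 2)
})

test_that("rotating the fish 180 degrees flips heading and swaps eye labels", {
  a <- pose_session(heading = 20, left = 15, right = -9)
  b <- pose_session(heading = 200, left = 15, right = -9)
  pa <- local({
    st <- render_frames(a, NULL, times = 0, view = "crop",
                        include_prey = FALSE)
    detect_fish(st$frames[[1]], stack_background(st, 1))
  })
  pb <- local({
    st <- render_frames(b, NULL, times = 0, view = "crop",
                        include_prey = FALSE)
    detect_fish(st$frames[[1]], stack_background(st, 1))
  })
  expect_lt(abs(abs(wrap180_t(pa$heading - pb$heading)) - 180), 2)
  # the physical eyes keep their angles; the left/right labels follow the
  # (rotated) heading so each label still reads its own side's eye
  expect_lt(abs(pa$left_eye_angle - pb$left_eye_angle), 3)
  expect_lt(abs(pa$right_eye_angle - pb$right_eye_angle), 3)
})

test_that("tail tracer returns 9 points and 8 angles, straight tail is flat", {
  ses <- pose_session(heading = 75)
  st <- render_frames(ses, NULL, times = 0, view = "crop",
                      include_prey = FALSE)
  pose <- detect_fish(st$frames[[1]], stack_background(st, 1))
  tt <- trace_tail(st$frames[[1]], pose)
  expect_identical(dim(tt$points), c(9L, 2L))
  expect_length(tt$angles, 8L)
  expect_true(all(tt$point_valid))
  expect_lt(max(abs(tt$angles)), 1.5)
  expect_lt(abs(tt$curvature), 4)
})

test_that("a rightward C-bend gives positive curvature", {
  ses <- pose_session(heading = 10, tail = c(2, 4, 8, 12, 16, 20, 22, 24))
  st <- render_frames(ses, NULL, times = 0, view = "crop",
                      include_prey = FALSE)
  pose <- detect_fish(st$frames[[1]], stack_background(st, 1))
  tt <- trace_tail(st$frames[[1]], pose)
  expect_gt(tt$curvature, 60)
})

test_that("constant-curvature arcs are recovered within 15% per segment", {
  for (cv in c(12, -12)) for (hd in c(15, 160, 285)) {
    ses <- pose_session(heading = hd, tail = rep(cv, 8))
    st <- render_frames(ses, NULL, times = 0, view = "crop",
                        include_prey = FALSE)
    pose <- detect_fish(st$frames[[1]], stack_background(st, 1))
    tt <- trace_tail(st$frames[[1]], pose)
    expect_lt(max(abs(tt$angles - cv)) / abs(cv), 0.15)
  }
})

test_that("an invalid pose cannot be traced", {
  bg <- matrix(0.9, 60, 60)
  expect_error(trace_tail(bg, detect_fish(bg, bg)), "invalid")
})

test_that("prey detection finds isolated blobs and merges close pairs", {
  n <- 400
  bg <- matrix(0.9, n, n)
  fr <- bg
  pts <- cbind(x = c(60, 120, 200, 320, 80, 250, 340, 160, 300, 40),
               y = c(50, 300, 150, 80, 200, 330, 240, 60, 350, 320))
  for (k in seq_len(nrow(pts)))
    fr <- fr - 0.35 * exp(-(outer((seq_len(n) - pts[k, "y"])^2,
                                  (seq_len(n) - pts[k, "x"])^2, "+")) / 8)
  det <- detect_prey(fr, bg)
  expect_identical(nrow(det), 10L)
  dd <- sqrt(outer(pts[, "x"], det[, 1], "-")^2 +
               outer(pts[, "y"], det[, 2], "-")^2)
  expect_lt(max(apply(dd, 1, min)), 1)
  # empty frame
  expect_identical(nrow(detect_prey(bg, bg)), 0L)
  # two blobs 2 px apart merge under sigma = 7 smoothing
  fr2 <- bg
  for (x in c(200, 202))
    fr2 <- fr2 - 0.35 * exp(-(outer((seq_len(n) - 200)^2,
                                    (seq_len(n) - x)^2, "+")) / 8)
  expect_identical(nrow(detect_prey(fr2, bg)), 1L)
})

test_that("Hungarian assignment equals the brute-force optimum", {
  set.seed(31)
  for (r in 1:30) {
    nr <- sample(1:5, 1); nc <- sample(nr:6, 1)
    cost <- matrix(runif(nr * nc), nr, nc)
    a <- solve_assignment(cost)
    expect_equal(assignment_cost(cost, a),
                 brute_force_assignment_cost(cost), tolerance = 1e-12)
  }
  expect_error(solve_assignment(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("track linking: persistence, gaps and crossings", {
  # single static detection over 50 frames -> one track of length 50
  dets <- rep(list(cbind(10, 20)), 50)
  tr <- link_tracks(dets, max_link_distance = 5)
  expect_identical(nrow(tr$tracks), 1L)
  expect_identical(tr$tracks$n_points, 50L)
  # disappearance longer than gap_frames splits the track
  dets2 <- c(rep(list(cbind(10, 20)), 10), rep(list(NULL), 4),
             rep(list(cbind(10, 20)), 10))
  tr2 <- link_tracks(dets2, max_link_distance = 5, gap_frames = 2)
  expect_identical(nrow(tr2$tracks), 2L)
  # ...but a short gap is bridged
  dets3 <- c(rep(list(cbind(10, 20)), 10), rep(list(NULL), 2),
             rep(list(cbind(10, 20)), 10))
  tr3 <- link_tracks(dets3, max_link_distance = 5, gap_frames = 2)
  expect_identical(nrow(tr3$tracks), 1L)
  # two crossing particles with distinct speeds follow the min-cost linking
  t <- 0:20
  p1 <- cbind(10 + 2 * t, 50)
  p2 <- cbind(50 - 2 * t, 50)
  dets4 <- lapply(seq_along(t), function(k) rbind(p1[k, ], p2[k, ]))
  tr4 <- link_tracks(dets4, max_link_distance = 6)
  expect_identical(nrow(tr4$tracks), 2L)
  pts <- tr4$points
  for (id in tr4$tracks$track_id) {
    px <- pts$x[pts$track_id == id]
    expect_true(all(diff(px) > 0) || all(diff(px) < 0))
  }
})
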