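# Synthetic video rendering.
#
# Draws grayscale frames (dark fish and prey on a light background, the
# contrast polarity of IR illumination) in which the body/eye centroids and
# orientations and the prey blob centers equal the simulation ground truth to
# sub-pixel accuracy. Frames are matrices indexed [row = y, col = x] with
# intensities in [0, 1]; pixel (r, c) has center (x = c, y = r).

# fixed fish morphology (px at 24.8 px/mm); the body is a tapered capsule
# (radius growing linearly from tail to head along the axis) whose continuous
# centroid sits `centroid_s` ahead of the shape anchor -- the shape is drawn
# anchored so that its binary-mask centroid equals the nominal body centroid,
# and its mass taper gives the negative third-moment skew along the heading
# that disambiguates front from back
FISH_GEOM <- list(
  r_tail = 3, r_head = 9.5, s_tail = -14, s_head = 6,
  centroid_s = 1.4303,               # numeric centroid of the taper
  eye_fwd = 4.3, eye_lat = 4.6, eye_a = 4.6, eye_b = 2.4,
  tail_base = 20, tail_seg = 9, tail_halfwidth = 2.2,
  int_body = 0.45, int_eye = 0.08, int_tail = 0.74,
  int_bg = 0.92, vignette = 0.04, prey_amp = 0.35, prey_sd = 2)

# blend the tapered-capsule body into `M`, centered (binary-mask centroid)
# at (cx, cy) with the head pointing along `heading`; `scale` rescales the
# morphology from its 24.8 px/mm reference
blend_body <- function(M, cx, cy, heading, scale = 1) {
  g <- FISH_GEOM
  sk <- seq(g$s_tail, g$s_head, by = 0.25) * scale
  rk <- (g$r_tail + (g$r_head - g$r_tail) *
           (sk / scale - g$s_tail) / (g$s_head - g$s_tail)) * scale
  u <- c(cos(deg2rad(heading)), sin(deg2rad(heading)))
  ax <- cx + (sk - g$centroid_s * scale) * u[1]
  ay <- cy + (sk - g$centroid_s * scale) * u[2]
  ext <- max(rk) + 2
  x0 <- max(1L, floor(min(ax) - ext)); x1 <- min(ncol(M), ceiling(max(ax) + ext))
  y0 <- max(1L, floor(min(ay) - ext)); y1 <- min(nrow(M), ceiling(max(ay) + ext))
  if (x0 > x1 || y0 > y1) return(M)
  xs <- x0:x1; ys <- y0:y1
  cov <- matrix(0, length(ys), length(xs))
  for (k in seq_along(sk)) {
    d <- sqrt(outer((ys - ay[k])^2, (xs - ax[k])^2, "+"))
    cov <- pmax(cov, pmin(pmax(rk[k] + 0.5 - d, 0), 1))
  }
  M[ys, xs] <- M[ys, xs] * (1 - cov) + g$int_body * cov
  M
}

# ground-truth tail geometry from a pose. The tail is drawn as a smooth
# curve: each of the 8 segments is subdivided into `m` sub-chords whose
# directions fan symmetrically around the segment's nominal direction, so
# that the coarse chord between consecutive tail coordinates turns by
# exactly the nominal inter-segment angle while the rendered line bends
# gradually (no sharp vertices). Returns the 9 coarse points and the fine
# polyline used for rendering.
tail_polyline <- function(cx, cy, heading, angles,
                          base = FISH_GEOM$tail_base,
                          seg = FISH_GEOM$tail_seg, m = 3L) {
  dirs <- heading + 180 + cumsum(angles)        # nominal segment directions
  spread <- (c(angles[-1], angles[8]) + angles) / 2
  fine_dir <- numeric(8L * m)
  for (k in 1:8) {
    off <- ((seq_len(m) - (m + 1) / 2) / m) * spread[k]
    fine_dir[(k - 1L) * m + seq_len(m)] <- dirs[k] + off
  }
  lens <- rep(c(base, rep(seg, 7L)) / m, each = m)
  fx <- cx + cumsum(lens * cos(deg2rad(fine_dir)))
  fy <- cy + cumsum(lens * sin(deg2rad(fine_dir)))
  fine <- cbind(c(cx, fx), c(cy, fy))
  coarse <- fine[1L + m * (0:8), , drop = FALSE]
  list(fine = fine, coarse = coarse)
}

# blend a solid disc with 1 px anti-aliased edge into image `M`
blend_disc <- function(M, cx, cy, r, value) {
  x0 <- max(1L, floor(cx - r - 2)); x1 <- min(ncol(M), ceiling(cx + r + 2))
  y0 <- max(1L, floor(cy - r - 2)); y1 <- min(nrow(M), ceiling(cy + r + 2))
  if (x0 > x1 || y0 > y1) return(M)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  M[ys, xs] <- M[ys, xs] * (1 - cov) + value * cov
  M
}

# blend a rotated ellipse (3x3 supersampled coverage) into `M`
blend_ellipse <- function(M, cx, cy, a, b, angle, value) {
  ext <- max(a, b) + 2
  x0 <- max(1L, floor(cx - ext)); x1 <- min(ncol(M), ceiling(cx + ext))
  y0 <- max(1L, floor(cy - ext)); y1 <- min(nrow(M), ceiling(cy + ext))
  if (x0 > x1 || y0 > y1) return(M)
  xs <- x0:x1; ys <- y0:y1
  S <- 6L                              # supersampling factor
  off <- (seq_len(S) - (S + 1) / 2) / S
  cov <- matrix(0, length(ys), length(xs))
  cr <- cos(deg2rad(angle)); sr <- sin(deg2rad(angle))
  for (ox in off) for (oy in off) {
    dx <- outer(rep(1, length(ys)), xs + ox - cx)
    dy <- outer(ys + oy - cy, rep(1, length(xs)))
    s <- dx * cr + dy * sr
    n <- -dx * sr + dy * cr
    cov <- cov + ((s / a)^2 + (n / b)^2 <= 1)
  }
  cov <- cov / S^2
  M[ys, xs] <- M[ys, xs] * (1 - cov) + value * cov
  M
}

# blend a whole polyline (union of capsules, single max-coverage field)
# into `M`; a single blend avoids seams at segment joints
blend_polyline <- function(M, pts, halfwidth, value) {
  x0 <- max(1L, floor(min(pts[, 1]) - halfwidth - 2))
  x1 <- min(ncol(M), ceiling(max(pts[, 1]) + halfwidth + 2))
  y0 <- max(1L, floor(min(pts[, 2]) - halfwidth - 2))
  y1 <- min(nrow(M), ceiling(max(pts[, 2]) + halfwidth + 2))
  if (x0 > x1 || y0 > y1) return(M)
  xs <- x0:x1; ys <- y0:y1
  cov <- matrix(0, length(ys), length(xs))
  for (s in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1L, ]
    vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
    L2 <- vx^2 + vy^2
    dx <- outer(rep(1, length(ys)), xs - p0[1])
    dy <- outer(ys - p0[2], rep(1, length(xs)))
    tt <- if (L2 > 0) pmin(pmax((dx * vx + dy * vy) / L2, 0), 1) else 0
    d <- sqrt((dx - tt * vx)^2 + (dy - tt * vy)^2)
    cov <- pmax(cov, pmin(pmax(halfwidth + 0.5 - d, 0), 1))
  }
  M[ys, xs] <- pmin(M[ys, xs], M[ys, xs] * (1 - cov) + value * cov)
  M
}

# blend a capsule (thick segment) into `M`
blend_capsule <- function(M, p0, p1, halfwidth, value) {
  x0 <- max(1L, floor(min(p0[1], p1[1]) - halfwidth - 2))
  x1 <- min(ncol(M), ceiling(max(p0[1], p1[1]) + halfwidth + 2))
  y0 <- max(1L, floor(min(p0[2], p1[2]) - halfwidth - 2))
  y1 <- min(nrow(M), ceiling(max(p0[2], p1[2]) + halfwidth + 2))
  if (x0 > x1 || y0 > y1) return(M)
  xs <- x0:x1; ys <- y0:y1
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  L2 <- vx^2 + vy^2
  dx <- outer(rep(1, length(ys)), xs - p0[1])
  dy <- outer(ys - p0[2], rep(1, length(xs)))
  tt <- if (L2 > 0) pmin(pmax((dx * vx + dy * vy) / L2, 0), 1) else 0
  d <- sqrt((dx - tt * vx)^2 + (dy - tt * vy)^2)
  cov <- pmin(pmax(halfwidth + 0.5 - d, 0), 1)
  M[ys, xs] <- pmin(M[ys, xs], M[ys, xs] * (1 - cov) + value * cov)
  M
}

# subtract a Gaussian prey spot (sub-pixel center) from `M`
blend_prey <- function(M, cx, cy, amp = FISH_GEOM$prey_amp,
                       sd = FISH_GEOM$prey_sd) {
  ext <- ceiling(4 * sd)
  x0 <- max(1L, floor(cx - ext)); x1 <- min(ncol(M), ceiling(cx + ext))
  y0 <- max(1L, floor(cy - ext)); y1 <- min(nrow(M), ceiling(cy + ext))
  if (x0 > x1 || y0 > y1) return(M)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  M[ys, xs] <- M[ys, xs] - amp * exp(-d2 / (2 * sd^2))
  M
}

#' Render the fish-free background of the synthetic arena
#'
#' The smooth background (with its radial vignette) in full-frame
#' coordinates, as used behind every rendered frame; pass it to
#' [background_model()] or directly to the detectors as the clean
#' background estimate for rendered scenes.
#'
#' @param nrow_,ncol_ output size (px).
#' @param center_full arena center in full-frame pixel coordinates.
#' @param radius_px arena radius (px).
#' @param origin full-frame pixel coordinate of the output's (1,1) pixel
#'   (from a `frame_stack`'s `origin` row, for crop views).
#' @return an intensity matrix.
#' @export
render_background <- function(nrow_, ncol_, center_full, radius_px,
                              origin = c(1, 1)) {
  xs <- origin[1] + seq_len(ncol_) - 1
  ys <- origin[2] + seq_len(nrow_) - 1
  r2 <- outer((ys - center_full[2])^2, (xs - center_full[1])^2, "+")
  FISH_GEOM$int_bg - FISH_GEOM$vignette * r2 / radius_px^2
}

# world mm -> full-frame px for a given scale and frame size
world_to_px <- function(xy_mm, ppm, frame_center) {
  cbind(frame_center[1] + xy_mm[, 1] * ppm,
        frame_center[2] + xy_mm[, 2] * ppm)
}

#' Render video frames from a simulated session
#'
#' Produces grayscale frames in which body, eye and prey centers and
#' orientations equal the ground truth to sub-pixel accuracy. Two views are
#' available: the fish-centered crop (7.25 mm window, matching the high-rate
#' kinematics video) and the full arena frame (used for prey tracking).
#'
#' @param session a [behavior_session].
#' @param prey a `prey_truth` object (may be `NULL` with
#'   `include_prey = FALSE`).
#' @param times times (s) at which to render; snapped to the nearest
#'   kinematic sample.
#' @param view `"crop"` or `"full"`.
#' @param crop_mm side length of the fish-centered crop window (mm).
#' @param include_fish,include_prey toggles for scene content.
#' @return object of class `frame_stack`: list with `frames` (list of
#'   matrices in [0, 1]), `times`, `view`, `px_per_mm`, `origin` (n x 2
#'   full-frame pixel coordinate of each frame's (1,1) pixel), `frame_center`
#'   (arena center, full-frame px) and `truth` (per-frame ground truth:
#'   body/eye centers in frame px, heading, eye angles, tail points, prey
#'   centers in frame px).
#' @export
render_frames <- function(session, prey = NULL, times, view = c("crop", "full"),
                          crop_mm = 7.25, include_fish = TRUE,
                          include_prey = TRUE) {
  view <- match.arg(view)
  ppm <- session$px_per_mm
  arena_px <- ceiling(session$arena_diameter * ppm)
  frame_center <- c((arena_px + 1) / 2, (arena_px + 1) / 2)
  crop_px <- round(crop_mm * ppm)
  if (include_fish && view == "crop" && crop_px < 2 * (FISH_GEOM$tail_base +
      7 * FISH_GEOM$tail_seg) * ppm / 24.8 * 1.05)
    stop("crop view smaller than the fish; increase crop_mm")
  idx <- vapply(times, function(tt) which.min(abs(session$time - tt)), 1L)
  n <- length(idx)
  frames <- vector("list", n)
  truth <- vector("list", n)
  origin <- matrix(1, n, 2L)
  geom_scale <- ppm / 24.8          # morphology defined at 24.8 px/mm
  g <- FISH_GEOM
  for (k in seq_len(n)) {
    i <- idx[k]
    C <- world_to_px(cbind(session$body_x[i], session$body_y[i]), ppm,
                     frame_center)[1, ]
    h <- session$heading[i]
    if (view == "crop") {
      o <- round(C) - floor(crop_px / 2)
      nr <- crop_px; nc <- crop_px
    } else {
      o <- c(1, 1)
      nr <- arena_px; nc <- arena_px
    }
    M <- render_background(nr, nc, frame_center, arena_px / 2, o)
    loc <- function(p) c(p[1] - o[1] + 1, p[2] - o[2] + 1)
    tr <- list()
    if (include_fish) {
      u <- c(cos(deg2rad(h)), sin(deg2rad(h)))
      vleft <- c(u[2], -u[1])
      Cl <- loc(C)
      tp <- tail_polyline(Cl[1], Cl[2], h, session$tail_angles[i, ],
                          base = g$tail_base * geom_scale,
                          seg = g$tail_seg * geom_scale)
      M <- blend_polyline(M, tp$fine, g$tail_halfwidth * geom_scale,
                          g$int_tail)
      M <- blend_body(M, Cl[1], Cl[2], h, scale = geom_scale)
      eyeL <- Cl + g$eye_fwd * geom_scale * u + g$eye_lat * geom_scale * vleft
      eyeR <- Cl + g$eye_fwd * geom_scale * u - g$eye_lat * geom_scale * vleft
      M <- blend_ellipse(M, eyeL[1], eyeL[2], g$eye_a * geom_scale,
                         g$eye_b * geom_scale, h + session$left_eye[i],
                         g$int_eye)
      M <- blend_ellipse(M, eyeR[1], eyeR[2], g$eye_a * geom_scale,
                         g$eye_b * geom_scale, h + session$right_eye[i],
                         g$int_eye)
      tr$body <- Cl
      tr$heading <- h
      tr$eye_left <- eyeL
      tr$eye_right <- eyeR
      tr$left_eye_angle <- session$left_eye[i]
      tr$right_eye_angle <- session$right_eye[i]
      tr$tail_points <- tp$coarse
      tr$tail_angles <- session$tail_angles[i, ]
    }
    if (include_prey && !is.null(prey) && ncol(prey$x) > 0) {
      tt <- session$time[i]
      pxy <- cbind(
        vapply(seq_len(ncol(prey$x)), function(p)
          stats::approx(prey$time, prey$x[, p], tt, rule = 2)$y, 1),
        vapply(seq_len(ncol(prey$y)), function(p)
          stats::approx(prey$time, prey$y[, p], tt, rule = 2)$y, 1))
      pp <- world_to_px(pxy, ppm, frame_center)
      pp[, 1] <- pp[, 1] - o[1] + 1
      pp[, 2] <- pp[, 2] - o[2] + 1
      vis <- pp[, 1] > -10 & pp[, 1] < nc + 10 &
             pp[, 2] > -10 & pp[, 2] < nr + 10
      for (p in which(vis)) M <- blend_prey(M, pp[p, 1], pp[p, 2])
      tr$prey <- pp[vis, , drop = FALSE]
      tr$prey_id <- which(vis)
    }
    frames[[k]] <- pmin(pmax(M, 0), 1)
    truth[[k]] <- tr
    origin[k, ] <- o
  }
  structure(list(frames = frames, times = session$time[idx], view = view,
                 px_per_mm = ppm, origin = origin,
                 frame_center = frame_center, truth = truth),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("frame_stack:", length(x$frames), x$view, "frames of", d[1], "x", d[2],
      "px at", x$px_per_mm, "px/mm\n")
  invisible(x)
}

#' Write a frame stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack a [render_frames()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' @param path TIFF file.
#' @param times optional frame times (s); defaults to frame index.
#' @param px_per_mm image scale.
#' @return a `frame_stack` (without ground truth).
#' @export
read_frames_tiff <- function(path, times = NULL, px_per_mm = 24.8) {
  fr <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(fr)) fr <- list(fr)
  fr <- lapply(fr, function(f) if (length(dim(f)) == 3L) f[, , 1] else f)
  structure(list(frames = fr,
                 times = if (is.null(times)) seq_along(fr) - 1 else times,
                 view = "full", px_per_mm = px_per_mm,
                 origin = matrix(1, length(fr), 2L),
                 frame_center = c((ncol(fr[[1]]) + 1) / 2,
                                  (nrow(fr[[1]]) + 1) / 2),
                 truth = NULL),
            class = "frame_stack")
}
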