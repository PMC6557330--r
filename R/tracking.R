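# Fish and prey tracking from grayscale frames: exponentially updated
# background model, moments-based body/eye pose extraction, annular tail
# tracing and Gaussian-smoothed local-maximum prey detection.

#' Create a background model
#'
#' @param init initial background estimate (intensity matrix, typically a
#'   fish-free frame or the first frame).
#' @param update_rate exponential moving-average weight in (0, 1] applied per
#'   frame.
#' @return object of class `background_model`.
#' @export
background_model <- function(init, update_rate = 0.02) {
  stopifnot(is.matrix(init), update_rate > 0, update_rate <= 1)
  structure(list(background = init, update_rate = update_rate),
            class = "background_model")
}

#' Update a background model with a new frame
#'
#' Exponential moving average: `bg <- (1 - a) * bg + a * frame` with
#' `a = update_rate`.
#'
#' @param model a [background_model()].
#' @param frame intensity matrix of the same shape.
#' @return the updated model.
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(model$background), dim(frame)))
    stop("frame shape does not match the background model")
  a <- model$update_rate
  model$background <- (1 - a) * model$background + a * frame
  model
}

# centroid and orientation (deg) of a pixel set, with the 180-degree
# ambiguity resolved so that the third central moment along the returned
# direction is negative (the mass distribution tails away behind the head)
mask_moments <- function(ys, xs, w = NULL) {
  if (is.null(w)) w <- rep(1, length(xs))
  W <- sum(w)
  cx <- sum(w * xs) / W
  cy <- sum(w * ys) / W
  dx <- xs - cx; dy <- ys - cy
  mu20 <- sum(w * dx^2) / W
  mu02 <- sum(w * dy^2) / W
  mu11 <- sum(w * dx * dy) / W
  theta <- rad2deg(0.5 * atan2(2 * mu11, mu20 - mu02))
  s <- dx * cos(deg2rad(theta)) + dy * sin(deg2rad(theta))
  if (sum(w * s^3) > 0) theta <- theta + 180
  list(cx = cx, cy = cy, theta = theta %% 360,
       mu20 = mu20, mu02 = mu02, mu11 = mu11,
       elong = {
         tr <- mu20 + mu02; dd <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
         (tr + dd) / max(tr - dd, 1e-12)
       })
}

invalid_pose <- function() {
  structure(list(valid = FALSE, body = c(NA_real_, NA_real_),
                 heading = NA_real_, left_eye_angle = NA_real_,
                 right_eye_angle = NA_real_,
                 eye_left = c(NA_real_, NA_real_),
                 eye_right = c(NA_real_, NA_real_)),
            class = "fish_pose")
}

#' Detect the fish body and eye pose in one frame
#'
#' The background-subtracted frame is thresholded twice: a body threshold
#' selects the largest binary object within the body area limits, whose
#' binary centroid and second/third central moments give the body centroid
#' and heading (the 180-degree ambiguity is resolved by the third-moment skew
#' along the body axis). A second, stricter threshold selects eye candidates
#' in close proximity to the body centroid; each eye's orientation comes from
#' its intensity-weighted central moments and is reported relative to the
#' heading, clockwise-positive. Failure to find an in-range body blob or two
#' eye candidates yields an invalid pose, not an error.
#'
#' @param frame intensity matrix.
#' @param model a [background_model()] (or a background matrix).
#' @param body_threshold background-minus-frame threshold for body pixels.
#' @param eye_threshold stricter threshold for eye pixels.
#' @param body_area_limits,eye_area_limits c(min, max) blob areas (px).
#' @param eye_radius maximum eye-centroid distance from the body centroid (px).
#' @return object of class `fish_pose`: `valid`, `body` (x, y px), `heading`
#'   (deg), `left_eye_angle`, `right_eye_angle` (deg, clockwise-positive
#'   relative to heading), `eye_left`, `eye_right` (centers, px).
#' @export
detect_fish <- function(frame, model, body_threshold = 0.235,
                        eye_threshold = 0.65,
                        body_area_limits = c(120, 2000),
                        eye_area_limits = c(4, 120), eye_radius = 20) {
  bg <- if (inherits(model, "background_model")) model$background else model
  if (!identical(dim(bg), dim(frame)))
    stop("frame shape does not match the background model")
  diffim <- bg - frame
  bodymask <- diffim > body_threshold
  if (!any(bodymask)) return(invalid_pose())
  lab <- EBImage::bwlabel(EBImage::Image(bodymask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  areas <- tabulate(lab[lab > 0])
  ok <- which(areas >= body_area_limits[1] & areas <= body_area_limits[2])
  if (length(ok) == 0L) return(invalid_pose())
  body_lab <- ok[which.max(areas[ok])]
  bidx <- which(lab == body_lab, arr.ind = TRUE)
  bm <- mask_moments(bidx[, 1], bidx[, 2])
  heading <- bm$theta
  body <- c(bm$cx, bm$cy)

  eyemask <- diffim > eye_threshold
  pose <- invalid_pose()
  pose$valid <- TRUE
  pose$body <- body
  pose$heading <- heading
  if (!any(eyemask)) { pose$valid <- FALSE; return(pose) }
  elab <- EBImage::bwlabel(EBImage::Image(eyemask * 1))
  elab <- as.matrix(EBImage::imageData(elab))
  eareas <- tabulate(elab[elab > 0])
  cand <- which(eareas >= eye_area_limits[1] & eareas <= eye_area_limits[2])
  stats_list <- list()
  for (l in cand) {
    eidx <- which(elab == l, arr.ind = TRUE)
    cx <- mean(eidx[, 2]); cy <- mean(eidx[, 1])
    if (sqrt((cx - body[1])^2 + (cy - body[2])^2) <= eye_radius)
      stats_list[[length(stats_list) + 1L]] <-
        list(label = l, area = eareas[l], idx = eidx)
  }
  if (length(stats_list) < 2L) { pose$valid <- FALSE; return(pose) }
  # if more than two candidates near the body, keep the two largest
  ordv <- order(vapply(stats_list, function(s) s$area, 1), decreasing = TRUE)
  eyes <- stats_list[ordv[1:2]]
  em <- lapply(eyes, function(e) {
    # above-threshold excess weights de-emphasize quantized edge pixels
    w <- pmax(diffim[e$idx] - eye_threshold, 0)
    if (sum(w) < 1e-9) w <- rep(1, nrow(e$idx))
    m <- mask_moments(e$idx[, 1], e$idx[, 2], w = w)
    ang <- wrap180(m$theta - heading)
    if (ang > 90) ang <- ang - 180
    if (ang <= -90) ang <- ang + 180
    list(center = c(m$cx, m$cy), angle = ang)
  })
  u <- c(cos(deg2rad(heading)), sin(deg2rad(heading)))
  crossz <- vapply(em, function(e) {
    v <- e$center - body
    u[1] * v[2] - u[2] * v[1]
  }, 1)
  # fish's left side: cross product of heading with the eye vector negative
  iL <- which.min(crossz); iR <- which.max(crossz)
  if (iL == iR) { pose$valid <- FALSE; return(pose) }
  pose$eye_left <- em[[iL]]$center
  pose$eye_right <- em[[iR]]$center
  pose$left_eye_angle <- em[[iL]]$angle
  pose$right_eye_angle <- em[[iR]]$angle
  pose
}

#' @export
print.fish_pose <- function(x, ...) {
  if (!x$valid) cat("fish_pose: invalid\n")
  else cat(sprintf(
    "fish_pose: body (%.1f, %.1f), heading %.1f, eyes L %.1f / R %.1f deg\n",
    x$body[1], x$body[2], x$heading, x$left_eye_angle, x$right_eye_angle))
  invisible(x)
}

# separable Gaussian blur as two banded-matrix products, with edge
# renormalization; the banded operators are cached per (size, sigma)
.blur_cache <- new.env(parent = emptyenv())

blur_operator <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  if (!is.null(.blur_cache[[key]])) return(.blur_cache[[key]])
  hw <- ceiling(4 * sigma)
  k <- stats::dnorm(-hw:hw, sd = sigma)
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - hw - 1L
    idx <- seq_len(n)
    src <- idx + off
    okk <- src >= 1L & src <= n
    K[cbind(idx[okk], src[okk])] <- K[cbind(idx[okk], src[okk])] + k[j]
  }
  K <- K / rowSums(K)
  .blur_cache[[key]] <- K
  K
}

gaussian_blur <- function(M, sigma) {
  Kr <- blur_operator(nrow(M), sigma)
  Kc <- blur_operator(ncol(M), sigma)
  Kr %*% M %*% t(Kc)
}

# bilinear image sampling at floating-point (x, y)
sample_bilinear <- function(M, x, y) {
  x <- pmin(pmax(x, 1), ncol(M) - 1e-6)
  y <- pmin(pmax(y, 1), nrow(M) - 1e-6)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, ncol(M)); y1 <- pmin(y0 + 1, nrow(M))
  M[cbind(y0, x0)] * (1 - fx) * (1 - fy) + M[cbind(y0, x1)] * fx * (1 - fy) +
    M[cbind(y1, x0)] * (1 - fx) * fy + M[cbind(y1, x1)] * fx * fy
}

#' Trace the tail by consecutive annular scans
#'
#' Starting from the body centroid and progressing toward the tail tip, each
#' step scans an arc of fixed radius centered on the previous point and
#' restricted to a forward sector around the previous segment direction; the
#' angular position of the intensity minimum (sub-sample refined by a
#' quadratic fit) defines the next of the 9 equidistant tail coordinates.
#' Eight inter-segment angles are returned, the first relative to the
#' caudally directed body axis; rightward (clockwise) bending is positive and
#' the cumulative tail curvature is their sum.
#'
#' @param frame intensity matrix.
#' @param pose a valid [detect_fish()] pose (or a list with `body` and
#'   `heading`).
#' @param base_radius radius of the first scan (px), clearing the body.
#' @param seg_length radius step of subsequent scans (px).
#' @param sector half-width of the forward search sector (deg).
#' @param step_deg angular sampling of each arc (deg).
#' @param smooth_sigma anti-alias Gaussian smoothing (px) applied to the
#'   frame before the arcs are sampled (0 to disable).
#' @return list with `points` (9 x 2 matrix, first row the body centroid),
#'   `angles` (8 inter-segment angles, deg), `curvature` (their sum) and
#'   `point_valid` (logical 9; points whose scan left the frame are invalid).
#' @export
trace_tail <- function(frame, pose, base_radius = 20, seg_length = 9,
                       sector = 60, step_deg = 1, smooth_sigma = 0.8) {
  if (inherits(pose, "fish_pose") && !pose$valid)
    stop("cannot trace tail from an invalid pose")
  if (smooth_sigma > 0) frame <- gaussian_blur(frame, smooth_sigma)
  pts <- matrix(NA_real_, 9L, 2L)
  valid <- rep(FALSE, 9L)
  pts[1, ] <- pose$body
  valid[1] <- TRUE
  dir <- (pose$heading + 180) %% 360
  cur <- pose$body
  angles <- rep(NA_real_, 8L)
  for (k in 1:8) {
    r <- if (k == 1L) base_radius else seg_length
    th <- seq(dir - sector, dir + sector, by = step_deg)
    xs <- cur[1] + r * cos(deg2rad(th))
    ys <- cur[2] + r * sin(deg2rad(th))
    inside <- xs >= 1 & xs <= ncol(frame) & ys >= 1 & ys <= nrow(frame)
    if (mean(inside) < 0.5) break
    vals <- rep(Inf, length(th))
    vals[inside] <- sample_bilinear(frame, xs[inside], ys[inside])
    j <- which.min(vals)
    # the dark line has a flat-bottomed profile across its width: localize
    # the dip by the intensity-weighted centroid of the contiguous
    # above-half-depth region around the minimum
    base <- max(vals[is.finite(vals)])
    depth <- base - vals[j]
    w <- pmax(base - vals - 0.4 * depth, 0)
    w[!is.finite(vals)] <- 0
    lo <- j; hi <- j
    while (lo > 1L && w[lo - 1L] > 0) lo <- lo - 1L
    while (hi < length(w) && w[hi + 1L] > 0) hi <- hi + 1L
    best <- if (depth > 1e-6)
      sum(w[lo:hi] * th[lo:hi]) / sum(w[lo:hi]) else th[j]
    angles[k] <- wrap180(best - dir)
    dir <- best %% 360
    cur <- cur + r * c(cos(deg2rad(best)), sin(deg2rad(best)))
    pts[k + 1, ] <- cur
    valid[k + 1] <- TRUE
  }
  list(points = pts, angles = angles,
       curvature = sum(angles, na.rm = TRUE), point_valid = valid)
}

#' Detect prey in a full-frame image
#'
#' The background-subtracted image (dark prey become positive peaks) is
#' smoothed with a 2-D Gaussian filter (default sigma 7 px at 24.8 px/mm)
#' and prey are detected as local maxima exceeding a minimum prominence,
#' with sub-pixel refinement by a separable quadratic fit.
#'
#' @param frame intensity matrix (full, low-rate frame).
#' @param model a [background_model()] or background matrix.
#' @param sigma Gaussian smoothing sigma (px).
#' @param min_prominence minimum smoothed peak height.
#' @param exclude optional c(x, y, radius): suppress detections within
#'   `radius` px of (x, y) (e.g. around the fish).
#' @return matrix with columns `x`, `y` (px); zero rows when nothing is
#'   detected.
#' @export
detect_prey <- function(frame, model, sigma = 7, min_prominence = 0.012,
                        exclude = NULL) {
  bg <- if (inherits(model, "background_model")) model$background else model
  diffim <- bg - frame
  diffim[diffim < 0] <- 0
  sm <- gaussian_blur(diffim, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 5L || nc < 5L) return(matrix(numeric(0), 0L, 2L,
                                        dimnames = list(NULL, c("x", "y"))))
  core <- sm[3:(nr - 2), 3:(nc - 2)]
  ismax <- core >= min_prominence
  for (dy in -2:2) for (dx in -2:2) {
    if (dy == 0L && dx == 0L) next
    ismax <- ismax & (core >= sm[(3 + dy):(nr - 2 + dy),
                                 (3 + dx):(nc - 2 + dx)])
  }
  hits <- which(ismax, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(matrix(numeric(0), 0L, 2L,
                                      dimnames = list(NULL, c("x", "y"))))
  ys <- hits[, 1] + 2L
  xs <- hits[, 2] + 2L
  # collapse plateaus: keep one representative per 8-connected plateau group
  if (nrow(hits) > 1L) {
    keep <- rep(TRUE, length(xs))
    o <- order(ys, xs)
    for (a in seq_along(o)[-1]) {
      i <- o[a]
      for (b in seq_len(a - 1)) {
        j <- o[b]
        if (keep[j] && abs(xs[i] - xs[j]) <= 2 && abs(ys[i] - ys[j]) <= 2) {
          keep[i] <- FALSE; break
        }
      }
    }
    xs <- xs[keep]; ys <- ys[keep]
  }
  # sub-pixel quadratic refinement
  rx <- ry <- numeric(length(xs))
  for (k in seq_along(xs)) {
    x <- xs[k]; y <- ys[k]
    dxn <- sm[y, x - 1]; dxp <- sm[y, x + 1]; d0 <- sm[y, x]
    dyn <- sm[y - 1, x]; dyp <- sm[y + 1, x]
    ddx <- dxn - 2 * d0 + dxp
    ddy <- dyn - 2 * d0 + dyp
    rx[k] <- x + if (abs(ddx) > 1e-12) 0.5 * (dxn - dxp) / ddx else 0
    ry[k] <- y + if (abs(ddy) > 1e-12) 0.5 * (dyn - dyp) / ddy else 0
  }
  out <- cbind(x = rx, y = ry)
  if (!is.null(exclude)) {
    d <- sqrt((out[, 1] - exclude[1])^2 + (out[, 2] - exclude[2])^2)
    out <- out[d > exclude[3], , drop = FALSE]
  }
  out
}
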