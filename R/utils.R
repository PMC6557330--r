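#' @keywords internal
"_PACKAGE"

# Shared geometry, run-detection and RNG helpers.
#
# Coordinate convention (package-wide): image origin top-left, x rightward,
# y downward; angles in degrees, clockwise-positive when viewed in image
# coordinates; heading 0 degrees along +x. World (arena) coordinates in mm
# share the same orientation with origin at the arena center.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees.
#' @keywords internal
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# angle (deg, clockwise-positive in image coords) of vector (dx, dy)
vec_angle <- function(dx, dy) rad2deg(atan2(dy, dx))

# unit vector of an angle in degrees
ang_unit <- function(a) cbind(cos(deg2rad(a)), sin(deg2rad(a)))

# rotate points (n x 2) by `a` degrees (clockwise-positive, y-down coords)
rot2 <- function(p, a) {
  r <- deg2rad(a)
  cbind(p[, 1] * cos(r) - p[, 2] * sin(r),
        p[, 1] * sin(r) + p[, 2] * cos(r))
}

#' Find contiguous above-threshold runs in a logical vector
#'
#' Returns maximal runs of TRUE, optionally merging runs separated by gaps of
#' at most `merge_gap` samples and dropping runs shorter than `min_len`.
#'
#' @param x logical vector.
#' @param merge_gap maximum gap (samples) bridged between consecutive runs.
#' @param min_len minimum run length (samples) retained after merging.
#' @return data.frame with columns `start`, `end` (sample indices, inclusive).
#' @keywords internal
find_runs <- function(x, merge_gap = 0L, min_len = 1L) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  n <- length(x)
  if (n == 0L || !any(x)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  d <- diff(c(FALSE, x, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (merge_gap > 0L && length(starts) > 1L) {
    keep_start <- c(TRUE, (starts[-1L] - ends[-length(ends)] - 1L) > merge_gap)
    grp <- cumsum(keep_start)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  keep <- (ends - starts + 1L) >= min_len
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
             row.names = NULL)
}

# Deterministic fan-out of one user seed into per-subsystem seeds, so that
# subsystems can be re-simulated independently of one another.
fanout_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate `expr` under a local RNG stream seeded by `seed` without
# disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mean of x over index windows [starts_i, ends_i] (inclusive) of a circularly
# shifted series: equivalent to shifting the series right by `shift` frames.
# `x` is a matrix (cells x T); returns matrix (cells x n_windows).
circ_window_means <- function(x, starts, ends, shift = 0L) {
  Tn <- ncol(x)
  out <- matrix(NA_real_, nrow(x), length(starts))
  for (k in seq_along(starts)) {
    idx <- ((seq.int(starts[k], ends[k]) - 1L - shift) %% Tn) + 1L
    out[, k] <- rowMeans(x[, idx, drop = FALSE])
  }
  out
}

# linear interpolation of an (n x 2) path sampled at `t_from` onto `t_to`
interp_path <- function(t_from, path, t_to) {
  cbind(stats::approx(t_from, path[, 1], xout = t_to, rule = 2)$y,
        stats::approx(t_from, path[, 2], xout = t_to, rule = 2)$y)
}
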