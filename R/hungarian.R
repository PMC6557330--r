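# Minimum-cost bipartite assignment (Hungarian algorithm), used for
# frame-by-frame prey track linking. Implemented here with the augmenting-path
# / dual-potential formulation because no linear assignment solver is
# available among the package's dependencies.

#' Solve the linear sum assignment problem
#'
#' Finds the assignment of rows to columns of a cost matrix that minimizes
#' the total cost, by the Hungarian algorithm with dual potentials
#' (O(n^2 m) time). When `nrow(cost) > ncol(cost)` the problem is solved on
#' the transpose.
#'
#' @param cost numeric cost matrix (finite entries; use large values, not
#'   `Inf`, to discourage links).
#' @return integer vector of length `nrow(cost)`; entry `i` is the column
#'   assigned to row `i` (0 if the row is unassigned, which can only happen
#'   when `nrow > ncol`).
#' @examples
#' solve_assignment(matrix(c(1, 2, 2, 1), 2, 2))  # 1, 2
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  if (nrow(cost) == 0L || ncol(cost) == 0L) return(integer(nrow(cost)))
  if (nrow(cost) > ncol(cost)) {
    a <- solve_assignment(t(cost))
    out <- integer(nrow(cost))
    out[a[a > 0L]] <- which(a > 0L)
    return(out)
  }
  n <- nrow(cost)
  m <- ncol(cost)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)    # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      js <- which(!used[-1L])
      cur <- cost[i0, js] - u[i0 + 1L] - v[js + 1L]
      upd <- cur < minv[js]
      if (any(upd)) {
        minv[js[upd]] <- cur[upd]
        way[js[upd] + 1L] <- j0
      }
      k <- which.min(minv[js])
      j1 <- js[k]
      delta <- minv[j1]
      ju <- which(used) - 1L              # columns in the alternating tree
      u[p[ju + 1L] + 1L] <- u[p[ju + 1L] + 1L] + delta
      v[ju + 1L] <- v[ju + 1L] - delta
      minv[js] <- minv[js] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

#' Link per-frame prey detections into persistent tracks
#'
#' Frame-by-frame minimum-cost linking: for each consecutive frame pair the
#' Euclidean-cost assignment between active track heads and new detections is
#' solved with the Hungarian algorithm; assigned pairs farther apart than
#' `max_link_distance` are rejected. Unmatched detections start new tracks;
#' tracks unmatched for more than `gap_frames` frames are closed.
#'
#' @param detections list (one element per frame) of two-column matrices of
#'   detection centers (x, y), as returned by [detect_prey()]; elements may
#'   have zero rows.
#' @param max_link_distance maximum distance (same units as detections) for a
#'   frame-to-frame link.
#' @param gap_frames number of consecutive frames a track may go undetected
#'   before it is closed (0 = close immediately).
#' @return object of class `prey_tracks`: list with `points` (data.frame
#'   `frame`, `x`, `y`, `track_id`) and `tracks` (data.frame `track_id`,
#'   `birth`, `death`, `n_points`).
#' @export
link_tracks <- function(detections, max_link_distance, gap_frames = 2L) {
  stopifnot(is.list(detections), max_link_distance > 0)
  n_frames <- length(detections)
  pts <- vector("list", n_frames)
  # active track state
  act_id <- integer(0)
  act_xy <- matrix(numeric(0), 0L, 2L)
  act_last <- integer(0)
  next_id <- 1L
  big <- 4 * max_link_distance + 1e6
  for (t in seq_len(n_frames)) {
    d <- detections[[t]]
    d <- if (is.null(d) || length(d) == 0L) matrix(numeric(0), 0L, 2L)
         else matrix(as.numeric(d), ncol = 2L)
    # drop expired tracks
    alive <- (t - act_last - 1L) <= gap_frames
    act_id <- act_id[alive]
    act_xy <- act_xy[alive, , drop = FALSE]
    act_last <- act_last[alive]
    assigned_track <- rep(0L, nrow(d))
    if (nrow(d) > 0L && length(act_id) > 0L) {
      dx <- outer(act_xy[, 1], d[, 1], "-")
      dy <- outer(act_xy[, 2], d[, 2], "-")
      cost <- sqrt(dx^2 + dy^2)
      cost[cost > max_link_distance] <- big
      a <- solve_assignment(cost)
      for (i in seq_along(a)) {
        j <- a[i]
        if (j > 0L && cost[i, j] <= max_link_distance) {
          assigned_track[j] <- act_id[i]
          act_xy[i, ] <- d[j, ]
          act_last[i] <- t
        }
      }
    }
    if (nrow(d) > 0L) {
      new <- which(assigned_track == 0L)
      if (length(new) > 0L) {
        ids <- seq.int(next_id, length.out = length(new))
        next_id <- next_id + length(new)
        assigned_track[new] <- ids
        act_id <- c(act_id, ids)
        act_xy <- rbind(act_xy, d[new, , drop = FALSE])
        act_last <- c(act_last, rep(t, length(new)))
      }
      pts[[t]] <- data.frame(frame = t, x = d[, 1], y = d[, 2],
                             track_id = assigned_track)
    }
  }
  points <- do.call(rbind, pts)
  if (is.null(points)) {
    points <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                         track_id = integer(0))
  }
  tracks <- if (nrow(points) > 0L) {
    agg <- split(points$frame, points$track_id)
    data.frame(track_id = as.integer(names(agg)),
               birth = vapply(agg, min, 1L),
               death = vapply(agg, max, 1L),
               n_points = lengths(agg), row.names = NULL)
  } else {
    data.frame(track_id = integer(0), birth = integer(0), death = integer(0),
               n_points = integer(0))
  }
  structure(list(points = points, tracks = tracks[order(tracks$track_id), ]),
            class = "prey_tracks")
}

#' @export
print.prey_tracks <- function(x, ...) {
  cat("prey_tracks:", nrow(x$tracks), "tracks,", nrow(x$points),
      "linked detections\n")
  invisible(x)
}
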