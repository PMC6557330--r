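# Calcium-trace statistics: z-scoring, visual response vectors (VRVs),
# two-stage correlation-distance clustering, the convergence modulation
# index (CMI, Sp-CMI) and its circular-shuffle null, and region summaries.

#' Z-score fluorescence traces
#'
#' Per-ROI standardization over the full recording: `(x - mean) / sd`.
#' Flat traces (SD below `eps`) map to all-zero and are flagged.
#'
#' @param raw matrix (ROIs x frames) of fluorescence.
#' @param frame_times frame times (s); defaults to frame index.
#' @param rois optional data.frame with per-ROI `region` and `side` labels.
#' @param eps SD floor below which a trace is considered flat.
#' @return object of class `activity_matrix`: list with `F` (z-scored
#'   matrix), `time`, `rois`, `flat` (logical per ROI).
#' @export
zscore <- function(raw, frame_times = NULL, rois = NULL, eps = 1e-6) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stop("traces must be finite")
  mu <- rowMeans(raw)
  sd_ <- apply(raw, 1, stats::sd)
  flat <- sd_ < eps
  Fz <- (raw - mu) / ifelse(flat, 1, sd_)
  Fz[flat, ] <- 0
  if (is.null(frame_times)) frame_times <- seq_len(ncol(raw))
  structure(list(F = Fz, time = frame_times, rois = rois, flat = flat),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("activity_matrix:", nrow(x$F), "ROIs x", ncol(x$F), "frames",
      if (any(x$flat)) paste0("(", sum(x$flat), " flat)") else "", "\n")
  invisible(x)
}

#' Build visual response vectors
#'
#' For each stimulus type, every epoch's trace is resampled onto a fixed
#' epoch-relative grid (linear interpolation; epoch onsets are asynchronous
#' to the frame clock) and averaged over repetitions; the per-type averages
#' are concatenated in a fixed stimulus order to form each ROI's VRV.
#'
#' @param activity an [activity_matrix][zscore].
#' @param trials a `trial_table` (list with `stimuli` data.frame) or the
#'   `stimuli` data.frame itself (columns `type`, `onset`, `offset`).
#' @param stim_order stimulus types, fixed concatenation order; defaults to
#'   the sorted unique types present.
#' @param grid_hz resampling rate of the epoch-relative grid (defaults to
#'   the recording frame rate).
#' @return object of class `vrv_set`: `vrv` (ROIs x total length),
#'   `segments` (data.frame `type`, `start`, `end` column indices).
#' @export
build_vrvs <- function(activity, trials, stim_order = NULL, grid_hz = NULL) {
  stim <- if (inherits(trials, "trial_table")) trials$stimuli else trials
  if (is.null(stim_order)) stim_order <- sort(unique(stim$type))
  if (is.null(grid_hz))
    grid_hz <- 1 / stats::median(diff(activity$time))
  Fz <- activity$F
  segs <- list(); pieces <- list()
  col0 <- 0L
  for (ty in stim_order) {
    ep <- stim[stim$type == ty, , drop = FALSE]
    if (nrow(ep) == 0L) {
      warning("stimulus type ", ty, " has zero repetitions; excluded")
      next
    }
    dur <- stats::median(ep$offset - ep$onset)
    grid <- seq(0, dur, by = 1 / grid_hz)
    acc <- matrix(0, nrow(Fz), length(grid))
    for (k in seq_len(nrow(ep))) {
      tt <- ep$onset[k] + grid
      # linear interpolation of every ROI onto the epoch-relative grid
      idx <- findInterval(tt, activity$time, all.inside = TRUE)
      t0 <- activity$time[idx]; t1 <- activity$time[idx + 1L]
      w <- (tt - t0) / (t1 - t0)
      acc <- acc + Fz[, idx, drop = FALSE] * rep(1 - w, each = nrow(Fz)) +
        Fz[, idx + 1L, drop = FALSE] * rep(w, each = nrow(Fz))
    }
    acc <- acc / nrow(ep)
    pieces[[ty]] <- acc
    segs[[ty]] <- data.frame(type = ty, start = col0 + 1L,
                             end = col0 + ncol(acc))
    col0 <- col0 + ncol(acc)
  }
  structure(list(vrv = do.call(cbind, pieces),
                 segments = do.call(rbind, c(segs, make.row.names = FALSE))),
            class = "vrv_set")
}

#' @export
print.vrv_set <- function(x, ...) {
  cat("vrv_set:", nrow(x$vrv), "ROIs, length", ncol(x$vrv), "(",
      paste(x$segments$type, collapse = ", "), ")\n")
  invisible(x)
}

# correlation distance (1 - Pearson r) between rows of M and a centroid
cor_dist_to <- function(M, centroid) {
  suppressWarnings(d <- 1 - as.numeric(stats::cor(t(M), centroid)))
  d[!is.finite(d)] <- 2
  d
}

#' Two-stage clustering of visual response vectors
#'
#' Stage 1: agglomerative clustering (average linkage) with correlation
#' distance `1 - r`, cut at the strict threshold (r = 0.9). Stage 2: each
#' strict cluster's centroid (member mean) is pruned of members farther than
#' the distance limit (0.5); surviving clusters with at least `min_size`
#' members define archetypal centroids. Stage 3: clusters are re-formed at
#' the lenient threshold (r = 0.7) and every member of a lenient cluster is
#' assigned de novo to the closest archetype within the distance limit;
#' anything else is unassigned.
#'
#' @param vrvs a `vrv_set` or a numeric matrix (ROIs x length).
#' @param strict_r,lenient_r correlation thresholds of the two passes.
#' @param dist_limit maximum correlation distance from a centroid.
#' @param min_size minimum members for an archetype.
#' @return object of class `vrv_clusters`: `assignment` (integer archetype
#'   id per ROI, NA = unassigned), `archetypes` (matrix, one row per
#'   archetype), `n_archetypes`, `stage1` (strict-pass labels).
#' @export
cluster_vrvs <- function(vrvs, strict_r = 0.9, lenient_r = 0.7,
                         dist_limit = 0.5, min_size = 5L) {
  V <- if (inherits(vrvs, "vrv_set")) vrvs$vrv else as.matrix(vrvs)
  n <- nrow(V)
  if (n < 2L) stop("need at least 2 VRVs to cluster")
  keep <- apply(V, 1, stats::sd) > 0
  assignment <- rep(NA_integer_, n)
  if (sum(keep) < 2L) {
    return(structure(list(assignment = assignment,
                          archetypes = matrix(numeric(0), 0, ncol(V)),
                          n_archetypes = 0L,
                          stage1 = rep(NA_integer_, n)),
                     class = "vrv_clusters"))
  }
  Vk <- V[keep, , drop = FALSE]
  suppressWarnings(cm <- stats::cor(t(Vk)))
  cm[!is.finite(cm)] <- 0
  D <- stats::as.dist(1 - cm)
  hc <- stats::hclust(D, method = "average")
  lab1 <- stats::cutree(hc, h = 1 - strict_r)
  # stage 2: centroids, single-pass pruning, archetype selection
  archetypes <- list()
  for (cl in sort(unique(lab1))) {
    members <- which(lab1 == cl)
    if (length(members) < min_size) next
    centroid <- colMeans(Vk[members, , drop = FALSE])
    d <- cor_dist_to(Vk[members, , drop = FALSE], centroid)
    retained <- members[d <= dist_limit]
    if (length(retained) >= min_size)
      archetypes[[length(archetypes) + 1L]] <-
        colMeans(Vk[retained, , drop = FALSE])
  }
  if (length(archetypes) == 0L) {
    return(structure(list(assignment = assignment,
                          archetypes = matrix(numeric(0), 0, ncol(V)),
                          n_archetypes = 0L,
                          stage1 = replace(rep(NA_integer_, n), which(keep),
                                           lab1)),
                     class = "vrv_clusters"))
  }
  A <- do.call(rbind, archetypes)
  # stage 3: lenient clusters, de novo assignment to nearest archetype
  lab2 <- stats::cutree(hc, h = 1 - lenient_r)
  ak <- rep(NA_integer_, nrow(Vk))
  in_lenient <- lab2 %in% unique(lab2)        # all lenient-cluster members
  dmat <- vapply(seq_len(nrow(A)), function(j)
    cor_dist_to(Vk, A[j, ]), numeric(nrow(Vk)))
  dmat <- matrix(dmat, nrow = nrow(Vk))
  nearest <- max.col(-dmat, ties.method = "first")
  dmin <- dmat[cbind(seq_len(nrow(Vk)), nearest)]
  ok <- in_lenient & dmin <= dist_limit
  ak[ok] <- nearest[ok]
  assignment[keep] <- ak
  structure(list(assignment = assignment, archetypes = A,
                 n_archetypes = nrow(A),
                 stage1 = replace(rep(NA_integer_, n), which(keep), lab1)),
            class = "vrv_clusters")
}

#' @export
print.vrv_clusters <- function(x, ...) {
  cat("vrv_clusters:", x$n_archetypes, "archetypes;",
      sum(!is.na(x$assignment)), "of", length(x$assignment),
      "ROIs assigned\n")
  invisible(x)
}

# ---- CMI ------------------------------------------------------------------

# frame-index window [start, end] covering [t - half, t + half]
time_window <- function(frame_times, t, half) {
  c(findInterval(t - half, frame_times) + 1L,
    findInterval(t + half, frame_times))
}

# collect GO-event windows and matched NO-GO windows (frame index ranges)
cmi_windows <- function(activity, trials, side, window = 4, min_nogo = 3,
                        spontaneous = FALSE) {
  stim <- trials$stimuli
  convs <- trials$convergences
  ft <- activity$time
  Tn <- length(ft)
  half <- window / 2
  out <- list()
  if (!spontaneous) {
    go_tr <- stim[isTRUE_v(stim$go) & stim$conv_side == side, , drop = FALSE]
    for (k in seq_len(nrow(go_tr))) {
      tc <- go_tr$conv_time[k]
      w <- time_window(ft, tc, half)
      if (w[2] - w[1] + 1 < ceiling(window / 2 * 1 / median(diff(ft))) / 2)
        next
      dt <- tc - go_tr$onset[k]              # epoch-relative window center
      ng <- stim[stim$type == go_tr$type[k] & !isTRUE_v(stim$go) &
                   !is.na(stim$go), , drop = FALSE]
      refs <- list()
      for (j in seq_len(nrow(ng))) {
        tn <- ng$onset[j] + dt
        wn <- time_window(ft, tn, half)
        # drop windows truncated at the recording edges (< 50% samples)
        if (wn[1] < 1L || wn[2] > Tn) next
        if ((wn[2] - wn[1] + 1) < 0.5 * (w[2] - w[1] + 1)) next
        refs[[length(refs) + 1L]] <- wn
      }
      if (length(refs) < min_nogo) next
      out[[length(out) + 1L]] <- list(go = w, refs = refs)
    }
  } else {
    sp <- convs[convs$spontaneous & convs$side == side, , drop = FALSE]
    # reference windows: stimulus-free times with no convergence within the
    # window span
    tmax <- max(ft)
    cand <- seq(2 + half, tmax - half, by = 1.5)
    busy <- vapply(cand, function(x)
      any(x + half > stim$onset - 0.5 & x - half < stim$offset + 0.5) ||
        any(abs(x - convs$time) < window), TRUE)
    cand <- cand[!busy]
    if (length(cand) > 20L)
      cand <- cand[round(seq(1, length(cand), length.out = 20L))]
    refs <- lapply(cand, function(x) time_window(ft, x, half))
    refs <- refs[vapply(refs, function(w) w[1] >= 1 && w[2] <= Tn, TRUE)]
    if (length(refs) >= min_nogo) {
      for (k in seq_len(nrow(sp))) {
        w <- time_window(ft, sp$time[k], half)
        if (w[1] < 1L || w[2] > Tn) next
        out[[length(out) + 1L]] <- list(go = w, refs = refs)
      }
    }
  }
  out
}

# window means for a set of [start, end] ranges under a circular shift
cmi_from_windows <- function(Fz, wins, shift = 0L, eps = 1e-6) {
  if (length(wins) == 0L)
    return(list(cmi = rep(NA_real_, nrow(Fz)),
                d = matrix(numeric(0), nrow(Fz), 0L), n_used = 0L))
  d_list <- list()
  for (k in seq_along(wins)) {
    w <- wins[[k]]
    xg <- circ_window_means(Fz, w$go[1], w$go[2], shift = shift)[, 1]
    starts <- vapply(w$refs, `[`, 1L, 1)
    ends <- vapply(w$refs, `[`, 1L, 2)
    xr <- circ_window_means(Fz, starts, ends, shift = shift)
    mu <- rowMeans(xr)
    sg <- apply(xr, 1, stats::sd)          # sample (n-1) SD
    d <- (xg - mu) / sg
    d[sg < eps] <- NA                      # degenerate reference: dropped
    d_list[[k]] <- d
  }
  D <- do.call(cbind, d_list)
  list(cmi = rowMeans(D, na.rm = TRUE), d = D, n_used = length(wins))
}

#' Compute the convergence modulation index
#'
#' For each GO event (convergent saccade during a prey-spot trial of the
#' given dominant-eye side), the mean z-scored activity in a `window`-s
#' window centered on the saccade is compared with the activity in the same
#' epoch-relative window of NO-GO trials of the same stimulus type:
#' `d_i = (X_GOi - mu_NOGO) / sigma_NOGO`. The CMI is the mean of the `d_i`
#' over GO events; cells with CMI above `positive_cutoff` are flagged CMI+.
#' With `spontaneous = TRUE` the same computation runs on spontaneous
#' convergences referenced against stimulus-free baseline windows (Sp-CMI).
#'
#' @param activity an [activity_matrix][zscore].
#' @param trials a `trial_table` (from [simulate_calcium()] or constructed:
#'   list with `stimuli` and `convergences` data.frames).
#' @param side `"left"` or `"right"` dominant-eye convergences.
#' @param window window length (s) centered on the saccade.
#' @param min_nogo minimum matching NO-GO epochs per GO event.
#' @param positive_cutoff CMI+ threshold.
#' @param spontaneous compute Sp-CMI instead of CMI.
#' @return object of class `cmi_result`: data.frame-like list with `cmi`
#'   per ROI, `d` (ROIs x events matrix of distances), `n_events`, `side`,
#'   `positive` (CMI+ flags), `spontaneous`.
#' @export
compute_cmi <- function(activity, trials, side = c("left", "right"),
                        window = 4, min_nogo = 3, positive_cutoff = 3,
                        spontaneous = FALSE) {
  side <- match.arg(side)
  wins <- cmi_windows(activity, trials, side, window = window,
                      min_nogo = min_nogo, spontaneous = spontaneous)
  res <- cmi_from_windows(activity$F, wins)
  if (res$n_used == 0L)
    warning("no usable ", if (spontaneous) "spontaneous " else "",
            "convergence events for side ", side)
  structure(list(cmi = res$cmi, d = res$d, n_events = res$n_used,
                 side = side, positive = !is.na(res$cmi) &
                   res$cmi > positive_cutoff,
                 positive_cutoff = positive_cutoff,
                 spontaneous = spontaneous, windows = wins),
            class = "cmi_result")
}

#' @export
print.cmi_result <- function(x, ...) {
  cat(if (x$spontaneous) "Sp-CMI" else "CMI", "(", x$side, "):",
      x$n_events, "events;", sum(x$positive, na.rm = TRUE), "of",
      length(x$cmi), "ROIs ", paste0("CMI>", x$positive_cutoff), "\n")
  invisible(x)
}

#' Circular-shuffle null distribution of the CMI
#'
#' Recomputes the CMI after circularly permuting each ROI's time series by a
#' uniformly random shift, `n_perm` times with the event/trial structure
#' fixed, giving the chance-level CMI distribution.
#'
#' @inheritParams compute_cmi
#' @param n_perm number of random circular shifts.
#' @param seed seed for the shifts.
#' @return object of class `cmi_null`: `null` (ROIs x n_perm matrix),
#'   `null_mean` per ROI, `null_positive_rate` (fraction of shifts with
#'   CMI above the cutoff, per ROI), `shifts`.
#' @export
shuffle_null <- function(activity, trials, side = c("left", "right"),
                         window = 4, min_nogo = 3, positive_cutoff = 3,
                         spontaneous = FALSE, n_perm = 1000, seed = 1L) {
  side <- match.arg(side)
  wins <- cmi_windows(activity, trials, side, window = window,
                      min_nogo = min_nogo, spontaneous = spontaneous)
  Tn <- ncol(activity$F)
  shifts <- with_seed(seed, sample.int(Tn, n_perm, replace = TRUE) - 1L)
  null <- matrix(NA_real_, nrow(activity$F), n_perm)
  for (p in seq_len(n_perm))
    null[, p] <- cmi_from_windows(activity$F, wins, shift = shifts[p])$cmi
  structure(list(null = null, null_mean = rowMeans(null, na.rm = TRUE),
                 null_positive_rate = rowMeans(null > positive_cutoff,
                                               na.rm = TRUE),
                 shifts = shifts, side = side),
            class = "cmi_null")
}

#' @export
print.cmi_null <- function(x, ...) {
  cat("cmi_null:", ncol(x$null), "shuffles; grand mean",
      round(mean(x$null_mean, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Region-level summaries of convergence modulation and visual identity
#'
#' Per region, the mean CMI and CMI+ fraction are reported separately for
#' convergences ipsilateral and contralateral to each ROI's hemisphere
#' (ipsilateral = the hemisphere on the side of the more-converging eye),
#' with chance levels from a shuffle null when provided, plus a
#' cross-tabulation of visual-cluster identity against CMI+.
#'
#' @param cmi_left,cmi_right [compute_cmi()] results for left- and
#'   right-dominant convergences.
#' @param rois data.frame with `region` and `side` per ROI.
#' @param clusters optional [cluster_vrvs()] result for the cross-tab.
#' @param null_left,null_right optional [shuffle_null()] results.
#' @return list with `regions` (data.frame: region, n, mean_cmi_ipsi,
#'   mean_cmi_contra, frac_pos_ipsi, frac_pos_contra, chance_mean_ipsi,
#'   chance_frac_pos_ipsi) and `cluster_cross` (table or NULL).
#' @export
region_summaries <- function(cmi_left, cmi_right, rois, clusters = NULL,
                             null_left = NULL, null_right = NULL) {
  stopifnot(nrow(rois) == length(cmi_left$cmi),
            nrow(rois) == length(cmi_right$cmi))
  ipsi <- ifelse(rois$side == "left", cmi_left$cmi, cmi_right$cmi)
  contra <- ifelse(rois$side == "left", cmi_right$cmi, cmi_left$cmi)
  ipsi_pos <- ifelse(rois$side == "left", cmi_left$positive,
                     cmi_right$positive)
  contra_pos <- ifelse(rois$side == "left", cmi_right$positive,
                       cmi_left$positive)
  ch_mean <- ch_pos <- rep(NA_real_, nrow(rois))
  if (!is.null(null_left) && !is.null(null_right)) {
    ch_mean <- ifelse(rois$side == "left", null_left$null_mean,
                      null_right$null_mean)
    ch_pos <- ifelse(rois$side == "left", null_left$null_positive_rate,
                     null_right$null_positive_rate)
  }
  regs <- sort(unique(rois$region))
  rows <- lapply(regs, function(rg) {
    sel <- rois$region == rg
    if (!any(sel)) {
      warning("region ", rg, " is empty; omitted")
      return(NULL)
    }
    data.frame(region = rg, n = sum(sel),
               mean_cmi_ipsi = mean(ipsi[sel], na.rm = TRUE),
               mean_cmi_contra = mean(contra[sel], na.rm = TRUE),
               frac_pos_ipsi = mean(ipsi_pos[sel], na.rm = TRUE),
               frac_pos_contra = mean(contra_pos[sel], na.rm = TRUE),
               chance_mean_ipsi = mean(ch_mean[sel], na.rm = TRUE),
               chance_frac_pos_ipsi = mean(ch_pos[sel], na.rm = TRUE))
  })
  cross <- NULL
  if (!is.null(clusters)) {
    cl <- factor(ifelse(is.na(clusters$assignment), "unclustered",
                        paste0("cluster_", clusters$assignment)))
    pos <- ipsi_pos
    pos[is.na(pos)] <- FALSE
    cross <- table(cluster = cl, cmi_positive = pos)
  }
  list(regions = do.call(rbind, rows), cluster_cross = cross)
}
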