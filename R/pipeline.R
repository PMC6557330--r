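# Configuration, file I/O and the end-to-end pipeline driver.
#
# The pipeline configuration holds every analysis constant at the assay's
# standard values (500 deg/s bout threshold, 75 mm/s escape threshold,
# 6 mm / 120 deg reactive field, 4 s CMI window, CMI+ cutoff 3, clustering
# thresholds 0.9/0.7 with 0.5 distance limit, 1000 shuffles); overrides are
# validated and logged in the provenance record.

#' Default pipeline configuration
#'
#' @param seed master seed fanned out to all subsystems.
#' @param behavior named list of [behavior_sim_config()] overrides.
#' @param calcium named list of [calcium_sim_config()] overrides.
#' @param analysis named list of analysis-constant overrides (see Details).
#' @details Analysis constants and defaults: `bout_velocity_threshold` (500
#'   deg/s), `escape_speed_threshold` (75 mm/s), `target_max_distance`
#'   (6 mm), `target_max_azimuth` (120 deg), `cmi_window` (4 s),
#'   `cmi_positive_cutoff` (3), `cluster_strict_r` (0.9),
#'   `cluster_lenient_r` (0.7), `cluster_dist_limit` (0.5), `n_shuffle`
#'   (1000), `epoch_merge_gap` (0.07 s), `epoch_min_duration` (0.1 s),
#'   `bout_merge_gap` (0.03 s), `bout_min_duration` (0.02 s).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, behavior = list(), calcium = list(),
                            analysis = list()) {
  defaults <- list(
    bout_velocity_threshold = 500, escape_speed_threshold = 75,
    target_max_distance = 6, target_max_azimuth = 120,
    cmi_window = 4, cmi_positive_cutoff = 3,
    cluster_strict_r = 0.9, cluster_lenient_r = 0.7,
    cluster_dist_limit = 0.5, n_shuffle = 1000,
    epoch_merge_gap = 0.07, epoch_min_duration = 0.1,
    bout_merge_gap = 0.03, bout_min_duration = 0.02)
  unknown <- setdiff(names(analysis), names(defaults))
  if (length(unknown))
    stop("unknown analysis field: ", paste(unknown, collapse = ", "))
  analysis <- utils::modifyList(defaults, analysis)
  overridden <- names(analysis)[!vapply(names(analysis), function(n)
    identical(analysis[[n]], defaults[[n]]), TRUE)]
  cfg <- list(seed = as.integer(seed), behavior = behavior,
              calcium = calcium, analysis = analysis,
              overridden = overridden)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  a <- cfg$analysis
  for (f in c("bout_velocity_threshold", "escape_speed_threshold",
              "target_max_distance", "cmi_window", "n_shuffle"))
    if (a[[f]] <= 0) stop("analysis field '", f, "' must be > 0")
  if (a$target_max_azimuth <= 0 || a$target_max_azimuth > 180)
    stop("analysis field 'target_max_azimuth' must lie in (0, 180]")
  for (f in c("cluster_strict_r", "cluster_lenient_r"))
    if (a[[f]] <= 0 || a[[f]] >= 1)
      stop("analysis field '", f, "' must lie in (0, 1)")
  for (f in intersect(names(cfg$behavior),
                      c("p_abort", "p_ram_given_attempt",
                        "p_success_given_attempt", "neg_gain_rate_abort",
                        "neg_gain_rate_attempt")))
    if (cfg$behavior[[f]] < 0 || cfg$behavior[[f]] > 1)
      stop("behavior field '", f, "' must lie in [0, 1]")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return a [pipeline_config()] (reader) or `path` invisibly (writer).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(seed = if (is.null(y$seed)) 1L else y$seed,
                  behavior = if (is.null(y$behavior)) list() else y$behavior,
                  calcium = if (is.null(y$calcium)) list() else y$calcium,
                  analysis = if (is.null(y$analysis)) list() else y$analysis)
}

#' @rdname read_config_yaml
#' @param config a [pipeline_config()].
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(list(seed = config$seed, behavior = config$behavior,
                        calcium = config$calcium,
                        analysis = config$analysis), path)
  invisible(path)
}

# small deterministic content hash (polynomial rolling hash, mod 2^31)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Export a behavior session to CSV
#'
#' One row per sample: time, body centroid, heading, eye angles, vergence
#' and the 8 tail inter-segment angles.
#'
#' @param session a [behavior_session].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  d <- data.frame(time = session$time, body_x = session$body_x,
                  body_y = session$body_y, heading = session$heading,
                  left_eye = session$left_eye,
                  right_eye = session$right_eye,
                  vergence = session$vergence)
  ta <- as.data.frame(session$tail_angles)
  names(ta) <- paste0("tail_angle_", 1:8)
  utils::write.csv(cbind(d, ta), path, row.names = FALSE)
  invisible(path)
}

#' Read a behavior session from CSV
#'
#' @param path CSV written by [write_session_csv()].
#' @param px_per_mm,eye_offset_mm,arena_diameter session metadata (not
#'   stored in the CSV).
#' @return a [behavior_session].
#' @export
read_session_csv <- function(path, px_per_mm = 24.8, eye_offset_mm = 0.25,
                             arena_diameter = 35) {
  d <- utils::read.csv(path)
  rate <- 1 / stats::median(diff(d$time))
  behavior_session(d$time, d$body_x, d$body_y, d$heading, d$left_eye,
                   d$right_eye,
                   as.matrix(d[, paste0("tail_angle_", 1:8)]),
                   sampling_rate = rate, px_per_mm = px_per_mm,
                   eye_offset_mm = eye_offset_mm,
                   arena_diameter = arena_diameter)
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a behavioral session and a calcium recording under the given
#' configuration, runs every analysis stage (vergence threshold, hunting
#' epochs, bouts, per-routine target assignment and gains, outcome
#' classification, ethogram, routine summaries; CMI per side, VRV
#' clustering, region summaries), optionally validates the video trackers
#' against rendered frames, and writes per-stage CSV outputs with a
#' provenance log.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing.
#' @param track_video render frames and run the video trackers on a subset,
#'   reporting ground-truth-recovery metrics.
#' @param n_pose_frames crop frames used for pose recovery when
#'   `track_video`.
#' @param track_seconds seconds of full-frame video used for prey
#'   detection/linking when `track_video`.
#' @return list with `behavior` (session, prey, log, threshold, epochs,
#'   bouts, routines, ethogram, summary), `calcium` (activity, trials, cmi,
#'   clusters, regions), `tracking` (NULL unless `track_video`),
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         track_video = FALSE, n_pose_frames = 20,
                         track_seconds = 5) {
  if (is.character(config)) config <- read_config_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  a <- config$analysis
  bcfg <- do.call(behavior_sim_config,
                  utils::modifyList(list(seed = config$seed),
                                    config$behavior))
  sim <- simulate_session(bcfg)
  thr <- fit_vergence_threshold(sim$session$vergence)
  epochs <- segment_hunting_epochs(sim$session, thr,
                                   merge_gap = a$epoch_merge_gap,
                                   min_duration = a$epoch_min_duration)
  bouts <- detect_bouts(sim$session,
                        velocity_threshold = a$bout_velocity_threshold,
                        merge_gap = a$bout_merge_gap,
                        min_duration = a$bout_min_duration)
  tracks <- as_track_list(sim$prey)
  routines <- list()
  for (k in seq_len(nrow(epochs))) {
    ep <- epochs[k, ]
    eb <- bouts[bouts$onset >= ep$onset - 0.05 &
                  bouts$onset <= ep$offset, , drop = FALSE]
    tgt <- assign_target(ep, tracks, sim$session, eb,
                         max_distance = a$target_max_distance,
                         max_azimuth = a$target_max_azimuth)
    oc <- classify_outcome(list(onset = ep$onset, offset = ep$offset),
                           sim$log$events)
    neg <- FALSE
    gains <- NULL
    if (!is.na(tgt$target) && nrow(eb) > 0) {
      gl <- lapply(seq_len(nrow(eb)), function(j)
        compute_gains(sim$session, tracks[[tgt$target]], eb[j, ]))
      gains <- data.frame(
        distance_gain = vapply(gl, function(g) g$distance_gain, 1),
        orientation_gain = vapply(gl, function(g) g$orientation_gain, 1))
      neg <- any(gains$distance_gain < 0 & gains$orientation_gain < 0,
                 na.rm = TRUE)
    }
    routines[[k]] <- data.frame(
      epoch_id = ep$epoch_id, onset = ep$onset, offset = ep$offset,
      dominant_eye = ep$dominant_eye, target = tgt$target,
      ambiguous = tgt$ambiguous, n_bouts = nrow(eb),
      outcome = oc$outcome, attempt_type = oc$attempt_type,
      success = oc$success, label = oc$label, neg_gain_bout = neg,
      fish = 1L)
  }
  routines <- if (length(routines)) do.call(rbind, routines) else NULL
  etho <- if (!is.null(routines) && nrow(routines) > 0)
    build_ethogram(routines) else NULL
  summary_r <- if (!is.null(routines))
    summarize_routines(routines, session_minutes = bcfg$duration_s / 60)
  else NULL

  ccfg <- do.call(calcium_sim_config,
                  utils::modifyList(list(seed = config$seed),
                                    config$calcium))
  csim <- simulate_calcium(ccfg)
  cmiL <- compute_cmi(csim$activity, csim$trials, "left",
                      window = a$cmi_window,
                      positive_cutoff = a$cmi_positive_cutoff)
  cmiR <- compute_cmi(csim$activity, csim$trials, "right",
                      window = a$cmi_window,
                      positive_cutoff = a$cmi_positive_cutoff)
  vr <- build_vrvs(csim$activity, csim$trials)
  cls <- cluster_vrvs(vr, strict_r = a$cluster_strict_r,
                      lenient_r = a$cluster_lenient_r,
                      dist_limit = a$cluster_dist_limit)
  regions <- region_summaries(cmiL, cmiR, csim$activity$rois,
                              clusters = cls)

  tracking <- NULL
  if (track_video) {
    tracking <- validate_tracking(sim, n_pose_frames = n_pose_frames,
                                  track_seconds = track_seconds)
  }
  provenance <- list(config_hash = config_hash(unclass(config)),
                     seed = config$seed,
                     overridden = config$overridden,
                     package_version =
                       as.character(utils::packageVersion("zfhunt")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- list(behavior = list(session = sim$session, prey = sim$prey,
                              log = sim$log, threshold = thr,
                              epochs = epochs, bouts = bouts,
                              routines = routines, ethogram = etho,
                              summary = summary_r),
              calcium = list(activity = csim$activity,
                             trials = csim$trials, truth = csim$truth,
                             cmi_left = cmiL, cmi_right = cmiR,
                             clusters = cls, regions = regions),
              tracking = tracking, provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# tracker ground-truth-recovery metrics on rendered frames
validate_tracking <- function(sim, n_pose_frames = 20, track_seconds = 5) {
  ses <- sim$session
  arena_px <- ceiling(ses$arena_diameter * ses$px_per_mm)
  tms <- seq(0.2, min(max(ses$time), 30), length.out = n_pose_frames)
  crop <- render_frames(ses, NULL, times = tms, view = "crop",
                        include_prey = FALSE)
  perr <- herr <- eerr <- c()
  for (k in seq_along(crop$frames)) {
    bg <- render_background(nrow(crop$frames[[k]]), ncol(crop$frames[[k]]),
                            crop$frame_center, arena_px / 2,
                            crop$origin[k, ])
    pose <- detect_fish(crop$frames[[k]], bg)
    tr <- crop$truth[[k]]
    if (!pose$valid) next
    perr <- c(perr, sqrt(sum((pose$body - tr$body)^2)))
    herr <- c(herr, abs(wrap180(pose$heading - tr$heading)))
    eerr <- c(eerr, abs(pose$left_eye_angle - tr$left_eye_angle),
              abs(pose$right_eye_angle - tr$right_eye_angle))
  }
  t_lo <- sim$prey$time[sim$prey$time <= track_seconds]
  full <- render_frames(ses, sim$prey, times = t_lo, view = "full",
                        include_fish = FALSE)
  bgf <- render_background(arena_px, arena_px, full$frame_center,
                           arena_px / 2)
  dets <- lapply(seq_along(full$frames), function(k)
    detect_prey(full$frames[[k]], bgf))
  derr <- c(); hit <- 0L; tot <- 0L
  for (k in seq_along(dets)) {
    tru <- full$truth[[k]]$prey
    tot <- tot + nrow(tru)
    if (nrow(dets[[k]]) == 0L) next
    dd <- sqrt(outer(tru[, 1], dets[[k]][, 1], "-")^2 +
                 outer(tru[, 2], dets[[k]][, 2], "-")^2)
    m <- apply(dd, 1, min)
    hit <- hit + sum(m <= 2)
    derr <- c(derr, m[m <= 2])
  }
  tracks <- link_tracks(dets, max_link_distance = 10)
  list(pose_centroid_err_px = stats::median(perr),
       pose_heading_err_deg = stats::median(herr),
       pose_eye_err_deg = stats::median(eerr),
       prey_detection_rate = hit / max(tot, 1L),
       prey_center_err_px = stats::median(derr),
       n_tracks = nrow(tracks$tracks))
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wp <- function(d, f) if (!is.null(d))
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  write_session_csv(out$behavior$session,
                    file.path(out_dir, "session.csv"))
  wp(out$behavior$log$routines, "true_routines.csv")
  wp(out$behavior$log$bouts, "true_bouts.csv")
  wp(out$behavior$epochs, "epochs.csv")
  wp(out$behavior$bouts, "bouts.csv")
  wp(out$behavior$routines, "routines.csv")
  if (!is.null(out$behavior$ethogram))
    wp(out$behavior$ethogram$per_fish, "ethogram.csv")
  wp(out$calcium$regions$regions, "region_summaries.csv")
  wp(data.frame(cell = seq_along(out$calcium$cmi_left$cmi),
                cmi_left = out$calcium$cmi_left$cmi,
                cmi_right = out$calcium$cmi_right$cmi,
                cluster = out$calcium$clusters$assignment),
     "cmi.csv")
  writeLines(paste0(names(out$provenance), ": ",
                    unlist(lapply(out$provenance, paste,
                                  collapse = ","))),
             file.path(out_dir, "provenance.log"))
  invisible(out_dir)
}
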