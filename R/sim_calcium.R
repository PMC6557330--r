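# Trial-structured calcium-recording simulator.
#
# Emulates a tethered virtual-hunting / loom imaging session sampled at
# 3.6 Hz: a pseudo-random stimulus sequence (prey-like moving spots CW/CCW,
# whole-field light/dark flashes, looming spots and the luminance-matched
# dimming control), GO/NO-GO outcomes on prey-spot trials with
# convergence events, spontaneous convergences between trials, and cells
# drawn from stimulus-locked or convergence-locked response classes whose
# event trains are convolved with an exponential nuclear-indicator kernel.

CALCIUM_CLASSES <- c("whole_field", "spot_cw", "spot_ccw", "loom_phasic",
                     "loom_sustained", "dimming_nonselective",
                     "convergence", "silent")

#' Configuration for the calcium simulator
#'
#' @param n_cells named integer vector of cells per region label (defaults
#'   cover the imaged field: both isthmic subregions, tectum, pretectum).
#' @param frame_rate imaging frame rate (Hz).
#' @param kernel_tau exponential decay constant of the indicator (s).
#' @param noise_sd Gaussian noise SD (fluorescence units; response events
#'   have unit amplitude times `amplitude`).
#' @param amplitude response amplitude per event.
#' @param mixture named fractions over response classes
#'   (`whole_field`, `spot_cw`, `spot_ccw`, `loom_phasic`, `loom_sustained`,
#'   `dimming_nonselective`, `convergence`); must sum to <= 1, the remainder
#'   is silent.
#' @param conv_region region to which convergence-modulated cells are
#'   restricted (NULL for no restriction).
#' @param go_fraction probability that a prey-spot trial is a GO trial.
#' @param n_repeats stimulus repetitions per type.
#' @param isi inter-stimulus interval (s).
#' @param spont_conv_per_min rate of spontaneous convergences outside
#'   stimulus epochs.
#' @param seed integer seed.
#' @return object of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(n_cells = c("aCh-A" = 50, "pCh-A" = 40,
                                           "Ch-B" = 30, "OT" = 80,
                                           "pretectum" = 40, "other" = 20),
                               frame_rate = 3.6,
                               kernel_tau = 3,
                               noise_sd = 0.4,
                               amplitude = 4,
                               mixture = c(whole_field = 0.25,
                                           spot_cw = 0.05, spot_ccw = 0.05,
                                           loom_phasic = 0.08,
                                           loom_sustained = 0.07,
                                           dimming_nonselective = 0.05,
                                           convergence = 0.15),
                               conv_region = "aCh-A",
                               go_fraction = 0.4,
                               n_repeats = 20,
                               isi = 10,
                               spont_conv_per_min = 1,
                               seed = 1L) {
  cfg <- as.list(environment())
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (kernel_tau <= 0) stop("kernel_tau must be > 0")
  if (any(mixture < 0) || sum(mixture) > 1 + 1e-9)
    stop("mixture fractions must be non-negative and sum to <= 1")
  if (!all(names(mixture) %in% setdiff(CALCIUM_CLASSES, "silent")))
    stop("unknown response class in mixture")
  if (go_fraction < 0 || go_fraction > 1) stop("go_fraction must be in [0,1]")
  structure(cfg, class = "calcium_sim_config")
}

#' @export
print.calcium_sim_config <- function(x, ...) {
  cat("calcium_sim_config:", sum(x$n_cells), "cells,", x$frame_rate,
      "Hz, tau =", x$kernel_tau, "s\n")
  invisible(x)
}

# stimulus set: type, duration (s)
calcium_stimulus_set <- function() {
  data.frame(
    type = c("spot_cw", "spot_ccw", "flash_light", "flash_dark", "loom",
             "dimming"),
    duration = c(5, 5, 3, 3, 3, 3))
}

#' Simulate a trial-structured calcium recording
#'
#' @param config a [calcium_sim_config()].
#' @return list with `raw` (cells x frames fluorescence), `activity` (the
#'   z-scored [activity_matrix]), `trials` (a `trial_table`), and `truth`
#'   (data.frame: cell, region, side, class, preferred convergence side).
#' @export
simulate_calcium <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  cfg <- config
  stimset <- calcium_stimulus_set()
  # --- trial schedule ---
  sched <- with_seed(fanout_seed(cfg$seed, "schedule"), {
    types <- rep(stimset$type, cfg$n_repeats)
    types <- sample(types)
    onset <- numeric(length(types)); t <- cfg$isi
    dur <- stimset$duration[match(types, stimset$type)]
    for (k in seq_along(types)) {
      onset[k] <- t
      t <- t + dur[k] + cfg$isi
    }
    data.frame(trial_id = seq_along(types), type = types, onset = onset,
               offset = onset + dur)
  })
  total_t <- max(sched$offset) + cfg$isi
  n_frames <- ceiling(total_t * cfg$frame_rate)
  ft <- (seq_len(n_frames) - 0.5) / cfg$frame_rate

  # --- GO/NO-GO outcomes and convergence events ---
  ev <- with_seed(fanout_seed(cfg$seed, "go"), {
    spot <- sched$type %in% c("spot_cw", "spot_ccw")
    go <- rep(NA, nrow(sched))
    go[spot] <- stats::runif(sum(spot)) < cfg$go_fraction
    conv_time <- rep(NA_real_, nrow(sched))
    conv_side <- rep(NA_character_, nrow(sched))
    gi <- which(isTRUE_v(go))
    conv_time[gi] <- sched$onset[gi] +
      stats::runif(length(gi), 0.8, pmax(0.9, sched$offset[gi] -
                                           sched$onset[gi] - 0.5))
    conv_side[gi] <- sample(c("left", "right"), length(gi), replace = TRUE)
    # spontaneous convergences in inter-stimulus gaps
    n_spont <- stats::rpois(1, cfg$spont_conv_per_min * total_t / 60)
    sp_t <- numeric(0); sp_s <- character(0)
    guard <- 2
    if (n_spont > 0) {
      cand <- stats::runif(n_spont * 4, 2, total_t - 2)
      in_stim <- vapply(cand, function(x)
        any(x >= sched$onset - guard & x <= sched$offset + guard), TRUE)
      cand <- cand[!in_stim]
      sp_t <- sort(utils::head(cand, n_spont))
      sp_s <- sample(c("left", "right"), length(sp_t), replace = TRUE)
    }
    list(go = go, conv_time = conv_time, conv_side = conv_side,
         spont_time = sp_t, spont_side = sp_s)
  })
  sched$go <- ev$go
  sched$conv_time <- ev$conv_time
  sched$conv_side <- ev$conv_side
  gi <- !is.na(sched$conv_time)
  convs <- rbind(
    data.frame(time = sched$conv_time[gi], side = sched$conv_side[gi],
               spontaneous = rep(FALSE, sum(gi))),
    data.frame(time = ev$spont_time, side = ev$spont_side,
               spontaneous = rep(TRUE, length(ev$spont_time))))
  convs <- convs[order(convs$time), , drop = FALSE]
  rownames(convs) <- NULL

  # --- cell identities ---
  truth <- with_seed(fanout_seed(cfg$seed, "cells"), {
    region <- rep(names(cfg$n_cells), cfg$n_cells)
    n <- length(region)
    side <- sample(c("left", "right"), n, replace = TRUE)
    probs <- c(cfg$mixture, silent = 1 - sum(cfg$mixture))
    cls <- sample(names(probs), n, replace = TRUE, prob = probs)
    if (!is.null(cfg$conv_region)) {
      # convergence-modulated cells live in the designated region only
      move <- cls == "convergence" & !(region %in% cfg$conv_region)
      cls[move] <- "silent"
      eligible <- which(region %in% cfg$conv_region & cls == "silent")
      n_add <- sum(move)
      if (n_add > 0 && length(eligible) > 0)
        cls[utils::head(eligible, n_add)] <- "convergence"
    }
    pref <- ifelse(cls == "convergence", side, NA)   # ipsilateral preference
    data.frame(cell = seq_len(n), region = region, side = side,
               class = cls, conv_pref = pref)
  })

  # --- event trains per cell class ---
  decay <- exp(-1 / (cfg$kernel_tau * cfg$frame_rate))
  event_times_for <- function(cls, pref) {
    tt <- numeric(0)
    on <- sched$onset; off <- sched$offset
    switch(cls,
      whole_field = {
        sel <- sched$type %in% c("flash_light", "flash_dark")
        tt <- on[sel]
      },
      spot_cw = {
        sel <- sched$type == "spot_cw"
        tt <- unlist(lapply(which(sel), function(k)
          seq(on[k], off[k] - 0.5, by = 1)))
      },
      spot_ccw = {
        sel <- sched$type == "spot_ccw"
        tt <- unlist(lapply(which(sel), function(k)
          seq(on[k], off[k] - 0.5, by = 1)))
      },
      loom_phasic = {
        sel <- sched$type == "loom"
        tt <- off[sel] - 0.3              # response at maximal expansion
      },
      loom_sustained = {
        sel <- sched$type == "loom"
        tt <- unlist(lapply(which(sel), function(k)
          seq(on[k], off[k] - 0.3, by = 0.75)))
      },
      dimming_nonselective = {
        sel <- sched$type %in% c("loom", "dimming")
        tt <- unlist(lapply(which(sel), function(k)
          seq(on[k], off[k] - 0.3, by = 0.75)))
      },
      convergence = {
        tt <- convs$time[convs$side == pref]
      },
      silent = numeric(0))
    tt
  }
  n_cells <- nrow(truth)
  raw <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    tt <- event_times_for(truth$class[i], truth$conv_pref[i])
    if (length(tt)) {
      train <- numeric(n_frames)
      fi <- pmin(pmax(ceiling(tt * cfg$frame_rate), 1L), n_frames)
      for (f in fi) train[f] <- train[f] + cfg$amplitude
      # exponential-kernel superposition as an exact AR(1) recursion
      raw[i, ] <- as.numeric(stats::filter(train, decay,
                                           method = "recursive"))
    }
  }
  if (cfg$noise_sd > 0) {
    raw <- raw + with_seed(fanout_seed(cfg$seed, "noise"),
                           matrix(stats::rnorm(n_cells * n_frames, 0,
                                               cfg$noise_sd),
                                  n_cells, n_frames))
  }
  trials <- structure(list(stimuli = sched, convergences = convs),
                      class = "trial_table")
  rois <- truth[, c("cell", "region", "side")]
  list(raw = raw, activity = zscore(raw, frame_times = ft, rois = rois),
       trials = trials, truth = truth)
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.trial_table <- function(x, ...) {
  cat("trial_table:", nrow(x$stimuli), "stimulus epochs,",
      nrow(x$convergences), "convergences (",
      sum(x$convergences$spontaneous), "spontaneous )\n")
  print(table(x$stimuli$type))
  invisible(x)
}
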