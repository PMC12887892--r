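# Stimulus schedules, trial segmentation and the four session metrics:
# visuomotor reaction speed (VMRS), displacement speed (DS), response
# capacity (RC) and the composite cognitive-motor speed (CMS = VMRS + DS).

#' Generate a randomized stimulus schedule
#'
#' A session presents `n_scenarios` game situations, half offensive and
#' half defensive, each owning a distinct (type, target zone) combination,
#' in seeded random order. Every scenario cycle is `config_s` of
#' configuration, `vis_s` of visualization and `response_s` of residual
#' response window; with the defaults a 16-scenario sequence lasts
#' 16 x 5 s = 80 s (excluding the countdown). `onset_time_s` is the
#' stimulus presentation instant, i.e. the end of the scenario's
#' configuration phase.
#'
#' @param seed Integer seed for the permutation.
#' @param n_scenarios Even number of scenarios.
#' @param config_s,vis_s,response_s Phase durations, seconds.
#' @param countdown_s Pre-sequence countdown, seconds.
#' @param fps Frame rate used to convert times to frames.
#' @return Object of class `stimulus_log`: list with `fps`, `countdown_s`
#'   and a `scenarios` data frame.
#' @export
schedule_session <- function(seed, n_scenarios = 16L, config_s = 1,
                             vis_s = 2, response_s = 2, countdown_s = 3,
                             fps = 30) {
  stopifnot(is_count(seed), config_s > 0, vis_s > 0, response_s > 0, fps > 0)
  n_scenarios <- as.integer(n_scenarios)
  if (n_scenarios %% 2L != 0L) {
    stopf("n_scenarios must be even to balance offensive and defensive situations")
  }
  half <- n_scenarios %/% 2L
  scen <- with_seed(seed, {
    zones_off <- sample(peripheral_ids())
    zones_def <- sample(peripheral_ids())
    pool <- data.frame(
      type = rep(c("offensive", "defensive"), each = half),
      target_zone = c(rep_len(zones_off, half), rep_len(zones_def, half)),
      stringsAsFactors = FALSE
    )
    pool[sample.int(n_scenarios), ]
  })
  cycle <- config_s + vis_s + response_s
  scen$index <- seq_len(n_scenarios)
  scen$onset_time_s <- countdown_s + config_s + (scen$index - 1L) * cycle
  scen$config_s <- config_s
  scen$vis_s <- vis_s
  scen$response_s <- response_s
  rownames(scen) <- NULL
  structure(list(fps = fps, countdown_s = countdown_s,
                 scenarios = scen[, c("index", "type", "target_zone",
                                      "onset_time_s", "config_s", "vis_s",
                                      "response_s")]),
            class = "stimulus_log")
}

#' Total scheduled duration of a stimulus sequence
#'
#' Sum of the per-scenario cycles (configuration + visualization +
#' response), excluding the countdown.
#'
#' @param log A [schedule_session()] result.
#' @return Seconds.
#' @export
session_duration_s <- function(log) {
  with(log$scenarios, sum(config_s + vis_s + response_s))
}

stimulus_frames <- function(log) {
  round(log$scenarios$onset_time_s * log$fps)
}

#' @export
print.stimulus_log <- function(x, ...) {
  tab <- table(x$scenarios$type)
  cat(sprintf("Stimulus schedule: %d scenarios (%s), %g s at %g fps\n",
              nrow(x$scenarios),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              session_duration_s(x), x$fps))
  invisible(x)
}

#' Write a stimulus schedule to JSON
#' @param log A `stimulus_log`.
#' @param path Output file.
#' @export
write_stimuli_json <- function(log, path) {
  obj <- list(fps = log$fps, countdown_s = log$countdown_s,
              scenarios = log$scenarios)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a stimulus schedule from JSON
#' @param path File written by [write_stimuli_json()].
#' @return A `stimulus_log`.
#' @export
read_stimuli_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(fps = obj$fps, countdown_s = obj$countdown_s,
                 scenarios = as.data.frame(obj$scenarios)),
            class = "stimulus_log")
}

#' Visuomotor reaction speed of one trial
#'
#' Seconds from stimulus presentation to the attacking foot completely
#' leaving the central circle.
#'
#' @param stimulus_frame,onset_frame Frame indices (onset >= stimulus).
#' @param fps Frame rate.
#' @return Seconds.
#' @export
compute_vmrs <- function(stimulus_frame, onset_frame, fps) {
  stopifnot(fps > 0)
  if (onset_frame < stimulus_frame) {
    stopf("movement onset (frame %s) precedes the stimulus (frame %s)",
          onset_frame, stimulus_frame)
  }
  (onset_frame - stimulus_frame) / fps
}

#' Displacement speed of one trial
#'
#' Seconds from the attacking foot leaving the central circle to the first
#' validated contact on the target point.
#'
#' @param onset_frame,arrival_frame Frame indices (arrival >= onset).
#' @param fps Frame rate.
#' @return Seconds.
#' @export
compute_ds <- function(onset_frame, arrival_frame, fps) {
  stopifnot(fps > 0)
  if (arrival_frame < onset_frame) {
    stopf("zone arrival (frame %s) precedes the movement onset (frame %s)",
          arrival_frame, onset_frame)
  }
  (arrival_frame - onset_frame) / fps
}

#' Response capacity
#'
#' Percentage of correct actions: correct divided by the total number of
#' game situations, times 100.
#'
#' @param n_correct,n_total Counts (0 <= n_correct <= n_total, n_total > 0).
#' @return Percent.
#' @export
compute_rc <- function(n_correct, n_total) {
  if (n_total <= 0) stopf("response capacity is undefined without game situations")
  if (n_correct < 0 || n_correct > n_total) {
    stopf("n_correct must lie in [0, n_total]")
  }
  100 * n_correct / n_total
}

#' Composite cognitive-motor speed
#'
#' Sum of the visuomotor reaction and displacement components, both in
#' seconds; no weighting or normalization is applied.
#'
#' @param mean_vmrs_s,mean_ds_s Component times, seconds (>= 0).
#' @return Seconds.
#' @export
compute_cms <- function(mean_vmrs_s, mean_ds_s) {
  stopifnot(mean_vmrs_s >= 0, mean_ds_s >= 0)
  mean_vmrs_s + mean_ds_s
}

#' Segment detected events into stimulus-locked trials
#'
#' Pairs each scheduled scenario with the detected movement onset and the
#' earliest validated peripheral-zone contact in its response window, then
#' classifies the outcome: `correct` when the arrival zone equals the
#' stimulus-defined target, `incorrect` for any other arrival, and
#' `no_response` when no validated arrival occurs before the next
#' stimulus. Per-trial VMRS and DS are attached where defined.
#'
#' @param log A `stimulus_log`.
#' @param events List of grounded `step_event`s (both feet).
#' @param onsets List with one [detect_onset()] result per scenario.
#' @param fps Frame rate of the analyzed stream; must equal the log's.
#' @return Data frame of class `trial_records`.
#' @export
segment_trials <- function(log, events, onsets, fps = log$fps) {
  stopifnot(inherits(log, "stimulus_log"))
  if (abs(fps - log$fps) > 1e-9) {
    stopf("synchronization error: stream fps (%g) differs from the stimuli log fps (%g)",
          fps, log$fps)
  }
  scen <- log$scenarios
  if (length(onsets) != nrow(scen)) {
    stopf("need one onset record per scenario (%d != %d)", length(onsets), nrow(scen))
  }
  sf <- stimulus_frames(log)
  cycle_frames <- round((scen$config_s + scen$vis_s + scen$response_s) * log$fps)
  next_sf <- c(sf[-1], sf[length(sf)] + cycle_frames[length(sf)])

  out <- lapply(seq_len(nrow(scen)), function(i) {
    ons <- onsets[[i]]
    arr <- detect_arrival(events, ons$onset_frame, next_sf[i])
    arrival_frame <- if (is.null(arr)) NA_integer_ else as.integer(arr$contact_frame)
    arrival_zone <- if (is.null(arr)) NA_character_ else arr$zone
    outcome <- if (is.null(arr)) "no_response"
      else if (identical(arrival_zone, scen$target_zone[i])) "correct"
      else "incorrect"
    vmrs <- if (!is.na(ons$onset_frame)) compute_vmrs(sf[i], ons$onset_frame, log$fps) else NA_real_
    ds <- if (!is.na(ons$onset_frame) && !is.na(arrival_frame)) {
      compute_ds(ons$onset_frame, arrival_frame, log$fps)
    } else NA_real_
    data.frame(scenario_index = scen$index[i], type = scen$type[i],
               target_zone = scen$target_zone[i], stimulus_frame = sf[i],
               onset_frame = if (is.na(ons$onset_frame)) NA_integer_ else as.integer(ons$onset_frame),
               arrival_frame = arrival_frame, arrival_zone = arrival_zone,
               outcome = outcome, vmrs_s = vmrs, ds_s = ds,
               flag = ons$flag %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("trial_records", "data.frame")
  res
}

#' Summarize a session into its four metrics
#'
#' VMRS and DS are averaged over the trials where they are defined
#' (no-response trials are excluded from the means but stay in the RC
#' denominator); RC is the percentage of correct trials over all
#' scenarios; CMS is the sum of the two mean components.
#'
#' @param trials A [segment_trials()] result.
#' @param athlete_id Identifier carried into the output row.
#' @return One-row data frame: `athlete_id`, `n_trials`, `mean_vmrs_s`,
#'   `mean_ds_s`, `rc_percent`, `cms_s`.
#' @export
summarize_session <- function(trials, athlete_id = "athlete") {
  if (is.null(trials) || nrow(trials) == 0L) {
    stopf("cannot summarize a session without trials")
  }
  vm <- trials$vmrs_s[!is.na(trials$vmrs_s)]
  ds <- trials$ds_s[!is.na(trials$ds_s)]
  rc <- compute_rc(sum(trials$outcome == "correct"), nrow(trials))
  mean_vmrs <- if (length(vm)) mean(vm) else NA_real_
  mean_ds <- if (length(ds)) mean(ds) else NA_real_
  cms <- if (!is.na(mean_vmrs) && !is.na(mean_ds)) compute_cms(mean_vmrs, mean_ds) else NA_real_
  data.frame(athlete_id = athlete_id, n_trials = nrow(trials),
             mean_vmrs_s = mean_vmrs, mean_ds_s = mean_ds,
             rc_percent = rc, cms_s = cms, stringsAsFactors = FALSE)
}

#' Run the full measurement pipeline on one session
#'
#' Smooths both foot trajectories, detects and grounds contact events,
#' locates per-scenario movement onsets, segments trials and summarizes
#' the session. Pixel thresholds are rescaled from their 1080p defaults to
#' the stream's image height.
#'
#' @param stream A [landmark_stream()].
#' @param calib A [zone_polygon_set()].
#' @param log A `stimulus_log`.
#' @param params [detector_params()] at 1080p scale.
#' @param window Smoothing window, frames.
#' @param dilation_px Footprint dilation at 1080p, px.
#' @param athlete_id Identifier for the summary row.
#' @return List with `metrics` (one-row data frame), `trials`, `events`
#'   and `onsets`.
#' @export
analyze_session <- function(stream, calib, log, params = detector_params(),
                            window = 3L, dilation_px = 10,
                            athlete_id = "athlete") {
  stopifnot(inherits(stream, "landmark_stream"),
            inherits(calib, "zone_polygon_set"),
            inherits(log, "stimulus_log"))
  s <- stream$image_size[2] / 1080
  p <- scale_detector_params(params, stream$image_size[2])
  dil <- dilation_px * s

  traj <- lapply(stats::setNames(FEET, FEET), function(f) {
    smooth_trajectory(stream, f, window = window)
  })
  events <- c(
    detect_contacts(traj$left, p, stream = stream, dilation_px = dil),
    detect_contacts(traj$right, p, stream = stream, dilation_px = dil)
  )
  events <- lapply(events, ground_contact_zone, zones = calib, params = p)

  sf <- stimulus_frames(log)
  cycle_frames <- round((log$scenarios$config_s + log$scenarios$vis_s +
                           log$scenarios$response_s) * log$fps)
  next_sf <- c(sf[-1], sf[length(sf)] + cycle_frames[length(sf)])
  onsets <- lapply(seq_along(sf), function(i) {
    detect_onset(traj$left, traj$right, calib$polygons[["C"]], sf[i],
                 params = p, stream = stream, next_stimulus_frame = next_sf[i],
                 dilation_px = dil, center_tolerance_px = 40 * s)
  })

  trials <- segment_trials(log, events, onsets, fps = stream$fps)
  metrics <- summarize_session(trials, athlete_id = athlete_id)
  list(metrics = metrics, trials = trials, events = events, onsets = onsets)
}

#' Write session metrics to CSV
#' @param metrics Data frame of session metric rows.
#' @param path Output file.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read session metrics from CSV
#' @param path File written by [write_metrics_csv()].
#' @return Data frame.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
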