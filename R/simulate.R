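# Fully synthetic, ground-truthed sessions: calibration scenes, stimulus
# schedules, landmark streams and two-group cohorts. The generator makes
# every other module testable without any recording, with exact knowledge
# of onset/arrival frames and trial outcomes.

#' Default floor-to-image camera map for the simulator
#'
#' A mildly perspective projective map emulating a webcam mounted above the
#' display and looking at the 5 m x 5 m surface: roughly 180 px/m
#' horizontally and 150 px/m vertically at the central marker, with
#' foreshortening along the floor's depth axis. All nine markers project
#' well inside a 1920 x 1080 frame.
#'
#' @return A [homography()].
#' @export
default_camera_homography <- function() {
  homography(matrix(c(180, 0, 960,
                      0, -150, 520,
                      0, 0.10, 1), 3, 3, byrow = TRUE))
}

#' Per-group athlete parameters for the simulator
#'
#' `reaction_sd_s` and `displacement_sd_s` are between-athlete standard
#' deviations: each athlete's latent mean is drawn from the group
#' distribution (truncated normal), matching how group summaries of
#' per-athlete session means are reported. Individual trials scatter
#' around the athlete's latent mean with the within-athlete SDs.
#'
#' @param n_athletes Number of athletes in the group.
#' @param reaction_mean_s,reaction_sd_s Group mean and between-athlete SD
#'   of the visuomotor reaction latency, seconds.
#' @param displacement_mean_s,displacement_sd_s Group mean and
#'   between-athlete SD of the center-to-target movement duration, seconds.
#' @param accuracy_prob Probability that a trial's executed zone is the
#'   intended one.
#' @param reaction_trial_sd_s,displacement_trial_sd_s Within-athlete
#'   trial-to-trial SDs, seconds.
#' @return List of class `group_params`.
#' @export
group_params <- function(n_athletes, reaction_mean_s, reaction_sd_s,
                         displacement_mean_s, displacement_sd_s,
                         accuracy_prob, reaction_trial_sd_s = 0.08,
                         displacement_trial_sd_s = 0.06) {
  stopifnot(n_athletes >= 1, reaction_sd_s >= 0, displacement_sd_s >= 0,
            accuracy_prob >= 0, accuracy_prob <= 1,
            reaction_mean_s > 0, displacement_mean_s > 0,
            reaction_trial_sd_s >= 0, displacement_trial_sd_s >= 0)
  structure(list(n_athletes = as.integer(n_athletes),
                 reaction_mean_s = reaction_mean_s,
                 reaction_sd_s = reaction_sd_s,
                 displacement_mean_s = displacement_mean_s,
                 displacement_sd_s = displacement_sd_s,
                 accuracy_prob = accuracy_prob,
                 reaction_trial_sd_s = reaction_trial_sd_s,
                 displacement_trial_sd_s = displacement_trial_sd_s),
            class = "group_params")
}

#' Two-group presets mirroring a professional vs. university cohort
#'
#' Reaction and displacement distributions use the reported group means and
#' SDs (0.77 +/- 0.12 s and 0.76 +/- 0.11 s for professionals, 0.96 +/-
#' 0.12 s and 0.64 +/- 0.06 s for university athletes). Accuracy presets
#' put the professional response-capacity median at 100% and the
#' university median at 15 correct of 16 (93.75%).
#'
#' @return Named list with `professional` and `university` [group_params()].
#' @export
cohort_presets <- function() {
  list(
    professional = group_params(15L, 0.77, 0.12, 0.76, 0.11, 0.97),
    university = group_params(14L, 0.96, 0.12, 0.64, 0.06, 0.9375)
  )
}

#' Simulator configuration
#'
#' @param seed Master seed; every derived random draw is a deterministic
#'   function of it.
#' @param fps Frame rate, frames per second.
#' @param image_size `c(width, height)`, pixels.
#' @param H Floor-to-image [homography()].
#' @param groups Named list of [group_params()].
#' @param landmark_noise_sd Gaussian jitter added to every landmark
#'   coordinate, px.
#' @param dropout_prob Per-landmark-per-frame probability of a visibility
#'   dropout.
#' @param n_scenarios Scenarios per session.
#' @param foot_length_m Heel-to-toe distance of the foot template on the
#'   floor plane.
#' @param foot_sep_m Lateral offset of the support (left) foot from the
#'   attacking (right) foot.
#' @param lift_px Peak image-space rise of the attacking foot while
#'   airborne. The lift rises to its peak within the first tenth of the
#'   flight (the way toe-off reads on 30 fps video) and touches down at
#'   75% of the flight, leaving the final approach to the minimum-jerk
#'   deceleration.
#' @param no_move_prob Probability that an inaccurate trial is executed as
#'   no movement at all (a no-response) rather than a wrong zone.
#' @param dilation_px Footprint dilation used for the ground-truth
#'   clearance geometry (1080p scale).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, fps = 30, image_size = c(1920L, 1080L),
                       H = default_camera_homography(),
                       groups = cohort_presets(),
                       landmark_noise_sd = 0.5, dropout_prob = 0,
                       n_scenarios = 16L, foot_length_m = 0.26,
                       foot_sep_m = 0.2, lift_px = 100,
                       no_move_prob = 0.1, dilation_px = 10) {
  stopifnot(fps > 0, landmark_noise_sd >= 0, dropout_prob >= 0,
            dropout_prob < 1, lift_px > 0)
  structure(list(seed = as.integer(seed), fps = fps,
                 image_size = as.integer(image_size), H = H,
                 groups = groups, landmark_noise_sd = landmark_noise_sd,
                 dropout_prob = dropout_prob,
                 n_scenarios = as.integer(n_scenarios),
                 foot_length_m = foot_length_m, foot_sep_m = foot_sep_m,
                 lift_px = lift_px, no_move_prob = no_move_prob,
                 dilation_px = dilation_px, layout = make_layout()),
            class = "sim_config")
}

# foot keypoint template on the floor plane (meters), centered on its
# centroid; the foot points toward the display (+y)
foot_template <- function(foot_length_m) {
  half <- foot_length_m / 2
  pts <- rbind(heel = c(0, -half), ankle = c(0.04, -half + 0.07),
               foot_index = c(0, half))
  sweep(pts, 2, colMeans(pts))
}

#' Synthetic ground-truth calibration from the simulator's camera map
#'
#' Zone polygons are the projected 24-gon outlines of the nine circular
#' markers.
#'
#' @param cfg A [sim_config()].
#' @return A [zone_polygon_set()] with source `"synthetic"`.
#' @export
make_synthetic_calibration <- function(cfg) {
  polys <- stats::setNames(lapply(zone_ids(), function(z) {
    project_marker_outline(cfg$H, cfg$layout, z)
  }), zone_ids())
  zone_polygon_set(polys, cfg$H, "synthetic", cfg$layout)
}

#' Render a synthetic calibration frame
#'
#' Draws the nine markers as high-contrast discs on a uniform background at
#' their projected image positions.
#'
#' @param cfg A [sim_config()].
#' @param background Background intensity in [0, 1].
#' @param contrast Disc intensity added over the background (0 yields a
#'   flat frame and therefore no detectable candidates).
#' @return List: `frame` (grayscale matrix, rows = y) and `truth` (the
#'   synthetic [zone_polygon_set()]).
#' @export
render_calibration_frame <- function(cfg, background = 0.15, contrast = 0.7) {
  w <- cfg$image_size[1]; h <- cfg$image_size[2]
  truth <- make_synthetic_calibration(cfg)
  frame <- matrix(background, nrow = h, ncol = w)
  for (z in zone_ids()) {
    pol <- truth$polygons[[z]]
    if (any(pol[, 1] < 0 | pol[, 1] > w - 1 | pol[, 2] < 0 | pol[, 2] > h - 1)) {
      stopf("render error: zone %s projects outside the %dx%d frame", z, w, h)
    }
    if (contrast == 0) next
    xr <- floor(min(pol[, 1])):ceiling(max(pol[, 1]))
    yr <- floor(min(pol[, 2])):ceiling(max(pol[, 2]))
    grid <- expand.grid(x = xr, y = yr)
    inside <- points_in_polygon(grid$x, grid$y, pol)
    px <- grid[inside, ]
    frame[cbind(px$y + 1L, px$x + 1L)] <- background + contrast
  }
  list(frame = frame, truth = truth)
}

minjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Normalized flight progress: minimum-jerk ease-in/ease-out truncated just
# before its asymptotic tail, so the foot lands with a small nonzero
# impact velocity and the stop is sharp within one frame -- an untruncated
# profile would creep over the last few pixels for several frames, leaving
# no observable landing frame at 30 fps. The truncation point is chosen
# per flight so the impact velocity is `v_impact` (m/s) regardless of the
# flight duration; the within-frame position jump at the stop stays under
# ~2 px.
flight_progress <- function(tau, duration_s, dist_m, v_impact = 0.35) {
  tc <- 1 - sqrt(v_impact * duration_s / (30 * dist_m))
  tc <- min(max(tc, 0.75), 0.99)
  pmin(minjerk(tc * pmin(pmax(tau, 0), 1)) / minjerk(tc), 1)
}

# Image-space lift of the airborne foot: a fast rise (full height within
# the first tenth of the flight, the way toe-off reads on 30 fps video)
# and a cosine descent that touches down at 75% of the flight, so the
# final approach to rest is governed by the minimum-jerk deceleration
# alone and stays monotone for the retrospective-window heuristic.
lift_profile <- function(tau) {
  out <- numeric(length(tau))
  rise <- tau > 0 & tau < 0.10
  out[rise] <- sin(pi / 2 * tau[rise] / 0.10)
  mid <- tau >= 0.10 & tau < 0.75
  out[mid] <- (1 + cos(pi * (tau[mid] - 0.10) / 0.65)) / 2
  out
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate one athlete's session with ground truth
#'
#' The athlete stands on the central marker (attacking right foot on the
#' circle, support foot offset laterally), waits out a per-trial reaction
#' latency after each stimulus presentation, then translates the attacking
#' foot to the executed zone along a minimum-jerk path with an airborne
#' image-space lift, rests on the target through the response window, and
#' returns to center during the next configuration phase. The executed
#' zone equals the intended zone with probability `accuracy_prob`,
#' otherwise it is a uniformly drawn wrong peripheral (or, with
#' probability `no_move_prob`, no movement at all). Flight timing is laid
#' out so that the foot completely clears the central circle at
#' presentation + reaction and lands on the target one displacement
#' duration later; the exact clearance frame is recorded by running the
#' footprint-against-center geometry on the noise-free trajectory.
#'
#' @param cfg A [sim_config()].
#' @param gpar A [group_params()].
#' @param athlete_id Identifier string.
#' @param seed Per-athlete seed.
#' @param log Optional pre-built `stimulus_log`; by default a fresh seeded
#'   schedule is drawn.
#' @return List: `stream` ([landmark_stream()]), `log`, `truth` (per-trial
#'   data frame with `true_onset_frame`, `true_arrival_frame`,
#'   `intended_zone`, `executed_zone`, `correct`, `no_move`, `reaction_s`,
#'   `displacement_s`), `athlete_id`.
#' @export
simulate_session <- function(cfg, gpar, athlete_id = "athlete", seed = cfg$seed,
                             log = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(gpar, "group_params"))
  fps <- cfg$fps
  if (is.null(log)) {
    log <- schedule_session(seed, n_scenarios = cfg$n_scenarios, fps = fps)
  }
  scen <- log$scenarios
  n_tr <- nrow(scen)
  pres_t <- scen$onset_time_s
  cycle <- scen$config_s + scen$vis_s + scen$response_s
  total_s <- log$countdown_s + scen$config_s[1] + sum(cycle) + 1
  n_frames <- ceiling(total_s * fps)
  t_frames <- (seq_len(n_frames) - 1L) / fps

  lay <- cfg$layout
  zcent <- layout_centers(lay)
  rownames(zcent) <- lay$zone

  draws <- with_seed(seed + 7L, {
    # athlete-level latent means, then trial-level scatter around them
    m_reaction <- rtruncnorm1(1L, gpar$reaction_mean_s, gpar$reaction_sd_s, 0.2, 1.6)
    m_displacement <- rtruncnorm1(1L, gpar$displacement_mean_s,
                                  gpar$displacement_sd_s, 0.3, 1.5)
    list(
      reaction = rtruncnorm1(n_tr, m_reaction, gpar$reaction_trial_sd_s, 0.1, 1.9),
      displacement = rtruncnorm1(n_tr, m_displacement,
                                 gpar$displacement_trial_sd_s, 0.25, 1.8),
      acc = stats::runif(n_tr), no_move = stats::runif(n_tr),
      wrong = vapply(as.character(scen$target_zone), function(tz) {
        sample(setdiff(peripheral_ids(), tz), 1L)
      }, character(1))
    )
  })

  # attacking (right) foot centroid path on the floor + image-space lift
  path <- matrix(rep(c(0, 0), each = n_frames), ncol = 2)
  lift <- numeric(n_frames)
  truth <- data.frame(
    scenario_index = scen$index, intended_zone = scen$target_zone,
    executed_zone = NA_character_, no_move = FALSE, correct = FALSE,
    reaction_s = draws$reaction, displacement_s = draws$displacement,
    stimulus_frame = round(pres_t * fps),
    true_onset_frame = NA_integer_, true_arrival_frame = NA_integer_,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n_tr)) {
    accurate <- draws$acc[i] <= gpar$accuracy_prob
    if (!accurate && draws$no_move[i] <= cfg$no_move_prob) {
      truth$no_move[i] <- TRUE
      next
    }
    zone <- if (accurate) scen$target_zone[i] else draws$wrong[i]
    truth$executed_zone[i] <- zone
    truth$correct[i] <- zone == scen$target_zone[i]
    r <- draws$reaction[i]
    d <- min(draws$displacement[i], 3.8 - r)
    target <- zcent[zone, ]

    # clearance at presentation + r; physical landing one frame before
    # presentation + r + d, so the smoothed stillness detector (whose
    # centered window reads a sharp stop one frame late) observes the
    # arrival at presentation + r + d
    t_start <- pres_t[i] + r - 1 / fps
    t_out <- d
    tau_out <- (t_frames - t_start) / t_out
    dist_m <- sqrt(sum(target^2))
    sel <- tau_out > 0 & tau_out <= 1.0001
    prog <- flight_progress(tau_out[sel], t_out, dist_m)
    path[sel, 1] <- target[1] * prog
    path[sel, 2] <- target[2] * prog
    lift[sel] <- pmax(lift[sel], cfg$lift_px * lift_profile(tau_out[sel]))

    # at the target through the response window
    t_back <- pres_t[i] + scen$vis_s[i] + scen$response_s[i] + 0.05
    hold <- t_frames > t_start + t_out & t_frames < t_back
    path[hold, 1] <- target[1]; path[hold, 2] <- target[2]

    # return flight to center during the next configuration phase
    tau_ret <- (t_frames - t_back) / 0.6
    selr <- tau_ret > 0 & tau_ret <= 1.0001
    prog_r <- flight_progress(tau_ret[selr], 0.6, dist_m)
    path[selr, 1] <- target[1] * (1 - prog_r)
    path[selr, 2] <- target[2] * (1 - prog_r)
    lift[selr] <- pmax(lift[selr], cfg$lift_px * lift_profile(tau_ret[selr]))
  }

  tmpl <- foot_template(cfg$foot_length_m)
  H <- cfg$H
  build_foot <- function(offset_m, moving) {
    lapply(rownames(tmpl), function(lm) {
      fl <- cbind(path[, 1] * moving + offset_m[1] + tmpl[lm, 1],
                  path[, 2] * moving + offset_m[2] + tmpl[lm, 2])
      im <- project_points(H, fl)
      if (moving) im[, 2] <- im[, 2] - lift
      im
    })
  }
  right <- stats::setNames(build_foot(c(0, 0), 1), rownames(tmpl))
  left <- stats::setNames(build_foot(c(-cfg$foot_sep_m, 0), 0), rownames(tmpl))

  # ground-truth onset: first frame whose noise-free footprint no longer
  # intersects the central circle; arrival: first frame at rest on target
  calib <- make_synthetic_calibration(cfg)
  czone <- calib$polygons[["C"]]
  dil <- cfg$dilation_px * cfg$image_size[2] / 1080
  for (i in seq_len(n_tr)) {
    if (truth$no_move[i]) next
    r <- draws$reaction[i]
    d <- min(draws$displacement[i], 3.8 - r)
    f_move <- floor((pres_t[i] + r - 1 / fps) * fps) + 1L  # first airborne frame
    for (f in f_move:(f_move + 12L)) {
      kp <- rbind(right$heel[f + 1L, ], right$ankle[f + 1L, ],
                  right$foot_index[f + 1L, ])
      fp <- buffer_convex(convex_hull(kp), dil)
      if (poly_intersection_area(czone, fp) <= 0) {
        truth$true_onset_frame[i] <- f
        break
      }
    }
    truth$true_arrival_frame[i] <- ceiling((pres_t[i] + r + d - 1 / fps) * fps - 1e-9)
  }

  frames_df <- with_seed(seed + 13L, {
    noise <- function(n) stats::rnorm(n, 0, cfg$landmark_noise_sd)
    rows <- lapply(list(left = left, right = right), function(foot_lms) {
      lapply(names(foot_lms), function(lm) {
        im <- foot_lms[[lm]]
        data.frame(frame = seq_len(n_frames) - 1L,
                   x_px = im[, 1] + noise(n_frames),
                   y_px = im[, 2] + noise(n_frames),
                   landmark = lm, stringsAsFactors = FALSE)
      })
    })
    df <- do.call(rbind, c(rows$left, rows$right))
    df$foot <- rep(c("left", "right"), each = 3L * n_frames)
    df$visibility <- ifelse(stats::runif(nrow(df)) < cfg$dropout_prob, 0.1, 0.98)
    df
  })
  frames_df$time_s <- frames_df$frame / fps
  stream <- landmark_stream(frames_df, fps = fps, image_size = cfg$image_size)

  list(stream = stream, log = log, truth = truth, athlete_id = athlete_id)
}

#' Simulate a full two-group cohort
#'
#' One seeded session per athlete per group; per-athlete seeds and
#' schedules are derived deterministically from the master seed, so equal
#' seeds give byte-identical cohorts.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort`: `sessions` (list with `group`
#'   attached to each element), `truth_metrics` (per-athlete true mean
#'   VMRS/DS and true RC), `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(cfg$groups)) stopf("the cohort needs at least one group")
  sessions <- list()
  truth_rows <- list()
  k <- 0L
  for (g in names(cfg$groups)) {
    gpar <- cfg$groups[[g]]
    if (gpar$n_athletes < 1L) stopf("group %s has no athletes", g)
    for (a in seq_len(gpar$n_athletes)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", g, a)
      ses <- simulate_session(cfg, gpar, athlete_id = id,
                              seed = cfg$seed + 1000L * k)
      ses$group <- g
      sessions[[id]] <- ses
      tr <- ses$truth
      moved <- !is.na(tr$true_onset_frame)
      vm <- (tr$true_onset_frame[moved] - tr$stimulus_frame[moved]) / cfg$fps
      ds <- (tr$true_arrival_frame[moved] - tr$true_onset_frame[moved]) / cfg$fps
      truth_rows[[id]] <- data.frame(
        athlete_id = id, group = g,
        true_mean_vmrs_s = mean(vm), true_mean_ds_s = mean(ds),
        true_rc_percent = 100 * mean(tr$correct),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(sessions = sessions,
                 truth_metrics = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
                 config = cfg),
            class = "sim_cohort")
}

#' Run the measurement pipeline over a simulated cohort
#'
#' Applies [analyze_session()] to every simulated session against the
#' cohort's synthetic calibration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param params [detector_params()] at 1080p scale.
#' @return Data frame of per-athlete session metrics with a `group` column.
#' @export
analyze_cohort <- function(cohort, params = detector_params()) {
  stopifnot(inherits(cohort, "sim_cohort"))
  calib <- make_synthetic_calibration(cohort$config)
  rows <- lapply(cohort$sessions, function(ses) {
    res <- analyze_session(ses$stream, calib, ses$log, params = params,
                           athlete_id = ses$athlete_id)
    cbind(res$metrics, group = ses$group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}
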