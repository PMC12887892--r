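# Stable ground-contact (step) events from foot trajectories, zone
# grounding by footprint overlap, movement onset and target arrival.

#' Detector parameters
#'
#' Thresholds for the joint contact heuristics. All pixel quantities are
#' defined at 1080p; use [scale_detector_params()] for other resolutions.
#'
#' @param move_threshold Minimal-movement threshold, px/frame: frames with a
#'   smaller displacement count as still.
#' @param stability_window Minimum length of a still run, frames.
#' @param retro_window Retrospective window checked for deceleration to
#'   rest, frames.
#' @param bounding_radius Radius of the compact bounding circle the still
#'   positions must fit in, px.
#' @param min_overlap Minimum footprint-zone overlap fraction that
#'   validates a contact's zone.
#' @param retro_slack_px Tolerated displacement increase within the
#'   retrospective window (absorbs landmark jitter), px/frame.
#' @param merge_gap Still runs separated by fewer than this many moving
#'   frames are merged.
#' @return Object of class `detector_params`.
#' @export
detector_params <- function(move_threshold = 2, stability_window = 3L,
                            retro_window = 5L, bounding_radius = 6,
                            min_overlap = 0.20, retro_slack_px = 0.5,
                            merge_gap = 2L) {
  stopifnot(move_threshold > 0, stability_window > 0, retro_window > 0,
            bounding_radius > 0, min_overlap > 0, min_overlap <= 1,
            retro_slack_px >= 0, merge_gap >= 1)
  structure(list(move_threshold = move_threshold,
                 stability_window = as.integer(stability_window),
                 retro_window = as.integer(retro_window),
                 bounding_radius = bounding_radius,
                 min_overlap = min_overlap,
                 retro_slack_px = retro_slack_px,
                 merge_gap = as.integer(merge_gap)),
            class = "detector_params")
}

#' Rescale pixel thresholds to another image height
#'
#' Pixel-valued detector parameters are defined at 1080p and scale linearly
#' with image height.
#'
#' @param params A [detector_params()].
#' @param image_height Height of the analyzed video, px.
#' @return Rescaled [detector_params()].
#' @export
scale_detector_params <- function(params, image_height) {
  s <- image_height / 1080
  detector_params(
    move_threshold = params$move_threshold * s,
    stability_window = params$stability_window,
    retro_window = params$retro_window,
    bounding_radius = params$bounding_radius * s,
    min_overlap = params$min_overlap,
    retro_slack_px = params$retro_slack_px * s,
    merge_gap = params$merge_gap
  )
}

#' Detect stable ground contacts in a foot trajectory
#'
#' A step event is declared on a maximal run of at least
#' `stability_window` consecutive frames whose smoothed displacement stays
#' below `move_threshold`, provided (i) the displacements over the
#' preceding `retro_window` frames are monotone non-increasing (within
#' `retro_slack_px`), consistent with deceleration to rest, and (ii) the
#' still positions fit inside a circle of radius `bounding_radius`. Runs
#' separated by fewer than `merge_gap` moving frames are merged. When a
#' `stream` is supplied, each event also carries the footprint polygon at
#' its contact frame.
#'
#' @param traj A [smooth_trajectory()] result.
#' @param params A [detector_params()].
#' @param stream Optional [landmark_stream()] used to attach footprints.
#' @param dilation_px Footprint dilation, see [footprint_polygon()].
#' @return List of `step_event` objects: `foot`, `contact_frame`,
#'   `end_frame`, `footprint` (or `NULL`), `zone` (`NA` until grounded) and
#'   `overlap_fraction`.
#' @export
detect_contacts <- function(traj, params = detector_params(), stream = NULL,
                            dilation_px = 10) {
  stopifnot(inherits(traj, "foot_trajectory"))
  n <- nrow(traj)
  if (n < params$stability_window) return(list())
  disp <- traj$displacement
  still <- !is.na(disp) & disp < params$move_threshold & traj$valid

  runs <- runs_of(still)
  if (nrow(runs) == 0L) return(list())
  runs <- merge_runs(runs, still, params$merge_gap)
  runs <- runs[runs$end - runs$start + 1L >= params$stability_window, , drop = FALSE]

  events <- list()
  for (k in seq_len(nrow(runs))) {
    a <- runs$start[k]; b <- runs$end[k]
    if (!retro_decelerating(disp, a, params)) next
    if (!positions_compact(traj$x[a:b], traj$y[a:b], params$bounding_radius)) next
    fp <- NULL
    if (!is.null(stream)) {
      fp <- tryCatch(
        footprint_polygon(stream, traj$frame[a], attr(traj, "foot"),
                          dilation_px = dilation_px),
        error = function(e) NULL
      )
    }
    events[[length(events) + 1L]] <- structure(
      list(foot = attr(traj, "foot"), contact_frame = traj$frame[a],
           end_frame = traj$frame[b], footprint = fp,
           zone = NA_character_, overlap_fraction = NA_real_),
      class = "step_event"
    )
  }
  events
}

runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs, flag, merge_gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, ]
  for (k in 2:nrow(runs)) {
    gap <- runs$start[k] - out$end[nrow(out)] - 1L
    if (gap < merge_gap) {
      out$end[nrow(out)] <- runs$end[k]
    } else {
      out <- rbind(out, runs[k, ])
    }
  }
  out
}

retro_decelerating <- function(disp, run_start, params) {
  lo <- max(2L, run_start - params$retro_window)
  if (lo >= run_start) return(TRUE)  # run begins at the trajectory start
  window <- disp[lo:run_start]
  if (anyNA(window)) return(FALSE)
  all(diff(window) <= params$retro_slack_px) &&
    window[length(window)] < params$move_threshold
}

positions_compact <- function(x, y, radius) {
  cx <- mean(x); cy <- mean(y)
  all(sqrt((x - cx)^2 + (y - cy)^2) <= radius)
}

#' Ground a contact event to a calibrated zone
#'
#' The footprint's overlap fraction (intersection area divided by footprint
#' area) is computed against each of the nine zone polygons; the zone with
#' the maximal fraction is assigned if the fraction reaches `min_overlap`
#' (exact ties resolve in zone index order C, P1..P8). Otherwise the zone
#' stays unassigned with the best fraction recorded.
#'
#' @param event A `step_event` carrying a footprint.
#' @param zones A [zone_polygon_set()].
#' @param params A [detector_params()].
#' @return The event with `zone` and `overlap_fraction` filled in.
#' @export
ground_contact_zone <- function(event, zones, params = detector_params()) {
  stopifnot(inherits(event, "step_event"), inherits(zones, "zone_polygon_set"))
  if (is.null(event$footprint) || event$footprint$area_px2 <= 0) {
    event$zone <- NA_character_
    event$overlap_fraction <- 0
    event$degenerate <- TRUE
    return(event)
  }
  fp <- event$footprint$polygon
  fp_area <- event$footprint$area_px2
  # the footprint (a buffered hull) is convex and serves as the clip
  # polygon, so zone polygons need not be
  frac <- vapply(zones$polygons, function(zp) {
    poly_intersection_area(zp, fp) / fp_area
  }, numeric(1))
  best <- which.max(frac)  # first index wins exact ties (zone order)
  if (frac[best] >= params$min_overlap) {
    event$zone <- names(zones$polygons)[best]
  } else {
    event$zone <- NA_character_
  }
  event$overlap_fraction <- unname(frac[best])
  event
}

point_poly_distance <- function(p, poly) {
  if (points_in_polygon(p[1], p[2], poly)) return(0)
  n <- nrow(poly)
  d2 <- vapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    sum((p - (a + t * ab))^2)
  }, numeric(1))
  sqrt(min(d2))
}

#' Detect movement onset after a stimulus
#'
#' The attacking foot is the first foot whose displacement exceeds
#' `move_threshold` for at least two consecutive frames after the stimulus;
#' the onset is the first frame at which that foot's footprint no longer
#' intersects the central zone (the foot has completely left the central
#' circle). Both feet must be at (or within `center_tolerance_px` of) the
#' central zone at the stimulus frame, otherwise the trial is flagged.
#'
#' @param traj_left,traj_right [smooth_trajectory()] results for the two
#'   feet.
#' @param central_zone Central-zone polygon (image pixels).
#' @param stimulus_frame Frame of stimulus presentation.
#' @param params A [detector_params()].
#' @param stream [landmark_stream()] used to form per-frame footprints.
#' @param next_stimulus_frame Search limit (exclusive).
#' @param center_tolerance_px Allowed distance of each foot's representative
#'   point from the central zone at the stimulus frame.
#' @param dilation_px Footprint dilation, px.
#' @return List with `onset_frame` (`NA` when no movement), `foot`, and
#'   `flag` (`NA`, or `"not_at_center"` when the precondition fails).
#' @export
detect_onset <- function(traj_left, traj_right, central_zone, stimulus_frame,
                         params = detector_params(), stream,
                         next_stimulus_frame = Inf,
                         center_tolerance_px = 40, dilation_px = 10) {
  trajs <- list(left = traj_left, right = traj_right)
  none <- list(onset_frame = NA_integer_, foot = NA_character_, flag = NA_character_)

  for (f in names(trajs)) {
    tr <- trajs[[f]]
    i <- match(stimulus_frame, tr$frame)
    if (is.na(i) || !tr$valid[i]) {
      none$flag <- "not_at_center"; return(none)
    }
    if (point_poly_distance(c(tr$x[i], tr$y[i]), central_zone) > center_tolerance_px) {
      none$flag <- "not_at_center"; return(none)
    }
  }

  move_start <- vapply(trajs, function(tr) {
    idx <- which(tr$frame > stimulus_frame & tr$frame < next_stimulus_frame)
    d <- tr$displacement[idx]
    moving <- !is.na(d) & d > params$move_threshold
    for (k in seq_len(max(0L, length(moving) - 1L))) {
      if (moving[k] && moving[k + 1L]) return(tr$frame[idx[k]])
    }
    NA_integer_
  }, integer(1))

  if (all(is.na(move_start))) return(none)
  foot <- names(which.min(move_start))
  start <- min(move_start, na.rm = TRUE)

  search <- start:(min(next_stimulus_frame - 1, max(trajs[[foot]]$frame)))
  for (fr in search) {
    fp <- tryCatch(footprint_polygon(stream, fr, foot, dilation_px = dilation_px),
                   error = function(e) NULL)
    if (is.null(fp)) next
    if (poly_intersection_area(central_zone, fp$polygon) <= 0) {
      return(list(onset_frame = as.integer(fr), foot = foot, flag = NA_character_))
    }
  }
  none
}

#' Select the zone arrival among detected contacts
#'
#' The arrival is the earliest zone-assigned step event of either foot
#' whose contact frame lies strictly between the movement onset and the
#' next stimulus. Contacts grounded to the central zone are not arrivals
#' (stepping back onto the center is part of the return, not a response).
#'
#' @param events List of grounded `step_event`s (both feet).
#' @param onset_frame Movement-onset frame.
#' @param next_stimulus_frame Upper bound (exclusive).
#' @return The arrival `step_event`, or `NULL` when absent.
#' @export
detect_arrival <- function(events, onset_frame, next_stimulus_frame) {
  if (is.na(onset_frame)) return(NULL)
  cand <- Filter(function(e) {
    !is.na(e$zone) && e$zone != "C" &&
      e$contact_frame > onset_frame && e$contact_frame < next_stimulus_frame
  }, events)
  if (!length(cand)) return(NULL)
  cand[[which.min(vapply(cand, `[[`, numeric(1), "contact_frame"))]]
}

#' Tabulate step events
#'
#' @param events List of `step_event`s.
#' @return Data frame with one row per event.
#' @export
events_table <- function(events) {
  if (!length(events)) {
    return(data.frame(foot = character(), contact_frame = integer(),
                      end_frame = integer(), zone = character(),
                      overlap_fraction = numeric()))
  }
  data.frame(
    foot = vapply(events, `[[`, character(1), "foot"),
    contact_frame = vapply(events, function(e) as.integer(e$contact_frame), integer(1)),
    end_frame = vapply(events, function(e) as.integer(e$end_frame), integer(1)),
    zone = vapply(events, `[[`, character(1), "zone"),
    overlap_fraction = vapply(events, `[[`, numeric(1), "overlap_fraction")
  )
}

#' Write step events to JSON
#'
#' @param events List of grounded `step_event`s.
#' @param path Output file.
#' @export
write_events_json <- function(events, path) {
  obj <- lapply(events, function(e) {
    list(foot = e$foot, contact_frame = e$contact_frame,
         end_frame = e$end_frame,
         zone = if (is.na(e$zone)) NULL else e$zone,
         overlap_fraction = e$overlap_fraction,
         footprint_vertices = if (!is.null(e$footprint)) {
           unname(apply(e$footprint$polygon, 1, function(v) c(v[1], v[2]),
                        simplify = FALSE))
         })
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
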