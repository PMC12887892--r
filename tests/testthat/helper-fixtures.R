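# Shared builders for synthetic test inputs. Everything is generated in
# code; no stored fixtures.

# landmark stream in which each foot's three keypoints ride a small fixed
# triangle around a supplied per-frame centroid path
stream_from_centroids <- function(right_xy, left_xy = NULL, fps = 30,
                                  image_size = c(1920L, 1080L),
                                  visibility = 0.9) {
  n <- nrow(right_xy)
  if (is.null(left_xy)) {
    left_xy <- cbind(right_xy[, 1] - 40, right_xy[, 2])
  }
  tmpl <- rbind(heel = c(0, -15), ankle = c(5, -6), foot_index = c(0, 18))
  tmpl <- sweep(tmpl, 2, colMeans(tmpl))
  one_foot <- function(xy, foot) {
    do.call(rbind, lapply(rownames(tmpl), function(lm) {
      data.frame(frame = seq_len(n) - 1L,
                 x_px = xy[, 1] + tmpl[lm, 1],
                 y_px = xy[, 2] + tmpl[lm, 2],
                 foot = foot, landmark = lm,
                 visibility = visibility, stringsAsFactors = FALSE)
    }))
  }
  landmark_stream(rbind(one_foot(right_xy, "right"), one_foot(left_xy, "left")),
                  fps = fps, image_size = image_size)
}

# foot_trajectory built directly from a point path (no smoothing), for
# exercising the contact detector in isolation
traj_from_points <- function(xy, fps = 30, foot = "right", valid = TRUE) {
  n <- nrow(xy)
  disp <- c(NA_real_, sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  out <- data.frame(frame = seq_len(n) - 1L, x = xy[, 1], y = xy[, 2],
                    displacement = disp, valid = rep_len(valid, n))
  attr(out, "foot") <- foot
  attr(out, "fps") <- fps
  class(out) <- c("foot_trajectory", "data.frame")
  out
}

# a centroid path that moves, decelerates to rest, holds, and moves on:
# speed px/frame over n_move frames with linear deceleration over the
# last decel frames, then n_still still frames, then moves again
scripted_move_stop_move <- function(n_move = 40, speed = 8, decel = 5,
                                    n_still = 20, n_tail = 20) {
  v <- c(rep(speed, n_move - decel), seq(speed, 0, length.out = decel + 1)[-1],
         rep(0, n_still), rep(speed, n_tail))
  x <- cumsum(c(0, v))
  cbind(x = 100 + x, y = rep(300, length(x)))
}

# nine well-separated square zones with an identity-scale homography, for
# grounding tests where exact overlap fractions are constructed by hand
square_zone_set <- function(side = 20, spacing = 120) {
  lay <- make_layout()
  ctr <- layout_centers(lay) * spacing / 2
  ctr[, 1] <- ctr[, 1] + 500
  ctr[, 2] <- ctr[, 2] + 500
  polys <- stats::setNames(lapply(seq_len(9), function(i) {
    cx <- ctr[i, 1]; cy <- ctr[i, 2]; h <- side / 2
    rbind(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h), c(cx - h, cy + h))
  }), lay$zone)
  H <- homography(matrix(c(spacing / 2, 0, 500, 0, spacing / 2, 500, 0, 0, 1),
                         3, 3, byrow = TRUE))
  zone_polygon_set(polys, H, "synthetic", lay)
}

mk_event <- function(polygon, foot = "right", frame = 10L, zone = NA_character_) {
  structure(list(foot = foot, contact_frame = frame, end_frame = frame + 5L,
                 footprint = structure(list(foot = foot, frame_index = frame,
                                            polygon = polygon,
                                            area_px2 = poly_area(polygon),
                                            mask_ignored = FALSE),
                                       class = "footprint_polygon"),
                 zone = zone, overlap_fraction = NA_real_),
            class = "step_event")
}

rect_poly <- function(x0, y0, w, h) {
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
}

# small simulated cohort config used across detector/pipeline tests
test_sim_config <- function(seed = 11, noise = 0.5, groups = NULL, ...) {
  if (is.null(groups)) {
    groups <- list(pro = group_params(2L, 0.77, 0.12, 0.76, 0.11, 1))
  }
  sim_config(seed = seed, landmark_noise_sd = noise, groups = groups, ...)
}
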