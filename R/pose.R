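# Per-frame foot-landmark streams from any pose backend (heel, ankle,
# foot-index per foot, pixel coordinates plus a visibility score), light
# temporal smoothing, and footprint polygons for contact grounding.

LANDMARKS <- c("heel", "ankle", "foot_index")
FEET <- c("left", "right")

#' Construct a landmark stream
#'
#' @param frames Data frame with columns `frame`, `foot`
#'   (`"left"`/`"right"`), `landmark` (`"heel"`, `"ankle"`, `"foot_index"`),
#'   `x_px`, `y_px`, `visibility` (in [0, 1]) and optionally `time_s`; one
#'   row per foot-landmark per frame.
#' @param fps Frame rate, frames per second (> 0).
#' @param image_size Integer `c(width, height)` of the source video, pixels.
#' @return Object of class `landmark_stream`.
#' @export
landmark_stream <- function(frames, fps = 30, image_size = c(1920L, 1080L)) {
  stopifnot(is.data.frame(frames), fps > 0)
  need <- c("frame", "foot", "landmark", "x_px", "y_px", "visibility")
  if (!all(need %in% names(frames))) {
    stopf("landmark frames need columns: %s", paste(need, collapse = ", "))
  }
  if (!all(frames$foot %in% FEET)) stopf("foot must be 'left' or 'right'")
  if (!all(frames$landmark %in% LANDMARKS)) {
    stopf("landmark must be one of %s", paste(LANDMARKS, collapse = ", "))
  }
  if (any(frames$visibility < 0 | frames$visibility > 1)) {
    stopf("visibility must lie in [0, 1]")
  }
  idx <- sort(unique(frames$frame))
  if (any(idx < 0) || any(idx != round(idx))) stopf("frame indices must be non-negative integers")
  if (!("time_s" %in% names(frames))) frames$time_s <- frames$frame / fps
  frames <- frames[order(frames$frame, frames$foot, match(frames$landmark, LANDMARKS)), ]
  rownames(frames) <- NULL
  structure(list(frames = frames, fps = fps, image_size = as.integer(image_size)),
            class = "landmark_stream")
}

#' @export
print.landmark_stream <- function(x, ...) {
  cat(sprintf("Landmark stream: %d frames at %g fps (%dx%d px)\n",
              length(unique(x$frames$frame)), x$fps,
              x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Read a landmark stream from CSV
#'
#' Expected columns: `frame,time_s,foot,landmark,x_px,y_px,visibility`, one
#' row per foot-landmark per frame.
#'
#' @param path CSV file.
#' @param fps Frame rate; when `NULL`, inferred from the `time_s` column.
#' @param image_size `c(width, height)` of the source video.
#' @return A [landmark_stream()].
#' @export
read_landmarks_csv <- function(path, fps = NULL, image_size = c(1920L, 1080L)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(fps)) {
    tt <- unique(df[, c("frame", "time_s")])
    tt <- tt[order(tt$frame), ]
    if (nrow(tt) < 2L) stopf("cannot infer fps from a single frame; pass fps")
    fps <- 1 / stats::median(diff(tt$time_s) / diff(tt$frame))
  }
  landmark_stream(df, fps = fps, image_size = image_size)
}

#' Write a landmark stream to CSV
#'
#' @param stream A [landmark_stream()].
#' @param path Output file.
#' @export
write_landmarks_csv <- function(stream, path) {
  cols <- c("frame", "time_s", "foot", "landmark", "x_px", "y_px", "visibility")
  utils::write.csv(stream$frames[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a foot trajectory
#'
#' The representative foot point is the centroid of the heel, ankle and
#' foot-index landmarks. Landmarks with visibility below
#' `visibility_threshold` are treated as dropouts: gaps of at most
#' `max_gap` frames are filled by linear interpolation, longer gaps mark
#' the trajectory invalid over the affected frames. The centroid sequence
#' is then smoothed with a centered moving average of odd length `window`
#' (truncated at the edges), and per-frame displacement magnitudes are the
#' Euclidean steps of the smoothed point.
#'
#' @param stream A [landmark_stream()].
#' @param foot `"left"` or `"right"`.
#' @param window Odd smoothing window length in frames (1 = no smoothing).
#' @param visibility_threshold Landmarks below this visibility count as
#'   missing.
#' @param max_gap Longest dropout (frames) bridged by interpolation.
#' @return Object of class `foot_trajectory`: data frame with columns
#'   `frame`, `x`, `y`, `displacement` (px/frame, `NA` on the first frame)
#'   and `valid`; attributes `foot` and `fps`.
#' @export
smooth_trajectory <- function(stream, foot = c("left", "right"), window = 3L,
                              visibility_threshold = 0.5, max_gap = 5L) {
  foot <- match.arg(foot)
  stopifnot(inherits(stream, "landmark_stream"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stopf("window must be a positive odd integer")

  df <- stream$frames[stream$frames$foot == foot, ]
  if (nrow(df) == 0L) stopf("stream contains no '%s' foot landmarks", foot)
  frames <- sort(unique(df$frame))
  n <- length(frames)

  # per-frame centroid, defined only when all three landmarks are visible
  cx <- cy <- rep(NA_real_, n)
  key <- match(df$frame, frames)
  vis_ok <- df$visibility >= visibility_threshold
  agg_n <- tapply(vis_ok, key, sum)
  sx <- tapply(ifelse(vis_ok, df$x_px, 0), key, sum)
  sy <- tapply(ifelse(vis_ok, df$y_px, 0), key, sum)
  full <- which(agg_n == length(LANDMARKS))
  cx[full] <- sx[full] / 3
  cy[full] <- sy[full] / 3

  valid <- !is.na(cx)
  if (!any(valid)) stopf("no frame has all three '%s' landmarks visible", foot)
  filled <- fill_gaps(cx, cy, valid, max_gap)
  cx <- filled$x; cy <- filled$y; valid <- filled$valid

  sm_x <- moving_average_na(cx, window)
  sm_y <- moving_average_na(cy, window)
  disp <- c(NA_real_, sqrt(diff(sm_x)^2 + diff(sm_y)^2))

  out <- data.frame(frame = frames, x = sm_x, y = sm_y,
                    displacement = disp, valid = valid)
  attr(out, "foot") <- foot
  attr(out, "fps") <- stream$fps
  class(out) <- c("foot_trajectory", "data.frame")
  out
}

# linear interpolation across dropout gaps of length <= max_gap; longer
# gaps (and leading/trailing missing stretches) stay invalid
fill_gaps <- function(x, y, valid, max_gap) {
  n <- length(x)
  miss <- !valid
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      a <- starts[k]; b <- ends[k]
      interior <- a > 1L && b < n
      if (interior && (b - a + 1L) <= max_gap) {
        t0 <- a - 1L; t1 <- b + 1L
        w <- (seq(a, b) - t0) / (t1 - t0)
        x[a:b] <- x[t0] + w * (x[t1] - x[t0])
        y[a:b] <- y[t0] + w * (y[t1] - y[t0])
        valid[a:b] <- TRUE
      }
    }
  }
  list(x = x, y = y, valid = valid)
}

moving_average_na <- function(x, window) {
  if (!anyNA(x)) return(moving_average(x, window))
  # average over valid runs independently so invalid gaps do not leak
  out <- x
  ok <- !is.na(x)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    out[idx] <- moving_average(x[idx], window)
  }
  out
}

#' Footprint polygon at a frame
#'
#' The footprint is the convex hull of the three foot keypoints dilated by
#' `dilation_px`. When a binary segmentation `mask` is supplied, the
#' footprint is intersected with the connected mask component containing
#' the keypoints; if all keypoints fall outside the mask, the mask is
#' ignored and the result flagged.
#'
#' @param stream A [landmark_stream()].
#' @param frame_index Frame to evaluate.
#' @param foot `"left"` or `"right"`.
#' @param mask Optional binary image matrix (rows = y).
#' @param dilation_px Hull dilation radius in pixels. The default 10 px is
#'   defined at 1080p; pass a scaled value for other resolutions.
#' @return Object of class `footprint_polygon`: list with `foot`,
#'   `frame_index`, `polygon` (vertex matrix, image pixels), `area_px2` and
#'   `mask_ignored`.
#' @export
footprint_polygon <- function(stream, frame_index, foot = c("left", "right"),
                              mask = NULL, dilation_px = 10) {
  foot <- match.arg(foot)
  stopifnot(inherits(stream, "landmark_stream"), dilation_px >= 0)
  df <- stream$frames
  sel <- df$frame == frame_index & df$foot == foot
  if (sum(sel) < length(LANDMARKS)) {
    stopf("frame %d does not carry all three %s-foot keypoints", frame_index, foot)
  }
  kp <- as.matrix(df[sel, c("x_px", "y_px")])
  hull <- if (nrow(unique(kp)) >= 3L && poly_area(kp[grDevices::chull(kp), , drop = FALSE]) > 0) {
    convex_hull(kp)
  } else kp  # collinear or coincident keypoints: dilation provides the area
  poly <- buffer_convex(hull, dilation_px)

  mask_ignored <- FALSE
  if (!is.null(mask)) {
    inside <- mask_values_at(mask, kp)
    if (!any(inside)) {
      mask_ignored <- TRUE
    } else {
      comp <- mask_component_polygon(mask, kp[which(inside)[1], ])
      if (!is.null(comp)) {
        clipped <- clip_polygon_convex(comp, poly)  # poly (convex) as clip
        if (nrow(clipped) >= 3L && poly_area(clipped) > 0) poly <- clipped
      }
    }
  }
  structure(list(foot = foot, frame_index = frame_index, polygon = poly,
                 area_px2 = poly_area(poly), mask_ignored = mask_ignored),
            class = "footprint_polygon")
}

mask_values_at <- function(mask, pts) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- pmin(pmax(round(pts[, 2]) + 1L, 1L), nr)  # 0-based y -> row
  c_ <- pmin(pmax(round(pts[, 1]) + 1L, 1L), nc)
  mask[cbind(r, c_)] > 0
}

mask_component_polygon <- function(mask, seed_xy) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask > 0)))
  sx <- pmin(pmax(round(seed_xy[1]) + 1L, 1L), dim(lab)[1])
  sy <- pmin(pmax(round(seed_xy[2]) + 1L, 1L), dim(lab)[2])
  id <- lab[sx, sy]
  if (id == 0) return(NULL)
  oc <- EBImage::ocontour(lab)[[id]]
  colnames(oc) <- c("x", "y")
  oc
}
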