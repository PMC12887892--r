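# Calibration of the nine floor-target zones in image space.
#
# Image convention throughout the package: a frame is a numeric matrix with
# rows = y (top to bottom) and columns = x (left to right), intensities in
# [0, 1]. Image coordinates are 0-based pixels, x right, y down. Floor
# coordinates are meters with the origin at the central marker.

#' Construct a calibrated zone-polygon set
#'
#' Bundles the nine target-zone polygons (image pixels) with the
#' floor-to-image homography and the calibration provenance.
#'
#' @param polygons Named list (names = [zone_ids()]) of n x 2 vertex
#'   matrices, each a simple polygon with positive area; interiors must be
#'   pairwise disjoint.
#' @param homography A [homography()] (floor meters -> image pixels).
#' @param source One of `"automatic"`, `"semiautomatic"`, `"synthetic"`.
#' @param layout The [make_layout()] the calibration refers to.
#' @return Object of class `zone_polygon_set`.
#' @export
zone_polygon_set <- function(polygons, homography, source, layout = make_layout()) {
  source <- match.arg(source, c("automatic", "semiautomatic", "synthetic"))
  ids <- zone_ids()
  if (!setequal(names(polygons), ids)) {
    stopf("polygons must be named by the nine zone ids C, P1..P8")
  }
  polygons <- lapply(polygons[ids], as_point_matrix)
  areas <- vapply(polygons, poly_area, numeric(1))
  if (any(areas <= 0)) stopf("every zone polygon must have positive area")
  for (i in 1:8) for (j in (i + 1):9) {
    ov <- poly_intersection_area(polygons[[i]], polygons[[j]])
    if (ov > 1e-6 * min(areas[i], areas[j])) {
      stopf("zone polygons %s and %s overlap", ids[i], ids[j])
    }
  }
  structure(
    list(polygons = polygons, homography = homography,
         source = source, layout = layout),
    class = "zone_polygon_set"
  )
}

#' @export
print.zone_polygon_set <- function(x, ...) {
  cat(sprintf("Zone calibration (%s): 9 polygons, homography RMS %s px\n",
              x$source,
              if (is.null(attr(x$homography, "rms_px"))) "n/a"
              else sprintf("%.3f", attr(x$homography, "rms_px"))))
  invisible(x)
}

#' Detect candidate marker regions in a still frame
#'
#' Contrast-based region finding: global Otsu threshold (the polarity whose
#' foreground is the sparser is taken as the markers), connected components,
#' then filtering by circularity `4*pi*A/P^2` and plausible area. Candidates
#' are returned ranked by circularity and closeness to the expected marker
#' area; fewer than nine candidates simply triggers the semiautomatic
#' fallback downstream.
#'
#' @param frame Grayscale image matrix (rows = y), intensities in [0, 1].
#' @param expected_area_px2 Expected marker area in px^2; when `NULL` the
#'   median area of the circular candidates is used as reference.
#' @param min_circularity Minimum circularity to keep a region.
#' @param area_range Acceptable area as multiples of the expected area.
#' @return List of candidates, each with `polygon` (contour vertices,
#'   0-based pixels), `centroid`, `area` and `circularity`; empty when the
#'   frame is flat or nothing passes the filters.
#' @export
detect_zone_regions <- function(frame, expected_area_px2 = NULL,
                                min_circularity = 0.6,
                                area_range = c(0.25, 4)) {
  frame <- as.matrix(frame)
  if (diff(range(frame)) < 1e-3) return(list())
  img <- EBImage::Image(t(frame))  # EBImage: first dimension is x
  th <- EBImage::otsu(img, range = range(frame))
  fg_hi <- img > th
  fg_lo <- img < th
  frac_hi <- mean(fg_hi); frac_lo <- mean(fg_lo)
  fg <- if (frac_hi > 0 && (frac_lo == 0 || frac_hi <= frac_lo)) fg_hi else fg_lo
  lab <- EBImage::bwlabel(fg)
  n_obj <- max(lab)
  if (n_obj == 0) return(list())

  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  contours <- EBImage::ocontour(lab)
  area <- shp[, "s.area"]
  per <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / per^2, 1)

  keep <- circ >= min_circularity & area >= 9
  if (!any(keep)) return(list())
  ref <- expected_area_px2 %||% stats::median(area[keep])
  keep <- keep & area >= area_range[1] * ref & area <= area_range[2] * ref
  if (!any(keep)) return(list())

  idx <- which(keep)
  score <- circ[idx] - abs(log(area[idx] / ref)) / 10
  idx <- idx[order(score, decreasing = TRUE)]
  lapply(idx, function(i) {
    # markers are circular: the convex hull cleans the pixel-staircase
    # contour and keeps downstream polygon clipping exact
    pol <- convex_hull(contours[[i]])
    colnames(pol) <- c("x", "y")
    list(
      polygon = pol,
      centroid = c(x = unname(mom[i, "m.cx"]) - 1, y = unname(mom[i, "m.cy"]) - 1),
      area = unname(area[i]),
      circularity = unname(circ[i])
    )
  })
}

# Exact minimal-total-cost assignment (rows -> distinct columns) by
# depth-first branch and bound; rows are processed in order and columns in
# increasing cost, so exact cost ties resolve deterministically.
assign_minimal <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  row_min <- apply(cost, 1, min)
  suffix_min <- rev(cumsum(rev(row_min)))  # lower bound over rows i..n
  best_cost <- Inf
  best_assign <- NULL
  used <- logical(m)
  cur <- integer(n)
  rec <- function(i, acc) {
    if (i > n) {
      if (acc < best_cost) { best_cost <<- acc; best_assign <<- cur }
      return()
    }
    if (acc + suffix_min[i] >= best_cost) return()
    for (j in order(cost[i, ])) {
      if (used[j]) next
      lb <- acc + cost[i, j] + if (i < n) suffix_min[i + 1] else 0
      if (lb >= best_cost) next
      used[j] <<- TRUE; cur[i] <<- j
      rec(i + 1, acc + cost[i, j])
      used[j] <<- FALSE
    }
  }
  rec(1L, 0)
  best_assign
}

projected_marker_radius <- function(H, layout, zone) {
  ctr <- as.numeric(layout[layout$zone == zone, c("cx", "cy")])
  r <- attr(layout, "marker_diameter_m") / 2
  outline <- project_points(H, circle_polygon(ctr[1], ctr[2], r))
  sqrt(poly_area(outline) / pi)
}

project_marker_outline <- function(H, layout, zone, n = 24L) {
  ctr <- as.numeric(layout[layout$zone == zone, c("cx", "cy")])
  r <- attr(layout, "marker_diameter_m") / 2
  project_points(H, circle_polygon(ctr[1], ctr[2], r, n))
}

# Label >= 9 candidates without prior zone knowledge. The candidate
# nearest the cloud centroid is the central marker. Because a floor-plane
# rotation composes with any homography into an equally valid homography,
# the ring of peripherals cannot be labeled from reprojection error alone;
# labels are anchored by the camera-orientation convention instead: the
# camera hangs upright above the display, so P1 (floor +x) is the
# peripheral to the image right of the center and P3 (floor +y, toward
# the display) points toward the image top. Among the 16 candidate
# (rotation, direction) labelings the one best aligned with those two
# axes wins; the homography is then estimated from all nine labeled
# centroids.
label_candidates_automatic <- function(cands, layout) {
  cents <- t(vapply(cands, `[[`, numeric(2), "centroid"))
  cloud <- colMeans(cents)
  d_cloud <- sqrt(rowSums(sweep(cents, 2, cloud)^2))
  ic <- which.min(d_cloud)
  per_idx <- setdiff(seq_len(nrow(cents)), ic)
  ang <- atan2(cents[per_idx, 2] - cents[ic, 2], cents[per_idx, 1] - cents[ic, 1])
  per_idx <- per_idx[order(ang)]
  lay_cent <- layout_centers(layout)

  unit_to <- function(i) {
    v <- cents[i, ] - cents[ic, ]
    v / sqrt(sum(v^2))
  }
  best <- NULL
  for (dir in c(1L, -1L)) for (rot in 0:7) {
    ordered <- if (dir == 1L) per_idx else rev(per_idx)
    cand_for_p <- ordered[((seq_len(8) - 1 + rot) %% 8) + 1]
    u1 <- unit_to(cand_for_p[1])            # should face image +x
    u3 <- unit_to(cand_for_p[3])            # should face image -y (up)
    score <- (1 - u1[1]) + (1 + u3[2])
    if (is.null(best) || score < best$score - 1e-9) {
      best <- list(score = score, idx = c(ic, cand_for_p))
    }
  }
  H <- estimate_homography(lay_cent, cents[best$idx, , drop = FALSE])
  list(idx = best$idx, H = H, rms = attr(H, "rms_px"))
}

#' Complete a nine-zone calibration from detected candidates
#'
#' Automatic path: with at least nine consistent candidates, labels are
#' assigned by minimal-total-distance matching against the projected layout
#' centers and the homography is estimated from all nine centroids.
#' Semiautomatic path: six or more clicked zone centers (with explicit zone
#' ids) determine the homography; the remaining centers are projected and
#' each synthesized polygon is re-centered onto the nearest candidate region
#' within a search radius of 1.5 projected marker radii.
#'
#' @param candidates Candidate list from [detect_zone_regions()] (may be
#'   empty on the semiautomatic path).
#' @param clicked_centers Optional data frame with columns `zone`, `x`, `y`:
#'   the clicked image centers of at least six zones (the near field).
#' @param layout A [make_layout()].
#' @return A [zone_polygon_set()].
#' @export
complete_calibration <- function(candidates, clicked_centers = NULL,
                                 layout = make_layout()) {
  ids <- zone_ids()
  lay_cent <- layout_centers(layout)

  if (is.null(clicked_centers)) {
    if (length(candidates) < 9L) {
      stopf("automatic calibration needs at least 9 candidate regions (got %d); supply clicked centers for the semiautomatic path",
            length(candidates))
    }
    cands <- candidates[seq_len(9L)]
    lab <- label_candidates_automatic(cands, layout)
    cents <- t(vapply(cands, `[[`, numeric(2), "centroid"))
    # refine labels with minimal-total-distance assignment (zones x candidates)
    proj <- project_points(lab$H, lay_cent)
    cost <- outer(seq_len(9L), seq_len(9L), Vectorize(function(z, ci) {
      sqrt(sum((proj[z, ] - cents[ci, ])^2))
    }))
    asg <- assign_minimal(cost)  # asg[z] = candidate index for zone z
    spacing <- min(stats::dist(proj))
    if (any(cost[cbind(seq_len(9L), asg)] > 0.5 * spacing)) {
      bad <- which(cost[cbind(seq_len(9L), asg)] > 0.5 * spacing)[1]
      stopf("labeling conflict: no unambiguous candidate for zone %s", ids[bad])
    }
    polys <- stats::setNames(lapply(asg, function(ci) cands[[ci]]$polygon), ids)
    H <- estimate_homography(lay_cent, cents[asg, , drop = FALSE])
    return(zone_polygon_set(polys, H, "automatic", layout))
  }

  clicks <- as.data.frame(clicked_centers)
  if (!all(c("zone", "x", "y") %in% names(clicks))) {
    stopf("clicked_centers must have columns zone, x, y")
  }
  clicks$zone <- as.character(clicks$zone)
  if (!all(clicks$zone %in% ids) || anyDuplicated(clicks$zone)) {
    stopf("clicked zone ids must be distinct and among C, P1..P8")
  }
  if (nrow(clicks) < 6L) {
    stopf("insufficient calibration: %d clicked centers, the semiautomatic path needs at least 6", nrow(clicks))
  }
  fl <- lay_cent[match(clicks$zone, ids), , drop = FALSE]
  H <- estimate_homography(fl, as.matrix(clicks[, c("x", "y")]))

  cents <- if (length(candidates)) {
    t(vapply(candidates, `[[`, numeric(2), "centroid"))
  } else matrix(numeric(0), 0, 2)

  polys <- vector("list", 9L); names(polys) <- ids
  for (z in ids) {
    proj_ctr <- drop(project_points(H, lay_cent[match(z, ids), , drop = FALSE]))
    radius <- projected_marker_radius(H, layout, z)
    outline <- project_marker_outline(H, layout, z)
    cand_i <- NA_integer_
    if (nrow(cents)) {
      d <- sqrt(rowSums(sweep(cents, 2, proj_ctr)^2))
      if (min(d) <= 1.5 * radius) cand_i <- which.min(d)
    }
    if (!is.na(cand_i)) {
      # re-center the projected outline onto the high-contrast region; the
      # detected contour itself is the best polygon when available
      polys[[z]] <- candidates[[cand_i]]$polygon
    } else if (z %in% clicks$zone) {
      shift <- as.numeric(clicks[match(z, clicks$zone), c("x", "y")]) - poly_centroid(outline)
      polys[[z]] <- sweep(outline, 2, shift, `+`)
    } else {
      polys[[z]] <- outline
    }
  }
  zone_polygon_set(polys, H, "semiautomatic", layout)
}

#' Write a calibration artifact to JSON
#'
#' @param zps A [zone_polygon_set()].
#' @param path Output file.
#' @export
write_calibration <- function(zps, path) {
  stopifnot(inherits(zps, "zone_polygon_set"))
  lay <- zps$layout
  obj <- list(
    layout = list(
      radius_m = sqrt(sum(as.numeric(lay[lay$zone == "P1", c("cx", "cy")])^2)),
      marker_diameter_m = attr(lay, "marker_diameter_m")
    ),
    homography = as.numeric(t(unclass(zps$homography))),  # row-major
    zones = lapply(zone_ids(), function(z) {
      list(id = z, vertices = unname(apply(zps$polygons[[z]], 1, function(v) c(v[1], v[2]), simplify = FALSE)))
    }),
    source = zps$source
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration artifact from JSON
#'
#' @param path File written by [write_calibration()].
#' @return A [zone_polygon_set()].
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- make_layout(radius_m = obj$layout$radius_m,
                     marker_diameter_m = obj$layout$marker_diameter_m)
  H <- homography(matrix(obj$homography, 3, 3, byrow = TRUE))
  zl <- obj$zones
  polys <- stats::setNames(
    lapply(seq_len(nrow(zl)), function(i) {
      v <- zl$vertices[[i]]
      m <- if (is.list(v)) do.call(rbind, v) else as.matrix(v)
      colnames(m) <- c("x", "y")
      m
    }),
    zl$id
  )
  zone_polygon_set(polys, H, obj$source, lay)
}

#' Read a still frame from a PNG file
#'
#' RGB images are converted to grayscale by luminance.
#'
#' @param path PNG file.
#' @return Grayscale matrix (rows = y), intensities in [0, 1].
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a
}

#' Write a grayscale frame to a PNG file
#'
#' @param frame Matrix (rows = y) with intensities in [0, 1].
#' @param path Output file.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(pmin(pmax(frame, 0), 1), path)
  invisible(path)
}
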