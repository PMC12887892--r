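# Planar polygon primitives used for footprints and calibrated target zones.
# Polygons are n x 2 matrices of vertices; the closing edge is implicit
# (first vertex is not repeated). Zone polygons are convex (projected circle
# outlines), which is what the clipping routine relies on.

signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a simple polygon
#'
#' @param p n x 2 vertex matrix (implicitly closed).
#' @return Absolute area in the square of the coordinate unit.
#' @export
poly_area <- function(p) {
  p <- as_point_matrix(p)
  if (nrow(p) < 3L) return(0)
  abs(signed_area(p))
}

ensure_ccw <- function(p) {
  if (signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Regular polygon approximating a circle
#'
#' @param cx,cy Center.
#' @param r Radius.
#' @param n Number of vertices.
#' @return n x 2 vertex matrix.
#' @export
circle_polygon <- function(cx, cy, r, n = 24L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

#' Convex hull of a point set
#'
#' @param pts n x 2 matrix of points.
#' @return Vertex matrix of the hull in counter-clockwise order.
#' @export
convex_hull <- function(pts) {
  pts <- as_point_matrix(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  ensure_ccw(pts[idx, , drop = FALSE])
}

#' Intersection of a polygon with a convex polygon
#'
#' Sutherland-Hodgman clipping of `subject` against the convex polygon
#' `clip`. Returns the clipped vertex matrix (possibly with zero rows when
#' the polygons are disjoint).
#'
#' @param subject n x 2 vertex matrix (any simple polygon).
#' @param clip m x 2 vertex matrix; must be convex.
#' @return Vertex matrix of the intersection polygon.
#' @export
clip_polygon_convex <- function(subject, clip) {
  out <- as_point_matrix(subject)
  clip <- ensure_ccw(as_point_matrix(clip))
  m <- nrow(clip)
  for (i in seq_len(m)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]
    b <- clip[if (i == m) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # cross((b - a), (p - a)): >= 0 lies inside the CCW clip edge
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    res <- matrix(0, 0, 2)
    for (k in seq_len(n)) {
      kn <- if (k == n) 1L else k + 1L
      p <- out[k, ]; q <- out[kn, ]
      pin <- side[k] >= 0; qin <- side[kn] >= 0
      if (pin) res <- rbind(res, p)
      if (xor(pin, qin)) {
        t <- side[k] / (side[k] - side[kn])
        res <- rbind(res, p + t * (q - p))
      }
    }
    out <- res
  }
  colnames(out) <- c("x", "y")
  out
}

#' Area of intersection between a polygon and a convex polygon
#'
#' @inheritParams clip_polygon_convex
#' @return Intersection area (0 when disjoint).
#' @export
poly_intersection_area <- function(subject, clip) {
  inter <- clip_polygon_convex(subject, clip)
  if (nrow(inter) < 3L) 0 else poly_area(inter)
}

#' Dilate (buffer) a convex polygon
#'
#' Minkowski sum of a convex polygon with a disc of radius `d`, realised as
#' the convex hull of `n_arc` samples on a circle of radius `d` around each
#' vertex. For `d = 0` the polygon is returned unchanged.
#'
#' @param p Vertex matrix of a convex polygon (or a point/segment as a
#'   degenerate polygon with fewer than three vertices).
#' @param d Dilation radius, same unit as the coordinates; must be >= 0.
#' @param n_arc Samples per vertex arc.
#' @return Vertex matrix of the dilated polygon.
#' @export
buffer_convex <- function(p, d, n_arc = 12L) {
  p <- as_point_matrix(p)
  stopifnot(d >= 0)
  if (d == 0) return(if (nrow(p) >= 3L) convex_hull(p) else p)
  ring <- circle_polygon(0, 0, d, n_arc)
  pts <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    sweep(ring, 2, p[i, ], `+`)
  }))
  convex_hull(pts)
}

#' Test whether points lie inside a polygon
#'
#' @param px,py Point coordinates.
#' @param poly Vertex matrix.
#' @param boundary Count boundary points as inside.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, poly, boundary = TRUE) {
  poly <- as_point_matrix(poly)
  pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = boundary)
}

poly_centroid <- function(p) {
  p <- as_point_matrix(p)
  a <- signed_area(p)
  if (abs(a) < 1e-12) return(colMeans(p))
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}
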