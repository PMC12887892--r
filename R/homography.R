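#' Construct a homography object
#'
#' A homography is a 3x3 invertible projective map taking floor-plane
#' coordinates (meters) to image coordinates (pixels). The matrix is stored
#' normalized so that the bottom-right entry is 1.
#'
#' @param matrix Numeric 3x3 matrix, floor -> image.
#' @return Object of class `homography`.
#' @export
homography <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !all(dim(m) == c(3L, 3L)) || any(!is.finite(m))) {
    stopf("a homography must be a finite numeric 3x3 matrix")
  }
  if (abs(det(m)) < 1e-12) {
    stopf("homography matrix is singular (rank-deficient)")
  }
  if (abs(m[3, 3]) < 1e-12) {
    stopf("homography cannot be normalized: bottom-right entry is zero")
  }
  m <- m / m[3, 3]
  structure(m, class = c("homography", "matrix", "array"))
}

#' @export
print.homography <- function(x, ...) {
  cat("Planar homography (floor meters -> image pixels):\n")
  print(unclass(x), ...)
  invisible(x)
}

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) {
    if (length(pts) != 2L) stopf("points must be an n x 2 matrix or a length-2 vector")
    pts <- matrix(pts, ncol = 2L)
  }
  pts <- as.matrix(pts)
  if (ncol(pts) != 2L) stopf("points must have two columns (x, y)")
  storage.mode(pts) <- "double"
  pts
}

#' Project points through a homography
#'
#' Applies the projective map with perspective division. With
#' `inverse = TRUE` the map is applied in the image -> floor direction.
#'
#' @param H A [homography()].
#' @param points n x 2 matrix (or length-2 vector) of points.
#' @param inverse Logical; apply the inverse map.
#' @return n x 2 matrix of projected points.
#' @export
project_points <- function(H, points, inverse = FALSE) {
  stopifnot(inherits(H, "homography"))
  pts <- as_point_matrix(points)
  M <- if (inverse) solve(unclass(H)) else unclass(H)
  ph <- cbind(pts, 1) %*% t(M)
  w <- ph[, 3]
  if (any(abs(w) < 1e-12)) {
    stopf("point projects to the plane at infinity (zero homogeneous scale)")
  }
  cbind(x = ph[, 1] / w, y = ph[, 2] / w)
}

# Hartley normalisation: translate centroid to origin, scale mean distance
# to sqrt(2). Returns the 3x3 conditioning transform.
normalising_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  md <- mean(d)
  s <- if (md > 0) sqrt(2) / md else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Estimate a floor-to-image homography from point correspondences
#'
#' Normalized direct linear transform (DLT) solved by least squares (SVD)
#' over all correspondences. At least four correspondences are required and
#' the configuration must not be degenerate (e.g. all floor points
#' collinear).
#'
#' @param floor_points n x 2 matrix of floor-plane points (meters).
#' @param image_points n x 2 matrix of the corresponding image points
#'   (pixels).
#' @return A [homography()] with attribute `rms_px`, the root-mean-square
#'   reprojection residual in pixels.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' H <- estimate_homography(sq, sq)   # identity
#' @export
estimate_homography <- function(floor_points, image_points) {
  fp <- as_point_matrix(floor_points)
  ip <- as_point_matrix(image_points)
  if (nrow(fp) != nrow(ip)) stopf("floor and image point counts differ")
  n <- nrow(fp)
  if (n < 4L) stopf("homography estimation is underdetermined: %d correspondence(s), need at least 4", n)

  Tf <- normalising_transform(fp)
  Ti <- normalising_transform(ip)
  fn <- cbind(fp, 1) %*% t(Tf)
  im <- cbind(ip, 1) %*% t(Ti)

  A <- matrix(0, 2 * n, 9)
  for (k in seq_len(n)) {
    X <- fn[k, ]; u <- im[k, 1]; v <- im[k, 2]
    A[2 * k - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * k, ] <- c(0, 0, 0, -X, v * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  # rank must be 8 for a unique (projective) solution
  if (sv$d[8] < max(sv$d) * 1e-10) {
    stopf("degenerate correspondence configuration (collinear points): homography is rank-deficient")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Ti) %*% Hn %*% Tf
  H <- homography(H)

  proj <- project_points(H, fp)
  rms <- sqrt(mean(rowSums((proj - ip)^2)))
  attr(H, "rms_px") <- rms
  H
}
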