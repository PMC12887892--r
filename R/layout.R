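#' Zone identifiers of the 3x3 floor-target layout
#'
#' The central marker `C` plus eight peripheral markers `P1`..`P8`.
#'
#' @return Character vector of the nine zone ids.
#' @export
zone_ids <- function() c("C", paste0("P", 1:8))

peripheral_ids <- function() paste0("P", 1:8)

#' Physical layout of the nine circular floor targets
#'
#' Builds the canonical target geometry on the floor plane: a central marker
#' at the origin and eight peripheral markers at a radial distance of 2 m,
#' separated by 45 degrees, all 15 cm in diameter, on a 5 m x 5 m surface.
#' Floor coordinates are in meters, x to the athlete's right and y toward
#' the display.
#'
#' @param radius_m Radial distance from the central marker to each peripheral
#'   marker, meters.
#' @param marker_diameter_m Diameter of each circular marker, meters.
#' @param surface_side_m Side length of the square interaction surface, meters.
#' @param start_angle_deg Floor-plane angle assigned to `P1`, degrees
#'   (counter-clockwise from the +x axis). Subsequent peripherals advance by
#'   45 degrees.
#' @return An object of class `zone_layout`: a data frame with columns
#'   `zone`, `cx`, `cy` (marker centers, meters) and attributes
#'   `marker_diameter_m` and `surface_side_m`.
#' @examples
#' lay <- make_layout()
#' subset(lay, zone == "P1")  # (2, 0)
#' @export
make_layout <- function(radius_m = 2, marker_diameter_m = 0.15,
                        surface_side_m = 5, start_angle_deg = 0) {
  stopifnot(radius_m > 0, marker_diameter_m > 0, surface_side_m > 0)
  ang <- (start_angle_deg + 45 * (0:7)) * pi / 180
  lay <- data.frame(
    zone = zone_ids(),
    cx = c(0, radius_m * cos(ang)),
    cy = c(0, radius_m * sin(ang)),
    stringsAsFactors = FALSE
  )
  attr(lay, "marker_diameter_m") <- marker_diameter_m
  attr(lay, "surface_side_m") <- surface_side_m
  class(lay) <- c("zone_layout", "data.frame")
  lay
}

layout_centers <- function(layout) {
  as.matrix(layout[, c("cx", "cy")])
}

#' @export
print.zone_layout <- function(x, ...) {
  cat(sprintf(
    "Floor-target layout: 9 zones, marker diameter %.2f m, surface %.1f m\n",
    attr(x, "marker_diameter_m"), attr(x, "surface_side_m")
  ))
  print.data.frame(x, ...)
  invisible(x)
}
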