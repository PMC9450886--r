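#' Tank geometry for the novel-tank assay
#'
#' Describes the square test tank: side length, water depth, the bottom plane,
#' the vertical center line and the voxel grid used for the percent-explored
#' measure. Distances are in centimetres. The default is a 15 x 15 x 15 cm
#' five-sided tank filled to ~11.1 cm (2.5 L over a 225 cm^2 footprint),
#' discretised into 10 x 10 x 10 = 1000 evenly spaced voxels spanning the full
#' tank cube.
#'
#' @param side Inner side length of the square tank, cm.
#' @param water_depth Water depth, cm; must not exceed `side`.
#' @param bottom_plane Coefficients `(a, b, c, d)` of the bottom plane
#'   `a*x + b*y + c*z + d = 0`. Rescaled to a unit normal oriented toward the
#'   water volume. Default is the horizontal plane `z = 0`.
#' @param center_line Two stacked rows (2 x 3 matrix) giving the center-top and
#'   center-bottom points of the vertical center line. Defaults to the vertical
#'   line through the horizontal center of the tank.
#' @param voxel_counts Integer vector `(nx, ny, nz)` of voxel subdivisions per
#'   axis; the grid spans `[0, side]` on every axis.
#'
#' @return An object of class `tank_geometry`.
#' @examples
#' geom <- tank_geometry()
#' geom$voxel_counts
#' @export
tank_geometry <- function(side = 15, water_depth = 11.1,
                          bottom_plane = c(0, 0, 1, 0),
                          center_line = NULL,
                          voxel_counts = c(10L, 10L, 10L)) {
  check_scalar(side, "side")
  check_scalar(water_depth, "water_depth")
  if (side <= 0) stop("`side` must be positive", call. = FALSE)
  if (water_depth <= 0 || water_depth > side) {
    stop("`water_depth` must lie in (0, side]", call. = FALSE)
  }
  if (length(bottom_plane) != 4L || any(!is.finite(bottom_plane))) {
    stop("`bottom_plane` must be four finite coefficients (a, b, c, d)", call. = FALSE)
  }
  nrm <- sqrt(sum(bottom_plane[1:3]^2))
  if (nrm == 0) stop("`bottom_plane` normal must be nonzero", call. = FALSE)
  plane <- bottom_plane / nrm
  # orient the normal toward the water volume (evaluate at the tank's interior)
  interior <- c(side / 2, side / 2, water_depth / 2)
  if (sum(plane[1:3] * interior) + plane[4] < 0) plane <- -plane
  if (is.null(center_line)) {
    center_line <- rbind(top = c(side / 2, side / 2, water_depth),
                         bottom = c(side / 2, side / 2, 0))
  }
  center_line <- as.matrix(center_line)
  if (!all(dim(center_line) == c(2L, 3L))) {
    stop("`center_line` must be a 2 x 3 matrix of endpoints", call. = FALSE)
  }
  if (all(center_line[1, ] == center_line[2, ])) {
    stop("`center_line` endpoints must differ", call. = FALSE)
  }
  voxel_counts <- as.integer(voxel_counts)
  if (length(voxel_counts) != 3L || any(voxel_counts < 1L)) {
    stop("`voxel_counts` must be three positive integers", call. = FALSE)
  }
  structure(list(side = side, water_depth = water_depth,
                 bottom_plane = plane, center_line = center_line,
                 voxel_counts = voxel_counts),
            class = "tank_geometry")
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("Tank geometry: %.4g x %.4g x %.4g cm, water depth %.4g cm\n",
              x$side, x$side, x$side, x$water_depth))
  cat(sprintf("  bottom plane: %.3f x + %.3f y + %.3f z + %.3f = 0\n",
              x$bottom_plane[1], x$bottom_plane[2], x$bottom_plane[3], x$bottom_plane[4]))
  cat(sprintf("  voxel grid: %d x %d x %d (%d voxels)\n",
              x$voxel_counts[1], x$voxel_counts[2], x$voxel_counts[3],
              prod(x$voxel_counts)))
  invisible(x)
}

#' Fit the tank bottom plane by least squares
#'
#' Fits `z = b0 + b1*x + b2*y` to a cloud of points sampled from the tank
#' floor and returns the plane in implicit form with a unit normal oriented
#' upward (toward the water).
#'
#' @param points Matrix or data frame with columns `x`, `y`, `z` (cm); at least
#'   three non-collinear points.
#' @return Numeric vector `(a, b, c, d)` with unit normal `(a, b, c)`.
#' @examples
#' pts <- cbind(x = runif(400, 0, 15), y = runif(400, 0, 15), z = 0)
#' fit_bottom_plane(pts)
#' @export
fit_bottom_plane <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(colnames(points))) colnames(points) <- c("x", "y", "z")
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(points))) stop("points must be finite", call. = FALSE)
  X <- cbind(1, points[, "x"], points[, "y"])
  qrX <- qr(X)
  if (qrX$rank < 3L) {
    stop("points are collinear or degenerate; cannot fit a plane", call. = FALSE)
  }
  beta <- qr.coef(qrX, points[, "z"])
  # z = b0 + b1 x + b2 y  ->  -b1 x - b2 y + z - b0 = 0 (normal has +z component)
  plane <- c(-beta[2], -beta[3], 1, -beta[1])
  unname(plane / sqrt(sum(plane[1:3]^2)))
}

# Unsigned distance from each row of an (n x 3) coordinate matrix to a plane
# given as unit-normal implicit coefficients.
point_plane_distance <- function(coords, plane) {
  abs(coords %*% plane[1:3] + plane[4])[, 1]
}

# Perpendicular distance from points to the (infinite) line through p1, p2.
point_line_distance <- function(coords, p1, p2) {
  d <- p2 - p1
  d <- d / sqrt(sum(d^2))
  rel <- sweep(coords, 2, p1)
  proj <- rel %*% d
  perp <- rel - proj %*% t(d)
  sqrt(rowSums(perp^2))
}
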