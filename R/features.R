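#' Fit the water diffraction depth correction
#'
#' Depth cameras under-range points seen through water; the correction is the
#' ordinary least-squares line mapping the in-water depth reading to the true
#' (no-water) depth, fitted from paired calibration measurements.
#'
#' @param calibration Data frame with columns `z_air_cm` (true depth measured
#'   without water) and `z_water_cm` (same point measured through water), at
#'   least two pairs.
#' @return An object of class `depth_correction` with elements `slope` and
#'   `intercept` such that `z_true = slope * z_water + intercept`.
#' @examples
#' cal <- data.frame(z_air_cm = c(0, 10), z_water_cm = c(0, 8))
#' fit_depth_correction(cal)  # slope 1.25
#' @export
fit_depth_correction <- function(calibration) {
  if (!all(c("z_air_cm", "z_water_cm") %in% names(calibration))) {
    stop("calibration needs columns `z_air_cm` and `z_water_cm`", call. = FALSE)
  }
  zw <- calibration$z_water_cm
  za <- calibration$z_air_cm
  if (length(zw) < 2L) stop("need at least 2 calibration pairs", call. = FALSE)
  if (any(!is.finite(zw)) || any(!is.finite(za))) {
    stop("calibration pairs must be finite", call. = FALSE)
  }
  if (stats::var(zw) == 0) {
    stop("calibration predictor (z_water_cm) has zero variance", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, zw), za)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1])),
            class = "depth_correction")
}

#' @export
print.depth_correction <- function(x, ...) {
  cat(sprintf("Depth correction: z_true = %.6g * z_water + %.6g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Apply a depth correction to a trace
#'
#' @param trace A [swim_trace()].
#' @param correction A [fit_depth_correction()] result, or `NULL` for the
#'   identity map.
#' @return The trace with corrected `z`; missing `z` stays missing.
#' @export
apply_depth_correction <- function(trace, correction) {
  if (is.null(correction)) return(trace)
  if (!inherits(correction, "depth_correction")) {
    stop("`correction` must be a depth_correction object or NULL", call. = FALSE)
  }
  replace_coords(trace, z = correction$slope * trace$z + correction$intercept)
}

#' Fill missing depth readings by interpolation
#'
#' Interior gaps are filled linearly in time; gaps at either end take the
#' nearest available value.
#'
#' @param trace A [swim_trace()], possibly with `NA` in `z`.
#' @return The trace with complete `z`; present values are unchanged.
#' @export
interpolate_missing_z <- function(trace) {
  z <- trace$z
  ok <- !is.na(z)
  if (all(ok)) return(trace)
  if (!any(ok)) stop("all z values are missing; cannot interpolate", call. = FALSE)
  z_new <- if (sum(ok) == 1L) {
    rep(z[ok], length(z))
  } else {
    stats::approx(trace$t[ok], z[ok], xout = trace$t, method = "linear", rule = 2)$y
  }
  z_new[ok] <- z[ok]
  replace_coords(trace, z = z_new)
}

#' Savitzky-Golay smoothing of a trace
#'
#' Smooths each coordinate channel with a Savitzky-Golay filter. Defaults are a
#' 7-frame window of polynomial order 3, which preserves cubic trends exactly
#' while attenuating frame-to-frame jitter.
#'
#' @param trace A complete [swim_trace()] (no missing `z`).
#' @param window Odd filter length in frames.
#' @param order Polynomial order, strictly less than `window`.
#' @return The smoothed trace, same length as the input.
#' @export
smooth_trace <- function(trace, window = 7L, order = 3L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L || window < 3L) stop("`window` must be odd and >= 3", call. = FALSE)
  if (order >= window || order < 0L) stop("`order` must satisfy 0 <= order < window", call. = FALSE)
  if (nrow(trace) < window) {
    stop(sprintf("trace has %d frames; smoothing window is %d", nrow(trace), window),
         call. = FALSE)
  }
  if (anyNA(trace$z)) stop("interpolate missing z before smoothing", call. = FALSE)
  replace_coords(trace,
                 x = signal::sgolayfilt(trace$x, p = order, n = window),
                 y = signal::sgolayfilt(trace$y, p = order, n = window),
                 z = signal::sgolayfilt(trace$z, p = order, n = window))
}

#' Mean distance to the tank bottom
#'
#' Trial mean of the unsigned point-to-plane distance between the fish and the
#' tank's bottom plane (geotaxis / bottom-dwelling measure).
#'
#' @param trace A complete [swim_trace()].
#' @param geometry A [tank_geometry()].
#' @return Mean distance, cm.
#' @export
bottom_distance <- function(trace, geometry) {
  if (nrow(trace) < 1L || anyNA(trace$z)) {
    stop("trace must be nonempty and complete", call. = FALSE)
  }
  mean(point_plane_distance(trace_coords(trace), geometry$bottom_plane))
}

#' Mean distance to the tank's vertical center line
#'
#' Trial mean of the perpendicular distance between the fish and the line
#' joining the center-top and center-bottom of the tank (thigmotaxis measure:
#' large values mean wall proximity).
#'
#' @inheritParams bottom_distance
#' @return Mean distance, cm.
#' @export
center_distance <- function(trace, geometry) {
  if (nrow(trace) < 1L || anyNA(trace$z)) {
    stop("trace must be nonempty and complete", call. = FALSE)
  }
  mean(point_line_distance(trace_coords(trace),
                           geometry$center_line[1, ], geometry$center_line[2, ]))
}

#' Total distance travelled
#'
#' Sum of Euclidean distances between successive frames.
#'
#' @inheritParams bottom_distance
#' @return Total path length, cm.
#' @export
distance_travelled <- function(trace) {
  if (nrow(trace) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (anyNA(trace$z)) stop("trace must be complete", call. = FALSE)
  sum(sqrt(diff(trace$x)^2 + diff(trace$y)^2 + diff(trace$z)^2))
}

# Integer voxel index (1-based, column-major over nx*ny*nz) per frame.
# Boxes are half-open [lo, hi) with the last box closed; out-of-bounds frames
# are clamped to the nearest boundary voxel with a warning.
voxel_index <- function(trace, geometry) {
  nv <- geometry$voxel_counts
  width <- geometry$side / nv
  coords <- trace_coords(trace)
  out <- coords < 0 | coords > geometry$side
  if (any(out)) {
    warning(sprintf("%d frame coordinate(s) outside tank bounds; clamped to boundary voxels",
                    sum(out)), call. = FALSE)
  }
  ix <- pmin(pmax(floor(coords[, 1] / width[1]), 0), nv[1] - 1L)
  iy <- pmin(pmax(floor(coords[, 2] / width[2]), 0), nv[2] - 1L)
  iz <- pmin(pmax(floor(coords[, 3] / width[3]), 0), nv[3] - 1L)
  as.integer(ix + nv[1] * iy + nv[1] * nv[2] * iz + 1L)
}

#' Percent of the tank explored
#'
#' Divides the tank into evenly spaced voxels (1000 by default) and reports the
#' percentage visited at least once. Computed on the unsmoothed trace.
#'
#' @inheritParams bottom_distance
#' @return Percentage in (0, 100].
#' @export
percent_explored <- function(trace, geometry) {
  if (nrow(trace) < 1L || anyNA(trace$z)) {
    stop("trace must be nonempty and complete", call. = FALSE)
  }
  100 * length(unique(voxel_index(trace, geometry))) / prod(geometry$voxel_counts)
}

#' Extract the four exploratory parameters from a trace
#'
#' Applies, in order: the depth (diffraction) correction, interpolation of
#' missing depth readings, Savitzky-Golay smoothing (for bottom distance,
#' center distance and distance travelled; percent explored uses the
#' unsmoothed trace), then the four extractors.
#'
#' @param trace A [swim_trace()].
#' @param geometry A [tank_geometry()].
#' @param correction Optional [fit_depth_correction()] result.
#' @param window,order Savitzky-Golay parameters, see [smooth_trace()].
#' @param smooth_explored If `TRUE`, percent explored is also computed on the
#'   smoothed trace. Default `FALSE`.
#' @return One-row data frame with columns `fish_id`, `session`, `bottom_cm`,
#'   `center_cm`, `distance_cm`, `percent_explored`.
#' @examples
#' geom <- tank_geometry()
#' tr <- swim_trace(t = 0:99 / 30, x = rep(7.5, 100), y = rep(7.5, 100),
#'                  z = rep(5, 100))
#' extract_features(tr, geom)
#' @export
extract_features <- function(trace, geometry, correction = NULL,
                             window = 7L, order = 3L, smooth_explored = FALSE) {
  trace <- apply_depth_correction(trace, correction)
  trace <- interpolate_missing_z(trace)
  smoothed <- smooth_trace(trace, window = window, order = order)
  e_trace <- if (smooth_explored) smoothed else trace
  data.frame(fish_id = attr(trace, "fish_id"),
             session = attr(trace, "session"),
             bottom_cm = bottom_distance(smoothed, geometry),
             center_cm = center_distance(smoothed, geometry),
             distance_cm = distance_travelled(smoothed),
             percent_explored = percent_explored(e_trace, geometry),
             stringsAsFactors = FALSE)
}

#' Extract features for a list of traces
#'
#' @param traces List of [swim_trace()] objects.
#' @inheritParams extract_features
#' @return Feature table with one row per trace.
#' @export
extract_features_table <- function(traces, geometry, correction = NULL,
                                   window = 7L, order = 3L,
                                   smooth_explored = FALSE) {
  rows <- lapply(traces, extract_features, geometry = geometry,
                 correction = correction, window = window, order = order,
                 smooth_explored = smooth_explored)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-binned exploratory features
#'
#' Splits a trace into `n_bins` contiguous, (near-)equal blocks of frames and
#' computes the four features per block, for habituation-style time-course
#' analyses. The whole trace is corrected, interpolated and smoothed once; the
#' step joining consecutive bins is credited to the later bin so per-bin
#' distance travelled sums exactly to the whole-trace value.
#'
#' @inheritParams extract_features
#' @param n_bins Number of contiguous time bins (default 6).
#' @return Feature table with one row per bin and an extra `bin` column.
#' @export
binned_features <- function(trace, geometry, correction = NULL, n_bins = 6L,
                            window = 7L, order = 3L, smooth_explored = FALSE) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("`n_bins` must be >= 1", call. = FALSE)
  trace <- apply_depth_correction(trace, correction)
  trace <- interpolate_missing_z(trace)
  smoothed <- smooth_trace(trace, window = window, order = order)
  e_trace <- if (smooth_explored) smoothed else trace
  n <- nrow(trace)
  if (n_bins > n) stop("more bins than frames", call. = FALSE)
  bin <- ceiling(seq_len(n) * n_bins / n)
  sm <- trace_coords(smoothed)
  step <- c(0, sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2 + diff(sm[, 3])^2))
  vox <- voxel_index(e_trace, geometry)
  bdist <- point_plane_distance(sm, geometry$bottom_plane)
  cdist <- point_line_distance(sm, geometry$center_line[1, ], geometry$center_line[2, ])
  total_vox <- prod(geometry$voxel_counts)
  rows <- lapply(seq_len(n_bins), function(b) {
    i <- which(bin == b)
    data.frame(fish_id = attr(trace, "fish_id"),
               session = attr(trace, "session"),
               bin = b,
               bottom_cm = mean(bdist[i]),
               center_cm = mean(cdist[i]),
               distance_cm = sum(step[i]),
               percent_explored = 100 * length(unique(vox[i])) / total_vox,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
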