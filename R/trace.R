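#' A single fish-session 3D swim trace
#'
#' Wraps a time-ordered table of 3D coordinates. `z` may contain missing values
#' (frames where no depth reading was available); these are filled by
#' [interpolate_missing_z()] before feature extraction.
#'
#' @param t Frame times in seconds, strictly increasing.
#' @param x,y Horizontal coordinates, cm.
#' @param z Height coordinate, cm; `NA` allowed.
#' @param fps Nominal frame rate, frames per second.
#' @param fish_id,session Identifiers carried through the pipeline.
#' @return An object of class `swim_trace` (a data frame with columns
#'   `t`, `x`, `y`, `z` and attributes `fps`, `fish_id`, `session`).
#' @export
swim_trace <- function(t, x, y, z, fps = NULL, fish_id = "fish", session = "1") {
  n <- length(t)
  if (n < 2L) stop("a swim trace needs at least 2 frames", call. = FALSE)
  if (length(x) != n || length(y) != n || length(z) != n) {
    stop("t, x, y, z must have equal length", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("frame times must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (any(!is.finite(z) & !is.na(z))) {
    stop("z must be finite or NA", call. = FALSE)
  }
  if (is.null(fps)) fps <- 1 / stats::median(diff(t))
  df <- data.frame(t = as.numeric(t), x = as.numeric(x),
                   y = as.numeric(y), z = as.numeric(z))
  structure(df, fps = fps, fish_id = as.character(fish_id),
            session = as.character(session),
            class = c("swim_trace", "data.frame"))
}

#' @export
print.swim_trace <- function(x, ...) {
  frac_na <- mean(is.na(x$z))
  cat(sprintf("Swim trace: fish %s, session %s, %d frames @ %.3g fps (%.1f s), %.2f%% missing z\n",
              attr(x, "fish_id"), attr(x, "session"), nrow(x), attr(x, "fps"),
              x$t[nrow(x)] - x$t[1], 100 * frac_na))
  invisible(x)
}

trace_coords <- function(trace) {
  cbind(x = trace$x, y = trace$y, z = trace$z)
}

# Rebuild a trace with new coordinate columns, keeping identity attributes.
replace_coords <- function(trace, x = trace$x, y = trace$y, z = trace$z) {
  swim_trace(trace$t, x, y, z, fps = attr(trace, "fps"),
             fish_id = attr(trace, "fish_id"), session = attr(trace, "session"))
}
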