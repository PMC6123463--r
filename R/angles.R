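#' Angle conversion and wrapping utilities
#'
#' Angles are stored internally in radians; user-facing I/O is in degrees.
#' Wrapping conventions: angles live on `[0, 2*pi)` (degrees: `[0, 360)`),
#' signed differences on `(-pi, pi]` (degrees: `(-180, 180]`).
#'
#' @param x numeric vector of angles.
#' @return numeric vector of the same length.
#' @name angles
NULL

#' @rdname angles
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname angles
#' @export
rad2deg <- function(x) x * 180 / pi

#' @rdname angles
#' @export
wrap_angle <- function(x) x %% (2 * pi)

#' @rdname angles
#' @export
wrap_angle_deg <- function(x) x %% 360

#' Signed circular difference (shorter arc)
#'
#' Returns `a - b` wrapped to `(-pi, pi]` (radians) or `(-180, 180]`
#' (degrees).
#'
#' @param a,b numeric vectors of angles.
#' @return signed differences on the shorter arc.
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' @rdname circ_diff
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular (absolute, shorter-arc) distance in radians
#' @inheritParams circ_diff
#' @return non-negative distances in `[0, pi]`.
#' @export
circ_dist <- function(a, b) abs(circ_diff(a, b))
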