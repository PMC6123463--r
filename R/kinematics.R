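#' Heading kinematics and behavioral-mode segmentation
#'
#' From a timestamped 3D trajectory (e.g. GPS positions at 1 Hz) the
#' heading azimuth is the planar angle of the displacement
#' `(dx, dy)` and the pitch is the elevation of `dz` against the
#' horizontal displacement magnitude.  Angular velocities are absolute,
#' wrap-aware first differences of the heading angles times the sampling
#' rate, combined as `v = sqrt(v_azimuth^2 + v_pitch^2)`.  Flight behavior
#' separates into a navigation mode (large horizontal displacement, low
#' angular velocity) and a maneuvering mode (small displacement, high
#' angular velocity); crawling behavior is split at a combined angular
#' velocity of 10 degrees per second.
#'
#' @name kinematics
NULL

#' Read a trajectory or head-angle CSV
#'
#' `read_trajectory_csv` expects columns `t, x, y, z` (seconds, meters);
#' `read_head_angles_csv` expects `t, azimuth, pitch` (seconds, degrees).
#'
#' @param path CSV file path.
#' @return a data.frame with validated, strictly increasing timestamps.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "x", "y", "z") %in% names(df)))
  if (any(diff(df$t) <= 0)) stop("timestamps must be strictly increasing")
  df
}

#' @rdname read_trajectory_csv
#' @export
read_head_angles_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t", "azimuth", "pitch") %in% names(df)))
  if (any(diff(df$t) <= 0)) stop("timestamps must be strictly increasing")
  df
}

#' Heading angles from positions
#'
#' Consecutive-sample displacements give, per interval, the azimuth
#' `angle(dx + i*dy)` (0 degrees = +x, counter-clockwise) and the pitch
#' `angle(sqrt(dx^2+dy^2) + i*dz)`.  Zero-displacement intervals have an
#' undefined heading and are masked (`NA`); a purely vertical step leaves
#' azimuth masked but defines pitch.
#'
#' @param trajectory data.frame with `t, x, y, z`.
#' @return data.frame with `t` (interval end time), `azimuth`, `pitch`
#'   (degrees, `[0, 360)`), `speed` (m/s), `horizontal_step` (m).
#' @export
heading_from_positions <- function(trajectory) {
  dx <- diff(trajectory$x); dy <- diff(trajectory$y)
  dz <- diff(trajectory$z); dt <- diff(trajectory$t)
  dh <- sqrt(dx^2 + dy^2)
  az <- wrap_angle_deg(rad2deg(atan2(dy, dx)))
  az[dh == 0] <- NA_real_
  pit <- wrap_angle_deg(rad2deg(atan2(dz, dh)))
  pit[dh == 0 & dz == 0] <- NA_real_
  data.frame(t = trajectory$t[-1], azimuth = az, pitch = pit,
             speed = sqrt(dx^2 + dy^2 + dz^2) / dt, horizontal_step = dh)
}

#' Angular velocities from heading angles
#'
#' Wrap-aware absolute first differences scaled by the sampling rate.
#' Velocities across masked (`NA`) samples are not computed.
#'
#' @param azimuth,pitch angle series in degrees.
#' @param sampling_rate samples per second.
#' @return data.frame with `v_azimuth`, `v_pitch`, `v_combined` (deg/s);
#'   row `i` is the velocity between samples `i` and `i + 1`, so the
#'   result has one row fewer than the input.
#' @export
angular_velocities <- function(azimuth, pitch, sampling_rate) {
  stopifnot(length(azimuth) == length(pitch), sampling_rate > 0)
  n <- length(azimuth)
  va <- abs(circ_diff_deg(azimuth[-1], azimuth[-n])) * sampling_rate
  vp <- abs(circ_diff_deg(pitch[-1], pitch[-n])) * sampling_rate
  data.frame(v_azimuth = va, v_pitch = vp,
             v_combined = sqrt(va^2 + vp^2))
}

#' Segment flight into navigation and maneuvering modes
#'
#' Excludes samples slower than `speed_min` (stationary hanging), computes
#' the horizontal displacement over a trailing window (Euclidean distance
#' between positions `window` seconds apart), and places the mode
#' threshold at the minimum of the (kernel-smoothed) displacement
#' distribution between its two largest modes.  High displacement is
#' labeled `"navigation"`, low displacement `"maneuvering"`.
#'
#' @param trajectory data.frame with `t, x, y, z` (regular sampling).
#' @param speed_min minimum instantaneous speed in m/s (default 0.5).
#' @param window displacement window in seconds (default 20).
#' @return list with `labels` (per retained sample), `t`, `displacement`,
#'   `threshold`, and the retained-row indices `index`.
#' @export
flight_mode_segmentation <- function(trajectory, speed_min = 0.5,
                                     window = 20) {
  dt <- stats::median(diff(trajectory$t))
  lag <- max(1L, round(window / dt))
  n <- nrow(trajectory)
  if (n <= lag) stop("trajectory shorter than the displacement window")
  idx <- (lag + 1):n
  disp <- sqrt((trajectory$x[idx] - trajectory$x[idx - lag])^2 +
                 (trajectory$y[idx] - trajectory$y[idx - lag])^2)
  head <- heading_from_positions(trajectory)
  speed <- c(head$speed[1], head$speed)[idx]  # speed at sample ~ interval
  keep <- speed > speed_min
  disp <- disp[keep]
  if (length(disp) < 10) stop("too few moving samples to segment")
  dens <- stats::density(disp, n = 512)
  # local maxima of the smoothed distribution; need two modes to separate
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2)
    stop("displacement distribution is unimodal: no navigation/",
         "maneuvering threshold found (range ",
         signif(min(disp), 3), "-", signif(max(disp), 3), " m)")
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- seq(top2[1], top2[2])
  threshold <- dens$x[valley[which.min(y[valley])]]
  labels <- ifelse(disp >= threshold, "navigation", "maneuvering")
  list(labels = labels, t = trajectory$t[idx][keep], displacement = disp,
       threshold = threshold, index = idx[keep])
}

#' Split crawling behavior at a combined angular velocity cutoff
#'
#' Samples at or above `cutoff` (inclusive) are `"high"`, below are
#' `"low"`; `NA` velocities stay unlabeled.
#'
#' @param v_combined combined angular velocity in deg/s.
#' @param cutoff threshold in deg/s (default 10).
#' @param sampling_rate samples per second (for occupancy durations).
#' @return list with `labels` (`"low"`/`"high"`/`NA`) and `occupancy`
#'   (seconds per label).
#' @export
crawl_velocity_split <- function(v_combined, cutoff = 10,
                                 sampling_rate = 1) {
  labels <- ifelse(is.na(v_combined), NA_character_,
                   ifelse(v_combined >= cutoff, "high", "low"))
  list(labels = labels,
       occupancy = c(low = sum(labels == "low", na.rm = TRUE),
                     high = sum(labels == "high", na.rm = TRUE)) /
         sampling_rate)
}
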