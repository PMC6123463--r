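#' Synthetic trajectories and head-direction recordings
#'
#' Generators that emulate the statistical structure the analysis modules
#' assume, with full ground truth: behavior alternates between a slow
#' (navigation-like) and a fast (maneuvering-like) mode with different
#' angular-velocity scales and positively correlated azimuth/pitch
#' velocities; head-direction cells are untuned, pure, or conjunctive,
#' optionally velocity-gated so a cell's effective tuning type differs
#' between low and high angular velocity.  Heading dynamics are a wrapped
#' random walk with mode-dependent increment scales -- a deliberately
#' simple stand-in for real movement statistics, not a model of them.
#'
#' @name synthetic
NULL

#' Behavior specification for the trajectory generator
#'
#' Angular-velocity magnitudes are generated as absolute values of
#' correlated bivariate Gaussians, so `v_scale` sets the per-dimension
#' Gaussian scale in deg/s and `v_correlation` the correlation of the
#' *absolute* velocities (the generator calibrates the underlying Gaussian
#' correlation accordingly).  Defaults: slow mode 3 deg/s, fast mode
#' 30 deg/s (clearly separated by the 10 deg/s cutoff), correlation 0.26
#' in the fast mode and 0.1 in the slow mode, 10 Hz sampling, mean mode
#' dwell time 20 s.
#'
#' @param v_scale_slow,v_scale_fast velocity scales in deg/s.
#' @param v_corr_slow,v_corr_fast absolute-velocity correlations.
#' @param dwell mean dwell time per mode in seconds.
#' @param sampling_rate samples per second.
#' @param pitch_limit crawling pitch range half-width in degrees
#'   (increments reflect at the bounds; default 45).
#' @param speed_slow,speed_fast flight speeds in m/s (3D trajectories).
#' @return a list of class `behavior_spec`.
#' @export
behavior_spec <- function(v_scale_slow = 3, v_scale_fast = 30,
                          v_corr_slow = 0.1, v_corr_fast = 0.26,
                          dwell = 20, sampling_rate = 10,
                          pitch_limit = 45, speed_slow = 8,
                          speed_fast = 3) {
  stopifnot(v_scale_slow > 0, v_scale_fast > 0, dwell > 0,
            sampling_rate > 0, v_corr_slow >= 0, v_corr_fast >= 0,
            v_corr_slow < 1, v_corr_fast < 1)
  structure(list(v_scale = c(slow = v_scale_slow, fast = v_scale_fast),
                 v_corr = c(slow = v_corr_slow, fast = v_corr_fast),
                 dwell = dwell, sampling_rate = sampling_rate,
                 pitch_limit = pitch_limit,
                 speed = c(slow = speed_slow, fast = speed_fast)),
            class = "behavior_spec")
}

#' Gaussian correlation that yields a target absolute-value correlation
#'
#' For bivariate standard normals with correlation `rho`, the correlation
#' of `(|Z1|, |Z2|)` is
#' `((2/pi)(sqrt(1-rho^2) + rho*asin(rho)) - 2/pi) / (1 - 2/pi)`.
#' This inverts that relation numerically.
#'
#' @param target desired correlation of absolute values, in `[0, 1)`.
#' @return the Gaussian correlation to use.
#' @export
gaussian_corr_for_abs <- function(target) {
  stopifnot(target >= 0, target < 1)
  if (target == 0) return(0)
  abscor <- function(rho)
    ((2 / pi) * (sqrt(1 - rho^2) + rho * asin(rho)) - 2 / pi) /
      (1 - 2 / pi)
  stats::uniroot(function(r) abscor(r) - target, c(0, 1 - 1e-9),
                 tol = 1e-10)$root
}

#' Generate a synthetic head-angle or flight trajectory
#'
#' Two-state (slow/fast) Markov mode sequence; within each mode, heading
#' increments are signed magnitudes of correlated Gaussians with the
#' mode's velocity scale.  For `type = "angles"` the pitch is reflected at
#' `+/- pitch_limit` (crawling).  For `type = "positions"` 3D positions
#' are integrated from the heading at the mode's speed (pitch scale is
#' reduced and unreflected so flight stays shallow).
#'
#' @param spec a [behavior_spec()].
#' @param duration session duration in seconds.
#' @param type `"angles"` (t, azimuth, pitch; degrees) or `"positions"`
#'   (t, x, y, z; meters).
#' @param seed optional seed.
#' @return data.frame as above, with attributes `mode` (per-sample
#'   `"slow"`/`"fast"`) and `sampling_rate`.
#' @export
generate_trajectory <- function(spec, duration, type = c("angles",
                                                         "positions"),
                                seed = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(spec, "behavior_spec"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  sr <- spec$sampling_rate
  n <- ceiling(duration * sr)
  p_switch <- min(1, 1 / (spec$dwell * sr))
  mode <- character(n)
  mode[1] <- sample(c("slow", "fast"), 1)
  switches <- stats::runif(n) < p_switch
  for (i in 2:n)
    mode[i] <- if (switches[i]) setdiff(c("slow", "fast"), mode[i - 1])
               else mode[i - 1]

  # signed increments (degrees per sample) with correlated magnitudes;
  # turn direction is persistent (sign flips ~ every 15 s) so headings
  # sweep the circle at the mode's angular speed instead of diffusing --
  # otherwise slow-mode sessions never cover the stimulus space
  z1 <- stats::rnorm(n)
  flip <- function() {
    s <- ifelse(stats::runif(n) < 1 / (15 * sr), -1, 1)
    s[1] <- sample(c(-1, 1), 1)
    cumprod(s)
  }
  sign_az <- flip(); sign_pi <- flip()
  inc <- matrix(0, n, 2)
  for (m in c("slow", "fast")) {
    sel <- mode == m
    rho <- gaussian_corr_for_abs(spec$v_corr[[m]])
    z2 <- rho * z1[sel] + sqrt(1 - rho^2) * stats::rnorm(sum(sel))
    scale <- spec$v_scale[[m]] / sr
    inc[sel, 1] <- sign_az[sel] * abs(z1[sel]) * scale
    inc[sel, 2] <- sign_pi[sel] * abs(z2) * scale
  }

  az <- wrap_angle_deg(cumsum(c(stats::runif(1, 0, 360), inc[-1, 1])))
  if (type == "angles") {
    # reflect pitch inside [-pitch_limit, pitch_limit]; a reflection also
    # reverses the persistent turn direction so the walk does not grind
    # against the boundary
    p <- numeric(n)
    p[1] <- stats::runif(1, -spec$pitch_limit, spec$pitch_limit)
    dir <- 1
    for (i in 2:n) {
      v <- p[i - 1] + dir * inc[i, 2]
      if (v > spec$pitch_limit) {
        v <- 2 * spec$pitch_limit - v; dir <- -dir
      } else if (v < -spec$pitch_limit) {
        v <- -2 * spec$pitch_limit - v; dir <- -dir
      }
      p[i] <- max(min(v, spec$pitch_limit), -spec$pitch_limit)
    }
    out <- data.frame(t = (seq_len(n) - 1) / sr, azimuth = az,
                      pitch = wrap_angle_deg(p))
  } else {
    pit <- deg2rad(cumsum(c(0, 0.2 * inc[-1, 2])))  # shallow flight pitch
    azr <- deg2rad(az)
    speed <- spec$speed[mode]
    dt <- 1 / sr
    dx <- speed * dt * cos(pit) * cos(azr)
    dy <- speed * dt * cos(pit) * sin(azr)
    dz <- speed * dt * sin(pit)
    out <- data.frame(t = (seq_len(n) - 1) / sr,
                      x = cumsum(dx) - dx[1], y = cumsum(dy) - dy[1],
                      z = cumsum(dz) - dz[1])
  }
  attr(out, "mode") <- mode
  attr(out, "sampling_rate") <- sr
  out
}

#' Specify a synthetic head-direction cell
#'
#' `label_low` and `label_high` give the cell's tuning type in the low and
#' high angular-velocity states; identical labels mean no velocity gating,
#' while e.g. `label_low = "pure_azimuth", label_high = "conjunctive"`
#' scripts a cell that gains pitch tuning during fast head turns.
#'
#' @param label_low,label_high one of `"untuned"`, `"pure_azimuth"`,
#'   `"pure_pitch"`, `"conjunctive"`.
#' @param pref_azimuth,pref_pitch preferred directions in degrees.
#' @param kappa von-Mises concentration (default 2.37, the 90-degree
#'   width fitted to recorded head-direction cells; much narrower tuning
#'   makes a 3.4 Hz conjunctive cell so sparse that it cannot meet the
#'   50-spike inclusion criterion in realistic session lengths).
#' @param peak_rate modulation depth in Hz (defaults follow recorded
#'   statistics: 1 Hz for pure, 3.4 Hz for conjunctive cells; untuned
#'   cells fire at `peak_rate` throughout).
#' @param baseline baseline rate in Hz.
#' @return a list of class `cell_spec`.
#' @export
cell_spec <- function(label_low, label_high = label_low,
                      pref_azimuth = NULL, pref_pitch = NULL,
                      kappa = 2.37, peak_rate = NULL, baseline = 0) {
  lv <- c("untuned", "pure_azimuth", "pure_pitch", "conjunctive")
  stopifnot(label_low %in% lv, label_high %in% lv)
  if (is.null(peak_rate))
    peak_rate <- if ("conjunctive" %in% c(label_low, label_high)) 3.4 else 1
  structure(list(label_low = label_low, label_high = label_high,
                 pref_azimuth = pref_azimuth %||% stats::runif(1, 0, 360),
                 pref_pitch = pref_pitch %||% stats::runif(1, -45, 45),
                 kappa = kappa, peak_rate = peak_rate, baseline = baseline),
            class = "cell_spec")
}

# rate time series for one cell given angles (deg) and velocity state
.cell_rate_series <- function(cell, azimuth, pitch, state) {
  label <- ifelse(state == "high", cell$label_high, cell$label_low)
  label[is.na(state)] <- cell$label_low
  az_on <- label %in% c("pure_azimuth", "conjunctive")
  pi_on <- label %in% c("pure_pitch", "conjunctive")
  ex <- ifelse(az_on,
               cell$kappa * (cos(deg2rad(azimuth - cell$pref_azimuth)) - 1),
               0) +
        ifelse(pi_on,
               cell$kappa * (cos(deg2rad(pitch - cell$pref_pitch)) - 1),
               0)
  cell$peak_rate * exp(ex) + cell$baseline
}

#' Generate a synthetic recording session
#'
#' Builds a crawling trajectory from `spec`, computes per-sample velocity
#' states (combined angular velocity against `cutoff`), evaluates each
#' cell's rate along the trajectory (tuning active according to its label
#' in the current velocity state), and draws spike times by thinning an
#' inhomogeneous Poisson process.
#'
#' @param spec a [behavior_spec()].
#' @param cells list of [cell_spec()] objects.
#' @param duration session duration in seconds.
#' @param cutoff velocity split in deg/s (default 10).
#' @param seed optional seed.
#' @return a session list: `angles` (t, azimuth, pitch), `sampling_rate`,
#'   `spikes` (per-cell spike-time vectors), and `truth` (a data.frame of
#'   the scripted labels and parameters).
#' @export
generate_session <- function(spec, cells, duration, cutoff = 10,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj <- generate_trajectory(spec, duration, "angles")
  sr <- attr(traj, "sampling_rate")
  labels <- .velocity_labels(traj, sr, cutoff)
  n <- nrow(traj)
  spikes <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    rate <- .cell_rate_series(cell, traj$azimuth, traj$pitch, labels)
    rmax <- cell$peak_rate + cell$baseline
    n_cand <- stats::rpois(1, rmax * duration)
    tt <- sort(stats::runif(n_cand, 0, duration))
    idx <- pmin(floor(tt * sr) + 1L, n)
    keep <- stats::runif(n_cand) < rate[idx] / rmax
    spikes[[ci]] <- tt[keep]
  }
  truth <- do.call(rbind, lapply(seq_along(cells), function(i)
    data.frame(cell = i, label_low = cells[[i]]$label_low,
               label_high = cells[[i]]$label_high,
               pref_azimuth = cells[[i]]$pref_azimuth,
               pref_pitch = cells[[i]]$pref_pitch,
               kappa = cells[[i]]$kappa,
               peak_rate = cells[[i]]$peak_rate)))
  list(angles = traj[, c("t", "azimuth", "pitch")], sampling_rate = sr,
       spikes = spikes, truth = truth,
       velocity_labels = labels)
}

#' Write a session to plain-text files
#'
#' Emits the head-angle CSV (`t, azimuth, pitch`), one spike-time CSV per
#' cell (`t`), and a ground-truth JSON manifest.
#'
#' @param session result of [generate_session()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(session$angles, file.path(dir, "angles.csv"),
                   row.names = FALSE)
  for (i in seq_along(session$spikes))
    utils::write.csv(data.frame(t = session$spikes[[i]]),
                     file.path(dir, sprintf("spikes_cell%03d.csv", i)),
                     row.names = FALSE)
  manifest <- file.path(dir, "truth.json")
  jsonlite::write_json(session$truth, manifest, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}
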