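#' Velocity-conditioned head-direction tuning analysis
#'
#' Occupancy-normalized 1D tuning curves per angular-velocity bin, tuning
#' statistics (Rayleigh vector length for azimuth, peak-to-baseline
#' modulation for pitch, full width at half-height), shuffle-based
#' significance, and per-cell classification into untuned, pure-azimuth,
#' pure-pitch, or conjunctive -- separately for low and high angular
#' velocity, so velocity-gated transitions (e.g. pure at slow head turns,
#' conjunctive at fast turns) are detectable.
#'
#' A *session* here is a list with `angles` (data.frame `t`, `azimuth`,
#' `pitch` in degrees, regularly sampled), `sampling_rate` (Hz), and
#' `spikes` (a list of per-cell spike-time vectors in seconds).
#'
#' @name hd_tuning
NULL

# per-sample velocity labels: velocity between samples i-1, i labels sample i
.velocity_labels <- function(angles, sampling_rate, cutoff = 10) {
  v <- angular_velocities(angles$azimuth, angles$pitch, sampling_rate)
  c(NA_character_,
    crawl_velocity_split(v$v_combined, cutoff, sampling_rate)$labels)
}

# map spike times to sample indices of a regularly sampled angle series
.spike_samples <- function(spike_times, t0, sampling_rate, n_samples) {
  idx <- floor((spike_times - t0) * sampling_rate) + 1L
  idx[idx >= 1L & idx <= n_samples]
}

#' Occupancy-normalized tuning curve
#'
#' Bins the angle series (restricted to samples carrying
#' `velocity_label`, when given) into `bin_width`-degree bins, accumulates
#' occupancy (seconds) and spike counts, and returns rate =
#' spikes / occupancy.  Bins with occupancy below `occupancy_floor` are
#' masked (`NA` rate).
#'
#' @param spike_times numeric vector of spike times (seconds).
#' @param angles session angle data.frame (`t`, `azimuth`, `pitch`).
#' @param sampling_rate angle sampling rate in Hz.
#' @param dimension `"azimuth"` or `"pitch"`.
#' @param labels optional per-sample velocity labels (same length as the
#'   angle series).
#' @param velocity_label label to restrict to (e.g. `"low"`); `NULL` uses
#'   all labeled samples.
#' @param bin_width angular bin width in degrees (default 6).
#' @param occupancy_floor minimum occupancy per bin in seconds
#'   (default 0.5).
#' @return a list of class `tuning_curve`: `bin_center` (degrees), `rate`
#'   (Hz, `NA` where masked), `occupancy` (s), `spikes` (counts),
#'   `dimension`, `velocity_label`.
#' @export
tuning_curve <- function(spike_times, angles, sampling_rate,
                         dimension = c("azimuth", "pitch"),
                         labels = NULL, velocity_label = NULL,
                         bin_width = 6, occupancy_floor = 0.5) {
  dimension <- match.arg(dimension)
  ang <- angles[[dimension]]
  n <- length(ang)
  keep <- !is.na(ang)
  if (!is.null(labels) && !is.null(velocity_label))
    keep <- keep & !is.na(labels) & labels == velocity_label
  if (!any(keep)) stop("no samples in the requested velocity bin")
  nbins <- round(360 / bin_width)
  bin_of <- function(a) pmin(floor(wrap_angle_deg(a) / bin_width) + 1L,
                             nbins)
  occ <- tabulate(bin_of(ang[keep]), nbins) / sampling_rate
  sp_idx <- .spike_samples(spike_times, angles$t[1], sampling_rate, n)
  sp_idx <- sp_idx[keep[sp_idx]]
  spikes <- tabulate(bin_of(ang[sp_idx]), nbins)
  rate <- ifelse(occ >= occupancy_floor, spikes / pmax(occ, 1e-12),
                 NA_real_)
  structure(list(bin_center = (seq_len(nbins) - 0.5) * bin_width,
                 rate = rate, occupancy = occ, spikes = spikes,
                 dimension = dimension,
                 velocity_label = velocity_label %||% "all"),
            class = "tuning_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rayleigh vector length of a tuning curve
#'
#' Resultant length of the rate-weighted unit vectors at the bin centers:
#' 0 for a flat curve, 1 for a single active bin.  For a von-Mises curve
#' with concentration `kappa` the expected value is `I1(kappa)/I0(kappa)`.
#'
#' @param curve a [tuning_curve()] (masked bins are ignored).
#' @return length in `[0, 1]`.
#' @export
rayleigh_vector <- function(curve) {
  ok <- !is.na(curve$rate)
  r <- curve$rate[ok]
  if (sum(r) == 0) return(0)
  th <- deg2rad(curve$bin_center[ok])
  sqrt(sum(r * cos(th))^2 + sum(r * sin(th))^2) / sum(r)
}

#' Full tuning width at half-height
#'
#' Baseline-subtracted width: with baseline the minimum unmasked rate and
#' peak the maximum, the width is the angular extent of the contiguous
#' run of bins (around the peak, on the circle) whose rate is at least
#' baseline + half the modulation.  Returns `NA` (flagged flat) when the
#' curve has no modulation.
#'
#' @param curve a [tuning_curve()].
#' @return width in degrees, or `NA` for a flat curve.
#' @export
tuning_width <- function(curve) {
  ok <- which(!is.na(curve$rate))
  if (length(ok) < 2) return(NA_real_)
  r <- curve$rate[ok]
  base <- min(r); peak <- max(r)
  if (peak <= base) return(NA_real_)
  half <- base + (peak - base) / 2
  above <- r >= half
  m <- length(ok)
  ipk <- which.max(r)
  # walk left and right from the peak along the (circular) unmasked bins
  run <- 1L
  i <- ipk
  repeat {
    j <- if (i == 1L) m else i - 1L
    if (j == ipk || !above[j]) break
    run <- run + 1L; i <- j
  }
  i <- ipk
  repeat {
    j <- if (i == m) 1L else i + 1L
    if (j == ipk || !above[j]) break
    run <- run + 1L; i <- j
  }
  bw <- 360 / length(curve$rate)
  min(run * bw, 360)
}

# tuning statistic used by the shuffle test: Rayleigh length for azimuth
# (fully sampled circle); occupancy-weighted rate dispersion for pitch,
# whose sampled range is clipped during crawling.  The dispersion uses
# the whole curve and is less sensitive to single low-occupancy bins
# than a peak-to-baseline difference.
.tuning_statistic <- function(curve, dimension) {
  ok <- !is.na(curve$rate)
  if (!any(ok)) return(0)
  if (dimension == "azimuth") return(rayleigh_vector(curve))
  r <- curve$rate[ok]
  w <- curve$occupancy[ok] / sum(curve$occupancy[ok])
  sqrt(sum(w * (r - sum(w * r))^2))
}

#' Shuffle test for directional tuning
#'
#' Builds a null distribution by circularly time-shifting the spike train
#' relative to the behavior (shift at least `min_lag` seconds, wrapped at
#' the session duration) and recomputing the tuning statistic: the
#' Rayleigh vector length for azimuth, the peak-to-baseline rate
#' modulation for pitch (appropriate when the sampled pitch range is
#' clipped).  Tuning is significant when the observed statistic exceeds
#' the `percentile` quantile of the null.
#'
#' @inheritParams tuning_curve
#' @param n_shuffles number of shuffles (default 1000; a warning is
#'   issued below 100).
#' @param min_lag minimum circular shift in seconds (default 20).
#' @param percentile null quantile for significance (default 0.99).
#' @param seed optional seed.
#' @return list with `observed`, `p_value`, `significant`, `threshold`,
#'   and the `null` statistics.
#' @export
shuffle_significance <- function(spike_times, angles, sampling_rate,
                                 dimension = c("azimuth", "pitch"),
                                 labels = NULL, velocity_label = NULL,
                                 n_shuffles = 1000, min_lag = 20,
                                 percentile = 0.99, bin_width = 6,
                                 occupancy_floor = 0.5, seed = NULL) {
  dimension <- match.arg(dimension)
  if (n_shuffles < 100)
    warning("fewer than 100 shuffles: the null quantile is unstable")
  if (!is.null(seed)) set.seed(seed)
  duration <- length(angles$t) / sampling_rate
  if (duration <= 2 * min_lag)
    stop("session shorter than twice the minimum shuffle lag")
  # occupancy and per-sample bins are invariant under time shifts of the
  # spike train; precompute them and only re-bin spikes per shuffle
  ang <- angles[[dimension]]
  n <- length(ang)
  keep <- !is.na(ang)
  if (!is.null(labels) && !is.null(velocity_label))
    keep <- keep & !is.na(labels) & labels == velocity_label
  if (!any(keep)) stop("no samples in the requested velocity bin")
  nbins <- round(360 / bin_width)
  bin <- pmin(floor(wrap_angle_deg(ang) / bin_width) + 1L, nbins)
  occ <- tabulate(bin[keep], nbins) / sampling_rate
  unmasked <- occ >= occupancy_floor
  stat_of <- function(times) {
    idx <- .spike_samples(times, angles$t[1], sampling_rate, n)
    idx <- idx[keep[idx]]
    rate <- tabulate(bin[idx], nbins) / pmax(occ, 1e-12)
    rate <- rate[unmasked]
    if (!length(rate)) return(0)
    if (dimension == "azimuth") {
      if (sum(rate) == 0) return(0)
      th <- deg2rad(((which(unmasked)) - 0.5) * bin_width)
      sqrt(sum(rate * cos(th))^2 + sum(rate * sin(th))^2) / sum(rate)
    } else {
      w <- occ[unmasked] / sum(occ[unmasked])
      sqrt(sum(w * (rate - sum(w * rate))^2))
    }
  }
  obs <- stat_of(spike_times)
  lags <- stats::runif(n_shuffles, min_lag, duration - min_lag)
  t0 <- angles$t[1]
  null <- vapply(lags, function(lag)
    stat_of(t0 + ((spike_times - t0 + lag) %% duration)), numeric(1))
  thr <- stats::quantile(null, percentile, names = FALSE)
  list(observed = obs,
       p_value = (sum(null >= obs) + 1) / (n_shuffles + 1),
       significant = obs > thr, threshold = thr, null = null)
}

#' Pearson stability of a tuning curve (odd versus even seconds)
#'
#' Splits the labeled data into odd and even seconds, recomputes the
#' tuning curve on each half, and returns the Pearson correlation of the
#' two rate vectors over bins unmasked in both.
#'
#' @inheritParams tuning_curve
#' @return correlation coefficient, or `NA` if undefined.
#' @export
tuning_stability <- function(spike_times, angles, sampling_rate,
                             dimension = c("azimuth", "pitch"),
                             labels = NULL, velocity_label = NULL,
                             bin_width = 6, occupancy_floor = 0.25) {
  dimension <- match.arg(dimension)
  sec <- floor(angles$t - angles$t[1])
  halves <- lapply(c(0, 1), function(par) {
    lab <- labels
    mask <- sec %% 2 == par
    if (is.null(lab)) lab <- ifelse(mask, "keep", NA_character_)
    else lab[!mask] <- NA_character_
    vl <- if (is.null(labels)) "keep" else velocity_label
    tryCatch(tuning_curve(spike_times, angles, sampling_rate, dimension,
                          lab, vl, bin_width, occupancy_floor),
             error = function(e) NULL)
  })
  if (any(vapply(halves, is.null, logical(1)))) return(NA_real_)
  r1 <- halves[[1]]$rate; r2 <- halves[[2]]$rate
  ok <- !is.na(r1) & !is.na(r2)
  if (sum(ok) < 3 || stats::sd(r1[ok]) == 0 || stats::sd(r2[ok]) == 0)
    return(NA_real_)
  stats::cor(r1[ok], r2[ok])
}

#' Classify cells by velocity-conditioned tuning
#'
#' For each cell and each angular-velocity bin (low/high split at
#' `cutoff`), applies inclusion criteria (at least `min_time` seconds of
#' data and `min_spikes` spikes in the bin), runs the shuffle test per
#' dimension, and assigns a label: `conjunctive` if both dimensions are
#' significant, `pure_azimuth`/`pure_pitch` if exactly one is, `untuned`
#' otherwise.  Excluded cells carry the label `excluded` and a reason
#' code.  An optional stability gate additionally requires an odd/even
#' Pearson correlation above `stability_r` for a dimension to count as
#' significant (used with finer velocity binnings).
#'
#' @param session list with `angles`, `sampling_rate`, `spikes` (see
#'   [hd_tuning]).
#' @param cutoff velocity split in deg/s (default 10).
#' @param min_time,min_spikes inclusion criteria per velocity bin
#'   (defaults 120 s and 50 spikes).
#' @param n_shuffles,min_lag,percentile shuffle-test parameters.
#' @param bin_width,occupancy_floor tuning-curve parameters.
#' @param stability_gate apply the stability criterion (default FALSE).
#' @param stability_r stability threshold (default 0.25).
#' @param seed optional seed (shuffle lags).
#' @return data.frame with one row per cell and velocity bin: `cell`,
#'   `velocity_bin`, `included`, `reason`, `sig_azimuth`, `sig_pitch`,
#'   `label`, `rayleigh_azimuth`, `width_azimuth`, `width_pitch`,
#'   `stability_azimuth`, `stability_pitch`, `n_spikes`.
#' @export
classify_cells <- function(session, cutoff = 10, min_time = 120,
                           min_spikes = 50, n_shuffles = 1000,
                           min_lag = 20, percentile = 0.99, bin_width = 6,
                           occupancy_floor = 0.5, stability_gate = FALSE,
                           stability_r = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  angles <- session$angles
  sr <- session$sampling_rate
  labels <- .velocity_labels(angles, sr, cutoff)
  n <- length(angles$t)
  rows <- list()
  for (ci in seq_along(session$spikes)) {
    st <- session$spikes[[ci]]
    sp_idx <- .spike_samples(st, angles$t[1], sr, n)
    for (vb in c("low", "high")) {
      occ <- sum(labels == vb, na.rm = TRUE) / sr
      nsp <- sum(labels[sp_idx] == vb, na.rm = TRUE)
      included <- TRUE; reason <- ""
      if (occ < min_time) { included <- FALSE; reason <- "min_time" }
      else if (nsp < min_spikes) { included <- FALSE
                                   reason <- "min_spikes" }
      row <- data.frame(cell = ci, velocity_bin = vb, included = included,
                        reason = reason, sig_azimuth = NA, sig_pitch = NA,
                        label = "excluded", rayleigh_azimuth = NA_real_,
                        width_azimuth = NA_real_, width_pitch = NA_real_,
                        stability_azimuth = NA_real_,
                        stability_pitch = NA_real_, n_spikes = nsp)
      if (included) {
        sig <- logical(2)
        for (di in 1:2) {
          dimension <- c("azimuth", "pitch")[di]
          sh <- shuffle_significance(st, angles, sr, dimension, labels,
                                     vb, n_shuffles, min_lag, percentile,
                                     bin_width, occupancy_floor)
          s <- sh$significant
          stab <- tuning_stability(st, angles, sr, dimension, labels, vb,
                                   bin_width)
          if (stability_gate)
            s <- s && !is.na(stab) && stab > stability_r
          sig[di] <- s
          if (dimension == "azimuth") row$stability_azimuth <- stab
          else row$stability_pitch <- stab
        }
        cv_az <- tuning_curve(st, angles, sr, "azimuth", labels, vb,
                              bin_width, occupancy_floor)
        cv_pi <- tuning_curve(st, angles, sr, "pitch", labels, vb,
                              bin_width, occupancy_floor)
        row$sig_azimuth <- sig[1]; row$sig_pitch <- sig[2]
        row$rayleigh_azimuth <- rayleigh_vector(cv_az)
        row$width_azimuth <- tuning_width(cv_az)
        row$width_pitch <- tuning_width(cv_pi)
        row$label <- if (sig[1] && sig[2]) "conjunctive"
          else if (sig[1]) "pure_azimuth"
          else if (sig[2]) "pure_pitch" else "untuned"
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Cross-tabulate tuning labels between velocity bins
#'
#' @param classifications output of [classify_cells()] (or any data.frame
#'   with `cell`, `velocity_bin`, `label`).
#' @return list with the label `counts` table (rows = low-velocity label,
#'   cols = high-velocity label, cells included in both bins only) and
#'   `percent_given_high` / `percent_given_low` conditional percentages
#'   (each column/row sums to 100).
#' @export
transition_analysis <- function(classifications) {
  lv <- classifications[classifications$velocity_bin == "low", ]
  hv <- classifications[classifications$velocity_bin == "high", ]
  m <- merge(lv[lv$label != "excluded", c("cell", "label")],
             hv[hv$label != "excluded", c("cell", "label")],
             by = "cell", suffixes = c("_low", "_high"))
  lvl <- c("untuned", "pure_azimuth", "pure_pitch", "conjunctive")
  counts <- table(factor(m$label_low, lvl), factor(m$label_high, lvl),
                  dnn = c("low", "high"))
  pg_high <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 100
  pg_low <- sweep(counts, 1, pmax(rowSums(counts), 1), "/") * 100
  list(counts = counts, percent_given_high = pg_high,
       percent_given_low = pg_low)
}
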