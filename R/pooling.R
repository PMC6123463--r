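#' Feed-forward pooling model of pure and conjunctive tuning
#'
#' Two upstream populations of `n0` Poisson neurons each (one tuned to
#' azimuth, one to pitch, von-Mises tuning with evenly spaced preferred
#' directions `2*pi*j/n0`) project to downstream populations.  A downstream
#' pure cell pools one upstream population with a von-Mises weight profile
#' centered on its preferred direction; a downstream conjunctive cell
#' multiplies the pooled azimuth and pitch inputs (divided by `t` so its
#' expected count stays linear in `t`).  Downstream counts are Poisson
#' given the pooled rates.  Because downstream cells share upstream
#' inputs, their counts are positively correlated for nearby preferred
#' directions, providing a mechanistic source of noise correlations.
#'
#' The pooling gains `a_pure` and `a_conj` are calibrated by Monte-Carlo so
#' the two downstream populations have equal mean population spike counts,
#' anchored to the count of a matched ideal pure population with peak rate
#' `r_ref`.
#'
#' @param n downstream population size per kind (`n/2` pure cells per
#'   dimension, `n` conjunctive cells).
#' @param n0 upstream population size per dimension.
#' @param kappa von-Mises concentration, upstream and downstream pooling
#'   profile (the model's default is 9.1, a 45-degree width).
#' @param r_upstream upstream peak rate in Hz.
#' @param r_ref reference pure peak rate (Hz) used to anchor the absolute
#'   downstream rate scale during calibration.
#' @param calib_stimuli,calib_t number of random stimuli and the decoding
#'   time used for gain calibration.
#' @param seed optional seed (used for downstream preferred directions and
#'   calibration).
#' @return an object of class `pooling_network`.
#' @export
pooling_network <- function(n, n0 = 4 * n, kappa = 9.1, r_upstream = 1,
                            r_ref = 1, calib_stimuli = 64, calib_t = 1,
                            seed = NULL) {
  stopifnot(n >= 2, n %% 2 == 0, n0 >= 2, kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  upstream_pref <- 2 * pi * seq_len(n0) / n0
  pref_az <- stats::runif(n / 2, 0, 2 * pi)
  pref_pi <- stats::runif(n / 2, 0, 2 * pi)
  pref_conj <- cbind(stats::runif(n, 0, 2 * pi), stats::runif(n, 0, 2 * pi))

  # pooling weight matrices: rows downstream, cols upstream
  w_az <- exp(kappa * cos(outer(pref_az, upstream_pref, "-")))
  w_pi <- exp(kappa * cos(outer(pref_pi, upstream_pref, "-")))
  w_conj_az <- exp(kappa * cos(outer(pref_conj[, 1], upstream_pref, "-")))
  w_conj_pi <- exp(kappa * cos(outer(pref_conj[, 2], upstream_pref, "-")))

  net <- structure(
    list(n = n, n0 = n0, kappa = kappa, r_upstream = r_upstream,
         upstream_pref = upstream_pref,
         pref_az = pref_az, pref_pitch = pref_pi, pref_conj = pref_conj,
         w_az = w_az, w_pitch = w_pi,
         w_conj_az = w_conj_az, w_conj_pitch = w_conj_pi,
         a_pure = 1, a_conj = 1, seed = seed),
    class = "pooling_network")

  # Monte-Carlo calibration of the gains over uniform stimuli: the target
  # population spike count is that of an ideal pure population with peak
  # rate r_ref (so pooled-model errors are comparable to the ideal model).
  target <- n * calib_t * r_ref * besselI(kappa, 0, expon.scaled = TRUE)
  sums <- c(pure = 0, conj = 0)
  for (i in seq_len(calib_stimuli)) {
    s <- stats::runif(2, 0, 2 * pi)
    r <- .pooled_rates(net, s, calib_t)
    sums["pure"] <- sums["pure"] + sum(r$pure_az + r$pure_pitch)
    sums["conj"] <- sums["conj"] + sum(r$conj)
  }
  net$a_pure <- target / (sums[["pure"]] / calib_stimuli)
  net$a_conj <- target / (sums[["conj"]] / calib_stimuli)
  net
}

# upstream spike counts and pooled downstream rates for one trial
.pooled_rates <- function(net, stimulus, t) {
  lam_az <- t * net$r_upstream *
    exp(net$kappa * (cos(stimulus[1] - net$upstream_pref) - 1))
  lam_pi <- t * net$r_upstream *
    exp(net$kappa * (cos(stimulus[2] - net$upstream_pref) - 1))
  m_az <- stats::rpois(net$n0, lam_az)
  m_pi <- stats::rpois(net$n0, lam_pi)
  list(
    pure_az    = net$a_pure * drop(net$w_az %*% m_az),
    pure_pitch = net$a_pure * drop(net$w_pitch %*% m_pi),
    conj       = (net$a_conj / t) *
      drop(net$w_conj_pitch %*% m_pi) * drop(net$w_conj_az %*% m_az),
    m_az = m_az, m_pitch = m_pi)
}

#' Pooled downstream Poisson means for one trial
#'
#' Draws one realization of upstream spike counts and returns the implied
#' downstream Poisson means, i.e. expected spike counts in the window of
#' duration `t`.  Because the upstream counts already scale linearly with
#' `t`, the pure pooled values do too, and the conjunctive product is
#' divided by `t` so its expectation is also linear in `t`.
#'
#' @param net a [pooling_network()].
#' @param stimulus length-2 stimulus (azimuth, pitch) in radians.
#' @param t decoding time in seconds.
#' @return list with `pure_az`, `pure_pitch`, `conj` vectors of expected
#'   counts, and the upstream counts `m_az`, `m_pitch`.
#' @export
pooled_rates <- function(net, stimulus, t) {
  stopifnot(inherits(net, "pooling_network"), t > 0, length(stimulus) == 2)
  .pooled_rates(net, stimulus, t)
}

#' Downstream spike counts from the pooling model
#'
#' For each trial, draws upstream counts, computes pooled rates, and draws
#' downstream Poisson counts.
#'
#' @inheritParams pooled_rates
#' @param trials number of trials.
#' @param seed optional seed.
#' @return list with integer count matrices `pure_az`, `pure_pitch`
#'   (`trials x n/2`) and `conj` (`trials x n`).
#' @export
sample_pooled <- function(net, stimulus, t, trials = 1, seed = NULL) {
  stopifnot(inherits(net, "pooling_network"), t > 0)
  if (!is.null(seed)) set.seed(seed)
  half <- net$n / 2
  out <- list(pure_az = matrix(0L, trials, half),
              pure_pitch = matrix(0L, trials, half),
              conj = matrix(0L, trials, net$n))
  for (tr in seq_len(trials)) {
    r <- .pooled_rates(net, stimulus, t)
    out$pure_az[tr, ] <- stats::rpois(half, r$pure_az)
    out$pure_pitch[tr, ] <- stats::rpois(half, r$pure_pitch)
    out$conj[tr, ] <- stats::rpois(net$n, r$conj)
  }
  out
}

#' Population-vector decoding of pooled downstream responses
#'
#' @param counts list as returned by [sample_pooled()] (single trial:
#'   first row of each matrix is used).
#' @param net the generating [pooling_network()].
#' @param trial trial (row) index to decode.
#' @return list with `pure` and `conj` estimates (radians, `NA` when the
#'   population emitted no spikes, the maximal-error convention).
#' @export
pv_decode_pooled <- function(counts, net, trial = 1) {
  pvang <- function(nn, pref) {
    x <- sum(nn * cos(pref)); y <- sum(nn * sin(pref))
    if (x == 0 && y == 0) NA_real_ else wrap_angle(atan2(y, x))
  }
  list(pure = c(pvang(counts$pure_az[trial, ], net$pref_az),
                pvang(counts$pure_pitch[trial, ], net$pref_pitch)),
       conj = c(pvang(counts$conj[trial, ], net$pref_conj[, 1]),
                pvang(counts$conj[trial, ], net$pref_conj[, 2])))
}

#' Pure/conjunctive error ratio in the pooling model
#'
#' Mean PV decoding errors of the downstream pure and conjunctive
#' populations over uniform stimuli, averaged over several independent
#' network realizations (downstream preferred directions are redrawn per
#' realization; with a single fixed network the conjunctive error carries
#' a realization-specific bias that does not average out over trials).
#'
#' @param n,n0 downstream and upstream population sizes.
#' @param t decoding time in seconds.
#' @param trials trials per network realization.
#' @param networks number of network realizations.
#' @param kappa concentration (default 9.1).
#' @param seed integer seed.
#' @return list with `ratio`, `err_pure`, `err_conj` (degrees), `se_ratio`.
#' @export
pooling_error_ratio <- function(n, n0, t = 10, trials = 30, networks = 10,
                                kappa = 9.1, seed = 1) {
  set.seed(seed)
  ep <- ec <- numeric(0)
  for (k in seq_len(networks)) {
    net <- pooling_network(n, n0, kappa)
    for (i in seq_len(trials)) {
      s <- stats::runif(2, 0, 2 * pi)
      sp <- sample_pooled(net, s, t, 1)
      est <- pv_decode_pooled(sp, net)
      ep <- c(ep, circular_error(est$pure, s)$scalar)
      ec <- c(ec, circular_error(est$conj, s)$scalar)
    }
  }
  m <- length(ep)
  ratio <- mean(ep) / mean(ec)
  se <- ratio * sqrt(stats::var(ep) / (m * mean(ep)^2) +
                       stats::var(ec) / (m * mean(ec)^2))
  list(ratio = ratio, err_pure = mean(ep), err_conj = mean(ec),
       se_ratio = se, n = n, n0 = n0, t = t,
       trials = trials * networks)
}
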