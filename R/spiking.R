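#' Spike-count generation
#'
#' Spike counts for a population at a fixed stimulus over a decoding window
#' of `t` seconds.  The baseline model draws each neuron's count
#' independently from a Poisson distribution with mean `rate * t`.  Three
#' dependent variants are provided: pairwise noise correlations via a
#' Gaussian copula ([sample_correlated()]), shared additive or
#' multiplicative gain fluctuations ([sample_gain()]), and a two-layer
#' feed-forward pooling model (see [pooling_network()]).
#'
#' @name spiking
NULL

# sub-population index: pure cells by tuned dimension, conjunctive cells 0
.subpop_id <- function(population) {
  id <- population$dim
  id[is.na(id)] <- 0L
  id
}

.spike_count_matrix <- function(counts, population, stimulus, t,
                                noise_model, seed) {
  structure(counts,
            stimulus = stimulus, t = t, noise_model = noise_model,
            seed = seed, class = c("spike_count_matrix", "matrix", "array"))
}

#' Independent Poisson spike counts
#'
#' @param population an [build_population()] object.
#' @param stimulus stimulus vector (radians), length `d`.
#' @param t decoding time in seconds.
#' @param trials number of independent trials.
#' @param seed optional integer seed.
#' @return a `trials x n` integer matrix of class `spike_count_matrix`
#'   with attributes `stimulus`, `t`, `noise_model`, `seed`.
#' @export
sample_independent <- function(population, stimulus, t, trials = 1,
                               seed = NULL) {
  stopifnot(t > 0, trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  lambda <- population_rates(population, stimulus) * t
  counts <- matrix(stats::rpois(trials * population$n,
                                rep(lambda, each = trials)),
                   trials, population$n)
  .spike_count_matrix(counts, population, stimulus, t, "independent", seed)
}

#' Noise-correlation structure from preferred-direction distances
#'
#' Pairwise distances between preferred directions: the shorter-arc
#' circular distance for two pure cells tuned to the same dimension, the
#' Euclidean combination of per-dimension shorter arcs for two conjunctive
#' cells.  Cells in different sub-populations (the two pure sub-populations
#' and the conjunctive population) are uncorrelated.  Off-diagonal
#' correlations follow `c = (1/4) cos(2 d) exp(-d^2)` with `d` in radians:
#' positive for nearby preferred directions, crossing zero at `d = pi/4`
#' (45 degrees), weakly negative around 60 degrees, and negligible beyond.
#'
#' @param population an `hd_population`.
#' @return a list of class `correlation_structure` with `distance`
#'   (radians; `NA` across sub-populations) and `correlation` matrices.
#' @export
correlation_from_distance <- function(population) {
  n <- population$n
  sub <- .subpop_id(population)
  dmat <- matrix(NA_real_, n, n)
  cmat <- diag(n)
  for (s in unique(sub)) {
    idx <- which(sub == s)
    if (length(idx) < 2) next
    if (s == 0L) {   # conjunctive: Euclidean combination over dimensions
      d2 <- matrix(0, length(idx), length(idx))
      for (k in seq_len(population$d)) {
        a <- population$pref[idx, k]
        d2 <- d2 + outer(a, a, circ_dist)^2
      }
      dd <- sqrt(d2)
    } else {         # pure: 1D circular distance on the tuned dimension
      a <- population$pref[idx, s]
      dd <- outer(a, a, circ_dist)
    }
    dmat[idx, idx] <- dd
    cc <- 0.25 * cos(2 * dd) * exp(-dd^2)
    diag(cc) <- 1
    cmat[idx, idx] <- cc
  }
  structure(list(distance = dmat, correlation = cmat),
            class = "correlation_structure")
}

# Cholesky factor of a correlation matrix, with nearest-PSD repair if the
# distance-derived structure is indefinite (possible for some geometries).
.corr_chol <- function(cmat, eig_floor = 1e-10) {
  ch <- tryCatch(chol(cmat), error = function(e) NULL)
  if (is.null(ch)) {
    repaired <- Matrix::nearPD(cmat, corr = TRUE, eig.tol = eig_floor,
                               posd.tol = eig_floor)
    cm <- as.matrix(repaired$mat)
    ch <- chol(cm + diag(eig_floor, nrow(cm)))
  }
  ch
}

#' Correlated Poisson spike counts via a Gaussian copula
#'
#' Draws correlated standard Gaussians with the correlation matrix from
#' [correlation_from_distance()] (or a user-supplied one), maps them
#' through the Gaussian CDF, and applies the inverse Poisson CDF with mean
#' `rate * t`.  Marginals are exactly Poisson; pairwise count correlations
#' approximate the target structure.
#'
#' @inheritParams sample_independent
#' @param structure optional `correlation_structure`; computed from the
#'   population when omitted.
#' @return a `spike_count_matrix` (noise model `"correlated"`).
#' @export
sample_correlated <- function(population, stimulus, t, trials = 1,
                              seed = NULL, structure = NULL) {
  stopifnot(t > 0, trials >= 1)
  if (is.null(structure)) structure <- correlation_from_distance(population)
  if (!is.null(seed)) set.seed(seed)
  n <- population$n
  lambda <- population_rates(population, stimulus) * t
  ch <- .corr_chol(structure$correlation)
  z <- matrix(stats::rnorm(trials * n), trials, n) %*% ch
  counts <- matrix(stats::qpois(stats::pnorm(z),
                                rep(lambda, each = trials)), trials, n)
  .spike_count_matrix(counts, population, stimulus, t, "correlated", seed)
}

#' Shared-gain tuning-curve modulation
#'
#' `apply_additive_gain()` shifts the normalized tuning of every cell in a
#' sub-population by a common `delta` (rate becomes
#' `peak * (tuning + delta)`, clamped at zero); per-trial deltas are drawn
#' uniformly on `[-0.2, 0.2]`.  `apply_multiplicative_gain()` scales each
#' sub-population's rates by a common log-normal factor with
#' `meanlog = -1/2, sdlog = 1`, so the mean gain is 1.
#'
#' Sub-populations (one per pure tuned dimension, plus the conjunctive
#' cells) receive independent gains.
#'
#' @param population an `hd_population`.
#' @param stimulus stimulus vector (radians).
#' @param gains named or ordered numeric vector with one gain per
#'   sub-population, in the order returned by
#'   `sort(unique(.subpop_id(population)))`.
#' @return vector of `n` non-negative rates in Hz.
#' @export
apply_additive_gain <- function(population, stimulus, gains) {
  sub <- .subpop_id(population)
  ids <- sort(unique(sub))
  stopifnot(length(gains) == length(ids))
  tuning <- (population_rates(population, stimulus) - population$baseline) /
    population$peak_rate
  rate <- population$peak_rate * (tuning + gains[match(sub, ids)]) +
    population$baseline
  pmax(rate, 0)
}

#' @rdname apply_additive_gain
#' @export
apply_multiplicative_gain <- function(population, stimulus, gains) {
  sub <- .subpop_id(population)
  ids <- sort(unique(sub))
  stopifnot(length(gains) == length(ids), all(gains >= 0))
  population_rates(population, stimulus) * gains[match(sub, ids)]
}

#' @rdname apply_additive_gain
#' @param n_subpops number of sub-populations to draw gains for.
#' @param type `"additive"` (uniform on \[-0.2, 0.2\]) or
#'   `"multiplicative"` (log-normal, mean 1).
#' @return `draw_gains`: a numeric vector of gains.
#' @export
draw_gains <- function(n_subpops, type = c("additive", "multiplicative")) {
  type <- match.arg(type)
  if (type == "additive") stats::runif(n_subpops, -0.2, 0.2)
  else stats::rlnorm(n_subpops, meanlog = -0.5, sdlog = 1)
}

#' Poisson spike counts under shared gain fluctuations
#'
#' One gain per sub-population is redrawn on every trial; spike counts are
#' then Poisson with mean `gain-modulated rate * t`.
#'
#' @inheritParams sample_independent
#' @param type `"additive"` or `"multiplicative"`; see
#'   [apply_additive_gain()].
#' @return a `spike_count_matrix` (noise model `"additive_gain"` or
#'   `"multiplicative_gain"`).
#' @export
sample_gain <- function(population, stimulus, t, trials = 1,
                        type = c("additive", "multiplicative"),
                        seed = NULL) {
  type <- match.arg(type)
  stopifnot(t > 0, trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub <- .subpop_id(population)
  k <- length(unique(sub))
  modulate <- if (type == "additive") apply_additive_gain
              else apply_multiplicative_gain
  counts <- matrix(0L, trials, population$n)
  for (tr in seq_len(trials)) {
    rate <- modulate(population, stimulus, draw_gains(k, type))
    counts[tr, ] <- stats::rpois(population$n, rate * t)
  }
  .spike_count_matrix(counts, population, stimulus, t,
                      paste0(type, "_gain"), seed)
}

#' Write spike counts to CSV (long format)
#'
#' One row per (trial, neuron) pair with the observed count; stimulus,
#' decoding time and noise model are carried in a comment-free header
#' column set so files round-trip with [read.csv()].
#'
#' @param counts a `spike_count_matrix`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
spike_counts_to_csv <- function(counts, path) {
  stopifnot(inherits(counts, "spike_count_matrix"))
  m <- unclass(counts)
  df <- data.frame(trial = rep(seq_len(nrow(m)), ncol(m)),
                   neuron = rep(seq_len(ncol(m)), each = nrow(m)),
                   count = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
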