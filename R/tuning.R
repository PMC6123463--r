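#' von-Mises tuning curves and head-direction populations
#'
#' A head-direction cell's mean firing rate as a function of a circular
#' stimulus is modeled by a circular-normal (von-Mises) function.  A *pure*
#' cell is tuned to a single stimulus dimension (azimuth or pitch); a
#' *conjunctive* cell is tuned jointly to all dimensions via the separable
#' product of per-dimension von-Mises factors.
#'
#' The rate of a 1D cell with preferred direction `phi_i`, concentration
#' `kappa`, modulation depth `R` (the "peak rate", rate at the preferred
#' direction above baseline) and baseline `b` is
#' `R * exp(kappa * (cos(phi - phi_i) - 1)) + b`.
#'
#' @name tuning
NULL

#' Construct a 1D von-Mises tuning curve
#'
#' @param preferred_direction preferred direction in radians.
#' @param kappa concentration parameter (> 0); see [kappa_from_width()].
#' @param peak_rate modulation depth in Hz: the rate at the preferred
#'   direction above baseline.
#' @param baseline_rate baseline firing rate in Hz (default 0).
#' @return an object of class `vonmises1d`.
#' @seealso [rate_1d()], [vonmises2d()]
#' @export
vonmises1d <- function(preferred_direction, kappa, peak_rate,
                       baseline_rate = 0) {
  stopifnot(is.finite(preferred_direction), kappa > 0, peak_rate > 0,
            baseline_rate >= 0)
  structure(
    list(preferred_direction = wrap_angle(preferred_direction),
         kappa = kappa, peak_rate = peak_rate,
         baseline_rate = baseline_rate),
    class = "vonmises1d")
}

#' Construct a 2D (conjunctive) von-Mises tuning curve
#'
#' Separable product form over azimuth and pitch: the marginal at the
#' preferred pitch is a 1D von-Mises in azimuth.
#'
#' @param preferred_azimuth,preferred_pitch preferred angles in radians.
#' @param kappa_azimuth,kappa_pitch concentration per dimension (> 0).
#' @param peak_rate modulation depth in Hz at the joint preferred direction.
#' @param baseline_rate baseline firing rate in Hz (default 0).
#' @return an object of class `vonmises2d`.
#' @export
vonmises2d <- function(preferred_azimuth, preferred_pitch,
                       kappa_azimuth, kappa_pitch, peak_rate,
                       baseline_rate = 0) {
  stopifnot(kappa_azimuth > 0, kappa_pitch > 0, peak_rate > 0,
            baseline_rate >= 0)
  structure(
    list(preferred_azimuth = wrap_angle(preferred_azimuth),
         preferred_pitch = wrap_angle(preferred_pitch),
         kappa_azimuth = kappa_azimuth, kappa_pitch = kappa_pitch,
         peak_rate = peak_rate, baseline_rate = baseline_rate),
    class = "vonmises2d")
}

#' Convert tuning width at half-height to von-Mises concentration
#'
#' The tuning width is the full width, in degrees, at half the tuning
#' curve's height above baseline.  The half-height condition
#' `exp(kappa * (cos(width/2) - 1)) = 1/2` gives
#' `kappa = log(2) / (1 - cos(width/2))`.  A 45-degree width corresponds to
#' `kappa = 9.11`, a 90-degree width to `kappa = 2.37`.
#'
#' @param width_deg full width at half-height in degrees, in (0, 360).
#' @return concentration parameter `kappa` (dimensionless).
#' @export
kappa_from_width <- function(width_deg) {
  if (any(width_deg <= 0) || any(width_deg >= 360))
    stop("tuning width must lie strictly between 0 and 360 degrees")
  log(2) / (1 - cos(deg2rad(width_deg) / 2))
}

#' @rdname kappa_from_width
#' @param kappa concentration parameter (> 0).
#' @return `width_from_kappa`: full width at half-height in degrees.
#' @export
width_from_kappa <- function(kappa) {
  if (any(kappa <= 0)) stop("kappa must be positive")
  2 * rad2deg(acos(1 - log(2) / kappa))
}

#' Evaluate a 1D von-Mises tuning curve
#'
#' @param curve a [vonmises1d()] object.
#' @param stimulus stimulus angle(s) in radians (any real; wrapped).
#' @return firing rate(s) in Hz.
#' @export
rate_1d <- function(curve, stimulus) {
  stopifnot(inherits(curve, "vonmises1d"))
  curve$peak_rate *
    exp(curve$kappa * (cos(stimulus - curve$preferred_direction) - 1)) +
    curve$baseline_rate
}

#' Evaluate a 2D von-Mises tuning curve
#'
#' @param curve a [vonmises2d()] object.
#' @param azimuth,pitch stimulus angles in radians.
#' @return firing rate(s) in Hz.
#' @export
rate_2d <- function(curve, azimuth, pitch) {
  stopifnot(inherits(curve, "vonmises2d"))
  curve$peak_rate *
    exp(curve$kappa_azimuth * (cos(azimuth - curve$preferred_azimuth) - 1) +
        curve$kappa_pitch * (cos(pitch - curve$preferred_pitch) - 1)) +
    curve$baseline_rate
}

#' Conjunctive peak rate for a matched pure/conjunctive comparison
#'
#' Given the peak rate of pure cells, returns the peak rate of conjunctive
#' cells under one of two normalization schemes:
#' \describe{
#'   \item{`equal_population_rate`}{both populations emit the same mean
#'     number of spikes (averaged over stimuli and preferred directions):
#'     `R_conj = R_pure * exp((D-1) * kappa) / I0(kappa)^(D-1)`.}
#'   \item{`equal_fisher_information`}{both populations carry the same
#'     Fisher information; divides the above by `D`.}
#' }
#'
#' @param r_pure peak rate of pure cells (Hz).
#' @param kappa concentration (equal along all dimensions).
#' @param d stimulus dimensionality (integer >= 2).
#' @param scheme `"equal_population_rate"` or `"equal_fisher_information"`.
#' @return conjunctive peak rate in Hz.
#' @export
conjunctive_peak_rate <- function(r_pure, kappa, d = 2,
                                  scheme = c("equal_population_rate",
                                             "equal_fisher_information")) {
  scheme <- match.arg(scheme)
  if (d < 2) stop("d must be >= 2: no pure/conjunctive distinction in 1D")
  stopifnot(r_pure > 0, kappa >= 0)
  # exp((D-1)k)/I0(k)^(D-1) computed with exponentially scaled Bessel to
  # stay finite at large kappa: I0(k) = besselI(k, 0, TRUE) * exp(k)
  i0s <- besselI(kappa, 0, expon.scaled = TRUE)  # = I0(k) e^-k
  r <- r_pure / i0s^(d - 1)
  if (scheme == "equal_fisher_information") r <- r / d
  r
}

#' Build a model population of head-direction cells
#'
#' Constructs `n` cells tuned to a `d`-dimensional circular stimulus.  For
#' `kind = "pure"` the population is split into `d` equal sub-populations
#' of `n/d` cells, each tuned to one dimension; for `kind = "conjunctive"`
#' all `n` cells are tuned to every dimension.  `kind = "mixed"` combines a
#' pure and a conjunctive part (see `pure_fraction`).  Preferred directions
#' are drawn uniformly on `[0, 2*pi)` per dimension.
#'
#' Peak rates: pure cells get `r_pure`; conjunctive cells get the rate
#' implied by `scheme` (see [conjunctive_peak_rate()]), or `r_conj` if
#' given explicitly (`scheme = "explicit"`).
#'
#' @param n total number of cells (divisible by `d` for pure; for mixed,
#'   the pure part must be divisible by `d`).
#' @param kind `"pure"`, `"conjunctive"`, or `"mixed"`.
#' @param d stimulus dimensionality (>= 1; >= 2 for conjunctive/mixed).
#' @param kappa concentration, recycled to length `d`.
#' @param r_pure pure-cell peak rate (Hz); also the reference rate used to
#'   normalize conjunctive cells.
#' @param scheme normalization scheme for conjunctive peak rates.
#' @param r_conj explicit conjunctive peak rate (only with
#'   `scheme = "explicit"`).
#' @param pure_fraction for `kind = "mixed"`: fraction of cells that are
#'   pure (rounded to a multiple of `d` cells).
#' @param baseline baseline rate in Hz (default 0).
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `hd_population`: a list with `n`, `d`,
#'   `kind`, `pref` (n x d matrix of preferred directions, radians),
#'   `dim` (tuned dimension index for pure cells, `NA` for conjunctive),
#'   `kappa` (n x d matrix, 0 for untuned dimensions), `peak_rate`,
#'   `baseline` (length-n vectors), `scheme`, and `seed`.
#' @export
build_population <- function(n, kind = c("pure", "conjunctive", "mixed"),
                             d = 2, kappa = 9.11, r_pure = 1,
                             scheme = c("equal_population_rate",
                                        "equal_fisher_information",
                                        "explicit"),
                             r_conj = NULL, pure_fraction = 0.5,
                             baseline = 0, seed = NULL) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  stopifnot(n >= 1, d >= 1)
  kappa <- rep_len(kappa, d)
  if (kind %in% c("conjunctive", "mixed") && d < 2)
    stop("conjunctive cells require d >= 2")
  if (!is.null(seed)) set.seed(seed)

  n_pure <- switch(kind,
                   pure = n,
                   conjunctive = 0L,
                   mixed = as.integer(round(n * pure_fraction / d) * d))
  n_conj <- n - n_pure
  if (kind == "pure" && n %% d != 0)
    stop("for a pure population, n must be divisible by d (equal ",
         "sub-populations of n/d cells per dimension)")

  pref <- matrix(stats::runif(n * d, 0, 2 * pi), n, d)
  dim_idx <- rep(NA_integer_, n)
  kap <- matrix(0, n, d)
  if (n_pure > 0) {
    dim_idx[seq_len(n_pure)] <- rep(seq_len(d), each = n_pure / d)
    for (i in seq_len(n_pure)) kap[i, dim_idx[i]] <- kappa[dim_idx[i]]
  }
  if (n_conj > 0)
    kap[(n_pure + 1):n, ] <- matrix(kappa, n_conj, d, byrow = TRUE)

  if (scheme == "explicit") {
    if (n_conj > 0 && is.null(r_conj))
      stop("scheme = 'explicit' requires r_conj")
  } else if (n_conj > 0) {
    # equal-kappa normalization; per-dimension kappas must agree
    if (length(unique(kappa)) != 1)
      stop("normalization schemes assume equal kappa along dimensions; ",
           "use scheme = 'explicit' with unequal kappa")
    r_conj <- conjunctive_peak_rate(r_pure, kappa[1], d, scheme)
  }
  peak <- c(rep(r_pure, n_pure), rep(if (n_conj > 0) r_conj else numeric(0),
                                     n_conj))

  structure(
    list(n = n, d = d, kind = kind, pref = pref, dim = dim_idx,
         kappa = kap, peak_rate = peak,
         baseline = rep_len(baseline, n), scheme = scheme, seed = seed),
    class = "hd_population")
}

#' @export
print.hd_population <- function(x, ...) {
  cat(sprintf("<hd_population> %d cells, kind=%s, D=%d, scheme=%s\n",
              x$n, x$kind, x$d, x$scheme))
  invisible(x)
}

#' Mean firing rates of a population at a stimulus
#'
#' @param population an [build_population()] object.
#' @param stimulus numeric vector of length `d` (radians).
#' @return vector of `n` rates in Hz.
#' @export
population_rates <- function(population, stimulus) {
  stopifnot(inherits(population, "hd_population"),
            length(stimulus) == population$d)
  # rate_i = peak_i * exp(sum_d kappa_id * (cos(s_d - pref_id) - 1)) + b_i
  expo <- rowSums(population$kappa *
                    (cos(sweep(-population$pref, 2, stimulus, "+")) - 1))
  population$peak_rate * exp(expo) + population$baseline
}

#' Serialize a population to JSON (and back)
#'
#' Angles are written in degrees so saved populations are human-readable;
#' [population_from_json()] restores the object exactly (up to angle
#' round-trip precision).
#'
#' @param population an `hd_population`.
#' @param path file path to write to (`population_to_json`) or read from.
#' @return `population_to_json` invisibly returns `path`;
#'   `population_from_json` returns an `hd_population`.
#' @export
population_to_json <- function(population, path) {
  stopifnot(inherits(population, "hd_population"))
  doc <- list(
    n = population$n, d = population$d, kind = population$kind,
    scheme = population$scheme,
    seed = if (is.null(population$seed)) NULL else population$seed,
    pref_deg = round(rad2deg(population$pref), 10),
    dim = population$dim, kappa = population$kappa,
    peak_rate = population$peak_rate, baseline = population$baseline)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname population_to_json
#' @export
population_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(n = as.integer(doc$n), d = as.integer(doc$d), kind = doc$kind,
         pref = deg2rad(matrix(doc$pref_deg, doc$n, doc$d)),
         dim = as.integer(doc$dim),
         kappa = matrix(doc$kappa, doc$n, doc$d),
         peak_rate = doc$peak_rate, baseline = doc$baseline,
         scheme = doc$scheme,
         seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed)),
    class = "hd_population")
}
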