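#' Fisher information of pure and conjunctive populations
#'
#' Closed-form Fisher information (FI) for large populations of von-Mises
#' tuned Poisson neurons with uniformly distributed preferred directions.
#' With independent noise the FI matrix is proportional to the identity, so
#' a single scalar `J` per population summarizes it; `1/sqrt(J)` is the
#' Cramer-Rao lower bound on the per-dimension decoding error.
#'
#' For a pure population of `N` cells (split equally over `D` dimensions,
#' peak rate `R`, decoding time `T`, concentration `kappa`):
#' `J_pure = (1/2) N R T kappa exp(-kappa) I1(kappa)` (for `D = 2`; each
#' sub-population of `N/2` cells informs one dimension).  For a conjunctive
#' population of `N` cells tuned to all `D` dimensions:
#' `J_conj = N R T kappa exp(-D*kappa) I0(kappa)^(D-1) I1(kappa)`.
#'
#' @name fisher
NULL

# exponentially scaled Bessel helpers: besselI(k, nu, TRUE) = I_nu(k) e^-k
.i0e <- function(k) besselI(k, 0, expon.scaled = TRUE)
.i1e <- function(k) besselI(k, 1, expon.scaled = TRUE)

#' Fisher information of a pure population (per dimension)
#'
#' @param n total number of cells in the pure population, split equally
#'   over the `d` dimensions; the per-dimension sub-population of `n/d`
#'   cells is what informs each coordinate, hence the leading `1/d`
#'   (`1/2` in the 2D case).
#' @param r_pure peak rate in Hz.
#' @param t decoding time in seconds.
#' @param kappa concentration.
#' @param d stimulus dimensionality (default 2).
#' @return scalar Fisher information in rad^-2.
#' @export
fi_pure <- function(n, r_pure, t, kappa, d = 2) {
  stopifnot(n > 0, r_pure > 0, t > 0, kappa > 0, d >= 1)
  (n / d) * r_pure * t * kappa * .i1e(kappa)
}

#' Fisher information of a conjunctive population (per dimension)
#'
#' @inheritParams fi_pure
#' @param r_conj conjunctive peak rate in Hz.
#' @param d stimulus dimensionality (>= 2).
#' @return scalar Fisher information in rad^-2.
#' @export
fi_conj <- function(n, r_conj, t, kappa, d = 2) {
  stopifnot(n > 0, r_conj > 0, t > 0, kappa > 0)
  if (d < 2) stop("d must be >= 2 for a conjunctive population")
  n * r_conj * t * kappa * .i0e(kappa)^(d - 1) * .i1e(kappa)
}

#' Expected total spike count of a population
#'
#' Mean number of spikes emitted by the whole population in time `t`,
#' averaged over uniformly distributed stimuli and preferred directions:
#' `N T R exp(-kappa) I0(kappa)` for pure cells and
#' `N T R exp(-D*kappa) I0(kappa)^D` for conjunctive cells.
#'
#' @inheritParams fi_pure
#' @param r peak rate in Hz.
#' @param kind `"pure"` or `"conjunctive"`.
#' @param d dimensionality (used for conjunctive).
#' @return expected spike count (dimensionless).
#' @export
mean_spikes <- function(n, r, t, kappa, kind = c("pure", "conjunctive"),
                        d = 2) {
  kind <- match.arg(kind)
  stopifnot(n > 0, r > 0, t > 0, kappa > 0)
  p <- if (kind == "pure") 1 else d
  n * t * r * .i0e(kappa)^p
}

#' Cramer-Rao bound on the per-dimension decoding error
#'
#' @param j scalar Fisher information in rad^-2 (> 0).
#' @return lower bound on the root-mean-square error, in degrees.
#' @export
cr_bound <- function(j) {
  if (any(j <= 0)) stop("Fisher information must be positive")
  rad2deg(1 / sqrt(j))
}

#' Fisher-information summary for a matched pure/conjunctive comparison
#'
#' Computes both populations' scalar FI, Cramer-Rao bounds and mean spike
#' counts for a given `(N, T, kappa, D)` and normalization scheme.
#'
#' @inheritParams fi_pure
#' @param d stimulus dimensionality.
#' @param scheme conjunctive peak-rate normalization; see
#'   [conjunctive_peak_rate()].
#' @return a list of class `fisher_result` with elements `J_pure`,
#'   `J_conj`, `cr_bound_pure`, `cr_bound_conj` (degrees), `n_spikes_pure`,
#'   `n_spikes_conj`, and a `params` echo.
#' @export
fisher_result <- function(n, r_pure = 1, t = 1, kappa = 9.11, d = 2,
                          scheme = c("equal_population_rate",
                                     "equal_fisher_information")) {
  scheme <- match.arg(scheme)
  r_conj <- conjunctive_peak_rate(r_pure, kappa, d, scheme)
  jp <- fi_pure(n, r_pure, t, kappa, d)
  jc <- fi_conj(n, r_conj, t, kappa, d)
  structure(
    list(J_pure = jp, J_conj = jc,
         cr_bound_pure = cr_bound(jp), cr_bound_conj = cr_bound(jc),
         n_spikes_pure = mean_spikes(n, r_pure, t, kappa, "pure"),
         n_spikes_conj = mean_spikes(n, r_conj, t, kappa, "conjunctive", d),
         D = d,
         params = list(n = n, r_pure = r_pure, r_conj = r_conj, t = t,
                       kappa = kappa, scheme = scheme)),
    class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf(
    "<fisher_result> N=%g T=%gs kappa=%.3g D=%d (%s)\n",
    x$params$n, x$params$t, x$params$kappa, x$D, x$params$scheme))
  cat(sprintf("  J_pure=%.6g  J_conj=%.6g  (ratio %.4g)\n",
              x$J_pure, x$J_conj, x$J_conj / x$J_pure))
  cat(sprintf("  CR bound: pure %.4g deg, conj %.4g deg\n",
              x$cr_bound_pure, x$cr_bound_conj))
  cat(sprintf("  mean spikes: pure %.5g, conj %.5g\n",
              x$n_spikes_pure, x$n_spikes_conj))
  invisible(x)
}

#' @rdname fisher_result
#' @param x a `fisher_result`.
#' @param path file path for the JSON document.
#' @export
fisher_result_to_json <- function(x, path) {
  stopifnot(inherits(x, "fisher_result"))
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
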