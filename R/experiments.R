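#' Simulation experiments over population size and decoding time
#'
#' Drivers that map decoding performance over the `(N, T)` plane and
#' implement the derived analyses: regime maps of the pure/conjunctive
#' error ratio, the critical population size `N_cr`, 2D-vs-1D error
#' ratios, error distributions, spike-count-conditioned errors, mixed
#' populations, and the error-versus-Fisher-information collapse.
#'
#' All drivers draw a fresh uniform stimulus per repeat and (by default)
#' resample preferred directions per repeat, and are reproducible given a
#' seed.  With the same seed, pure and conjunctive runs see the same
#' stimulus sequence, making error ratios better matched.
#'
#' @name experiments
NULL

#' Simulate per-trial decoding errors at a single (N, T) cell
#'
#' @param kind population kind: `"pure"`, `"conjunctive"`, or `"mixed"`.
#' @param n population size.
#' @param t decoding time in seconds.
#' @param repeats number of independent repeats (trials).
#' @param d stimulus dimensionality.
#' @param kappa von-Mises concentration.
#' @param r_pure pure peak rate in Hz.
#' @param scheme conjunctive normalization scheme.
#' @param decoder `"ml"` or `"pv"`.
#' @param noise `"independent"`, `"correlated"`, `"additive_gain"`, or
#'   `"multiplicative_gain"`.
#' @param resample_prefs resample preferred directions on every repeat
#'   (default) or fix one population for all repeats.
#' @param pure_fraction for mixed populations.
#' @param seed integer seed.
#' @param keep_counts also return per-trial total spike counts per
#'   sub-population (needed for conditional analyses).
#' @param ... further arguments to the decoder.
#' @return a data.frame of per-trial errors (degrees) as in
#'   [decode_trials()], plus spike-count columns when `keep_counts`.
#' @export
simulate_errors <- function(kind, n, t, repeats = 100, d = 2,
                            kappa = 9.11, r_pure = 1,
                            scheme = "equal_population_rate",
                            decoder = c("ml", "pv"),
                            noise = "independent",
                            resample_prefs = TRUE, pure_fraction = 0.5,
                            seed = NULL, keep_counts = FALSE, ...) {
  decoder <- match.arg(decoder)
  if (!is.null(seed)) set.seed(seed)
  stimuli <- matrix(stats::runif(repeats * d, 0, 2 * pi), repeats, d)
  pop <- NULL
  sampler <- switch(noise,
    independent = function(p, s) sample_independent(p, s, t, 1),
    correlated = function(p, s) sample_correlated(p, s, t, 1),
    additive_gain = function(p, s) sample_gain(p, s, t, 1, "additive"),
    multiplicative_gain = function(p, s)
      sample_gain(p, s, t, 1, "multiplicative"),
    stop("unknown noise model: ", noise))
  rows <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    if (is.null(pop) || resample_prefs)
      pop <- build_population(n, kind, d, kappa, r_pure, scheme,
                              pure_fraction = pure_fraction)
    s <- stimuli[i, ]
    counts <- sampler(pop, s)
    row <- decode_trials(counts, pop, t, s, decoder, ...)
    if (keep_counts) {
      sub <- .subpop_id(pop)
      for (k in sort(unique(sub))) {
        nm <- if (k == 0) "spikes_conj" else paste0("spikes_pure_", k)
        row[[nm]] <- sum(counts[1, sub == k])
      }
      row$spikes_total <- sum(counts)
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Mean decoding error over an (N, T) grid
#'
#' @inheritParams simulate_errors
#' @param n_grid integer vector of population sizes.
#' @param t_grid numeric vector of decoding times (seconds; typically
#'   log-spaced).
#' @param seed base seed; each grid cell gets a deterministic sub-seed, so
#'   two surfaces built with the same `seed` share stimulus sequences.
#' @return an object of class `error_surface`: list with `n_grid`,
#'   `t_grid`, matrices `mean_error` and `se` (degrees,
#'   rows = N, cols = T), `kind`, `repeats`, and the call parameters.
#' @export
error_surface <- function(kind, n_grid, t_grid, repeats = 100, d = 2,
                          kappa = 9.11, r_pure = 1,
                          scheme = "equal_population_rate",
                          decoder = "ml", noise = "independent",
                          seed = 1, ...) {
  if (repeats < 30)
    warning("fewer than 30 repeats per cell gives unstable contours")
  mean_error <- se <- matrix(
    NA_real_, length(n_grid), length(t_grid),
    dimnames = list(N = n_grid, T = signif(t_grid, 4)))
  for (i in seq_along(n_grid)) for (j in seq_along(t_grid)) {
    cell_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
    errs <- simulate_errors(kind, n_grid[i], t_grid[j], repeats, d,
                            kappa, r_pure, scheme, decoder, noise,
                            seed = cell_seed, ...)$scalar_error
    mean_error[i, j] <- mean(errs)
    se[i, j] <- stats::sd(errs) / sqrt(length(errs))
  }
  structure(list(kind = kind, n_grid = n_grid, t_grid = t_grid,
                 mean_error = mean_error, se = se, repeats = repeats,
                 d = d, kappa = kappa, scheme = scheme, decoder = decoder,
                 noise = noise, seed = seed),
            class = "error_surface")
}

#' Regime map of the pure/conjunctive error ratio
#'
#' Labels each `(N, T)` cell by comparing the error ratio
#' `epsilon_pure / epsilon_conj` to the Fisher-information prediction
#' `sqrt(D)`: regime 1 where the ratio is within `delta` of `sqrt(D)`
#' (both errors saturate the Cramer-Rao bound), regime 2 where it falls
#' below `sqrt(D) - delta` (small N, long T: pure cells close the gap and,
#' below `N_cr`, outperform in absolute terms), and regime 3 where it
#' exceeds `sqrt(D) + delta` (short T: conjunctive cells beat the FI
#' prediction).  `N_cr` is the largest N whose ratio is below 1 at
#' `T = 10` s (the nearest grid column).
#'
#' @param surface_pure,surface_conj matched [error_surface()] objects.
#' @param delta contour tolerance (default 0.02).
#' @param t_ncr decoding time at which `N_cr` is read off (default 10 s).
#' @return an object of class `regime_map`: `ratio` and `regime` matrices,
#'   `delta`, `sqrt_d`, `n_cr`.
#' @export
regime_map <- function(surface_pure, surface_conj, delta = 0.02,
                       t_ncr = 10) {
  stopifnot(identical(surface_pure$n_grid, surface_conj$n_grid),
            identical(surface_pure$t_grid, surface_conj$t_grid))
  ratio <- surface_pure$mean_error / surface_conj$mean_error
  sqrt_d <- sqrt(surface_pure$d)
  regime <- matrix(1L, nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
  regime[ratio < sqrt_d - delta] <- 2L
  regime[ratio > sqrt_d + delta] <- 3L
  jt <- which.min(abs(surface_pure$t_grid - t_ncr))
  below <- which(ratio[, jt] < 1)
  n_cr <- if (length(below)) max(surface_pure$n_grid[below]) else
    min(surface_pure$n_grid)
  structure(list(ratio = ratio, regime = regime, delta = delta,
                 sqrt_d = sqrt_d, n_cr = n_cr,
                 t_ncr = surface_pure$t_grid[jt]),
            class = "regime_map")
}

#' Critical population size across tuning widths and dimensionalities
#'
#' For each `(kappa, D)` pair, simulates the pure/conjunctive error ratio
#' along `n_grid` at fixed long decoding time and reports the largest N
#' with ratio below 1 (`N_cr` = grid minimum if the ratio never drops
#' below 1).  `N_cr` grows with narrower tuning (larger kappa) and with
#' dimensionality.
#'
#' @param kappa_list,d_list parameter vectors; the result has one row per
#'   combination.
#' @param n_grid candidate population sizes (must be divisible by each D).
#' @param t decoding time (default 10 s).
#' @param repeats repeats per cell.
#' @param seed base seed.
#' @return data.frame with columns `kappa`, `d`, `n_cr`.
#' @export
n_critical <- function(kappa_list, d_list, n_grid, t = 10, repeats = 100,
                       seed = 1) {
  out <- expand.grid(kappa = kappa_list, d = d_list)
  out$n_cr <- NA_real_
  for (r in seq_len(nrow(out))) {
    kk <- out$kappa[r]; dd <- out$d[r]
    ng <- n_grid[n_grid %% dd == 0]
    ratio <- vapply(seq_along(ng), function(i) {
      cs <- (seed + 1009L * r + 31L * i) %% .Machine$integer.max
      ep <- mean(simulate_errors("pure", ng[i], t, repeats, dd, kk,
                                 seed = cs)$scalar_error)
      ec <- mean(simulate_errors("conjunctive", ng[i], t, repeats, dd, kk,
                                 seed = cs)$scalar_error)
      ep / ec
    }, numeric(1))
    below <- which(ratio < 1)
    out$n_cr[r] <- if (length(below)) max(ng[below]) else min(ng)
  }
  out
}

#' Ratio of combined 2D error to per-dimension 1D error
#'
#' From a 2D simulation, computes `mean(scalar error) /
#' mean(|per-dimension error|)` at each decoding time.  If per-dimension
#' errors were independent zero-mean Gaussians the ratio would be
#' `pi/2 ~ 1.57` regardless of their scale (see
#' [gaussian_error_ratio_2d_1d()]); heavier-than-Gaussian tails (pure
#' cells at short T) push it above `pi/2`.
#'
#' @inheritParams simulate_errors
#' @param t_grid decoding times to evaluate.
#' @return data.frame with columns `t`, `ratio`, `mean_2d`, `mean_1d`,
#'   `se_ratio` (delta-method standard error).
#' @export
ratio_2d_1d <- function(kind, n, t_grid, repeats = 200, kappa = 9.11,
                        r_pure = 1, scheme = "equal_population_rate",
                        seed = 1, ...) {
  rows <- lapply(seq_along(t_grid), function(j) {
    cs <- (seed + 104729L * j) %% .Machine$integer.max
    df <- simulate_errors(kind, n, t_grid[j], repeats, 2, kappa, r_pure,
                          scheme, seed = cs, ...)
    e2 <- df$scalar_error
    e1 <- c(abs(df$error_1), abs(df$error_2))
    ratio <- mean(e2) / mean(e1)
    se <- ratio * sqrt(stats::var(e2) / (repeats * mean(e2)^2) +
                         stats::var(e1) / (length(e1) * mean(e1)^2))
    data.frame(t = t_grid[j], ratio = ratio, mean_2d = mean(e2),
               mean_1d = mean(e1), se_ratio = se)
  })
  do.call(rbind, rows)
}

#' Asymptotic Gaussian 2D/1D mean-error ratio
#'
#' For iid zero-mean Gaussian per-dimension errors with common standard
#' deviation `sigma`, the mean combined 2D error is `sqrt(pi/2) * sigma`
#' and the mean 1D (absolute) error is `sqrt(2/pi) * sigma`, so their
#' ratio is `pi/2`, independent of `sigma`.  Computed here by numeric
#' integration as an independent check of the closed forms.
#'
#' @param sigma standard deviation (result is independent of it).
#' @return list with `mean_2d`, `mean_1d`, `ratio`.
#' @export
gaussian_error_ratio_2d_1d <- function(sigma = 1) {
  # E[sqrt(ex^2+ey^2)] in polar form and E[|ex|], both under N(0, sigma^2)
  m2 <- stats::integrate(function(r) r^2 / sigma^2 * exp(-r^2 / (2 * sigma^2)),
                         0, Inf)$value
  m1 <- stats::integrate(function(x) 2 * x / sqrt(2 * pi * sigma^2) *
                           exp(-x^2 / (2 * sigma^2)), 0, Inf)$value
  list(mean_2d = m2, mean_1d = m1, ratio = m2 / m1)
}

#' Per-dimension error distribution summary
#'
#' @inheritParams simulate_errors
#' @return list with the per-trial error table, per-dimension variances,
#'   and per-dimension excess kurtosis.
#' @export
error_distribution <- function(kind, n, t, repeats = 500, kappa = 9.11,
                               seed = 1, ...) {
  df <- simulate_errors(kind, n, t, repeats, 2, kappa, seed = seed, ...)
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3
  list(errors = df,
       var = c(dim1 = stats::var(df$error_1), dim2 = stats::var(df$error_2)),
       excess_kurtosis = c(dim1 = kurt(df$error_1),
                           dim2 = kurt(df$error_2)))
}

#' Errors conditioned on minimum spike counts
#'
#' At short decoding times the pure population can lose a whole stimulus
#' dimension when one sub-population happens to emit very few spikes.
#' Conditioning removes such trials: the pure error is averaged over
#' trials where *each* sub-population emitted at least `n_min` spikes, the
#' conjunctive error over trials with at least `2 * n_min` total spikes
#' (so the compared spike budgets stay equal).  `n_min = 0` recovers the
#' unconditional means.
#'
#' @inheritParams simulate_errors
#' @param n_min_list integer thresholds to evaluate.
#' @return data.frame with one row per `n_min`: conditional mean errors,
#'   the pure/conjunctive ratio, and retention fractions.
#' @export
conditional_error <- function(n, t, n_min_list = 0:4, repeats = 500,
                              kappa = 9.11, r_pure = 1,
                              scheme = "equal_population_rate", seed = 1,
                              ...) {
  dfp <- simulate_errors("pure", n, t, repeats, 2, kappa, r_pure, scheme,
                         seed = seed, keep_counts = TRUE, ...)
  dfc <- simulate_errors("conjunctive", n, t, repeats, 2, kappa, r_pure,
                         scheme, seed = seed, keep_counts = TRUE, ...)
  rows <- lapply(n_min_list, function(nm) {
    keep_p <- dfp$spikes_pure_1 >= nm & dfp$spikes_pure_2 >= nm
    keep_c <- dfc$spikes_conj >= 2 * nm
    ep <- dfp$scalar_error[keep_p]; ec <- dfc$scalar_error[keep_c]
    ratio <- mean(ep) / mean(ec)
    se <- ratio * sqrt(stats::var(ep) / (length(ep) * mean(ep)^2) +
                         stats::var(ec) / (length(ec) * mean(ec)^2))
    data.frame(
      n_min = nm, err_pure = mean(ep), err_conj = mean(ec),
      ratio = ratio, se_ratio = se,
      retained_pure = mean(keep_p), retained_conj = mean(keep_c))
  })
  do.call(rbind, rows)
}

#' Synergy of mixed pure and conjunctive populations
#'
#' For each pure fraction, builds a mixed population, decodes the full
#' population jointly (`epsilon_mix`) and each sub-population alone from
#' the same trials, and compares `epsilon_mix` to the no-interaction
#' expectation `epsilon_mix_independent = ep * ec / sqrt(ep^2 + ec^2)`
#' obtained by adding the sub-populations' inverse squared errors as if
#' they were independent information sources.  A normalized ratio below 1
#' indicates synergy; at short decoding times it is smallest at
#' intermediate pure fractions.
#'
#' @inheritParams simulate_errors
#' @param pure_fraction_grid fractions in (0, 1) to evaluate (endpoints
#'   0/1 are allowed; the synergy ratio is `NA` there).
#' @return data.frame with per-fraction errors, `err_mix_independent`,
#'   and `synergy_ratio`.
#' @export
mixed_error <- function(pure_fraction_grid, n, t, repeats = 200,
                        kappa = 9.11, r_pure = 1,
                        scheme = "equal_population_rate", seed = 1, ...) {
  rows <- lapply(seq_along(pure_fraction_grid), function(fi) {
    f <- pure_fraction_grid[fi]
    cs <- (seed + 613L * fi) %% .Machine$integer.max
    set.seed(cs)
    stimuli <- matrix(stats::runif(repeats * 2, 0, 2 * pi), repeats, 2)
    e_mix <- e_p <- e_c <- rep(NA_real_, repeats)
    for (i in seq_len(repeats)) {
      pop <- build_population(n, "mixed", 2, kappa, r_pure, scheme,
                              pure_fraction = f)
      s <- stimuli[i, ]
      counts <- sample_independent(pop, s, t, 1)[1, ]
      e_mix[i] <- circular_error(
        ml_decode_conj(counts, pop, t, ...)$estimate, s)$scalar
      is_pure <- !is.na(pop$dim)
      if (any(is_pure)) {
        sub <- .subset_population(pop, which(is_pure))
        e_p[i] <- circular_error(
          ml_decode_pure(counts[is_pure], sub, t)$estimate, s)$scalar
      }
      if (any(!is_pure)) {
        sub <- .subset_population(pop, which(!is_pure))
        e_c[i] <- circular_error(
          ml_decode_conj(counts[!is_pure], sub, t, ...)$estimate, s)$scalar
      }
    }
    ep <- mean(e_p); ec <- mean(e_c); em <- mean(e_mix)
    e_ind <- if (is.finite(ep) && is.finite(ec))
      ep * ec / sqrt(ep^2 + ec^2) else NA_real_
    data.frame(pure_fraction = f, err_mix = em, err_pure_part = ep,
               err_conj_part = ec, err_mix_independent = e_ind,
               synergy_ratio = em / e_ind)
  })
  do.call(rbind, rows)
}

# view of a population restricted to a subset of its cells
.subset_population <- function(population, idx) {
  structure(
    list(n = length(idx), d = population$d,
         kind = if (all(is.na(population$dim[idx]))) "conjunctive"
                else if (all(!is.na(population$dim[idx]))) "pure"
                else "mixed",
         pref = population$pref[idx, , drop = FALSE],
         dim = population$dim[idx],
         kappa = population$kappa[idx, , drop = FALSE],
         peak_rate = population$peak_rate[idx],
         baseline = population$baseline[idx],
         scheme = population$scheme, seed = NULL),
    class = "hd_population")
}

#' Error-versus-Fisher-information collapse (1D)
#'
#' Simulates 1D decoding errors for a set of `(N, T)` pairs and expresses
#' them against the analytic Fisher information
#' `J = N R T kappa exp(-kappa) I1(kappa)` (all N cells tuned to the one
#' dimension).  Because the error depends on N and T only through J, pairs
#' with equal `N * T` collapse onto a single curve of `error / CR bound`
#' versus J.  Evaluating the fitted curve at `J` and `2 * J` predicts the
#' pure/conjunctive error ratio at matched population rates, which exceeds
#' `sqrt(2)` at small J.
#'
#' @param nt_pairs two-column matrix or data.frame of `(N, T)` pairs.
#' @param repeats repeats per pair.
#' @param kappa,r_pure tuning parameters.
#' @param seed base seed.
#' @return data.frame with `n`, `t`, `fi`, `mean_error`, `se`,
#'   `cr_bound`, `error_over_cr`.
#' @export
error_vs_fi <- function(nt_pairs, repeats = 300, kappa = 9.11, r_pure = 1,
                        seed = 1) {
  nt_pairs <- as.data.frame(nt_pairs)
  names(nt_pairs)[1:2] <- c("n", "t")
  rows <- lapply(seq_len(nrow(nt_pairs)), function(i) {
    nn <- nt_pairs$n[i]; tt <- nt_pairs$t[i]
    cs <- (seed + 389L * i) %% .Machine$integer.max
    errs <- simulate_errors("pure", nn, tt, repeats, d = 1, kappa = kappa,
                            r_pure = r_pure, seed = cs)$scalar_error
    j <- nn * r_pure * tt * kappa * .i1e(kappa)  # 1D: all N cells tuned
    data.frame(n = nn, t = tt, fi = j, mean_error = mean(errs),
               se = stats::sd(errs) / sqrt(repeats), cr_bound = cr_bound(j),
               error_over_cr = mean(errs) / cr_bound(j))
  })
  do.call(rbind, rows)
}

#' Pure/conjunctive error ratio predicted from the FI collapse
#'
#' Interpolates the collapsed error curve (log-FI versus log-error) and
#' returns `error(J) / error(2 J)`: the ratio expected between two
#' populations whose FI differs by a factor of two, as pure and
#' conjunctive populations at matched rates do.
#'
#' @param collapse result of [error_vs_fi()].
#' @param fi FI values at which to evaluate (must have `2 * fi` within
#'   range).
#' @return numeric vector of predicted ratios.
#' @export
fi_collapse_ratio <- function(collapse, fi) {
  o <- order(collapse$fi)
  f <- stats::approxfun(log(collapse$fi[o]), log(collapse$mean_error[o]),
                        ties = list("ordered", mean))
  exp(f(log(fi)) - f(log(2 * fi)))
}
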