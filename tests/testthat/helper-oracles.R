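# Independent numeric oracles used across tests.

# per-dimension Fisher information of a pure population by quadrature:
# J = (N/2) R T / (2 pi) * Int (kappa sin phi)^2 exp(kappa (cos phi - 1)) dphi
fi_pure_quadrature <- function(n, r, t, kappa) {
  f <- function(phi) kappa^2 * sin(phi)^2 * exp(kappa * (cos(phi) - 1))
  (n / 2) * r * t / (2 * pi) *
    stats::integrate(f, 0, 2 * pi, rel.tol = 1e-10)$value
}

# conjunctive 2D Fisher information by (separable) double quadrature:
# J = N R T / (4 pi^2) * Int Int (kappa sin phi)^2
#       exp(kappa (cos phi + cos theta - 2)) dphi dtheta
fi_conj_quadrature <- function(n, r, t, kappa) {
  fphi <- function(phi) kappa^2 * sin(phi)^2 * exp(kappa * (cos(phi) - 1))
  fthe <- function(theta) exp(kappa * (cos(theta) - 1))
  n * r * t / (4 * pi^2) *
    stats::integrate(fphi, 0, 2 * pi, rel.tol = 1e-10)$value *
    stats::integrate(fthe, 0, 2 * pi, rel.tol = 1e-10)$value
}

# mean rate of a 1D von-Mises cell over a uniform stimulus, by quadrature
mean_rate_quadrature <- function(peak, kappa, baseline = 0) {
  stats::integrate(function(phi)
    peak * exp(kappa * (cos(phi) - 1)) + baseline,
    0, 2 * pi, rel.tol = 1e-10)$value / (2 * pi)
}

# brute-force ML estimate on a dense grid (no refinement shortcuts)
brute_force_ml <- function(counts, population, t, step_deg = 0.1) {
  grid <- deg2rad(seq(0, 360 - step_deg, by = step_deg))
  d <- population$d
  if (d == 1) {
    ll <- vapply(grid, function(g) {
      rate <- population_rates(population, g)
      sum(counts * log(rate)) - t * sum(rate)
    }, numeric(1))
    return(grid[which.max(ll)])
  }
  stopifnot(d == 2)
  best <- c(NA, NA); best_ll <- -Inf
  for (g1 in grid) for (g2 in grid) {
    rate <- population_rates(population, c(g1, g2))
    ll <- sum(counts * log(rate)) - t * sum(rate)
    if (ll > best_ll) { best_ll <- ll; best <- c(g1, g2) }
  }
  best
}

expect_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol)
}
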