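test_that("simulate_errors is reproducible and bounded", {
  a <- simulate_errors("pure", 100, 0.5, 30, seed = 1)
  b <- simulate_errors("pure", 100, 0.5, 30, seed = 1)
  expect_identical(a, b)
  expect_true(all(a$scalar_error <= 180 * sqrt(2) + 1e-9))
  expect_true(all(abs(a$error_1) <= 180))
})

test_that("error decreases with T and approaches the CR bound", {
  errs <- vapply(c(0.05, 0.5, 10), function(t)
    mean(simulate_errors("conjunctive", 500, t, 60,
                         seed = 2)$scalar_error), numeric(1))
  expect_true(all(diff(errs) < 0))
  fr <- fisher_result(500, t = 10)
  pred <- sqrt(pi / 2) * fr$cr_bound_conj   # mean of a 2D Gaussian error
  expect_lt(abs(errs[3] - pred) / pred, 0.15)
})

test_that("T -> 0 errors approach the no-information ceiling", {
  # with almost no spikes nearly all trials are degenerate and carry the
  # maximal error pi per dimension (180 * sqrt(2) combined); the mean
  # scalar error must sit at or above the uniform-guess ceiling ~138
  e <- simulate_errors("pure", 50, 1e-4, 200, seed = 3)
  expect_gt(mean(e$degenerate), 0.9)
  expect_gt(mean(e$scalar_error), 138)
  expect_lte(max(e$scalar_error), 180 * sqrt(2) + 1e-9)
})

test_that("error_surface obeys monotonicity within sampling error", {
  surf <- error_surface("conjunctive", c(64, 256), c(0.1, 1, 10),
                        repeats = 60, seed = 4)
  expect_equal(dim(surf$mean_error), c(2, 3))
  # non-increasing in T and in N (allow 3 SE slack)
  slack <- 3 * (surf$se[, -1] + surf$se[, -3])
  expect_true(all(diff(t(surf$mean_error)) < slack))
  expect_true(all(surf$mean_error[2, ] < surf$mean_error[1, ] +
                    3 * (surf$se[1, ] + surf$se[2, ])))
  expect_warning(error_surface("pure", 64, 1, repeats = 10, seed = 1),
                 "repeats")
})

test_that("regime_map labels and N_cr extraction work on synthetic surfaces", {
  mk <- function(m) {
    structure(list(kind = "x", n_grid = c(100, 1000), t_grid = c(0.1, 10),
                   mean_error = m, se = m * 0, repeats = 1, d = 2,
                   kappa = 9.11, scheme = "equal_population_rate",
                   decoder = "ml", noise = "independent", seed = 1),
              class = "error_surface")
  }
  ratio <- matrix(c(1.50, 0.95, 1.415, 1.41), 2, 2)  # N x T
  sp <- mk(ratio); sc <- mk(matrix(1, 2, 2))
  rm <- regime_map(sp, sc, delta = 0.02)
  expect_equal(rm$regime[1, 1], 3L)   # small N (row1), small T: > sqrt2+d
  expect_equal(rm$regime[2, 1], 2L)   # ratio 0.95 < sqrt2 - d
  expect_equal(rm$regime[1, 2], 1L)   # within delta of sqrt2
  expect_equal(rm$n_cr, 100)   # T=10 column has no ratio < 1 -> minimum
  sc_bad <- sc; sc_bad$t_grid <- c(0.2, 10)
  expect_error(regime_map(sp, sc_bad), "identical")
})

test_that("simulated regimes: short T favors conjunctive, small N pure", {
  # regime 3: N large, T very small
  cs <- 5
  ep <- mean(simulate_errors("pure", 1000, 0.05, 250,
                             seed = cs)$scalar_error)
  ec <- mean(simulate_errors("conjunctive", 1000, 0.05, 250,
                             seed = cs)$scalar_error)
  expect_gt(ep / ec, sqrt(2) + 0.02)
  # regime 2 side: N small, T long -> ratio drops below 1 (below N_cr)
  ep2 <- mean(simulate_errors("pure", 8, 10, 250, seed = cs,
                              kappa = 9.11)$scalar_error)
  ec2 <- mean(simulate_errors("conjunctive", 8, 10, 250, seed = cs,
                              kappa = 9.11)$scalar_error)
  expect_lt(ep2 / ec2, 1)
})

test_that("1D interchangeability of N and T at fixed N*T", {
  e1 <- simulate_errors("pure", 400, 1, 300, d = 1, seed = 6)$scalar_error
  e2 <- simulate_errors("pure", 800, 0.5, 300, d = 1,
                        seed = 7)$scalar_error
  se <- sqrt(stats::var(e1) / 300 + stats::var(e2) / 300)
  expect_lt(abs(mean(e1) - mean(e2)), 3 * se)
})

test_that("gaussian 2D/1D closed forms and the Monte-Carlo check", {
  g <- gaussian_error_ratio_2d_1d(2.5)
  expect_equal(g$mean_2d, sqrt(pi / 2) * 2.5, tolerance = 1e-6)
  expect_equal(g$mean_1d, sqrt(2 / pi) * 2.5, tolerance = 1e-6)
  expect_equal(g$ratio, pi / 2, tolerance = 1e-6)
  expect_equal(gaussian_error_ratio_2d_1d(17)$ratio, pi / 2,
               tolerance = 1e-6)   # independent of sigma
  set.seed(8)
  ex <- stats::rnorm(2e5); ey <- stats::rnorm(2e5)
  expect_close(mean(sqrt(ex^2 + ey^2)) / mean(abs(ex)), pi / 2, 0.01)
})

test_that("2D/1D ratio: pure exceeds conjunctive at short T", {
  rp <- ratio_2d_1d("pure", 500, c(0.05, 10), repeats = 250, seed = 9)
  rc <- ratio_2d_1d("conjunctive", 500, c(0.05, 10), repeats = 250,
                    seed = 9)
  # long-T asymptote ~ pi/2 for both kinds
  expect_close(rp$ratio[2], pi / 2, 3 * rp$se_ratio[2])
  expect_close(rc$ratio[2], pi / 2, 3 * rc$se_ratio[2])
  # short-T: pure ratio rises above the conjunctive one
  expect_gt(rp$ratio[1], rc$ratio[1])
  expect_gt(rp$ratio[1], pi / 2)
})

test_that("error distributions: pure cells are heavy-tailed at short T", {
  dp <- error_distribution("pure", 1000, 0.05, 400, seed = 10)
  dc <- error_distribution("conjunctive", 1000, 0.05, 400, seed = 10)
  expect_gt(mean(dp$excess_kurtosis), mean(dc$excess_kurtosis))
  # long T: variances symmetric across dimensions
  dl <- error_distribution("conjunctive", 1000, 10, 400, seed = 11)
  expect_lt(abs(log(dl$var[["dim1"]] / dl$var[["dim2"]])), 0.5)
})

test_that("conditional errors: n_min = 0 recovers unconditional means", {
  ce <- conditional_error(300, 0.1, n_min_list = c(0, 2), repeats = 150,
                          seed = 12)
  un_p <- mean(simulate_errors("pure", 300, 0.1, 150, seed = 12,
                               keep_counts = TRUE)$scalar_error)
  expect_equal(ce$err_pure[1], un_p, tolerance = 1e-9)
  expect_equal(ce$retained_pure[1], 1)
  expect_lte(ce$retained_pure[2], ce$retained_pure[1])
  expect_lte(ce$retained_conj[2], ce$retained_conj[1])
  # conditioning on more spikes does not increase the mean error much
  expect_lt(ce$err_pure[2], ce$err_pure[1] + 5)
})

test_that("mixed populations: edge fractions match single-kind errors", {
  f0 <- mixed_error(c(0, 1), 200, 0.5, repeats = 120, seed = 13)
  ep <- mean(simulate_errors("pure", 200, 0.5, 120, seed = 21)$scalar_error)
  ec <- mean(simulate_errors("conjunctive", 200, 0.5, 120,
                             seed = 22)$scalar_error)
  se <- 6   # generous: independent seeds, 120 repeats
  expect_close(f0$err_mix[1], ec, se)
  expect_close(f0$err_mix[2], ep, se)
  # Eq.-25 algebra
  expect_equal(circular_error(0, 0)$scalar, 0)  # anchor trivial
  e <- 3.7
  expect_equal(e * e / sqrt(e^2 + e^2), e / sqrt(2))
})

test_that("error/FI collapse: equal N*T cells coincide; ratio > sqrt(2) at small FI", {
  nt <- rbind(c(400, 0.25), c(100, 1), c(25, 4),     # same N*T = 100
              c(400, 2.5), c(100, 10),               # same N*T = 1000
              c(100, 0.04), c(100, 0.1), c(100, 0.4))
  cl <- error_vs_fi(nt, repeats = 250, seed = 14)
  # collapse: equal-FI rows agree within 3 combined SE
  g1 <- cl[cl$fi == cl$fi[1], ]
  expect_lt(max(g1$mean_error) - min(g1$mean_error),
            3 * sqrt(sum(g1$se^2)))
  # CR saturation at large FI: mean |error| -> sqrt(2/pi) * CR bound
  big <- cl[cl$n == 100 & cl$t == 10, ]
  expect_lt(abs(big$mean_error - sqrt(2 / pi) * big$cr_bound) /
              big$cr_bound, 0.2)
  # predicted pure/conj ratio exceeds sqrt(2) at small FI
  small_fi <- sort(cl$fi)[2]
  expect_gt(fi_collapse_ratio(cl, small_fi), sqrt(2))
})
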