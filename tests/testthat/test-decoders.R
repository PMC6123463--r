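test_that("circular_error wraps, combines, and flags degenerates", {
  expect_equal(circular_error(1.5, 1.5)$scalar, 0)
  e <- circular_error(deg2rad(350), deg2rad(10))
  expect_equal(e$per_dimension, -20, tolerance = 1e-9)
  e2 <- circular_error(deg2rad(c(90, 90)), c(0, 0))
  expect_equal(e2$scalar, sqrt(2) * 90, tolerance = 1e-9)
  expect_close(e2$scalar, 127.28, 0.01)
  e3 <- circular_error(c(NA, 0), c(0, 0))
  expect_equal(e3$per_dimension[1], 180)
  expect_equal(e3$scalar, 180)
})

test_that("pure ML matches the dense brute-force oracle", {
  set.seed(1)
  for (rep in 1:20) {
    pop <- build_population(8, "pure", 1, 2.37, r_pure = 2)
    s <- stats::runif(1, 0, 2 * pi)
    cnt <- sample_independent(pop, s, 2, 1)[1, ]
    if (sum(cnt) == 0) next
    est <- ml_decode_pure(cnt, pop, 2)$estimate
    oracle <- brute_force_ml(cnt, pop, 2, step_deg = 0.1)
    expect_lt(abs(circ_diff(est, oracle)), deg2rad(0.2))
  }
})

test_that("conjunctive ML matches a brute-force grid on small trials", {
  set.seed(2)
  for (rep in 1:5) {
    pop <- build_population(6, "conjunctive", 2, 2.37, scheme = "explicit",
                            r_conj = 2)
    s <- stats::runif(2, 0, 2 * pi)
    cnt <- sample_independent(pop, s, 3, 1)[1, ]
    if (sum(cnt) == 0) next
    est <- ml_decode_conj(cnt, pop, 3)$estimate
    oracle <- brute_force_ml(cnt, pop, 3, step_deg = 1)
    # refinement can land closer to the continuous optimum than the
    # 1-degree oracle grid
    expect_lt(max(abs(circ_diff(est, oracle))), deg2rad(1.5))
  }
})

test_that("single-spike trials decode to the firing neuron's preference", {
  # one neuron, one spike: the one-term objective is maximal at the
  # preferred direction (for short T the coverage correction is small)
  pop <- build_population(1, "pure", 1, 9.11, seed = 3)
  est <- ml_decode_pure(1, pop, 0.1)$estimate
  expect_lt(abs(circ_diff(est, pop$pref[1, 1])), deg2rad(0.1))
  expect_lt(abs(circ_diff(brute_force_ml(1, pop, 0.1), pop$pref[1, 1])),
            deg2rad(0.2))
  # with several silent neighbors the optimum shifts only slightly
  pop5 <- build_population(5, "pure", 1, 9.11, seed = 3)
  cnt <- c(0, 0, 1, 0, 0)
  est5 <- ml_decode_pure(cnt, pop5, 0.1)$estimate
  expect_lt(abs(circ_diff(est5, brute_force_ml(cnt, pop5, 0.1))),
            deg2rad(0.2))
  pv <- pv_decode(cnt, pop5)
  expect_equal(pv$estimate, pop5$pref[3, 1], tolerance = 1e-9)
})

test_that("degenerate trials are flagged with error pi", {
  pop <- build_population(10, "pure", 2, 9.11, seed = 4)
  res <- ml_decode_pure(rep(0, 10), pop, 1)
  expect_true(all(res$degenerate))
  expect_equal(circular_error(res$estimate, c(0, 0))$per_dimension,
               c(180, 180))
  pc <- build_population(10, "conjunctive", 2, 9.11, seed = 5)
  resc <- ml_decode_conj(rep(0, 10), pc, 1)
  expect_true(all(resc$degenerate))
  respv <- pv_decode(rep(0, 10), pc)
  expect_true(all(respv$degenerate))
})

test_that("PV vector sum: two equal counts at 0 and 90 degrees give 45", {
  pop <- build_population(2, "pure", 1, 9.11, seed = 6)
  pop$pref[, 1] <- c(0, pi / 2)
  pv <- pv_decode(c(3, 3), pop)
  expect_equal(pv$estimate, pi / 4, tolerance = 1e-12)
})

test_that("PV converges to ML as N grows", {
  set.seed(7)
  meds <- vapply(c(50, 500, 5000), function(n) {
    pop <- build_population(n, "pure", 1, 9.11)
    diffs <- vapply(1:40, function(i) {
      s <- stats::runif(1, 0, 2 * pi)
      cnt <- sample_independent(pop, s, 0.5, 1)[1, ]
      if (sum(cnt) == 0) return(NA_real_)
      abs(circ_diff(ml_decode_pure(cnt, pop, 0.5)$estimate,
                    pv_decode(cnt, pop)$estimate))
    }, numeric(1))
    stats::median(diffs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("ML is invariant to joint rotation of stimulus and preferences", {
  set.seed(8)
  pop <- build_population(40, "conjunctive", 2, 2.37, seed = 8)
  s <- c(1, 2)
  cnt <- sample_independent(pop, s, 1, 1, seed = 9)[1, ]
  e1 <- circular_error(ml_decode_conj(cnt, pop, 1)$estimate, s)$scalar
  rot <- deg2rad(73)
  pop2 <- pop; pop2$pref <- wrap_angle(pop$pref + rot)
  e2 <- circular_error(ml_decode_conj(cnt, pop2, 1)$estimate,
                       s + rot)$scalar
  expect_equal(e1, e2, tolerance = 0.2)
})

test_that("symmetric two-neuron pattern decodes to the circular midpoint", {
  pop <- build_population(2, "conjunctive", 2, 2.37, scheme = "explicit",
                          r_conj = 1, seed = 10)
  pop$pref <- matrix(c(deg2rad(20), deg2rad(60), 1, 1), 2, 2)
  est <- ml_decode_conj(c(2, 2), pop, 0.5)$estimate
  expect_lt(abs(circ_diff(est[1], deg2rad(40))), deg2rad(0.5))
})

test_that("Gaussian-NC decoder reduces to ML at identity correlation", {
  set.seed(11)
  pop <- build_population(20, "conjunctive", 2, 2.37, seed = 11)
  s <- c(0.5, 4)
  cnt <- sample_independent(pop, s, 2, 1)[1, ]
  stI <- list(correlation = diag(20))
  a <- ml_decode_gaussian_nc(cnt, pop, 2, stI)
  b <- ml_decode_conj(cnt, pop, 2)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-9)
  expect_identical(a$decoder, "ml_gaussian_nc")
  # degenerate no-spike trial
  z <- ml_decode_gaussian_nc(rep(0, 20), pop, 2,
                             correlation_from_distance(pop))
  expect_true(all(z$degenerate))
})

test_that("correlation-aware decoding does not underperform naive ML", {
  # the Gaussian likelihood approximation is only faithful at high
  # counts, so the comparison is made in a high-rate regime
  set.seed(12)
  pop <- build_population(60, "pure", 2, 2.37, r_pure = 20, seed = 12)
  st <- correlation_from_distance(pop)
  trials <- 40
  e_naive <- e_nc <- numeric(trials)
  for (i in seq_len(trials)) {
    s <- stats::runif(2, 0, 2 * pi)
    cnt <- sample_correlated(pop, s, 5, 1, structure = st)[1, ]
    e_naive[i] <- circular_error(ml_decode_pure(cnt, pop, 5)$estimate,
                                 s)$scalar
    e_nc[i] <- circular_error(
      ml_decode_gaussian_nc(cnt, pop, 5, st, grid_deg = 10)$estimate,
      s)$scalar
  }
  # directional comparison (equality-level performance is acceptable)
  expect_lt(mean(e_nc), mean(e_naive) * 1.03)
})

test_that("decode_trials tabulates errors and degeneracy", {
  pop <- build_population(100, "conjunctive", 2, 9.11, seed = 13)
  s <- c(1, 5)
  cnt <- sample_independent(pop, s, 5, 8, seed = 14)
  df <- decode_trials(cnt, pop, 5, s, "ml")
  expect_equal(nrow(df), 8)
  expect_true(all(abs(df$error_1) <= 180))
  expect_true(all(df$scalar_error <= 180 * sqrt(2)))
  expect_equal(df$scalar_error,
               sqrt(df$error_1^2 + df$error_2^2), tolerance = 1e-9)
  expect_false(any(df$degenerate))
})
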