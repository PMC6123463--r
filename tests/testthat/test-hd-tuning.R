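# small synthetic session shared across tests in this file
make_session <- function(duration = 900, seed = 101,
                         cells = list(
                           cell_spec("untuned", peak_rate = 1.5),
                           cell_spec("pure_azimuth", pref_azimuth = 120,
                                     peak_rate = 1.5),
                           cell_spec("conjunctive", pref_azimuth = 240,
                                     pref_pitch = 20, peak_rate = 3.4))) {
  generate_session(behavior_spec(), cells, duration, seed = seed)
}

test_that("tuning curves conserve spikes and occupancy", {
  ses <- make_session(600)
  st <- ses$spikes[[2]]
  cv <- tuning_curve(st, ses$angles, ses$sampling_rate, "azimuth")
  # occupancy sums to the session duration
  expect_equal(sum(cv$occupancy), nrow(ses$angles) / ses$sampling_rate)
  # spikes within the session are all binned
  expect_equal(sum(cv$spikes),
               sum(st >= 0 & st < nrow(ses$angles) / ses$sampling_rate))
  # total spikes = sum rate * occupancy over unmasked bins (floor small)
  cv2 <- tuning_curve(st, ses$angles, ses$sampling_rate, "azimuth",
                      occupancy_floor = 0)
  expect_equal(sum(cv2$rate * cv2$occupancy), sum(cv2$spikes),
               tolerance = 1e-9)
})

test_that("tuning curves recover preferred directions; flat for untuned", {
  ses <- make_session(900)
  cv_t <- tuning_curve(ses$spikes[[2]], ses$angles, ses$sampling_rate,
                       "azimuth")
  pk <- cv_t$bin_center[which.max(cv_t$rate)]
  expect_lt(abs(circ_diff_deg(pk, 120)), 15)  # wide (90 deg) tuning: ~2 bins
  cv_u <- tuning_curve(ses$spikes[[1]], ses$angles, ses$sampling_rate,
                       "azimuth")
  ok <- !is.na(cv_u$rate)
  expect_lt(stats::sd(cv_u$rate[ok]) / mean(cv_u$rate[ok]), 0.5)
  expect_error(tuning_curve(ses$spikes[[1]], ses$angles,
                            ses$sampling_rate, "azimuth",
                            labels = rep("low", nrow(ses$angles)),
                            velocity_label = "absent"),
               "velocity bin")
})

test_that("rayleigh_vector: flat 0, point mass 1, von-Mises I1/I0", {
  flat <- structure(list(bin_center = seq(3, 357, by = 6),
                         rate = rep(2, 60)), class = "tuning_curve")
  expect_equal(rayleigh_vector(flat), 0, tolerance = 1e-12)
  point <- structure(list(bin_center = seq(3, 357, by = 6),
                          rate = c(5, rep(0, 59))), class = "tuning_curve")
  expect_equal(rayleigh_vector(point), 1)
  kap <- 9.11
  th <- seq(3, 357, by = 6)
  vm <- structure(list(bin_center = th,
                       rate = exp(kap * (cos(deg2rad(th - 70)) - 1))),
                  class = "tuning_curve")
  expect_close(rayleigh_vector(vm), besselI(kap, 1) / besselI(kap, 0),
               0.01)
})

test_that("tuning_width measures half-height width on the circle", {
  th <- seq(1.5, 358.5, by = 3)
  vm <- structure(list(bin_center = th,
                       rate = exp(9.11 * (cos(deg2rad(th - 200)) - 1))),
                  class = "tuning_curve")
  expect_close(tuning_width(vm), 45, 3.5)
  # two-level step curve: width of the high level
  step <- structure(list(bin_center = th,
                         rate = rep(c(4, 1), c(20, 100))),
                    class = "tuning_curve")
  expect_equal(tuning_width(step), 60)   # 20 bins x 3 deg
  flat <- structure(list(bin_center = th, rate = rep(2, 120)),
                    class = "tuning_curve")
  expect_true(is.na(tuning_width(flat)))
  # width estimated from generated spikes: a high-rate 45-deg cell
  ses <- generate_session(behavior_spec(),
                          list(cell_spec("pure_azimuth",
                                         pref_azimuth = 120,
                                         kappa = kappa_from_width(45),
                                         peak_rate = 4)),
                          1200, seed = 31)
  cv <- tuning_curve(ses$spikes[[1]], ses$angles, ses$sampling_rate,
                     "azimuth")
  expect_close(tuning_width(cv), 45, 14)
})

test_that("shuffle test: tuned significant, untuned calibrated", {
  ses <- make_session(900)
  sh_t <- shuffle_significance(ses$spikes[[2]], ses$angles,
                               ses$sampling_rate, "azimuth",
                               n_shuffles = 300, seed = 1)
  expect_true(sh_t$significant)
  sh_u <- shuffle_significance(ses$spikes[[1]], ses$angles,
                               ses$sampling_rate, "azimuth",
                               n_shuffles = 300, seed = 2)
  expect_false(sh_u$significant)
  # pitch statistic on a conjunctive cell (longer session: pitch power
  # is occupancy-limited under the clipped crawling pitch range)
  ses_c <- generate_session(
    behavior_spec(),
    list(cell_spec("conjunctive", pref_azimuth = 200, pref_pitch = -15,
                   peak_rate = 3.4)), 3000, seed = 2)
  sh_p <- shuffle_significance(ses_c$spikes[[1]], ses_c$angles,
                               ses_c$sampling_rate, "pitch",
                               n_shuffles = 300, seed = 3)
  expect_true(sh_p$significant)
  expect_warning(
    shuffle_significance(ses$spikes[[1]], ses$angles, ses$sampling_rate,
                         "azimuth", n_shuffles = 50, seed = 4),
    "100 shuffles")
})

test_that("classification recovers scripted labels and transitions", {
  # a session shaped like the recorded data: pure and untuned cells
  # throughout, plus velocity-gated cells that gain pitch tuning (turn
  # conjunctive) only during fast head turns
  set.seed(1)
  cells <- c(
    lapply(1:5, function(i) cell_spec("untuned", peak_rate = 1)),
    lapply(1:5, function(i)
      cell_spec("pure_azimuth", pref_azimuth = stats::runif(1, 0, 360),
                peak_rate = 1.5)),
    lapply(1:5, function(i)
      cell_spec("pure_pitch", pref_pitch = stats::runif(1, -40, 40),
                peak_rate = 1.5)),
    lapply(1:5, function(i)
      cell_spec("pure_azimuth", "conjunctive",
                pref_azimuth = stats::runif(1, 0, 360),
                pref_pitch = stats::runif(1, -40, 40), peak_rate = 3.4)))
  ses <- generate_session(behavior_spec(), cells, 3000, seed = 2)
  cls <- classify_cells(ses, n_shuffles = 300, seed = 3)
  expect_equal(nrow(cls), 2 * length(cells))
  inc <- cls[cls$included, ]
  truth <- ses$truth
  key <- ifelse(inc$velocity_bin == "low",
                truth$label_low[inc$cell], truth$label_high[inc$cell])
  acc <- mean(inc$label == key)
  expect_gte(acc, 0.9)
  # most gated cells transition pure_azimuth -> conjunctive
  tr <- transition_analysis(cls)
  expect_equal(sum(tr$counts), sum(cls$included) / 2)
  expect_gte(tr$counts["pure_azimuth", "conjunctive"], 3)
  cs <- colSums(tr$percent_given_high)
  expect_true(all(abs(cs[colSums(tr$counts) > 0] - 100) < 1e-9))
  # determinism
  cls2 <- classify_cells(ses, n_shuffles = 300, seed = 3)
  expect_identical(cls, cls2)
})

test_that("inclusion criteria: spike and time minimums exclude cells", {
  ses <- make_session(900)
  # a nearly silent cell fails the 50-spike criterion
  ses$spikes[[4]] <- sort(stats::runif(20, 0, 900))
  ses$truth <- rbind(ses$truth, ses$truth[1, ])
  cls <- classify_cells(ses, n_shuffles = 100, seed = 6)
  c4 <- cls[cls$cell == 4, ]
  expect_true(all(!c4$included))
  expect_true(all(c4$reason == "min_spikes"))
  expect_true(all(c4$label == "excluded"))
})

test_that("stability: tuned cells stable, noise cells not gated in", {
  ses <- make_session(900)
  lab <- ses$velocity_labels
  r_tuned <- tuning_stability(ses$spikes[[2]], ses$angles,
                              ses$sampling_rate, "azimuth")
  expect_gt(r_tuned, 0.25)
})
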