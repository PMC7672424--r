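test_that("population_from_binding follows the 1:1 shift law", {
  bp <- binding_params(kd = 0.53, f0 = 0.62, f_inf = 1.0)
  expect_equal(population_from_binding(bp, 0), 0.62)
  # at L = Kd the fraction sits at the midpoint (f0 + f_inf)/2
  expect_equal(population_from_binding(bp, 0.53), 0.81)
  expect_equal(population_from_binding(bp, 1e6), 1.0, tolerance = 1e-5)
  expect_error(population_from_binding(bp, -1), class = "gqfret_domain_error")
})

test_that("population_from_binding is monotone in conc and kd", {
  bp <- binding_params(kd = 0.5, f0 = 0.3, f_inf = 0.9)
  concs <- c(0, 0.1, 0.5, 1, 5, 20)
  f <- population_from_binding(bp, concs)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0.3 & f <= 0.9))
  # at fixed conc > 0, larger kd means weaker binding, lower fraction
  f_kd <- vapply(c(0.1, 0.5, 2, 10), function(kd)
    population_from_binding(binding_params(kd, 0.3, 0.9), 1), numeric(1))
  expect_true(all(diff(f_kd) < 0))
})

test_that("depletion-corrected variant converges to hyperbolic at trace DNA", {
  bp <- binding_params(kd = 0.53, f0 = 0.62, f_inf = 1.0)
  concs <- c(0.1, 0.5, 2)
  expect_equal(population_from_binding(bp, concs, dna_conc = 1e-6),
               population_from_binding(bp, concs), tolerance = 1e-5)
  # with appreciable DNA, free ligand is depleted and the fraction is lower
  expect_true(all(population_from_binding(bp, concs, dna_conc = 0.5) <
                  population_from_binding(bp, concs)))
})

test_that("binding and simulation configs validate their invariants", {
  expect_error(binding_params(kd = -1, f0 = 0.2, f_inf = 0.8),
               class = "gqfret_domain_error")
  expect_error(binding_params(kd = 1, f0 = 0.9, f_inf = 0.8),
               class = "gqfret_domain_error")
  expect_error(sim_config(states = data.frame(true_E = c(0.5, 0.8),
                                              weight = c(0.6, 0.6))),
               class = "gqfret_config_error")
  expect_error(sim_config(states = data.frame(true_E = c(-0.1, 0.8),
                                              weight = c(0.5, 0.5))),
               class = "gqfret_config_error")
})

test_that("degenerate simulations produce the forced streams", {
  empty <- simulate_photon_stream(sim_config(duration = 1, burst_rate = 0,
                                             bg_rate_dd = 0, bg_rate_da = 0,
                                             bg_rate_aa = 0))
  expect_equal(nrow(empty), 0L)
  zero_dur <- simulate_photon_stream(sim_config(duration = 0))
  expect_equal(nrow(zero_dur), 0L)
  # true_E = 1, no background, no acceptor-excitation window: every
  # donor-window photon must land in the acceptor channel
  st <- simulate_photon_stream(sim_config(
    duration = 5, burst_rate = 20, bg_rate_dd = 0, bg_rate_da = 0,
    bg_rate_aa = 0, aa_fraction = 0,
    states = data.frame(true_E = 1, weight = 1), seed = 3))
  expect_gt(nrow(st), 0)
  expect_true(all(st$channel == "acceptor"))
  expect_true(all(st$excitation == "donor_window"))
})

test_that("background-only stream is Poisson in its channel counts", {
  st <- simulate_photon_stream(sim_config(duration = 10, burst_rate = 0,
                                          bg_rate_dd = 1000, bg_rate_da = 0,
                                          bg_rate_aa = 0, seed = 7))
  n <- sum(st$channel == "donor")
  # exact two-sided Poisson tail test at alpha = 0.01, lambda = 10000
  expect_gt(n, qpois(0.005, 10000))
  expect_lt(n, qpois(0.995, 10000))
  expect_true(all(st$timestamp_s >= 0 & st$timestamp_s <= 10))
  expect_false(is.unsorted(st$timestamp_s))
})

test_that("burst state frequencies and photon partitions match configuration", {
  cfg <- sim_config(duration = 60, burst_rate = 40, bg_rate_dd = 0,
                    bg_rate_da = 0, bg_rate_aa = 0, aa_fraction = 0.25,
                    states = data.frame(true_E = c(0.2, 0.8),
                                        weight = c(0.3, 0.7)), seed = 5)
  st <- simulate_photon_stream(cfg)
  truth <- attr(st, "bursts_truth")
  n <- nrow(truth)
  p_hat <- mean(truth$state == 2)
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  # donor-window acceptor fraction of high-E bursts approximates true_E
  aa <- st$excitation == "acceptor_window"
  expect_lt(abs(mean(aa) - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(st)))
  dw <- st[!aa, ]
  # all photons pooled across bursts: acceptor fraction is the weight-mean E
  e_pool <- mean(dw$channel == "acceptor")
  expect_lt(abs(e_pool - (0.3 * 0.2 + 0.7 * 0.8)), 0.05)
})

test_that("streams are reproducible under seed and differ across seeds", {
  cfg <- sim_config(duration = 5, seed = 11)
  s1 <- simulate_photon_stream(cfg)
  s2 <- simulate_photon_stream(cfg)
  expect_identical(s1$timestamp_s, s2$timestamp_s)
  expect_identical(s1$channel, s2$channel)
  cfg2 <- sim_config(duration = 5, seed = 12)
  s3 <- simulate_photon_stream(cfg2)
  expect_false(identical(s1$timestamp_s, s3$timestamp_s))
})

test_that("titration streams follow the binding-adjusted state weights", {
  cfg <- sim_config(duration = 40, burst_rate = 50, bg_rate_dd = 0,
                    bg_rate_da = 0, bg_rate_aa = 0,
                    states = data.frame(true_E = c(0.3, 0.8),
                                        weight = c(0.6, 0.4)), seed = 9)
  bp <- binding_params(kd = 1, f0 = 0.4, f_inf = 1.0)
  tit <- simulate_titration(cfg, bp, concs = c(0, 1e6))
  for (i in 1:2) {
    truth <- attr(tit[[i]]$stream, "bursts_truth")
    f_hat <- mean(truth$state == 2)
    f_true <- population_from_binding(bp, tit[[i]]$conc)
    expect_lt(abs(f_hat - f_true),
              3 * sqrt(max(f_true * (1 - f_true), 1e-4) / nrow(truth)) + 1e-9)
  }
  expect_error(simulate_titration(cfg, bp, numeric(0)),
               class = "gqfret_argument_error")
  # same master seed -> identical series
  tit2 <- simulate_titration(cfg, bp, concs = c(0, 1e6))
  expect_identical(tit[[1]]$stream$timestamp_s, tit2[[1]]$stream$timestamp_s)
})

test_that("simulated melting curves match the sigmoid law", {
  cv <- simulate_melting_curve(tm = 60, width = 3, baselines = c(2, 10),
                               noise_sd = 0)
  # midpoint and asymptotes
  expect_equal(cv$signal[cv$temperature_C == 60], 6)
  expect_lt(abs(cv$signal[1] - 2), 1e-5)
  expect_lt(abs(cv$signal[nrow(cv)] - 10), 0.01)
  # dense-grid bisection oracle for the half-transition point
  dense <- simulate_melting_curve(60, 3, c(0, 1), temps = seq(4, 95, 0.001),
                                  noise_sd = 0)
  half <- dense$temperature_C[which.min(abs(dense$signal - 0.5))]
  expect_equal(half, 60, tolerance = 0.01)
  expect_error(simulate_melting_curve(60, width = 0),
               class = "gqfret_domain_error")
})
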