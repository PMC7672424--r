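make_bursts <- function(n_dd, n_da, n_aa, duration_s = 1e-3) {
  df <- data.frame(burst_id = seq_along(n_dd), start_s = 0, stop_s = duration_s,
                   n_dd = n_dd, n_da = n_da, n_aa = n_aa,
                   duration_s = duration_s, i_first = 1L, i_last_excl = 2L)
  class(df) <- c("burst_table", "data.frame")
  df
}

test_that("proximity ratio is the acceptor fraction of donor-window counts", {
  expect_equal(proximity_ratio(50, 50), 0.5)
  expect_equal(proximity_ratio(100, 0), 0)
  expect_equal(proximity_ratio(0, 100), 1)
  expect_error(proximity_ratio(0, 0), class = "gqfret_ratio_error")
})

test_that("corrected_E reduces to the proximity ratio at default corrections", {
  set.seed(3)
  b <- make_bursts(n_dd = rpois(50, 40) + 1, n_da = rpois(50, 30) + 1,
                   n_aa = rpois(50, 20))
  e <- corrected_E(b, correction_factors())
  expect_equal(e, proximity_ratio(b$n_dd, b$n_da), ignore_attr = TRUE)
})

test_that("leakage, direct-excitation and background corrections follow the algebra", {
  # alpha = 0.1: F_A = 60 - 0.1*100 = 50, E = 50/150
  b <- make_bursts(100, 60, 0)
  e <- corrected_E(b, correction_factors(leakage_alpha = 0.1))
  expect_equal(as.numeric(e), 1 / 3)
  # direct excitation subtracts delta * n_aa from the acceptor signal
  b2 <- make_bursts(100, 60, 50)
  e2 <- corrected_E(b2, correction_factors(direct_delta = 0.2))
  expect_equal(as.numeric(e2), 50 / 150)
  # background: rates * duration removed per channel
  b3 <- make_bursts(110, 70, 0, duration_s = 1)
  e3 <- corrected_E(b3, correction_factors(bg_rate_dd = 10, bg_rate_da = 10))
  expect_equal(as.numeric(e3), 60 / 160)
  # background-dominated burst is flagged and excluded as NA
  b4 <- make_bursts(5, 5, 0, duration_s = 1)
  expect_message(e4 <- corrected_E(b4, correction_factors(bg_rate_dd = 10,
                                                          bg_rate_da = 10)),
                 "excluded")
  expect_true(is.na(e4[1]))
  expect_equal(attr(e4, "excluded"), 1L)
})

test_that("gamma monotonically decreases E when donor signal is present", {
  b <- make_bursts(80, 40, 10)
  es <- vapply(c(0.5, 0.8, 1, 1.5, 2), function(g)
    as.numeric(corrected_E(b, correction_factors(gamma = g))), numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("stoichiometry separates donor-only, acceptor-only and dual species", {
  expect_equal(as.numeric(stoichiometry(make_bursts(50, 30, 0))), 1)
  expect_equal(as.numeric(stoichiometry(make_bursts(0, 0, 40))), 0)
  expect_equal(as.numeric(stoichiometry(make_bursts(40, 40, 80))), 0.5)
})

test_that("the stoichiometry gate keeps exactly the in-range bursts", {
  set.seed(8)
  n <- 200
  b <- make_bursts(rpois(n, 40), rpois(n, 30), rpois(n, 35))
  corr <- correction_factors()
  kept <- filter_dual_label(b, corr, s_min = 0.3, s_max = 0.8)
  s <- stoichiometry(b, corr)
  want <- which(!is.na(s) & s >= 0.3 & s <= 0.8)
  expect_equal(kept$burst_id, b$burst_id[want])
  # identity gate retains every burst with defined S
  all_kept <- filter_dual_label(b, corr, s_min = 0, s_max = 1)
  expect_equal(nrow(all_kept), sum(!is.na(s)))
  # donor-only bursts sit at S = 1 and are rejected by a (0.3, 0.8) gate
  donly <- make_bursts(rep(50, 5), rep(20, 5), rep(0, 5))
  expect_equal(nrow(filter_dual_label(donly, corr, 0.3, 0.8)), 0L)
  expect_error(filter_dual_label(b, corr, 0.9, 0.2),
               class = "gqfret_domain_error")
})

test_that("histograms conserve counts and report overflow", {
  h <- build_histogram(c(0.5, 0.5, 0.9), edges = seq(0, 1, 0.1))
  expect_equal(sum(h$count), 3L)
  expect_equal(h$count[h$bin_left == 0.5], 2L)
  expect_equal(h$count[h$bin_left == 0.9], 1L)
  h2 <- build_histogram(rep(0.42, 10), edges = seq(0, 1, 0.1))
  expect_equal(sum(h2$count > 0), 1L)
  h3 <- build_histogram(c(-0.5, 0.5, 1.7), edges = seq(0, 1, 0.1))
  expect_equal(attr(h3, "n_underflow"), 1L)
  expect_equal(attr(h3, "n_overflow"), 1L)
  expect_equal(sum(h3$count), 1L)
  expect_warning(build_histogram(numeric(0)), "empty")
  expect_error(build_histogram(0.5, edges = c(0, 0, 1)),
               class = "gqfret_domain_error")
})

test_that("uniform draws fill the histogram flatly (chi-square, alpha 0.01)", {
  set.seed(12)
  h <- build_histogram(runif(1000), edges = seq(0, 1, 0.1))
  chi2 <- sum((h$count - 100)^2 / 100)
  expect_lt(chi2, qchisq(0.99, df = 9))
})

test_that("mean corrected E over simulated single-state bursts matches true_E", {
  cfg <- sim_config(duration = 60, burst_rate = 25, burst_size_mean = 80,
                    bg_rate_dd = 0, bg_rate_da = 0, bg_rate_aa = 0,
                    states = data.frame(true_E = 0.7, weight = 1), seed = 31)
  st <- simulate_photon_stream(cfg)
  b <- search_bursts(st, burst_search_params())
  e <- corrected_E(b, correction_factors())
  expect_gt(length(e), 1000)
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - 0.7), 3 * se)
})

test_that("excitation windows can be assigned from timestamps at 32 MHz", {
  period <- 1 / 32e6
  t <- c(0.1, 0.4, 0.6, 0.9) * period
  expect_equal(assign_excitation_window(t),
               c("donor_window", "donor_window",
                 "acceptor_window", "acceptor_window"))
})
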