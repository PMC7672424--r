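test_that("bin_photons uses half-open 1 ms bins covering the acquisition", {
  st <- toy_stream(c(0.1, 0.4, 0.7) * 1e-3, duration = 1e-3)
  expect_equal(bin_photons(st, 1e-3), 3L)
  empty <- photon_stream(numeric(0), character(0), character(0),
                         duration = 3e-3)
  expect_equal(bin_photons(empty, 1e-3), c(0L, 0L, 0L))
  # photon exactly on a boundary goes to the later bin
  st2 <- toy_stream(c(0.5e-3, 1.0e-3), duration = 2e-3)
  expect_equal(bin_photons(st2, 1e-3), c(1L, 1L))
  # counts are conserved for arbitrary streams
  set.seed(1)
  st3 <- toy_stream(sort(runif(500, 0, 0.05)), duration = 0.05)
  expect_equal(sum(bin_photons(st3, 1e-3)), 500L)
})

test_that("search_bursts applies threshold and minimum-photon rules", {
  p <- burst_search_params(threshold = 5, min_photons = 25)
  # 30 photons in one bin -> one burst of 30
  st <- toy_stream(seq(0.1e-3, 0.9e-3, length.out = 30), duration = 5e-3)
  b <- search_bursts(st, p)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_dd + b$n_da + b$n_aa, 30L)
  # 10 photons clear the bin threshold but not the 25-photon minimum
  st2 <- toy_stream(seq(0.1e-3, 0.9e-3, length.out = 10), duration = 5e-3)
  expect_equal(nrow(search_bursts(st2, p)), 0L)
  # two adjacent bins of 15 photons merge into one 30-photon burst
  st3 <- toy_stream(c(seq(0.05e-3, 0.95e-3, length.out = 15),
                      seq(1.05e-3, 1.95e-3, length.out = 15)),
                    duration = 5e-3)
  b3 <- search_bursts(st3, p)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$n_dd + b3$n_da + b3$n_aa, 30L)
})

test_that("per-channel burst counts reflect channel and excitation labels", {
  times <- seq(0.1e-3, 0.9e-3, length.out = 30)
  ch <- rep(c("donor", "acceptor", "acceptor"), 10)
  ex <- rep(c("donor_window", "donor_window", "acceptor_window"), 10)
  st <- photon_stream(times, ch, ex, duration = 2e-3)
  b <- search_bursts(st, burst_search_params())
  expect_equal(b$n_dd, 10L)
  expect_equal(b$n_da, 10L)
  expect_equal(b$n_aa, 10L)
})

test_that("burst search matches the brute-force enumerator on random streams", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(0:200, 1)
    dur <- runif(1, 5e-3, 30e-3)
    times <- sort(runif(n, 0, dur))
    # cluster some photons to create genuine bursts
    if (n > 30) {
      ctr <- runif(1, 0, dur)
      times <- sort(c(times[-(1:30)], ctr + runif(30, 0, 1.5e-3)))
      times <- pmin(times, dur)
    }
    st <- toy_stream(times, duration = dur)
    for (thr in c(4L, 9L)) {
      p <- burst_search_params(threshold = thr, min_photons = 25)
      got <- search_bursts(st, p)
      want <- brute_force_bursts(st, p)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        expect_equal(got$n_dd, want$n_dd)
        expect_equal(got$n_da, want$n_da)
        expect_equal(got$n_aa, want$n_aa)
        expect_equal(got$i_first, want$i_first)
        expect_equal(got$i_last_excl, want$i_last_excl)
      }
    }
  }
})

test_that("raising threshold or min_photons never adds bursts", {
  set.seed(7)
  cfg <- sim_config(duration = 10, burst_rate = 20, seed = 77)
  st <- simulate_photon_stream(cfg)
  n_by_thr <- vapply(4:9, function(thr)
    nrow(search_bursts(st, burst_search_params(threshold = thr))), integer(1))
  expect_true(all(diff(n_by_thr) <= 0))
  n_by_min <- vapply(c(25, 40, 60, 100), function(mp)
    nrow(search_bursts(st, burst_search_params(min_photons = mp))), integer(1))
  expect_true(all(diff(n_by_min) <= 0))
})

test_that("bursts are time-ordered, non-overlapping, above the minimum", {
  cfg <- sim_config(duration = 20, burst_rate = 30, seed = 13)
  st <- simulate_photon_stream(cfg)
  b <- search_bursts(st, burst_search_params())
  expect_gt(nrow(b), 5)
  expect_true(all(b$n_dd + b$n_da + b$n_aa >= 25))
  expect_true(all(diff(b$start_s) > 0))
  expect_true(all(b$i_first < b$i_last_excl))
  expect_true(all(utils::head(b$i_last_excl, -1) <= utils::tail(b$i_first, -1)))
})

test_that("burst_rate is count over duration and detects the simulated rate", {
  expect_equal(burst_rate(data.frame()[0, ], 10), 0)
  expect_equal(burst_rate(data.frame(x = 1:20), 10), 2)
  expect_error(burst_rate(data.frame(), 0), class = "gqfret_domain_error")
  # generous thresholds so nearly every simulated transit is recovered:
  # geometric burst sizes make small bursts common, so the detected rate
  # only approaches the arrival rate when the photon cuts are loose
  cfg <- sim_config(duration = 100, burst_rate = 5, burst_size_mean = 300,
                    bg_rate_dd = 5, bg_rate_da = 5, bg_rate_aa = 5,
                    seed = 21)
  st <- simulate_photon_stream(cfg)
  b <- suppressWarnings(
    search_bursts(st, burst_search_params(threshold = 2, min_photons = 3)))
  r <- burst_rate(b, 100)
  expect_lt(abs(r - 5), 3 * sqrt(500) / 100)
})

test_that("threshold outside the customary range warns but works", {
  expect_warning(p <- burst_search_params(threshold = 10),
                 "outside the customary")
  expect_equal(p$threshold, 10L)
})
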