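# Shared fixtures built in code at test time.

# A small stream with photons at known times; channel/excitation cycled.
toy_stream <- function(times, channel = NULL, excitation = NULL,
                       duration = NULL) {
  n <- length(times)
  if (is.null(channel))
    channel <- rep(c("donor", "acceptor"), length.out = n)
  if (is.null(excitation)) excitation <- rep("donor_window", n)
  if (is.null(duration)) duration <- if (n) max(times) + 1e-3 else 1e-3
  photon_stream(sort(times), channel[order(times)],
                excitation[order(times)], duration = duration)
}

# Brute-force burst search: enumerate every bin and run explicitly.
# Independent of search_bursts' vectorized path.
brute_force_bursts <- function(stream, params) {
  w <- params$bin_width
  duration <- attr(stream, "duration")
  n_bins <- max(1L, as.integer(ceiling(duration / w - 1e-9)))
  bin_of <- function(t) min(floor(t / w), n_bins - 1L)
  counts <- integer(n_bins)
  for (t in stream$timestamp_s)
    counts[bin_of(t) + 1L] <- counts[bin_of(t) + 1L] + 1L
  above <- counts >= params$threshold
  bursts <- list()
  b <- 0L
  in_run <- FALSE
  run_bins <- integer(0)
  flush <- function(run_bins) {
    ph <- which(vapply(stream$timestamp_s,
                       function(t) (bin_of(t) + 1L) %in% run_bins,
                       logical(1)))
    if (length(ph) < params$min_photons) return(NULL)
    ch <- stream$channel[ph]; ex <- stream$excitation[ph]
    data.frame(n_dd = sum(ch == "donor" & ex == "donor_window"),
               n_da = sum(ch == "acceptor" & ex == "donor_window"),
               n_aa = sum(ch == "acceptor" & ex == "acceptor_window"),
               i_first = ph[1], i_last_excl = ph[length(ph)] + 1L)
  }
  for (i in seq_len(n_bins)) {
    if (above[i]) {
      run_bins <- c(run_bins, i); in_run <- TRUE
    } else if (in_run) {
      r <- flush(run_bins)
      if (!is.null(r)) bursts[[length(bursts) + 1L]] <- r
      run_bins <- integer(0); in_run <- FALSE
    }
  }
  if (in_run) {
    r <- flush(run_bins)
    if (!is.null(r)) bursts[[length(bursts) + 1L]] <- r
  }
  if (!length(bursts))
    return(data.frame(n_dd = integer(0), n_da = integer(0), n_aa = integer(0),
                      i_first = integer(0), i_last_excl = integer(0)))
  do.call(rbind, bursts)
}

# Draw n values from the two-species apo ensemble (means/weights of the
# resolved dimeric G4 conformers), component SD 0.05.
apo_ensemble_sample <- function(n = 5000, seed = 42) {
  set.seed(seed)
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.38, 0.62))
  stats::rnorm(n, mean = c(0.6, 0.8)[comp], sd = 0.05)
}
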