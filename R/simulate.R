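#' Simulation configuration for synthetic PIE photon streams
#'
#' Bundles the parameters of the confocal-diffusion emulator: burst arrival
#' rate, burst size law, per-channel background rates, the conformational-state
#' mixture (true FRET efficiency and weight per state), and the fraction of
#' burst photons falling in the acceptor-excitation (PIE) window.
#'
#' Bursts arrive as a Poisson process; each burst's photon count is geometric
#' with the given mean (heavy-tailed, like diffusing-molecule transits) and its
#' photons are spread uniformly over an exponential-duration window (mean
#' 1 ms, matching the burst-search bin width). Donor-excitation-window photons
#' are partitioned donor/acceptor binomially with acceptor probability equal
#' to the molecule's true FRET efficiency.
#'
#' @param duration acquisition length, seconds.
#' @param burst_rate molecule transits per second.
#' @param burst_size_mean mean photons per burst (geometric law, minimum 1).
#' @param bg_rate_dd,bg_rate_da,bg_rate_aa background rates (photons/s) in the
#'   donor-excitation/donor-channel, donor-excitation/acceptor-channel and
#'   acceptor-excitation/acceptor-channel streams.
#' @param states data.frame or list with columns/fields \code{true_E} (in
#'   \eqn{[0,1]}) and \code{weight} (summing to 1): the conformational mixture.
#' @param aa_fraction fraction of a burst's photons emitted in the
#'   acceptor-excitation window (stoichiometry signal).
#' @param seed master RNG seed.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(duration = 30, burst_rate = 20, burst_size_mean = 60,
                       bg_rate_dd = 200, bg_rate_da = 200, bg_rate_aa = 200,
                       states = data.frame(true_E = c(0.6, 0.8),
                                           weight = c(0.38, 0.62)),
                       aa_fraction = 0.25, seed = 1L) {
  assert_scalar_num(duration, "duration", lower = 0)
  assert_scalar_num(burst_rate, "burst_rate", lower = 0)
  assert_scalar_num(burst_size_mean, "burst_size_mean", lower = 1)
  assert_scalar_num(bg_rate_dd, "bg_rate_dd", lower = 0)
  assert_scalar_num(bg_rate_da, "bg_rate_da", lower = 0)
  assert_scalar_num(bg_rate_aa, "bg_rate_aa", lower = 0)
  assert_scalar_num(aa_fraction, "aa_fraction", lower = 0, upper = 1)
  states <- as.data.frame(states)
  if (!all(c("true_E", "weight") %in% names(states)))
    stop_domain("'states' needs columns true_E and weight", "gqfret_config_error")
  if (any(states$true_E < 0 | states$true_E > 1))
    stop_domain("state true_E values must lie in [0, 1]", "gqfret_config_error")
  if (any(states$weight < 0) || abs(sum(states$weight) - 1) > 1e-9)
    stop_domain("state weights must be non-negative and sum to 1 (tol 1e-9)",
                "gqfret_config_error")
  structure(list(duration = duration, burst_rate = burst_rate,
                 burst_size_mean = burst_size_mean,
                 bg_rate_dd = bg_rate_dd, bg_rate_da = bg_rate_da,
                 bg_rate_aa = bg_rate_aa, states = states,
                 aa_fraction = aa_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Parameters of the 1:1 conformational-selection binding model
#'
#' @param kd dissociation constant, micromolar; must be positive.
#' @param f0 high-FRET population fraction at zero ligand.
#' @param f_inf high-FRET fraction at ligand saturation.
#' @return An object of class \code{binding_params}.
#' @export
binding_params <- function(kd, f0, f_inf) {
  assert_scalar_num(kd, "kd", lower = 0, strict_lower = TRUE)
  assert_scalar_num(f0, "f0", lower = 0, upper = 1)
  assert_scalar_num(f_inf, "f_inf", lower = 0, upper = 1)
  if (f0 > f_inf)
    stop_domain("f0 must not exceed f_inf", "gqfret_domain_error")
  structure(list(kd = kd, f0 = f0, f_inf = f_inf), class = "binding_params")
}

#' High-FRET population fraction at a given ligand concentration
#'
#' The 1:1 population-shift law \eqn{f(L) = f_0 + (f_\infty - f_0) L/(K_D + L)}
#' (hyperbolic in total ligand; the DNA is at ~100 pM, far below ligand, so
#' depletion is negligible). A depletion-corrected quadratic form is available
#' via \code{dna_conc}.
#'
#' @param params a \code{\link{binding_params}} object.
#' @param conc ligand concentration(s), micromolar, non-negative.
#' @param dna_conc optional total DNA concentration (micromolar); when given,
#'   the free-ligand concentration is obtained from the quadratic 1:1 depletion
#'   solution before applying the shift law.
#' @return Fraction(s) in \eqn{[f_0, f_\infty]}.
#' @export
population_from_binding <- function(params, conc, dna_conc = NULL) {
  stopifnot(inherits(params, "binding_params"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_domain("ligand concentrations must be finite and non-negative",
                "gqfret_domain_error")
  L <- conc
  if (!is.null(dna_conc)) {
    assert_scalar_num(dna_conc, "dna_conc", lower = 0)
    # free ligand from [L]free^2 + (Kd + R - L)[L]free - Kd L = 0
    b <- params$kd + dna_conc - conc
    L <- (-b + sqrt(b^2 + 4 * params$kd * conc)) / 2
  }
  params$f0 + (params$f_inf - params$f0) * L / (params$kd + L)
}

#' Simulate a PIE confocal photon stream
#'
#' Generates timestamped photon events from diffusing-molecule bursts over a
#' Poisson background, following \code{\link{sim_config}}. Each burst draws a
#' conformational state from the (possibly ligand-adjusted) weights; its
#' donor-window photons split donor/acceptor binomially with acceptor
#' probability equal to that state's true FRET efficiency, and a binomial
#' \code{aa_fraction} of its photons fall in the acceptor-excitation window.
#'
#' For a two-state configuration, supplying \code{conc} and \code{binding}
#' replaces the weight of the higher-E state with
#' \code{\link{population_from_binding}} at that concentration.
#'
#' @param config a \code{\link{sim_config}}.
#' @param conc optional ligand concentration (micromolar).
#' @param binding optional \code{\link{binding_params}}; required with
#'   \code{conc}.
#' @return A \code{photon_stream}: data.frame with columns \code{timestamp_s}
#'   (non-decreasing), \code{channel} (\code{"donor"}/\code{"acceptor"}),
#'   \code{excitation} (\code{"donor_window"}/\code{"acceptor_window"});
#'   attributes \code{duration}, \code{sync_rate_hz} (32 MHz) and a
#'   \code{bursts_truth} data.frame (burst start, state index, size) for
#'   simulator-level oracles.
#' @export
simulate_photon_stream <- function(config, conc = NULL, binding = NULL) {
  stopifnot(inherits(config, "sim_config"))
  states <- config$states
  if (!is.null(conc)) {
    if (is.null(binding))
      stop_domain("'binding' must be supplied with 'conc'", "gqfret_config_error")
    f <- population_from_binding(binding, conc)
    hi <- which.max(states$true_E)
    w <- rep((1 - f) / max(1L, nrow(states) - 1L), nrow(states))
    w[hi] <- f
    states$weight <- w
  }
  with_seed(config$seed, {
    n_bursts <- stats::rpois(1L, config$burst_rate * config$duration)
    if (n_bursts > 0) {
      t0 <- sort(stats::runif(n_bursts, 0, config$duration))
      state <- sample.int(nrow(states), n_bursts, replace = TRUE,
                          prob = states$weight)
      size <- 1L + stats::rgeom(n_bursts,
                                prob = 1 / config$burst_size_mean)
      bdur <- stats::rexp(n_bursts, rate = 1000)  # mean 1 ms transit
      ts <- rep(t0, size) +
        stats::runif(sum(size), 0, rep(bdur, size))
      trueE <- rep(states$true_E[state], size)
      in_aa <- stats::runif(sum(size)) < config$aa_fraction
      is_acc <- in_aa | (stats::runif(sum(size)) < trueE)
      b_ts <- ts
      b_ch <- ifelse(is_acc, "acceptor", "donor")
      b_ex <- ifelse(in_aa, "acceptor_window", "donor_window")
      truth <- data.frame(start_s = t0, state = state, size = size,
                          duration_s = bdur)
    } else {
      b_ts <- numeric(0); b_ch <- character(0); b_ex <- character(0)
      truth <- data.frame(start_s = numeric(0), state = integer(0),
                          size = integer(0), duration_s = numeric(0))
    }
    bg <- function(rate, ch, ex) {
      n <- stats::rpois(1L, rate * config$duration)
      list(ts = stats::runif(n, 0, config$duration),
           ch = rep(ch, n), ex = rep(ex, n))
    }
    g1 <- bg(config$bg_rate_dd, "donor", "donor_window")
    g2 <- bg(config$bg_rate_da, "acceptor", "donor_window")
    g3 <- bg(config$bg_rate_aa, "acceptor", "acceptor_window")
    ts <- c(b_ts, g1$ts, g2$ts, g3$ts)
    ch <- c(b_ch, g1$ch, g2$ch, g3$ch)
    ex <- c(b_ex, g1$ex, g2$ex, g3$ex)
    keep <- ts <= config$duration   # burst tails may spill past the end
    ord <- order(ts[keep])
    photon_stream(ts[keep][ord], ch[keep][ord], ex[keep][ord],
                  duration = config$duration, bursts_truth = truth)
  })
}

#' Construct a photon stream object
#'
#' @param timestamp_s photon arrival times, seconds, non-decreasing.
#' @param channel \code{"donor"}/\code{"acceptor"} per photon.
#' @param excitation \code{"donor_window"}/\code{"acceptor_window"} per photon.
#' @param duration acquisition duration, seconds.
#' @param sync_rate_hz excitation sync rate (default 32 MHz PIE).
#' @param bursts_truth optional simulator ground-truth table.
#' @return A \code{photon_stream} data.frame.
#' @export
photon_stream <- function(timestamp_s, channel, excitation, duration,
                          sync_rate_hz = 32e6, bursts_truth = NULL) {
  if (is.unsorted(timestamp_s))
    stop_domain("timestamps must be non-decreasing", "gqfret_input_error")
  if (length(timestamp_s) &&
      (min(timestamp_s) < 0 || max(timestamp_s) > duration))
    stop_domain("timestamps must lie within [0, duration]", "gqfret_input_error")
  if (!all(channel %in% c("donor", "acceptor")) ||
      !all(excitation %in% c("donor_window", "acceptor_window")))
    stop_domain("invalid channel/excitation labels", "gqfret_input_error")
  df <- data.frame(timestamp_s = as.double(timestamp_s),
                   channel = as.character(channel),
                   excitation = as.character(excitation),
                   stringsAsFactors = FALSE)
  attr(df, "duration") <- duration
  attr(df, "sync_rate_hz") <- sync_rate_hz
  if (!is.null(bursts_truth)) attr(df, "bursts_truth") <- bursts_truth
  class(df) <- c("photon_stream", "data.frame")
  df
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("PIE photon stream: %d photons over %.3g s (sync %.3g MHz)\n",
              nrow(x), attr(x, "duration"), attr(x, "sync_rate_hz") / 1e6))
  tab <- table(x$channel, x$excitation)
  if (nrow(x)) print(tab)
  invisible(x)
}

#' Simulate a ligand titration series of photon streams
#'
#' One stream per concentration; the high-E state weight at each point follows
#' \code{\link{population_from_binding}}. Per-stream seeds derive
#' deterministically from \code{config$seed} and the point index.
#'
#' @param config a \code{\link{sim_config}}.
#' @param binding a \code{\link{binding_params}}.
#' @param concs non-empty vector of non-negative concentrations (micromolar).
#' @return List of \code{list(conc =, stream =)} in input order.
#' @export
simulate_titration <- function(config, binding, concs) {
  stopifnot(inherits(config, "sim_config"), inherits(binding, "binding_params"))
  if (length(concs) == 0)
    stop_domain("'concs' must be non-empty", "gqfret_argument_error")
  if (any(concs < 0))
    stop_domain("'concs' must be non-negative", "gqfret_argument_error")
  lapply(seq_along(concs), function(i) {
    cfg <- config
    cfg$seed <- as.integer(derive_seed(config$seed, i))
    list(conc = concs[i],
         stream = simulate_photon_stream(cfg, conc = concs[i],
                                         binding = binding))
  })
}

#' Simulate a thermal melting curve
#'
#' Boltzmann sigmoid \eqn{s(T) = low + (high - low)/(1 + e^{(T_m - T)/w})}
#' with additive Gaussian noise — the shape of a 295 nm ellipticity melt of an
#' antiparallel/hybrid G-quadruplex band.
#'
#' @param tm melting midpoint, degrees Celsius.
#' @param width transition width, degrees Celsius, positive.
#' @param baselines length-2 numeric \code{c(low, high)}: folded and unfolded
#'   plateau signals (arbitrary units).
#' @param temps measurement temperatures, degrees Celsius.
#' @param noise_sd Gaussian noise SD in signal units.
#' @param seed RNG seed.
#' @param label curve label.
#' @return A \code{melting_curve}: data.frame \code{temperature_C},
#'   \code{signal} with a \code{label} attribute.
#' @export
simulate_melting_curve <- function(tm, width, baselines = c(0, 1),
                                   temps = seq(4, 95, by = 1),
                                   noise_sd = 0, seed = 1L, label = "curve") {
  assert_scalar_num(width, "width", lower = 0, strict_lower = TRUE)
  if (length(temps) == 0)
    stop_domain("'temps' must be non-empty", "gqfret_argument_error")
  low <- baselines[1]; high <- baselines[2]
  sig <- low + (high - low) / (1 + exp((tm - temps) / width))
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, stats::rnorm(length(temps), sd = noise_sd))
  melting_curve(temps, sig, label = label)
}

#' Construct a melting curve object
#'
#' @param temperature_C strictly increasing temperatures.
#' @param signal signal values (same length).
#' @param label curve label.
#' @return A \code{melting_curve} data.frame.
#' @export
melting_curve <- function(temperature_C, signal, label = "curve") {
  if (length(temperature_C) != length(signal))
    stop_domain("temperature and signal lengths differ", "gqfret_input_error")
  if (length(temperature_C) < 8)
    stop_domain("a melting curve needs at least 8 points", "gqfret_input_error")
  if (is.unsorted(temperature_C, strictly = TRUE))
    stop_domain("temperatures must be strictly increasing", "gqfret_input_error")
  df <- data.frame(temperature_C = as.double(temperature_C),
                   signal = as.double(signal))
  attr(df, "label") <- label
  class(df) <- c("melting_curve", "data.frame")
  df
}
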