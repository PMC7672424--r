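#' PIE/ALEX correction factors
#'
#' Standard corrections applied to burst photon counts before computing FRET
#' efficiency and stoichiometry: detection/quantum-yield factor gamma, donor
#' leakage into the acceptor channel (alpha), acceptor direct excitation by the
#' donor laser (delta), and per-channel background rates. The defaults reduce
#' the corrected efficiency to the uncorrected proximity ratio; instrument
#' calibration values are user-supplied configuration.
#'
#' @param gamma detection-efficiency/quantum-yield correction, positive.
#' @param leakage_alpha donor leakage fraction into the acceptor channel.
#' @param direct_delta acceptor direct-excitation factor.
#' @param bg_rate_dd,bg_rate_da,bg_rate_aa background rates, counts/s.
#' @return An object of class \code{correction_factors}.
#' @export
correction_factors <- function(gamma = 1, leakage_alpha = 0, direct_delta = 0,
                               bg_rate_dd = 0, bg_rate_da = 0, bg_rate_aa = 0) {
  assert_scalar_num(gamma, "gamma", lower = 0, strict_lower = TRUE)
  assert_scalar_num(leakage_alpha, "leakage_alpha", lower = 0)
  assert_scalar_num(direct_delta, "direct_delta", lower = 0)
  assert_scalar_num(bg_rate_dd, "bg_rate_dd", lower = 0)
  assert_scalar_num(bg_rate_da, "bg_rate_da", lower = 0)
  assert_scalar_num(bg_rate_aa, "bg_rate_aa", lower = 0)
  structure(list(gamma = gamma, leakage_alpha = leakage_alpha,
                 direct_delta = direct_delta, bg_rate_dd = bg_rate_dd,
                 bg_rate_da = bg_rate_da, bg_rate_aa = bg_rate_aa),
            class = "correction_factors")
}

#' Uncorrected proximity ratio
#'
#' \eqn{E_{raw} = n_{DA}/(n_{DA} + n_{DD})} from donor-excitation counts.
#'
#' @param n_dd donor-excitation donor-channel counts.
#' @param n_da donor-excitation acceptor-channel counts.
#' @return Proximity ratio(s) in \eqn{[0, 1]}.
#' @export
proximity_ratio <- function(n_dd, n_da) {
  if (any(n_dd + n_da <= 0))
    stop_domain("proximity ratio undefined: n_dd + n_da must be positive",
                "gqfret_ratio_error")
  n_da / (n_da + n_dd)
}

# Background-corrected signals per burst; vectorized over burst rows.
corrected_signals <- function(bursts, corr) {
  dur <- bursts$duration_s
  f_dd <- bursts$n_dd - corr$bg_rate_dd * dur
  f_da <- bursts$n_da - corr$bg_rate_da * dur
  f_aa <- bursts$n_aa - corr$bg_rate_aa * dur
  list(f_dd = f_dd,
       f_a = f_da - corr$leakage_alpha * f_dd - corr$direct_delta * f_aa,
       f_aa = f_aa)
}

#' Corrected FRET efficiency per burst
#'
#' Applies leakage, direct-excitation, background and gamma corrections:
#' \deqn{F_A = (n_{DA} - b_{DA}\tau) - \alpha (n_{DD} - b_{DD}\tau)
#'   - \delta (n_{AA} - b_{AA}\tau),\quad
#'   E = F_A / (F_A + \gamma (n_{DD} - b_{DD}\tau)).}
#' E is not clamped to \eqn{[0,1]}: shot noise legitimately places bursts
#' slightly outside and clamping would distort the mixture tails. Bursts whose
#' corrected denominator is non-positive (background-dominated) are flagged
#' and get \code{NA}.
#'
#' @param bursts a \code{burst_table}.
#' @param corr a \code{\link{correction_factors}}.
#' @return Numeric vector of E, one per burst row, \code{NA} where excluded;
#'   attribute \code{excluded} holds the flagged row indices.
#' @export
corrected_E <- function(bursts, corr = correction_factors()) {
  stopifnot(inherits(corr, "correction_factors"))
  s <- corrected_signals(bursts, corr)
  denom <- s$f_a + corr$gamma * s$f_dd
  bad <- !is.finite(denom) | denom <= 0
  e <- ifelse(bad, NA_real_, s$f_a / denom)
  if (any(bad))
    message(sum(bad), " burst(s) excluded from E: non-positive corrected signal")
  attr(e, "excluded") <- which(bad)
  e
}

#' PIE stoichiometry per burst
#'
#' \eqn{S = (\gamma F_{DD} + F_A)/(\gamma F_{DD} + F_A + F_{AA})} with
#' background-corrected signals: ~1 for donor-only molecules, ~0 for
#' acceptor-only, intermediate for dual-labelled.
#'
#' @inheritParams corrected_E
#' @return Numeric vector of S, \code{NA} where the total corrected signal is
#'   non-positive.
#' @export
stoichiometry <- function(bursts, corr = correction_factors()) {
  stopifnot(inherits(corr, "correction_factors"))
  s <- corrected_signals(bursts, corr)
  dex <- corr$gamma * s$f_dd + s$f_a
  tot <- dex + s$f_aa
  ifelse(!is.finite(tot) | tot <= 0, NA_real_, dex / tot)
}

#' Keep dual-labelled bursts by stoichiometry gate
#'
#' Retains bursts with \code{s_min <= S <= s_max} (order preserved), the
#' standard PIE filter rejecting donor-only (S ~ 1) and acceptor-only (S ~ 0)
#' species. Off by default in the pipeline; enable explicitly.
#'
#' @param bursts a \code{burst_table}.
#' @param corr a \code{\link{correction_factors}}.
#' @param s_min,s_max gate bounds, \code{0 <= s_min < s_max <= 1}.
#' @return The retained subset of \code{bursts}.
#' @export
filter_dual_label <- function(bursts, corr = correction_factors(),
                              s_min = 0.25, s_max = 0.85) {
  if (!(s_min >= 0 && s_min < s_max && s_max <= 1))
    stop_domain("need 0 <= s_min < s_max <= 1", "gqfret_domain_error")
  s <- stoichiometry(bursts, corr)
  keep <- !is.na(s) & s >= s_min & s <= s_max
  out <- bursts[keep, , drop = FALSE]
  as_burst_table(out, attr(bursts, "search_params"))
}

#' Histogram of burst FRET efficiencies
#'
#' @param e numeric E values (NAs dropped with a message).
#' @param edges strictly increasing bin edges; default covers -0.1 to 1.1 so
#'   that noise-broadened tails are retained rather than clipped.
#' @return A \code{fret_histogram}: data.frame \code{bin_left},
#'   \code{bin_right}, \code{count}; attributes \code{n_underflow},
#'   \code{n_overflow}, \code{n_values}.
#' @export
build_histogram <- function(e, edges = seq(-0.1, 1.1, by = 0.025)) {
  if (any(diff(edges) <= 0))
    stop_domain("histogram edges must be strictly increasing",
                "gqfret_domain_error")
  na <- sum(is.na(e))
  if (na) message(na, " NA E value(s) dropped from histogram")
  e <- e[!is.na(e)]
  if (!length(e)) warning("empty E set: histogram has zero counts")
  under <- sum(e < edges[1])
  over <- sum(e >= edges[length(edges)])
  inside <- e[e >= edges[1] & e < edges[length(edges)]]
  counts <- if (length(inside))
    tabulate(findInterval(inside, edges), nbins = length(edges) - 1L)
  else integer(length(edges) - 1L)
  h <- data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
                  count = counts)
  attr(h, "n_underflow") <- under
  attr(h, "n_overflow") <- over
  attr(h, "n_values") <- length(e)
  class(h) <- c("fret_histogram", "data.frame")
  h
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("FRET histogram: %d values in %d bins [%g, %g)",
              attr(x, "n_values"), nrow(x), x$bin_left[1],
              x$bin_right[nrow(x)]))
  if (attr(x, "n_underflow") + attr(x, "n_overflow") > 0)
    cat(sprintf(" (+%d under, +%d over)", attr(x, "n_underflow"),
                attr(x, "n_overflow")))
  cat("\n")
  invisible(x)
}

#' Assign PIE excitation windows from timestamps
#'
#' For photon tables lacking explicit excitation labels: the 32 MHz sync
#' period (31.25 ns) is split at mid-period, first half donor window.
#'
#' @param timestamp_s photon times, seconds.
#' @param sync_rate_hz sync rate, Hz (default 32e6).
#' @return Character vector of window labels.
#' @export
assign_excitation_window <- function(timestamp_s, sync_rate_hz = 32e6) {
  period <- 1 / sync_rate_hz
  phase <- timestamp_s %% period
  ifelse(phase < period / 2, "donor_window", "acceptor_window")
}
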