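#' Burst-search parameters
#'
#' Fixed-bin burst search: photon traces are binned at \code{bin_width}
#' (1 ms), runs of consecutive bins with at least \code{threshold} counts are
#' candidate bursts, and candidates with fewer than \code{min_photons} total
#' photons (all channels and excitation windows) are discarded. The customary
#' threshold range for this instrument class is 4–9 counts/bin; values outside
#' it are allowed with a warning.
#'
#' @param bin_width bin width, seconds.
#' @param threshold minimum counts per bin, integer >= 1.
#' @param min_photons minimum total photons per burst, integer >= 1.
#' @param gap_tolerance number of consecutive below-threshold bins allowed
#'   inside one burst (default 0: strictly contiguous runs).
#' @return An object of class \code{burst_search_params}.
#' @export
burst_search_params <- function(bin_width = 0.001, threshold = 5L,
                                min_photons = 25L, gap_tolerance = 0L) {
  assert_scalar_num(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  assert_scalar_num(threshold, "threshold", lower = 1)
  assert_scalar_num(min_photons, "min_photons", lower = 1)
  assert_scalar_num(gap_tolerance, "gap_tolerance", lower = 0)
  if (threshold < 4 || threshold > 9)
    warning("threshold ", threshold,
            " is outside the customary 4-9 counts/bin range", call. = FALSE)
  structure(list(bin_width = bin_width, threshold = as.integer(threshold),
                 min_photons = as.integer(min_photons),
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "burst_search_params")
}

#' Bin a photon stream into fixed-width count bins
#'
#' Bins are half-open \eqn{[k w, (k+1) w)}; a photon exactly on a boundary
#' belongs to the later bin. Bins cover \eqn{[0, duration)}.
#'
#' @param stream a \code{photon_stream}.
#' @param bin_width bin width, seconds.
#' @return Integer vector of per-bin total counts.
#' @export
bin_photons <- function(stream, bin_width = 0.001) {
  assert_scalar_num(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (is.unsorted(stream$timestamp_s))
    stop_domain("photon stream must be time-sorted", "gqfret_input_error")
  duration <- attr(stream, "duration")
  if (is.null(duration))
    duration <- if (nrow(stream)) max(stream$timestamp_s) else 0
  n_bins <- max(1L, as.integer(ceiling(duration / bin_width - 1e-9)))
  idx <- pmin(floor(stream$timestamp_s / bin_width), n_bins - 1L)
  tabulate(idx + 1L, nbins = n_bins)
}

#' Search bursts in a photon stream
#'
#' Maximal runs of consecutive bins with counts at or above the threshold
#' (optionally bridging up to \code{gap_tolerance} sub-threshold bins) are
#' candidate bursts; those with total photons below \code{min_photons} are
#' dropped. Per-channel counts n_dd (donor-excitation/donor), n_da
#' (donor-excitation/acceptor) and n_aa (acceptor-excitation/acceptor) come
#' from the channel-by-excitation labels of the burst's photons.
#'
#' @param stream a \code{photon_stream}.
#' @param params a \code{\link{burst_search_params}}.
#' @return A \code{burst_table}: data.frame with columns \code{burst_id},
#'   \code{start_s}, \code{stop_s}, \code{n_dd}, \code{n_da}, \code{n_aa},
#'   \code{duration_s}, plus half-open photon index range columns
#'   \code{i_first}, \code{i_last_excl}; time-ordered, non-overlapping.
#' @export
search_bursts <- function(stream, params = burst_search_params()) {
  stopifnot(inherits(params, "burst_search_params"))
  counts <- bin_photons(stream, params$bin_width)
  above <- counts >= params$threshold
  runs <- find_runs(above, params$gap_tolerance)
  empty <- data.frame(burst_id = integer(0), start_s = numeric(0),
                      stop_s = numeric(0), n_dd = integer(0),
                      n_da = integer(0), n_aa = integer(0),
                      duration_s = numeric(0), i_first = integer(0),
                      i_last_excl = integer(0))
  if (nrow(runs) == 0) return(as_burst_table(empty, params))
  w <- params$bin_width
  bin_idx <- pmin(floor(stream$timestamp_s / w), length(counts) - 1L)
  # stream is time-sorted so bin_idx is non-decreasing: photon index ranges
  # per run come from findInterval, per-channel counts from cumulative sums
  lo <- findInterval(runs$first - 0.5, bin_idx) + 1L
  hi <- findInterval(runs$last + 0.5, bin_idx)
  n_tot <- hi - lo + 1L
  keep <- n_tot >= params$min_photons
  if (!any(keep)) return(as_burst_table(empty, params))
  lo <- lo[keep]; hi <- hi[keep]
  is_dd <- stream$channel == "donor" & stream$excitation == "donor_window"
  is_da <- stream$channel == "acceptor" & stream$excitation == "donor_window"
  is_aa <- stream$excitation == "acceptor_window" &
    stream$channel == "acceptor"
  c_dd <- c(0L, cumsum(is_dd)); c_da <- c(0L, cumsum(is_da))
  c_aa <- c(0L, cumsum(is_aa))
  t1 <- stream$timestamp_s[lo]; t2 <- stream$timestamp_s[hi]
  df <- data.frame(
    burst_id = seq_along(lo),
    start_s = t1, stop_s = t2,
    n_dd = c_dd[hi + 1L] - c_dd[lo],
    n_da = c_da[hi + 1L] - c_da[lo],
    n_aa = c_aa[hi + 1L] - c_aa[lo],
    duration_s = pmax(t2 - t1, .Machine$double.eps),
    i_first = lo, i_last_excl = hi + 1L)
  as_burst_table(df, params)
}

# Maximal runs of TRUE in `x`, merging runs separated by <= gap FALSE bins.
# Returns data.frame(first, last) of 0-based bin indices.
find_runs <- function(x, gap = 0L) {
  if (!length(x) || !any(x))
    return(data.frame(first = integer(0), last = integer(0)))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values] - 1L, last = ends[r$values] - 1L)
  if (gap > 0L && nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2L:nrow(runs)) {
      if (runs$first[i] - merged$last[nrow(merged)] - 1L <= gap)
        merged$last[nrow(merged)] <- runs$last[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  runs
}

as_burst_table <- function(df, params) {
  rownames(df) <- NULL
  attr(df, "search_params") <- params
  class(df) <- c("burst_table", "data.frame")
  df
}

#' @export
print.burst_table <- function(x, ...) {
  p <- attr(x, "search_params")
  cat(sprintf(
    "Burst table: %d bursts (bin %.3g ms, threshold %d/bin, min %d photons)\n",
    nrow(x), p$bin_width * 1e3, p$threshold, p$min_photons))
  if (nrow(x)) {
    tot <- x$n_dd + x$n_da + x$n_aa
    cat(sprintf("  photons/burst: median %d, range %d-%d\n",
                as.integer(stats::median(tot)), min(tot), max(tot)))
  }
  invisible(x)
}

#' Burst detection rate
#'
#' @param bursts a \code{burst_table} (or anything with \code{nrow}).
#' @param duration acquisition duration, seconds, positive.
#' @return Bursts per second.
#' @export
burst_rate <- function(bursts, duration) {
  assert_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  nrow(bursts) / duration
}
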