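#' Fit a melting midpoint to a thermal denaturation curve
#'
#' Least-squares Boltzmann sigmoid fit
#' \deqn{s(T) = low + (high - low)/(1 + e^{(T_m - T)/w})}
#' to a melting curve (e.g. ellipticity at 295 nm versus temperature).
#' Initialization takes \eqn{T_m} from the extremum of the smoothed numerical
#' derivative of the signal; the fit is sign-invariant (an inverted band gives
#' the same midpoint). A derivative-extremum estimate is always computed as a
#' cross-check and a warning is raised when the two disagree by more than
#' 1 degree. Baselines are horizontal by default; \code{sloped_baselines}
#' adds linear folded/unfolded baseline slopes.
#'
#' @param curve a \code{\link{melting_curve}}.
#' @param sloped_baselines allow linear baseline slopes.
#' @return An object of class \code{tm_fit}: \code{tm}, \code{width},
#'   \code{baselines} (low, high), \code{rss}, \code{tm_derivative}
#'   (cross-check estimate), \code{method}.
#' @export
fit_tm <- function(curve, sloped_baselines = FALSE) {
  stopifnot(inherits(curve, "melting_curve"))
  temps <- curve$temperature_C
  sig <- curve$signal
  amp0 <- diff(range(sig))
  if (amp0 == 0)
    stop_domain("flat curve: no melting transition", "gqfret_no_transition_error")
  tm0 <- tm_derivative_estimate(temps, sig)
  n <- length(temps)
  low0 <- mean(sig[seq_len(5L)])
  high0 <- mean(sig[seq.int(n - 4L, n)])
  rng <- diff(range(temps))
  boltz <- function(T, tm, width, low, high, s_low = 0, s_high = 0) {
    frac <- 1 / (1 + exp((tm - T) / width))
    (low + s_low * (T - tm)) * (1 - frac) + (high + s_high * (T - tm)) * frac
  }
  form <- if (sloped_baselines)
    sig ~ boltz(temps, tm, width, low, high, s_low, s_high)
  else sig ~ boltz(temps, tm, width, low, high)
  # deterministic multistart: the single derivative-based start can land on
  # a degenerate gradient for late/sharp transitions, so cross a small grid
  # of midpoints and widths and keep the best residual sum of squares
  tm_starts <- unique(c(tm0, stats::quantile(temps, c(0.25, 0.5, 0.75),
                                             names = FALSE)))
  width_starts <- rng / c(40, 20, 8)
  fit <- NULL
  for (tms in tm_starts) for (ws in width_starts) {
    start <- list(tm = tms, width = ws, low = low0, high = high0)
    if (sloped_baselines) start <- c(start, list(s_low = 0, s_high = 0))
    cand <- tryCatch(
      minpack.lm::nlsLM(form, start = start,
                        lower = c(tm = min(temps), width = 1e-3,
                                  rep(-Inf, length(start) - 2L)),
                        upper = c(tm = max(temps), width = rng,
                                  rep(Inf, length(start) - 2L)),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rss <- sum(stats::residuals(cand)^2)
    if (is.null(fit) || rss < sum(stats::residuals(fit)^2) - 1e-12)
      fit <- cand
  }
  if (is.null(fit)) {
    # every start failed: either no transition at all or hopeless data;
    # distinguish by the plateau difference relative to the local scatter
    scatter <- stats::sd(stats::residuals(stats::lm(sig ~ temps)))
    if (abs(high0 - low0) <= 3 * scatter)
      stop_domain("no resolvable transition: amplitude within noise",
                  "gqfret_no_transition_error")
    stop_domain("melting fit failed to converge from every start",
                "gqfret_fit_error")
  }
  cf <- stats::coef(fit)
  resid_sd <- stats::sd(stats::residuals(fit))
  amp <- abs(cf["high"] - cf["low"])
  if (amp <= 3 * resid_sd)
    stop_domain("no resolvable transition: amplitude within noise",
                "gqfret_no_transition_error")
  tm <- unname(cf["tm"])
  if (tm <= min(temps) + 1e-6 || tm >= max(temps) - 1e-6)
    warning("fitted Tm lies at the boundary of the measured range",
            call. = FALSE)
  if (abs(tm - tm0) > 1)
    warning(sprintf(
      "sigmoid Tm (%.2f) and derivative-extremum Tm (%.2f) differ by > 1 C",
      tm, tm0), call. = FALSE)
  structure(list(tm = tm, width = unname(cf["width"]),
                 baselines = c(low = unname(cf["low"]),
                               high = unname(cf["high"])),
                 rss = sum(stats::residuals(fit)^2),
                 tm_derivative = tm0,
                 method = if (sloped_baselines) "boltzmann_sloped"
                          else "boltzmann",
                 label = attr(curve, "label"), nls = fit, curve = curve),
            class = "tm_fit")
}

# Midpoint estimate from the extremum of the smoothed numerical derivative.
tm_derivative_estimate <- function(temps, sig) {
  n <- length(temps)
  win <- max(3L, min(7L, n %/% 4L * 2L + 1L))   # odd running-mean window
  sm <- stats::filter(sig, rep(1 / win, win), sides = 2)
  sm[is.na(sm)] <- sig[is.na(sm)]
  d <- diff(as.numeric(sm)) / diff(temps)
  i <- which.max(abs(d))
  (temps[i] + temps[i + 1]) / 2
}

#' Ligand-induced melting-temperature shift
#'
#' \eqn{\Delta T_m = T_m(\mathrm{with\ ligand}) - T_m(\mathrm{without})};
#' negative values indicate destabilization.
#'
#' @param with_ligand,without \code{tm_fit} objects.
#' @return Shift in degrees Celsius.
#' @export
delta_tm <- function(with_ligand, without) {
  stopifnot(inherits(with_ligand, "tm_fit"), inherits(without, "tm_fit"))
  with_ligand$tm - without$tm
}

#' @export
print.tm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Melting fit '%s' (%s): Tm = %.*g C, width = %.3g C\n",
              x$label, x$method, digits, x$tm, x$width))
  cat(sprintf("  baselines %.3g / %.3g, RSS %.3g, derivative Tm %.4g C\n",
              x$baselines["low"], x$baselines["high"], x$rss,
              x$tm_derivative))
  invisible(x)
}

#' @export
coef.tm_fit <- function(object, ...) {
  c(tm = object$tm, width = object$width, object$baselines)
}

#' Predicted melting signal at given temperatures
#'
#' @param object a \code{tm_fit}.
#' @param newdata temperatures (degrees Celsius); default the fitted curve's.
#' @param ... ignored.
#' @return Predicted signal.
#' @export
predict.tm_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$curve$temperature_C else newdata
  low <- object$baselines["low"]; high <- object$baselines["high"]
  unname(low + (high - low) / (1 + exp((object$tm - T) / object$width)))
}

#' @export
residuals.tm_fit <- function(object, ...) {
  object$curve$signal - predict(object)
}

#' Plot a melting curve with its Boltzmann fit
#'
#' @param x a \code{tm_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.tm_fit <- function(x, ...) {
  graphics::plot(x$curve$temperature_C, x$curve$signal, pch = 1,
                 xlab = "temperature (C)", ylab = "signal", ...)
  grid <- seq(min(x$curve$temperature_C), max(x$curve$temperature_C),
              length.out = 300)
  graphics::lines(grid, predict(x, grid), lwd = 2)
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Batch delta-Tm table from a curve manifest
#'
#' Fits every curve and pairs each ligand-bound curve with its reference
#' (apo) curve to produce a stabilization table.
#'
#' @param curves named list of \code{melting_curve} objects.
#' @param pairs data.frame with columns \code{label} (ligand-bound curve
#'   name) and \code{reference} (apo curve name).
#' @return data.frame \code{label}, \code{tm_C}, \code{reference},
#'   \code{tm_ref_C}, \code{delta_tm_C}.
#' @export
delta_tm_table <- function(curves, pairs) {
  fits <- lapply(curves, fit_tm)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- fits[[pairs$label[i]]]; b <- fits[[pairs$reference[i]]]
    data.frame(label = pairs$label[i], tm_C = a$tm,
               reference = pairs$reference[i], tm_ref_C = b$tm,
               delta_tm_C = delta_tm(a, b))
  }))
}
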