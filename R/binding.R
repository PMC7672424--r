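#' Build a titration series from per-concentration mixture fits
#'
#' Extracts the high-FRET (largest-mean) species weight from each fitted
#' mixture and assembles the concentration-response table used for the
#' dissociation-constant fit. Single-component models are treated as a fully
#' shifted population (fraction 1) with a warning.
#'
#' @param models list of \code{list(conc =, model =)} pairs, each model a
#'   \code{\link{fit_mixture}} result (optionally with \code{n_bursts}; else
#'   taken from the model's \code{n_points}).
#' @return A \code{titration_series}: data.frame \code{conc_uM},
#'   \code{high_fret_fraction}, \code{n_bursts}, sorted by concentration.
#' @export
build_titration <- function(models) {
  if (length(models) < 3L)
    stop_domain("need at least 3 concentration points", "gqfret_data_error")
  rows <- lapply(models, function(m) {
    stopifnot(inherits(m$model, "fret_mixture"))
    f <- if (m$model$k == 1L) {
      warning("single-component model at conc ", m$conc,
              ": high-FRET fraction taken as 1", call. = FALSE)
      1.0
    } else attr(population_fractions(m$model), "high_fret")
    data.frame(conc_uM = m$conc, high_fret_fraction = f,
               n_bursts = if (!is.null(m$n_bursts)) m$n_bursts
                          else m$model$n_points)
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$conc_uM))
    stop_domain("duplicate titration concentrations", "gqfret_data_error")
  if (!any(df$conc_uM == 0))
    warning("no apo (zero-concentration) point in titration", call. = FALSE)
  df <- df[order(df$conc_uM), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("titration_series", "data.frame")
  df
}

#' Construct a titration series directly
#'
#' @param conc_uM ligand concentrations, micromolar, non-negative, distinct.
#' @param high_fret_fraction high-FRET population fractions in \eqn{[0,1]}.
#' @param n_bursts burst counts per point (fit weights); default 1.
#' @return A \code{titration_series} data.frame sorted by concentration.
#' @export
titration_series <- function(conc_uM, high_fret_fraction,
                             n_bursts = rep(1L, length(conc_uM))) {
  if (any(conc_uM < 0) || anyDuplicated(conc_uM))
    stop_domain("concentrations must be non-negative and distinct",
                "gqfret_data_error")
  if (any(high_fret_fraction < 0 | high_fret_fraction > 1))
    stop_domain("fractions must lie in [0, 1]", "gqfret_data_error")
  df <- data.frame(conc_uM = conc_uM, high_fret_fraction = high_fret_fraction,
                   n_bursts = n_bursts)
  df <- df[order(df$conc_uM), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("titration_series", "data.frame")
  df
}

#' Fit the dissociation constant from a population-shift titration
#'
#' Weighted least squares of the conformational-selection isotherm
#' \eqn{f(L) = f_0 + (f_\infty - f_0)\, L/(K_D + L)} (or its
#' depletion-corrected quadratic variant) to the high-FRET fraction versus
#' ligand concentration. Weights default to per-point burst counts. A
#' deterministic multistart over \eqn{\log_{10} K_D \in \{-2,\dots,2\}}
#' guards against local minima; each start is refined by Levenberg-Marquardt.
#' \eqn{f_\infty} is a free parameter, not pinned to 1, because a residual
#' low-FRET population can persist at the highest measured concentration.
#'
#' @param series a \code{\link{titration_series}}.
#' @param model \code{"hyperbolic"} (1:1 in total ligand, appropriate when
#'   the labelled DNA is orders of magnitude below the ligand) or
#'   \code{"quadratic_depletion"} (explicit free-ligand solution; requires
#'   \code{dna_conc}).
#' @param weighted logical; weight residuals by \code{n_bursts}.
#' @param dna_conc total DNA concentration (micromolar) for the depletion
#'   model.
#' @return An object of class \code{binding_fit}: \code{kd}, \code{f0},
#'   \code{f_inf}, standard errors from the fit curvature, \code{rss},
#'   \code{n_points}, \code{model}.
#' @export
fit_kd <- function(series, model = c("hyperbolic", "quadratic_depletion"),
                   weighted = TRUE, dna_conc = 1e-4) {
  model <- match.arg(model)
  stopifnot(is.data.frame(series))
  L <- series$conc_uM
  f <- series$high_fret_fraction
  if (length(unique(L)) < 3L)
    stop_domain("need at least 3 distinct concentrations", "gqfret_data_error")
  rng <- diff(range(f))
  if (rng == 0)
    stop_domain("flat titration: Kd is not identifiable", "gqfret_identifiability_error")
  if (rng < 0.05)
    warning("titration dynamic range ", signif(rng, 2),
            " < 0.05: Kd poorly constrained", call. = FALSE)
  wts <- if (weighted && !is.null(series$n_bursts)) series$n_bursts
         else rep(1, length(L))
  fun <- function(kd, f0, finf) {
    Lf <- L
    if (model == "quadratic_depletion") {
      b <- kd + dna_conc - L
      Lf <- (-b + sqrt(b^2 + 4 * kd * L)) / 2
    }
    f0 + (finf - f0) * Lf / (kd + Lf)
  }
  f0_init <- f[which.min(L)]
  finf_init <- f[which.max(L)]
  best <- NULL
  for (lk in -2:2) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ fun(kd, f0, finf),
        start = list(kd = 10^lk, f0 = f0_init, finf = finf_init),
        weights = wts,
        lower = c(kd = 1e-9, f0 = -0.5, finf = -0.5),
        upper = c(kd = 1e6, f0 = 1.5, finf = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(wts * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop_domain("isotherm fit failed to converge from every start",
                "gqfret_fit_error")
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, 3))
  structure(list(kd = unname(cf["kd"]), f0 = unname(cf["f0"]),
                 f_inf = unname(cf["finf"]),
                 se = c(kd = unname(se[1]), f0 = unname(se[2]),
                        f_inf = unname(se[3])),
                 rss = best$rss, n_points = length(L), model = model,
                 weighted = weighted, series = series, nls = best$fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Conformational-selection binding fit (%s, %d points)\n",
              x$model, x$n_points))
  cat(sprintf("  Kd    = %.*g uM (SE %.2g)\n", digits, x$kd, x$se["kd"]))
  cat(sprintf("  f0    = %.*g (SE %.2g)\n", digits, x$f0, x$se["f0"]))
  cat(sprintf("  f_inf = %.*g (SE %.2g)\n", digits, x$f_inf, x$se["f_inf"]))
  cat(sprintf("  weighted RSS = %.3g\n", x$rss))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, f0 = object$f0, f_inf = object$f_inf)
}

#' @export
vcov.binding_fit <- function(object, ...) stats::vcov(object$nls)

#' Predicted high-FRET fraction at given concentrations
#'
#' @param object a \code{binding_fit}.
#' @param newdata concentrations (micromolar); default the fitted series.
#' @param ... ignored.
#' @return Predicted fractions.
#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$series$conc_uM else newdata
  object$f0 + (object$f_inf - object$f0) * L / (object$kd + L)
}

#' @export
residuals.binding_fit <- function(object, ...) {
  object$series$high_fret_fraction -
    predict(object, object$series$conc_uM)
}

#' Plot a binding titration with its fitted isotherm
#'
#' @param x a \code{binding_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.binding_fit <- function(x, ...) {
  s <- x$series
  grid <- seq(0, max(s$conc_uM) * 1.05, length.out = 200)
  graphics::plot(s$conc_uM, s$high_fret_fraction, pch = 19,
                 xlab = "ligand (uM)", ylab = "high-FRET fraction", ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}
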