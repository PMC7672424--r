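#' Fit a Gaussian mixture to burst FRET efficiencies
#'
#' Maximum-likelihood decomposition of the per-burst FRET-efficiency
#' distribution into K Gaussian components ("FRET species") by
#' expectation-maximization, the standard analysis for resolving coexisting
#' conformers of a dual-labelled molecule. Fitting on the per-burst values
#' (not the binned histogram) uses all the information in the sample; a
#' histogram least-squares backend is available via
#' \code{\link{fit_mixture_histogram}} as a cross-check.
#'
#' Initialization is deterministic: component means at the k interior
#' quantiles of the data, common sigma = pooled SD / k, uniform weights.
#' Optional seeded random restarts perturb the quantile means. Convergence is
#' declared when the log-likelihood gain drops below \code{tol} (1e-8) or
#' after \code{max_iter} (500) iterations. Component sigmas are floored at
#' \code{sigma_floor} to prevent singular collapse on repeated values;
#' components stuck at the floor with vanishing weight are flagged.
#' Components are reported sorted by mean ascending.
#'
#' @param e numeric FRET efficiencies (NAs dropped); need at least 10 k values.
#' @param k number of components, >= 1.
#' @param init \code{"quantile"} (deterministic) or \code{"random"} (seeded
#'   restarts around the quantile solution).
#' @param seed seed for random restarts.
#' @param n_restarts number of restarts when \code{init = "random"}.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param sigma_floor lower bound on component SD.
#' @param fixed_means,fixed_sigmas optional length-k vectors freezing the
#'   component positions and widths; EM then updates the weights only. This
#'   is the shared-component mode used across a ligand titration, where the
#'   species' FRET efficiencies do not shift and only their populations
#'   change.
#' @return An object of class \code{fret_mixture} with elements \code{k},
#'   \code{means}, \code{sigmas}, \code{weights} (sum to 1), \code{log_likelihood},
#'   \code{bic}, \code{n_points}, \code{n_iter}, \code{converged},
#'   \code{flags}, and \code{responsibilities} (n x k posterior matrix).
#' @seealso \code{\link{population_fractions}}, \code{\link{select_components}}
#' @export
fit_mixture <- function(e, k = 2L, init = c("quantile", "random"), seed = 1L,
                        n_restarts = 5L, tol = 1e-8, max_iter = 500L,
                        sigma_floor = 1e-3, fixed_means = NULL,
                        fixed_sigmas = NULL) {
  init <- match.arg(init)
  e <- e[!is.na(e)]
  k <- as.integer(k)
  if (k < 1L) stop_domain("k must be >= 1", "gqfret_domain_error")
  if (length(e) < 10L * k)
    stop_domain(sprintf("need at least %d values for k = %d (got %d)",
                        10L * k, k, length(e)), "gqfret_data_error")
  fixed <- !is.null(fixed_means)
  if (fixed) {
    if (is.null(fixed_sigmas) || length(fixed_means) != k ||
        length(fixed_sigmas) != k)
      stop_domain("fixed_means and fixed_sigmas must both have length k",
                  "gqfret_domain_error")
    starts <- list(list(means = fixed_means,
                        sigmas = pmax(fixed_sigmas, sigma_floor),
                        weights = rep(1 / k, k)))
  } else {
    starts <- list(quantile_start(e, k))
    if (init == "random" && n_restarts > 0L) {
      starts <- c(starts,
                  with_seed(seed, lapply(seq_len(n_restarts), function(i) {
        s <- quantile_start(e, k)
        s$means <- sort(s$means + stats::rnorm(k, sd = stats::sd(e) / 2))
        s
      })))
    }
  }
  fits <- lapply(starts, function(s)
    em_gaussian(e, s, tol = tol, max_iter = max_iter,
                sigma_floor = sigma_floor, weights_only = fixed))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "log_likelihood"))]]
  ord <- order(best$means)
  best$means <- best$means[ord]
  best$sigmas <- best$sigmas[ord]
  best$weights <- best$weights[ord]
  best$responsibilities <- best$responsibilities[, ord, drop = FALSE]
  n <- length(e)
  # free parameters: k means + k sigmas + (k-1) weights, or weights only
  p <- if (fixed) k - 1L else 3L * k - 1L
  best$bic <- -2 * best$log_likelihood + p * log(n)
  best$k <- k
  best$n_points <- n
  flags <- character(0)
  if (any(best$sigmas <= best$sigma_floor * (1 + 1e-12) &
          best$weights < 1 / (10 * k)))
    flags <- c(flags, "degenerate_component")
  best$flags <- flags
  best$method <- if (fixed) "em_fixed_shapes" else "em"
  best$call <- match.call()
  class(best) <- "fret_mixture"
  best
}

quantile_start <- function(e, k) {
  qs <- stats::quantile(e, probs = (seq_len(k) - 0.5) / k, names = FALSE,
                        type = 7)
  list(means = as.double(qs),
       sigmas = rep(max(stats::sd(e) / k, 1e-3), k),
       weights = rep(1 / k, k))
}

# Plain EM for a univariate Gaussian mixture; log-likelihood is guaranteed
# non-decreasing (up to sigma flooring) and recorded per iteration.
# weights_only freezes means/sigmas (shared-component titration mode).
em_gaussian <- function(e, start, tol, max_iter, sigma_floor,
                        weights_only = FALSE) {
  n <- length(e)
  mu <- start$means; sg <- pmax(start$sigmas, sigma_floor)
  w <- start$weights / sum(start$weights)
  k <- length(mu)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(e, mu[j], sg[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    r <- dens / rowsum_d
    nk <- colSums(r)
    nk[nk < .Machine$double.xmin] <- .Machine$double.xmin
    if (!weights_only) {
      mu <- colSums(r * e) / nk
      sg <- pmax(sqrt(colSums(r * (outer(e, mu, "-"))^2) / nk), sigma_floor)
    }
    w <- nk / n
  }
  dens <- matrix(vapply(seq_len(k),
                        function(j) w[j] * stats::dnorm(e, mu[j], sg[j]),
                        numeric(n)), nrow = n)
  rs <- rowSums(dens)
  rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
  list(means = mu, sigmas = sg, weights = w,
       log_likelihood = sum(log(rs)),
       ll_trace = ll_trace, n_iter = length(ll_trace),
       converged = converged, sigma_floor = sigma_floor,
       responsibilities = dens / rs)
}

#' Choose the number of mixture components by BIC
#'
#' Fits k = 1..k_max and returns every model plus the BIC-minimal k.
#' Candidate k for which the sample is too small (fewer than 10 k values)
#' are skipped with a warning.
#'
#' @inheritParams fit_mixture
#' @param k_max largest component count to consider.
#' @param criterion only \code{"bic"} currently.
#' @return List with \code{k} (chosen), \code{models} (named list
#'   \code{"k=1"}, ...), \code{bic} (vector).
#' @export
select_components <- function(e, k_max = 4L, criterion = "bic", ...) {
  criterion <- match.arg(criterion, "bic")
  e <- e[!is.na(e)]
  ks <- seq_len(k_max)
  feasible <- ks[10L * ks <= length(e)]
  if (length(feasible) < length(ks))
    warning("skipping k > ", max(feasible, 0),
            ": fewer than 10*k data points", call. = FALSE)
  if (!length(feasible))
    stop_domain("too few points for any candidate k", "gqfret_data_error")
  models <- lapply(feasible, function(kk) fit_mixture(e, k = kk, ...))
  names(models) <- paste0("k=", feasible)
  bics <- vapply(models, `[[`, numeric(1), "bic")
  list(k = feasible[which.min(bics)], models = models, bic = bics)
}

#' Population fractions of the FRET species
#'
#' Mixture weights in mean-ascending order (low-FRET first); the high-FRET
#' species is the largest-mean component.
#'
#' @param model a fitted \code{fret_mixture}.
#' @return Named numeric vector of fractions; attribute \code{high_fret}
#'   gives the high-FRET (last) fraction.
#' @export
population_fractions <- function(model) {
  stopifnot(inherits(model, "fret_mixture"))
  f <- model$weights                      # already sorted by mean
  names(f) <- paste0("E=", formatC(model$means, digits = 3, format = "g"))
  attr(f, "high_fret") <- f[[length(f)]]
  f
}

#' Least-squares mixture fit on the binned histogram
#'
#' Alternative backend fitting Gaussian component curves to histogram counts
#' by nonlinear least squares; used to cross-check the per-burst EM fit.
#'
#' @param hist a \code{\link{build_histogram}} result.
#' @param k number of components.
#' @return A \code{fret_mixture} (without responsibilities; log-likelihood
#'   and BIC are NA).
#' @export
fit_mixture_histogram <- function(hist, k = 2L) {
  stopifnot(inherits(hist, "fret_histogram"))
  mid <- (hist$bin_left + hist$bin_right) / 2
  cnt <- hist$count
  n <- sum(cnt)
  if (n < 10L * k)
    stop_domain("too few counts for histogram mixture fit", "gqfret_data_error")
  binw <- hist$bin_right - hist$bin_left
  # moment-style start: split mass at quantile midpoints
  cum <- cumsum(cnt) / n
  mu0 <- vapply(seq_len(k), function(j)
    mid[which.min(abs(cum - (j - 0.5) / k))], numeric(1))
  sd0 <- rep(max(sqrt(sum(cnt * (mid - sum(cnt * mid) / n)^2) / n) / k, 1e-3), k)
  par0 <- c(mu0, log(sd0), rep(0, k - 1))  # weights via softmax-style logits
  pred <- function(par) {
    mu <- par[seq_len(k)]
    sg <- exp(par[k + seq_len(k)])
    lg <- c(par[2 * k + seq_len(max(k - 1, 0))], 0)
    w <- exp(lg) / sum(exp(lg))
    rowSums(vapply(seq_len(k), function(j)
      n * binw * w[j] * stats::dnorm(mid, mu[j], sg[j]), numeric(length(mid))))
  }
  fit <- minpack.lm::nls.lm(par = par0,
                            fn = function(p) cnt - pred(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- fit$par
  mu <- par[seq_len(k)]
  sg <- exp(par[k + seq_len(k)])
  lg <- c(par[2 * k + seq_len(max(k - 1, 0))], 0)
  w <- exp(lg) / sum(exp(lg))
  ord <- order(mu)
  structure(list(k = k, means = mu[ord], sigmas = sg[ord], weights = w[ord],
                 log_likelihood = NA_real_, bic = NA_real_, n_points = n,
                 n_iter = fit$niter, converged = fit$info %in% 1:4,
                 flags = character(0), method = "histogram_ls"),
            class = "fret_mixture")
}

#' @export
print.fret_mixture <- function(x, digits = 3, ...) {
  cat(sprintf("Gaussian mixture of %d FRET species (n = %d bursts)\n",
              x$k, x$n_points))
  tab <- data.frame(mean_E = round(x$means, digits),
                    sigma = round(x$sigmas, digits),
                    weight = round(x$weights, digits))
  rownames(tab) <- c("low-FRET", rep("", x$k - 2L), "high-FRET")[seq_len(x$k)]
  if (x$k == 1L) rownames(tab) <- "species"
  print(tab)
  if (is.finite(x$bic))
    cat(sprintf("logLik %.2f, BIC %.2f, %d EM iterations%s\n",
                x$log_likelihood, x$bic, x$n_iter,
                if (isTRUE(x$converged)) "" else " (not converged)"))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fret_mixture <- function(object, ...) {
  print(object, ...)
  f <- population_fractions(object)
  cat(sprintf("high-FRET population: %.1f%%\n", 100 * attr(f, "high_fret")))
  invisible(object)
}

#' @export
coef.fret_mixture <- function(object, ...) {
  c(stats::setNames(object$means, paste0("mean", seq_len(object$k))),
    stats::setNames(object$sigmas, paste0("sigma", seq_len(object$k))),
    stats::setNames(object$weights, paste0("weight", seq_len(object$k))))
}

#' @export
logLik.fret_mixture <- function(object, ...) {
  structure(object$log_likelihood, df = 3L * object$k - 1L,
            nobs = object$n_points, class = "logLik")
}

#' Mixture density at given FRET efficiencies
#'
#' @param object a \code{fret_mixture}.
#' @param newdata numeric E values at which to evaluate the density.
#' @param ... ignored.
#' @return Density values.
#' @export
predict.fret_mixture <- function(object, newdata = seq(-0.1, 1.1, by = 0.005),
                                 ...) {
  rowSums(vapply(seq_len(object$k), function(j)
    object$weights[j] * stats::dnorm(newdata, object$means[j],
                                     object$sigmas[j]),
    numeric(length(newdata))))
}

#' Draw burst FRET values from a fitted mixture
#'
#' @param object a \code{fret_mixture}.
#' @param nsim number of values.
#' @param seed RNG seed.
#' @param ... ignored.
#' @return Numeric vector of simulated E values.
#' @export
simulate.fret_mixture <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    stats::rnorm(nsim, object$means[comp], object$sigmas[comp])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Plot a FRET histogram with fitted mixture components
#'
#' @param x a \code{fret_mixture}.
#' @param hist optional \code{fret_histogram} to draw behind the fit.
#' @param ... passed to \code{plot}.
#' @export
plot.fret_mixture <- function(x, hist = NULL, ...) {
  grid <- seq(-0.1, 1.1, by = 0.005)
  dens <- predict(x, grid)
  if (!is.null(hist)) {
    binw <- hist$bin_right - hist$bin_left
    scale <- attr(hist, "n_values")
    graphics::plot((hist$bin_left + hist$bin_right) / 2,
                   hist$count / (scale * binw), type = "h", col = "grey70",
                   xlab = "FRET efficiency", ylab = "density", ...)
    graphics::lines(grid, dens, lwd = 2)
  } else {
    graphics::plot(grid, dens, type = "l", lwd = 2,
                   xlab = "FRET efficiency", ylab = "density", ...)
  }
  for (j in seq_len(x$k))
    graphics::lines(grid, x$weights[j] * stats::dnorm(grid, x$means[j],
                                                      x$sigmas[j]),
                    lty = 2, col = j + 1)
  invisible(x)
}
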