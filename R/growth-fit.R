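#' Estimate instantaneous doubling rates from a sparse growth curve
#'
#' The central estimator. A stride-1 sliding window of three time points is
#' regressed (log2 density on time); each window's slope, and the slope plus
#' and minus its standard error, is assigned to the window's start, middle
#' and end times (nine candidates per window); the median candidate rate at
#' each unique time gives the instantaneous doubling-rate series; a
#' decreasing sigmoid fitted to that series delimits the exponential phase
#' at its inflection point, falling back to the three largest-magnitude
#' rates when the fit fails.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param window sliding window width in points (only 3 supported).
#' @param n_top fallback count for exponential-phase selection.
#' @return An object of class \code{"growth_fit"}: a list with the input
#'   \code{curve}, the \code{windows} table, the \code{candidates} table,
#'   the median \code{rates} series, the \code{sigmoid} fit and the selected
#'   \code{exp_phase} rates.
#' @seealso \code{\link{summarize_condition}}, \code{\link{growth_envelope}}
#' @examples
#' gc <- simulate_growth_curve(seq(0, 6, length.out = 10),
#'                             N0 = 1e4, mu = 1.5, K = 1e7, seed = 1)
#' fit <- growth_fit(gc)
#' coef(fit)
#' @export
growth_fit <- function(curve, window = 3L, n_top = 3L) {
  stopifnot(inherits(curve, "growth_curve"))
  windows <- window_estimates(curve, window = window)
  candidates <- rate_candidates(windows)
  rates <- median_rate_series(candidates)
  sigmoid <- fit_sigmoid_decay(rates)
  exp_phase <- exponential_phase_rates(rates, sigmoid, n_top = n_top)
  structure(list(curve = curve, windows = windows, candidates = candidates,
                 rates = rates, sigmoid = sigmoid, exp_phase = exp_phase,
                 call = match.call()),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Sparse growth-curve fit:", x$curve$strain_id, "/",
      x$curve$replicate_id, "\n")
  cat(sprintf("  %d points, %d sliding windows, %d candidate rates\n",
              length(x$curve$times), nrow(x$windows), nrow(x$candidates)))
  sel <- attr(x$exp_phase, "selection")
  if (identical(sel, "inflection"))
    cat(sprintf("  exponential phase: t < %.4g d (sigmoid inflection)\n",
                x$sigmoid$t_inflect))
  else
    cat("  exponential phase: top-|rate| fallback (sigmoid fit not used)\n")
  cat(sprintf("  representative rate: %s doublings/day (median of %d exponential-phase rates)\n",
              format(stats::median(x$exp_phase$rate), digits = digits),
              nrow(x$exp_phase)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  out <- c(rate = stats::median(object$exp_phase$rate))
  if (isTRUE(object$sigmoid$converged))
    out <- c(out, r_high = object$sigmoid$r_high, r_low = object$sigmoid$r_low,
             t_inflect = object$sigmoid$t_inflect, tau = object$sigmoid$tau)
  out
}

#' @export
summary.growth_fit <- function(object, ...) {
  r <- object$exp_phase$rate
  d <- object$curve$densities
  structure(list(
    strain = object$curve$strain_id,
    replicate = object$curve$replicate_id,
    condition = object$curve$condition,
    n_points = length(object$curve$times),
    n_windows = nrow(object$windows),
    selection = attr(object$exp_phase, "selection"),
    sigmoid = object$sigmoid,
    rate_median = stats::median(r),
    rate_mean = mean(r),
    rate_sd = if (length(r) > 1L) stats::sd(r) else 0,
    rate_range = range(r),
    max_density = max(d),
    fold_increase = max(d) / d[1L]), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, digits = 4, ...) {
  cat("Growth fit summary:", x$strain, "/", x$replicate, "\n")
  cat(sprintf("  points %d | windows %d | phase selection: %s\n",
              x$n_points, x$n_windows, x$selection))
  print(x$sigmoid)
  cat(sprintf("  exponential-phase rate: median %.*g, mean %.*g, sd %.*g, range [%.*g, %.*g] doublings/day\n",
              digits, x$rate_median, digits, x$rate_mean, digits, x$rate_sd,
              digits, x$rate_range[1], digits, x$rate_range[2]))
  cat(sprintf("  max density %.4g cells/ml, fold increase %.4g\n",
              x$max_density, x$fold_increase))
  invisible(x)
}

#' Predict the instantaneous doubling rate at new times
#'
#' Uses the converged sigmoid where available; otherwise linear
#' interpolation of the median-rate series (constant beyond the range).
#'
#' @param object a \code{"growth_fit"}.
#' @param times times (days) at which to predict; defaults to the series
#'   times.
#' @param ... unused.
#' @export
predict.growth_fit <- function(object, times = object$rates$time, ...) {
  if (isTRUE(object$sigmoid$converged))
    return(sigmoid_rate(object$sigmoid, times))
  stats::approx(object$rates$time, object$rates$median_rate, xout = times,
                rule = 2)$y
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...)
  object$rates$median_rate - fitted(object)

#' Plot a sparse growth-curve fit
#'
#' Two panels: log2 cell density versus time, and the median instantaneous
#' doubling rate series with the fitted sigmoid (dashed inflection line) and
#' the selected exponential-phase points filled.
#'
#' @param x a \code{"growth_fit"}.
#' @param ... passed to the underlying plot calls.
#' @export
plot.growth_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$curve$times, log2(x$curve$densities),
                 xlab = "time (days)", ylab = "log2 density (cells/ml)",
                 main = paste(x$curve$strain_id, x$curve$replicate_id),
                 pch = 19, ...)
  graphics::plot(x$rates$time, x$rates$median_rate,
                 xlab = "time (days)", ylab = "doublings/day",
                 main = "instantaneous rate", pch = 1, ...)
  inphase <- x$rates$time %in% x$exp_phase$time
  graphics::points(x$rates$time[inphase], x$rates$median_rate[inphase],
                   pch = 19)
  if (isTRUE(x$sigmoid$converged)) {
    tt <- seq(min(x$rates$time), max(x$rates$time), length.out = 100)
    graphics::lines(tt, sigmoid_rate(x$sigmoid, tt))
    graphics::abline(v = x$sigmoid$t_inflect, lty = 2)
  }
  invisible(x)
}
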