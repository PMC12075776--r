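#' Fit a decreasing sigmoid to an instantaneous-rate series
#'
#' Fits the 4-parameter decreasing logistic
#' \deqn{r(t) = r_{low} + (r_{high} - r_{low}) / (1 + \exp((t - t_{inflect}) / \tau))}
#' to the median instantaneous doubling rates versus time by bounded
#' Levenberg-Marquardt least squares. The inflection point \eqn{t_{inflect}}
#' marks the end of the exponential phase. The fit is declared converged only
#' if the optimizer succeeds, the fitted inflection lies within the observed
#' time span, \eqn{r_{high} > r_{low}} and \eqn{\tau > 0}; otherwise a
#' non-converged fit is returned (never an error), triggering the fallback in
#' \code{\link{exponential_phase_rates}}. Series with fewer than 4 distinct
#' times return non-converged immediately.
#'
#' Initial values are \eqn{r_{high} = \max r}, \eqn{r_{low} = \min r},
#' \eqn{t_{inflect}} at the midpoint of the time span and \eqn{\tau =
#' \mathrm{span}/8}; up to 5 deterministic restarts perturb these initials
#' before failure is declared.
#'
#' @param series data.frame with columns \code{time} and \code{median_rate}
#'   (or \code{rate}), as produced by \code{\link{median_rate_series}}.
#' @param restarts maximum number of additional jittered starts.
#' @return An object of class \code{"sigmoid_decay"}: a list with
#'   \code{r_high}, \code{r_low}, \code{t_inflect}, \code{tau},
#'   \code{converged}, \code{rss}.
#' @export
fit_sigmoid_decay <- function(series, restarts = 5L) {
  stopifnot(is.data.frame(series))
  rate_col <- if ("median_rate" %in% names(series)) "median_rate" else "rate"
  if (!all(c("time", rate_col) %in% names(series)))
    stop("series must have columns `time` and `median_rate` (or `rate`)",
         call. = FALSE)
  t <- series$time
  r <- series[[rate_col]]
  if (anyNA(t) || anyNA(r)) stop("series contains NA", call. = FALSE)
  failed <- structure(list(r_high = NA_real_, r_low = NA_real_,
                           t_inflect = NA_real_, tau = NA_real_,
                           converged = FALSE, rss = NA_real_),
                      class = "sigmoid_decay")
  if (length(unique(t)) < 4L) return(failed)
  span <- diff(range(t))
  if (span <= 0 || diff(range(r)) == 0) return(failed)
  df <- data.frame(t = t, r = r)
  start0 <- c(r_high = max(r), r_low = min(r),
              t_inflect = mean(range(t)), tau = span / 8)
  # deterministic jitter multipliers for restarts (no RNG involved)
  jit <- list(c(1, 1, 1, 1), c(1, 1, 0.75, 0.5), c(1, 1, 1.25, 2),
              c(1.1, 0.9, 0.5, 1), c(0.9, 1.1, 1.5, 0.25),
              c(1, 1, 1, 4))
  best <- NULL
  for (k in seq_len(min(restarts + 1L, length(jit)))) {
    st <- start0 * jit[[k]]
    st["tau"] <- max(st["tau"], 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ r_low + (r_high - r_low) / (1 + exp((t - t_inflect) / tau)),
        data = df, start = as.list(st),
        lower = c(r_high = -Inf, r_low = -Inf, t_inflect = -Inf, tau = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed)
  cf <- stats::coef(best$fit)
  ok <- is.finite(best$rss) &&
    cf[["t_inflect"]] >= min(t) && cf[["t_inflect"]] <= max(t) &&
    cf[["r_high"]] > cf[["r_low"]] && cf[["tau"]] > 0
  structure(list(r_high = cf[["r_high"]], r_low = cf[["r_low"]],
                 t_inflect = cf[["t_inflect"]], tau = cf[["tau"]],
                 converged = isTRUE(ok), rss = best$rss),
            class = "sigmoid_decay")
}

#' @export
print.sigmoid_decay <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Sigmoid decay fit: r_high = %.4g, r_low = %.4g, inflection at t = %.4g d, tau = %.4g d (rss %.3g)\n",
      x$r_high, x$r_low, x$t_inflect, x$tau, x$rss))
  } else {
    cat("Sigmoid decay fit: not converged (fallback phase selection applies)\n")
  }
  invisible(x)
}

# Evaluate the decreasing logistic at times tt.
sigmoid_rate <- function(fit, tt) {
  fit$r_low + (fit$r_high - fit$r_low) / (1 + exp((tt - fit$t_inflect) / fit$tau))
}

#' Select the exponential-phase rates of a series
#'
#' If the sigmoid fit converged, the exponential phase is every time point
#' strictly before the fitted inflection; if no point precedes the
#' inflection, or the fit did not converge, the fallback returns the (up to)
#' three entries with the largest absolute rates, ties broken by earlier
#' time, results ordered by ascending time.
#'
#' @param series data.frame with columns \code{time} and \code{median_rate}
#'   (or \code{rate}).
#' @param fit a \code{"sigmoid_decay"} object from
#'   \code{\link{fit_sigmoid_decay}}.
#' @param n_top fallback count (default 3).
#' @return A data.frame with columns \code{time} and \code{rate}, plus an
#'   attribute \code{"selection"} of \code{"inflection"} or \code{"top_abs"}.
#' @export
exponential_phase_rates <- function(series, fit, n_top = 3L) {
  stopifnot(is.data.frame(series))
  rate_col <- if ("median_rate" %in% names(series)) "median_rate" else "rate"
  if (nrow(series) == 0L) stop("empty rate series", call. = FALSE)
  t <- series$time
  r <- series[[rate_col]]
  if (inherits(fit, "sigmoid_decay") && isTRUE(fit$converged)) {
    keep <- t < fit$t_inflect
    if (any(keep)) {
      out <- data.frame(time = t[keep], rate = r[keep])
      out <- out[order(out$time), , drop = FALSE]
      rownames(out) <- NULL
      attr(out, "selection") <- "inflection"
      return(out)
    }
  }
  # fallback: top |rate|, earlier time wins ties
  ord <- order(-abs(r), t)
  pick <- sort(ord[seq_len(min(n_top, length(r)))])
  out <- data.frame(time = t[pick], rate = r[pick])
  rownames(out) <- NULL
  attr(out, "selection") <- "top_abs"
  out
}
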