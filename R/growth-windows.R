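# Sliding-window log2 regression: the primitive behind the instantaneous
# doubling-rate estimator. Each consecutive 3-point window gets an OLS fit of
# log2(density) on time; the slope is the instantaneous doubling rate over
# that window and its standard error (1 residual df) carries the uncertainty.

#' Sliding-window log2 regressions over a growth curve
#'
#' Applies a stride-1 sliding window of three consecutive time points and
#' fits an ordinary least-squares regression of log2(cell density) on time
#' within each window. The slope is the instantaneous doubling rate
#' (doublings/day); its standard error uses the single residual degree of
#' freedom a 3-point fit provides, \eqn{\sqrt{SSE / \sum (t_i - \bar t)^2}}.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param window window width in points. Only 3 is supported.
#' @return A data.frame with one row per window: \code{window_index}
#'   (0-based), \code{t_start}, \code{t_mid}, \code{t_end}, \code{slope},
#'   \code{slope_se}, \code{intercept}.
#' @seealso \code{\link{rate_candidates}}, \code{\link{growth_fit}}
#' @examples
#' gc <- growth_curve(0:2, c(1000, 2000, 4000))
#' window_estimates(gc)  # slope 1 doubling/day, se 0
#' @export
window_estimates <- function(curve, window = 3L) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!identical(as.integer(window), 3L))
    stop("only window = 3 is supported", call. = FALSE)
  n <- length(curve$times)
  if (n < 3L)
    stop("too few points: need at least 3, got ", n, call. = FALSE)
  t <- curve$times
  y <- log2(curve$densities)
  k <- n - 2L
  out <- data.frame(window_index = seq_len(k) - 1L,
                    t_start = t[seq_len(k)],
                    t_mid   = t[seq_len(k) + 1L],
                    t_end   = t[seq_len(k) + 2L],
                    slope = NA_real_, slope_se = NA_real_,
                    intercept = NA_real_)
  for (i in seq_len(k)) {
    idx <- i:(i + 2L)
    fit <- ols3(t[idx], y[idx])
    out$slope[i] <- fit$slope
    out$slope_se[i] <- fit$se
    out$intercept[i] <- fit$intercept
  }
  out
}

# Closed-form OLS for a window: slope, intercept, and slope SE with
# (n - 2) residual df. Errors on zero time variance (duplicate times).
ols3 <- function(t, y) {
  n <- length(t)
  tbar <- mean(t); ybar <- mean(y)
  sxx <- sum((t - tbar)^2)
  if (sxx <= 0)
    stop("zero time variance within a window (duplicate times)", call. = FALSE)
  sxy <- sum((t - tbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * tbar
  sse <- sum((y - intercept - slope * t)^2)
  list(slope = slope,
       intercept = intercept,
       se = sqrt(sse / (n - 2L) / sxx))
}

#' Expand window estimates into candidate instantaneous rates
#'
#' Each window's slope, and the slope plus and minus its standard error, is
#' assigned to the start, middle, and end time of the window: the Cartesian
#' product gives exactly nine candidate instantaneous doubling rates per
#' window. Because stride-1 windows overlap, an interior time point collects
#' candidates from up to three windows.
#'
#' @param windows a data.frame from \code{\link{window_estimates}}.
#' @return A data.frame of candidates with columns \code{window_index},
#'   \code{time}, \code{rate}, \code{offset_tag} (\code{minus},
#'   \code{center}, \code{plus}) and \code{position_tag} (\code{start},
#'   \code{middle}, \code{end}).
#' @export
rate_candidates <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("t_start", "t_mid", "t_end", "slope", "slope_se") %in%
                  names(windows)))
  if (nrow(windows) == 0L) stop("no windows supplied", call. = FALSE)
  if (any(!is.finite(windows$slope)) || any(windows$slope_se < 0))
    stop("invalid window estimates", call. = FALSE)
  offsets <- c(minus = -1, center = 0, plus = 1)
  positions <- c(start = "t_start", middle = "t_mid", end = "t_end")
  pieces <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    grid <- expand.grid(offset_tag = names(offsets),
                        position_tag = names(positions),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pieces[[i]] <- data.frame(
      window_index = w$window_index,
      time = as.numeric(w[unlist(positions[grid$position_tag])]),
      rate = w$slope + offsets[grid$offset_tag] * w$slope_se,
      offset_tag = grid$offset_tag,
      position_tag = grid$position_tag,
      row.names = NULL)
  }
  do.call(rbind, pieces)
}

#' Median instantaneous rate per unique time point
#'
#' Pools all candidate rates assigned to each unique sampling time and takes
#' the median. The result does not depend on candidate ordering.
#'
#' @param candidates a data.frame from \code{\link{rate_candidates}} (columns
#'   \code{time} and \code{rate}).
#' @return A data.frame sorted by time with columns \code{time},
#'   \code{median_rate} and \code{n_candidates}.
#' @export
median_rate_series <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("time", "rate") %in% names(candidates)))
  if (nrow(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  times <- sort(unique(candidates$time))
  med <- vapply(times, function(tt)
    stats::median(candidates$rate[candidates$time == tt]), numeric(1))
  n <- vapply(times, function(tt)
    sum(candidates$time == tt), integer(1))
  data.frame(time = times, median_rate = med, n_candidates = n)
}
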