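#' Summarize replicate growth curves for one condition
#'
#' Runs the full instantaneous-rate chain (\code{\link{growth_fit}}) on each
#' replicate, pools the exponential-phase rates, and calls growth or no
#' growth. The representative rate is the pooled median; dispersion is the
#' pooled sample standard deviation (0 for a single value); the mean is also
#' reported since published center +/- spread conventions vary. Growth is
#' called when the representative rate reaches \code{rate_floor} AND the
#' largest replicate fold increase (max density over initial density)
#' reaches \code{fold_floor}.
#'
#' @param curves list of \code{\link{growth_curve}} replicates sharing one
#'   condition.
#' @param rate_floor minimum representative rate (doublings/day) for a
#'   growth call.
#' @param fold_floor minimum max-density fold increase for a growth call.
#' @param window passed to \code{\link{growth_fit}}.
#' @return An object of class \code{"condition_summary"}.
#' @export
summarize_condition <- function(curves, rate_floor = 0.1, fold_floor = 4,
                                window = 3L) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no replicate curves supplied", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "growth_curve")))
  fits <- lapply(curves, growth_fit, window = window)
  pooled <- do.call(rbind, lapply(fits, function(f) f$exp_phase))
  folds <- vapply(curves, function(cv) max(cv$densities) / cv$densities[1L],
                  numeric(1))
  rep_rate <- stats::median(pooled$rate)
  structure(list(
    condition = curves[[1L]]$condition,
    strain = curves[[1L]]$strain_id,
    n_replicates = length(curves),
    exp_phase_rates = pooled,
    representative_rate = rep_rate,
    rate_mean = mean(pooled$rate),
    rate_dispersion = if (nrow(pooled) > 1L) stats::sd(pooled$rate) else 0,
    rate_range = range(pooled$rate),
    max_density = max(vapply(curves, function(cv) max(cv$densities),
                             numeric(1))),
    fold_increase = max(folds),
    growth_call = rep_rate >= rate_floor && max(folds) >= fold_floor,
    rate_floor = rate_floor, fold_floor = fold_floor,
    fits = fits), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, digits = 4, ...) {
  cond <- if (length(x$condition))
    paste(names(x$condition), unlist(x$condition), sep = "=", collapse = ", ")
  else "none"
  cat("Condition summary:", x$strain, "@", cond, "\n")
  cat(sprintf("  %d replicate(s), %d pooled exponential-phase rates\n",
              x$n_replicates, nrow(x$exp_phase_rates)))
  cat(sprintf("  rate: median %.*g +/- %.*g (sd), mean %.*g, range [%.*g, %.*g] doublings/day\n",
              digits, x$representative_rate, digits, x$rate_dispersion,
              digits, x$rate_mean, digits, x$rate_range[1], digits,
              x$rate_range[2]))
  cat(sprintf("  max density %.4g cells/ml (%.3g-fold); growth: %s\n",
              x$max_density, x$fold_increase,
              if (x$growth_call) "YES" else "no"))
  invisible(x)
}

#' Growth envelope across a condition gradient
#'
#' Orders condition summaries along one condition variable and reports the
#' permissive range (the span of values with a positive growth call), the
#' maximum representative rate among growth-positive conditions, and the
#' condition at which it occurs. With no growth-positive condition the
#' envelope is flagged empty rather than raising.
#'
#' @param summaries list of \code{\link{summarize_condition}} results that
#'   share every condition variable except \code{variable}.
#' @param variable name of the condition variable that varies (e.g.
#'   \code{"temperature_C"}).
#' @return An object of class \code{"growth_envelope"} with a per-condition
#'   \code{table}, \code{max_rate}, \code{max_rate_condition} and
#'   \code{permissive_range}.
#' @export
growth_envelope <- function(summaries, variable) {
  if (inherits(summaries, "condition_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "condition_summary")))
  vals <- vapply(summaries, function(s) {
    v <- s$condition[[variable]]
    if (is.null(v)) stop("condition variable `", variable,
                         "` missing from a summary", call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  # all other condition variables must agree across summaries
  others <- lapply(summaries, function(s) s$condition[
    setdiff(names(s$condition), variable)])
  if (length(unique(vapply(others, function(o)
    paste(names(o), unlist(o), sep = "=", collapse = ";"), character(1)))) > 1L)
    stop("summaries differ in condition variables other than `", variable, "`",
         call. = FALSE)
  ord <- order(vals)
  summaries <- summaries[ord]
  vals <- vals[ord]
  tab <- data.frame(
    value = vals,
    representative_rate = vapply(summaries, `[[`, numeric(1),
                                 "representative_rate"),
    rate_sd = vapply(summaries, `[[`, numeric(1), "rate_dispersion"),
    rate_mean = vapply(summaries, `[[`, numeric(1), "rate_mean"),
    fold_increase = vapply(summaries, `[[`, numeric(1), "fold_increase"),
    growth_call = vapply(summaries, `[[`, logical(1), "growth_call"))
  names(tab)[1L] <- variable
  pos <- which(tab$growth_call)
  if (length(pos)) {
    imax <- pos[which.max(tab$representative_rate[pos])]
    max_rate <- tab$representative_rate[imax]
    max_cond <- summaries[[imax]]$condition
    prange <- range(vals[pos])
  } else {
    max_rate <- NA_real_
    max_cond <- NULL
    prange <- c(NA_real_, NA_real_)
  }
  structure(list(variable = variable, table = tab, max_rate = max_rate,
                 max_rate_condition = max_cond, permissive_range = prange,
                 any_growth = length(pos) > 0L,
                 summaries = summaries), class = "growth_envelope")
}

#' @export
print.growth_envelope <- function(x, digits = 4, ...) {
  cat("Growth envelope across", x$variable, "\n")
  print(x$table, digits = digits, row.names = FALSE)
  if (x$any_growth) {
    cat(sprintf("  permissive range: %.4g to %.4g %s\n",
                x$permissive_range[1], x$permissive_range[2], x$variable))
    cat(sprintf("  max rate %.4g doublings/day at %s = %.4g\n",
                x$max_rate, x$variable,
                as.numeric(x$max_rate_condition[[x$variable]])))
  } else {
    cat("  no growth-positive condition (empty envelope)\n")
  }
  invisible(x)
}

#' @export
plot.growth_envelope <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab[[x$variable]], tab$representative_rate,
                 xlab = x$variable, ylab = "doublings/day",
                 pch = ifelse(tab$growth_call, 19, 1), type = "b", ...)
  if (x$any_growth)
    graphics::abline(v = x$permissive_range, lty = 3)
  invisible(x)
}
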