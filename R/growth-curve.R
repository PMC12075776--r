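#' Construct a growth curve
#'
#' A growth curve is a single strain x replicate x condition time series of
#' cell densities. Times are in days, densities in cells/ml. Densities must
#' be strictly positive (log2 transformation is taken downstream) and times
#' strictly increasing.
#'
#' @param times numeric vector of sampling times (days), strictly increasing.
#' @param densities numeric vector of cell densities (cells/ml), all > 0.
#' @param strain strain identifier.
#' @param replicate replicate identifier.
#' @param condition named list of condition variables, e.g.
#'   \code{list(temperature_C = 18.5, salinity_ppt = 30)}.
#' @return An object of class \code{"growth_curve"}.
#' @examples
#' gc <- growth_curve(0:4, 1000 * 2^(0:4))
#' gc
#' @export
growth_curve <- function(times, densities, strain = "strain",
                         replicate = "rep1", condition = list()) {
  times <- as.numeric(times)
  densities <- as.numeric(densities)
  if (length(times) != length(densities))
    stop("`times` and `densities` must have equal length", call. = FALSE)
  if (length(times) < 1L)
    stop("a growth curve needs at least one point", call. = FALSE)
  if (anyNA(times) || anyNA(densities))
    stop("`times` and `densities` must not contain NA", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(densities <= 0))
    stop("densities must be strictly positive (log2 is taken); zero counts are rejected, not floored",
         call. = FALSE)
  structure(
    list(times = times, densities = densities,
         strain_id = as.character(strain),
         replicate_id = as.character(replicate),
         condition = as.list(condition)),
    class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cond <- if (length(x$condition))
    paste(names(x$condition), unlist(x$condition), sep = "=", collapse = ", ")
  else "none"
  cat("Growth curve:", x$strain_id, "/", x$replicate_id, "\n")
  cat("  condition:", cond, "\n")
  cat(sprintf("  %d points over %.3g days; density %.3g to %.3g cells/ml\n",
              length(x$times), diff(range(x$times)),
              min(x$densities), max(x$densities)))
  invisible(x)
}

#' @export
as.data.frame.growth_curve <- function(x, ...) {
  df <- data.frame(strain = x$strain_id, replicate = x$replicate_id,
                   time_days = x$times, density_cells_per_ml = x$densities,
                   stringsAsFactors = FALSE)
  for (v in names(x$condition)) df[[v]] <- x$condition[[v]]
  df
}

#' Read growth curves from a long-format delimited table
#'
#' Expects a header with columns \code{strain}, \code{replicate},
#' \code{time_days}, \code{density_cells_per_ml}; any remaining columns are
#' treated as condition variables (e.g. \code{temperature_C},
#' \code{salinity_ppt}, \code{carbon_uM}). Comma- or tab-separated files are
#' detected from the first line.
#'
#' @param path path to a CSV/TSV file.
#' @return A list of \code{\link{growth_curve}} objects, one per unique
#'   strain x replicate x condition combination.
#' @export
read_growth_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("strain", "replicate", "time_days", "density_cells_per_ml")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("growth table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cond_vars <- setdiff(names(df), required)
  key <- do.call(paste, c(df[c("strain", "replicate", cond_vars)], sep = "\r"))
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_days), , drop = FALSE]
    growth_curve(d$time_days, d$density_cells_per_ml,
                 strain = d$strain[1L], replicate = d$replicate[1L],
                 condition = as.list(d[1L, cond_vars, drop = FALSE]))
  })
}
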