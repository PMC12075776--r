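# Medium-design calculators used in the growth experiments: chlorinity to
# salinity, two-batch salinity mixing series, and molar-ratio carbon-mix
# accounting. All linear and exact.

#' Convert chlorinity to salinity
#'
#' Classical seawater conversion: salinity (ppt) = 1.80655 x chlorinity
#' (ppt). Chlorinity is taken from the base salts; trace chloride from
#' nutrient stocks is negligible by default but can be added via
#' \code{additive_cl}.
#'
#' @param cl chlorinity in ppt (>= 0), vectorized.
#' @param additive_cl extra chlorinity (ppt) from nutrient stocks, default 0.
#' @return Salinity in ppt.
#' @examples
#' chlorinity_to_salinity(1)       # 1.80655
#' chlorinity_to_salinity(19.374)  # ~35 ppt seawater
#' @export
chlorinity_to_salinity <- function(cl, additive_cl = 0) {
  total <- cl + additive_cl
  if (any(total < 0)) stop("chlorinity must be non-negative", call. = FALSE)
  1.80655 * total
}

#' Two-batch salinity mixing series
#'
#' Given low- and high-salinity medium batches, computes the volume fraction
#' of the high batch needed for each target salinity:
#' \code{fraction_hi = (target - lo) / (hi - lo)}. Reconstruction
#' \code{lo + f (hi - lo)} is exact.
#'
#' @param lo salinity of the low batch (ppt).
#' @param hi salinity of the high batch (ppt), \code{> lo}.
#' @param targets target salinities, all within \code{[lo, hi]}.
#' @return A data.frame with \code{target}, \code{fraction_hi},
#'   \code{fraction_lo} and \code{achieved}.
#' @examples
#' mixing_fractions(0, 50, c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 49))
#' @export
mixing_fractions <- function(lo, hi, targets) {
  if (lo >= hi) stop("`lo` must be below `hi`", call. = FALSE)
  if (any(targets < lo | targets > hi))
    stop("every target must lie within [lo, hi]", call. = FALSE)
  f <- (targets - lo) / (hi - lo)
  data.frame(target = targets, fraction_hi = f, fraction_lo = 1 - f,
             achieved = lo + f * (hi - lo))
}

#' Carbon atoms per molecule for the compounds used in the media
#'
#' A small reference table; counts are always supplied explicitly to the
#' calculators, never inferred from names elsewhere.
#'
#' @format Named integer vector (atoms of carbon per molecule).
#' @export
carbon_atoms <- c(methionine = 5L, glycine = 2L, pyruvate = 3L,
                  asparagine = 4L)

#' Total carbon concentration of a mixture
#'
#' @param concentration_uM component concentrations in uM (>= 0).
#' @param atoms carbon atoms per molecule for each component (> 0 integers),
#'   same length.
#' @return Total carbon in uM: \code{sum(concentration * atoms)}.
#' @examples
#' # the AMS1 carbon mix: 10 uM methionine + 50 uM glycine + 50 uM pyruvate
#' carbon_total(c(10, 50, 50), carbon_atoms[c("methionine", "glycine", "pyruvate")])
#' @export
carbon_total <- function(concentration_uM, atoms) {
  if (length(concentration_uM) != length(atoms))
    stop("`concentration_uM` and `atoms` must have equal length", call. = FALSE)
  if (any(concentration_uM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(atoms <= 0)) stop("carbon atom counts must be positive", call. = FALSE)
  sum(concentration_uM * atoms)
}

#' Component concentrations achieving a target total carbon
#'
#' Scales a molar ratio so that the mixture's total carbon equals
#' \code{target_uM_C} exactly; \code{\link{carbon_total}} of the result
#' reproduces the target.
#'
#' @param ratio molar ratio per component (> 0).
#' @param atoms carbon atoms per molecule per component.
#' @param target_uM_C target total carbon (uM, >= 0).
#' @return Named numeric vector of component concentrations (uM).
#' @examples
#' # 1:5:5 Met:Gly:Pyr at 300 uM carbon -> 10, 50, 50 uM
#' mix_for_target(c(methionine = 1, glycine = 5, pyruvate = 5),
#'                carbon_atoms[c("methionine", "glycine", "pyruvate")], 300)
#' @export
mix_for_target <- function(ratio, atoms, target_uM_C) {
  if (length(ratio) != length(atoms))
    stop("`ratio` and `atoms` must have equal length", call. = FALSE)
  if (any(ratio <= 0)) stop("ratio entries must be positive", call. = FALSE)
  if (any(atoms <= 0)) stop("carbon atom counts must be positive", call. = FALSE)
  if (target_uM_C < 0) stop("target carbon must be >= 0", call. = FALSE)
  per_unit <- sum(ratio * atoms)
  if (per_unit <= 0) stop("ratio contributes zero carbon", call. = FALSE)
  out <- ratio * (target_uM_C / per_unit)
  stats::setNames(as.numeric(out), names(ratio))
}
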