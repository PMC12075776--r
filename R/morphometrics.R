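# Capsule (spherocylinder) morphometrics. A cell is modelled as a cylinder
# of height h capped by two hemispheres of radius r; total length l = h + 2r.
# Its 2-D projection is a stadium of area S = 2r(l - 2r) + pi r^2, which is
# inverted to recover l from a segmented area and a measured radius.

#' Stadium (2-D capsule projection) area
#'
#' @param l capsule length (um), \code{l >= 2r}.
#' @param r cap radius (um), \code{> 0}.
#' @return Projected area \code{2r(l - 2r) + pi r^2} (um^2).
#' @export
stadium_area <- function(l, r) {
  check_capsule(l, r)
  2 * r * (l - 2 * r) + pi * r^2
}

#' Capsule length from projected area and radius
#'
#' Inverts the stadium area: \code{l = (S - pi r^2) / (2r) + 2r}. An area
#' smaller than the circle of the given radius is geometrically impossible
#' and raises an error.
#'
#' @param S projected area (um^2), \code{S >= pi r^2}.
#' @param r radius (um), \code{> 0}.
#' @return Capsule length l (um).
#' @export
length_from_area <- function(S, r) {
  stopifnot(length(S) == length(r) || length(S) == 1L || length(r) == 1L)
  if (any(r <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(S < pi * r^2 * (1 - 1e-12)))
    stop("radius inconsistent with area: S < pi*r^2", call. = FALSE)
  pmax(S - pi * r^2, 0) / (2 * r) + 2 * r
}

#' Capsule volume
#'
#' Cylinder plus two hemispheres: \code{V = pi r^2 (l - 2r) + (4/3) pi r^3}.
#'
#' @inheritParams stadium_area
#' @return Volume (um^3).
#' @export
capsule_volume <- function(l, r) {
  check_capsule(l, r)
  pi * r^2 * (l - 2 * r) + (4 / 3) * pi * r^3
}

#' Capsule surface area
#'
#' Cylinder side plus sphere: \code{SA = 2 pi r (l - 2r) + 4 pi r^2}.
#'
#' @inheritParams stadium_area
#' @return Surface area (um^2).
#' @export
capsule_surface_area <- function(l, r) {
  check_capsule(l, r)
  2 * pi * r * (l - 2 * r) + 4 * pi * r^2
}

check_capsule <- function(l, r) {
  if (any(r <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(l < 2 * r * (1 - 1e-12)))
    stop("capsule length must be at least 2r", call. = FALSE)
  invisible(TRUE)
}

#' Per-cell capsule geometry from a segmented area and multi-point radii
#'
#' Pleomorphic cells are measured with one projected area S (pixel^2) and
#' several radii (pixels) taken at different sections; each radius yields its
#' own length, cylinder height, surface area and volume from the shared S.
#' Radii for which S < pi r^2 (the projection cannot contain the circle) are
#' flagged invalid and excluded from the cell-level mean and median; an error
#' is raised only when no radius is valid.
#'
#' @param area_px2 segmented projected area in pixel^2 (> 0).
#' @param radii_px one or more measured radii in pixels (> 0).
#' @param scale_um_per_px microns per pixel (> 0).
#' @param cell_id identifier carried into the output.
#' @return An object of class \code{"cell_geometry"}: a per-radius
#'   \code{records} data.frame (\code{radius_um}, \code{length_um},
#'   \code{height_um}, \code{surface_area_um2}, \code{volume_um3},
#'   \code{valid}) plus \code{mean} and \code{median} summaries over the
#'   valid records.
#' @export
per_cell_geometry <- function(area_px2, radii_px, scale_um_per_px,
                              cell_id = "cell") {
  if (length(area_px2) != 1L || area_px2 <= 0)
    stop("`area_px2` must be a single positive value", call. = FALSE)
  if (length(radii_px) < 1L || any(radii_px <= 0))
    stop("need at least one positive radius", call. = FALSE)
  if (length(scale_um_per_px) != 1L || scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be a single positive value", call. = FALSE)
  S <- area_px2 * scale_um_per_px^2
  r <- radii_px * scale_um_per_px
  valid <- S >= pi * r^2 * (1 - 1e-12)
  if (!any(valid))
    stop("all radii are inconsistent with the area (S < pi*r^2)",
         call. = FALSE)
  l <- h <- sa <- v <- rep(NA_real_, length(r))
  l[valid] <- length_from_area(S, r[valid])
  h[valid] <- pmax(l[valid] - 2 * r[valid], 0)
  sa[valid] <- capsule_surface_area(l[valid], r[valid])
  v[valid] <- capsule_volume(l[valid], r[valid])
  records <- data.frame(radius_um = r, length_um = l, height_um = h,
                        surface_area_um2 = sa, volume_um3 = v, valid = valid)
  params <- c("radius_um", "length_um", "height_um", "surface_area_um2",
              "volume_um3")
  ok <- records[valid, params, drop = FALSE]
  structure(list(cell_id = as.character(cell_id), area_um2 = S,
                 records = records,
                 mean = vapply(ok, mean, numeric(1)),
                 median = vapply(ok, stats::median, numeric(1))),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, digits = 4, ...) {
  cat("Cell geometry:", x$cell_id, "\n")
  cat(sprintf("  projected area %.4g um^2, %d radii (%d valid)\n",
              x$area_um2, nrow(x$records), sum(x$records$valid)))
  cat(sprintf("  median: r %.*g um, l %.*g um, SA %.*g um^2, V %.*g um^3\n",
              digits, x$median[["radius_um"]], digits,
              x$median[["length_um"]], digits,
              x$median[["surface_area_um2"]], digits,
              x$median[["volume_um3"]]))
  invisible(x)
}

#' Population morphology from per-cell geometries
#'
#' Collects one representative value per cell and parameter (median by
#' default, matching median bars on violin plots; mean available) and
#' reports population mean, median and SD plus a long-format table ready for
#' violin plotting.
#'
#' @param cells list of \code{\link{per_cell_geometry}} results.
#' @param representative \code{"median"} or \code{"mean"} per-cell summary.
#' @return An object of class \code{"population_morphology"} with
#'   \code{per_cell} (wide), \code{long} (violin-ready) and \code{stats}
#'   data.frames.
#' @export
population_summary <- function(cells, representative = c("median", "mean")) {
  representative <- match.arg(representative)
  if (inherits(cells, "cell_geometry")) cells <- list(cells)
  if (length(cells) == 0L) stop("no cells supplied", call. = FALSE)
  stopifnot(all(vapply(cells, inherits, logical(1), "cell_geometry")))
  per_cell <- do.call(rbind, lapply(cells, function(cg)
    data.frame(cell_id = cg$cell_id, t(cg[[representative]]))))
  params <- setdiff(names(per_cell), "cell_id")
  long <- do.call(rbind, lapply(params, function(p)
    data.frame(parameter = p, cell_id = per_cell$cell_id,
               value = per_cell[[p]])))
  stats_df <- data.frame(
    parameter = params,
    mean = vapply(per_cell[params], mean, numeric(1)),
    median = vapply(per_cell[params], stats::median, numeric(1)),
    sd = vapply(per_cell[params], function(v)
      if (length(v) > 1L) stats::sd(v) else 0, numeric(1)),
    row.names = NULL)
  structure(list(n_cells = length(cells), representative = representative,
                 per_cell = per_cell, long = long, stats = stats_df),
            class = "population_morphology")
}

#' @export
print.population_morphology <- function(x, digits = 4, ...) {
  cat(sprintf("Population morphology: %d cells (per-cell %s)\n",
              x$n_cells, x$representative))
  print(x$stats, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Read cell measurements from a delimited table
#'
#' Two dialects are accepted: long format with one row per radius (columns
#' \code{cell_id}, \code{area_px2}, \code{scale_um_per_px},
#' \code{radius_px}), or one row per cell with a \code{radii_px} column
#' holding values separated by \code{";"}.
#'
#' @param path path to a CSV/TSV file.
#' @return A list of measurement lists (\code{cell_id}, \code{area_px2},
#'   \code{radii_px}, \code{scale_um_per_px}) suitable for
#'   \code{\link{per_cell_geometry}}.
#' @export
read_cell_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "area_px2", "scale_um_per_px")
  if (!all(need %in% names(df)))
    stop("cell table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    radii <- if ("radius_px" %in% names(d)) as.numeric(d$radius_px)
             else if ("radii_px" %in% names(d))
               as.numeric(unlist(strsplit(as.character(d$radii_px[1L]), ";")))
             else stop("cell table needs `radius_px` or `radii_px`",
                       call. = FALSE)
    list(cell_id = d$cell_id[1L], area_px2 = d$area_px2[1L],
         radii_px = radii, scale_um_per_px = d$scale_um_per_px[1L])
  })
}
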