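# Seeded generators emulating the statistical structure the analyses assume:
# lag -> exponential -> stationary growth with multiplicative lognormal count
# noise and sparse sampling; pleomorphic capsule cells with noisy multi-point
# radius measurements; sample x genome recruitment counts with
# environment-driven abundance structure. All deterministic given a seed and
# leave the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# sd of log-scale noise giving a multiplicative coefficient of variation cv
lognorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a sparse growth curve
#'
#' Truth model: constant \code{N0} during the lag, then logistic growth
#' \deqn{N(t) = K / (1 + (K/N_0 - 1) e^{-\mu \ln 2 (t - lag)}}
#' with \eqn{\mu} in doublings/day (Gompertz available). Observations carry
#' multiplicative lognormal noise with coefficient of variation
#' \code{noise_cv} (the log-scale sd is \code{sqrt(log(1 + cv^2))}, so the
#' observed mean is \code{N(t) exp(sdlog^2 / 2)}).
#'
#' @param times sampling times (days), strictly increasing.
#' @param N0 inoculum density (cells/ml).
#' @param mu true exponential rate (doublings/day).
#' @param K carrying capacity (cells/ml), \code{> N0}.
#' @param lag lag duration (days, >= 0).
#' @param noise_cv coefficient of variation of observation noise (>= 0).
#' @param seed integer seed; identical seeds reproduce the curve exactly.
#' @param model \code{"logistic"} (default) or \code{"gompertz"} truth
#'   trajectory.
#' @param strain,replicate,condition metadata passed to
#'   \code{\link{growth_curve}}.
#' @return A \code{\link{growth_curve}} with attribute \code{"truth"}
#'   holding the noise-free trajectory.
#' @export
simulate_growth_curve <- function(times, N0, mu, K, lag = 0, noise_cv = 0,
                                  seed = NULL,
                                  model = c("logistic", "gompertz"),
                                  strain = "sim", replicate = "rep1",
                                  condition = list()) {
  model <- match.arg(model)
  stopifnot(N0 > 0, K > N0, is.finite(mu), lag >= 0, noise_cv >= 0)
  truth <- growth_truth(times, N0, mu, K, lag, model)
  obs <- if (noise_cv > 0)
    with_seed(seed, truth * exp(stats::rnorm(length(truth),
                                             sd = lognorm_sdlog(noise_cv))))
  else truth
  out <- growth_curve(times, obs, strain = strain, replicate = replicate,
                      condition = condition)
  attr(out, "truth") <- truth
  out
}

growth_truth <- function(times, N0, mu, K, lag, model) {
  te <- pmax(times - lag, 0)
  if (mu == 0) return(rep(N0, length(times)))
  if (model == "logistic")
    K / (1 + (K / N0 - 1) * exp(-mu * log(2) * te))
  else
    K * (N0 / K)^(exp(-mu * log(2) * te))
}

#' Cardinal (CTMI) response of growth rate to temperature or salinity
#'
#' Rosso's cardinal model: zero at and outside \code{(x_min, x_max)},
#' peaking at \code{mu_opt} when \code{x = x_opt}, with the asymmetric shape
#' typical of microbial thermal envelopes (slow rise, sharp fall above the
#' optimum). The response is bounded by \code{mu_opt} only when
#' \code{x_opt >= (x_min + x_max) / 2}; other geometries are rejected.
#'
#' @param x condition values (e.g. temperature in degrees C), vectorized.
#' @param x_min,x_opt,x_max cardinal values, strictly increasing.
#' @param mu_opt rate at the optimum (doublings/day).
#' @return Rates (doublings/day), zero outside the permissive interval.
#' @export
cardinal_mu <- function(x, x_min, x_opt, x_max, mu_opt) {
  if (!(x_min < x_opt && x_opt < x_max))
    stop("cardinal values must satisfy x_min < x_opt < x_max", call. = FALSE)
  if (x_opt < (x_min + x_max) / 2)
    stop("the cardinal model requires x_opt >= (x_min + x_max)/2; ",
         "closer-to-minimum optima make the response exceed mu_opt",
         call. = FALSE)
  num <- (x - x_max) * (x - x_min)^2
  den <- (x_opt - x_min) *
    ((x_opt - x_min) * (x - x_opt) - (x_opt - x_max) * (x_opt + x_min - 2 * x))
  mu <- mu_opt * num / den
  mu[x <= x_min | x >= x_max | !is.finite(mu)] <- 0
  pmax(mu, 0)
}

#' Simulate a condition-gradient growth experiment
#'
#' Generates replicate growth curves across a gradient (temperature or
#' salinity analogue) with the true rate at each condition given by the
#' cardinal model; conditions outside the permissive interval give flat
#' (no-growth) curves.
#'
#' @param conditions condition values to simulate.
#' @param reps replicates per condition.
#' @param x_min,x_opt,x_max,mu_opt cardinal response, see
#'   \code{\link{cardinal_mu}}.
#' @param times,N0,K,lag,noise_cv,model base curve parameters, see
#'   \code{\link{simulate_growth_curve}}.
#' @param variable condition variable name used in the curve metadata.
#' @param strain strain id.
#' @param seed integer seed.
#' @return A list of \code{\link{growth_curve}} objects.
#' @export
simulate_envelope_experiment <- function(conditions, reps = 2L,
                                         x_min, x_opt, x_max, mu_opt,
                                         times = seq(0, 6, length.out = 10),
                                         N0 = 1e4, K = 1e7, lag = 0.5,
                                         noise_cv = 0.01,
                                         model = "logistic",
                                         variable = "temperature_C",
                                         strain = "sim", seed = NULL) {
  mus <- cardinal_mu(conditions, x_min, x_opt, x_max, mu_opt)
  with_seed(seed, {
    out <- list()
    for (i in seq_along(conditions)) {
      for (rr in seq_len(reps)) {
        cond <- stats::setNames(list(conditions[i]), variable)
        out[[length(out) + 1L]] <- simulate_growth_curve(
          times, N0 = N0, mu = mus[i], K = K, lag = lag,
          noise_cv = noise_cv, seed = NULL, model = model, strain = strain,
          replicate = paste0("rep", rr), condition = cond)
      }
    }
    out
  })
}

#' Simulate a pleomorphic capsule-shaped cell population
#'
#' Draws true lengths and radii from lognormal distributions (resampling any
#' draw violating \code{l >= 2r}), computes the exact stadium projection
#' area, and emits pixel-unit measurements: one segmented area per cell and
#' \code{radii_per_cell} noisy radius readings (multiplicative lognormal
#' noise with coefficient of variation \code{radius_noise_cv}).
#'
#' @param n_cells number of cells.
#' @param length_median,length_gsd lognormal length distribution (median um,
#'   geometric sd > 1).
#' @param radius_median,radius_gsd lognormal radius distribution.
#' @param radii_per_cell radius measurements per cell (>= 1).
#' @param radius_noise_cv measurement noise on radii (>= 0).
#' @param scale_um_per_px microns per pixel.
#' @param seed integer seed.
#' @return A list of measurement lists (as \code{\link{read_cell_table}}
#'   returns), with attribute \code{"truth"}: a data.frame of the true
#'   per-cell length, radius and volume.
#' @export
simulate_cell_population <- function(n_cells = 24L,
                                     length_median = 1.65, length_gsd = 1.3,
                                     radius_median = 0.23, radius_gsd = 1.15,
                                     radii_per_cell = 3L,
                                     radius_noise_cv = 0.05,
                                     scale_um_per_px = 0.01,
                                     seed = NULL) {
  stopifnot(n_cells >= 1L, radii_per_cell >= 1L, radius_noise_cv >= 0,
            length_gsd >= 1, radius_gsd >= 1, scale_um_per_px > 0)
  with_seed(seed, {
    draw <- function(n, med, gsd)
      stats::rlnorm(n, meanlog = log(med), sdlog = log(gsd))
    l <- draw(n_cells, length_median, length_gsd)
    r <- draw(n_cells, radius_median, radius_gsd)
    bad <- which(l < 2 * r)
    while (length(bad)) {
      l[bad] <- draw(length(bad), length_median, length_gsd)
      r[bad] <- draw(length(bad), radius_median, radius_gsd)
      bad <- bad[l[bad] < 2 * r[bad]]
    }
    S <- stadium_area(l, r)
    cells <- lapply(seq_len(n_cells), function(i) {
      robs <- r[i] * exp(stats::rnorm(radii_per_cell,
                                      sd = lognorm_sdlog(radius_noise_cv)))
      list(cell_id = sprintf("cell%03d", i),
           area_px2 = S[i] / scale_um_per_px^2,
           radii_px = robs / scale_um_per_px,
           scale_um_per_px = scale_um_per_px)
    })
    attr(cells, "truth") <- data.frame(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      length_um = l, radius_um = r, volume_um3 = capsule_volume(l, r))
    cells
  })
}

#' Simulate a metagenomic recruitment count table
#'
#' Per-genome log abundance is linear in an environmental variable plus
#' lognormal noise: \code{log(a[g, s]) = baseline_g + slope_g * env_s +
#' noise}. Abundances are normalized within each sample to relative shares;
#' read counts are the share of the per-sample read budget (total recruited
#' bp over the read length), rounded; \code{recruited_bp} is taken as
#' counts x read length summed per sample, so it is exactly consistent with
#' the counts.
#'
#' @param genome_lengths_bp named vector of genome lengths (bp).
#' @param env per-sample environmental values (e.g. temperature); names
#'   become sample ids (defaults \code{s1, s2, ...}).
#' @param baseline per-genome intercept of log abundance (recycled).
#' @param slope per-genome slope of log abundance on \code{env} (recycled).
#' @param noise_sd sd of the lognormal noise on log abundance.
#' @param total_bp per-sample recruited base-pair budget (recycled).
#' @param read_length_bp read length (bp).
#' @param seed integer seed.
#' @return A list of class \code{"recruitment_table"}: \code{counts}
#'   (genomes x samples), \code{genome_lengths_bp}, \code{recruited_bp},
#'   and \code{metadata} (per-sample env values).
#' @export
simulate_recruitment <- function(genome_lengths_bp, env,
                                 baseline = 0, slope = 0, noise_sd = 0.25,
                                 total_bp = 1e8, read_length_bp = 150,
                                 seed = NULL) {
  ng <- length(genome_lengths_bp)
  ns <- length(env)
  stopifnot(ng >= 1L, ns >= 1L, all(genome_lengths_bp > 0),
            all(total_bp > 0), read_length_bp > 0, noise_sd >= 0)
  genomes <- names(genome_lengths_bp)
  if (is.null(genomes))
    genomes <- names(genome_lengths_bp) <- paste0("g", seq_len(ng))
  samples <- names(env)
  if (is.null(samples)) samples <- paste0("s", seq_len(ns))
  baseline <- rep_len(baseline, ng)
  slope <- rep_len(slope, ng)
  total_bp <- rep_len(total_bp, ns)
  with_seed(seed, {
    loga <- outer(baseline, rep(1, ns)) + outer(slope, env) +
      matrix(stats::rnorm(ng * ns, sd = noise_sd), ng, ns)
    share <- apply(exp(loga), 2L, function(a) a / sum(a))
    share <- matrix(share, ng, ns)
    budget_reads <- floor(total_bp / read_length_bp)
    counts <- round(sweep(share, 2L, budget_reads, `*`))
    dimnames(counts) <- list(genomes, samples)
    structure(list(counts = counts,
                   genome_lengths_bp = genome_lengths_bp,
                   recruited_bp = stats::setNames(
                     colSums(counts) * read_length_bp, samples),
                   metadata = data.frame(sample = samples, env = env,
                                         row.names = NULL)),
              class = "recruitment_table")
  })
}

#' @export
print.recruitment_table <- function(x, ...) {
  cat(sprintf("Recruitment table: %d genomes x %d samples, %.3g total recruited bp\n",
              nrow(x$counts), ncol(x$counts), sum(x$recruited_bp)))
  invisible(x)
}
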