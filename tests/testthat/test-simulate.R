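test_that("generators are deterministic per seed and leave the RNG alone", {
  t <- seq(0, 6, length.out = 10)
  a <- simulate_growth_curve(t, 1e4, 1.5, 1e7, lag = 0.5, noise_cv = 0.02,
                             seed = 123)
  b <- simulate_growth_curve(t, 1e4, 1.5, 1e7, lag = 0.5, noise_cv = 0.02,
                             seed = 123)
  c <- simulate_growth_curve(t, 1e4, 1.5, 1e7, lag = 0.5, noise_cv = 0.02,
                             seed = 124)
  expect_identical(a$densities, b$densities)
  expect_false(identical(a$densities, c$densities))
  set.seed(99); before <- runif(1)
  set.seed(99)
  invisible(simulate_growth_curve(t, 1e4, 1.5, 1e7, noise_cv = 0.02,
                                  seed = 5))
  expect_identical(runif(1), before)  # global RNG stream untouched
  cells1 <- simulate_cell_population(n_cells = 5, seed = 7)
  cells2 <- simulate_cell_population(n_cells = 5, seed = 7)
  expect_identical(cells1, cells2)
  rec1 <- simulate_recruitment(c(g1 = 1e6, g2 = 2e6), env = 1:4, seed = 3)
  rec2 <- simulate_recruitment(c(g1 = 1e6, g2 = 2e6), env = 1:4, seed = 3)
  expect_identical(rec1$counts, rec2$counts)
})

test_that("noise-free logistic curves grow at exactly mu before saturation", {
  mu <- 1.2
  t <- seq(0, 3, by = 0.5)
  gc <- simulate_growth_curve(t, N0 = 1e3, mu = mu, K = 1e9, lag = 0,
                              noise_cv = 0)
  # K/N0 = 1e6: early logistic is exponential to high accuracy
  slopes <- diff(log2(gc$densities)) / diff(t)
  expect_equal(slopes, rep(mu, length(slopes)), tolerance = 1e-3)
  w <- window_estimates(gc)
  expect_equal(w$slope, rep(mu, nrow(w)), tolerance = 1e-3)
  # zero noise -> zero estimator dispersion
  expect_true(all(w$slope_se < 1e-3))
  # flat during lag
  gl <- simulate_growth_curve(0:5, 1e3, 2, 1e8, lag = 3, noise_cv = 0)
  expect_equal(gl$densities[1:3], rep(1e3, 3))
})

test_that("cardinal response is zero outside the permissive interval", {
  expect_equal(cardinal_mu(20, 13, 20, 27, 1.5), 1.5)
  expect_equal(cardinal_mu(c(5, 13, 27, 35), 13, 20, 27, 1.5), rep(0, 4))
  x <- seq(13.5, 26.5, by = 0.5)
  mu <- cardinal_mu(x, 13, 20, 27, 1.5)
  expect_true(all(mu > 0))
  expect_true(all(mu <= 1.5 + 1e-12))
  expect_error(cardinal_mu(20, 25, 20, 27, 1.5), "x_min < x_opt < x_max")
})

test_that("simulated envelopes are recovered within one grid step", {
  grid <- seq(4, 36, by = 4)
  curves <- simulate_envelope_experiment(
    grid, reps = 2, x_min = 14, x_opt = 21, x_max = 27, mu_opt = 1.5,
    seed = 42)
  key <- vapply(curves, function(g) g$condition$temperature_C, numeric(1))
  summaries <- lapply(split(curves, key), summarize_condition)
  env <- growth_envelope(summaries, "temperature_C")
  # true permissive interval (14, 27); grid step 4
  expect_true(env$any_growth)
  expect_lte(abs(env$permissive_range[1] - 14), 4)
  expect_lte(abs(env$permissive_range[2] - 27), 4)
  # conditions far outside never grow; near the optimum always
  tab <- env$table
  expect_false(any(tab$growth_call[tab$temperature_C <= 12]))
  expect_true(all(tab$growth_call[tab$temperature_C == 20]))
})

test_that("zero-noise cell populations invert exactly through morphometrics", {
  cells <- simulate_cell_population(n_cells = 10, radii_per_cell = 1,
                                    radius_noise_cv = 0, seed = 13)
  truth <- attr(cells, "truth")
  for (i in seq_along(cells)) {
    cg <- per_cell_geometry(cells[[i]]$area_px2, cells[[i]]$radii_px,
                            cells[[i]]$scale_um_per_px)
    expect_equal(cg$median[["length_um"]], truth$length_um[i],
                 tolerance = 1e-9)
    expect_equal(cg$median[["volume_um3"]], truth$volume_um3[i],
                 tolerance = 1e-9)
  }
  # the l >= 2r constraint is never violated
  big <- simulate_cell_population(n_cells = 200, seed = 19)
  bt <- attr(big, "truth")
  expect_true(all(bt$length_um >= 2 * bt$radius_um))
})

test_that("noisy cell populations recover the true volume distribution", {
  cells <- simulate_cell_population(n_cells = 200, radii_per_cell = 3,
                                    radius_noise_cv = 0.05, seed = 23)
  truth <- attr(cells, "truth")
  pop <- population_summary(lapply(cells, function(m)
    per_cell_geometry(m$area_px2, m$radii_px, m$scale_um_per_px,
                      cell_id = m$cell_id)))
  est <- pop$stats$median[pop$stats$parameter == "volume_um3"]
  expect_lt(abs(est - median(truth$volume_um3)) / median(truth$volume_um3),
            0.10)
})

test_that("simulated recruitment is internally consistent", {
  len <- c(g1 = 1e6, g2 = 1e6)
  # equal abundances, equal lengths -> equal RPKMs
  rec <- simulate_recruitment(len, env = rep(0, 6), baseline = 0, slope = 0,
                              noise_sd = 0, seed = 1)
  rt <- compute_rpkm(rec$counts, rec$genome_lengths_bp, rec$recruited_bp)
  expect_equal(rt$rpkm["g1", ], rt$rpkm["g2", ])
  # counts x read length never exceed the per-sample budget
  rec2 <- simulate_recruitment(c(g1 = 1e6, g2 = 3e6, g3 = 5e5),
                               env = rnorm(10), baseline = c(0, 1, -1),
                               slope = c(0.5, -0.2, 0), total_bp = 1e7,
                               read_length_bp = 150, seed = 11)
  expect_true(all(colSums(rec2$counts) * 150 <= 1e7 + 150 * nrow(rec2$counts)))
  expect_equal(rec2$recruited_bp, colSums(rec2$counts) * 150,
               ignore_attr = FALSE)
})

test_that("an environment-driven abundance gradient is detected end to end", {
  env <- seq(5, 25, length.out = 50)          # e.g. temperature
  len <- c(sc1g1 = 3.5e6, sc1g2 = 3.6e6, sc2g1 = 3.4e6)
  rec <- simulate_recruitment(len, env = setNames(env, paste0("s", 1:50)),
                              baseline = c(0, 0, 0),
                              slope = c(-0.15, -0.15, 0.05),
                              noise_sd = 0.2, total_bp = 1e8, seed = 31)
  rt <- compute_rpkm(rec$counts, rec$genome_lengths_bp, rec$recruited_bp)
  sums <- subcluster_abundance(rt, c(sc1g1 = "sc1", sc1g2 = "sc1",
                                     sc2g1 = "sc2"))$sums
  corr <- env_abundance_correlation(sums, setNames(env, colnames(sums)))
  expect_lt(corr$rho[corr$subcluster == "sc1"], 0)   # negative slope recovered
  expect_gt(corr$rho[corr$subcluster == "sc2"], 0)
})
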