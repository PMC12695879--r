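test_that("generators are byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- generate_point_observations(cfg)
  b <- generate_point_observations(cfg)
  expect_identical(a$observations, b$observations)
  pa <- generate_panel(cfg)
  pb <- generate_panel(cfg)
  expect_identical(pa$panel, pb$panel)
  expect_identical(pa$baseline, pb$baseline)
  ga <- generate_covariate_grid(cfg)
  gb <- generate_covariate_grid(cfg)
  expect_identical(ga$grid, gb$grid)
  expect_identical(ga$truth, gb$truth)
})

test_that("zero-noise efficiencies equal the ground-truth function", {
  cfg <- tiny_config(seed = 2, noise_sd_efficiency = 0, missing_rate = 0,
                     availability_n = 1, availability_p = 1)
  out <- generate_point_observations(cfg)
  expect_equal(out$observations$nue, out$truth$nue, tolerance = 1e-12)
  expect_equal(out$observations$pue, out$truth$pue, tolerance = 1e-12)
})

test_that("generated efficiencies are never negative", {
  cfg <- tiny_config(seed = 3, noise_sd_efficiency = 40)
  out <- generate_point_observations(cfg)
  expect_true(all(out$observations$nue >= 0, na.rm = TRUE))
  expect_true(all(out$observations$pue >= 0, na.rm = TRUE))
})

test_that("noise model is centred: mean deviation within 3 SE of zero", {
  cfg <- generator_config(seed = 4, n_sites = 2000, missing_rate = 0,
                          availability_n = 1, availability_p = 1)
  out <- generate_point_observations(cfg)
  dev <- out$observations$nue - out$truth$nue
  # truncation at zero is negligible at this noise level
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se)
})

test_that("panel mass balance holds exactly by construction", {
  cfg <- tiny_config(seed = 5)
  pan <- generate_panel(cfg)
  ti <- pan$truth$true_intensities
  agg_n <- tapply(ti$intensity_n * ti$area / 1000, ti$year, sum)
  agg_p <- tapply(ti$intensity_p * ti$area / 1000, ti$year, sum)
  tot <- unique(pan$panel[, c("year", "total_n", "total_p")])
  expect_equal(as.numeric(agg_n[as.character(tot$year)]), tot$total_n,
               tolerance = 1e-12)
  expect_equal(as.numeric(agg_p[as.character(tot$year)]), tot$total_p,
               tolerance = 1e-12)
})

test_that("true intensities in a baseline year equal the baseline table", {
  cfg <- generator_config(seed = 6, n_sites = 50, n_countries = 6)
  pan <- generate_panel(cfg)
  ti <- pan$truth$true_intensities
  bf <- pan$truth$baseline_full
  for (by in c(1990, 1999, 2018)) {
    t_by <- ti[ti$year == by, ]
    b_by <- bf[bf$baseline_year == by, ]
    m <- match(paste(t_by$country, t_by$crop), paste(b_by$country, b_by$crop))
    expect_equal(t_by$intensity_n, b_by$intensity_n[m], tolerance = 1e-12)
  }
})

test_that("configured breakpoints are stored in the ground truth", {
  cfg <- tiny_config(seed = 7, breakpoint_year = 8)
  pan <- generate_panel(cfg)
  expect_true(all(pan$truth$true_breakpoints == 8))
})

test_that("grid residual field variogram rises with lag up to the range", {
  cfg <- generator_config(seed = 8, n_sites = 50, spatial_range = 5,
                          resolution = 1)
  g <- generate_covariate_grid(cfg)
  vg <- empirical_variogram(g$grid$lon, g$grid$lat, g$truth$residual_n,
                            n_bins = 10, cutoff = 10)
  short <- mean(vg$gamma[vg$lag < 2])
  at_range <- mean(vg$gamma[vg$lag > 4 & vg$lag < 8])
  expect_gt(at_range, short)
})

test_that("scenario grids carry the configured perturbations and labels", {
  cfg <- tiny_config(seed = 9)
  g <- generate_covariate_grid(cfg)
  pert <- generate_scenario_deltas(cfg, g$grid)
  expect_identical(names(pert), c("SSP126", "SSP245", "SSP585"))
  expect_equal(pert$SSP245$mat, g$grid$mat + 2.2, tolerance = 1e-12)
  expect_equal(pert$SSP245$map, g$grid$map, tolerance = 1e-12)
  none <- generate_scenario_deltas(cfg, g$grid,
                                   deltas = list(base = c(mat = 0, map = 0)))
  expect_equal(none$base, g$grid, tolerance = 1e-12)
})

test_that("generator config validates and round-trips through YAML", {
  expect_error(generator_config(n_years = 5), "n_years")
  expect_error(generator_config(crops = c("rice", "rice")))
  cfg <- tiny_config(seed = 10)
  path <- tempfile(fileext = ".yml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$breakpoint_year, cfg$breakpoint_year)
  expect_identical(generate_panel(cfg2)$panel, generate_panel(cfg)$panel)
})

test_that("latent-variable generator encodes the configured signs", {
  out <- generate_latent_data(n = 200, seed = 1)
  expect_identical(unname(out$truth$true_path_signs),
                   c(-1, 1, 1, 1))
  expect_equal(ncol(out$data), 13) # 4 blocks x 3 manifests + efficiency
})
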