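toy_surface <- function() {
  data.frame(lon = c(0, 1, 0, 1), lat = c(30.5, 30.5, 31.5, 31.5),
             area = c(1, 3, 2, 2), mean = c(40, 60, 50, 70))
}

test_that("grid prediction masks unplanted cells and matches tabular predictions", {
  d <- make_sf_data(200, seed = 11)
  m <- tune_and_fit(d, "sf", soil_fraction_features(),
                    grid = data.frame(ntree = 50, mtry = 4, nodesize = 5),
                    seed = 5, folds = 4)
  grid <- make_sf_data(50, seed = 12)
  grid$lon <- runif(50, 0, 10); grid$lat <- runif(50, 30, 40)
  grid$area_rice <- c(rep(0, 10), runif(40, 1, 5))
  surf <- predict_grid(m, grid, "area_rice")
  expect_equal(nrow(surf), 40) # zero-area cells masked out
  tab <- predict_with_uncertainty(m, grid[11:50, ])
  expect_equal(surf$mean, tab$mean, tolerance = 1e-10)
  expect_equal(surf$sd, tab$sd, tolerance = 1e-10)
})

test_that("constant covariates give a constant surface", {
  d <- make_sf_data(150, seed = 13)
  m <- tune_and_fit(d, "sf", soil_fraction_features(),
                    grid = data.frame(ntree = 40, mtry = 4, nodesize = 5),
                    seed = 6, folds = 4)
  grid <- d[rep(1, 25), ]
  grid$lon <- runif(25); grid$lat <- runif(25, 30, 31)
  grid$area_rice <- 1
  surf <- predict_grid(m, grid, "area_rice")
  expect_equal(max(surf$mean) - min(surf$mean), 0, tolerance = 1e-10)
})

test_that("ordinary kriging interpolates exactly at observations when nugget is zero", {
  set.seed(14)
  obs <- data.frame(lon = runif(30, 0, 10), lat = runif(30, 30, 40))
  obs$z <- sin(obs$lon) + cos(obs$lat) # smooth field
  vgm <- list(nugget = 0, psill = 1, range = 5, model = "exponential")
  pred <- krige_ordinary(obs, obs[, c("lon", "lat")], vgm)
  expect_equal(pred, obs$z, tolerance = 1e-6)
})

test_that("zero residuals leave the surface uncorrected", {
  set.seed(15)
  surf <- data.frame(lon = runif(40, 0, 10), lat = runif(40, 30, 40),
                     area = 1, mean = 50)
  obs <- data.frame(lon = runif(25, 0, 10), lat = runif(25, 30, 40))
  obs$observed <- 10; obs$predicted <- 10
  out <- suppressWarnings(krige_residual_correction(surf, obs, loo = FALSE))
  expect_equal(out$surface$corrected, out$surface$mean, tolerance = 1e-8)
})

test_that("kriging correction lowers leave-one-out RMSE on an autocorrelated field", {
  cfg <- generator_config(seed = 16, n_sites = 50, spatial_range = 5)
  set.seed(16)
  n <- 150
  lon <- runif(n, 0, 20); lat <- runif(n, 30, 50)
  z <- cropnue:::exponential_field(lon, lat, range = 5, sd = 3) +
    rnorm(n, 0, 0.5)
  surf <- data.frame(lon = 10, lat = 40, area = 1, mean = 0)
  obs <- data.frame(lon = lon, lat = lat, observed = z, predicted = 0)
  out <- krige_residual_correction(surf, obs, loo = TRUE)
  expect_lt(out$cv_report$rmse_after, out$cv_report$rmse_before)
})

test_that("variogram fitting recovers a rising structure", {
  set.seed(17)
  n <- 200
  lon <- runif(n, 0, 20); lat <- runif(n, 30, 50)
  z <- cropnue:::exponential_field(lon, lat, range = 5, sd = 3)
  vg <- empirical_variogram(lon, lat, z)
  fit <- fit_variogram(vg, "exponential")
  expect_true(fit$converged)
  expect_gt(fit$psill, fit$nugget) # structure dominates noise
  expect_gt(fit$range, 0)
})

test_that("latitudinal profile reproduces hand-computed weighted means", {
  prof <- latitudinal_profile(toy_surface(), "mean", band_width = 1)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$mean[prof$lat == 30.5], (1 * 40 + 3 * 60) / 4)
  expect_equal(prof$mean[prof$lat == 31.5], (2 * 50 + 2 * 70) / 4)
  # constant surface: zero dispersion, single band when filtered
  const <- toy_surface(); const$mean <- 55
  prof2 <- latitudinal_profile(const, "mean")
  expect_equal(prof2$sd, c(0, 0))
  one_band <- latitudinal_profile(const[const$lat < 31, ], "mean")
  expect_equal(nrow(one_band), 1)
})

test_that("Dunn pairwise statistics match the direct-formula oracle", {
  set.seed(18)
  values <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 3))
  groups <- rep(c("a", "b", "c"), each = 5)
  dn <- dunn_test(values, groups)
  for (i in seq_len(nrow(dn$pairs))) {
    o <- dunn_oracle(values, groups, dn$pairs$a[i], dn$pairs$b[i])
    expect_equal(dn$pairs$z[i], o$z, tolerance = 1e-12)
    expect_equal(dn$pairs$p[i], o$p, tolerance = 1e-12)
  }
  # tie handling: duplicated values flow through the correction
  values2 <- c(1, 1, 2, 2, 3, 3, 4, 4, 9, 9, 10, 11)
  groups2 <- rep(c("a", "b", "c"), each = 4)
  dn2 <- dunn_test(values2, groups2)
  o2 <- dunn_oracle(values2, groups2, "a", "c")
  i2 <- which(dn2$pairs$a == "a" & dn2$pairs$b == "c")
  expect_equal(dn2$pairs$z[i2], o2$z, tolerance = 1e-12)
})

test_that("compact letters share a letter exactly when groups are indistinct", {
  # identical zones share a letter; separated zones get distinct letters
  set.seed(19)
  surf <- data.frame(lon = 0, lat = 0, area = 1,
                     mean = c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 50)),
                     zone = rep(c("z1", "z2", "z3"), each = 10))
  zs <- zonal_summary(surf, "zone", "mean")
  lt <- zs$summary$letter
  names(lt) <- zs$summary$zone
  shared12 <- any(strsplit(lt["z1"], "")[[1]] %in% strsplit(lt["z2"], "")[[1]])
  shared13 <- any(strsplit(lt["z1"], "")[[1]] %in% strsplit(lt["z3"], "")[[1]])
  expect_true(shared12)
  expect_false(shared13)
})

test_that("letter display is consistent with pairwise p-values on random cases", {
  set.seed(20)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    groups <- paste0("g", seq_len(k))
    cmb <- combn(groups, 2)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ],
                        p = runif(ncol(cmb)), stringsAsFactors = FALSE)
    lt <- compact_letters(pairs, groups, alpha = 0.05)
    for (i in seq_len(nrow(pairs))) {
      share <- any(strsplit(lt[pairs$a[i]], "")[[1]] %in%
                     strsplit(lt[pairs$b[i]], "")[[1]])
      expect_identical(share, pairs$p[i] >= 0.05)
    }
  }
})

test_that("zonal means agree with an independent group-by oracle", {
  set.seed(21)
  surf <- data.frame(lon = 0, lat = 0, area = 1, mean = rnorm(60),
                     zone = sample(c("a", "b", "c"), 60, TRUE))
  zs <- zonal_summary(surf, "zone", "mean")
  oracle <- groupby_mean_oracle(surf$mean, surf$zone)
  expect_equal(zs$summary$mean, unname(oracle[zs$summary$zone]),
               tolerance = 1e-10)
})

test_that("scenario re-prediction is null under a null perturbation", {
  d <- make_sf_data(200, seed = 22)
  m <- tune_and_fit(d, "sf", soil_fraction_features(),
                    grid = data.frame(ntree = 50, mtry = 4, nodesize = 5),
                    seed = 7, folds = 4)
  grid <- make_sf_data(40, seed = 23)
  grid$lon <- runif(40, 0, 10); grid$lat <- runif(40, 30, 40)
  grid$area_rice <- 1
  out <- scenario_reprediction(m, grid, list(null = grid, warm = within(
    grid, mat <- mat + 3)), "area_rice")
  expect_identical(names(out$scenarios), c("null", "warm"))
  expect_equal(out$scenarios$null$delta, rep(0, 40), tolerance = 1e-12)
})

test_that("perturbing a feature with no true effect barely moves predictions", {
  set.seed(24)
  n <- 400
  d <- make_sf_data(n, seed = 24)
  d$sf <- 100 * plogis(0.02 * (d$input_n - 90)) + rnorm(n, 0, 2) # mat-free
  m <- tune_and_fit(d, "sf", soil_fraction_features(),
                    grid = data.frame(ntree = 100, mtry = 6, nodesize = 5),
                    seed = 8, folds = 4)
  grid <- d[1:60, ]
  grid$lon <- runif(60, 0, 10); grid$lat <- runif(60, 30, 40)
  grid$area_rice <- 1
  warm <- grid; warm$mat <- warm$mat + 4
  out <- scenario_reprediction(m, grid, list(warm = warm), "area_rice")
  expect_lt(abs(mean(out$scenarios$warm$delta)), 1.5)
})
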