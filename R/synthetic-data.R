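#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study system: paired field trials,
#' a country-by-crop-by-year fertilizer/production panel with baseline
#' input intensities, and a gridded covariate stack. The generated world has
#' fully known ground truth (soil-derived uptake fractions, efficiency
#' functions, trend breakpoints), so each downstream stage can be validated
#' against it.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param n_sites number of paired field-trial observations.
#' @param n_countries number of reporting countries.
#' @param n_years length of the annual panel (default 58, emulating
#'   1961--2018).
#' @param crops character vector of distinct crop identifiers.
#' @param noise_sd_efficiency Gaussian noise SD added to generated
#'   efficiencies, percentage points.
#' @param spatial_range range (degrees) of the exponential spatial
#'   autocorrelation of the residual field on the covariate grid.
#' @param breakpoint_year year index (1-based) of the kink in the true
#'   efficiency trajectories; recycled over crops.
#' @param effect_coefficients named list of slopes of the true
#'   soil-fraction function (names `mat`, `map`, `ph`, `tn`, `input`).
#' @param missing_rate MCAR missingness rate applied to site covariates.
#' @param availability_n,availability_p probability that a site reports the
#'   nitrogen (phosphorus) pair; defaults reproduce the compiled database's
#'   imbalance (2354 N and 1006 P records out of 2919).
#' @param baseline_missing_rate fraction of baseline-intensity cells
#'   blanked to exercise gap filling.
#' @param resolution grid cell size in degrees.
#' @param lon_range,lat_range extent of the synthetic domain (degrees).
#' @return object of class `nue_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_sites = 2919L,
                             n_countries = 24L,
                             n_years = 58L,
                             crops = c("rice", "wheat", "maize", "soybean"),
                             noise_sd_efficiency = 5,
                             spatial_range = 5,
                             breakpoint_year = 15L,
                             effect_coefficients = list(
                               mat = 0.2, map = 0.0025, ph = 0.6,
                               tn = 1.0, input = -0.025),
                             missing_rate = 0.1,
                             availability_n = 2354 / 2919,
                             availability_p = 1006 / 2919,
                             baseline_missing_rate = 0.05,
                             resolution = 0.5,
                             lon_range = c(-10, 10),
                             lat_range = c(30, 50)) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_sites >= 1, n_countries >= 2, n_years >= 10,
            length(crops) >= 1, !anyDuplicated(crops),
            noise_sd_efficiency >= 0, spatial_range > 0,
            missing_rate >= 0, missing_rate < 1,
            resolution > 0)
  breakpoint_year <- rep_len(as.integer(breakpoint_year), length(crops))
  names(breakpoint_year) <- crops
  if (any(breakpoint_year < 3 | breakpoint_year > n_years - 3))
    stop("breakpoint_year must lie well inside 1..n_years", call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    n_countries = as.integer(n_countries), n_years = as.integer(n_years),
    crops = crops, noise_sd_efficiency = noise_sd_efficiency,
    spatial_range = spatial_range, breakpoint_year = breakpoint_year,
    effect_coefficients = effect_coefficients,
    missing_rate = missing_rate,
    availability_n = availability_n, availability_p = availability_p,
    baseline_missing_rate = baseline_missing_rate,
    resolution = resolution, lon_range = lon_range, lat_range = lat_range,
    start_year = 1961L
  ), class = "nue_generator_config")
}

#' Read / write a generator configuration as YAML
#'
#' @param config a `nue_generator_config`.
#' @param path file path.
#' @return `read_generator_config` returns a `nue_generator_config`.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$breakpoint_year <- as.list(x$breakpoint_year)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(generator_config, x[setdiff(names(x), "start_year")])
}

# Crop-typical fertilizer input intensities (kg ha^-1), shared by the
# trial and panel generators so trial inputs span the panel's range.
crop_base_intensity <- function(crops, nutrient = c("N", "P")) {
  nutrient <- match.arg(nutrient)
  base <- if (nutrient == "N")
    c(rice = 90, wheat = 100, maize = 110, soybean = 25)
  else
    c(rice = 15, wheat = 20, maize = 20, soybean = 10)
  out <- base[crops]
  out[is.na(out)] <- if (nutrient == "N") 80 else 15
  names(out) <- crops
  unname(out)
}

# Deterministic smooth covariate fields over the synthetic domain.
# All site- and grid-level covariates derive from these surfaces so that
# grid-based imputation and grid prediction are consistent with the sites.
covariate_fields <- function(lon, lat) {
  mat <- 28 - 0.6 * (lat - 30) + 1.5 * sin(lon / 3)
  map <- 900 + 25 * lon + 8 * (lat - 40) + 60 * cos(lat / 4)
  pet <- 1250 - 15 * (lat - 30) + 20 * sin(lon / 5)
  et <- pmin(0.65 * map, 0.8 * pet)
  ph <- 6.5 + 0.05 * (lat - 40) + 0.3 * sin(lon / 2.5)
  tn <- 1.5 + 0.35 * sin(lat / 2) + 0.1 * cos(lon / 3)
  tc <- 10 * tn + 2 + 0.5 * sin(lon / 4)
  tp <- 0.6 + 0.1 * cos(lat / 3)
  ap <- 15 + 6 * sin(lon / 4 + lat / 6)
  bd <- 1.35 + 0.08 * cos(lat / 5)
  sand <- 40 + 12 * sin(lon / 4)
  clay <- 30 - 6 * sin(lon / 4) + 3 * cos(lat / 6)
  silt <- 100 - sand - clay
  ind <- 12 + 4 * sin(lon / 6) # inorganic N deposition, kg ha-1
  ond <- 4 + 1.5 * cos(lat / 5)
  data.frame(mat = mat, map = map, pet = pet, et = et, ai = map / pet,
             ph = ph, tn = tn, tc = tc, tp = tp, ap = ap, bd = bd,
             sand = sand, silt = silt, clay = clay, ind = ind, ond = ond)
}

# True soil-derived uptake fraction (0..1) as a smooth monotone function of
# climate, soil and input intensity. `input` is the fertilizer intensity of
# the matching nutrient (kg ha^-1).
true_soil_fraction_fn <- function(cov, input, nutrient = c("N", "P"),
                                  coefs = list(mat = 0.2, map = 0.0025,
                                               ph = 0.6, tn = 1.0,
                                               input = -0.025)) {
  nutrient <- match.arg(nutrient)
  lin <- coefs$mat * (cov$mat - 22) + coefs$map * (cov$map - 900) +
    coefs$ph * (cov$ph - 6.5) + coefs$tn * (cov$tn - 1.5)
  if (nutrient == "N") {
    0.10 + 0.80 * stats::plogis(lin + coefs$input * (input - 90))
  } else {
    # P uptake leans more heavily on the soil pool
    0.35 + 0.60 * stats::plogis(lin + coefs$input * 4 * (input - 20))
  }
}

# Uptake-to-input ratio: with the soil fraction this fixes the true
# efficiency, NUE% = 100 * ratio * (1 - soil_fraction).
true_uptake_ratio_fn <- function(cov, input, tillage, nutrient = c("N", "P")) {
  nutrient <- match.arg(nutrient)
  if (nutrient == "N") {
    base <- 1.0 + 0.15 * tillage + 0.01 * (cov$ap - 15) - 0.002 * (input - 90)
  } else {
    base <- 1.1 + 0.12 * tillage + 0.012 * (cov$ap - 15) - 0.006 * (input - 20)
  }
  pmin(pmax(base, 0.3), 1.8)
}

true_efficiency_fn <- function(cov, input, tillage, nutrient,
                               coefs) {
  sf <- true_soil_fraction_fn(cov, input, nutrient, coefs)
  r <- true_uptake_ratio_fn(cov, input, tillage, nutrient)
  100 * r * (1 - sf)
}

#' Generate paired field-trial observations with known ground truth
#'
#' Draws sites over the synthetic domain, evaluates the deterministic
#' covariate surfaces plus site-level noise, and generates NUE/PUE as the
#' true efficiency function plus Gaussian noise (SD
#' `config$noise_sd_efficiency`), truncated below at zero. Fertilized and
#' control uptakes are emitted consistently with the noisy efficiency, so
#' recomputing the efficiency from uptake reproduces the generated value.
#' A `missing_rate` share of covariate cells is blanked completely at
#' random to exercise imputation, and per-nutrient availability rates
#' reproduce the N/P imbalance of compiled field databases.
#'
#' @param config a [generator_config()].
#' @return list with `observations` (data frame, one row per site-nutrient
#'   pair) and `truth` (functions and per-record true values).
#' @export
generate_point_observations <- function(config) {
  stopifnot(inherits(config, "nue_generator_config"))
  set.seed(config$seed)
  n <- config$n_sites
  lon <- stats::runif(n, config$lon_range[1], config$lon_range[2])
  lat <- stats::runif(n, config$lat_range[1], config$lat_range[2])
  cov <- covariate_fields(lon, lat)
  # site-level heterogeneity on top of the smooth surfaces
  cov$mat <- cov$mat + stats::rnorm(n, 0, 0.8)
  cov$map <- cov$map + stats::rnorm(n, 0, 50)
  cov$ph <- cov$ph + stats::rnorm(n, 0, 0.25)
  cov$tn <- pmax(cov$tn + stats::rnorm(n, 0, 0.15), 0.3)
  cov$tc <- pmax(10 * cov$tn + stats::rnorm(n, 0, 1.5), 2)
  cov$ap <- pmax(cov$ap + stats::rnorm(n, 0, 3), 1)
  cov$ai <- cov$map / cov$pet

  crop <- sample(config$crops, n, replace = TRUE)
  tillage <- stats::rbinom(n, 1, 0.4) # 1 = no-till / conservation
  duration <- sample(1:20, n, replace = TRUE)
  # inputs lognormal around crop-typical intensities so trials span the
  # low historical intensities the panel reconstruction must predict for
  input_n <- crop_base_intensity(crop, "N") * exp(stats::rnorm(n, -0.25, 0.55))
  input_p <- crop_base_intensity(crop, "P") * exp(stats::rnorm(n, -0.25, 0.55))
  input_k <- stats::runif(n, 20, 80)
  fat <- sample(c("inorganic", "organic", "combined"), n, TRUE, c(.6, .1, .3))
  faf <- sample(1:4, n, TRUE)
  fap <- sample(c("surface", "deep", "mixed", "foliar"), n, TRUE)
  im <- sample(c("flooding", "intermittent", "drip", "none"), n, TRUE)
  gdppc <- exp(stats::rnorm(n, 9, 0.8))
  pd <- exp(stats::rnorm(n, 4.5, 1))
  ur <- pmin(pmax(stats::rnorm(n, 55, 15), 5), 95)
  mys <- pmin(pmax(stats::rnorm(n, 9, 2.5), 1), 15)

  coefs <- config$effect_coefficients
  sf_n <- true_soil_fraction_fn(cov, input_n, "N", coefs)
  sf_p <- true_soil_fraction_fn(cov, input_p, "P", coefs)
  r_n <- true_uptake_ratio_fn(cov, input_n, tillage, "N")
  r_p <- true_uptake_ratio_fn(cov, input_p, tillage, "P")
  true_nue <- 100 * r_n * (1 - sf_n)
  true_pue <- 100 * r_p * (1 - sf_p)

  sd_e <- config$noise_sd_efficiency
  nue <- pmax(true_nue + stats::rnorm(n, 0, sd_e), 0)
  pue <- pmax(true_pue + stats::rnorm(n, 0, sd_e), 0)

  # uptakes consistent with the noisy efficiencies
  u_fert_n <- r_n * input_n
  u_ctrl_n <- pmax(u_fert_n - nue / 100 * input_n, 0)
  u_fert_p <- r_p * input_p
  u_ctrl_p <- pmax(u_fert_p - pue / 100 * input_p, 0)

  avail_n <- stats::runif(n) < config$availability_n
  avail_p <- stats::runif(n) < config$availability_p
  nue[!avail_n] <- NA; u_fert_n[!avail_n] <- NA; u_ctrl_n[!avail_n] <- NA
  pue[!avail_p] <- NA; u_fert_p[!avail_p] <- NA; u_ctrl_p[!avail_p] <- NA

  obs <- data.frame(
    site = seq_len(n), latitude = lat, longitude = lon, crop = crop,
    cov,
    tillage = tillage, duration = duration,
    input_n = input_n, input_p = input_p, input_k = input_k,
    fat = fat, faf = faf, fap = fap, im = im,
    gdppc = gdppc, pd = pd, ur = ur, mys = mys,
    field_control = TRUE,
    nue = nue, pue = pue,
    u_fert_n = u_fert_n, u_ctrl_n = u_ctrl_n,
    u_fert_p = u_fert_p, u_ctrl_p = u_ctrl_p,
    stringsAsFactors = FALSE
  )

  # MCAR missingness on environmental covariates only
  if (config$missing_rate > 0) {
    miss_vars <- c("mat", "map", "pet", "et", "ai", "ph", "tn", "tc", "tp",
                   "ap", "bd", "sand", "silt", "clay", "ind", "ond")
    for (v in miss_vars) {
      hole <- stats::runif(n) < config$missing_rate
      obs[[v]][hole] <- NA
    }
  }

  truth <- list(
    true_soil_fraction_fn = function(cov, input, nutrient)
      true_soil_fraction_fn(cov, input, nutrient, coefs),
    true_efficiency_fn = function(cov, input, tillage, nutrient)
      true_efficiency_fn(cov, input, tillage, nutrient, coefs),
    soil_fraction_n = 100 * sf_n, soil_fraction_p = 100 * sf_p,
    nue = true_nue, pue = true_pue,
    true_path_signs = c(climate = -1, management = 1)
  )
  list(observations = obs, truth = truth)
}

# Piecewise-linear trajectory with one kink (year index bp, 1-based).
piecewise_trajectory <- function(t, start, slope1, slope2, bp) {
  start + slope1 * (t - 1) + pmax(t - bp, 0) * (slope2 - slope1)
}

#' Generate the country-by-crop-by-year panel and baseline intensities
#'
#' Builds an internally consistent fertilizer/production panel: true input
#' intensities are a per-country baseline times a global year scalar, so
#' national totals equal the aggregate of intensity times area exactly and
#' the intensity reconciliation has a known answer. Production is backed out
#' from a piecewise-linear true efficiency trajectory (kink at
#' `config$breakpoint_year`) together with the true soil-derived fractions,
#' then perturbed with multiplicative noise; the efficiency series implied
#' by the final (noisy) panel is stored in the ground truth.
#'
#' @param config a [generator_config()].
#' @return list with `panel`, `baseline` (with `baseline_missing_rate` cells
#'   blanked and the complete table in `truth`), `contents`, `countries`,
#'   and `truth` (true intensities, soil fractions, implied annual
#'   NUE/PUE series, breakpoints).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "nue_generator_config"))
  set.seed(config$seed + 1L)
  crops <- config$crops
  n_co <- config$n_countries
  n_yr <- config$n_years
  years <- config$start_year + seq_len(n_yr) - 1L

  # country centroids on the domain; 5 synthetic regions by longitude strip
  co_lon <- stats::runif(n_co, config$lon_range[1], config$lon_range[2])
  co_lat <- stats::runif(n_co, config$lat_range[1], config$lat_range[2])
  region <- paste0("R", 1 + (findInterval(co_lon,
    seq(config$lon_range[1], config$lon_range[2], length.out = 6)[2:5])))
  developed <- region %in% c("R1", "R2")
  countries <- data.frame(country = sprintf("C%02d", seq_len(n_co)),
                          lon = co_lon, lat = co_lat, region = region,
                          developed = developed, stringsAsFactors = FALSE)
  co_cov <- covariate_fields(co_lon, co_lat)

  contents <- crop_nutrient_contents(crops)

  cells <- expand.grid(country = countries$country, crop = crops,
                       stringsAsFactors = FALSE)
  co_factor <- exp(stats::rnorm(nrow(cells), 0, 0.3))
  int_n0 <- crop_base_intensity(cells$crop, "N") * co_factor
  int_p0 <- crop_base_intensity(cells$crop, "P") * co_factor
  area0 <- exp(stats::rnorm(nrow(cells), log(2e5), 0.6)) # ha

  # baseline intensities: period factors for the three reference years
  period_factor <- c(`1990` = 0.85, `1999` = 1.0, `2018` = 1.2)
  baseline_full <- do.call(rbind, lapply(names(period_factor), function(by) {
    data.frame(country = cells$country, crop = cells$crop,
               baseline_year = as.integer(by),
               intensity_n = int_n0 * period_factor[[by]],
               intensity_p = int_p0 * period_factor[[by]],
               fill_source = "reported", stringsAsFactors = FALSE)
  }))

  # global year scalar: fertilizer growth that decelerates at year 25;
  # within each baseline period it is renormalised so intensities in a
  # baseline year equal that year's baseline table exactly
  t <- seq_len(n_yr)
  s_at <- function(tt) piecewise_trajectory(tt, 0.45, 0.022, 0.009, 25L)

  panel <- vector("list", n_yr)
  true_int <- vector("list", n_yr)
  for (i in t) {
    by <- map_year_to_baseline(years[i])
    pf <- period_factor[[as.character(by)]]
    s_i <- s_at(i) / s_at(by - config$start_year + 1L)
    area <- area0 * (1 + 0.004 * (i - 1))
    intensity_n <- int_n0 * pf * s_i
    intensity_p <- int_p0 * pf * s_i
    true_int[[i]] <- data.frame(country = cells$country, crop = cells$crop,
                                year = years[i], intensity_n = intensity_n,
                                intensity_p = intensity_p, area = area,
                                stringsAsFactors = FALSE)
    panel[[i]] <- data.frame(country = cells$country, crop = cells$crop,
                             year = years[i], area = area,
                             stringsAsFactors = FALSE)
  }
  true_int <- do.call(rbind, true_int)
  panel <- do.call(rbind, panel)

  # national (global) totals, tonnes, by construction
  tot <- stats::aggregate(cbind(n_kg = intensity_n * area,
                                p_kg = intensity_p * area) ~ year,
                          data = true_int, FUN = sum)
  panel$total_n <- kg_to_t(tot$n_kg[match(panel$year, tot$year)])
  panel$total_p <- kg_to_t(tot$p_kg[match(panel$year, tot$year)])

  # true soil fractions per country x crop x year (soil static, input varies)
  ti <- true_int
  cov_i <- co_cov[match(ti$country, countries$country), ]
  coefs <- config$effect_coefficients
  ti$sf_n <- true_soil_fraction_fn(cov_i, ti$intensity_n, "N", coefs)
  ti$sf_p <- true_soil_fraction_fn(cov_i, ti$intensity_p, "P", coefs)

  # back out production from target efficiency trajectories
  bp <- config$breakpoint_year
  prod <- vector("list", length(crops))
  for (k in seq_along(crops)) {
    cr <- crops[k]
    tgt_nue <- piecewise_trajectory(t, 46, -0.5, 0.3, bp[[cr]])
    tgt_pue <- piecewise_trajectory(t, 34, -0.4, 0.25, bp[[cr]])
    rows <- ti[ti$crop == cr, ]
    cc <- contents[contents$crop == cr, ]
    upt_n <- cc$n_grain + cc$residue_grain_ratio * cc$n_residue # t nutrient / t grain
    f_n <- rows$intensity_n * rows$area / 1000 # t
    spl <- split(seq_len(nrow(rows)), rows$year)
    q <- numeric(nrow(rows))
    for (y in seq_along(spl)) {
      id <- spl[[y]]
      w <- f_n[id] / sum(f_n[id])
      sf_w <- sum(w * rows$sf_n[id])
      u_tot <- tgt_nue[y] / 100 * sum(f_n[id]) / (1 - sf_w)
      q[id] <- u_tot * w / upt_n
    }
    q <- q * exp(stats::rnorm(length(q), 0, 0.02))
    rows$production <- q
    prod[[k]] <- rows[, c("country", "crop", "year", "production")]
  }
  prod <- do.call(rbind, prod)
  key <- function(d) paste(d$country, d$crop, d$year)
  panel$production <- prod$production[match(key(panel), key(prod))]

  # implied annual efficiency series from the final panel + true fractions
  implied <- implied_series(panel, true_int, ti, contents)

  # blank a share of baseline cells to exercise gap filling
  baseline <- baseline_full
  if (config$baseline_missing_rate > 0) {
    hole <- stats::runif(nrow(baseline)) < config$baseline_missing_rate
    baseline$intensity_n[hole] <- NA
    baseline$intensity_p[hole] <- NA
    baseline$fill_source[hole] <- NA
  }

  truth <- list(true_intensities = true_int, soil_fractions = ti,
                baseline_full = baseline_full,
                implied_series = implied,
                true_breakpoints = bp,
                countries = countries)
  list(panel = panel, baseline = baseline, contents = contents,
       countries = countries, truth = truth)
}

# Annual efficiency series implied by a panel given known intensities and
# soil fractions (the generator-side mirror of the reconstruction).
implied_series <- function(panel, intensities, sf, contents) {
  key <- function(d) paste(d$country, d$crop, d$year)
  m <- match(key(panel), key(intensities))
  stopifnot(!anyNA(m))
  p <- panel
  p$intensity_n <- intensities$intensity_n[m]
  p$intensity_p <- intensities$intensity_p[m]
  p$sf_n <- sf$sf_n[match(key(p), key(sf))]
  p$sf_p <- sf$sf_p[match(key(p), key(sf))]
  cc <- contents[match(p$crop, contents$crop), ]
  un <- p$production * (cc$n_grain + cc$residue_grain_ratio * cc$n_residue)
  up <- p$production * (cc$p_grain + cc$residue_grain_ratio * cc$p_residue)
  out <- lapply(split(seq_len(nrow(p)), list(p$crop, p$year), drop = TRUE),
                function(id) {
    f_n <- sum(p$intensity_n[id] * p$area[id]) / 1000
    f_p <- sum(p$intensity_p[id] * p$area[id]) / 1000
    u_n <- sum(un[id]); u_p <- sum(up[id])
    u0_n <- sum(un[id] * p$sf_n[id]); u0_p <- sum(up[id] * p$sf_p[id])
    data.frame(crop = p$crop[id[1]], year = p$year[id[1]],
               nue = 100 * (u_n - u0_n) / f_n,
               pue = 100 * (u_p - u0_p) / f_p)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$crop, out$year), ]
  rownames(out) <- NULL
  out
}

#' Crop nutrient contents and residue-grain ratios
#'
#' Typical whole-plant composition for the four major crops: grain and
#' residue N and P contents as mass fractions of dry weight and the
#' residue-to-grain mass ratio used to scale grain production to
#' whole-plant uptake. Unknown crops fall back to cereal-like values.
#'
#' @param crops character vector of crop names.
#' @return data frame with columns `crop`, `n_grain`, `n_residue`,
#'   `p_grain`, `p_residue`, `residue_grain_ratio` (contents as fractions).
#' @export
crop_nutrient_contents <- function(crops = c("rice", "wheat", "maize",
                                             "soybean")) {
  ref <- data.frame(
    crop = c("rice", "wheat", "maize", "soybean"),
    n_grain = c(0.012, 0.020, 0.013, 0.060),
    n_residue = c(0.006, 0.006, 0.008, 0.015),
    p_grain = c(0.0025, 0.0035, 0.0028, 0.0055),
    p_residue = c(0.0010, 0.0008, 0.0012, 0.0015),
    residue_grain_ratio = c(1.0, 1.3, 1.2, 1.5),
    stringsAsFactors = FALSE
  )
  out <- ref[match(crops, ref$crop), ]
  fallback <- is.na(out$crop)
  if (any(fallback)) {
    out[fallback, -1] <- ref[ref$crop == "wheat", -1]
    out$crop[fallback] <- crops[fallback]
  }
  rownames(out) <- NULL
  out
}

# Gaussian random field with exponential covariance on scattered points.
# Dense Cholesky; intended for desk-scale grids (a few thousand cells).
exponential_field <- function(lon, lat, range, sd) {
  n <- length(lon)
  d <- as.matrix(stats::dist(cbind(lon, lat)))
  k <- sd^2 * exp(-d / range)
  diag(k) <- diag(k) + 1e-8
  l <- chol(k)
  as.numeric(crossprod(l, stats::rnorm(n)))
}

#' Generate the gridded covariate stack with spatial residual field
#'
#' Evaluates the deterministic covariate surfaces on a regular lon/lat grid
#' (cell-centre registration, half-open cells), adds per-crop nonnegative
#' planted-area layers, a 5-class climate-zone raster, a country raster
#' (nearest country centroid), and management intensity layers. The true
#' efficiency on the grid is the point-scale efficiency function plus a
#' spatially autocorrelated residual field (exponential covariance, range
#' `config$spatial_range`), so kriging residual correction has signal to
#' recover.
#'
#' @param config a [generator_config()].
#' @param countries optional country table from [generate_panel()]; if
#'   missing, country centroids are drawn from the config seed.
#' @return list with `grid` (data frame, one row per cell) and `truth`
#'   (per-cell true NUE/PUE with and without the residual field).
#' @export
generate_covariate_grid <- function(config, countries = NULL) {
  stopifnot(inherits(config, "nue_generator_config"))
  set.seed(config$seed + 2L)
  res <- config$resolution
  lon_c <- seq(config$lon_range[1] + res / 2, config$lon_range[2] - res / 2,
               by = res)
  lat_c <- seq(config$lat_range[1] + res / 2, config$lat_range[2] - res / 2,
               by = res)
  g <- expand.grid(lon = lon_c, lat = lat_c)
  cov <- covariate_fields(g$lon, g$lat)
  n <- nrow(g)

  if (is.null(countries)) {
    countries <- data.frame(
      country = sprintf("C%02d", seq_len(config$n_countries)),
      lon = stats::runif(config$n_countries, config$lon_range[1],
                         config$lon_range[2]),
      lat = stats::runif(config$n_countries, config$lat_range[1],
                         config$lat_range[2]), stringsAsFactors = FALSE)
  }
  nearest <- apply(outer(g$lon, countries$lon, "-")^2 +
                     outer(g$lat, countries$lat, "-")^2, 1, which.min)
  country <- countries$country[nearest]

  # 5-class synthetic climate zone by temperature bands
  zone <- cut(cov$mat, breaks = c(-Inf, 16, 19, 22, 25, Inf),
              labels = c("polar", "cold", "temperate", "arid", "tropical"))

  input_n <- pmax(90 + 0.4 * (cov$mat - 22) * 10 + 15 * sin(g$lon / 3), 5)
  input_p <- pmax(18 + 2.5 * sin(g$lat / 4) + 0.05 * (cov$map - 900) / 10, 1)
  tillage <- as.integer(stats::runif(n) < 0.4)

  grid <- data.frame(g, cov, zone = as.character(zone), country = country,
                     input_n = input_n, input_p = input_p, tillage = tillage,
                     stringsAsFactors = FALSE)
  for (cr in config$crops) {
    pa <- 3000 * pmax(0, sin((g$lon + 10) / 7 + match(cr, config$crops)) +
                        0.6 * cos(g$lat / 5) + stats::rnorm(n, 0.2, 0.4))
    grid[[paste0("area_", cr)]] <- pa
  }

  coefs <- config$effect_coefficients
  resid_n <- exponential_field(g$lon, g$lat, config$spatial_range, 3)
  resid_p <- exponential_field(g$lon, g$lat, config$spatial_range, 3)
  smooth_nue <- true_efficiency_fn(cov, input_n, tillage, "N", coefs)
  smooth_pue <- true_efficiency_fn(cov, input_p, tillage, "P", coefs)
  truth <- list(nue_smooth = smooth_nue, pue_smooth = smooth_pue,
                nue = smooth_nue + resid_n, pue = smooth_pue + resid_p,
                residual_n = resid_n, residual_p = resid_p)
  attr(grid, "resolution") <- res
  attr(grid, "registration") <- "cell-centre, half-open [west, east)"
  list(grid = grid, truth = truth)
}

#' Perturbed covariate grids for climate scenarios
#'
#' Applies additive mean-annual-temperature and multiplicative
#' precipitation deltas to a base grid, one perturbed copy per scenario
#' label, leaving every other layer untouched.
#'
#' @param config a [generator_config()].
#' @param grid base covariate grid.
#' @param deltas named list of `c(mat = <degC>, map = <fraction>)` per
#'   scenario; defaults emulate low/intermediate/high-forcing pathways.
#' @return named list of perturbed grids.
#' @export
generate_scenario_deltas <- function(config, grid,
                                     deltas = list(
                                       SSP126 = c(mat = 1.0, map = 0.02),
                                       SSP245 = c(mat = 2.2, map = 0.00),
                                       SSP585 = c(mat = 4.4, map = -0.04))) {
  stopifnot(is.data.frame(grid), all(c("mat", "map") %in% names(grid)))
  lapply(deltas, function(d) {
    g <- grid
    g$mat <- g$mat + d[["mat"]]
    g$map <- g$map * (1 + d[["map"]])
    g$ai <- g$map / g$pet
    g
  })
}

#' Latent-structured data for path-model validation
#'
#' Generates observations from an explicit latent-variable model: four
#' exogenous latents (climate, soil, management, socio-economy) each with
#' three manifest indicators (loading 0.9 plus noise), and an efficiency
#' outcome driven by configured path signs. Used to verify that path-model
#' estimation recovers the configured direction of each effect.
#'
#' @param n number of observations.
#' @param seed integer seed.
#' @param path_coefficients named numeric vector of true structural
#'   coefficients on the standardized latents.
#' @return list with `data` (manifest variables plus `efficiency`) and
#'   `truth` (`path_coefficients`, `true_path_signs`).
#' @export
generate_latent_data <- function(n = 1000, seed = 1,
                                 path_coefficients = c(climate = -0.45,
                                                       soil = 0.25,
                                                       management = 0.5,
                                                       socioeconomy = 0.15)) {
  set.seed(seed)
  blocks <- names(path_coefficients)
  lv <- sapply(blocks, function(b) stats::rnorm(n))
  data <- list()
  for (b in blocks) {
    for (j in 1:3) {
      data[[paste0(b, "_", j)]] <- 0.9 * lv[, b] + stats::rnorm(n, 0, sqrt(1 - 0.81))
    }
  }
  eta <- as.numeric(lv %*% path_coefficients)
  data$efficiency <- eta + stats::rnorm(n, 0, 0.6)
  list(data = as.data.frame(data),
       truth = list(path_coefficients = path_coefficients,
                    true_path_signs = sign(path_coefficients)))
}

#' Simulate an annual series with one trend breakpoint
#'
#' Piecewise-linear mean with a single kink plus Gaussian noise; the
#' workhorse for breakpoint-recovery experiments.
#'
#' @param n series length.
#' @param breakpoint kink position (index on `1:n`).
#' @param slopes length-2 vector of pre/post-break slopes.
#' @param intercept value at `x = 1`.
#' @param sd noise SD.
#' @param seed optional seed.
#' @return data frame with `x` and `y`.
#' @export
simulate_breakpoint_series <- function(n = 58, breakpoint = 14,
                                       slopes = c(-0.5, 0.3),
                                       intercept = 50, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(n)
  mu <- piecewise_trajectory(x, intercept, slopes[1], slopes[2], breakpoint)
  data.frame(x = x, y = mu + stats::rnorm(n, 0, sd))
}
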