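#' Pipeline run configuration
#'
#' Declarative configuration for an end-to-end synthetic run: the
#' generator block, per-stage seeds, stage toggles, the random-forest
#' tuning grid, and an optional output directory for CSV/JSON artefacts.
#'
#' @param synth a [generator_config()] (or list of its arguments).
#' @param seed global seed; stage seeds derive from it unless given.
#' @param stages named logical toggles for the optional stages
#'   (`trends`, `maps`, `drivers`, `assess`, `scenarios`).
#' @param rf_grid hyper-parameter grid for the pipeline's forest fits; the
#'   default single combination keeps a full run inside desk-scale
#'   runtimes (the tuning surface is exercised by [tune_and_fit()]
#'   directly).
#' @param per_crop_sf fit soil-fraction models per crop (pooled fallback
#'   below `min_crop_n` rows).
#' @param min_crop_n minimum rows for a per-crop model.
#' @param max_krige_obs observation cap for the kriging correction.
#' @param strict_paper use as-printed variants (MAT/PET aridity index).
#' @param outdir optional output directory.
#' @return object of class `nue_run_config`.
#' @export
pipeline_config <- function(synth = generator_config(),
                            seed = 1,
                            stages = c(trends = TRUE, maps = TRUE,
                                       drivers = TRUE, assess = TRUE,
                                       scenarios = TRUE),
                            rf_grid = data.frame(ntree = 300, mtry = 4,
                                                 nodesize = 5),
                            per_crop_sf = TRUE, min_crop_n = 100,
                            max_krige_obs = 300,
                            strict_paper = FALSE,
                            outdir = NULL) {
  if (!inherits(synth, "nue_generator_config"))
    synth <- do.call(generator_config, synth)
  defaults <- c(trends = TRUE, maps = TRUE, drivers = TRUE, assess = TRUE,
                scenarios = TRUE)
  defaults[names(stages)] <- stages
  structure(list(synth = synth, seed = as.integer(seed), stages = defaults,
                 rf_grid = rf_grid, per_crop_sf = per_crop_sf,
                 min_crop_n = min_crop_n, max_krige_obs = max_krige_obs,
                 strict_paper = strict_paper, outdir = outdir),
            class = "nue_run_config")
}

#' Validate a run configuration
#'
#' Schema check of the configuration and of any referenced input files:
#' stage toggles named correctly, seeds present, tuning grid columns
#' complete. Returns a human-readable report rather than stopping at the
#' first problem.
#'
#' @param config a [pipeline_config()] (or list).
#' @return list with `ok` (logical) and `errors` (character).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  if (!inherits(config, "nue_run_config"))
    errors <- c(errors, "config is not a `nue_run_config`")
  else {
    if (!inherits(config$synth, "nue_generator_config"))
      errors <- c(errors, "missing or invalid `synth` generator block")
    if (is.null(config$seed) || !is.finite(config$seed))
      errors <- c(errors, "missing global `seed`")
    need <- c("ntree", "mtry", "nodesize")
    if (!all(need %in% names(config$rf_grid)))
      errors <- c(errors, paste("rf_grid lacks column(s):",
                                paste(setdiff(need, names(config$rf_grid)),
                                      collapse = ", ")))
    bad <- setdiff(names(config$stages),
                   c("trends", "maps", "drivers", "assess", "scenarios"))
    if (length(bad))
      errors <- c(errors, paste("unknown stage toggle(s):",
                                paste(bad, collapse = ", ")))
  }
  list(ok = length(errors) == 0, errors = errors)
}

# long-format observation table (one row per site x nutrient) for
# screening and soil-fraction accounting
observations_long <- function(obs) {
  base <- obs[, setdiff(names(obs), c("nue", "pue", "u_fert_n", "u_ctrl_n",
                                      "u_fert_p", "u_ctrl_p"))]
  n <- cbind(base, nutrient = "N", efficiency = obs$nue,
             u_fert = obs$u_fert_n, u_ctrl = obs$u_ctrl_n,
             input = obs$input_n)
  p <- cbind(base, nutrient = "P", efficiency = obs$pue,
             u_fert = obs$u_fert_p, u_ctrl = obs$u_ctrl_p,
             input = obs$input_p)
  rbind(n, p)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: synthesize, screen/account,
#' soil-fraction modelling, panel reconstruction, then the toggled stages
#' (trend fits and group contrasts; grid mapping with kriging correction;
#' driver analysis; quadrant/surplus assessment; climate-scenario
#' re-prediction). Identical configurations give identical results; a run
#' manifest records seeds, record counts in/out per stage (screening
#' exclusions by reason) and per-stage runtimes. When `config$outdir` is
#' set, tables are written as CSV and the manifest as JSON.
#'
#' @param config a [pipeline_config()].
#' @return list with the per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  v <- validate_config(config)
  if (!v$ok) stop("invalid config: ", paste(v$errors, collapse = "; "),
                  call. = FALSE)
  stages <- config$stages
  manifest <- list(seed = config$seed, stages = as.list(stages),
                   timings = list(), counts = list())
  res <- list(config = config)
  tic <- function() proc.time()[["elapsed"]]
  mark <- function(name, t0) manifest$timings[[name]] <<- round(tic() - t0, 2)

  ## synthesize -------------------------------------------------------
  t0 <- tic()
  synth_pts <- generate_point_observations(config$synth)
  synth_pan <- generate_panel(config$synth)
  synth_grid <- generate_covariate_grid(config$synth,
                                        countries = synth_pan$countries)
  res$points <- synth_pts
  res$panel_data <- synth_pan
  res$grid_data <- synth_grid
  mark("synthesize", t0)

  if (config$strict_paper) { # as-printed aridity index variant
    strict_ai <- function(mat, pet) {
      ok <- is.finite(pet) & pet > 0 & is.finite(mat)
      out <- rep(NA_real_, length(pet))
      out[ok] <- aridity_index(pet = pet[ok], mat = mat[ok], strict = TRUE)
      out # missing cells fall to grid imputation downstream
    }
    synth_grid$grid$ai <- strict_ai(synth_grid$grid$mat, synth_grid$grid$pet)
    synth_pts$observations$ai <- strict_ai(synth_pts$observations$mat,
                                           synth_pts$observations$pet)
  }

  ## screen / account -------------------------------------------------
  t0 <- tic()
  long <- observations_long(synth_pts$observations)
  long <- impute_covariates(long, synth_grid$grid)
  screened <- screen_observations(long)
  kept <- screened[screened$keep, ]
  # soil-derived fraction per record (efficiency as a fraction)
  kept$sf <- as.numeric(soil_fraction(kept$u_fert,
                                      kept$efficiency_used / 100,
                                      kept$input))
  manifest$counts$screened_in <- nrow(screened)
  manifest$counts$screened_kept <- nrow(kept)
  manifest$counts$exclusions <- as.list(table(
    screened$reason[!screened$keep]))
  res$observations <- kept
  res$exclusion_report <- screened[!screened$keep,
                                   c("site", "nutrient", "reason")]
  mark("account", t0)

  ## soil-fraction models ---------------------------------------------
  t0 <- tic()
  feats <- soil_fraction_features()
  fit_sf <- function(d) tune_and_fit(d, "sf", feats, grid = config$rf_grid,
                                     seed = config$seed)
  sf_models <- list()
  for (nu in c("N", "P")) {
    dn <- kept[kept$nutrient == nu & !is.na(kept$sf), ]
    models <- list()
    if (config$per_crop_sf) {
      for (cr in config$synth$crops) {
        dcr <- dn[dn$crop == cr, ]
        models[[cr]] <- if (nrow(dcr) >= config$min_crop_n) fit_sf(dcr)
                        else NULL
      }
    }
    models[["pooled"]] <- fit_sf(dn)
    sf_models[[nu]] <- models
  }
  res$sf_models <- sf_models
  mark("sf_models", t0)

  ## reconstruct ------------------------------------------------------
  t0 <- tic()
  pan <- synth_pan
  baseline <- fill_baseline_gaps(pan$baseline, pan$panel, pan$countries)
  intens <- adjust_intensities(baseline, pan$panel)
  # country covariates from the nearest grid cell to each centroid
  cc <- pan$countries
  cov_frame <- data.frame(latitude = cc$lat, longitude = cc$lon)
  for (f in setdiff(feats, c("input_n", "input_p"))) cov_frame[[f]] <- NA_real_
  cov_frame <- impute_covariates(cov_frame, synth_grid$grid,
                                 vars = setdiff(feats, c("input_n", "input_p")))
  cov_frame$country <- cc$country
  pred_frame <- merge(intens, cov_frame, by = "country")
  pred_frame$input_n <- pred_frame$intensity_n
  pred_frame$input_p <- pred_frame$intensity_p
  sf_pred <- pred_frame[, c("country", "crop", "year")]
  for (nu in c("N", "P")) {
    col <- if (nu == "N") "sf_n" else "sf_p"
    sf_pred[[col]] <- NA_real_
    for (cr in config$synth$crops) {
      m <- sf_models[[nu]][[cr]]
      if (is.null(m)) m <- sf_models[[nu]][["pooled"]]
      sel <- pred_frame$crop == cr
      sf_pred[[col]][sel] <- predict_with_uncertainty(
        m, pred_frame[sel, ], clip = c(0, 100))$mean
    }
  }
  series <- lapply(config$synth$crops, function(cr)
    reconstruct_series(pan$panel, intens, pan$contents, sf_pred, cr))
  names(series) <- config$synth$crops
  res$baseline <- baseline
  res$intensities <- intens
  res$soil_fraction_predictions <- sf_pred
  res$series <- series
  mark("reconstruct", t0)

  ## trends -----------------------------------------------------------
  if (stages[["trends"]]) {
    t0 <- tic()
    yr0 <- config$synth$start_year
    fits <- list(); contrasts <- list()
    for (cr in config$synth$crops) {
      s <- series[[cr]]
      for (vn in c("nue", "pue")) {
        f <- fit_segmented(s$year - yr0 + 1, s[[vn]])
        fits[[paste(cr, vn, sep = ".")]] <- f
        contrasts[[paste(cr, vn, sep = ".")]] <- tryCatch(
          pre_post_break_contrast(s$year - yr0 + 1, s[[vn]], f),
          error = function(e) NULL)
      }
    }
    # developed vs developing annual efficiency contrast
    dev_co <- pan$countries$country[pan$countries$developed]
    group_series <- function(countries) {
      sub <- pan$panel[pan$panel$country %in% countries, ]
      do.call(rbind, lapply(config$synth$crops, function(cr)
        reconstruct_series(sub, intens[intens$country %in% countries, ],
                           pan$contents,
                           sf_pred[sf_pred$country %in% countries, ], cr)))
    }
    s_dev <- group_series(dev_co)
    s_dvg <- group_series(setdiff(pan$countries$country, dev_co))
    res$group_contrast <- list(
      nue = compare_groups(s_dev$nue, s_dvg$nue),
      pue = compare_groups(s_dev$pue, s_dvg$pue))
    res$trend_fits <- fits
    res$break_contrasts <- contrasts
    mark("trends", t0)
  }

  ## maps -------------------------------------------------------------
  if (stages[["maps"]]) {
    t0 <- tic()
    grid <- synth_grid$grid
    eff_feats <- c(feats, "tillage")
    surfaces <- list()
    for (nu in c("N", "P")) {
      eff_col <- if (nu == "N") "nue" else "pue"
      dn <- kept[kept$nutrient == nu, ]
      dn[[eff_col]] <- dn$efficiency_used
      for (cr in config$synth$crops) {
        dcr <- dn[dn$crop == cr, ]
        if (nrow(dcr) < config$min_crop_n) dcr <- dn
        model <- tune_and_fit(dcr, eff_col, eff_feats,
                              grid = config$rf_grid, seed = config$seed)
        surf <- predict_grid(model, grid, paste0("area_", cr))
        obs_pred <- predict_with_uncertainty(model, dcr)$mean
        obs <- data.frame(lon = dcr$longitude, lat = dcr$latitude,
                          observed = dcr[[eff_col]], predicted = obs_pred)
        if (nrow(obs) > config$max_krige_obs) {
          set.seed(config$seed)
          obs <- obs[sample.int(nrow(obs), config$max_krige_obs), ]
        }
        kc <- suppressWarnings(
          krige_residual_correction(surf, obs, loo = FALSE))
        surf2 <- kc$surface
        surf2$zone <- grid$zone[match(paste(surf2$lon, surf2$lat),
                                      paste(grid$lon, grid$lat))]
        surfaces[[paste(cr, tolower(nu), sep = ".")]] <-
          list(model = model, surface = surf2,
               variogram = kc$variogram,
               profile = latitudinal_profile(surf2, "corrected"),
               zones = zonal_summary(surf2, "zone", "corrected"))
      }
    }
    res$surfaces <- surfaces
    mark("maps", t0)
  }

  ## drivers ----------------------------------------------------------
  if (stages[["drivers"]]) {
    t0 <- tic()
    covs <- c("mat", "map", "et", "ai", "ind", "ond", "sand", "silt",
              "clay", "bd", "ph", "tc", "tn", "tp", "ap", "tillage",
              "duration", "input_n", "input_p", "input_k",
              "gdppc", "pd", "ur", "mys")
    wide <- kept
    wide$eff <- wide$efficiency_used
    corr <- spearman_bh(wide, "eff", covs, by = "nutrient")
    blocks <- list(climate = c("mat", "pet"), soil = c("tc", "tn"),
                   management = "input_n", socioeconomy = "gdppc",
                   efficiency = "eff")
    paths <- list(efficiency = c("climate", "soil", "management",
                                 "socioeconomy"))
    pls <- fit_plspm(wide[wide$nutrient == "N", ], blocks, paths,
                     bootstrap_n = 100, seed = config$seed)
    res$correlations <- corr
    res$path_model <- pls
    mark("drivers", t0)
  }

  ## assessment -------------------------------------------------------
  if (stages[["assess"]] && stages[["maps"]]) {
    t0 <- tic()
    grid <- synth_grid$grid
    assess <- list()
    for (cr in config$synth$crops) {
      sn <- res$surfaces[[paste(cr, "n", sep = ".")]]$surface
      sp <- res$surfaces[[paste(cr, "p", sep = ".")]]$surface
      cat_ <- classify_quadrants(sn$corrected, sp$corrected)
      props <- area_proportions(cat_, sn$area)
      cell_idx <- match(paste(sn$lon, sn$lat),
                        paste(grid$lon, grid$lat))
      sp_n <- surplus(sn$corrected, grid$input_n[cell_idx], sn$area,
                      grid$country[cell_idx])
      sp_p <- surplus(sp$corrected, grid$input_p[cell_idx], sp$area,
                      grid$country[cell_idx])
      ratio <- efficiency_ratio(sn$corrected, sp$corrected)
      prod_final <- stats::aggregate(
        production ~ country,
        data = pan$panel[pan$panel$crop == cr &
                           pan$panel$year == max(pan$panel$year), ], sum)
      sp_n$surplus_per_yield <- surplus_per_yield(
        sp_n$load_t,
        prod_final$production[match(sp_n$unit, prod_final$country)])
      assess[[cr]] <- list(proportions = props, surplus_n = sp_n,
                           surplus_p = sp_p,
                           mean_ratio = mean(ratio, na.rm = TRUE))
    }
    res$assessment <- assess
    mark("assess", t0)
  }

  ## scenarios --------------------------------------------------------
  if (stages[["scenarios"]] && stages[["maps"]]) {
    t0 <- tic()
    pert <- generate_scenario_deltas(config$synth, synth_grid$grid)
    cr <- config$synth$crops[1]
    model <- res$surfaces[[paste(cr, "n", sep = ".")]]$model
    sc <- scenario_reprediction(model, synth_grid$grid, pert,
                                paste0("area_", cr))
    res$scenarios <- list(
      crop = cr,
      mean_delta = vapply(sc$scenarios, function(s) mean(s$delta),
                          numeric(1)))
    mark("scenarios", t0)
  }

  res$manifest <- manifest
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  res
}

# write the main tables and the manifest; file checksums recorded
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    path <- file.path(outdir, name)
    utils::write.csv(x, path, row.names = FALSE)
    path
  }
  paths <- c(
    wr(res$observations, "observations_screened.csv"),
    wr(res$exclusion_report, "exclusions.csv"),
    wr(res$intensities, "adjusted_intensities.csv"),
    wr(do.call(rbind, res$series), "efficiency_series.csv"))
  if (!is.null(res$trend_fits)) {
    fits <- do.call(rbind, lapply(names(res$trend_fits), function(k) {
      f <- res$trend_fits[[k]]
      data.frame(series = k, breakpoint = f$breakpoint,
                 se = f$breakpoint_se, slope_pre = f$slopes[1],
                 slope_post = f$slopes[2], rss = f$rss)
    }))
    paths <- c(paths, wr(fits, "trend_fits.csv"))
  }
  res$manifest$checksums <- as.list(tools::md5sum(paths))
  jsonlite::write_json(res$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
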