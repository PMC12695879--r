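test_that("year-to-baseline mapping is total with the documented boundaries", {
  expect_equal(map_year_to_baseline(1961), 1990)
  expect_equal(map_year_to_baseline(1994), 1990)
  expect_equal(map_year_to_baseline(1995), 1999)
  expect_equal(map_year_to_baseline(2006), 1999)
  expect_equal(map_year_to_baseline(2007), 2018)
  expect_equal(map_year_to_baseline(2018), 2018)
  expect_error(map_year_to_baseline(1960))
  expect_error(map_year_to_baseline(2019))
  # total over the full span
  expect_true(all(map_year_to_baseline(1961:2018) %in% c(1990, 1999, 2018)))
})

baseline_fixture <- function() {
  data.frame(
    country = rep(c("A", "B", "C"), each = 3),
    crop = "rice",
    baseline_year = rep(c(1990, 1999, 2018), 3),
    intensity_n = c(100, 110, NA, 50, NA, 60, NA, NA, NA),
    intensity_p = c(10, 11, NA, 5, NA, 6, NA, NA, NA),
    fill_source = NA_character_,
    stringsAsFactors = FALSE)
}

panel_fixture <- function() {
  expand.grid(country = c("A", "B", "C"), crop = "rice",
              year = c(1990, 1999, 2018), stringsAsFactors = FALSE) |>
    transform(area = ifelse(country == "A", 10, ifelse(country == "B", 20, 5)),
              production = 100, total_n = 2.5, total_p = 0.25)
}

regions_fixture <- function() {
  data.frame(country = c("A", "B", "C"), region = "R1",
             stringsAsFactors = FALSE)
}

test_that("baseline gap filling applies the rules in priority order", {
  out <- fill_baseline_gaps(baseline_fixture(), panel_fixture(),
                            regions_fixture())
  expect_true(all(!is.na(out$intensity_n)))
  # reported cells unchanged
  expect_equal(out$intensity_n[out$country == "A" & out$baseline_year == 1990], 100)
  expect_equal(out$fill_source[out$country == "A" & out$baseline_year == 1990],
               "reported")
  # A/2018: nearest other baseline year for A is 1999
  a2018 <- out[out$country == "A" & out$baseline_year == 2018, ]
  expect_equal(a2018$intensity_n, 110)
  expect_equal(a2018$fill_source, "adjacent_year")
  # B/1999: 1990 (9 years away) is nearer than 2018 -> its value is copied
  b1999 <- out[out$country == "B" & out$baseline_year == 1999, ]
  expect_equal(b1999$intensity_n, 50)
  expect_equal(b1999$fill_source, "adjacent_year")
  # C/1990: nothing reported for C anywhere -> regional area-weighted mean
  c1990 <- out[out$country == "C" & out$baseline_year == 1990, ]
  expect_equal(c1990$intensity_n, (100 * 10 + 50 * 20) / 30) # hand-computed
  expect_equal(c1990$fill_source, "regional")
})

test_that("gap filling falls back to the global mean and errors on empty crops", {
  b <- baseline_fixture()
  r <- data.frame(country = c("A", "B", "C"),
                  region = c("R1", "R1", "R2"), stringsAsFactors = FALSE)
  out <- fill_baseline_gaps(b, panel_fixture(), r)
  # C sits alone in R2: no regional donors, global mean applies
  c1990 <- out[out$country == "C" & out$baseline_year == 1990, ]
  expect_equal(c1990$intensity_n, mean(c(100, 50)))
  expect_equal(c1990$fill_source, "global_mean")

  b$intensity_n <- NA_real_
  expect_error(fill_baseline_gaps(b, panel_fixture(), r), "crop")
})

test_that("intensity adjustment reproduces the worked reconciliation example", {
  baseline <- data.frame(country = c("A", "B"), crop = "rice",
                         baseline_year = 1990,
                         intensity_n = c(100, 50), intensity_p = c(100, 50),
                         fill_source = "reported", stringsAsFactors = FALSE)
  panel <- data.frame(country = c("A", "B"), crop = "rice", year = 1990,
                      area = c(10, 20), production = 1,
                      total_n = 2.5, total_p = 2.5, stringsAsFactors = FALSE)
  adj <- adjust_intensities(baseline, panel)
  # scalar = 2500 kg / (100*10 + 50*20) = 1.25
  expect_equal(adj$intensity_n, c(125, 62.5))
  # post-adjustment identity
  expect_equal(sum(adj$intensity_n * panel$area) / 1000, 2.5,
               tolerance = 1e-9)
})

test_that("consistent totals leave intensities unchanged (scalar one)", {
  baseline <- data.frame(country = c("A", "B"), crop = "rice",
                         baseline_year = 1990,
                         intensity_n = c(100, 50), intensity_p = c(10, 5),
                         fill_source = "reported", stringsAsFactors = FALSE)
  panel <- data.frame(country = c("A", "B"), crop = "rice", year = 1990,
                      area = c(10, 20), production = 1,
                      total_n = 2.0, total_p = 0.2, stringsAsFactors = FALSE)
  adj <- adjust_intensities(baseline, panel)
  expect_equal(adj$intensity_n, c(100, 50), tolerance = 1e-12)
  expect_equal(adj$intensity_p, c(10, 5), tolerance = 1e-12)
})

test_that("zero aggregate intensity-area is a named error", {
  baseline <- data.frame(country = "A", crop = "rice", baseline_year = 1990,
                         intensity_n = 0, intensity_p = 0,
                         fill_source = "reported", stringsAsFactors = FALSE)
  panel <- data.frame(country = "A", crop = "rice", year = 1990, area = 10,
                      production = 1, total_n = 1, total_p = 1,
                      stringsAsFactors = FALSE)
  expect_error(adjust_intensities(baseline, panel), "1990")
})

test_that("series reconstruction matches the hand-worked single-country case", {
  panel <- data.frame(country = "A", crop = "rice", year = 1990,
                      area = 100, production = 1000,
                      total_n = 7.5, total_p = 7.5, stringsAsFactors = FALSE)
  intens <- data.frame(country = "A", crop = "rice", year = 1990,
                       intensity_n = 75, intensity_p = 75,
                       stringsAsFactors = FALSE) # 75 kg/ha * 100 ha = 7.5 t
  contents <- data.frame(crop = "rice", n_grain = 0.01, n_residue = 0.005,
                         p_grain = 0.01, p_residue = 0.005,
                         residue_grain_ratio = 1, stringsAsFactors = FALSE)
  sf <- data.frame(country = "A", crop = "rice", year = 1990,
                   sf_n = 50, sf_p = 100, stringsAsFactors = FALSE)
  s <- reconstruct_series(panel, intens, contents, sf, "rice")
  expect_equal(s$uptake_n, 15)       # 1000 t * (0.01 + 1*0.005)
  expect_equal(s$uptake_soil_n, 7.5)
  expect_equal(s$nue, 100)           # (15 - 7.5) / 7.5 * 100
  expect_equal(s$pue, 0)             # all uptake from soil
})

test_that("reconstruction is homogeneous in production", {
  cfg <- tiny_config(seed = 21, baseline_missing_rate = 0)
  pan <- generate_panel(cfg)
  bl <- fill_baseline_gaps(pan$baseline, pan$panel, pan$countries)
  intens <- adjust_intensities(bl, pan$panel)
  sf <- pan$truth$soil_fractions
  sf_pct <- data.frame(country = sf$country, crop = sf$crop, year = sf$year,
                       sf_n = 100 * sf$sf_n, sf_p = 100 * sf$sf_p,
                       stringsAsFactors = FALSE)
  s1 <- reconstruct_series(pan$panel, intens, pan$contents, sf_pct, "rice")
  pan2 <- pan$panel
  pan2$production <- 2 * pan2$production
  s2 <- reconstruct_series(pan2, intens, pan$contents, sf_pct, "rice")
  expect_equal(s2$uptake_n, 2 * s1$uptake_n, tolerance = 1e-12)
  expect_equal(s2$nue, 2 * s1$nue, tolerance = 1e-12)
})

test_that("reconstruction recovers the generator-implied series exactly with true inputs", {
  cfg <- tiny_config(seed = 22, baseline_missing_rate = 0)
  pan <- generate_panel(cfg)
  bl <- fill_baseline_gaps(pan$baseline, pan$panel, pan$countries)
  intens <- adjust_intensities(bl, pan$panel)
  sf <- pan$truth$soil_fractions
  sf_pct <- data.frame(country = sf$country, crop = sf$crop, year = sf$year,
                       sf_n = 100 * sf$sf_n, sf_p = 100 * sf$sf_p,
                       stringsAsFactors = FALSE)
  imp <- pan$truth$implied_series
  for (cr in cfg$crops) {
    s <- reconstruct_series(pan$panel, intens, pan$contents, sf_pct, cr)
    ref <- imp[imp$crop == cr, ]
    expect_equal(s$nue, ref$nue, tolerance = 1e-8)
    expect_equal(s$pue, ref$pue, tolerance = 1e-8)
  }
})

test_that("efficiency-intensity regression reports finite diagnostics", {
  cfg <- tiny_config(seed = 23, baseline_missing_rate = 0)
  pan <- generate_panel(cfg)
  bl <- fill_baseline_gaps(pan$baseline, pan$panel, pan$countries)
  intens <- adjust_intensities(bl, pan$panel)
  sf <- pan$truth$soil_fractions
  sf_pct <- data.frame(country = sf$country, crop = sf$crop, year = sf$year,
                       sf_n = 100 * sf$sf_n, sf_p = 100 * sf$sf_p,
                       stringsAsFactors = FALSE)
  s <- reconstruct_series(pan$panel, intens, pan$contents, sf_pct, "wheat")
  d <- efficiency_intensity_regression(s, intens, pan$panel, "N")
  expect_true(is.finite(d$slope))
  expect_true(d$p_value >= 0 && d$p_value <= 1)
})
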