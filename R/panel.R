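#' Map a panel year to its baseline reference year
#'
#' Baseline input-intensity reports exist for 1990, 1999 and 2018 only;
#' every panel year is anchored to one of them by fixed period divisions:
#' 1961--1994 to 1990, 1995--2006 to 1999, and 2007--2018 to 2018.
#'
#' @param year integer vector of years in 1961--2018.
#' @return integer vector of baseline years.
#' @examples
#' map_year_to_baseline(c(1994, 1995, 2018))  # 1990 1999 2018
#' @export
map_year_to_baseline <- function(year) {
  if (any(year < 1961 | year > 2018))
    stop("years must lie in 1961..2018", call. = FALSE)
  out <- integer(length(year))
  out[year <= 1994] <- 1990L
  out[year >= 1995 & year <= 2006] <- 1999L
  out[year >= 2007] <- 2018L
  out
}

#' Fill gaps in baseline fertilizer input intensities
#'
#' Completes every country-by-crop-by-baseline-year cell of the baseline
#' intensity table, applying the first rule that yields a value:
#' \enumerate{
#'   \item \emph{adjacent year}: copy the same country/crop cell from the
#'     nearest other baseline year that reports it;
#'   \item \emph{regional}: planted-area-weighted mean of reported
#'     intensities for the same crop and baseline year among countries in
#'     the same region;
#'   \item \emph{global mean}: mean of all reported intensities for the
#'     crop at that baseline year (falling back to all baseline years).
#' }
#' A cell is treated as missing when either nutrient intensity is `NA`;
#' both nutrients are filled from the same donor rule so the pair stays
#' coherent. `fill_source` records the rule used for every cell.
#'
#' @param baseline data frame with `country`, `crop`, `baseline_year`,
#'   `intensity_n`, `intensity_p`, `fill_source`.
#' @param panel panel data frame supplying `area` weights (country, crop,
#'   year, area).
#' @param regions data frame mapping `country` to `region`.
#' @return completed baseline table.
#' @export
fill_baseline_gaps <- function(baseline, panel, regions) {
  stopifnot(all(c("country", "crop", "baseline_year", "intensity_n",
                  "intensity_p") %in% names(baseline)))
  for (cr in unique(baseline$crop)) {
    sub <- baseline[baseline$crop == cr, ]
    if (all(is.na(sub$intensity_n)))
      stop("no reported intensity anywhere for crop '", cr, "'",
           call. = FALSE)
  }
  reported <- !is.na(baseline$intensity_n) & !is.na(baseline$intensity_p)
  baseline$fill_source[reported] <- "reported"
  region_of <- regions$region[match(baseline$country, regions$country)]

  # area of each country x crop at (or nearest to) each baseline year
  area_at <- function(country, crop, by) {
    rows <- panel[panel$country == country & panel$crop == crop, ]
    if (nrow(rows) == 0) return(NA_real_)
    rows$area[which.min(abs(rows$year - by))]
  }

  for (i in which(!reported)) {
    co <- baseline$country[i]; cr <- baseline$crop[i]
    by <- baseline$baseline_year[i]
    # (i) adjacent baseline year, same country and crop
    cand <- baseline[baseline$country == co & baseline$crop == cr &
                       baseline$baseline_year != by & reported, ]
    if (nrow(cand) > 0) {
      cand <- cand[order(abs(cand$baseline_year - by), cand$baseline_year), ]
      baseline$intensity_n[i] <- cand$intensity_n[1]
      baseline$intensity_p[i] <- cand$intensity_p[1]
      baseline$fill_source[i] <- "adjacent_year"
      next
    }
    # (ii) area-weighted regional mean, same crop and baseline year
    reg <- baseline[baseline$crop == cr & baseline$baseline_year == by &
                      reported & region_of == region_of[i], ]
    if (nrow(reg) > 0) {
      w <- vapply(reg$country, area_at, numeric(1), crop = cr, by = by)
      w[is.na(w)] <- 0
      if (sum(w) > 0) {
        baseline$intensity_n[i] <- sum(w * reg$intensity_n) / sum(w)
        baseline$intensity_p[i] <- sum(w * reg$intensity_p) / sum(w)
      } else {
        baseline$intensity_n[i] <- mean(reg$intensity_n)
        baseline$intensity_p[i] <- mean(reg$intensity_p)
      }
      baseline$fill_source[i] <- "regional"
      next
    }
    # (iii) global mean for the crop
    glob <- baseline[baseline$crop == cr & baseline$baseline_year == by &
                       reported, ]
    if (nrow(glob) == 0)
      glob <- baseline[baseline$crop == cr & reported, ]
    baseline$intensity_n[i] <- mean(glob$intensity_n)
    baseline$intensity_p[i] <- mean(glob$intensity_p)
    baseline$fill_source[i] <- "global_mean"
  }
  baseline
}

#' Reconcile baseline intensities with national fertilizer totals
#'
#' Adjusts baseline per-hectare input intensities so that their aggregate
#' over all countries and crops reproduces the reported national total for
#' each year:
#' \deqn{Input_{co,cr,yr} = Input\_base_{co,cr} \times
#'   \frac{T_{yr}}{\sum_{co}\sum_{cr} Input\_base_{co,cr} A_{co,cr,yr}}}
#' applied independently per nutrient. Totals are tonnes, intensities
#' kg ha^-1, areas ha; the 1000-fold unit change is handled internally.
#' After adjustment the identity \eqn{\sum adjusted \times area = T_{yr}}
#' holds to numerical precision.
#'
#' @param baseline completed baseline table (see [fill_baseline_gaps()]).
#' @param panel panel with `country`, `crop`, `year`, `area`, `total_n`,
#'   `total_p` (totals constant within year).
#' @param years years to adjust; default all years in the panel.
#' @return data frame `country`, `crop`, `year`, `intensity_n`,
#'   `intensity_p` (kg ha^-1).
#' @export
adjust_intensities <- function(baseline, panel, years = NULL) {
  if (is.null(years)) years <- sort(unique(panel$year))
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    p <- panel[panel$year == yr, ]
    by <- map_year_to_baseline(yr)
    b <- baseline[baseline$baseline_year == by, ]
    m <- match(paste(p$country, p$crop), paste(b$country, b$crop))
    if (anyNA(m))
      stop("baseline intensities missing for some country x crop in ", yr,
           call. = FALSE)
    int_n <- b$intensity_n[m]; int_p <- b$intensity_p[m]
    den_n <- sum(int_n * p$area); den_p <- sum(int_p * p$area)
    if (den_n <= 0 || den_p <= 0)
      stop("zero aggregate baseline intensity x area in year ", yr,
           call. = FALSE)
    scalar_n <- t_to_kg(p$total_n[1]) / den_n
    scalar_p <- t_to_kg(p$total_p[1]) / den_p
    out[[k]] <- data.frame(country = p$country, crop = p$crop, year = yr,
                           intensity_n = int_n * scalar_n,
                           intensity_p = int_p * scalar_p,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reconstruct annual NUE/PUE series for a crop
#'
#' Implements the four-step panel accounting: per-crop fertilizer input
#' \eqn{F = \sum_{co} Input_{co,cr,yr} A_{co,cr,yr}} (tonnes); whole-plant
#' uptake \eqn{U = Q (c_G + R\,c_S)} with production \eqn{Q} (t), grain and
#' residue nutrient contents as mass fractions and residue-grain ratio
#' \eqn{R}; soil-only uptake \eqn{U_0 = U \times sf/100} using the
#' predicted soil-derived fraction (percent); and
#' \eqn{NUE = 100 (U - U_0)/F}.
#'
#' @param panel panel rows (country, crop, year, area, production).
#' @param intensities adjusted intensity table from [adjust_intensities()].
#' @param contents crop nutrient content table
#'   (see [crop_nutrient_contents()]), contents as fractions.
#' @param soil_fractions data frame `country`, `crop`, `year`, `sf_n`,
#'   `sf_p` with soil-derived uptake fractions in percent.
#' @param crop crop to reconstruct.
#' @return data frame per year: fertilizer totals `fert_n`/`fert_p` (t),
#'   uptakes `uptake_n`/`uptake_p` and soil-only uptakes `uptake_soil_*`
#'   (t), and `nue`, `pue` (percent; `NA` with a warning when the
#'   fertilizer total is zero).
#' @export
reconstruct_series <- function(panel, intensities, contents, soil_fractions,
                               crop) {
  p <- panel[panel$crop == crop, ]
  if (nrow(p) == 0) stop("crop not present in panel: ", crop, call. = FALSE)
  key <- function(d) paste(d$country, d$year)
  ii <- intensities[intensities$crop == crop, ]
  m <- match(key(p), key(ii))
  stopifnot(!anyNA(m))
  p$intensity_n <- ii$intensity_n[m]
  p$intensity_p <- ii$intensity_p[m]
  sf <- soil_fractions[soil_fractions$crop == crop, ]
  ms <- match(key(p), key(sf))
  stopifnot(!anyNA(ms))
  p$sf_n <- sf$sf_n[ms]; p$sf_p <- sf$sf_p[ms]
  if (any(p$sf_n < 0 | p$sf_n > 100 | p$sf_p < 0 | p$sf_p > 100, na.rm = TRUE))
    stop("soil fractions must be percentages in [0, 100]", call. = FALSE)
  cc <- contents[contents$crop == crop, ]
  if (nrow(cc) != 1) stop("contents must have one row for crop ", crop,
                          call. = FALSE)
  upt_n <- cc$n_grain + cc$residue_grain_ratio * cc$n_residue
  upt_p <- cc$p_grain + cc$residue_grain_ratio * cc$p_residue

  out <- lapply(split(p, p$year), function(d) {
    f_n <- kg_to_t(sum(d$intensity_n * d$area))
    f_p <- kg_to_t(sum(d$intensity_p * d$area))
    u_n <- sum(d$production * upt_n)
    u_p <- sum(d$production * upt_p)
    u0_n <- sum(d$production * upt_n * d$sf_n / 100)
    u0_p <- sum(d$production * upt_p * d$sf_p / 100)
    data.frame(crop = crop, year = d$year[1],
               fert_n = f_n, fert_p = f_p,
               uptake_n = u_n, uptake_p = u_p,
               uptake_soil_n = u0_n, uptake_soil_p = u0_p,
               nue = if (f_n > 0) 100 * (u_n - u0_n) / f_n else NA_real_,
               pue = if (f_p > 0) 100 * (u_p - u0_p) / f_p else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (anyNA(out$nue) || anyNA(out$pue))
    warning("efficiency undefined in years with zero fertilizer input")
  out[order(out$year), ]
}

#' Diagnostic regression of efficiency on input intensity
#'
#' Ordinary least squares of an annual efficiency series on the matching
#' area-weighted mean input intensity, reported as a diagnostic of the
#' efficiency-intensity relationship (it plays no role in the series
#' reconstruction itself).
#'
#' @param series output of [reconstruct_series()].
#' @param intensities adjusted intensity table.
#' @param panel panel (for area weights).
#' @param nutrient "N" or "P".
#' @return list with `slope`, `p_value`, `r_squared`.
#' @export
efficiency_intensity_regression <- function(series, intensities, panel,
                                            nutrient = c("N", "P")) {
  nutrient <- match.arg(nutrient)
  crop <- series$crop[1]
  ii <- intensities[intensities$crop == crop, ]
  pp <- panel[panel$crop == crop, ]
  key <- function(d) paste(d$country, d$year)
  ii$area <- pp$area[match(key(ii), key(pp))]
  v <- if (nutrient == "N") ii$intensity_n else ii$intensity_p
  mean_int <- vapply(split(seq_len(nrow(ii)), ii$year), function(id)
    stats::weighted.mean(v[id], ii$area[id]), numeric(1))
  y <- if (nutrient == "N") series$nue else series$pue
  x <- mean_int[match(as.character(series$year), names(mean_int))]
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p_value = unname(s$coefficients[2, 4]),
       r_squared = s$r.squared)
}
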