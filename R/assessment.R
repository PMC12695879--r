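#' Classify cells into efficiency quadrants
#'
#' Four-way classification of cells by NUE and PUE against a threshold
#' (default 50\%): `lowN-lowP`, `highN-lowP`, `highN-highP`, `lowN-highP`.
#' Cells exactly at the threshold are classified "low" (the category
#' definitions use strict inequalities on both sides, leaving equality
#' unassigned; the low side is the documented tie rule). Cells where
#' either surface is missing are `NA`.
#'
#' @param nue,pue numeric vectors (percent), aligned.
#' @param threshold classification threshold in percent (default 50).
#' @return character vector of categories.
#' @examples
#' classify_quadrants(60, 40)  # "highN-lowP"
#' @export
classify_quadrants <- function(nue, pue, threshold = 50) {
  stopifnot(length(nue) == length(pue))
  hn <- nue > threshold
  hp <- pue > threshold
  out <- ifelse(hn & hp, "highN-highP",
         ifelse(hn & !hp, "highN-lowP",
         ifelse(!hn & hp, "lowN-highP", "lowN-lowP")))
  out[is.na(nue) | is.na(pue)] <- NA_character_
  out
}

#' Planted-area proportions of the efficiency categories
#'
#' Share of planted area in each quadrant category,
#' \eqn{\sum_{i \in c} Area_i / \sum_i Area_i}; the fractions sum to one
#' over the classified cells.
#'
#' @param categories character vector from [classify_quadrants()].
#' @param area planted areas (aligned, nonnegative, positive total).
#' @return named numeric vector of fractions over all four categories.
#' @export
area_proportions <- function(categories, area) {
  stopifnot(length(categories) == length(area))
  keep <- !is.na(categories) & !is.na(area)
  categories <- categories[keep]; area <- area[keep]
  if (sum(area) <= 0) stop("total classified area must be > 0", call. = FALSE)
  lev <- c("lowN-lowP", "highN-lowP", "highN-highP", "lowN-highP")
  tot <- vapply(lev, function(l) sum(area[categories == l]), numeric(1))
  tot / sum(area)
}

#' Fertilizer surplus loads and intensities per reporting unit
#'
#' For each unit (country or region), the surplus load is the applied
#' nutrient not recovered in incremental uptake,
#' \eqn{\sum_i Area_i \cdot input_i \cdot (1 - E_i)} (kg, reported in
#' tonnes), the surplus intensity is the load per unit area (kg ha^-1,
#' i.e. the area-weighted mean per-cell surplus intensity), and the
#' intensity SD is the unweighted sample standard deviation (n-1) of the
#' per-cell surplus intensities. An area-weighted SD is available under
#' `weighted_sd = TRUE`, clearly a departure from the unweighted
#' definition.
#'
#' @param efficiency efficiency per cell, percent.
#' @param input input intensity per cell, kg ha^-1.
#' @param area planted area per cell, ha.
#' @param unit unit (country/region) id per cell.
#' @param weighted_sd use an area-weighted SD instead of the unweighted
#'   cell dispersion.
#' @return data frame per unit: `unit`, `n_cells`, `area` (ha), `load_t`
#'   (tonnes), `intensity` and `intensity_sd` (kg ha^-1). Units with zero
#'   area get a missing intensity.
#' @export
surplus <- function(efficiency, input, area, unit, weighted_sd = FALSE) {
  stopifnot(length(efficiency) == length(input),
            length(input) == length(area), length(area) == length(unit))
  cell_int <- input * (1 - efficiency / 100) # kg ha^-1 surplus per cell
  out <- lapply(split(seq_along(unit), unit), function(id) {
    a <- area[id]; ci <- cell_int[id]
    load_kg <- sum(a * ci)
    tot_a <- sum(a)
    intensity <- if (tot_a > 0) load_kg / tot_a else NA_real_
    sdv <- if (weighted_sd && tot_a > 0) {
      sqrt(sum(a * (ci - intensity)^2) / tot_a)
    } else if (length(id) > 1 && !is.na(intensity)) {
      sqrt(sum((ci - intensity)^2) / (length(id) - 1))
    } else NA_real_
    data.frame(unit = unit[id[1]], n_cells = length(id), area = tot_a,
               load_t = kg_to_t(load_kg), intensity = intensity,
               intensity_sd = sdv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' NUE:PUE ratio per cell
#'
#' Per-cell ratio of nitrogen to phosphorus use efficiency; cells with
#' zero or missing PUE are returned missing, with the count of zero-PUE
#' cells attached as attribute `"n_zero_pue"`. Note that the ratio of
#' unit means and the mean of per-cell ratios differ in general; both can
#' be derived from the returned vector and the surfaces.
#'
#' @param nue,pue numeric vectors, percent.
#' @return numeric vector of ratios.
#' @export
efficiency_ratio <- function(nue, pue) {
  stopifnot(length(nue) == length(pue))
  zero <- !is.na(pue) & pue == 0
  out <- ifelse(zero | is.na(pue), NA_real_, nue / pue)
  structure(out, n_zero_pue = sum(zero))
}

#' Surplus per unit of yield
#'
#' Surplus load divided by production: kg of surplus nutrient per tonne of
#' grain, a joint food-security/pollution indicator.
#'
#' @param load_t surplus load, tonnes.
#' @param production_t production, tonnes (> 0).
#' @return kg surplus per tonne grain.
#' @export
surplus_per_yield <- function(load_t, production_t) {
  if (any(!is.na(production_t) & production_t <= 0))
    stop("production must be > 0", call. = FALSE)
  t_to_kg(load_t) / production_t
}
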