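#' Difference-method nutrient use efficiency
#'
#' Computes the recovery efficiency of applied fertilizer nutrient as the
#' uptake gap between fertilized and unfertilized plots divided by the
#' amount applied:
#' \deqn{NUE = 100 (U - U_0) / Input}
#' where \eqn{U} is nutrient uptake with fertilization (kg ha^-1),
#' \eqn{U_0} uptake of the unfertilized control, and \eqn{Input} the
#' fertilizer nutrient applied (kg ha^-1, elemental).
#'
#' Negative values (control outyields the fertilized plot) are returned as
#' computed, not clipped: real fertilizer recovery cannot be negative, so
#' such records are flagged for exclusion downstream by
#' [screen_observations()] rather than silently dropped here. Values above
#' 100\% are likewise returned as computed.
#'
#' @param u_fert uptake under fertilization, kg ha^-1 (>= 0).
#' @param u_ctrl uptake of the unfertilized control, kg ha^-1 (>= 0).
#' @param input fertilizer nutrient applied, kg ha^-1 (> 0).
#' @return efficiency in percent (vectorized).
#' @examples
#' efficiency_diff(96, 48, 120)  # 40
#' @export
efficiency_diff <- function(u_fert, u_ctrl, input) {
  if (any(!is.finite(input) | input <= 0))
    stop("efficiency undefined: fertilizer input must be > 0", call. = FALSE)
  if (any(u_fert < 0, na.rm = TRUE) || any(u_ctrl < 0, na.rm = TRUE))
    stop("uptake values must be >= 0", call. = FALSE)
  100 * (u_fert - u_ctrl) / input
}

#' Whole-plant nutrient uptake from biomass partition
#'
#' Uptake as grain mass times grain nutrient content plus residue mass times
#' residue nutrient content, \eqn{U = G N_G + S N_S}. Contents are mass
#' fractions of dry weight (e.g. 0.012 for 1.2\%), masses kg ha^-1.
#'
#' @param grain_mass,residue_mass dry masses, kg ha^-1 (>= 0).
#' @param grain_content,residue_content nutrient mass fractions in `[0, 0.1]`.
#' @return uptake in kg ha^-1.
#' @examples
#' uptake_from_biomass(5000, 0.012, 6000, 0.006)  # 96
#' @export
uptake_from_biomass <- function(grain_mass, grain_content,
                                residue_mass, residue_content) {
  if (any(c(grain_mass, residue_mass) < 0, na.rm = TRUE))
    stop("biomass masses must be >= 0", call. = FALSE)
  if (any(c(grain_content, residue_content) < 0, na.rm = TRUE) ||
      any(c(grain_content, residue_content) > 0.1, na.rm = TRUE))
    stop("nutrient contents must be fractions in [0, 0.1]", call. = FALSE)
  grain_mass * grain_content + residue_mass * residue_content
}

#' Share of crop nutrient uptake derived from soil
#'
#' The proportion of uptake attributable to the soil pool rather than the
#' fertilizer applied in the trial:
#' \deqn{soil\ fraction = 100 (U - NUE \cdot Input) / U}
#' with efficiency as a fraction. Values are clipped to `[0, 100]`; the
#' number of clipped cells is attached as attribute `"n_clipped"` because
#' noisy inputs can push the raw quantity out of range.
#'
#' @param uptake crop nutrient uptake, kg ha^-1 (> 0).
#' @param efficiency fertilizer recovery efficiency as a fraction (0.40 for 40\%).
#' @param input fertilizer nutrient applied, kg ha^-1.
#' @return soil-derived share of uptake in percent, clipped to `[0, 100]`.
#' @examples
#' soil_fraction(96, 0.40, 120)  # 50
#' @export
soil_fraction <- function(uptake, efficiency, input) {
  if (any(!is.finite(uptake) | uptake <= 0))
    stop("soil fraction undefined: uptake must be > 0", call. = FALSE)
  raw <- 100 * (uptake - efficiency * input) / uptake
  clipped <- pmin(pmax(raw, 0), 100)
  structure(clipped, n_clipped = sum(clipped != raw, na.rm = TRUE))
}

#' Aridity index
#'
#' Moisture availability ratio used as a climate covariate. The conventional
#' definition (default) is mean annual precipitation over potential
#' evapotranspiration, `MAP/PET`. `strict = TRUE` instead returns `MAT/PET`
#' (mean annual temperature over PET), a dimensionally anomalous variant
#' kept available as a switch; see the methods vignette for the rationale.
#'
#' @param map mean annual precipitation, mm yr^-1.
#' @param pet potential evapotranspiration, mm yr^-1 (> 0).
#' @param mat mean annual temperature, degrees C (only used when `strict`).
#' @param strict logical; use the MAT/PET variant.
#' @return dimensionless aridity index.
#' @examples
#' aridity_index(500, 1000)              # 0.5
#' aridity_index(pet = 1000, mat = 20, strict = TRUE)  # 0.02
#' @export
aridity_index <- function(map = NULL, pet, mat = NULL, strict = FALSE) {
  if (any(!is.finite(pet) | pet <= 0))
    stop("aridity index undefined: PET must be > 0", call. = FALSE)
  if (strict) {
    if (is.null(mat)) stop("strict mode requires `mat`", call. = FALSE)
    mat / pet
  } else {
    if (is.null(map)) stop("default mode requires `map`", call. = FALSE)
    map / pet
  }
}

#' Screen field-trial observations for inclusion
#'
#' Applies the database inclusion criteria to a point-observation table:
#' \enumerate{
#'   \item explicit efficiency values or crop nutrient uptake reported;
#'   \item at least one complete crop cycle (duration >= 1 year);
#'   \item geographical location reported;
#'   \item paired fertilized/control treatments conducted in the field;
#'   \item crop species, cropping system and fertilizer inputs reported;
#' }
#' plus the exclusion of negative efficiencies (real fertilizer recovery
#' cannot fall below zero, so negative values are treated as outliers).
#' When both reported efficiency and uptake data are present, the value
#' recomputed from uptake takes precedence (`efficiency_used`).
#'
#' @param obs data frame with columns `nutrient` ("N"/"P"), `efficiency`
#'   (percent, may be NA), `u_fert`, `u_ctrl` (kg ha^-1, may be NA),
#'   `input` (kg ha^-1), `duration` (years), `latitude`, `longitude`,
#'   `field_control` (logical), `crop`.
#' @return the input with columns `keep` (logical), `reason` (empty string
#'   when kept; machine-readable code otherwise) and `efficiency_used`.
#' @export
screen_observations <- function(obs) {
  stopifnot(is.data.frame(obs))
  n <- nrow(obs)
  reason <- character(n)
  has_uptake <- !is.na(obs$u_fert) & !is.na(obs$u_ctrl)
  has_eff <- !is.na(obs$efficiency)
  has_input <- !is.na(obs$input) & obs$input > 0

  # precedence: uptake-derived efficiency over the reported value
  eff <- ifelse(has_uptake & has_input,
                100 * (obs$u_fert - obs$u_ctrl) / obs$input,
                obs$efficiency)

  miss <- function(x) is.na(x)
  rule <- function(cond, code) {
    hit <- cond & reason == ""
    reason[hit] <<- code
  }
  rule(!(has_eff | has_uptake), "criterion 1: no efficiency or uptake")
  rule(miss(obs$duration) | obs$duration < 1, "criterion 2: incomplete crop cycle")
  rule(miss(obs$latitude) | miss(obs$longitude), "criterion 3: no location")
  rule(miss(obs$field_control) | !obs$field_control, "criterion 4: no field control")
  rule(miss(obs$crop) | !has_input, "criterion 5: crop or fertilizer input missing")
  rule(!is.na(eff) & eff < 0, "negative efficiency")

  obs$efficiency_used <- eff
  obs$keep <- reason == ""
  obs$reason <- reason
  obs
}

#' Impute missing covariates from a covariate grid
#'
#' Fills missing numeric covariates of point observations with the value of
#' the nearest grid cell (squared-degree distance on lon/lat), mirroring the
#' common practice of drawing missing climate and soil attributes from
#' gridded products at the site's coordinates.
#'
#' @param obs point-observation data frame with `latitude`, `longitude`.
#' @param grid covariate grid data frame (`lat`, `lon` plus layer columns).
#' @param vars covariate columns to impute; default every shared column.
#' @return `obs` with missing values filled; attribute `"n_imputed"` counts
#'   the filled cells.
#' @export
impute_covariates <- function(obs, grid, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(intersect(names(obs), names(grid)), c("lat", "lon", "latitude", "longitude"))
  idx <- vapply(seq_len(nrow(obs)), function(i) {
    which.min((grid$lat - obs$latitude[i])^2 + (grid$lon - obs$longitude[i])^2)
  }, integer(1))
  n_imputed <- 0L
  for (v in vars) {
    na <- is.na(obs[[v]])
    if (any(na)) {
      obs[[v]][na] <- grid[[v]][idx[na]]
      n_imputed <- n_imputed + sum(na)
    }
  }
  structure(obs, n_imputed = n_imputed)
}
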