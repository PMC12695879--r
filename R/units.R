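#' Unit conversions at the I/O boundary
#'
#' All nutrient masses inside the package are elemental (kg N, kg P),
#' intensities kg ha^-1 and national totals tonnes. Fertilizer statistics
#' are often reported as P2O5 rather than elemental P; these helpers convert
#' at read/write time so a single canonical representation is used internally.
#'
#' @param x numeric vector of masses (any consistent unit).
#' @return numeric vector in the converted unit.
#' @examples
#' p2o5_to_p(100)      # 43.64 kg P
#' p_to_p2o5(p2o5_to_p(1)) # exact round trip
#' @name unit-conversions
NULL

# mass fraction of P in P2O5 (2*30.974 / 141.945)
P_IN_P2O5 <- 0.4364

#' @rdname unit-conversions
#' @export
p2o5_to_p <- function(x) x * P_IN_P2O5

#' @rdname unit-conversions
#' @export
p_to_p2o5 <- function(x) x / P_IN_P2O5

#' @rdname unit-conversions
#' @export
kg_to_t <- function(x) x / 1000

#' @rdname unit-conversions
#' @export
t_to_kg <- function(x) x * 1000
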