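# Mechanical-index and dilution arithmetic of the acquisition protocol.

#' Peak negative pressure from a mechanical index
#'
#' The regulatory definition MI = PNP\[MPa\] / sqrt(f\[MHz\]) with no
#' derating, inverted to pressure: `pnp = mi * sqrt(f) * 1000` kPa.
#' Reported pressures are conventionally rounded to the nearest 10 kPa.
#'
#' @param mi mechanical index (> 0).
#' @param f transmit frequency in MHz (> 0).
#' @param round_to optional rounding granularity in kPa (e.g. 10); `NULL`
#'   for the exact value.
#' @return Peak negative pressure in kPa.
#' @export
mi_to_pressure <- function(mi, f, round_to = NULL) {
  if (any(mi <= 0) || any(f <= 0)) {
    stop("mi and f must be positive", call. = FALSE)
  }
  p <- mi * sqrt(f) * 1000
  if (!is.null(round_to)) p <- round(p / round_to) * round_to
  p
}

#' Mechanical index from a peak negative pressure
#'
#' Inverse of [mi_to_pressure()]: `mi = (pnp / 1000) / sqrt(f)`.
#'
#' @param pnp_kPa peak negative pressure in kPa (> 0).
#' @param f transmit frequency in MHz (> 0).
#' @return Mechanical index.
#' @export
pressure_to_mi <- function(pnp_kPa, f) {
  if (any(pnp_kPa <= 0) || any(f <= 0)) {
    stop("pressure and f must be positive", call. = FALSE)
  }
  (pnp_kPa / 1000) / sqrt(f)
}

#' Final concentration of a two-step dilution
#'
#' Stock concentration `stock_mass / stock_volume` diluted by taking
#' `aliquot` into `diluent`:
#' `(stock_mass / stock_volume) * aliquot / (aliquot + diluent)` mg/mL.
#'
#' @param stock_mass dry mass in the stock (mg).
#' @param stock_volume stock volume (mL).
#' @param aliquot aliquot taken from the stock (mL).
#' @param diluent volume the aliquot is diluted into (mL).
#' @param digits optional rounding (decimal places) for reporting.
#' @return Final concentration in mg/mL.
#' @export
dilution_concentration <- function(stock_mass, stock_volume, aliquot,
                                   diluent, digits = NULL) {
  check_scalar(stock_mass, "stock_mass", positive = TRUE)
  check_scalar(stock_volume, "stock_volume", positive = TRUE)
  check_scalar(aliquot, "aliquot", positive = TRUE)
  check_scalar(diluent, "diluent", nonnegative = TRUE)
  conc <- (stock_mass / stock_volume) * aliquot / (aliquot + diluent)
  if (!is.null(digits)) conc <- round(conc, digits)
  conc
}

#' Bubble number density from a mass concentration
#'
#' The per-mg bubble count depends on the agent's gas-volume calculation and
#' must be supplied by the user; no default is asserted.
#'
#' @param concentration_mg_per_mL mass concentration (mg/mL, >= 0).
#' @param bubbles_per_mg bubbles per mg of dry material (> 0).
#' @return Number density in bubbles/mL.
#' @export
number_density <- function(concentration_mg_per_mL, bubbles_per_mg) {
  if (any(concentration_mg_per_mL < 0)) {
    stop("concentration must be nonnegative", call. = FALSE)
  }
  if (any(bubbles_per_mg <= 0)) {
    stop("bubbles_per_mg must be positive", call. = FALSE)
  }
  concentration_mg_per_mL * bubbles_per_mg
}
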