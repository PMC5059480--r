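#' Physical constants used throughout the package
#'
#' Energies are stored internally in eV, times in fs, rates in fs^-1;
#' spin-orbit coupling constants are stored in cm^-1 and converted to eV when
#' a Hamiltonian is built.
#'
#' @format A named list with elements
#' \describe{
#'   \item{ev_nm}{wavelength-energy product, 1239.84198 eV nm}
#'   \item{cm1_per_ev}{wavenumbers per eV, 8065.543937 cm^-1/eV}
#'   \item{hbar_ev_fs}{reduced Planck constant, 0.6582119569 eV fs}
#' }
#' @export
td_constants <- list(
  ev_nm      = 1239.84198,
  cm1_per_ev = 8065.543937,
  hbar_ev_fs = 0.6582119569
)

.td_units <- c("eV", "cm^-1", "nm", "fs^-1")

#' Create an energy value with a unit
#'
#' @param value numeric value(s)
#' @param unit one of `"eV"`, `"cm^-1"`, `"nm"`, `"fs^-1"`
#' @return an object of class `energy_value`
#' @export
energy_value <- function(value, unit = "eV") {
  unit <- match.arg(unit, .td_units)
  if (unit == "nm" && any(value <= 0)) {
    stop("wavelengths must be positive", call. = FALSE)
  }
  structure(list(value = value, unit = unit), class = "energy_value")
}

#' @method print energy_value
#' @export
print.energy_value <- function(x, ...) {
  cat(format(x$value), x$unit, "\n")
  invisible(x)
}

# value in `unit` -> eV (nm is reciprocal)
.to_ev <- function(value, unit) {
  switch(unit,
    "eV"    = value,
    "cm^-1" = value / td_constants$cm1_per_ev,
    "nm"    = td_constants$ev_nm / value,
    "fs^-1" = value * td_constants$hbar_ev_fs
  )
}

.from_ev <- function(ev, unit) {
  switch(unit,
    "eV"    = ev,
    "cm^-1" = ev * td_constants$cm1_per_ev,
    "nm"    = td_constants$ev_nm / ev,
    "fs^-1" = ev / td_constants$hbar_ev_fs
  )
}

#' Convert an energy-like quantity between units
#'
#' Supported units are eV, cm^-1, nm and fs^-1 (angular frequency via
#' E = hbar * omega). Conversions through the reciprocal nm unit require
#' positive values. Round trips are exact to better than 1e-12 relative.
#'
#' @param x an [energy_value], or a numeric vector if `from` is given
#' @param target_unit unit to convert to
#' @param from unit of `x` when `x` is numeric
#' @return an [energy_value] in the target unit (numeric vector if the input
#'   was numeric)
#' @examples
#' convert_energy(energy_value(1239.84198, "nm"), "eV")$value  # 1
#' convert_energy(3.65, "nm", from = "eV")                     # ~339.7 nm
#' @export
convert_energy <- function(x, target_unit, from = NULL) {
  target_unit <- match.arg(target_unit, .td_units)
  numeric_in <- FALSE
  if (!inherits(x, "energy_value")) {
    if (is.null(from)) stop("numeric input requires `from =` a unit", call. = FALSE)
    x <- energy_value(x, from)
    numeric_in <- TRUE
  }
  if ((x$unit == "nm" || target_unit == "nm") && any(x$value <= 0)) {
    stop("conversion through nm requires positive values", call. = FALSE)
  }
  out <- .from_ev(.to_ev(x$value, x$unit), target_unit)
  if (numeric_in) out else energy_value(out, target_unit)
}
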