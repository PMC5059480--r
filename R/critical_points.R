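#' Load the packaged critical-point energy table for 2-thiocytosine
#'
#' Stationary points and surface crossings of the excited-state landscape of
#' 2-thiocytosine (energies in eV above the ground-state minimum, computed at
#' the MS-CASPT2 level): the Franck-Condon energy of the bright singlet
#' pi_s-pi* state, the two excited singlet minima, the two triplet minima,
#' the singlet/singlet and triplet/triplet conical intersections, the two
#' singlet-triplet minimum-energy crossing points, and the lower bound on the
#' barrier separating the lowest singlet minimum from ground-state-recovery
#' crossings.
#'
#' @param path optional path to an alternative delimited-text table
#' @return a data frame with columns `label`, `kind` (one of minimum, CoIn,
#'   MECP, FC-point, barrier), `states` (one or two labels separated by `|`),
#'   `energy_ev`, and `bound` (`"eq"` for equality calibration targets,
#'   `"ge"` for lower bounds)
#' @export
critical_point_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "critical_points_2tc.csv", package = "thiodyn")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("label", "kind", "states", "energy_ev", "bound") %in% names(tab)))
  stopifnot(all(tab$kind %in% c("minimum", "CoIn", "MECP", "FC-point", "barrier")))
  tab
}

#' Load the packaged spin-orbit coupling reference table
#'
#' Three magnitudes are reported for 2-thiocytosine: a maximum of 170 cm^-1
#' near the singlet-triplet crossing points, and trajectory averages of about
#' 160 cm^-1 (S1-T2) and 50 cm^-1 (S1-T1). They refer to different
#' geometries, so all three are kept under distinct labels.
#'
#' @return a data frame with columns `label`, `pair`, `magnitude_cm1`
#' @export
soc_reference_table <- function() {
  path <- system.file("extdata", "soc_reference_2tc.csv", package = "thiodyn")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
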