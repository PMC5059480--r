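#' Stick spectrum of an electronic state
#'
#' @param state_label text label, e.g. `"1pispi*"`
#' @param energy_ev transition energies in eV (> 0)
#' @param f oscillator strengths (>= 0), same length
#' @return an object of class `stick_spectrum`
#' @export
stick_spectrum <- function(state_label, energy_ev = numeric(0), f = numeric(0)) {
  if (length(energy_ev) != length(f)) stop("energies and strengths differ in length")
  if (any(energy_ev <= 0)) stop("transition energies must be positive")
  if (any(f < 0)) stop("oscillator strengths must be non-negative")
  structure(list(state_label = state_label,
                 transitions = data.frame(energy_ev = energy_ev, f = f)),
            class = "stick_spectrum")
}

#' Broaden a stick spectrum into a band spectrum
#'
#' Each transition becomes a Gaussian in the *energy* domain with constant
#' width `fwhm_ev` and amplitude proportional to its oscillator strength:
#' \deqn{I(\lambda) = \sum_k f_k \exp\left(-\frac{(E(\lambda)-E_k)^2}{2\sigma_E^2}\right)}
#' with `sigma_E = fwhm_ev / (2 sqrt(2 log 2))`, sampled on the wavelength
#' grid. By default no Jacobian reweighting is applied when evaluating on the
#' nm grid (set `jacobian = TRUE` to multiply by `dE/dlambda`).
#'
#' @param sticks a [stick_spectrum]; an empty one yields the zero spectrum
#' @param fwhm_ev Gaussian full width at half maximum in eV (default 0.7)
#' @param grid wavelength grid in nm
#' @param jacobian apply the energy-to-wavelength Jacobian `|dE/dlambda|`
#' @return a `band_spectrum`: list with `wavelengths` (nm) and `intensity`
#'   (arbitrary units, >= 0)
#' @export
broaden <- function(sticks, fwhm_ev = 0.7, grid = seq(300, 750, by = 0.5),
                    jacobian = FALSE) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  if (fwhm_ev <= 0) stop("fwhm_ev must be positive")
  sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
  e_grid <- convert_energy(grid, "eV", from = "nm")
  intensity <- rep(0, length(grid))
  tr <- sticks$transitions
  for (k in seq_len(nrow(tr))) {
    intensity <- intensity +
      tr$f[k] * exp(-(e_grid - tr$energy_ev[k])^2 / (2 * sigma^2))
  }
  if (jacobian) intensity <- intensity * td_constants$ev_nm / grid^2
  structure(list(wavelengths = grid, intensity = intensity,
                 state_label = sticks$state_label),
            class = "band_spectrum")
}

#' Non-negative linear combination of component spectra
#'
#' Solves `min || sum_i w_i comp_i - target ||^2` subject to `w_i >= 0`
#' (active-set non-negative least squares) and reports the weights as
#' percentages of their sum, as used to decompose transient spectra into
#' excited-state absorption components.
#'
#' @param components list of `band_spectrum` objects on a common grid
#' @param target numeric vector on the same grid
#' @return list with `weights` (>= 0), `percent` (sums to 100 when any
#'   weight is positive), `residual_rms`, and `fitted`
#' @export
fit_combination <- function(components, target) {
  if (length(components) < 1) stop("need at least one component")
  n <- length(target)
  mat <- vapply(components, function(b) {
    if (length(b$intensity) != n) stop("component grid does not match target")
    b$intensity
  }, numeric(n))
  mat <- as.matrix(mat)
  w <- pracma::lsqnonneg(mat, target)$x
  fitted <- drop(mat %*% w)
  total <- sum(w)
  percent <- if (total > 0) 100 * w / total else rep(0, length(w))
  labels <- vapply(components, function(b) b$state_label %||% "", character(1))
  names(w) <- names(percent) <- labels
  list(weights = w, percent = percent,
       residual_rms = sqrt(mean((target - fitted)^2)), fitted = fitted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a band spectrum as two-column delimited text
#'
#' @param band a `band_spectrum` (from [broaden])
#' @param path file path
#' @export
write_band_spectrum <- function(band, path) {
  utils::write.table(data.frame(wavelength_nm = band$wavelengths,
                                intensity = band$intensity),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_band_spectrum
#' @export
read_band_spectrum <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(list(wavelengths = tab$wavelength_nm, intensity = tab$intensity,
                 state_label = NULL), class = "band_spectrum")
}

#' Read / write stick spectra as delimited text
#'
#' Three columns: `state_label`, `energy_ev`, `f`. One file can hold several
#' states; `read_stick_spectra` returns a named list of [stick_spectrum].
#'
#' @param sticks list of [stick_spectrum]
#' @param path file path
#' @export
write_stick_spectra <- function(sticks, path) {
  rows <- do.call(rbind, lapply(sticks, function(s) {
    data.frame(state_label = s$state_label,
               energy_ev = s$transitions$energy_ev, f = s$transitions$f)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stick_spectra
#' @export
read_stick_spectra <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$state_label), function(d) {
    stick_spectrum(d$state_label[1], d$energy_ev, d$f)
  })
  out[unique(tab$state_label)]
}
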