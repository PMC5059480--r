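# Synthetic-data generators: broadband delta-A maps with known ground truth,
# and fixture stick spectra. All generators are pure functions of
# (config, seed): identical inputs give bit-identical outputs.

#' Configuration for the synthetic TAS generator
#'
#' Defaults emulate the measured 2-thiocytosine data: a two-lifetime
#' sequential band system (UV band near 355 nm decaying, visible band near
#' 525 nm rising, a broad featureless initial component), lifetimes 210 and
#' 480 fs, a 200 fs Gaussian IRF, polynomial probe chirp, iid Gaussian noise
#' and a masked pump-overtone window at 600-632 nm (the second harmonic of a
#' 308 nm pump falls at 616 nm). The delay grid mixes 20 fs linear spacing
#' up to 1 ps with logarithmic spacing beyond, as in typical pump-probe
#' acquisition.
#'
#' @param wavelengths probe grid (nm)
#' @param delays delay grid (fs)
#' @param tau1,tau2 generating lifetimes (fs)
#' @param irf_fwhm IRF width (fs)
#' @param t0 common time zero (fs)
#' @param das_shapes list of three data frames (components A, B, C), each
#'   with columns `center` (nm), `sd` (nm), `amp` (mOD): sums of Gaussians
#'   in wavelength
#' @param chirp polynomial chirp coefficients (fs, fs/nm, fs/nm^2, ...)
#' @param noise_sd Gaussian noise standard deviation (mOD)
#' @param mask_window wavelength window to mask (nm pair)
#' @param seed RNG seed
#' @return a `tas_gen_config` list
#' @export
tas_gen_config <- function(wavelengths = seq(320, 710, by = 2),
                           delays = c(seq(-1000, 980, by = 20),
                                      exp(seq(log(1000), log(5000),
                                              length.out = 50))),
                           tau1 = 210, tau2 = 480, irf_fwhm = 200, t0 = 0,
                           das_shapes = list(
                             A = data.frame(center = 500, sd = 150, amp = 0.35),
                             B = data.frame(center = c(355, 581),
                                            sd = c(25, 60),
                                            amp = c(1.0, 0.6)),
                             C = data.frame(center = c(525, 355),
                                            sd = c(55, 30),
                                            amp = c(0.8, 0.15))),
                           chirp = c(600, -2.0, 1.6e-3),
                           noise_sd = 0.05,
                           mask_window = c(600, 632),
                           seed = 1) {
  stopifnot(tau1 > 0, tau2 > 0, irf_fwhm > 0, noise_sd >= 0,
            length(das_shapes) == 3)
  if (length(wavelengths) < 2 || length(delays) < 10) {
    stop("degenerate wavelength or delay grid", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, delays = delays, tau1 = tau1,
                 tau2 = tau2, irf_fwhm = irf_fwhm, t0 = t0,
                 das_shapes = das_shapes, chirp = chirp, noise_sd = noise_sd,
                 mask_window = mask_window, seed = seed),
            class = "tas_gen_config")
}

# evaluate a sum-of-Gaussians band shape on the wavelength grid
.das_shape <- function(shape, wavelengths) {
  out <- rep(0, length(wavelengths))
  for (r in seq_len(nrow(shape))) {
    out <- out + shape$amp[r] *
      exp(-(wavelengths - shape$center[r])^2 / (2 * shape$sd[r]^2))
  }
  out
}

#' Generate a synthetic broadband TAS map with known ground truth
#'
#' Composes the bilinear map from the configured decay-associated spectra
#' and the IRF-convolved sequential profiles, imprints the probe chirp, adds
#' iid Gaussian noise, and masks the pump-overtone window.
#'
#' @param config a [tas_gen_config]
#' @return list with `map` (a [tas_map]) and `truth` (generating DAS,
#'   lifetimes, IRF, t0 and chirp coefficients)
#' @export
generate_tas <- function(config = tas_gen_config()) {
  stopifnot(inherits(config, "tas_gen_config"))
  das <- t(vapply(config$das_shapes, .das_shape, numeric(length(config$wavelengths)),
                  wavelengths = config$wavelengths))
  model <- sequential_model(config$tau1, config$tau2)
  irf <- irf_model(config$irf_fwhm, config$t0)
  prof <- sequential_profiles(model, irf, config$delays)
  map <- compose_map(das, prof, config$wavelengths, config$delays)
  if (any(config$chirp != 0)) map <- apply_chirp(map, config$chirp)
  if (config$noise_sd > 0) {
    rng <- .seeded_rng(config$seed)
    noise <- matrix(rng$norm(length(map$amplitudes), sd = config$noise_sd),
                    nrow(map$amplitudes), ncol(map$amplitudes))
    amp <- map$amplitudes + noise
    amp[map$mask] <- NA_real_
    map <- tas_map(map$wavelengths, map$delays, amp, map$mask)
  }
  in_window <- map$wavelengths >= config$mask_window[1] &
               map$wavelengths <= config$mask_window[2]
  if (any(in_window)) {
    msk <- map$mask
    msk[in_window, ] <- TRUE
    map <- tas_map(map$wavelengths, map$delays, map$amplitudes, msk)
  }
  list(map = map,
       truth = list(das = das, tau1 = config$tau1, tau2 = config$tau2,
                    irf_fwhm = config$irf_fwhm, t0 = config$t0,
                    chirp = config$chirp, noise_sd = config$noise_sd))
}

#' Fixture stick spectra for the four excited states
#'
#' Approximate stick positions at the published band maxima (the bright
#' pi_s-pi* singlet near 363 nm; the pi_s-pi* triplet at 441 and 546 nm;
#' the n_s-pi* singlet/triplet pairs at 333/576 and 333/574 nm) with
#' invented oscillator strengths honouring the 10-fold weaker absorbance of
#' the n_s-pi* states relative to the pi_s-pi* states. Fixtures for testing
#' and demonstration only.
#'
#' @return named list of four [stick_spectrum] objects
#' @export
fixture_sticks <- function() {
  nm <- function(x) convert_energy(x, "eV", from = "nm")
  list(
    "1pispi*" = stick_spectrum("1pispi*", nm(363), 1.0),
    "3pispi*" = stick_spectrum("3pispi*", nm(c(441, 546)), c(0.9, 0.9)),
    "1nspi*"  = stick_spectrum("1nspi*", nm(c(333, 576)), c(0.10, 0.05)),
    "3nspi*"  = stick_spectrum("3nspi*", nm(c(333, 574)), c(0.10, 0.05))
  )
}
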