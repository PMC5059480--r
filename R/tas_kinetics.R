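#' Gaussian instrument-response model
#'
#' @param fwhm full width at half maximum in fs (must be > 0)
#' @param t0 time zero in fs (single global value)
#' @return an object of class `irf_model` with fields `fwhm`, `t0` and the
#'   derived Gaussian width `sigma = fwhm / (2 sqrt(2 log 2))`
#' @export
irf_model <- function(fwhm, t0 = 0) {
  if (!is.numeric(fwhm) || length(fwhm) != 1 || fwhm <= 0) {
    stop("IRF fwhm must be a single positive number (fs)", call. = FALSE)
  }
  structure(list(fwhm = fwhm, t0 = t0, sigma = fwhm / (2 * sqrt(2 * log(2)))),
            class = "irf_model")
}

#' Two-component sequential kinetic model A -> B -> C
#'
#' @param tau1,tau2 lifetimes in fs of the first and second step
#' @param has_offset logical; keep the long-lived offset component C
#' @return an object of class `sequential_model`
#' @export
sequential_model <- function(tau1, tau2, has_offset = TRUE) {
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, has_offset = has_offset),
            class = "sequential_model")
}

#' Exponential decay convolved with a Gaussian IRF (closed form)
#'
#' Evaluates the exponentially modified Gaussian
#' \deqn{c(t) = \tfrac12 e^{-k(t-t_0) + k^2\sigma^2/2}\,
#'   \mathrm{erfc}\!\left(\frac{t_0 - t + k\sigma^2}{\sigma\sqrt2}\right)}
#' i.e. the convolution of `exp(-k (t - t0)) * H(t - t0)` with a unit-area
#' Gaussian of width `sigma`. Computed on the log scale so that large
#' `k * sigma` does not overflow. `rate = 0` gives the IRF-convolved step.
#'
#' @param rate decay rate in fs^-1 (>= 0)
#' @param irf an [irf_model]
#' @param delays numeric vector of delays (fs)
#' @return numeric vector of the same length as `delays`, values in [0, 1]
#' @export
emg_profile <- function(rate, irf, delays) {
  stopifnot(inherits(irf, "irf_model"))
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  s <- irf$sigma
  tau <- delays - irf$t0
  # log c = [-k tau + k^2 s^2 / 2] + log(Phi((tau - k s^2)/s))
  a <- -rate * tau + rate^2 * s^2 / 2
  lp <- stats::pnorm((tau - rate * s^2) / s, log.p = TRUE)
  exp(a + lp)
}

# d/dk of emg_profile at rate k (analytic); used for the tau1 == tau2 limit
.emg_dk <- function(rate, irf, delays) {
  s <- irf$sigma
  tau <- delays - irf$t0
  c0 <- emg_profile(rate, irf, delays)
  (s^2 * rate - tau) * c0 - (s / sqrt(2 * pi)) * exp(-tau^2 / (2 * s^2))
}

#' Concentration profiles of the sequential model A -> B -> C
#'
#' Returns the IRF-convolved populations of the initial species A, the
#' intermediate B, and the long-lived offset C. The three profiles sum to the
#' IRF-convolved step at every delay. The degenerate case `tau1 == tau2`
#' (within `1e-12` in rate) is handled by the analytic limit, a t-weighted
#' EMG term, to avoid catastrophic cancellation.
#'
#' @param model a [sequential_model]
#' @param irf an [irf_model]
#' @param delays numeric vector of delays (fs)
#' @return a matrix `[length(delays) x 3]` with columns `A`, `B`, `C`
#' @export
sequential_profiles <- function(model, irf, delays) {
  stopifnot(inherits(model, "sequential_model"))
  k1 <- 1 / model$tau1
  k2 <- 1 / model$tau2
  cA <- emg_profile(k1, irf, delays)
  if (abs(k1 - k2) < 1e-12) {
    cB <- -k1 * .emg_dk(k1, irf, delays)
  } else {
    cB <- k1 / (k1 - k2) * (emg_profile(k2, irf, delays) - cA)
  }
  step <- emg_profile(0, irf, delays)
  cC <- if (model$has_offset) step - cA - cB else rep(0, length(delays))
  cbind(A = cA, B = cB, C = cC)
}

#' Spectro-temporal difference-absorption map
#'
#' @param wavelengths strictly increasing probe wavelengths (nm)
#' @param delays strictly increasing pump-probe delays (fs)
#' @param amplitudes matrix `[n_wavelengths x n_delays]` of delta-A in mOD
#' @param mask logical matrix of the same shape; `TRUE` = excluded point.
#'   `NA` amplitudes are masked automatically.
#' @return an object of class `tas_map`
#' @export
tas_map <- function(wavelengths, delays, amplitudes, mask = NULL) {
  if (is.unsorted(wavelengths, strictly = TRUE) ||
      is.unsorted(delays, strictly = TRUE)) {
    stop("wavelength and delay axes must be strictly increasing", call. = FALSE)
  }
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != length(wavelengths) ||
      ncol(amplitudes) != length(delays)) {
    stop("amplitude matrix must be [n_wavelengths x n_delays]", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(amplitudes), ncol(amplitudes))
  mask <- mask | is.na(amplitudes)
  structure(list(wavelengths = wavelengths, delays = delays,
                 amplitudes = amplitudes, mask = mask),
            class = "tas_map")
}

#' @method print tas_map
#' @export
print.tas_map <- function(x, ...) {
  cat(sprintf("tas_map: %d wavelengths (%.0f-%.0f nm) x %d delays (%.0f-%.0f fs), %d masked\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              length(x$delays), min(x$delays), max(x$delays), sum(x$mask)))
  invisible(x)
}

#' Compose a map from decay-associated spectra and kinetic profiles
#'
#' The bilinear model underlying global analysis:
#' `amplitudes[i, j] = sum_comp das[comp, i] * profiles[j, comp]`.
#'
#' @param das matrix `[3 x n_wavelengths]`, rows A, B, C (mOD)
#' @param profiles matrix `[n_delays x 3]` from [sequential_profiles]
#' @param wavelengths,delays the axes
#' @return a [tas_map]
#' @export
compose_map <- function(das, profiles, wavelengths, delays) {
  das <- as.matrix(das)
  profiles <- as.matrix(profiles)
  if (ncol(das) != length(wavelengths) || nrow(das) != ncol(profiles) ||
      nrow(profiles) != length(delays)) {
    stop("dimension mismatch between DAS, profiles and axes", call. = FALSE)
  }
  tas_map(wavelengths, delays, t(das) %*% t(profiles))
}

# polynomial time zero t0(lambda) = sum_m a_m lambda^m, lambda in nm, t0 in fs
.chirp_t0 <- function(coeffs, wavelengths) {
  drop(outer(wavelengths, seq_along(coeffs) - 1, "^") %*% coeffs)
}

#' Shift each wavelength trace by a polynomial time zero (forward chirp)
#'
#' Used by the synthetic-data generator to imprint group-velocity dispersion:
#' the trace at wavelength `lambda` is delayed by `t0(lambda)`, i.e. the
#' recorded value at delay `t` is the undispersed value at `t - t0(lambda)`.
#'
#' @param map a [tas_map]
#' @param chirp_coeffs polynomial coefficients `a_0, a_1, ...` (fs per nm^m)
#' @return a [tas_map]
#' @export
apply_chirp <- function(map, chirp_coeffs) {
  .chirp_resample(map, -.chirp_t0(chirp_coeffs, map$wavelengths))
}

#' Correct a map for probe chirp (group-velocity dispersion)
#'
#' Each wavelength's trace is resampled onto the common delay axis by
#' interpolating at `t + t0(lambda)` where `t0(lambda)` is the polynomial in
#' `chirp_coeffs`. Points shifted outside the recorded window become masked.
#' With all coefficients zero the map is returned unchanged.
#'
#' @inheritParams apply_chirp
#' @return a [tas_map]
#' @export
chirp_correct <- function(map, chirp_coeffs) {
  .chirp_resample(map, .chirp_t0(chirp_coeffs, map$wavelengths))
}

.chirp_resample <- function(map, shift_fs) {
  stopifnot(inherits(map, "tas_map"))
  if (is.unsorted(map$delays, strictly = TRUE)) stop("delay axis must be monotone")
  amp <- map$amplitudes
  msk <- map$mask
  for (i in seq_along(map$wavelengths)) {
    if (shift_fs[i] == 0) next
    ok <- !msk[i, ]
    if (sum(ok) < 2L) { msk[i, ] <- TRUE; next }
    xout <- map$delays + shift_fs[i]
    y <- stats::approx(map$delays[ok], amp[i, ok], xout = xout, rule = 1)$y
    amp[i, ] <- y
    msk[i, ] <- is.na(y)
  }
  tas_map(map$wavelengths, map$delays, amp, msk)
}

# Conditionally linear (variable projection) residuals: given profiles C,
# solve the DAS row-wise on unmasked points and return residuals and DAS.
.varpro <- function(map, profiles) {
  nwl <- length(map$wavelengths)
  das <- matrix(0, 3, nwl, dimnames = list(c("A", "B", "C"), NULL))
  res <- rep(0, sum(!map$mask))
  pos <- 1L
  for (i in seq_len(nwl)) {
    ok <- !map$mask[i, ]
    n_ok <- sum(ok)
    if (n_ok == 0L) next
    Ci <- profiles[ok, , drop = FALSE]
    yi <- map$amplitudes[i, ok]
    fit <- stats::lm.fit(Ci, yi)
    das[, i] <- fit$coefficients
    das[is.na(das[, i]), i] <- 0
    res[pos:(pos + n_ok - 1L)] <- yi - Ci %*% das[, i]
    pos <- pos + n_ok
  }
  list(das = das, residuals = res)
}

#' Global target fit of a TAS map with the sequential model
#'
#' Minimises the summed squared residuals over (tau1, tau2, t0) — and the IRF
#' width if `fix_irf = FALSE` — with the decay-associated spectra solved as
#' the conditionally linear part (variable projection). The nonlinear part
#' uses bounded Levenberg-Marquardt least squares with a 3-point multi-start
#' log-spaced around the initial lifetimes; ties are broken by lowest
#' residual, then lowest tau1. Deterministic given identical inputs.
#'
#' @param map a [tas_map]; at least 2 wavelengths and 10 delays unmasked
#' @param init a [sequential_model] with the starting lifetimes
#' @param irf an [irf_model]; the width is held fixed when `fix_irf = TRUE`
#'   (the protocol value is 200 fs)
#' @param fix_irf keep the IRF width fixed at `irf$fwhm`
#' @param tau_bounds lifetime search interval in fs
#' @param multistart_factors multiplicative factors applied to both starting
#'   lifetimes
#' @return an object of class `tas_global_fit` with elements `model`
#'   (fitted [sequential_model]), `das` (`[3 x n_wavelengths]`), `irf`
#'   (fitted [irf_model]), `residual_rms` (mOD), `profiles`,
#'   `non_identifiable` flag, `convergence` info and `lifetime_uncertainties`
#'   (`NA` here; see [lifetime_uncertainty])
#' @export
global_fit <- function(map, init, irf, fix_irf = TRUE,
                       tau_bounds = c(5, 5e5),
                       multistart_factors = c(0.5, 1, 2)) {
  stopifnot(inherits(map, "tas_map"), inherits(init, "sequential_model"),
            inherits(irf, "irf_model"))
  unmasked_wl <- sum(rowSums(!map$mask) > 0)
  unmasked_delays <- sum(colSums(!map$mask) > 0)
  if (unmasked_wl < 2 || unmasked_delays < 10) {
    stop("need at least 2 wavelengths and 10 delays unmasked", call. = FALSE)
  }

  make_resid <- function() {
    function(p) {
      m <- sequential_model(exp(p[1]), exp(p[2]), init$has_offset)
      f <- if (fix_irf) irf$fwhm else exp(p[4])
      prof <- sequential_profiles(m, irf_model(f, p[3]), map$delays)
      .varpro(map, prof)$residuals
    }
  }
  resid_fn <- make_resid()

  lower <- c(log(tau_bounds[1]), log(tau_bounds[1]), min(map$delays))
  upper <- c(log(tau_bounds[2]), log(tau_bounds[2]), max(map$delays))
  if (!fix_irf) {
    lower <- c(lower, log(1)); upper <- c(upper, log(5e3))
  }

  best <- NULL
  for (f in multistart_factors) {
    p0 <- c(log(init$tau1 * f), log(init$tau2 * f), irf$t0)
    if (!fix_irf) p0 <- c(p0, log(irf$fwhm))
    p0 <- pmin(pmax(p0, lower), upper)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(ans)) next
    ss <- sum(ans$fvec^2)
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 && exp(ans$par[1]) < exp(best$par[1]))) {
      best <- list(par = ans$par, ss = ss, info = ans$info,
                   message = ans$message, niter = ans$niter)
    }
  }
  if (is.null(best)) stop("global fit failed to converge from all starts", call. = FALSE)

  par <- best$par
  tau <- exp(par[1:2])
  # exchange symmetry of the bilinear model: report the fast lifetime first
  if (tau[1] > tau[2]) tau <- rev(tau)
  fwhm <- if (fix_irf) irf$fwhm else exp(par[4])
  irf_fit <- irf_model(fwhm, par[3])
  model_fit <- sequential_model(tau[1], tau[2], init$has_offset)
  prof <- sequential_profiles(model_fit, irf_fit, map$delays)
  vp <- .varpro(map, prof)

  at_bound <- any(abs(par[1:2] - lower[1:2]) < 1e-6) ||
              any(abs(par[1:2] - upper[1:2]) < 1e-6)
  # a lifetime is non-identifiable when perturbing it leaves the
  # profile-subspace residual unchanged (flat direction of the fit)
  ss0 <- sum(vp$residuals^2)
  scale <- sum(map$amplitudes[!map$mask]^2)
  flat <- vapply(1:2, function(i) {
    taus <- c(model_fit$tau1, model_fit$tau2)
    taus[i] <- taus[i] * 1.5
    prof_p <- sequential_profiles(sequential_model(taus[1], taus[2],
                                                   init$has_offset),
                                  irf_fit, map$delays)
    ss_p <- sum(.varpro(map, prof_p)$residuals^2)
    (ss_p - ss0) <= max(1e-7 * ss0, 1e-10 * scale)
  }, logical(1))
  weak_c <- max(abs(vp$das[3, ])) < 1e-6 * (max(abs(vp$das[1, ])) + 1e-12)

  structure(list(
    model = model_fit, das = vp$das, irf = irf_fit,
    residual_rms = sqrt(mean(vp$residuals^2)),
    profiles = prof,
    non_identifiable = at_bound || any(flat),
    offset_absent = weak_c,
    lifetime_uncertainties = c(NA_real_, NA_real_),
    convergence = list(info = best$info, message = best$message,
                       niter = best$niter, ss = best$ss)
  ), class = "tas_global_fit")
}

#' @method print tas_global_fit
#' @export
print.tas_global_fit <- function(x, ...) {
  cat(sprintf("global fit: tau1 = %.1f fs, tau2 = %.1f fs, t0 = %.1f fs, IRF %.0f fs, rms %.4g mOD%s\n",
              x$model$tau1, x$model$tau2, x$irf$t0, x$irf$fwhm, x$residual_rms,
              if (x$non_identifiable) " [non-identifiable]" else ""))
  invisible(x)
}

#' Lifetime uncertainty across repeated fits
#'
#' Reported as twice the standard deviation of each lifetime across
#' independent fits, following the convention of analysing replicate
#' experiments separately.
#'
#' @param fits a list of [global_fit] results
#' @return named numeric vector `c(tau1 = , tau2 = )` in fs
#' @export
lifetime_uncertainty <- function(fits) {
  t1 <- vapply(fits, function(f) f$model$tau1, numeric(1))
  t2 <- vapply(fits, function(f) f$model$tau2, numeric(1))
  c(tau1 = 2 * stats::sd(t1), tau2 = 2 * stats::sd(t2))
}

#' Observed and fitted kinetic trace at one probe wavelength
#'
#' @param map a [tas_map]
#' @param wavelength probe wavelength in nm (nearest axis point is used)
#' @param fit a [global_fit] result for the same map
#' @return list with `wavelength` (the matched axis value), `delays`,
#'   `observed`, `fitted` (masked points are `NA` in `observed`)
#' @export
kinetic_trace <- function(map, wavelength, fit) {
  stopifnot(inherits(map, "tas_map"), inherits(fit, "tas_global_fit"))
  if (wavelength < min(map$wavelengths) || wavelength > max(map$wavelengths)) {
    stop("wavelength outside the probe axis", call. = FALSE)
  }
  i <- which.min(abs(map$wavelengths - wavelength))
  if (all(map$mask[i, ])) stop("trace is fully masked at this wavelength", call. = FALSE)
  obs <- map$amplitudes[i, ]
  obs[map$mask[i, ]] <- NA_real_
  fitted <- drop(fit$profiles %*% fit$das[, i])
  list(wavelength = map$wavelengths[i], delays = map$delays,
       observed = obs, fitted = fitted)
}

#' Write / read a TAS map as delimited text
#'
#' Layout: first row holds the probe wavelengths (nm), first column the
#' delays (fs), cells are delta-A in mOD; masked points are written as `NaN`.
#'
#' @param map a [tas_map]
#' @param path file path
#' @return `write_tas_map` returns `path` invisibly; `read_tas_map` a [tas_map]
#' @export
write_tas_map <- function(map, path) {
  amp <- map$amplitudes
  amp[map$mask] <- NaN
  out <- rbind(c(NA, map$wavelengths), cbind(map$delays, t(amp)))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "NaN")
  invisible(path)
}

#' @rdname write_tas_map
#' @export
read_tas_map <- function(path) {
  raw <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     na.strings = c("NaN", "NA")))
  wavelengths <- raw[1, -1]
  delays <- raw[-1, 1]
  amp <- t(raw[-1, -1, drop = FALSE])
  dimnames(amp) <- NULL
  tas_map(as.numeric(wavelengths), as.numeric(delays), amp)
}

#' Write decay-associated spectra as delimited text
#'
#' @param fit a [global_fit] result
#' @param wavelengths the probe axis (nm)
#' @param path file path
#' @export
write_das <- function(fit, wavelengths, path) {
  utils::write.table(
    data.frame(wavelength_nm = wavelengths,
               A = fit$das[1, ], B = fit$das[2, ], C = fit$das[3, ]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
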