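test_that("compose_map implements the bilinear model", {
  wl <- seq(350, 360, by = 5)
  t <- seq(-100, 400, by = 50)
  prof <- sequential_profiles(sequential_model(100, 300), irf_model(50), t)
  das0 <- matrix(0, 3, length(wl))
  expect_true(all(compose_map(das0, prof, wl, t)$amplitudes == 0))
  # one component, one wavelength: row = profile scaled by the DAS value
  das <- das0; das[2, 2] <- 1.5
  m <- compose_map(das, prof, wl, t)
  expect_equal(m$amplitudes[2, ], 1.5 * prof[, "B"])
  expect_true(all(m$amplitudes[-2, ] == 0))
  expect_error(compose_map(das, prof, wl[-1], t), "mismatch")
})

test_that("a noiseless synthetic map round-trips to its generating truth", {
  g <- noiseless_tas()
  fit <- global_fit(g$map, sequential_model(150, 700), irf_model(200, 0))
  expect_equal(fit$model$tau1, 210, tolerance = 1e-3)
  expect_equal(fit$model$tau2, 480, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
  # DAS comparable only where the map has unmasked data (the overtone
  # window rows are fully masked, so their DAS are undetermined)
  seen <- rowSums(!g$map$mask) > 0
  expect_equal(unname(fit$das[, seen]), unname(g$truth$das[, seen]),
               tolerance = 1e-4)
  # fitted trace equals observed identically in the exact model class
  tr <- kinetic_trace(g$map, 355, fit)
  expect_lt(max(abs(tr$observed - tr$fitted)), 1e-6)
})

test_that("variable projection agrees with a fully joint nonlinear fit", {
  cfg <- tas_gen_config(wavelengths = seq(340, 600, by = 40),
                        delays = seq(-600, 3000, by = 40),
                        noise_sd = 0.02, chirp = c(0, 0, 0), seed = 4)
  g <- generate_tas(cfg)
  irf <- irf_model(200, 0)
  vp <- global_fit(g$map, sequential_model(150, 700), irf)

  nwl <- length(g$map$wavelengths)
  joint_resid <- function(p) {
    m <- sequential_model(exp(p[1]), exp(p[2]))
    prof <- sequential_profiles(m, irf_model(200, p[3]), g$map$delays)
    das <- matrix(p[-(1:3)], 3, nwl)
    as.vector(g$map$amplitudes - t(das) %*% t(prof))
  }
  p0 <- c(log(vp$model$tau1 * 1.15), log(vp$model$tau2 * 0.9), 5,
          as.vector(vp$das * 1.1))
  joint <- minpack.lm::nls.lm(p0, fn = joint_resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  expect_equal(exp(joint$par[1]), vp$model$tau1, tolerance = 1e-6)
  expect_equal(exp(joint$par[2]), vp$model$tau2, tolerance = 1e-6)
})

test_that("a single-component map is flagged non-identifiable", {
  wl <- seq(350, 500, by = 10)
  t <- seq(-600, 4000, by = 25)
  prof <- sequential_profiles(sequential_model(210, 480), irf_model(200), t)
  das <- rbind(exp(-(wl - 400)^2 / 900), 0, 0)
  m <- compose_map(das, prof, wl, t)
  fit <- global_fit(m, sequential_model(150, 700), irf_model(200, 0))
  expect_true(fit$non_identifiable)
})

test_that("global_fit is deterministic and reports the fast lifetime first", {
  g <- memo("noisy_tas_seed2", function() generate_tas(tas_gen_config(seed = 2)))
  mc <- chirp_correct(g$map, g$truth$chirp)
  f1 <- global_fit(mc, sequential_model(150, 700), irf_model(200, 0))
  f2 <- global_fit(mc, sequential_model(150, 700), irf_model(200, 0))
  expect_identical(f1$model, f2$model)
  expect_identical(f1$das, f2$das)
  expect_lte(f1$model$tau1, f1$model$tau2)
  # swapped initialization converges to the same optimum
  f3 <- global_fit(mc, sequential_model(700, 150), irf_model(200, 0))
  expect_equal(f3$model$tau1, f1$model$tau1, tolerance = 1e-3)
})

test_that("kinetic_trace validates inputs and matches the composed model", {
  g <- noiseless_tas()
  fit <- global_fit(g$map, sequential_model(150, 700), irf_model(200, 0))
  expect_error(kinetic_trace(g$map, 9000, fit), "outside")
  tr <- kinetic_trace(g$map, 523, fit)
  i <- which.min(abs(g$map$wavelengths - 523))
  expect_equal(tr$wavelength, g$map$wavelengths[i])
  expect_equal(tr$fitted, drop(fit$profiles %*% fit$das[, i]))
  # fully masked wavelength errors out
  msk <- g$map$mask; msk[i, ] <- TRUE
  m2 <- tas_map(g$map$wavelengths, g$map$delays, g$map$amplitudes, msk)
  expect_error(kinetic_trace(m2, 523, fit), "masked")
})

test_that("lifetime uncertainty is twice the sd across replicate fits", {
  fits <- lapply(c(200, 210, 220), function(tau) {
    list(model = sequential_model(tau, 2 * tau))
  })
  u <- lifetime_uncertainty(fits)
  expect_equal(unname(u["tau1"]), 2 * stats::sd(c(200, 210, 220)))
  expect_equal(unname(u["tau2"]), 2 * stats::sd(c(400, 420, 440)))
})

test_that("TAS maps and DAS survive a text round trip", {
  g <- memo("noisy_tas_seed2", function() generate_tas(tas_gen_config(seed = 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tas_map(g$map, path)
  back <- read_tas_map(path)
  expect_equal(back$wavelengths, g$map$wavelengths)
  expect_equal(back$delays, g$map$delays)
  expect_equal(back$mask, g$map$mask)
  keep <- !g$map$mask
  expect_equal(back$amplitudes[keep], g$map$amplitudes[keep])
})
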