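hbar <- td_constants$hbar_ev_fs

test_that("Wigner sampling has the harmonic ground-state moments", {
  m <- model_2tc_template()
  ws <- wigner_sample(m, 4000, seed = 123)
  # per-mode variance 1/2 within +/- 3 standard errors
  for (k in seq_len(ncol(ws$q))) {
    expect_gt(stats::var(ws$q[, k]), 0.46)
    expect_lt(stats::var(ws$q[, k]), 0.54)
    expect_gt(stats::var(ws$p[, k]), 0.46)
    expect_lt(stats::var(ws$p[, k]), 0.54)
  }
  # mean energy per mode is the zero-point energy omega/2
  for (k in seq_len(ncol(ws$q))) {
    e <- m$frequencies[k] / 2 * (ws$q[, k]^2 + ws$p[, k]^2)
    expect_equal(mean(e), m$frequencies[k] / 2, tolerance = 0.05)
  }
  # bit-identical under the same seed, independent of the global RNG stream
  set.seed(99)
  ws2 <- wigner_sample(m, 4000, seed = 123)
  expect_identical(ws, ws2)
})

test_that("initial-state selection windows, weights and rejection behave", {
  m <- model_2tc()
  # a window excluding every state rejects everything
  ws <- wigner_sample(m, 20, seed = 3)
  rejected <- vapply(seq_len(20), function(i) {
    !select_initial_state(m, ws$q[i, ], c(9.0, 9.5), u = 0.5)$accepted
  }, logical(1))
  expect_true(all(rejected))
  expect_error(select_initial_state(m, ws$q[1, ], c(3.9, 3.4), 0.5), "empty")

  # window on the bright-state FC energy: majority of accepted starts have
  # dominant pi_s-pi* character
  ws <- wigner_sample(m, 300, seed = 5)
  set.seed(1)
  us <- stats::runif(300)
  bright <- 0L; acc <- 0L
  b_idx <- match("1pispi*", m$labels)
  for (i in seq_len(300)) {
    sel <- select_initial_state(m, ws$q[i, ], c(3.4, 3.9), us[i])
    if (!sel$accepted) next
    acc <- acc + 1L
    sf <- spinfree_states(m, ws$q[i, ])
    chars <- sf$singlet$vectors[, sel$adiabatic_index]^2
    if (which.max(chars) == which(sf$singlet$index == b_idx)) bright <- bright + 1L
  }
  expect_gt(acc, 50)
  expect_gt(bright / acc, 0.6)
})

test_that("a symmetric two-state tie selects 50/50", {
  m <- vibronic_model(0.05,
    states = list(
      list(label = "g", multiplicity = 1, energy = 0, kappa = 0, f_weight = 0),
      list(label = "e1", multiplicity = 1, energy = 3, kappa = 0, f_weight = 1),
      list(label = "e2", multiplicity = 1, energy = 3, kappa = 0, f_weight = 1)))
  set.seed(8)
  us <- stats::runif(10000)
  picks <- vapply(us, function(u) {
    sel <- select_initial_state(m, 0, c(2.5, 3.5), u)
    if (sel$accepted) sel$adiabatic_index else NA_integer_
  }, numeric(1))
  expect_true(all(!is.na(picks)))
  frac <- mean(picks == 2)
  expect_equal(frac, 0.5, tolerance = 3 * 0.5 / sqrt(10000) + 0.02)
})

test_that("electronic_step with identity overlap and diagonal H is pure phase", {
  E <- c(0.1, 0.7, 1.3)
  c0 <- c(0.6, 0.64, 0.48) + 0i
  c1 <- electronic_step(c0, diag(E), diag(E), diag(3), dt = 0.5, substeps = 25)
  expect_equal(Mod(c1)^2, Mod(c0)^2, tolerance = 1e-12)
  expect_equal(c1, c0 * exp(-1i * E * 0.5 / hbar), tolerance = 1e-10)
})

test_that("degenerate two-state coupling gives Rabi oscillation", {
  V <- 0.05
  H <- matrix(c(0, V, V, 0), 2, 2)
  cc <- c(1 + 0i, 0i)
  for (s in 1:100) cc <- electronic_step(cc, H, H, diag(2), 0.5, 25)
  t_end <- 50
  expect_equal(Mod(cc[1])^2, cos(V * t_end / hbar)^2, tolerance = 1e-6)
  expect_equal(Mod(cc[2])^2, sin(V * t_end / hbar)^2, tolerance = 1e-6)
  # period pi hbar / V: populations return to the start
  cc <- c(1 + 0i, 0i)
  period <- pi * hbar / V
  nstep <- 200
  for (s in 1:nstep) cc <- electronic_step(cc, H, H, diag(2), period / nstep, 25)
  expect_equal(Mod(cc[1])^2, 1, tolerance = 1e-6)
})

test_that("a random 4-state walk agrees with a fine-step reference", {
  # Hamiltonian scales of the near-degenerate manifold whose amplitudes
  # actually interfere: ~0.1-0.3 eV spreads, ~0.02 eV couplings, drifting by
  # ~0.01 eV per 0.5 fs nuclear step
  set.seed(17)
  n <- 4
  rand_herm <- function(scale) {
    A <- matrix(stats::rnorm(n * n), n) + 1i * matrix(stats::rnorm(n * n), n)
    scale * (A + Conj(t(A))) / 4
  }
  rand_overlap <- function() {
    K <- rand_herm(0.05)
    eg <- eigen(K)
    eg$vectors %*% diag(exp(1i * Re(eg$values))) %*% Conj(t(eg$vectors))
  }
  H <- diag(c(0, 0.1, 0.2, 0.3)) + rand_herm(0.02)
  H1s <- list(); H2s <- list(); Ss <- list()
  for (i in 1:20) {
    H1s[[i]] <- H
    H <- H + rand_herm(0.01)
    H2s[[i]] <- H
    Ss[[i]] <- rand_overlap()
  }
  prop <- function(substeps) {
    cc <- c(1, 0, 0, 0) + 0i
    for (i in 1:20) cc <- electronic_step(cc, H1s[[i]], H2s[[i]], Ss[[i]],
                                          0.5, substeps)
    cc
  }
  coarse <- prop(25)
  fine <- prop(2500)
  expect_lt(max(abs(Mod(coarse)^2 - Mod(fine)^2)), 1e-6)
  # norm conserved to numerical precision
  expect_equal(sum(Mod(coarse)^2), 1, tolerance = 1e-10)
})

test_that("electronic substep errors scale as dt^2", {
  set.seed(23)
  n <- 4
  A <- matrix(stats::rnorm(n * n), n) + 1i * matrix(stats::rnorm(n * n), n)
  H1 <- (A + Conj(t(A))) / 4
  B <- matrix(stats::rnorm(n * n), n) + 1i * matrix(stats::rnorm(n * n), n)
  H2 <- (B + Conj(t(B))) / 4
  c0 <- sqrt(c(0.4, 0.3, 0.2, 0.1)) + 0i
  ref <- electronic_step(c0, H1, H2, diag(n), 2, 4000)
  err <- vapply(c(5, 10, 20), function(ns) {
    max(abs(Mod(electronic_step(c0, H1, H2, diag(n), 2, ns))^2 - Mod(ref)^2))
  }, numeric(1))
  # halving the substep size quarters the error (order 2)
  expect_gt(err[1] / err[2], 2.5)
  expect_lt(err[1] / err[2], 6)
  expect_gt(err[2] / err[3], 2.5)
  expect_lt(err[2] / err[3], 6)
})

test_that("near-singular overlaps raise a diagnostics error", {
  S <- diag(2); S[2, 2] <- 1e-12
  expect_error(electronic_step(c(1, 0) + 0i, diag(2), diag(2), S, 0.5, 5),
               "overlap")
})

test_that("hop probabilities follow the population flux", {
  # stationary populations: no hops
  cc <- sqrt(c(0.5, 0.3, 0.2)) + 0i
  expect_equal(hop_probabilities(cc, cc, 1), rep(0, 3))
  # monotone transfer to one state: probability equals the fractional loss
  cb <- sqrt(c(0.8, 0.2, 0)) + 0i
  ca <- sqrt(c(0.7, 0.3, 0)) + 0i
  P <- hop_probabilities(cb, ca, 1)
  expect_equal(P[2], (0.8 - 0.7) / 0.8, tolerance = 1e-12)
  expect_equal(P[1], 0)
  expect_equal(P[3], 0)
  # gaining active state: no downward flux
  expect_equal(hop_probabilities(ca, cb, 1), rep(0, 3))
  expect_true(sum(P) <= 1)
})

test_that("hop decisions conserve energy by uniform momentum rescaling", {
  omega <- c(0.03, 0.02)
  p <- c(2, -1)
  energies <- c(3.0, 2.8, 3.4)
  ekin <- 0.5 * sum(omega * p^2)
  # downhill hop: accepted, kinetic energy grows by the gap
  dec <- hop_decision(c(0, 0.9, 0), active = 1, energies, p, omega, u = 0.5)
  expect_true(dec$hopped)
  expect_equal(dec$new_active, 2)
  expect_equal(0.5 * sum(omega * dec$p^2), ekin + energies[1] - energies[2],
               tolerance = 1e-12)
  expect_equal(dec$p / p, rep(dec$p[1] / p[1], 2))  # uniform rescale
  # frustrated uphill hop: momenta untouched
  dec2 <- hop_decision(c(0, 0, 0.9), active = 1, energies, p, omega, u = 0.5)
  expect_false(dec2$hopped)
  expect_true(dec2$frustrated)
  expect_identical(dec2$p, p)
  # no decision drawn above the cumulative probability
  dec3 <- hop_decision(c(0, 0.1, 0), active = 1, energies, p, omega, u = 0.95)
  expect_false(dec3$hopped)
})

test_that("energy-based decoherence damps and renormalizes as the closed form", {
  # C = 0, gap 1 eV, dt 0.5 fs: damping factor exp(-0.5 |dE| / hbar)
  cc <- sqrt(c(0.7, 0.3)) + 0i
  out <- decoherence_correct(cc, c(1.0, 2.0), active = 1,
                             kinetic_energy = 0.37, dt = 0.5, C = 0)
  f <- exp(-0.5 * 1.0 / hbar)
  expect_equal(Mod(out[2]), sqrt(0.3) * f, tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # all population already active: unchanged
  c1 <- c(1, 0) + 0i
  expect_equal(decoherence_correct(c1, c(1, 2), 1, 0.3, 0.5), c1)
  # zero gap: no damping, no division error
  out0 <- decoherence_correct(cc, c(1.5, 1.5), 1, 0.3, 0.5)
  expect_equal(Mod(out0), Mod(cc), tolerance = 1e-12)
  # random inputs renormalize exactly
  set.seed(3)
  for (i in 1:5) {
    cr <- stats::rnorm(5) + 1i * stats::rnorm(5)
    cr <- cr / sqrt(sum(Mod(cr)^2))
    outr <- decoherence_correct(cr, stats::runif(5, 1, 4), 2, 0.25, 0.5)
    expect_equal(sum(Mod(outr)^2), 1, tolerance = 1e-12)
  }
})
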