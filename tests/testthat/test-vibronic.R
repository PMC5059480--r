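# two-state 1D toy: ground state harmonic, excited state shifted/tilted
toy_2state <- function(lambda = 0, omega = 1) {
  vibronic_model(
    frequencies = omega,
    states = list(
      list(label = "g", multiplicity = 1, energy = 0, kappa = 0),
      list(label = "e", multiplicity = 1, energy = 1, kappa = -1)
    ),
    couplings = if (lambda > 0) {
      data.frame(state_i = "g", state_j = "e", mode = 1L, lambda = lambda)
    } else NULL
  )
}

test_that("the spin-free Hamiltonian is the LVC form with exact gradients", {
  m <- model_2tc_template()
  nm <- length(m$frequencies)
  # q = 0: diagonal equals the vertical energies
  h0 <- spinfree_hamiltonian(m, rep(0, nm))
  expect_equal(diag(h0$H),
               vapply(m$states, `[[`, numeric(1), "energy"))
  expect_true(all(h0$H == t(h0$H)))
  # finite differences vs analytic gradients at a random point
  set.seed(42)
  q <- stats::rnorm(nm)
  hg <- spinfree_hamiltonian(m, q)
  h <- 1e-5
  for (k in seq_len(nm)) {
    dq <- rep(0, nm); dq[k] <- h
    fd <- (spinfree_hamiltonian(m, q + dq)$H -
             spinfree_hamiltonian(m, q - dq)$H) / (2 * h)
    expect_lt(max(abs(fd - hg$grad[, , k])), 1e-6)
  }
})

test_that("with zero couplings the eigenvalues are the shifted diagonals", {
  m <- toy_2state(lambda = 0)
  for (q in c(-1.3, 0, 2.2)) {
    H <- spinfree_hamiltonian(m, q)$H
    expect_equal(sort(eigen(H, symmetric = TRUE)$values), sort(diag(H)))
  }
})

test_that("the total Hamiltonian is Hermitian and SOC blocks carry the magnitude", {
  m <- model_2tc_template()
  set.seed(7)
  for (i in 1:5) {
    q <- stats::rnorm(length(m$frequencies))
    H <- total_hamiltonian(spinfree_hamiltonian(m, q)$H, m)
    expect_lt(max(abs(H - Conj(t(H)))), 1e-14)
  }
  # singlet-triplet block Frobenius norm equals the configured magnitude
  S <- soc_matrix(m)
  map <- spin_expansion_map(m)
  row <- which(map == match("1nspi*", m$labels))
  cols <- which(map == match("3pispi*", m$labels))
  expect_equal(sqrt(sum(Mod(S[row, cols])^2)),
               160 / td_constants$cm1_per_ev, tolerance = 1e-12)
  # non-unit sublevel pattern is rejected
  expect_error(vibronic_model(0.1,
    list(list(label = "s", multiplicity = 1, energy = 0, kappa = 0),
         list(label = "t", multiplicity = 3, energy = 1, kappa = 0)),
    soc = data.frame(singlet = "s", triplet = "t", magnitude_cm1 = 100),
    sublevel_pattern = c(1, 1, 0)), "unit norm")
})

test_that("triplet sublevels are exactly degenerate without SOC", {
  m <- model_2tc_template(soc_scale = 0)
  q <- c(1.2, -0.4, 0.3, 0, 0.1, -0.2, 0, 0.05)
  H <- total_hamiltonian(spinfree_hamiltonian(m, q)$H, m)
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  # 9 levels: 3 singlets + 2 triply degenerate triplets
  tab <- table(round(ev, 10))
  expect_setequal(as.integer(tab), c(1L, 1L, 1L, 3L, 3L))
})

test_that("a 2-state toy with constant coupling has the closed-form spectrum", {
  m <- vibronic_model(0.1,
    list(list(label = "s", multiplicity = 1, energy = 0, kappa = 0),
         list(label = "t", multiplicity = 3, energy = 0.5, kappa = 0)),
    soc = data.frame(singlet = "s", triplet = "t", magnitude_cm1 = 400),
    sublevel_pattern = c(1, 0, 0))
  V <- 400 / td_constants$cm1_per_ev
  H <- total_hamiltonian(spinfree_hamiltonian(m, 0)$H, m)
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  delta <- 0.5
  coupled <- 0.25 + c(-1, 1) * sqrt((delta / 2)^2 + V^2)
  expect_equal(ev, sort(c(coupled, 0.5, 0.5)), tolerance = 1e-12)
})

test_that("minima and crossings of a 1D toy match a dense scan oracle", {
  m <- toy_2state(lambda = 0)
  tab <- data.frame(label = c("g min", "e min", "crossing"),
                    kind = c("minimum", "minimum", "CoIn"),
                    states = c("g", "e", "g|e"),
                    energy_ev = c(0, 0.5, 0.5),
                    bound = "eq", stringsAsFactors = FALSE)
  rep_ <- locate_critical_points(m, tab)
  # oracle: scan q in [-3, 3]
  q <- seq(-3, 3, by = 1e-4)
  e1 <- q^2 / 2
  e2 <- 1 - q + q^2 / 2
  cross_energy <- e1[which.min(abs(e1 - e2))]
  expect_equal(rep_$model_ev[1], 0, tolerance = 1e-8)
  expect_equal(rep_$model_ev[2], min(e2), tolerance = 1e-8)
  # the penalty search stops at a 1e-4 eV gap, which bounds the energy error
  expect_equal(rep_$model_ev[3], cross_energy, tolerance = 1e-4)
  expect_true(all(rep_$converged))
})

test_that("single harmonic state has its minimum at the origin", {
  m <- vibronic_model(c(0.1, 0.2),
    list(list(label = "g", multiplicity = 1, energy = 0, kappa = c(0, 0))))
  tab <- data.frame(label = "g min", kind = "minimum", states = "g",
                    energy_ev = 0, bound = "eq", stringsAsFactors = FALSE)
  rep_ <- locate_critical_points(m, tab)
  expect_equal(rep_$model_ev, 0, tolerance = 1e-10)
})

test_that("calibration of an already-exact template is a no-op", {
  m <- toy_2state(lambda = 0)
  tab <- data.frame(label = c("FC e", "e min"),
                    kind = c("FC-point", "minimum"),
                    states = c("e", "e"),
                    energy_ev = c(1, 0.5),
                    bound = "eq", stringsAsFactors = FALSE)
  cal <- calibrate_model(tab, m, free = list(energies = "e",
                                             kappas = list(e = 1L)))
  expect_lt(attr(cal, "parameter_change"), 1e-8)
})

test_that("the shipped calibrated model reproduces every printed energy", {
  rep_ <- locate_critical_points(model_2tc())
  expect_true(all(rep_$converged))
  expect_true(all(rep_$abs_error_ev <= 0.05))
  get <- function(lbl) rep_$model_ev[rep_$label == lbl]
  expect_equal(get("FC 1pispi*"), 3.65, tolerance = 0.05 / 3.65)
  expect_equal(get("1pispi*/1nspi* CoIn"), 3.02, tolerance = 0.05 / 3.02)
  expect_equal(get("3pispi* min"), 2.85, tolerance = 0.05 / 2.85)
  # ground-state recovery barrier from the lowest singlet minimum
  expect_gte(get("S0 relaxation barrier"), 0.8)
})

test_that("calibration failure reports the offending targets", {
  m <- toy_2state(lambda = 0)
  tab <- data.frame(label = "e min", kind = "minimum", states = "e",
                    energy_ev = 0.5, bound = "eq", stringsAsFactors = FALSE)
  expect_error(calibrate_model(tab, m, free = list(energies = character(0),
                                                   kappas = list()),
                               tol_ev = 1e-9),
               NA)  # exact already, no error even at a tight tolerance
  tab$energy_ev <- 2.0
  expect_error(calibrate_model(tab, m, free = list(energies = character(0),
                                                   kappas = list())),
               "calibration failed")
})

test_that("models survive a YAML round trip", {
  m <- model_2tc()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_vibronic_model(m, path)
  back <- read_vibronic_model(path)
  expect_equal(back$frequencies, m$frequencies)
  expect_equal(back$states, m$states)
  expect_equal(back$soc, m$soc)
  expect_equal(back$sublevel_pattern, m$sublevel_pattern)
})
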