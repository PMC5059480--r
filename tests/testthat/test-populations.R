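# minimal model for hand-worked classification: one excited singlet and one
# triplet on one mode
micro_model <- function(soc = 100) {
  vibronic_model(0.05,
    states = list(
      list(label = "g", multiplicity = 1, energy = 0, kappa = 0),
      list(label = "s", multiplicity = 1, energy = 2, kappa = -0.1),
      list(label = "t", multiplicity = 3, energy = 1.5, kappa = 0.1)),
    soc = data.frame(singlet = "s", triplet = "t", magnitude_cm1 = soc),
    sublevel_pattern = c(1, 0, 0))
}

test_that("classification assigns by dominant spin-free weight with tie-breaks", {
  m <- micro_model()
  # expanded basis: g, s, t(ms1), t(ms2), t(ms3); at q = 0 couplings are the
  # only mixing, so unit vectors classify to their own state
  expect_equal(classify_state(m, 0, c(1, 0, 0, 0, 0)), 1)  # S0
  expect_equal(classify_state(m, 0, c(0, 1, 0, 0, 0)), 2)  # S1
  expect_equal(classify_state(m, 0, c(0, 0, 1, 0, 0)), 3)  # T1
  expect_equal(classify_state(m, 0, c(0, 0, 0, 0, 1)), 3)  # any sublevel
  # hand-worked mixtures: 60/40 goes to the majority side
  expect_equal(classify_state(m, 0, sqrt(c(0, 0.6, 0.4, 0, 0))), 2)
  expect_equal(classify_state(m, 0, sqrt(c(0, 0.4, 0.3, 0.3, 0))), 3)
  # exact tie breaks toward the lower (singlet) class
  expect_equal(classify_state(m, 0, sqrt(c(0, 0.5, 0.5, 0, 0))), 2)
})

test_that("a hand-built three-snapshot ensemble averages as computed by hand", {
  m <- micro_model()
  # snapshot classes: S1, S1, T1 -> fractions S1 = 2/3, T1 = 1/3
  us <- list(sqrt(c(0, 0.9, 0.1, 0, 0)),
             sqrt(c(0, 0.7, 0.1, 0.1, 0.1)),
             sqrt(c(0, 0.2, 0.8, 0, 0)))
  cls <- vapply(us, function(u) classify_state(m, 0, u), numeric(1))
  expect_equal(cls, c(2, 2, 3))
})

test_that("population series are simplex-valued with pooled sublevels", {
  pop <- classify_populations(tc_ensemble())
  expect_true(all(pop$populations >= 0 & pop$populations <= 1))
  expect_equal(colSums(pop$populations), rep(1, length(pop$times)),
               tolerance = 1e-12)
  expect_setequal(pop$labels, c("S0", "S1", "S2", "T1", "T2"))
})

test_that("an exact exponential is recovered to high precision", {
  times <- seq(0, 2000, by = 10)
  series <- structure(list(
    times = times,
    populations = rbind(S2 = exp(-times / 250), S1 = 1 - exp(-times / 250)),
    labels = c("S2", "S1"), n_traj = 1,
    class_matrix = matrix(1L, 1, length(times))), class = "population_series")
  fit <- fit_population_decay(series, "S2", n_boot = 0)
  expect_equal(fit$tau, 250, tolerance = 1e-6)
  rise <- fit_population_decay(series, "S1", type = "rise", n_boot = 0)
  expect_equal(rise$tau, 250, tolerance = 1e-4)
})

test_that("flat populations are rejected as non-identifiable", {
  times <- seq(0, 100, by = 10)
  series <- structure(list(
    times = times, populations = rbind(S1 = rep(0.5, 11), S2 = rep(0.5, 11)),
    labels = c("S1", "S2"), n_traj = 1,
    class_matrix = matrix(1L, 1, 11)), class = "population_series")
  expect_error(fit_population_decay(series, "S1", n_boot = 0),
               "not identifiable")
})

test_that("single-state jump trajectories stay put", {
  rates <- data.frame(from = "S1", to = "T1", rate = 0)
  ens <- generate_trajectory_ensemble(rates, 20, 500, seed = 2)
  pop <- classify_populations(ens)
  expect_true(all(pop$populations["S1", ] == 1))
  expect_equal(triplet_yield(pop, 500), 0)
})

test_that("the deterministic master equation matches the closed form", {
  rates <- data.frame(from = "S2", to = "S1", rate = 1 / 160)
  ms <- markov_scheme(rates, n_traj = 10, t_max = 1000, seed = 3)
  expect_equal(ms$deterministic["S2", ], exp(-ms$times / 160),
               tolerance = 1e-10)
  expect_equal(colSums(ms$deterministic), rep(1, length(ms$times)),
               tolerance = 1e-10)
})

test_that("stochastic populations converge to the master equation", {
  ms <- markov_scheme(kinetic_scheme_2tc(), n_traj = 10000, t_max = 1000,
                      seed = 5, times = seq(0, 1000, by = 25))
  for (k in seq_along(ms$labels)) {
    p <- ms$deterministic[k, ]
    se <- sqrt(pmax(p * (1 - p), 1e-6) / 10000)
    expect_true(all(abs(ms$stochastic$populations[k, ] - p) <= 3.5 * se + 1e-3),
                label = ms$labels[k])
  }
})

test_that("branching fractions follow the configured rate ratio", {
  rates <- kinetic_scheme_2tc()
  ens <- generate_trajectory_ensemble(rates, 4000, 4000, seed = 6)
  # first jump out of S1 goes to T2 with probability 0.0028 / 0.0040
  to_t2 <- 0L; n_s1 <- 0L
  for (j in ens$jumps) {
    i <- which(j$state == "S1")[1]
    if (is.na(i) || i >= nrow(j)) next
    n_s1 <- n_s1 + 1L
    if (j$state[i + 1] == "T2") to_t2 <- to_t2 + 1L
  }
  p_hat <- to_t2 / n_s1
  p_true <- 0.0028 / (0.0028 + 0.0012)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n_s1))
})

test_that("mean S2 residence time matches the generating constant", {
  rates <- kinetic_scheme_2tc()
  ens <- generate_trajectory_ensemble(rates, 10000, 4000, seed = 8)
  waits <- vapply(ens$jumps, function(j) {
    if (nrow(j) < 2) NA_real_ else j$time[2]
  }, numeric(1))
  waits <- waits[!is.na(waits)]
  expect_equal(mean(waits), 160, tolerance = 2 * 160 / sqrt(length(waits)) / 160)
})

test_that("bootstrap CI width shrinks like one over root n", {
  rates <- kinetic_scheme_2tc()
  width <- vapply(c(137, 548), function(n) {
    ens <- generate_trajectory_ensemble(rates, n, 1000, seed = 9)
    pop <- classify_populations(ens)
    fit <- fit_population_decay(pop, "S2", n_boot = 120, seed = 2)
    diff(fit$ci_95)
  }, numeric(1))
  ratio <- width[1] / width[2]
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("triplet yield sums the T classes and validates its argument", {
  ens <- generate_trajectory_ensemble(
    data.frame(from = "T1", to = "T2", rate = 0), 5, 100, seed = 1)
  pop <- classify_populations(ens)
  expect_equal(triplet_yield(pop, 100), 1)
  expect_error(triplet_yield(pop, 1e6), "outside")
})
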