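# Spin-free population analysis of trajectory ensembles, exponential
# lifetime fitting, and a continuous-time Markov surrogate of the
# three-step relaxation scheme.

#' Classify one diagonal-basis state vector into a spin-free class
#'
#' The active diagonal state is assigned to the spin-free adiabatic class
#' (S0, S1, ..., T1, ... ordered energetically at the geometry) carrying the
#' largest squared weight; triplet sublevels are pooled. Ties within 1e-6
#' break deterministically toward the lower spin-free index.
#'
#' @param model a [vibronic_model]
#' @param q geometry
#' @param u complex state vector in the expanded (spin) basis
#' @return 1-based class index into [class_labels]
#' @export
classify_state <- function(model, q, u) {
  sf <- spinfree_states(model, q)
  map <- spin_expansion_map(model)
  w <- numeric(0)
  for (i in seq_along(sf$singlet$energies)) {
    amp <- 0i
    for (a in seq_along(sf$singlet$index)) {
      pos <- which(map == sf$singlet$index[a])[1]
      amp <- amp + sf$singlet$vectors[a, i] * u[pos]
    }
    w <- c(w, Mod(amp)^2)
  }
  if (!is.null(sf$triplet)) {
    for (j in seq_along(sf$triplet$energies)) {
      wt <- 0
      for (s in 1:3) {
        amp <- 0i
        for (b in seq_along(sf$triplet$index)) {
          pos <- which(map == sf$triplet$index[b])[s]
          amp <- amp + sf$triplet$vectors[b, j] * u[pos]
        }
        wt <- wt + Mod(amp)^2
      }
      w <- c(w, wt)
    }
  }
  which.max(w + 1e-12 * rev(seq_along(w)))
}

#' Spin-free electronic-state populations of an ensemble
#'
#' Per trajectory and time step the active diagonal state's spin-free class
#' (recorded during propagation) is counted; class fractions are averaged
#' over trajectories. Populations are simplex-valued at every time.
#'
#' @param ensemble an `sh_ensemble` or `jump_ensemble`
#' @param times optional time grid (fs); defaults to the recorded grid
#' @return a `population_series`: list with `times`, `populations`
#'   (`[n_classes x n_times]`, columns summing to 1), `labels`, `n_traj`,
#'   and `class_matrix` (`[n_traj x n_times]` integer classes, used for
#'   trajectory bootstraps)
#' @export
classify_populations <- function(ensemble, times = NULL) {
  UseMethod("classify_populations")
}

#' @export
classify_populations.sh_ensemble <- function(ensemble, times = NULL) {
  trajs <- ensemble$trajectories
  t_ref <- trajs[[1]]$log[, "time"]
  if (is.null(times)) times <- t_ref
  cm <- vapply(trajs, function(tr) {
    idx <- findInterval(times, tr$log[, "time"])
    idx[idx < 1L] <- 1L
    as.integer(tr$log[idx, "class"])
  }, integer(length(times)))
  cm <- t(matrix(cm, ncol = length(trajs)))
  .population_series(cm, times, ensemble$labels)
}

#' @export
classify_populations.jump_ensemble <- function(ensemble, times = NULL) {
  if (is.null(times)) times <- seq(0, ensemble$t_max, length.out = 201L)
  labels <- ensemble$labels
  cm <- t(vapply(ensemble$jumps, function(j) {
    idx <- findInterval(times, j$time)
    match(j$state[idx], labels)
  }, integer(length(times))))
  .population_series(cm, times, labels)
}

.population_series <- function(class_matrix, times, labels) {
  pop <- vapply(seq_along(labels), function(k) colMeans(class_matrix == k),
                numeric(length(times)))
  pop <- t(matrix(pop, ncol = length(labels)))
  rownames(pop) <- labels
  structure(list(times = times, populations = pop, labels = labels,
                 n_traj = nrow(class_matrix), class_matrix = class_matrix),
            class = "population_series")
}

#' @method print population_series
#' @export
print.population_series <- function(x, ...) {
  cat(sprintf("population_series: %d classes x %d times (0-%.0f fs), %d trajectories\n",
              nrow(x$populations), length(x$times), max(x$times), x$n_traj))
  invisible(x)
}

#' Write a population series as delimited text (time + one column per class)
#' @param series a `population_series`
#' @param path file path
#' @export
write_population_series <- function(series, path) {
  d <- data.frame(time_fs = series$times, t(series$populations))
  names(d)[-1] <- series$labels
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# delayed monoexponential model value
.delayed_exp <- function(par, t, rise) {
  A <- par[1]; td <- par[2]; tau <- exp(par[3])
  core <- exp(-pmax(t - td, 0) / tau)
  if (rise) A * (1 - core) else A * core
}

.fit_exp_curve <- function(t, y, rise, free_delay, free_amplitude) {
  A0 <- if (rise) max(y) else max(y)
  tau0 <- max(diff(range(t)) / 5, 1)
  obj <- function(par) {
    p <- c(if (free_amplitude) par[1] else A0,
           if (free_delay) par[2] else 0,
           par[3])
    sum((y - .delayed_exp(c(p[1], p[2], p[3]), t, rise))^2)
  }
  par0 <- c(A0, 0, log(tau0))
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  # polish with a second start at the optimum (restarted simplex)
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(amplitude = if (free_amplitude) opt$par[1] else A0,
       t_delay = if (free_delay) opt$par[2] else 0,
       tau = exp(opt$par[3]), ss = opt$value)
}

#' Fit a (delayed) monoexponential to one population class
#'
#' Least-squares fit of `p(t) = A exp(-max(t - t_d, 0)/tau)` for a decay, or
#' its complement for a rise. The 95% confidence interval is obtained by
#' bootstrap over trajectories (resampling rows of the class matrix),
#' seeded for reproducibility.
#'
#' @param series a `population_series` from [classify_populations]
#' @param class_label one of `series$labels`
#' @param type `"decay"` or `"rise"`
#' @param free_delay fit the onset `t_d` (default) or pin it at 0
#' @param free_amplitude fit the amplitude (default) or pin it at the curve
#'   maximum
#' @param n_boot bootstrap resamples (default 200; 0 disables the CI)
#' @param seed bootstrap seed
#' @return a `lifetime_fit`: list with `tau` (fs), `t_delay`, `amplitude`,
#'   `ci_95` (fs pair) and `boot_tau`
#' @export
fit_population_decay <- function(series, class_label, type = c("decay", "rise"),
                                 free_delay = TRUE, free_amplitude = TRUE,
                                 n_boot = 200, seed = 1) {
  type <- match.arg(type)
  k <- match(class_label, series$labels)
  if (is.na(k)) stop("unknown class label: ", class_label, call. = FALSE)
  y <- series$populations[k, ]
  if (max(y) <= 0 || stats::sd(y) < 1e-12) {
    stop("population of class ", class_label,
         " is flat; lifetime not identifiable", call. = FALSE)
  }
  fit <- .fit_exp_curve(series$times, y, type == "rise", free_delay, free_amplitude)
  ci <- c(NA_real_, NA_real_)
  boot_tau <- numeric(0)
  if (n_boot > 0) {
    rng <- .seeded_rng(seed)
    n <- nrow(series$class_matrix)
    boot_tau <- vapply(seq_len(n_boot), function(b) {
      rows <- rng$int(n, n)
      yb <- colMeans(series$class_matrix[rows, , drop = FALSE] == k)
      .fit_exp_curve(series$times, yb, type == "rise", free_delay,
                     free_amplitude)$tau
    }, numeric(1))
    ci <- stats::quantile(boot_tau, c(0.025, 0.975), names = FALSE)
  }
  structure(list(tau = fit$tau, t_delay = fit$t_delay,
                 amplitude = fit$amplitude, ci_95 = ci, boot_tau = boot_tau,
                 class_label = class_label, type = type),
            class = "lifetime_fit")
}

#' @method print lifetime_fit
#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("%s %s: tau = %.1f fs (95%% CI %.1f-%.1f), onset %.1f fs\n",
              x$class_label, x$type, x$tau, x$ci_95[1], x$ci_95[2], x$t_delay))
  invisible(x)
}

#' Stochastic jump trajectories on a kinetic state graph
#'
#' Exact event-driven (Gillespie) realizations of a continuous-time Markov
#' chain with the given first-order rate constants, all trajectories
#' starting in `initial_state`. Reproducible under the seed.
#'
#' @param rates data frame with columns `from`, `to`, `rate` (fs^-1, >= 0)
#' @param n_traj number of realizations
#' @param t_max total time (fs)
#' @param seed RNG seed
#' @param initial_state starting state label (default the first `from`)
#' @return a `jump_ensemble`: list of jump tables (`time`, `state` holding
#'   from t = 0), plus `labels` and `t_max`
#' @export
generate_trajectory_ensemble <- function(rates, n_traj, t_max, seed,
                                         initial_state = rates$from[1]) {
  if (any(rates$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  labels <- unique(c(rates$from, rates$to))
  rng <- .seeded_rng(seed)
  jumps <- lapply(seq_len(n_traj), function(i) {
    t <- 0
    s <- initial_state
    tt <- 0
    ss <- s
    repeat {
      out <- rates[rates$from == s & rates$rate > 0, ]
      if (!nrow(out)) break
      total <- sum(out$rate)
      t <- t - log(rng$unif(1)) / total
      if (t > t_max) break
      s <- if (nrow(out) == 1) out$to else {
        out$to[findInterval(rng$unif(1), c(0, cumsum(out$rate / total))) ]
      }
      tt <- c(tt, t)
      ss <- c(ss, s)
    }
    data.frame(time = tt, state = ss, stringsAsFactors = FALSE)
  })
  structure(list(jumps = jumps, labels = labels, t_max = t_max),
            class = "jump_ensemble")
}

#' Continuous-time Markov surrogate of the relaxation scheme
#'
#' Runs [generate_trajectory_ensemble] on the rate graph and additionally
#' solves the deterministic master equation `dp/dt = Q p` (matrix
#' exponential of the generator) on the same grid.
#'
#' @inheritParams generate_trajectory_ensemble
#' @param times output grid (fs)
#' @return list with `stochastic` (a `population_series`), `deterministic`
#'   (matrix `[n_classes x n_times]`), `times`, `labels`
#' @export
markov_scheme <- function(rates, n_traj, t_max, seed,
                          times = seq(0, t_max, length.out = 201L),
                          initial_state = rates$from[1]) {
  ens <- generate_trajectory_ensemble(rates, n_traj, t_max, seed,
                                      initial_state)
  series <- classify_populations(ens, times)
  labels <- ens$labels
  n <- length(labels)
  Q <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(rates))) {
    Q[rates$to[r], rates$from[r]] <- Q[rates$to[r], rates$from[r]] + rates$rate[r]
    Q[rates$from[r], rates$from[r]] <- Q[rates$from[r], rates$from[r]] - rates$rate[r]
  }
  p0 <- as.numeric(labels == initial_state)
  det <- vapply(times, function(t) {
    as.numeric(Matrix::expm(Q * t) %*% p0)
  }, numeric(n))
  det <- matrix(det, n, length(times), dimnames = list(labels, NULL))
  list(stochastic = series, deterministic = det, times = times,
       labels = labels)
}

#' Default kinetic scheme of 2-thiocytosine relaxation
#'
#' Three-step scheme S2 -> S1 -> {T2, T1}, T2 -> T1 with first-order rate
#' constants anchored to the simulated time constants: S2 depopulation at
#' 1/160 fs^-1, total S1 intersystem crossing at 1/250 fs^-1 split 70/30 in
#' favour of T2 (which is populated faster than T1), and T2 -> T1 internal
#' conversion at 1/480 fs^-1.
#'
#' @return data frame with columns `from`, `to`, `rate` (fs^-1)
#' @export
kinetic_scheme_2tc <- function() {
  path <- system.file("extdata", "kinetic_scheme_2tc.csv", package = "thiodyn")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Total triplet population at a time
#'
#' @param series a `population_series`
#' @param t time in fs (nearest grid point is used; must lie in the grid range)
#' @return sum of the populations of all T classes
#' @export
triplet_yield <- function(series, t) {
  if (t < min(series$times) || t > max(series$times)) {
    stop("t outside the population time grid", call. = FALSE)
  }
  j <- which.min(abs(series$times - t))
  tr <- grepl("^T", series$labels)
  sum(series$populations[tr, j])
}
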