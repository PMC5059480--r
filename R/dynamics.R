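# Surface hopping with spin-orbit coupling on a vibronic model.
# The inner loop lives in src/dynamics.cpp; the step primitives exposed here
# call the same compiled code paths the full propagator uses.

# pack a vibronic_model into the flat list the C++ core consumes
.dyn_model_pack <- function(model) {
  stopifnot(inherits(model, "vibronic_model"))
  n <- length(model$states)
  m <- length(model$frequencies)
  kappa <- t(vapply(model$states, `[[`, numeric(m), "kappa"))
  quad <- t(vapply(model$states, function(s) {
    if (is.null(s$quad)) rep(0, m) else s$quad
  }, numeric(m)))
  cp <- model$couplings
  cpl <- if (nrow(cp)) {
    cbind(match(cp$state_i, model$labels), match(cp$state_j, model$labels),
          cp$mode, cp$lambda)
  } else matrix(0, 0, 4)
  soc <- soc_matrix(model)
  list(omega = model$frequencies,
       E0 = vapply(model$states, `[[`, numeric(1), "energy"),
       kappa = matrix(kappa, n, m), quad = matrix(quad, n, m),
       cpl = cpl, mult = as.integer(model$multiplicities),
       map = as.integer(spin_expansion_map(model)),
       soc_re = Re(soc), soc_im = Im(soc))
}

#' Ensemble specification for surface-hopping runs
#'
#' @param n_traj number of trajectories
#' @param t_max total simulation time (fs)
#' @param dt_nuclear nuclear time step (fs); default 0.5
#' @param dt_electronic electronic time step (fs); default 0.02. The ratio
#'   `dt_nuclear / dt_electronic` must be a positive integer (default 25
#'   substeps per nuclear step).
#' @param seed base RNG seed; trajectory i uses `seed + i - 1`
#' @param decoherence_C energy-based decoherence constant in eV (default the
#'   customary 0.1 hartree = 2.7211 eV)
#' @param record_stride store every k-th nuclear step (1 = all)
#' @return an object of class `ensemble_spec`
#' @export
ensemble_spec <- function(n_traj = 137, t_max = 1000, dt_nuclear = 0.5,
                          dt_electronic = 0.02, seed = 1,
                          decoherence_C = 2.7211386, record_stride = 1L) {
  substeps <- dt_nuclear / dt_electronic
  if (abs(substeps - round(substeps)) > 1e-9 || substeps < 1) {
    stop("dt_nuclear / dt_electronic must be a positive integer", call. = FALSE)
  }
  structure(list(n_traj = n_traj, t_max = t_max, dt_nuclear = dt_nuclear,
                 dt_electronic = dt_electronic, substeps = as.integer(round(substeps)),
                 seed = as.integer(seed), decoherence_C = decoherence_C,
                 record_stride = as.integer(record_stride)),
            class = "ensemble_spec")
}

#' Sample initial conditions from the ground-state harmonic Wigner function
#'
#' Positions and momenta of each dimensionless mode are independent Gaussians
#' with mean 0 and variance 1/2, the Wigner distribution of the vibrational
#' ground state. Reproducible under the seed.
#'
#' @param model a [vibronic_model] (only the mode count is used)
#' @param n number of samples
#' @param seed RNG seed
#' @return list with matrices `q` and `p`, each `[n x n_modes]`
#' @export
wigner_sample <- function(model, n, seed) {
  m <- length(model$frequencies)
  rng <- .seeded_rng(seed)
  q <- matrix(rng$norm(n * m, sd = sqrt(0.5)), n, m)
  p <- matrix(rng$norm(n * m, sd = sqrt(0.5)), n, m)
  list(q = q, p = p)
}

# small private RNG so sampling does not disturb the global stream
.seeded_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  use <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n, sd = 1) use(stats::rnorm, n, sd = sd),
       unif = function(n) use(stats::runif, n),
       int = function(n, max) use(function(n, max) sample.int(max, n, replace = TRUE), n, max))
}

#' Spin-free adiabatic states at a geometry
#'
#' Diagonalizes the singlet and triplet blocks of the spin-free Hamiltonian
#' separately and orders each by energy (S0, S1, ...; T1, T2, ...).
#'
#' @param model a [vibronic_model]
#' @param q coordinate vector
#' @return list with `singlet` and `triplet`, each containing `energies` and
#'   `vectors` (columns, in the diabatic state basis of that block) and
#'   `index` (spin-free state indices of the block)
#' @export
spinfree_states <- function(model, q) {
  H <- spinfree_hamiltonian(model, q)$H
  out <- list()
  for (mult in c(1, 3)) {
    idx <- which(model$multiplicities == mult)
    nm <- if (mult == 1) "singlet" else "triplet"
    if (!length(idx)) { out[[nm]] <- NULL; next }
    e <- eigen(H[idx, idx, drop = FALSE], symmetric = TRUE)
    ord <- order(e$values)
    out[[nm]] <- list(energies = e$values[ord],
                      vectors = e$vectors[, ord, drop = FALSE], index = idx)
  }
  out
}

#' Select the initial electronic state for a sampled geometry
#'
#' Excited singlet adiabatic states whose vertical excitation energy at the
#' geometry falls inside the window are candidates; the sample is accepted
#' into candidate i with probability proportional to its
#' oscillator-strength surrogate weight (the diabatic `f_weight`s contracted
#' with the adiabatic character), normalised by the largest weight in the
#' model, and rejected otherwise.
#'
#' @param model a [vibronic_model] with `f_weight` entries
#' @param q sampled geometry
#' @param excitation_window eV pair `c(lo, hi)`
#' @param u uniform random number in [0,1) driving the accept/reject draw
#' @return list with `accepted`, and when accepted `adiabatic_index` (within
#'   the singlet block), `energy_ev`, and `state_vector` (expanded basis,
#'   ready for [run_trajectory])
#' @export
select_initial_state <- function(model, q, excitation_window, u) {
  if (excitation_window[1] >= excitation_window[2]) {
    stop("empty excitation window", call. = FALSE)
  }
  sf <- spinfree_states(model, q)
  es <- sf$singlet$energies
  exc <- es - es[1]
  f <- vapply(model$states, function(s) s$f_weight %||% 0, numeric(1))
  f_ref <- max(f)
  if (f_ref <= 0) stop("model has no oscillator-strength surrogate weights", call. = FALSE)
  w <- rep(0, length(es))
  for (i in seq_along(es)[-1]) {
    chars <- sf$singlet$vectors[, i]^2
    w[i] <- sum(chars * f[sf$singlet$index])
  }
  cand <- which(exc >= excitation_window[1] & exc <= excitation_window[2])
  cand <- setdiff(cand, 1L)
  if (!length(cand)) return(list(accepted = FALSE))
  p <- w[cand] / f_ref
  if (sum(p) > 1) p <- p / sum(p)
  cum <- cumsum(p)
  j <- findInterval(u, c(0, cum))
  if (j > length(cand)) return(list(accepted = FALSE))
  i <- cand[j]
  vec <- rep(0, length(spin_expansion_map(model)))
  pos <- match(sf$singlet$index, spin_expansion_map(model))
  vec[pos] <- sf$singlet$vectors[, i]
  list(accepted = TRUE, adiabatic_index = i, energy_ev = exc[i],
       state_vector = vec)
}

# expanded-basis unit vector for a diabatic state label (first sublevel)
.diabatic_state_vector <- function(model, label) {
  a <- match(label, model$labels)
  if (is.na(a)) stop("unknown state label: ", label, call. = FALSE)
  map <- spin_expansion_map(model)
  v <- rep(0, length(map))
  v[which(map == a)[1]] <- 1
  v
}

#' Propagate a single surface-hopping trajectory
#'
#' Velocity-Verlet nuclear motion on the active diagonal (spin-mixed)
#' surface; per nuclear step the total Hamiltonian is diagonalized, the
#' electronic coefficients are propagated by local diabatization over
#' `substeps` electronic substeps, an energy-based decoherence correction is
#' applied, and a fewest-switches hop decision is drawn. Hops conserve total
#' energy by uniform momentum rescaling; energetically frustrated hops leave
#' the momenta unchanged. Trajectories whose total-energy drift exceeds
#' 0.1 eV are flagged invalid.
#'
#' @param model a [vibronic_model]
#' @param ic list with `q`, `p` and either `state` (a diabatic label) or
#'   `state_vector` (expanded-basis amplitude vector, e.g. from
#'   [select_initial_state])
#' @param spec an [ensemble_spec]
#' @param seed RNG seed for the hop decisions (defaults to `spec$seed`)
#' @param stop_q1_above optional early-stop threshold on the first coordinate
#' @param gap_thresh energy gap (eV) below which the nuclear step is
#'   adaptively subdivided in proportion to the gap, so that close passages
#'   at surface intersections are resolved instead of stepped over
#' @param max_subdiv cap on the subdivision factor
#' @return an `sh_trajectory`: list with `log` (matrix, one row per recorded
#'   step), `cols` (column-name map), hop/frustration counts, `max_drift`,
#'   `max_norm_err`, `invalid`, `final_class`
#' @export
run_trajectory <- function(model, ic, spec, seed = spec$seed,
                           stop_q1_above = 1e300, gap_thresh = 0.1,
                           max_subdiv = 256L) {
  v <- if (!is.null(ic$state_vector)) ic$state_vector
       else .diabatic_state_vector(model, ic$state)
  res <- run_trajectory_cpp(.dyn_model_pack(model), ic$q, ic$p,
                            as.complex(v), spec$t_max, spec$dt_nuclear,
                            spec$substeps, spec$decoherence_C,
                            as.integer(seed), stop_q1_above,
                            spec$record_stride, 0.1, gap_thresh, max_subdiv)
  m <- length(model$frequencies)
  N <- length(spin_expansion_map(model))
  cols <- c("time", paste0("q", seq_len(m)), paste0("p", seq_len(m)),
            "active", "class", "ekin", "etot", "norm_err", "hops",
            paste0("E", seq_len(N)))
  colnames(res$log) <- cols
  res$cols <- cols
  class(res) <- "sh_trajectory"
  res
}

#' Class labels of the spin-free adiabatic states of a model
#'
#' @param model a [vibronic_model]
#' @return character vector, singlets first: `S0, S1, ..., T1, T2, ...`
#' @export
class_labels <- function(model) {
  ns <- sum(model$multiplicities == 1)
  nt <- sum(model$multiplicities == 3)
  c(paste0("S", seq_len(ns) - 1), if (nt) paste0("T", seq_len(nt)))
}

#' Run a surface-hopping ensemble
#'
#' Initial conditions are drawn from the ground-state Wigner distribution;
#' when an excitation window is given, geometries are filtered through
#' [select_initial_state] (sampling continues until `n_traj` acceptances),
#' otherwise every trajectory starts in `initial_state`. Trajectory i uses
#' seed `spec$seed + i - 1`, so the ensemble is reproducible and its
#' observables do not depend on evaluation order.
#'
#' @param model a [vibronic_model]
#' @param spec an [ensemble_spec]
#' @param window optional excitation window in eV, e.g. `c(3.4, 3.9)`
#' @param initial_state diabatic label used when `window` is `NULL`
#' @param max_flagged_frac error threshold on the fraction of
#'   energy-drift-flagged trajectories (default 0.2)
#' @return an `sh_ensemble`: list of `sh_trajectory` plus `spec`, per-run
#'   summary counts and the class-label map
#' @export
run_ensemble <- function(model, spec, window = NULL,
                         initial_state = "1pispi*",
                         max_flagged_frac = 0.2) {
  rng <- .seeded_rng(spec$seed)
  ics <- list()
  n_sampled <- 0L
  batch <- max(64L, spec$n_traj)
  while (length(ics) < spec$n_traj) {
    ws <- wigner_sample(model, batch, spec$seed + 7919L + n_sampled)
    us <- rng$unif(batch)
    for (i in seq_len(batch)) {
      if (length(ics) >= spec$n_traj) break
      if (is.null(window)) {
        ics[[length(ics) + 1L]] <- list(q = ws$q[i, ], p = ws$p[i, ],
                                        state = initial_state)
      } else {
        sel <- select_initial_state(model, ws$q[i, ], window, us[i])
        if (sel$accepted) {
          ics[[length(ics) + 1L]] <- list(q = ws$q[i, ], p = ws$p[i, ],
                                          state_vector = sel$state_vector)
        }
      }
    }
    n_sampled <- n_sampled + batch
    if (n_sampled > 1000L * spec$n_traj) {
      stop("initial-state selection rejected nearly all samples", call. = FALSE)
    }
  }
  trajs <- vector("list", spec$n_traj)
  for (i in seq_len(spec$n_traj)) {
    trajs[[i]] <- run_trajectory(model, ics[[i]], spec, seed = spec$seed + i - 1L)
  }
  invalid <- vapply(trajs, `[[`, logical(1), "invalid")
  if (mean(invalid) > max_flagged_frac) {
    stop(sprintf("%.0f%% of trajectories flagged for energy drift",
                 100 * mean(invalid)), call. = FALSE)
  }
  structure(list(trajectories = trajs, spec = spec,
                 labels = class_labels(model),
                 n_frustrated = sum(vapply(trajs, `[[`, numeric(1), "n_frustrated")),
                 n_hops = sum(vapply(trajs, `[[`, numeric(1), "n_hops")),
                 n_invalid = sum(invalid)),
            class = "sh_ensemble")
}

#' @method print sh_ensemble
#' @export
print.sh_ensemble <- function(x, ...) {
  cat(sprintf("sh_ensemble: %d trajectories, %d hops, %d frustrated, %d flagged\n",
              length(x$trajectories), x$n_hops, x$n_frustrated, x$n_invalid))
  invisible(x)
}

#' Electronic propagation over one nuclear step (local diabatization)
#'
#' Löwdin-orthonormalizes the overlap matrix, transforms the end-of-step
#' Hamiltonian into the locally diabatic frame, propagates the coefficients
#' with a linearly interpolated Hamiltonian over `substeps` substeps and
#' rotates into the new adiabatic basis. Norm-conserving to numerical
#' precision.
#'
#' @param coeffs complex coefficient vector at the start of the step
#' @param H1 Hamiltonian (eV) in the current basis at t
#' @param H2 Hamiltonian (eV) in the new basis at t + dt
#' @param overlap basis overlap matrix between t and t + dt
#' @param dt nuclear step (fs)
#' @param substeps number of electronic substeps
#' @return complex coefficient vector in the new basis
#' @export
electronic_step <- function(coeffs, H1, H2, overlap, dt, substeps = 25L) {
  drop(electronic_step_cpp(as.complex(coeffs), .as_cx_mat(H1), .as_cx_mat(H2),
                           .as_cx_mat(overlap), dt, as.integer(substeps)))
}

.as_cx_mat <- function(x) matrix(as.complex(x), nrow(x), ncol(x))

#' Fewest-switches hop probabilities from the population flux
#'
#' The fraction of active-state population lost over the nuclear step is
#' distributed over the states that gained population; with stationary
#' populations all probabilities are zero, and a monotonic transfer to a
#' single target carries the full fractional loss.
#'
#' @param coeffs_before,coeffs_after complex coefficients at the start/end of
#'   the nuclear step
#' @param active 1-based index of the active state
#' @return numeric vector of per-state hop probabilities (sum <= 1)
#' @export
hop_probabilities <- function(coeffs_before, coeffs_after, active) {
  drop(hop_probabilities_cpp(as.complex(coeffs_before),
                             as.complex(coeffs_after), as.integer(active)))
}

#' Draw a hop decision and conserve energy by uniform momentum rescaling
#'
#' @param probabilities per-state probabilities from [hop_probabilities]
#' @param active current active state (1-based)
#' @param energies diagonal energies (eV) at the end of the step
#' @param p momentum vector
#' @param omega mode frequencies (eV)
#' @param u uniform random number in [0,1)
#' @return list with `new_active`, `p` (possibly rescaled), `hopped`,
#'   `frustrated`
#' @export
hop_decision <- function(probabilities, active, energies, p, omega, u) {
  cum <- cumsum(probabilities)
  target <- findInterval(u, c(0, cum))
  if (target > length(probabilities) || target == active ||
      probabilities[target] <= 0) {
    return(list(new_active = active, p = p, hopped = FALSE, frustrated = FALSE))
  }
  ekin <- 0.5 * sum(omega * p^2)
  ekin_new <- ekin + energies[active] - energies[target]
  if (ekin_new < 0 || ekin <= 0) {
    return(list(new_active = active, p = p, hopped = FALSE, frustrated = TRUE))
  }
  list(new_active = target, p = p * sqrt(ekin_new / ekin), hopped = TRUE,
       frustrated = FALSE)
}

#' Energy-based decoherence correction
#'
#' Damps each non-active amplitude by `exp(-dt / tau_k)` with
#' `tau_k = hbar / |E_k - E_active| * (1 + C / E_kin)` and rescales the
#' active amplitude to restore unit norm. A vanishing gap means an infinite
#' damping time (no damping).
#'
#' @param coeffs complex coefficient vector
#' @param energies diagonal energies (eV)
#' @param active 1-based active-state index
#' @param kinetic_energy nuclear kinetic energy (eV)
#' @param dt nuclear time step (fs)
#' @param C decoherence constant (eV); default 0.1 hartree
#' @return corrected complex coefficient vector (unit norm)
#' @export
decoherence_correct <- function(coeffs, energies, active, kinetic_energy, dt,
                                C = 2.7211386) {
  drop(decoherence_cpp(as.complex(coeffs), energies, as.integer(active),
                       kinetic_energy, dt, C))
}

#' One-dimensional two-state avoided-crossing toy model
#'
#' A singlet and a triplet diabat with slopes `kappa1`, `kappa2` on one mode
#' (plus a weak harmonic term), coupled by a constant spin-orbit matrix
#' element concentrated in a single sublevel, so the physics is an effective
#' two-state Landau-Zener problem.
#'
#' @param kappa1,kappa2 diabatic slopes (eV per unit coordinate)
#' @param soc_cm coupling magnitude in cm^-1
#' @param omega mode frequency (eV)
#' @return a [vibronic_model]
#' @export
lz_toy_model <- function(kappa1 = -0.1, kappa2 = -0.3, soc_cm = 282,
                         omega = 0.01) {
  vibronic_model(
    frequencies = omega,
    states = list(
      list(label = "d1", multiplicity = 1, energy = 0, kappa = kappa1,
           f_weight = 1),
      list(label = "d2", multiplicity = 3, energy = 0, kappa = kappa2,
           f_weight = 0)
    ),
    soc = data.frame(singlet = "d1", triplet = "d2", magnitude_cm1 = soc_cm),
    sublevel_pattern = c(1, 0, 0)
  )
}

#' Landau-Zener diabatic survival probability
#'
#' `exp(-2 pi V^2 / (hbar v |dk|))` for a linearly swept crossing with
#' constant coupling V, crossing speed v (coordinate units per fs) and
#' difference of diabatic slopes `dk` (eV per coordinate unit).
#'
#' @param V coupling in eV
#' @param v speed at the crossing (1/fs)
#' @param dkappa absolute slope difference (eV)
#' @return probability of remaining on the initial diabat
#' @export
landau_zener_probability <- function(V, v, dkappa) {
  exp(-2 * pi * V^2 / (td_constants$hbar_ev_fs * v * abs(dkappa)))
}

#' Write an ensemble to a directory with a manifest
#'
#' One delimited-text log per trajectory plus a `manifest.yaml` recording
#' the run specification, seed and summary counts — sufficient to reproduce
#' the ensemble bit-for-bit.
#'
#' @param ensemble an `sh_ensemble`
#' @param dir output directory (created if needed)
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$trajectories)) {
    write_trajectory(ensemble$trajectories[[i]],
                     file.path(dir, sprintf("trajectory_%03d.tsv", i)))
  }
  yaml::write_yaml(list(
    n_traj = ensemble$spec$n_traj, t_max = ensemble$spec$t_max,
    dt_nuclear = ensemble$spec$dt_nuclear,
    dt_electronic = ensemble$spec$dt_electronic,
    decoherence_C = ensemble$spec$decoherence_C,
    seed = ensemble$spec$seed, labels = as.list(ensemble$labels),
    n_hops = ensemble$n_hops, n_frustrated = ensemble$n_frustrated,
    n_invalid = ensemble$n_invalid),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write a trajectory log as delimited text
#'
#' One row per recorded nuclear step: time, coordinates, momenta, active
#' diagonal state, spin-free class, kinetic and total energy, norm error and
#' diagonal energies.
#'
#' @param traj an `sh_trajectory`
#' @param path file path
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj$log), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
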