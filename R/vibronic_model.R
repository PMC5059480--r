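#' Few-mode diabatic vibronic model with spin-orbit coupling
#'
#' A linear-vibronic-coupling (LVC) Hamiltonian over dimensionless normal
#' coordinates `q`:
#' \deqn{H_{\alpha\alpha}(q) = E_\alpha + \sum_i \kappa_{\alpha i} q_i +
#'   \sum_i (\omega_i/2 + \delta_{\alpha i}) q_i^2, \quad
#'   H_{\alpha\beta}(q) = \sum_i \lambda_{\alpha\beta i} q_i}
#' with interstate couplings only between states of the same multiplicity and
#' coordinate-independent (Condon) spin-orbit couplings between singlets and
#' triplets. Triplets carry three sublevels, degenerate in the spin-free part.
#'
#' @param frequencies mode frequencies in eV per dimensionless coordinate (> 0)
#' @param states list of state definitions; each a list with `label`,
#'   `multiplicity` (1 or 3), `energy` (vertical energy, eV), `kappa`
#'   (gradient vector, eV, length `n_modes`), optional `quad` (extra
#'   quadratic shifts, eV) and optional `f_weight` (oscillator-strength
#'   surrogate used for initial-state selection)
#' @param couplings data frame with columns `state_i`, `state_j` (labels of
#'   same-multiplicity states), `mode`, `lambda` (eV); may be empty
#' @param soc data frame with columns `singlet`, `triplet`,
#'   `magnitude_cm1`; may be empty
#' @param sublevel_pattern complex unit 3-vector distributing each coupling
#'   magnitude over the triplet sublevels (default: equally over ms = +/-1)
#' @return an object of class `vibronic_model`
#' @export
vibronic_model <- function(frequencies, states, couplings = NULL, soc = NULL,
                           sublevel_pattern = c(1, 0, 1) / sqrt(2)) {
  if (any(frequencies <= 0)) stop("mode frequencies must be positive", call. = FALSE)
  m <- length(frequencies)
  labels <- vapply(states, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("state labels must be unique", call. = FALSE)
  mult <- vapply(states, `[[`, numeric(1), "multiplicity")
  if (!all(mult %in% c(1, 3))) stop("multiplicity must be 1 or 3", call. = FALSE)
  for (s in states) {
    if (length(s$kappa) != m) stop("kappa must have one entry per mode", call. = FALSE)
    if (!is.null(s$quad) && length(s$quad) != m) stop("quad must have one entry per mode", call. = FALSE)
  }
  if (is.null(couplings)) {
    couplings <- data.frame(state_i = character(0), state_j = character(0),
                            mode = integer(0), lambda = numeric(0))
  }
  if (nrow(couplings)) {
    mi <- mult[match(couplings$state_i, labels)]
    mj <- mult[match(couplings$state_j, labels)]
    if (any(is.na(mi)) || any(is.na(mj)) || any(mi != mj)) {
      stop("interstate couplings only between states of the same multiplicity",
           call. = FALSE)
    }
  }
  if (is.null(soc)) {
    soc <- data.frame(singlet = character(0), triplet = character(0),
                      magnitude_cm1 = numeric(0))
  }
  if (nrow(soc)) {
    ms <- mult[match(soc$singlet, labels)]
    mt <- mult[match(soc$triplet, labels)]
    if (any(is.na(ms)) || any(ms != 1) || any(is.na(mt)) || any(mt != 3)) {
      stop("SOC entries must pair a singlet with a triplet", call. = FALSE)
    }
  }
  if (abs(sum(Mod(sublevel_pattern)^2) - 1) > 1e-10) {
    stop("sublevel pattern must have unit norm", call. = FALSE)
  }
  structure(list(frequencies = frequencies, states = states,
                 couplings = couplings, soc = soc,
                 sublevel_pattern = as.complex(sublevel_pattern),
                 labels = labels, multiplicities = mult),
            class = "vibronic_model")
}

#' @method print vibronic_model
#' @export
print.vibronic_model <- function(x, ...) {
  cat(sprintf("vibronic_model: %d modes, %d states (%d singlet, %d triplet), %d couplings, %d SOC pairs\n",
              length(x$frequencies), length(x$states),
              sum(x$multiplicities == 1), sum(x$multiplicities == 3),
              nrow(x$couplings), nrow(x$soc)))
  invisible(x)
}

#' Spin-free LVC Hamiltonian and its analytic gradient
#'
#' @param model a [vibronic_model]
#' @param q coordinate vector, one entry per mode
#' @return list with `H` (real symmetric `[n_states x n_states]`, eV) and
#'   `grad` (array `[n_states x n_states x n_modes]` of exact derivatives)
#' @export
spinfree_hamiltonian <- function(model, q) {
  stopifnot(inherits(model, "vibronic_model"))
  m <- length(model$frequencies)
  if (length(q) != m) stop("q must have one entry per mode", call. = FALSE)
  n <- length(model$states)
  H <- matrix(0, n, n)
  grad <- array(0, c(n, n, m))
  harm <- sum(model$frequencies / 2 * q^2)
  for (a in seq_len(n)) {
    s <- model$states[[a]]
    quad <- if (is.null(s$quad)) 0 else sum(s$quad * q^2)
    H[a, a] <- s$energy + sum(s$kappa * q) + harm + quad
    gq <- if (is.null(s$quad)) 0 else 2 * s$quad * q
    grad[a, a, ] <- s$kappa + model$frequencies * q + gq
  }
  cp <- model$couplings
  for (r in seq_len(nrow(cp))) {
    i <- match(cp$state_i[r], model$labels)
    j <- match(cp$state_j[r], model$labels)
    k <- cp$mode[r]
    H[i, j] <- H[i, j] + cp$lambda[r] * q[k]
    H[j, i] <- H[i, j]
    grad[i, j, k] <- grad[i, j, k] + cp$lambda[r]
    grad[j, i, k] <- grad[i, j, k]
  }
  list(H = H, grad = grad)
}

#' Expanded (spin) basis indexing of a vibronic model
#'
#' Singlets occupy one expanded level, triplets three consecutive sublevels.
#'
#' @param model a [vibronic_model]
#' @return integer vector of length `n_singlets + 3 n_triplets` mapping each
#'   expanded index to its spin-free state index
#' @export
spin_expansion_map <- function(model) {
  rep(seq_along(model$states),
      times = ifelse(model$multiplicities == 3, 3L, 1L))
}

#' Constant spin-orbit coupling matrix in the expanded (spin) basis
#'
#' Each configured singlet-triplet pair contributes a 1x3 block
#' `magnitude_eV * pattern`, so its Frobenius norm equals the configured
#' magnitude after cm^-1 to eV conversion.
#'
#' @param model a [vibronic_model]
#' @return complex Hermitian `[N x N]` matrix, `N = n_singlets + 3 n_triplets`
#' @export
soc_matrix <- function(model) {
  map <- spin_expansion_map(model)
  N <- length(map)
  S <- matrix(0 + 0i, N, N)
  if (!nrow(model$soc)) return(S)
  for (r in seq_len(nrow(model$soc))) {
    si <- match(model$soc$singlet[r], model$labels)
    ti <- match(model$soc$triplet[r], model$labels)
    mag <- model$soc$magnitude_cm1[r] / td_constants$cm1_per_ev
    row <- which(map == si)
    cols <- which(map == ti)
    S[row, cols] <- mag * model$sublevel_pattern
    S[cols, row] <- Conj(mag * model$sublevel_pattern)
  }
  S
}

#' Total (spin-orbit) Hamiltonian in the expanded basis
#'
#' Expands the spin-free Hamiltonian over triplet sublevels (degenerate in
#' the spin-free part) and adds the constant SOC matrix.
#'
#' @param H_spinfree real symmetric spin-free Hamiltonian from
#'   [spinfree_hamiltonian]
#' @param model the [vibronic_model] supplying multiplicities and SOC
#' @return complex Hermitian `[N x N]` matrix
#' @export
total_hamiltonian <- function(H_spinfree, model) {
  map <- spin_expansion_map(model)
  sub <- c(0L, cumsum(ifelse(model$multiplicities == 3, 3L, 1L)))
  N <- length(map)
  H <- matrix(0 + 0i, N, N)
  for (a in seq_along(model$states)) {
    for (b in seq_along(model$states)) {
      if (H_spinfree[a, b] == 0) next
      if (model$multiplicities[a] != model$multiplicities[b]) next
      na <- if (model$multiplicities[a] == 3) 3L else 1L
      for (s in seq_len(na)) {
        H[sub[a] + s, sub[b] + s] <- H_spinfree[a, b]
      }
    }
  }
  H + soc_matrix(model)
}

# Character-tracked adiabatic energy of the spin-free Hamiltonian:
# the eigenstate with the largest weight on diabatic state `alpha`.
# Returns energy, analytic gradient, tracked index and weight.
adiabatic_tracked <- function(model, q, alpha) {
  hg <- spinfree_hamiltonian(model, q)
  e <- eigen(hg$H, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  w <- vecs[alpha, ]^2
  j <- which.max(w + 1e-12 * rev(seq_along(w)))  # tie-break to lower index
  v <- vecs[, j]
  g <- vapply(seq_along(q), function(k) drop(crossprod(v, hg$grad[, , k] %*% v)),
              numeric(1))
  list(energy = vals[j], grad = g, index = j, weight = w[j])
}

# Derivative-based descent on a character-tracked adiabatic surface.
.track_minimum <- function(model, alpha, start) {
  fn <- function(q) adiabatic_tracked(model, q, alpha)$energy
  gr <- function(q) adiabatic_tracked(model, q, alpha)$grad
  opt <- stats::nlminb(start, fn, gr,
                       control = list(rel.tol = 1e-12, iter.max = 500))
  list(q = opt$par, energy = opt$objective, converged = opt$convergence == 0)
}

# Minimum-energy crossing search between two character-tracked surfaces by
# minimising the mean energy under a squared-gap penalty whose weight is
# ramped x10 per cycle until the gap is below `gap_tol` (eV).
.crossing_search <- function(model, alpha, beta, start, gap_tol = 1e-4,
                             w0 = 10, max_cycles = 14) {
  q <- start
  w <- w0
  gap <- Inf
  for (cycle in seq_len(max_cycles)) {
    fn <- function(q) {
      a <- adiabatic_tracked(model, q, alpha)
      b <- adiabatic_tracked(model, q, beta)
      (a$energy + b$energy) / 2 + w * (a$energy - b$energy)^2
    }
    gr <- function(q) {
      a <- adiabatic_tracked(model, q, alpha)
      b <- adiabatic_tracked(model, q, beta)
      (a$grad + b$grad) / 2 + 2 * w * (a$energy - b$energy) * (a$grad - b$grad)
    }
    opt <- stats::nlminb(q, fn, gr,
                         control = list(rel.tol = 1e-12, iter.max = 500))
    q <- opt$par
    a <- adiabatic_tracked(model, q, alpha)
    b <- adiabatic_tracked(model, q, beta)
    gap <- abs(a$energy - b$energy)
    if (gap < gap_tol) break
    w <- w * 10
  }
  list(q = q, energy = (a$energy + b$energy) / 2, gap = gap,
       converged = gap < gap_tol)
}

# Starting guess: minimum of the pure diabatic surface of state alpha.
.diabatic_min_guess <- function(model, alpha) {
  s <- model$states[[alpha]]
  curv <- model$frequencies + if (is.null(s$quad)) 0 else 2 * s$quad
  -s$kappa / curv
}

#' Locate stationary and crossing points of a vibronic model
#'
#' Minima are found by derivative-based descent on each character-tracked
#' adiabatic spin-free surface (started from the diabatic minimum); crossing
#' seams (conical intersections for equal multiplicity, minimum-energy
#' crossing points otherwise) by minimising the mean energy under a
#' squared-gap penalty ramped tenfold per cycle until the gap is below
#' 1e-4 eV. The barrier entry reports the lowest crossing energy between the
#' ground state and any excited singlet surface, minus the energy of the
#' lowest singlet minimum named in the table row. All energies are relative
#' to the ground-state (first singlet state) minimum.
#'
#' @param model a [vibronic_model] whose first state is the ground state
#' @param table a [critical_point_table]-style data frame of targets
#' @return a `calibration_report` data frame with columns `label`, `kind`,
#'   `target_ev`, `model_ev`, `abs_error_ev`, `converged`. For `ge`-bound
#'   rows `abs_error_ev` is the shortfall (0 when the bound holds).
#' @export
locate_critical_points <- function(model, table = critical_point_table()) {
  ground <- model$labels[1]
  s0 <- .track_minimum(model, 1L, .diabatic_min_guess(model, 1L))
  e0 <- s0$energy

  find_min <- function(lbl) {
    a <- match(lbl, model$labels)
    .track_minimum(model, a, .diabatic_min_guess(model, a))
  }
  find_cross <- function(l1, l2) {
    a <- match(l1, model$labels)
    b <- match(l2, model$labels)
    start <- (.diabatic_min_guess(model, a) + .diabatic_min_guess(model, b)) / 2
    .crossing_search(model, a, b, start)
  }

  min_cache <- list()
  rows <- lapply(seq_len(nrow(table)), function(r) {
    kind <- table$kind[r]
    st <- strsplit(table$states[r], "|", fixed = TRUE)[[1]]
    if (kind == "FC-point") {
      a <- match(st[1], model$labels)
      hg <- spinfree_hamiltonian(model, rep(0, length(model$frequencies)))
      val <- hg$H[a, a] - e0
      conv <- TRUE
    } else if (kind == "minimum") {
      res <- find_min(st[1])
      min_cache[[st[1]]] <<- res
      val <- res$energy - e0
      conv <- res$converged
    } else if (kind %in% c("CoIn", "MECP")) {
      res <- find_cross(st[1], st[2])
      val <- res$energy - e0
      conv <- res$converged
    } else if (kind == "barrier") {
      # lowest S0/excited-singlet crossing relative to the reference minimum
      exc_singlets <- model$labels[model$multiplicities == 1 & model$labels != ground]
      cr <- vapply(exc_singlets, function(l) {
        res <- find_cross(ground, l)
        if (res$converged) res$energy else Inf
      }, numeric(1))
      ref <- min_cache[[st[1]]]
      if (is.null(ref)) ref <- find_min(st[1])
      val <- min(cr) - ref$energy
      conv <- is.finite(val)
    } else {
      val <- NA_real_; conv <- FALSE
    }
    err <- if (table$bound[r] == "ge") max(0, table$energy_ev[r] - val)
           else abs(val - table$energy_ev[r])
    data.frame(label = table$label[r], kind = kind,
               target_ev = table$energy_ev[r], model_ev = val,
               abs_error_ev = err, converged = conv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_report", class(out))
  out
}

# pack/unpack the free parameters of a calibration template
.calib_pack <- function(model, free) {
  p <- numeric(0)
  for (lbl in free$energies) p <- c(p, model$states[[match(lbl, model$labels)]]$energy)
  for (lbl in names(free$kappas)) {
    a <- match(lbl, model$labels)
    p <- c(p, model$states[[a]]$kappa[free$kappas[[lbl]]])
  }
  p
}

.calib_unpack <- function(model, free, p) {
  i <- 1L
  for (lbl in free$energies) {
    a <- match(lbl, model$labels)
    model$states[[a]]$energy <- p[i]; i <- i + 1L
  }
  for (lbl in names(free$kappas)) {
    a <- match(lbl, model$labels)
    ks <- free$kappas[[lbl]]
    model$states[[a]]$kappa[ks] <- p[i:(i + length(ks) - 1L)]
    i <- i + length(ks)
  }
  model
}

#' Calibrate a vibronic model against a critical-point table
#'
#' Least-squares adjusts the declared free parameters (vertical energies and
#' selected gradients of the excited states) so that
#' [locate_critical_points] reproduces every equality target; `ge`-bound rows
#' enter as one-sided hinge penalties. The procedure is deterministic given
#' the template (which doubles as the start point).
#'
#' @param table target table (see [critical_point_table])
#' @param template a [vibronic_model] start point
#' @param free list with `energies` (state labels whose vertical energy is
#'   free) and `kappas` (named list: label -> integer mode indices whose
#'   gradients are free). Default frees all excited-state energies and their
#'   tuning-mode gradients (all modes but the last, by convention the
#'   coupling mode).
#' @param tol_ev acceptance tolerance; any equality target missed by more
#'   than this raises an error listing the offenders
#' @param max_iterations optimiser iteration cap
#' @return the calibrated [vibronic_model] with attributes `report` (the
#'   final `calibration_report`) and `parameter_change` (max absolute change)
#' @export
calibrate_model <- function(table, template, free = NULL, tol_ev = 0.05,
                            max_iterations = 400) {
  stopifnot(inherits(template, "vibronic_model"))
  if (is.null(free)) {
    exc <- template$labels[-1]
    tuning <- seq_len(max(1L, length(template$frequencies) - 1L))
    free <- list(energies = exc,
                 kappas = stats::setNames(rep(list(tuning), length(exc)), exc))
  }
  p0 <- .calib_pack(template, free)
  obj <- function(p) {
    m <- .calib_unpack(template, free, p)
    rep_ <- locate_critical_points(m, table)
    sum(rep_$abs_error_ev^2) + 10 * sum(!rep_$converged)
  }
  if (length(p0)) {
    opt <- stats::nlminb(p0, obj,
                         control = list(rel.tol = 1e-10, abs.tol = 1e-12,
                                        iter.max = max_iterations))
  } else {
    opt <- list(par = p0)  # nothing declared free: evaluation only
  }
  model <- .calib_unpack(template, free, opt$par)
  report <- locate_critical_points(model, table)
  bad <- report$abs_error_ev > tol_ev
  if (any(bad)) {
    stop("calibration failed for: ",
         paste(sprintf("%s (|err| = %.3f eV)", report$label[bad],
                       report$abs_error_ev[bad]), collapse = ", "),
         call. = FALSE)
  }
  attr(model, "report") <- report
  attr(model, "parameter_change") <- if (length(p0)) max(abs(opt$par - p0)) else 0
  model
}

#' Serialize / load a vibronic model (YAML)
#'
#' @param model a [vibronic_model]
#' @param path file path
#' @export
write_vibronic_model <- function(model, path) {
  obj <- list(
    frequencies = as.numeric(model$frequencies),
    states = lapply(model$states, function(s) {
      out <- list(label = s$label, multiplicity = s$multiplicity,
                  energy = s$energy, kappa = as.numeric(s$kappa))
      if (!is.null(s$quad)) out$quad <- as.numeric(s$quad)
      if (!is.null(s$f_weight)) out$f_weight <- s$f_weight
      out
    }),
    couplings = if (nrow(model$couplings)) {
      lapply(seq_len(nrow(model$couplings)), function(r) as.list(model$couplings[r, ]))
    } else list(),
    soc = if (nrow(model$soc)) {
      lapply(seq_len(nrow(model$soc)), function(r) as.list(model$soc[r, ]))
    } else list(),
    sublevel_pattern = list(re = as.numeric(Re(model$sublevel_pattern)),
                            im = as.numeric(Im(model$sublevel_pattern)))
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_vibronic_model
#' @export
read_vibronic_model <- function(path) {
  obj <- yaml::read_yaml(path)
  cp <- if (length(obj$couplings)) {
    do.call(rbind, lapply(obj$couplings, as.data.frame))
  } else NULL
  soc <- if (length(obj$soc)) {
    do.call(rbind, lapply(obj$soc, as.data.frame))
  } else NULL
  vibronic_model(
    frequencies = as.numeric(obj$frequencies),
    states = obj$states,
    couplings = cp, soc = soc,
    sublevel_pattern = complex(real = obj$sublevel_pattern$re,
                               imaginary = obj$sublevel_pattern$im))
}

#' The packaged calibrated model of 2-thiocytosine
#'
#' Three effective modes (two tuning, one coupling), five spin-free states
#' (S0 and the nspi*/pispi* singlet and triplet pairs), calibrated so that
#' its stationary and crossing points reproduce the packaged critical-point
#' energies within 0.05 eV. SOC magnitudes default to the trajectory-average
#' values (160 cm^-1 between opposite-character singlet-triplet pairs,
#' 50 cm^-1 between same-character pairs).
#'
#' @return a [vibronic_model]
#' @export
model_2tc <- function() {
  read_vibronic_model(system.file("extdata", "model_2tc.yaml",
                                  package = "thiodyn"))
}

#' Uncalibrated template for the 2-thiocytosine model
#'
#' Start point for [calibrate_model]; its parameters are hand-placed near the
#' printed landscape (see the methods vignette) but not yet optimised. Eight
#' effective modes: two tuning modes carrying the landscape, one coupling
#' mode hosting the same-multiplicity interstate couplings, and five weakly
#' displaced low-frequency bath modes that act as a vibrational energy sink
#' (the irreversibility a full-dimensional molecule has and a bare
#' three-mode model lacks).
#'
#' @param soc_scale multiply all SOC magnitudes (useful for sensitivity runs)
#' @return a [vibronic_model]
#' @export
model_2tc_template <- function(soc_scale = 1) {
  bath <- list(
    "S0"      = c(0, 0, 0, 0, 0),
    "1nspi*"  = c(+0.015, -0.012, +0.010, -0.008, +0.006),
    "1pispi*" = c(-0.012, +0.015, -0.008, +0.010, -0.006),
    "3nspi*"  = c(+0.010, -0.008, -0.012, +0.006, +0.015),
    "3pispi*" = c(-0.015, +0.010, +0.012, -0.006, -0.008))
  core <- list(
    list(label = "S0", multiplicity = 1, energy = 0,
         kappa = c(0, 0, 0), f_weight = 0),
    list(label = "1nspi*", multiplicity = 1, energy = 3.328,
         kappa = c(-0.0841, 0.1141, 0), f_weight = 0.1),
    list(label = "1pispi*", multiplicity = 1, energy = 3.650,
         kappa = c(-0.1489, 0.1141, 0), f_weight = 1),
    list(label = "3nspi*", multiplicity = 3, energy = 3.616,
         kappa = c(-0.1888, 0.0108, 0), f_weight = 0),
    list(label = "3pispi*", multiplicity = 3, energy = 3.032,
         kappa = c(-0.0841, -0.0566, 0), f_weight = 0)
  )
  states <- lapply(core, function(s) {
    s$kappa <- c(s$kappa, bath[[s$label]])
    s
  })
  vibronic_model(
    frequencies = c(0.030, 0.025, 0.020, 0.028, 0.022, 0.018, 0.014, 0.011),
    states = states,
    couplings = data.frame(
      state_i = c("1nspi*", "3nspi*"),
      state_j = c("1pispi*", "3pispi*"),
      mode = c(3L, 3L),
      lambda = c(0.040, 0.030)
    ),
    soc = data.frame(
      singlet = c("1nspi*", "1pispi*", "1nspi*", "1pispi*"),
      triplet = c("3pispi*", "3nspi*", "3nspi*", "3pispi*"),
      magnitude_cm1 = soc_scale * c(160, 160, 50, 50)
    )
  )
}

#' Default free-parameter specification for 2-thiocytosine calibration
#'
#' Frees the vertical energies of the four excited states and their
#' gradients on the two tuning modes; the coupling-mode and bath-mode
#' parameters stay at their template values.
#'
#' @param template the template model (for the state labels)
#' @return a `free` list for [calibrate_model]
#' @export
model_2tc_free <- function(template = model_2tc_template()) {
  exc <- template$labels[-1]
  list(energies = exc, kappas = stats::setNames(rep(list(1:2), length(exc)), exc))
}
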