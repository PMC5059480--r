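# Shared fixtures. Expensive objects (surface-hopping ensembles) are built
# once per test run and memoized here so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# 64-trajectory, 1 ps ensemble of the shipped calibrated model with
# window-selected initial conditions (the conservation/mechanism workhorse)
tc_ensemble <- function() {
  memo("tc_ensemble", function() {
    spec <- ensemble_spec(n_traj = 64, t_max = 1000, seed = 11,
                          record_stride = 10L)
    run_ensemble(model_2tc(), spec, window = c(3.4, 3.9))
  })
}

# same ensemble conditions with all SOC magnitudes scaled down tenfold
tc_ensemble_weak_soc <- function() {
  memo("tc_ensemble_weak_soc", function() {
    model <- calibrate_model(critical_point_table(),
                             model_2tc_template(soc_scale = 0.1),
                             free = model_2tc_free())
    spec <- ensemble_spec(n_traj = 64, t_max = 1000, seed = 11,
                          record_stride = 10L)
    run_ensemble(model, spec, window = c(3.4, 3.9))
  })
}

# maximum total-energy drift within segments between accepted hops
between_hop_drift <- function(traj) {
  et <- traj$log[, "etot"]
  seg <- cumsum(traj$log[, "hops"])
  maxd <- 0
  for (s in unique(seg)) {
    i <- which(seg == s)
    maxd <- max(maxd, max(abs(et[i] - et[i[1]])))
  }
  maxd
}

# a small noiseless synthetic map fixture (no chirp) with known truth
noiseless_tas <- function() {
  memo("noiseless_tas", function() {
    generate_tas(tas_gen_config(noise_sd = 0, chirp = c(0, 0, 0)))
  })
}
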