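# One shared SPC reference simulation for the liquid-water observables:
# 216 molecules at 997 kg/m3, 10 ps NPT equilibration + 30 ps NPT sampling
# at 300 K / 1 atm, dt = 2 fs with SHAKE-rigid SPC, reaction field with
# relative permittivity 61. The 0.9 nm cutoff is the largest value
# compatible with the minimum-image convention in this box (half edge
# 0.93 nm). Computed lazily once and reused by every test that needs it.
spc_reference_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    wb <- build_water_box(216, density = 997, seed = 1)
    params <- mm_params(rf_cutoff = 0.9, rf_epsilon = 61,
                        pairlist_cutoff = 0.9)
    equil_cfg <- run_config(dt = 0.002, n_steps = 5000, ensemble = "NPT",
                            T0 = 300, tau_T = 0.1, P0 = 1, tau_P = 0.5,
                            seed = 11, com_removal_interval = 500,
                            sample_interval = 1000)
    eq <- run_simulation(wb$topology, wb$state, equil_cfg, params)
    sample_cfg <- run_config(dt = 0.002, n_steps = 15000, ensemble = "NPT",
                             T0 = 300, tau_T = 0.1, P0 = 1, tau_P = 0.5,
                             seed = 12, com_removal_interval = 500,
                             sample_interval = 50)
    pr <- run_simulation(wb$topology, eq$final_state, sample_cfg, params)
    euv <- vapply(seq_along(pr$trajectory$positions), function(f) {
      st <- system_state(pr$trajectory$positions[[f]],
                         box = pr$trajectory$boxes[[f]])
      interaction_energy(wb$topology, st, 1:3, params)
    }, 1)
    cache <<- list(wb = wb, params = params, trajectory = pr$trajectory,
                   energies = pr$energies, euv = euv)
    cache
  }
})
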