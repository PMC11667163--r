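# shared fixtures, built once per test run
ref_net <- reference_adipocyte_network()
ref_basis <- free_flux_basis(ref_net)

# small MFA problem on the condensation-cycle toy: cheap enough for unit
# tests of the fitting machinery
toy_mfa_problem <- function(noise_sd = 0.003, seed = 1, n_replicates = 2) {
  toy <- toy_networks()$condensation_cycle
  frags <- data.frame(species = c("CIT.c", "AKG.c", "SUC.c", "OAA.c"),
                      carbons = c(6L, 5L, 4L, 4L), stringsAsFactors = FALSE)
  rmap <- list(acetate = c(v_ac_in = 1), oaa_in = c(v_oaa_in = 1))
  ds <- generate_tracer_dataset(toy$network, toy$fluxes,
                                tracers = list(ace = toy$tracer),
                                noise_sd = noise_sd,
                                rate_noise_rel = if (noise_sd > 0) 0.05 else 0,
                                n_replicates = n_replicates,
                                seed = seed, fragments = frags, rate_map = rmap)
  list(net = toy$network, truth = toy$fluxes, experiments = ds$experiments)
}
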