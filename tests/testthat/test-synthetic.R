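test_that("scenario flux vectors are feasible and encode the knockout edits", {
  ctrl <- sample_feasible_fluxes(ref_net, scenario = "control")
  ko <- sample_feasible_fluxes(ref_net, scenario = "bckdha_ko")
  S <- stoichiometry(ref_net)
  expect_lt(max(abs(S %*% ctrl$net)), 1e-8)
  expect_lt(max(abs(S %*% ko$net)), 1e-8)
  irrev <- setdiff(reaction_ids(ref_net), reversible_ids(ref_net))
  expect_gt(min(ctrl$net[irrev]), 0)
  expect_gt(min(ko$net[irrev]), 0)
  # BCKDH silenced below 1% of control
  expect_lt(ko$net[["v_bckdh_l"]], 0.01 * ctrl$net[["v_bckdh_l"]])
  # PDH and PC rise
  expect_gt(ko$net[["v_pdh"]], ctrl$net[["v_pdh"]])
  expect_gt(ko$net[["v_pc"]], ctrl$net[["v_pc"]])
  # oxPPP ratio fixed at 0.3% in both scenarios
  expect_equal(ctrl$net[["v_oxppp"]] / ctrl$net[["v_glc_up"]], 0.003,
               tolerance = 1e-9)
  expect_equal(ko$net[["v_oxppp"]] / ko$net[["v_glc_up"]], 0.003,
               tolerance = 1e-9)
  # anaplerosis to succinyl-CoA stays low in both
  expect_lt(ctrl$net[["v_pcc"]], 0.05 * ctrl$net[["v_cs"]])
  # glutamine uptake and secretion both rise in the knockout
  expect_gt(ko$net[["v_gln_up"]], ctrl$net[["v_gln_up"]])
  expect_gt(ko$net[["v_gln_sec"]], ctrl$net[["v_gln_sec"]])
  # jittered truths stay feasible and differ
  j1 <- sample_feasible_fluxes(ref_net, seed = 3, jitter_sd = 0.1)
  expect_gt(min(j1$net[irrev]), 0)
  expect_false(identical(j1$net, ctrl$net))
})

test_that("tracer datasets are deterministic given the seed and honor noise_sd", {
  truth <- sample_feasible_fluxes(ref_net, scenario = "control")
  d1 <- generate_tracer_dataset(ref_net, truth, seed = 42)
  d2 <- generate_tracer_dataset(ref_net, truth, seed = 42)
  expect_identical(d1$experiments, d2$experiments)
  d3 <- generate_tracer_dataset(ref_net, truth, seed = 43)
  expect_false(identical(d1$experiments, d3$experiments))
  # noise-free datasets reproduce the simulation exactly
  d0 <- generate_tracer_dataset(ref_net, truth, noise_sd = 0,
                                rate_noise_rel = 0, seed = 1, n_replicates = 1)
  sys <- emu_decompose(ref_net, reference_measured_fragments()$species)
  sim <- emu_evaluate(sys, truth, d0$experiments$glucose$tracer)
  expect_equal(drop(d0$experiments$glucose$mids[["PYR.c"]]$values),
               sim[["PYR.c[1,2,3]"]], tolerance = 1e-12)
  # rates carry the linear-combination coefficients
  rt <- d0$experiments$glucose$rates
  gln <- rt[[which(sapply(rt, `[[`, "name") == "glutamine")]]
  expect_equal(gln$value,
               truth$net[["v_gln_up"]] - truth$net[["v_gln_sec"]])
})

test_that("MID noise has the stated per-channel scale", {
  truth <- sample_feasible_fluxes(ref_net, scenario = "control")
  sys <- emu_decompose(ref_net, "PYR.c")
  sim <- emu_evaluate(sys, truth, default_tracers()$glucose)[[1]]
  set.seed(10)
  noise_sd <- 0.003
  devs <- replicate(1000, adipoflux:::add_mid_noise(sim, noise_sd) - sim)
  # mean absolute deviation of a zero-sum Gaussian with per-channel variance
  # sd^2 * n/(n+1): sqrt(2/pi) * sd * sqrt(n/(n+1))
  expected <- sqrt(2 / pi) * noise_sd * sqrt(3 / 4)
  expect_equal(mean(abs(devs)), expected, tolerance = 0.1)
  # each noisy draw stays on the simplex
  expect_equal(max(abs(colSums(matrix(devs, nrow = 4)))), 0, tolerance = 1e-12)
})

test_that("ISA fixtures have the right channel counts and round-trip through the fit", {
  d <- generate_isa_dataset(list("C15:0" = c(D = 0.4, g = 0.3),
                                 "C16:0" = c(D = 0.6, g = 0.5)),
                            noise_sd = 0, seed = 1)
  expect_length(d$mids[["C15:0"]], 16)  # M0..M15
  expect_length(d$mids[["C16:0"]], 17)
  # D = 1, g = 1 puts all mass at the top channel
  d2 <- generate_isa_dataset(list("C16:0" = c(D = 1, g = 1)), noise_sd = 0)
  expect_equal(d2$mids[[1]][17], 1)
  fit <- isa_fit(d$mids[["C15:0"]], isa_model("C15:0"))
  expect_equal(fit$D, 0.4, tolerance = 1e-5)
  expect_equal(fit$g, 0.3, tolerance = 1e-5)
})

test_that("medium time courses invert through exchange_rate", {
  rates <- data.frame(species = c("glucose", "lactate"),
                      rate = c(100, 150),
                      direction = c("uptake", "secretion"),
                      stringsAsFactors = FALSE)
  fresh <- c(glucose = 25, lactate = 0)
  tc <- generate_medium_timecourse(rates, fresh, volume_ul = 1000, hours = 48,
                                   noise_rel = 0, seed = 1)
  back <- read_back <- do.call(rbind, lapply(seq_len(nrow(tc)), function(i) {
    exchange_rate(tc$species[i], tc$fresh_conc[i], tc$spent_conc[i],
                  tc$volume_ul[i], tc$hours[i], tc$direction[i])
  }))
  expect_equal(back$flux, rates$rate, tolerance = 1e-9)
  # with noise the recovery stays within 3 relative SDs
  tcn <- generate_medium_timecourse(rates, fresh, noise_rel = 0.05, seed = 2)
  backn <- exchange_rate("glucose", tcn$fresh_conc[1], tcn$spent_conc[1],
                         tcn$volume_ul[1], tcn$hours[1], "uptake")
  expect_lt(abs(backn$flux - 100), 3 * 5)
  # zero rates leave the medium unchanged
  tc0 <- generate_medium_timecourse(
    data.frame(species = "glucose", rate = 0, direction = "uptake"),
    fresh, noise_rel = 0, seed = 1)
  expect_equal(tc0$spent_conc, tc0$fresh_conc)
  # infeasible drawdown errors
  expect_error(generate_medium_timecourse(
    data.frame(species = "glucose", rate = 1e5, direction = "uptake"),
    fresh, noise_rel = 0), "exceeds")
})

test_that("net glutamine drawdown reflects uptake minus secretion", {
  truth <- sample_feasible_fluxes(ref_net, scenario = "control")
  net_rate <- truth$net[["v_gln_up"]] - truth$net[["v_gln_sec"]]
  tc <- generate_medium_timecourse(
    data.frame(species = "glutamine", rate = net_rate, direction = "uptake"),
    c(glutamine = 4), volume_ul = 1000, hours = 48, noise_rel = 0)
  r <- exchange_rate("glutamine", tc$fresh_conc, tc$spent_conc,
                     tc$volume_ul, tc$hours, "uptake")
  expect_equal(r$flux, net_rate, tolerance = 1e-9)
})
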