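test_that("SSR is zero for noise-free data, additive, and order-invariant", {
  prob <- toy_mfa_problem(noise_sd = 0, seed = 3)
  expect_lt(ssr(prob$net, prob$truth, prob$experiments), 1e-12)
  # perturbing one measured M0 by +1 sd raises the SSR by exactly 1
  e2 <- prob$experiments
  sd0 <- e2[[1]]$mids[["CIT.c"]]$sd
  e2[[1]]$mids[["CIT.c"]]$values[1, 1] <-
    e2[[1]]$mids[["CIT.c"]]$values[1, 1] + sd0
  expect_equal(ssr(prob$net, prob$truth, e2), 1, tolerance = 1e-8)
  # SSR is invariant to the order of experiments
  noisy <- toy_mfa_problem(noise_sd = 0.003, seed = 4)
  two <- list(noisy$experiments[[1]], e2[[1]])
  expect_equal(ssr(prob$net, prob$truth, two),
               ssr(prob$net, prob$truth, rev(two)), tolerance = 1e-10)
})

test_that("chi-squared acceptance interval matches the inverse CDF", {
  g <- chi2_goodness_of_fit(10, dof = 10, alpha = 0.01)
  expect_true(g$accepted)  # SSR at its expectation
  expect_equal(g$interval, c(2.155856, 25.18818), tolerance = 1e-5)
  expect_false(chi2_goodness_of_fit(30, dof = 10, alpha = 0.01)$accepted)
  expect_false(chi2_goodness_of_fit(1, dof = 10, alpha = 0.01)$accepted)
  expect_error(chi2_goodness_of_fit(5, dof = 0), "dof")
})

test_that("zero-noise fit recovers the toy fluxes exactly", {
  prob <- toy_mfa_problem(noise_sd = 0, seed = 5)
  fit <- fit_fluxes(prob$net, prob$experiments, n_restarts = 4, seed = 7)
  expect_lt(fit$ssr, 1e-6)
  expect_equal(fit$fluxes$net, prob$truth$net, tolerance = 1e-3)
  expect_equal(fit$restarts, 4)
  # n_restarts = 20 is the documented default of the fit driver
  expect_equal(eval(formals(fit_fluxes)$n_restarts), 20)
})

test_that("fits are deterministic under a fixed seed", {
  prob <- toy_mfa_problem(noise_sd = 0.003, seed = 6)
  f1 <- fit_fluxes(prob$net, prob$experiments, n_restarts = 3, seed = 99)
  f2 <- fit_fluxes(prob$net, prob$experiments, n_restarts = 3, seed = 99)
  expect_identical(f1$fluxes, f2$fluxes)
  expect_identical(f1$restart_ssr, f2$restart_ssr)
  expect_equal(f1$ssr, min(f1$restart_ssr))
  # dof bookkeeping: channels above M0 per fragment per replicate + rates
  # minus free parameters
  n_chan <- 2 * (6 + 5 + 4 + 4)  # 2 replicates of CIT, AKG, SUC, OAA
  expect_equal(f1$dof, n_chan + 2 - (free_flux_basis(prob$net)$d +
                                       length(reversible_ids(prob$net))))
})

test_that("profile CIs bracket identifiable fluxes and flag unidentifiable exchange", {
  prob <- toy_mfa_problem(noise_sd = 0.003, seed = 8)
  fit <- fit_fluxes(prob$net, prob$experiments, n_restarts = 3, seed = 11)
  ci <- flux_confidence_interval(fit, "v_ac_in", maxiter = 15)
  expect_lte(ci$lower, fit$fluxes$net[["v_ac_in"]])
  expect_gte(ci$upper, fit$fluxes$net[["v_ac_in"]])
  expect_true(is.finite(ci$lower) && is.finite(ci$upper))
  # true value inside the CI for this realization
  expect_gte(prob$truth$net[["v_ac_in"]], ci$lower)
  expect_lte(prob$truth$net[["v_ac_in"]], ci$upper)
})

test_that("CI width shrinks when measurement noise shrinks", {
  width <- function(sdv, seed) {
    toy <- toy_networks()$condensation_cycle
    frags <- data.frame(species = c("CIT.c", "SUC.c"), carbons = c(6L, 4L))
    ds <- generate_tracer_dataset(toy$network, toy$fluxes,
                                  tracers = list(ace = toy$tracer),
                                  noise_sd = 0, n_replicates = 2, seed = seed,
                                  fragments = frags,
                                  rate_map = list(ace = c(v_ac_in = 1)))
    # same noise-free data, scaled stated uncertainty
    for (i in seq_along(ds$experiments)) {
      for (nm in names(ds$experiments[[i]]$mids)) {
        ds$experiments[[i]]$mids[[nm]]$sd <- sdv
      }
    }
    fit <- fit_fluxes(toy$network, ds$experiments, n_restarts = 2, seed = 5)
    ci <- flux_confidence_interval(fit, "v_oaa_in", maxiter = 12)
    ci$upper - ci$lower
  }
  expect_lt(width(0.0015, 21), width(0.006, 21))
})

test_that("fit results serialize to JSON and a net(exchange) table", {
  prob <- toy_mfa_problem(noise_sd = 0.003, seed = 12)
  fit <- fit_fluxes(prob$net, prob$experiments, n_restarts = 2, seed = 3)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_fit(fit, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$ssr, fit$ssr, tolerance = 1e-9)
  tab <- read.csv(cp)
  expect_true(all(c("reaction", "net", "exchange", "label") %in% names(tab)))
  expect_match(tab$label[tab$reaction == "v_sdh"], "\\(")
})
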