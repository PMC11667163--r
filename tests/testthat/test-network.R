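test_that("reaction grammar parses and enforces atom balance", {
  net <- parse_network("v1: A (ab) -> B (ab)")
  expect_s3_class(net, "flux_network")
  expect_length(net$reactions, 1)
  # one-reaction network: A and B live in the default internal compartment,
  # so validation flags both as dead ends
  val <- validate_network(net)
  expect_setequal(val$dead_ends, c("A.c", "B.c"))

  expect_error(parse_network("v2: OAA (abcd) -> PYR (abc) + CO2 (e)"),
               "unbalanced atom map")
  expect_error(parse_network(c("v1: A (ab) -> B (ab)", "v1: B (ab) -> C (ab)")),
               "duplicate reaction id")
  expect_error(parse_network(c("v1: A (ab) -> B (ab)", "v2: B (abc) -> C (abc)")),
               "carbon-count mismatch")
  expect_error(parse_network("v1: A (aa) -> B (ab)"), "duplicate atom label")
})

test_that("the reference network encodes the compartmentalized model", {
  sp <- species_table(ref_net)
  # separate mitochondrial and cytosolic pyruvate pools
  expect_true(all(c("PYR.c", "PYR.m") %in% sp$species))
  # PDH and PC are distinct mitochondrial pyruvate consumers
  ids <- reaction_ids(ref_net)
  expect_true(all(c("v_pdh", "v_pc") %in% ids))
  # oxPPP fixed at 0.3% of glucose uptake
  r <- ref_net$ratios
  expect_true(any(r$a == "v_oxppp" & r$b == "v_glc_up" & r$ratio == 0.003))
  # symmetric succinate and fumarate
  expect_setequal(ref_net$symmetric, c("SUC.m", "FUM.m"))
  # clean validation: no atom-balance failures, no dead ends, feasible
  val <- validate_network(ref_net)
  expect_length(val$atom_balance, 0)
  expect_length(val$dead_ends, 0)
  expect_length(val$unreachable, 0)
  expect_true(val$feasible)
  # reaction kinds
  kinds <- vapply(ref_net$reactions, `[[`, "", "kind")
  names(kinds) <- ids
  expect_equal(unname(kinds["v_glc_up"]), "uptake")
  expect_equal(unname(kinds["v_lac_sec"]), "secretion")
  expect_equal(unname(kinds["v_fas16"]), "biomass-sink")
  expect_equal(unname(kinds["v_gln_dil"]), "dilution")
})

test_that("a network recycling its own CO2 triggers the reincorporation warning", {
  txt <- "
v_in:  A.x (abc) -> A (abc)
v_dec: A (abc) -> B (ab) + CO2 (c)
v_car: B (ab) + CO2 (c) -> A (abc)
v_out: A (abc) -> S.s (abc)"
  val <- validate_network(parse_network(txt))
  expect_match(val$warnings, "reincorporate", all = FALSE)
  # the reference network keeps carboxylation on the dilution inflow
  expect_length(validate_network(ref_net)$warnings, 0)
})

test_that("network round-trips through its text serialization", {
  txt <- serialize_network(ref_net)
  back <- parse_network(txt)
  expect_equal(serialize_network(back), txt)
  expect_equal(stoichiometry(back), stoichiometry(ref_net))
  expect_equal(back$ratios, ref_net$ratios)
  expect_setequal(back$symmetric, ref_net$symmetric)
})

test_that("free-flux basis dimension and reconstruction", {
  # linear chain: one pathway, one free flux
  lin <- parse_network("
v_in: A.x (a) -> A (a)
v1: A (a) -> B (a)
v_out: B (a) -> B.s (a)")
  expect_equal(free_flux_basis(lin)$d, 1L)
  # diamond: one split, two free fluxes
  dia <- toy_networks()$diamond$network
  expect_equal(free_flux_basis(dia)$d, 2L)
  # reference network: dimension equals the rank deficiency of the
  # constraint matrix, computed independently by SVD
  S <- ref_basis$S
  rank <- sum(svd(S)$d > max(dim(S)) * max(svd(S)$d) * .Machine$double.eps)
  expect_equal(ref_basis$d, ncol(S) - rank)
  # any reconstruction satisfies mass balance to machine precision
  set.seed(4)
  for (i in 1:10) {
    v <- flux_from_free(ref_basis, rnorm(ref_basis$d, 0, 100))
    expect_lt(max(abs(stoichiometry(ref_net) %*% v)),
              1e-9 * max(1, max(abs(v))))
  }
})

test_that("the reference network admits a strictly positive feasible flux", {
  v <- find_feasible_flux(ref_net)
  expect_false(is.null(v))
  irrev <- setdiff(reaction_ids(ref_net), reversible_ids(ref_net))
  expect_gt(min(v[irrev]), 0)
  expect_lt(max(abs(stoichiometry(ref_net) %*% v)), 1e-8)
})

test_that("flux_vector validates balance, signs and ratios", {
  truth <- sample_feasible_fluxes(ref_net, scenario = "control")
  expect_s3_class(truth, "flux_vector")
  bad <- truth$net
  bad["v_pdh"] <- bad["v_pdh"] + 5
  expect_error(flux_vector(bad, network = ref_net), "mass balance")
  expect_error(flux_vector(truth$net, exchange = c(v_sdh = -1), network = ref_net),
               "non-negative")
  expect_error(flux_vector(truth$net, exchange = c(v_pdh = 1), network = ref_net),
               "irreversible")
})
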