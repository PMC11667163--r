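#' Shipped toy networks
#'
#' Small atom-mapped networks used to cross-validate the EMU simulator
#' against the brute-force positional isotopomer oracle: a linear chain, a
#' diamond with atom scrambling, a condensation cycle with a symmetric
#' intermediate (miniature TCA), and a reversible-exchange motif with an
#' unlabeled dilution inflow. Each entry carries a feasible `fluxes` vector
#' and a `tracer` as attributes of the list element.
#'
#' @return Named list; each element has `network`, `fluxes` (a
#'   [flux_vector]), `tracer` and `targets`.
#' @export
toy_networks <- function() {
  linear_net <- parse_network("
v_in:  A.x (ab) -> A (ab)
v1:    A (ab) -> B (ab)
v_out: B (ab) -> B.s (ab)")
  linear <- list(
    network = linear_net,
    fluxes = flux_vector(c(v_in = 1, v1 = 1, v_out = 1), network = linear_net),
    tracer = tracer_spec("A.x", 1:2, purity = 1),
    targets = c("A.c", "B.c"))

  diamond_net <- parse_network("
v_in:  A.x (ab) -> A (ab)
v1:    A (ab) -> B (ab)
v2:    A (ab) -> C (ba)
v3:    B (ab) -> D (ab)
v4:    C (ab) -> D (ab)
v_out: D (ab) -> D.s (ab)")
  diamond <- list(
    network = diamond_net,
    fluxes = flux_vector(c(v_in = 2, v1 = 1.4, v2 = 0.6, v3 = 1.4, v4 = 0.6,
                           v_out = 2), network = diamond_net),
    tracer = tracer_spec("A.x", 1, purity = 0.99),
    targets = c("D.c", "D.c[1]", "D.c[2]"))

  tca_net <- parse_network("
#symmetric SUC.c
v_ac_in:  ACE.x (ab) -> AC (ab)
v_oaa_in: OAX.x (abcd) -> OAA (abcd)
v_cs:     OAA (abcd) + AC (ef) -> CIT (dcbfea)
v_cit_out: CIT (abcdef) -> CITS.s (abcdef)
v_idh:    CIT (abcdef) -> AKG (abcde) + CO2.s (f)
v_akgdh:  AKG (abcde) -> SUC (bcde) + CO2.s (a)
v_sdh:    SUC (abcd) <-> MALX (abcd)
v_mdh:    MALX (abcd) -> OAA (abcd)")
  tca <- list(
    network = tca_net,
    fluxes = flux_vector(
      c(v_ac_in = 10, v_oaa_in = 4, v_cs = 10, v_cit_out = 4, v_idh = 6,
        v_akgdh = 6, v_sdh = 6, v_mdh = 6),
      exchange = c(v_sdh = 3), network = tca_net),
    tracer = tracer_spec("ACE.x", 1:2, purity = 0.99),
    targets = c("CIT.c", "AKG.c", "SUC.c", "MALX.c", "OAA.c"))

  exch_net <- parse_network("
v_in:   AX.x (a) -> A (a)
v_ab:   A (a) <-> B (a)
v_bdil: BX.x (b) -> B (b)
v_out:  B (a) -> BS.s (a)")
  exch <- list(
    network = exch_net,
    fluxes = flux_vector(c(v_in = 1, v_ab = 1, v_bdil = 1, v_out = 2),
                         exchange = c(v_ab = 5), network = exch_net),
    tracer = tracer_spec("AX.x", 1, purity = 1),
    targets = c("A.c", "B.c"))

  list(linear = linear, diamond = diamond, condensation_cycle = tca,
       exchange = exch)
}
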