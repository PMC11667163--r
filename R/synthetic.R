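#' Default tracer panel
#'
#' The three-tracer design of the study: [U-13C6]glucose, [U-13C5]valine and
#' [U-13C6]leucine, each fully replacing its substrate at 0.99 isotopic
#' purity per position.
#'
#' @param purity Per-position isotopic enrichment.
#' @return Named list of [tracer_spec]s.
#' @export
default_tracers <- function(purity = 0.99) {
  list(glucose = tracer_spec("GLC.x", 1:6, purity = purity, name = "[U-13C6]glucose"),
       valine  = tracer_spec("VAL.x", 1:5, purity = purity, name = "[U-13C5]valine"),
       leucine = tracer_spec("LEU.x", 1:6, purity = purity, name = "[U-13C6]leucine"))
}

#' Measured extracellular rates as flux combinations
#'
#' Maps each measured medium species to the linear combination of reference
#' network net fluxes it reports: simple uptakes/secretions for glucose,
#' lactate, alanine, valine and leucine; net uptake (uptake minus secretion)
#' for glutamine and glutamate, whose medium pools exchange in both
#' directions.
#'
#' @return Named list of coefficient vectors over reaction ids.
#' @export
reference_rate_map <- function() {
  list(glucose   = c(v_glc_up = 1),
       lactate   = c(v_lac_sec = 1),
       alanine   = c(v_ala_sec = 1),
       valine    = c(v_val_up = 1),
       leucine   = c(v_leu_up = 1),
       glutamine = c(v_gln_up = 1, v_gln_sec = -1),
       glutamate = c(v_glu_up = 1, v_glu_sec = -1))
}

# scenario definitions: pinned fluxes determining the whole net-flux vector,
# plus exchange fluxes. Magnitudes are order-consistent with the printed
# glutamine fluxes (tens of nmol/well/h); the knockout scenario silences
# BCKDH, raises PDH/PC and glutamine turnover, and shifts fatty acid
# synthesis from odd chains to palmitate.
scenario_table <- function(scenario) {
  switch(scenario,
    control = list(
      pins = c(v_glc_up = 100, v_lac_sec = 150, v_ala_sec = 10,
               v_gln_up = 45, v_gln_sec = 39, v_glu_up = 5, v_glu_sec = 8,
               v_leu_up = 6, v_val_up = 0.6, v_ile_up = 0.3,
               v_fas16 = 4.675, v_fas15 = 0.2, v_fas17 = 0.2, v_pc = 12),
      exchange = c(v_pyrt = 20, v_sdh = 15, v_fum = 30, v_mdh = 40,
                   v_malt = 10, v_gls = 10, v_gdh = 20,
                   v_bcat_l = 30, v_bcat_v = 20)),
    bckdha_ko = list(
      pins = c(v_glc_up = 90, v_lac_sec = 120, v_ala_sec = 8,
               v_gln_up = 56, v_gln_sec = 43, v_glu_up = 5, v_glu_sec = 8,
               v_leu_up = 0.05, v_val_up = 0.05, v_ile_up = 0.3,
               v_fas16 = 4.9, v_fas15 = 0.05, v_fas17 = 0.05, v_pc = 18),
      exchange = c(v_pyrt = 20, v_sdh = 15, v_fum = 30, v_mdh = 40,
                   v_malt = 10, v_gls = 10, v_gdh = 80,
                   v_bcat_l = 30, v_bcat_v = 20)),
    stop("unknown scenario: ", scenario))
}

#' Free net fluxes of the reference network
#'
#' The reaction set whose net fluxes parameterize the flux space of the
#' reference network (uptakes, secretions, fatty acid synthesis sinks,
#' pyruvate carboxylase): together they pin every other net flux through
#' mass balance and the fixed ratios. Used for reporting parameter-recovery
#' coverage.
#'
#' @return Character vector of reaction ids.
#' @export
reference_free_fluxes <- function() {
  names(scenario_table("control")$pins)
}

#' Ground-truth feasible flux vector for a study scenario
#'
#' Builds a strictly feasible flux vector on the reference network for the
#' `"control"` or `"bckdha_ko"` scenario. The knockout scenario differs from
#' control only in the documented edits (BCKDH flux silenced to < 1% of
#' control, PDH/PC and glutamine uptake/secretion raised, odd-chain FA
#' synthesis collapsed) plus the mass-balance rebalancing they imply.
#' With `jitter_sd > 0` the pinned fluxes are multiplied by seeded
#' log-normal noise (resampling until feasible), for simulation studies
#' over varied truths.
#'
#' @param net The reference `flux_network`.
#' @param seed RNG seed (only used when `jitter_sd > 0`).
#' @param scenario `"control"` or `"bckdha_ko"`.
#' @param jitter_sd Log-scale SD of multiplicative jitter (default 0).
#' @return A [flux_vector].
#' @export
sample_feasible_fluxes <- function(net, seed = NULL,
                                   scenario = c("control", "bckdha_ko"),
                                   jitter_sd = 0) {
  scenario <- match.arg(scenario)
  tab <- scenario_table(scenario)
  basis <- free_flux_basis(net)
  irrev <- setdiff(reaction_ids(net), reversible_ids(net))
  if (jitter_sd > 0 && !is.null(seed)) set.seed(seed)
  for (attempt in 1:50) {
    pins <- tab$pins
    if (jitter_sd > 0) pins <- pins * exp(stats::rnorm(length(pins), 0, jitter_sd))
    v <- pin_fluxes(basis, pins)
    if (all(v[irrev] > 0)) {
      return(flux_vector(v, exchange = tab$exchange, network = net))
    }
    if (jitter_sd == 0) break
  }
  stop("could not construct a feasible scenario flux vector")
}

# Gaussian noise in the tangent space of the probability simplex: measured
# MID channels are fractions of a total ion count, so their errors are
# sum-constrained; zero-sum noise keeps every noisy vector summing to one
# and the per-fragment SSR exactly chi-squared with (channels - 1) degrees
# of freedom. Unoccupied channels may go slightly negative, exactly as real
# natural-abundance-corrected MID tables do.
add_mid_noise <- function(midv, sd) {
  eps <- stats::rnorm(length(midv), 0, sd)
  midv + eps - mean(eps)
}

#' Generate a noisy multi-tracer dataset with known ground truth
#'
#' Simulates steady-state corrected MIDs of the measured fragments under
#' each tracer, adds independent Gaussian noise (clipped at zero and
#' renormalized), and emits matching noisy exchange-rate measurements, all
#' from a known flux vector.
#'
#' @param net The reference `flux_network`.
#' @param fluxes Ground-truth [flux_vector].
#' @param tracers Named list of [tracer_spec]s (default [default_tracers()]).
#' @param noise_sd MID channel noise SD (default 0.003 mol fraction).
#' @param rate_noise_rel Relative SD of rate measurements (default 5%).
#' @param n_replicates MID replicates per tracer (default 3).
#' @param seed RNG seed.
#' @param fragments Data frame of measured fragments (default
#'   [reference_measured_fragments()]).
#' @param rate_map Rate coefficient map (default [reference_rate_map()]).
#' @return List: `experiments` (list of [tracer_experiment]), `truth`
#'   (the flux vector), `seed`.
#' @export
generate_tracer_dataset <- function(net, fluxes, tracers = default_tracers(),
                                    noise_sd = 0.003, rate_noise_rel = 0.05,
                                    n_replicates = 3, seed = NULL,
                                    fragments = reference_measured_fragments(),
                                    rate_map = reference_rate_map()) {
  if (!is.null(seed)) set.seed(seed)
  sys <- emu_decompose(net, fragments$species)
  experiments <- lapply(tracers, function(tr) {
    sim <- emu_evaluate(sys, fluxes, tr)
    mids <- list()
    for (i in seq_len(nrow(fragments))) {
      sp <- fragments$species[i]
      key <- emu_key(sp, seq_len(fragments$carbons[i]))
      truemid <- sim[[key]]
      vals <- t(vapply(seq_len(n_replicates), function(r) {
        if (noise_sd > 0) add_mid_noise(truemid, noise_sd) else truemid
      }, numeric(length(truemid))))
      mids[[sp]] <- list(values = vals, sd = max(noise_sd, 1e-3))
    }
    rates <- lapply(names(rate_map), function(spp) {
      coef <- rate_map[[spp]]
      true <- sum(coef * fluxes$net[names(coef)])
      sd <- max(rate_noise_rel * abs(true), 1e-3)
      list(name = spp, coef = coef,
           value = true + if (rate_noise_rel > 0) stats::rnorm(1, 0, sd) else 0,
           sd = sd)
    })
    tracer_experiment(tr, mids, rates)
  })
  list(experiments = experiments, truth = fluxes, seed = seed,
       noise_sd = noise_sd)
}

# Euclidean projection onto the probability simplex (uniform shift + clip):
# unlike proportional renormalization it does not preferentially shrink the
# large channels, so clipped near-zero channels do not masquerade as extra
# labeling
simplex_project <- function(x) {
  u <- sort(x, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(x - tau, 0)
}

#' Generate a synthetic ISA fatty-acid dataset
#'
#' Builds measured MIDs from the ISA forward model `D * synthesized + (1 - D)
#' * unlabeled` plus Gaussian noise, simplex-projected.
#'
#' @param truth Named list (per FA) of `c(D = ..., g = ...)`.
#' @param noise_sd Channel noise SD.
#' @param seed RNG seed.
#' @return List: `mids` (named list of numeric MIDs), `truth`, `seed`.
#' @export
generate_isa_dataset <- function(truth, noise_sd = 0.003, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mids <- lapply(names(truth), function(fa) {
    par <- truth[[fa]]
    stopifnot(par[["D"]] >= 0, par[["D"]] <= 1, par[["g"]] >= 0, par[["g"]] <= 1)
    model <- isa_model(fa)
    m <- par[["D"]] * synthesized_mid(model, par[["g"]]) +
      (1 - par[["D"]]) * c(1, numeric(model$carbons))
    if (noise_sd > 0) {
      simplex_project(m + stats::rnorm(length(m), 0, noise_sd))
    } else m
  })
  names(mids) <- names(truth)
  list(mids = mids, truth = truth, seed = seed, noise_sd = noise_sd)
}

#' Generate a medium concentration time course
#'
#' Converts target uptake/secretion rates into fresh/spent concentration
#' pairs over the tracing window: `spent = fresh -/+ rate * hours / volume`,
#' with multiplicative noise on the concentration change. Applying
#' [exchange_rate()] to the output recovers the targets within noise.
#'
#' @param rates Data frame with `species`, `rate` (nmol/well/h, >= 0) and
#'   `direction` (`"uptake"` or `"secretion"`).
#' @param fresh Named vector of fresh-medium concentrations (nmol/ul).
#' @param volume_ul Medium volume per well.
#' @param hours Tracing window (default 48).
#' @param noise_rel Relative SD on the concentration change (default 5%).
#' @param seed RNG seed.
#' @return Data frame: species, fresh_conc, spent_conc, volume_ul, hours,
#'   direction.
#' @export
generate_medium_timecourse <- function(rates, fresh, volume_ul = 1000,
                                       hours = 48, noise_rel = 0.05,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(rates$direction %in% c("uptake", "secretion")),
            all(is.finite(rates$rate)))
  out <- lapply(seq_len(nrow(rates)), function(i) {
    sp <- rates$species[i]
    delta <- rates$rate[i] * hours / volume_ul
    if (noise_rel > 0) delta <- delta * (1 + stats::rnorm(1, 0, noise_rel))
    f <- fresh[[sp]]
    s <- if (rates$direction[i] == "uptake") f - delta else f + delta
    if (s < 0) stop("drawdown of ", sp, " exceeds its fresh concentration")
    data.frame(species = sp, fresh_conc = f, spent_conc = s,
               volume_ul = volume_ul, hours = hours,
               direction = rates$direction[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}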