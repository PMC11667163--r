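# adipoflux

Stable-isotope tracing computations for cultured adipocytes: natural-abundance
correction of GC-MS mass isotopomer distributions (MIDs), mole percent
enrichment, extracellular exchange rates, steady-state ¹³C label simulation by
the elementary metabolite unit (EMU) framework, nonlinear least-squares
metabolic flux analysis (¹³C-MFA) with χ² goodness-of-fit and
profile-likelihood confidence intervals, and isotopomer spectral analysis
(ISA) of de novo lipogenesis.

The package is aimed at metabolism labs analyzing multi-tracer
([U-¹³C₆]glucose, [U-¹³C₅]valine, [U-¹³C₆]leucine) steady-state labeling
experiments in 3T3-L1-style adipocytes, in particular the rewiring of central
carbon metabolism when branched-chain amino acid (BCAA) catabolism is
disrupted at BCKDH. It ships an atom-mapped, compartmentalized reference
network (glycolysis, oxPPP branch fixed at 0.3% of glucose uptake, TCA cycle
with symmetric succinate/fumarate, pyruvate cycling, glutamine/glutamate
medium pools, BCKDH-gated BCAA oxidation, propionyl-CoA anaplerosis, fatty
acid synthesis sinks for C16:0/C15:0/C17:0) and a synthetic-data generator
with known ground truth, so the entire pipeline is validated end-to-end
without external data.

## The core computations

**Label simulation.** For a flux vector $v$ (net + exchange per reversible
reaction, the net(exchange) convention), the steady-state MID of every
measured fragment solves the EMU balance equations: per EMU size, a linear
system whose coefficients are flux-weighted atom transfers, with condensation
reactions entering as convolutions of smaller EMUs. A brute-force positional
isotopomer solver serves as an independent oracle (agreement < 1e-9 on all
shipped toy networks).

**Flux estimation.** Fluxes minimize the variance-weighted SSR

$$\mathrm{SSR}(v) = \sum_{\text{channels}} \left(\frac{\hat m_i(v) - m_i}{\sigma_i}\right)^2 + \sum_{\text{rates}} \left(\frac{\hat r_j(v) - r_j}{\sigma_j}\right)^2$$

jointly over all tracer experiments, from 20 random feasible restarts
(default). Fit quality is assessed by the two-sided χ² test at α = 0.01 on
dof = measurements − free parameters; per-flux 95% CIs come from profile
likelihood at the SSR_min + 3.84 threshold.

**ISA.** A newly synthesized palmitate is the 8-fold convolution of an
acetyl-CoA unit that is M+2 with probability $g$ (the lipogenic precursor
enrichment); odd chains add one propionyl-CoA primer to 6–7 acetyl units. The
measured FA pool is $D\,\cdot$ synthesized $+\,(1-D)\,\cdot$ unlabeled, and
$(D, g)$ are fitted with profile CIs; group differences are called by
non-overlapping 95% CIs.

## Worked example

Simulate a control-condition three-tracer dataset from a known flux vector,
fit it, and profile one flux:

```r
library(adipoflux)
net   <- reference_adipocyte_network()
truth <- sample_feasible_fluxes(net, scenario = "control")
ds    <- generate_tracer_dataset(net, truth, seed = 7)   # 3 tracers x 3 replicates
fit   <- fit_fluxes(net, ds$experiments, n_restarts = 5, seed = 1)
fit
#> mfa_fit: SSR = 939.266 on 952 dof (accept interval [843.36, 1068.15] at alpha = 0.01): ACCEPTED
#> best of 5 restarts (SSR range 939.266 .. 2829.780)
#>   reaction         net exchange     label
#>   v_glc_up 102.5731249       NA       103
#>    v_oxppp   0.3077194       NA     0.308
#>     v_glyc 102.2654055       NA       102
#>  v_lac_sec 154.9564200       NA       155
#>  ...
flux_confidence_interval(fit, "v_pdh")
#> v_pdh: 43.13  95% CI [40.85, 45.4]
truth$net[["v_pdh"]]
#> [1] 42.9
```

The SSR lands inside the χ² acceptance interval (the data were generated at
the stated noise level, 0.003 mol fraction per MID channel and 5% on rates),
the fitted glucose uptake (102.6) recovers the true 100 within noise, the
oxPPP flux sits at 0.3% of it by construction, and the true PDH flux (42.9)
falls inside its 95% profile CI.

ISA on a synthetic palmitate MID generated with D = 0.6, g = 0.45:

```r
isa_ds <- generate_isa_dataset(list("C16:0" = c(D = 0.6, g = 0.45)), seed = 2)
isa_confidence(isa_fit(isa_ds$mids[["C16:0"]], isa_model("C16:0")))
#> ISA C16:0: D = 0.6044, g = 0.4501 (SSR 5.58)
#>   D 95% CI [0.5990, 0.6098], g CI [0.4449, 0.4554]
mpe(mid(c(0.5, 0.25, 0.25)))
#> [1] 37.5
```

Both parameters are recovered within their intervals: 60.4% of the pool newly
synthesized over the window, with glucose-derived carbon contributing 45% of
lipogenic acetyl-CoA.

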