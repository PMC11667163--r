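---
title: "Methods: isotope tracing and 13C flux analysis in adipoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope tracing and 13C flux analysis in adipoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adipoflux implements the computation stack behind steady-state
$^{13}$C-tracer studies of cultured adipocytes: correction of GC-MS mass
isotopomer distributions (MIDs) for natural isotope abundance, mole percent
enrichment (MPE), extracellular exchange rates from medium concentrations,
forward simulation of labeling by the elementary metabolite unit (EMU)
framework on an atom-mapped compartmentalized network, flux estimation by
weighted nonlinear least squares with a $\chi^2$ goodness-of-fit test and
profile-likelihood confidence intervals, and isotopomer spectral analysis
(ISA) of de novo lipogenesis. A synthetic-data module generates
ground-truth-known datasets so that every stage of the pipeline is testable
without any external measurement.

```{r setup}
library(adipoflux)
```

## The metabolic model

The shipped reference network (`reference_adipocyte_network()`) covers
glycolysis (lumped glucose &rarr; 2 pyruvate, since no glycolytic
intermediate is measured), an oxidative pentose-phosphate branch, lactate
and alanine secretion, compartmentalized pyruvate pools with pyruvate
dehydrogenase (PDH) and pyruvate carboxylase (PC), malic-enzyme pyruvate
cycling, the full TCA cycle, the citrate shuttle to cytosolic acetyl-CoA,
glutamine and glutamate medium pools with simultaneous uptake and
secretion, BCKDH-gated oxidation of leucine, valine and isoleucine,
propionyl-CoA anaplerosis to succinyl-CoA, and fatty acid synthesis sinks
for C16:0, C15:0 and C17:0.

Modeling assumptions, mirrored in the network file and its validation:

* metabolic and isotopic steady state; constant extracellular fluxes over
  the tracing window;
* no biomass drain other than the fatty-acid synthesis sinks (terminally
  differentiated, non-dividing cells);
* succinate and fumarate are rotationally symmetric: every reaction
  consuming them is expanded into the two atom orientations at half weight;
* CO$_2$ released by decarboxylation is diluted into the medium and does
  not reincorporate: all carboxylation reactions (PC, the
  methylcrotonyl-CoA carboxylase step inside the lumped leucine oxidation,
  propionyl-CoA carboxylase) draw from an unlabeled CO$_2$ dilution pool,
  and `validate_network()` warns if a network recycles its own CO$_2$;
* separate mitochondrial and cytosolic pools of pyruvate, acetyl-CoA,
  oxaloacetate, malate, citrate, glutamate and glutamine, with a reversible
  malate carrier and glutamate/&alpha;-ketoglutarate exchange;
* the oxidative PPP branch is fixed at 0.3% of glucose uptake via a
  `#ratio` constraint. At that magnitude the non-oxidative return to
  glycolysis is unidentifiable and its labeling signature is far below
  measurement noise, so the branch terminates in a pentose sink rather
  than re-entering glycolysis with full transketolase atom scrambling.

Two deliberate simplifications: aspartate pools are omitted because no
measured fragment constrains them (the malate carrier plus cytosolic
malate dehydrogenase carry the same exchange role), and malic enzyme is a
single lumped reaction because its compartment assignment is not
resolvable from these data. BCAA oxidation below the committed BCKDH step
is lumped into one reaction per amino acid; isoleucine enters as an
unlabeled acetyl-CoA/propionyl-CoA source with a free uptake flux.

Carbon atoms are numbered from C1 by standard biochemical convention
(pyruvate C1 = carboxyl). The medium glutamine and glutamate pools are
modeled as large dilution pools: fresh-medium inflow fixed at 20 times the
uptake flux, so that secreted label is diluted about 20:1, approximating a
large, slowly-turning-over medium reservoir whose extracellular glutamine
MID is measurable.

## Label simulation

`emu_decompose()` traces the atoms of the measured fragments backwards
through the atom maps, producing one linear balance system per EMU size;
`emu_evaluate()` (a compiled core) assembles the flux-weighted systems and
solves them in increasing size order, convolving smaller-EMU solutions at
condensation reactions. Reversible reactions contribute forward and
backward directed fluxes `max(net, 0) + exchange` and
`max(-net, 0) + exchange`. Directed fluxes are floored at $10^{-12}$ so
that transiently degenerate points visited by the optimizer keep a
regular system; an exactly singular system (a zero-flux trapped cycle) is
reported with the offending EMU set, or ridge-regularized
(`singular = "ridge"`) inside the fitting objective so the optimizer sees
a smooth penalty landscape rather than a cliff.

Simulation operates in corrected-MID space: the $^{12}$C backbone
contributes no natural abundance, boundary substrates are unlabeled except
the tracer (default purity 0.99 per labeled position), and dilution
species enter unlabeled. `brute_force_isotopomer_sim()` is an independent
verification oracle: it enumerates all positional isotopomers of every
species and solves the (bilinear, because of condensations) balance by
damped Gauss–Seidel iteration to $10^{-13}$, with symmetric species
averaged at consumption. The two implementations agree to better than
$10^{-9}$ on all shipped toy networks (`toy_networks()`), which exercise
transfer, scrambling, condensation cycles, symmetry and reversible
exchange.

One property worth noting: reducing the tracer's fractional abundance
monotonically reduces the enrichment of every single-carbon EMU, but *not*
every mass channel of a multi-unit product — M1/M3 of citrate can rise
under dilution as mixed labeled/unlabeled unit combinations become more
likely. The test suite asserts the per-carbon version.

## Flux estimation

`fit_fluxes()` minimizes the variance-weighted SSR
$\sum \left((\hat{m} - m)/\sigma\right)^2$ over all mass channels of all
replicates of all tracer experiments, plus rate residuals
$\left((\hat{v} - v)/\sigma_v\right)^2$, where measured rates are linear
combinations of net fluxes (net glutamine uptake is
`v_gln_up - v_gln_sec`, and so on).

Parameterization: net fluxes live in an orthonormal null-space basis of
the stoichiometric matrix augmented with the ratio constraints, so mass
balance and fixed ratios hold exactly at every iterate; exchanges are
optimized through the bounded transform $x/(1+x) \in [0, 1)$.
Irreversibility is kept by hinge penalty residuals (weight 30 per
nmol/well/h of violation), inactive at any interior optimum.

The restart strategy matters on this landscape. The dominant spurious
attractor is *full scrambling*: all exchanges at their upper bound, where
the objective is nearly flat in the exchange directions. Each restart
therefore (1) samples a feasible net-flux vector by hit-and-run from an
interior point, (2) snaps it onto the measured rates by a linear
least-squares correction (rates are linear in the free coordinates),
blending back toward the interior point if the snap leaves the feasible
cone, (3) draws exchanges log-uniformly in [0.1, 1000], and (4) optimizes
in two stages — net fluxes first with exchanges frozen (clipped below full
scrambling), then everything free — with bounded Levenberg–Marquardt
(`minpack.lm`, ftol = ptol = $10^{-10}$, numerical Jacobian). The default
is 20 restarts. A basin-hopping polish follows: seeded perturbations of the
incumbent best (10% scale on the net-flux coordinates, logistic jitter on
the exchanges), re-optimized with the same two-stage search and kept when
they lower the SSR. This matters most when a tracer carries little label
information — with BCKDH silenced the leucine/valine experiments are nearly
unlabeled and the remaining landscape has shallow spurious minima. The best
SSR is kept, and per-restart SSRs are reported.

Goodness of fit uses the two-sided $\chi^2$ interval
$[\chi^2_{\alpha/2, \nu}, \chi^2_{1-\alpha/2, \nu}]$ at $\alpha = 0.01$
with $\nu$ = (mass channels above M0 per fragment per replicate + rate
measurements) − free parameters. Confidence intervals are
profile-likelihood: `flux_confidence_interval()` steps one reaction's net
flux away from the optimum, re-optimizing everything else until the SSR
crosses $\mathrm{SSR}_{\min} + \chi^2_{0.95,1} = 3.84$, and refines the
crossing by bisection. Profiling is done by continuation (each step warm
starts from the previous profile point); a pin far from the optimum is
otherwise prone to falling into the scrambled attractor. Unbounded
directions are reported as infinite with a flag.

## Isotopomer spectral analysis

Under a uniformly labeled tracer the lipogenic acetyl-CoA pool is a
two-state mixture — M+2 with probability $g$, unlabeled otherwise — and a
newly synthesized fatty acid is the $n$-fold convolution of that unit
(8 units for palmitate; 6 or 7 acetyl units plus one propionyl primer for
C15:0/C17:0, with an optional M+3 propionyl enrichment parameter, fixed
at 0 for glucose-tracer fits). The measured pool is
$D \cdot \text{synthesized}(g) + (1-D) \cdot \text{unlabeled}$, where $D$
is the fraction of the pool newly synthesized during the 48 h window.
M+1 acetyl units are neglected, which is appropriate for uniformly
labeled tracers at high purity but not for partially labeled ones.
Pre-existing fatty acids are fully unlabeled in corrected-MID space, and
C18 species are excluded (elongation is not modeled).

`isa_fit()` minimizes the SD-weighted SSR over $(D, g) \in [0,1]^2$ with
an 11&times;11 grid initialization followed by bounded quasi-Newton — the
$D$–$g$ trade-off creates local minima that a single start can fall into.
`isa_confidence()` profiles each parameter (the other re-optimized) to
the 3.84 threshold, clipped to $[0,1]$; an unlabeled pool is flagged as
the $D \cdot g \approx 0$ boundary where the parameters are not separately
identifiable. Group comparisons use non-overlapping 95% CIs
(`isa_compare()`).

## Measurement processing

`correction_matrix()` builds the natural-abundance correction matrix of a
derivatized fragment by convolving the isotope distributions (NIST
abundances for C, H, N, O, Si, S) of all atoms that are not tracer-labeled
carbons; column $j$ is the predicted observed distribution with exactly
$j$ backbone $^{13}$C. `correct_mid()` inverts it by non-negative least
squares and renormalizes to the simplex. Methyl-ester carbons of FAME
fragments are treated as derivatization (unlabeled) atoms, not backbone.
MPE is $100 \sum_i M_i \, i / n$. Exchange rates are
$(\Delta \text{concentration}) \times \text{volume} / \text{time}$ in
nmol/well/h (per-well normalization throughout); no evaporation control is
applied. The desaturation index is C16:1/C16:0 and C18:1/C18:0, and
absolute DNL is $D \times$ pool size per fatty acid.

## The synthetic-data generator

`sample_feasible_fluxes()` returns documented ground-truth flux vectors.
The control scenario pins glucose uptake at 100, lactate secretion at 150,
glutamine uptake/secretion at 45/39, glutamate uptake/secretion at 5/8,
leucine 6, valine 0.6, isoleucine 0.3, palmitate synthesis 4.675 and OCFA
synthesis 0.2 + 0.2 nmol/well/h, with PC at 12 — magnitudes chosen to sit
on the scale of the study's printed glutamine fluxes (tens of nmol/well/h);
every other net flux follows from mass balance. The `bckdha_ko` scenario
differs only in the documented edits: BCKDH silenced to 0.05 (< 1% of
control), glucose/lactate reduced, glutamine uptake/secretion raised to
56/43, PDH/PC raised, odd-chain synthesis collapsed and palmitate slightly
increased, plus the rebalancing these imply. Exchange fluxes are set to
moderate values (10–40) with glutamate/&alpha;KG exchange raised to 80 in
the knockout. A log-normal jitter option varies the truth across
simulation replicates.

`generate_tracer_dataset()` simulates the corrected MIDs of the measured
fragment panel (pyruvate, TCA intermediates, intracellular and
extracellular glutamine, glutamate, leucine, KIC, valine, C15:0, C16:0,
C17:0) under the three-tracer design ([U-$^{13}$C$_6$]glucose,
[U-$^{13}$C$_5$]valine, [U-$^{13}$C$_6$]leucine), in three replicates, and
adds Gaussian noise with SD 0.003 mol fraction — typical GC-MS precision.
Noise is drawn in the tangent space of the probability simplex (zero-sum
across channels): measured MID channels are fractions of a total ion
count, so their errors are intrinsically sum-constrained, and zero-sum
noise makes the per-fragment SSR exactly $\chi^2$ with (channels − 1)
degrees of freedom — consistent with the dof bookkeeping of the fit.
Unoccupied channels may go slightly negative in the noisy fixtures,
exactly as real natural-abundance-corrected MID tables do; clipping them
to zero and renormalizing would bias the large channels downward (which
masquerades as extra labeling) and inflate the SSR by roughly 10%,
destroying the $\chi^2$ calibration. Rates
get 5% relative noise. The ISA generator projects noisy MIDs onto the
simplex by Euclidean projection (uniform shift + clip), which, unlike
proportional renormalization, does not shrink M0 preferentially and
therefore does not masquerade as extra labeling. Channel noise is
independent across mass channels; real replicate noise is likely
correlated, which the generator does not emulate — nor does it emulate
chromatographic artifacts, derivatization variability, cell growth, or
non-stationary labeling. Passing the synthetic validation therefore
demonstrates correctness of the computations, not robustness to every
real-data pathology.

## Validation problem sizes

The shipped validation (test suite and `scripts/acceptance.R`) uses: oracle
equivalence on four toy networks; $\chi^2$ calibration of the
true-flux SSR over 200 noise realizations (975 measurements each);
parameter recovery on 20 jittered-truth three-tracer datasets fitted with
5 restarts, scoring the 14 free net fluxes against their 95% profile CIs
via the profile SSR at the true value; an ISA identifiability sweep over a
$(D, g)$ grid plus 200-replicate CI coverage; and one control-vs-knockout
fit pair for the qualitative contrast. These sizes give stable pass/fail
behavior on a single CPU while keeping each stage's statistical claim
meaningful.

## Known limitations

* Exchange fluxes are weakly identified (as expected at isotopic steady
  state); their CIs are frequently unbounded and the medium-pool
  uptake/secretion pairs are identified mainly through their difference
  and the extracellular glutamine MID.
* The optimizer's two-stage restarts make the global basin reachable in a
  handful of restarts on the reference network, but as with all
  multistart local optimization there is no guarantee; per-restart SSRs
  are reported so rugged fits are visible.
* The lumped leucine oxidation draws its carboxyl carbon from the CO$_2$
  dilution pool in a single reaction; positional fidelity within the
  lumped step is approximate (documented in the network file).
* Only $^{13}$C single-element tracers are supported; isotopically
  non-stationary MFA and $^2$H tracers are out of scope.
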