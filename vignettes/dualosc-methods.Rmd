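---
title: "Modelling reporter load on the AraC/LacI dual-feedback oscillator"
author: "dualosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reporter load on the AraC/LacI dual-feedback oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualosc)
```

## The question the package addresses

A downstream reporter gene is supposed to read out an upstream circuit
without changing it. In practice it can perturb the circuit through two
distinct channels: **retroactivity** — the reporter promoter's
protein-binding sites titrate free regulatory proteins away from the
circuit — and **resource competition**, here the sharing of the ClpXP
protease among all SsrA-tagged proteins, so that reporter protein load
slows the degradation of the circuit's own regulators. `dualosc` builds a
mechanistic ODE model of an AraC/LacI dual-feedback (Smolen-type)
oscillator with three alternative GFP reporter configurations and makes
the two channels independently switchable, so their contributions can be
separated cleanly in silico.

## The circuit and its promoter microstates

The regulatory core is fixed: *araC* (activator plasmid,
`n_activator_dna` copies) and *lacI* (repressor plasmid,
`n_repressor_dna` copies) are each transcribed from a hybrid lac/ara
promoter carrying one AraC-dimer binding site and two LacI operators.
AraC (arabinose-activated) closes a positive feedback loop; LacI
(IPTG-inactivated) closes a delayed negative loop. The reporter variant
differs per `circuitConfig()`:

* `lac_ara` — GFP from the same hybrid promoter (adds 1 AraC site + 2
  operators per plasmid copy);
* `lac` — GFP from a two-operator lac promoter (no AraC site);
* `lac_decoy` — the lac reporter plus a transcriptionally inert AraC
  decoy site, equalising the *total* binding-site census with `lac_ara`;
* `none` — the bare oscillator.

Promoter occupancy is resolved at the microstate level
(`buildPromoterModel()`). The LacI patterns of a two-operator promoter
are `{empty, O1, O2, both-bound, looped}`; a *single* tetramer bridges
the operators in the looped state. Crossed with the AraC site this gives
10 microstates for a lac/ara promoter, 5 for a lac promoter, 2 for the
decoy. Three loop rates govern repression memory: capture from a
singly-bound state (`k_loop`), opening back to a singly-bound state
(`k_unloop`, split evenly between O1 and O2 since the looped complex
does not remember its anchor), and full dissociation to the empty
pattern with release of the tetramer (`k_loop_diss`). Giving the loop
two distinct exit routes is forced by having three named rates: opening
preserves the bound tetramer, dissociation releases it.

Transcription is zero from every LacI-occupied state; the activated
state (AraC bound, operators clear) of a lac/ara promoter transcribes at
its maximum; the unbound, unrepressed state at a small basal rate. A lac
promoter needs no activator — its empty state transcribes at its
maximum. This is why, at equal maximum rates, the lac reporter expresses
much more GFP over an oscillation cycle than the lac/ara reporter: free
AraC is low through most of the cycle, so the hybrid promoter rarely
reaches its activated state while the lac promoter is open whenever
active LacI is low.

## Assembled dynamics

`assembleOdes()` builds the master equations for every promoter class
(weighted by plasmid copy number), an explicit mRNA stage per gene
(transcription, decay `delta_m`, dilution), translation into functional
units (two monomers per AraC dimer, four per LacI tetramer), binding
fluxes that deplete and replenish the free pools, shared degradation and
first-order dilution `lambda` on proteins and mRNA (DNA is not diluted;
copy number is a fixed census). A lumped mode (`mrna = FALSE`)
substitutes quasi-steady mRNA for testing.

Degradation (`degradationFlux()`) is competitive Michaelis–Menten over
the free tagged pools: with sharing on,
\(v_x = V_{\max}\, x / (K_M + a + l + g)\) for \(x \in \{a, l, g\}\);
with sharing off, GFP is degraded through an identical but independent
channel while AraC and LacI keep their shared denominator. Dimerisation
and tetramerisation are treated as fast, so the model tracks functional
dimer/tetramer pools directly.

The toggles act **only** on downstream terms. With
`retroactivity_on = FALSE` the reporter/decoy occupancies still evolve —
they *sense* the free pools, so occupancy trajectories remain observable
— but exchange no molecules with them. With
`protease_sharing_on = FALSE` GFP leaves the shared queue. With both
off, the free-protein subsystem of all three reporter circuits is
mathematically identical, and with sharing off the lac/ara-reporter and
lac-plus-decoy circuits coincide exactly, because the AraC site of the
hybrid promoter toggles independently of the operators, so its marginal
occupancy — and hence its titration load — equals the decoy's. The test
suite verifies both identities numerically to ~1e-5 relative.

## Inducer response

Active fractions (`activeFractions()`) scale the binding on-rates.
LacI: \(f_L = 1/(1 + (\mathrm{IPTG}/K_I)^{n_I})\). AraC:
\(f_A = f_0 + (1 - f_0)\,H(\mathrm{ara})\, / (1 +
(\mathrm{IPTG}/K_{IA})^{n_{IA}})\), i.e. IPTG weakly inhibits only the
arabinose-dependent part, so the floor at zero arabinose is
IPTG-independent. The arabinose Hill coefficient is deliberately steep
(n = 4): it lumps the all-or-none character of arabinose uptake
induction into the effective activation, and it keeps the oscillation's
low-arabinose boundary sharp so that sub-threshold conditions stay
quiescent even when a heavy GFP load slows effective degradation.

## Parameter defaults and how they were fixed

All defaults (units: molecules/cell, minutes; inducers in % w/v and mM)
are listed with one-line provenance in `parameterProvenance()`. The
magnitudes follow the dual-feedback oscillator modelling literature for
this circuit family; within those ranges the constants were calibrated,
by randomized scanning and local refinement, so that the default circuit
reproduces the qualitative behavior of the system: relaxation
oscillations with periods of tens of minutes across the high-arabinose
half of the inducer plane, a quiescent low-arabinose region, survival of
the core at the top of the IPTG range, and a protease-sharing-driven
loss of oscillation for the heavily expressing lac reporter at high
IPTG. The load-bearing features of the calibrated set are:

* **Deep queueing**: \(K_M \approx 8\) molecules with \(V_{\max} = 420\)
  molecules/min, far below peak production, so degradation is
  near-zero-order at oscillation amplitudes — the relaxation mechanism.
* **A slow mRNA stage** (`delta_m` = 0.064/min) providing the
  transcriptional lag of the negative loop.
* **Sticky, slow-engaging LacI binding** (`kr_on` small, `kr_off`
  small): repression engages only at tens of active tetramers and, once
  looped, persists for minutes independent of the free pool — the
  refractory memory of the cycle.
* **Fast dilution** (`lambda` = 0.06/min, ~11.5-min doubling): keeps the
  quiescent state's protein floor dilution-dominated rather than
  protease-dominated, which is what prevents a large GFP queue from
  igniting oscillations below the arabinose threshold.
* **Reporter maxima well below the regulatory promoter's** (0.24 vs 3.8
  mRNA/min/copy, equal between the two reporter promoters): the GFP
  burden is then a perturbation of order \(V_{\max}\), not an
  annihilating flood. With reporter maxima equal to the regulatory
  maximum the queue saturates everywhere and no configuration
  oscillates.

## Stability analysis

The total occupancy of each promoter class is conserved, so the full
Jacobian is structurally singular. Equilibrium and stability work
therefore run in reduced coordinates with the fully-unbound state of
each class eliminated (`jacobianAt(..., reduced = TRUE)`).
`findEquilibria()` is a damped Newton–Raphson with central-difference
Jacobians (step scaled per state component), step-halving line search,
relative-distance deduplication at 1e-6, and explicit reporting of
nonconverged guesses. Classification (`classifyStability()`) is decided
by eigenvalue real parts; a leading real part within 1e-8 (scaled) of
zero is flagged marginal rather than silently resolved. An independent
Routh–Hurwitz test on Faddeev–LeVerrier characteristic-polynomial
coefficients cross-validates the decision for systems up to 12 states —
beyond that the polynomial's conditioning in double precision makes the
array unreliable, so the cross-check is restricted rather than trusted
blindly. An all-zero Routh row (symmetric root pairs) is treated as
not-stable, matching the strict eigenvalue criterion.

## Sweeps and oscillation metrics

`runSweep()` integrates every grid cell from a standard initial state
(all DNA unbound, small seed pools), classifies the attractor from the
post-transient trajectory, and can confirm fixed cells with the Newton
route. A sustained limit cycle wins over a coexisting stable equilibrium
(flagged `coexistence`). Per-cell failures are recorded in place.

`oscillationMetrics()` discards the first half of the horizon, detects
peaks by derivative sign change with a minimum separation of a quarter
of the running period estimate, and calls a species oscillatory only if
at least two full periods are observed **and** the swing over the last
cycles exceeds 1 molecule/cell — deterministic swings below one molecule
are numerical fictions in a molecules-per-cell model, and strongly
damped transients are thereby classified fixed. Amplitude is
peak-to-trough over the last full cycles (recorded in the output
settings); the period is the mean inter-peak interval.

Default problem sizes: sweeps in the documentation, tests and the
acceptance script use a reduced 7 × 8 grid spanning the full
experimental ranges (0.01–1.0 % arabinose, 0.001–31.6 mM IPTG,
log-spaced, endpoints exact) with a 600-min horizon sampled every
minute; the full-resolution 21 × 46 grid is the `gridSpec()` default for
production runs.

## Synthetic microscopy traces and bottom counting

`generateTrace()` emulates a per-colony fluorescence time course sampled
every 3 min for 3 h: baseline plus optional linear drift, an
exponentially damped sinusoid, and i.i.d. multiplicative Gaussian noise
(default scale 0.05 — constitutive expression in vivo shows weak
fluctuations of roughly this order; the scale is config-exposed because
its true value is not identified). It does **not** emulate cell growth,
lineage structure, segmentation error, photobleaching or background
drift correlated across colonies; passing scores on synthetic panels
therefore validate the scoring pipeline's logic, not its robustness to
imaging artefacts. Panels derive per-trace seeds by hashing (master
seed, cell, replicate), so sub-panels regenerate identically.
`tracesFromModel()` resamples a simulated GFP trajectory over the final
180 min and adds the same noise, bridging model to scorer.

Bottom counting (`detectBottoms()`) smooths with a centred 3-sample
(9-min) moving average and keeps interior local minima whose topographic
prominence is at least 10% of the mean smoothed intensity. The
prominence reference is the mean level, not the intensity range: both
choices are invariant to rescaling a trace by a positive constant, but a
range-relative criterion cannot reject a constitutive trace, whose
entire range *is* noise, whereas noise dips scale with the noise
amplitude and genuine expression troughs scale with the expression
level. Runs of equal samples are collapsed so a flat-sampled trough
counts once; endpoints never count. A trace with ≥ 3 bottoms is scored
oscillating, and `scoreCondition()` reports the fraction of such traces
per condition (the relative bottom count) plus the descending-order
cumulative distribution of counts. A consequence of the 3-h observation
cap: a trace slower than ~60 min/period can never reach 3 bottoms, so
slow oscillators are systematically scored as non-oscillating — a
limitation shared with the experimental protocol, not an artefact of the
implementation.

## Known limitations

* The model is deterministic; at low molecule numbers (< 1 per cell)
  stochastic effects the ODEs cannot represent will matter in vivo.
* The parameter set is a calibrated reconstruction, not a fitted
  estimate; conclusions should be read as structural (which competition
  channel does what), not quantitative predictions of rates.
* Host-level resource competition (RNA polymerase, ribosomes) is out of
  scope; only the tag-specific protease is shared.
* Near the oscillation boundary, classification depends on the
  1-molecule amplitude threshold and the 600-min horizon; cells with
  extremely slow transients could be misclassified at shorter horizons.
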