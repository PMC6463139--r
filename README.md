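# dualosc

Mechanistic modelling of how a downstream GFP reporter perturbs the
AraC/LacI dual-feedback genetic oscillator — separating **retroactivity**
(titration of regulatory proteins by the reporter's binding sites) from
**protease sharing** (competition of all SsrA-tagged proteins for a
limited ClpXP pool).

The package is for synthetic/systems biologists who want to ask, before
building a strain: *will this reporter change the circuit it is supposed
to observe, and through which channel?*

## The model

The core is a Smolen-type oscillator: *araC* and *lacI* are both driven
by a hybrid lac/ara promoter (one AraC site, two lac operators), giving
interlinked positive (AraC + arabinose) and negative (LacI, inactivated
by IPTG) feedback. Promoter occupancy is resolved as microstates — the
LacI patterns {empty, O1, O2, both, looped} crossed with the AraC site,
with a single tetramer forming the DNA loop (rates k_l, k_-l for loop
formation/opening, k_ul for dissociation). All tagged proteins share
ClpXP degradation as competitive Michaelis–Menten kinetics:

    v_x = V_max · x / (K_M + a + l + g),   x ∈ {a, l, g}

where `a`, `l`, `g` are free AraC dimers, LacI tetramers and GFP. Three
reporter variants (lac/ara promoter, lac promoter, lac promoter + AraC
decoy site) attach downstream, and the two competition channels can be
toggled independently: with titration off, downstream sites sense but do
not consume the free pools; with sharing off, GFP is degraded through an
identical but independent channel.

On top of the ODE model sit equilibrium finding (damped Newton–Raphson),
linear stability classification (eigenvalues, Routh–Hurwitz
cross-check), two-inducer (arabinose × IPTG) phase-diagram sweeps with
amplitude/period maps, a trough-counting ("bottom count") scorer for
fluorescence time courses, and a synthetic microscopy-trace generator.

## Worked example

```r
library(dualosc)

cfg  <- circuitConfig("lac_ara")            # GFP from the lac/ara promoter
p    <- oscillatorParameters()              # defaults; see parameterProvenance()
sys  <- assembleOdes(cfg, p, inducerCondition(arabinose = 1.0, iptg = 0.01))
traj <- integrateOdes(sys, t_end = 600)     # minutes
oscillationMetrics(traj)
#> <oscillation metrics> overall: oscillatory
#>   a: oscillatory, amplitude 642, period 24.5 min
#>   l: oscillatory, amplitude 146, period 24.5 min
#>   g: oscillatory, amplitude 86.2, period 24.5 min
```

At 1.0 % arabinose and 0.01 mM IPTG the circuit runs a relaxation
oscillation with a ~25-min period; the amplitudes are peak-to-trough
molecule counts per cell of free AraC dimers (`a`), free LacI tetramers
(`l`) and GFP (`g`) over the last cycles. Swapping `"lac_ara"` for
`"lac"` gives a heavier GFP load (the lac promoter needs no activator);
at high IPTG that load is enough to pull the oscillator to a stable
fixed point while the lac/ara-reporter circuit keeps oscillating —
compare the two with:

```r
g  <- gridSpec(ara_n = 7, iptg_n = 8)     # reduced grid, full ranges
s1 <- runSweep(circuitConfig("lac_ara"), p, g)
s2 <- runSweep(circuitConfig("lac"), p, g)
compareSweeps(s1, s2)                      # areas, set relations, deltas
```

Fluorescence-trace scoring works on measured or synthetic traces:

```r
panel <- generatePanel(gridSpec(ara_n = 2, iptg_n = 2),
                       defaultRegimeMap(), n_traces_per_cell = 10, seed = 1)
s <- scoreCondition(Filter(function(tr) tr$condition$arabinose == 1 &&
                             tr$condition$iptg == 0.001, panel))
s$relative_bottom_count   # fraction of traces with >= 3 detected troughs
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/dualosc.R` (subcommands `sweep`, `score`, `gen`).

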