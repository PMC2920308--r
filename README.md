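# minsignet

Stochastic simulation and analysis of a **minimal two-pathway signaling
network** — a four-reaction model of how a cell can respond to a strong
stimulus quickly and deterministically, yet respond to a weak stimulus
slowly, with enormous cell-to-cell variability. The network is a minimal
model of apoptosis (programmed cell death) signaling, where a fast
receptor-proximal route and a slow, fluctuation-dominated mitochondrial
route converge on the same downstream effector; lowering the slow rate
constant emulates increasing levels of the apoptosis inhibitor Bcl-2.

The package is aimed at systems biologists and modelers who want an exact,
reproducible sandbox for the deterministic-to-stochastic transition in
signaling: single-cell trajectories, population ensembles, noise
statistics, and regime classification, from R or from the shell.

## The model

Three species X1, X2, X3 interconvert irreversibly from inactive to active
form under a constant stimulus with copy number *x₀*; every reaction is
mass-action and catalytic in its activator, so inactive + active copies are
conserved per species:

| channel | reaction | propensity |
|---|---|---|
| A  | stimulus activates X3 (one step, deterministic pathway) | *kₐ·x₀·x₃* |
| B1 | stimulus activates X1 (fast) | *k_b1·x₀·x₁* |
| B2 | X1\* activates X2 (**slow** — the noise generator) | *k_b2·x₁\*·x₂* |
| B3 | X2\* activates X3 (fast completion) | *k_b3·x₂\*·x₃* |

Channels A and B3 both produce active X3, joining the two pathways in a
loop. In the chemical-Langevin picture each rate *r* carries noise of
amplitude √*r*, so relative noise is 1/√*r*: the slow step keeps
fluctuations at order one **even with large copy numbers**. Under a weak
stimulus the first slow-step firing is a rare event per cell and the fast
completion then finishes activation abruptly: all-or-none activation,
bimodal population snapshots, Fano factors in the tens.

Closed-form thresholds on *x₀* separate the regimes (exposed by
`classify_regime_analytic()`): type A dominates above
*k_b3·√(k_b2·x₁ᵗ·x₂ᵗ)/kₐ*, type B below *k_b2·x₁ᵗ·x₂ᵗ/(kₐ·x₃ᵗ)*, with a
mixed band between.

Engines: exact Gillespie SSA (direct method, C++ inner loop, per-channel
event counters) and Euler–Maruyama integration of the chemical-Langevin
equations, plus exact closed-form oracles for the one-step subnetwork
(binomial master-equation solution; Ornstein–Uhlenbeck transition of the
√-transformed Langevin equation). See the vignette in `vignettes/` for the
methods and design choices.

## Worked example

A weak-stimulus population of 100 cells:

```r
library(minsignet)

p <- network_preset("weak")   # x0 = 5, slow step k_b2 = 1e-6
ens <- simulate_population(p, n_cells = 100, t_max = 2000,
                           record_times = seq(0, 2000, length.out = 1001),
                           master_seed = 1)

ensemble_moments(ens)[c(26, 51, 101, 251), ]
#>     time mean variance  fano fraction_activated
#> 26    50 38.5     2344 60.86               0.38
#> 51   100 67.4     2176 32.26               0.67
#> 101  200 87.2     1116 12.81               0.87
#> 251  500 98.0      192  1.96               0.98

snapshot_distribution(ens, t = 100)
#> <snapshot> t = 100, 100 cells, 20 bins over [0, 100], modality: bimodal

channel_attribution(ens)$pooled
#> [1] 0.0046
```

Reading: halfway through population activation the across-cell Fano factor
of active X3 is ≈ 32 (a Poisson process would give 1) — cells are either
essentially OFF or fully ON, which is why the snapshot at *t* = 100 is
bimodal. Only 0.5% of X3 activation events went through the one-step
deterministic channel: the stochastic cascade owns this regime. With the
`strong` preset (*x₀* = 10⁶) the same calls give a Fano factor below 1, a
single peak traveling upward in time, and attribution ≈ 0.99.

The same runs from the shell:

```sh
Rscript inst/scripts/minsignet.R simulate --preset weak --cells 100 \
    --tmax 2000 --seed 1 --out weak.tsv
Rscript inst/scripts/minsignet.R analyze weak.tsv --at-time 100 --bins 20
Rscript inst/scripts/minsignet.R sweep --kb2 1e-6,1e-4 --x0 0.5,2e6 \
    --cells 40 --tmax 2000 --seed 1 --out phases.tsv
```

Trajectories are tidy TSV (one row per cell per record time, schema
`cell_id time x1 x1a x2 x2a x3 x3a fireA fireB1 fireB2 fireB3 engine`) with
a JSON sidecar holding parameters and the full seed chain, so every run —
and every individual cell — is exactly reproducible.

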