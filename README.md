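# forcemelt

Simulation and analysis of force-induced DNA melting in optical-tweezers
pull–relax experiments.

## What this is for

Short designed DNA duplexes, pulled by their ends at constant trap velocity,
overstretch near 60–70 pN by three distinguishable mechanisms: **peeling**
(melting from a free end, one strand carrying all tension), **internal
melting** (bubbles inside a duplex sealed at both ends, tension shared) and
the **B-to-S transition** (a longer, still base-paired form). In
force-versus-trap-position trajectories these appear as abrupt rips with
hysteretic rezipping, gradual reversible transitions, and bistable hopping
between conformational branches.

`forcemelt` provides, for researchers analysing such trajectories:

* a **kinetic Monte-Carlo simulator** of pull–relax cycles for three
  constructs — a one-end-sealed 64 bp AT-rich duplex (`5AT`), the same duplex
  sealed at both ends (`35AT`), and a 122 bp composite of the AT core plus a
  GC-rich part (`ATGC`) — at high (1 M) and low (5 mM) NaCl, with full
  ground-truth event logs;
* the **analysis pipeline**: rip/zip change-point detection, bistable-hopping
  detection, linear branch fits, reaction-extent computation, hysteresis
  classification, and the equilibrium inference core:

  - two-state fit `phi(F) = 1 / (1 + exp(-delta (F - F_tr)/kBT))` for the
    midpoint force `F_tr` and cooperative length `delta`;
  - three-state Boltzmann population fit (`w_i = exp(-(G_i - F x_i)/kBT)`)
    with the derived crossing forces `F_tr^I = G_I/x_I`,
    `F_tr^II = (G_S - G_I)/(x_S - x_I)` and the intermediate-population
    maximum `F_tr`;
  - Bell–Evans kinetics: `k(F) = k0 exp(F x/kBT)`, the Evans–Ritchie mean
    rupture force `(kBT/x) e^a E1(a)` with `a = k0 kBT/(r x)`, and its
    inversion for calibrating `k0` from a target mean force;

* **reporting**: per-bp extensions at printed precision, cooperative length
  in bp, per-construct summaries and force histograms, and a plain-text TSV
  trajectory format.

## Worked example

Simulate five pull–relax cycles of the one-end-sealed peeling construct at
1 M NaCl and analyse them:

```r
library(forcemelt)

spec <- construct_spec("5AT", "1M")
mol  <- simulate_molecule(spec, n_cycles = 5, seed = 42)
peel <- analyze_peeling(mol)
round(peel[, c("cycle", "melt_force_pN", "rezip_force_pN", "extension_nm")], 2)
#>   cycle melt_force_pN rezip_force_pN extension_nm
#> 1     1         61.14          21.28        15.16
#> 2     2         59.90          21.34        15.00
#> 3     3         61.33          22.43        14.70
#> 4     4         63.20          23.49        14.90
#> 5     5         62.26          23.46        14.74
```

Each cycle shows one melting rip near 61.5 pN, a hysteretic rezip near
22 pN, and a branch separation at the melt of ~14.7 nm (0.230 nm/bp over
64 bp) — the calibrated study conditions. The gradual internal melting of
the double-sealed construct is analysed with the two-state equilibrium fit:

```r
spec35 <- construct_spec("35AT", "1M")
mol35  <- simulate_molecule(spec35, n_cycles = 5, seed = 1)
res <- analyze_internal_melting(mol35, spec35)
res$fit
#> <two_state_fit> F_tr = 67.78 +/- 0.00 pN, delta = 2.91 +/- 0.01 nm
cooperative_length_bp(res$fit$delta)
#> [1] 18
res$verdicts
#> [1] "REVERSIBLE" "REVERSIBLE" "HYSTERETIC" "REVERSIBLE" "HYSTERETIC"
```

The fitted midpoint recovers the configured 67.8 pN; the cooperative length
(configured 2.6 nm, 16 bp) comes back a little high because the method
describes curved worm-like-chain branches with straight lines — see the
methods vignette (`vignettes/force-melting.Rmd`) for the estimator and its
known biases. Some relax phases follow the hysteretic rezip pathway; their
fraction is a binomial draw at 34/155 per relax curve.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/forcemelt.R", package="forcemelt"))')" \
  simulate --construct 5AT --salt 1M --cycles 2 --seed 1 --out traj%d.tsv
```

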