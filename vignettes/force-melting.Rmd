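---
title: "Simulating and analysing force-induced DNA melting in pull-relax experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing force-induced DNA melting in pull-relax experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcemelt)
```

## The experiment this package emulates and analyses

When torsionally unconstrained double-stranded DNA is pulled by its ends it
overstretches near 60--70 pN, lengthening by up to ~70 % without full strand
dissociation. Three mechanisms can contribute: *peeling* (melting that starts
at a free duplex end, leaving one strand under the full tension and the other
relaxed), *internal melting* (bubbles nucleated inside the duplex, tension
shared by both strands) and the *B-to-S transition* (a longer, still
base-paired form). Short designed duplexes with covalent inter-strand seals
at one or both ends isolate these mechanisms:

* **5'AT** -- 64 bp AT-rich duplex, one end sealed. Peels abruptly on pull
  (~61.5 pN in 1 M NaCl, ~43.6 pN in 5 mM NaCl) and rezips hysteretically on
  relax (~21.7 / ~17.3 pN), with a reversible, bistable partial-peel
  intermediate riding on the B-form branch just below the rip.
* **3'5'AT** -- the same duplex sealed at both ends. At 1 M NaCl it melts
  *internally*: a gradual, non-cooperative transition over 60--70 pN with no
  rips, usually reversible, but ~22 % of relax curves (34 of 155) instead
  return to the B-form in one abrupt, hysteretic step. At 5 mM NaCl it melts
  and rezips in single abrupt steps (~61.0 / ~41.1 pN).
* **ATGC** -- a 122 bp composite: the 60 bp AT core next to a 62 bp GC-rich
  part. At 1 M NaCl, reversible AT peeling (population crossing near
  62.1 pN) is followed by a reversible, bistable B-to-S transition of the GC
  part; the three-state analysis puts the intermediate-population maximum at
  64.3 pN. At 5 mM NaCl the AT step splits in two (~45 and ~49 pN), the
  B-to-S step stays near 59 pN, and an irreversible full melt with ~20 pN
  rezipping appears above it.

The instrument moves an optical trap at 50 nm/s; force versus trap position
is recorded at 1 kHz; with a trap stiffness of 0.156 pN/nm the loading rate
is ~7.8 pN/s. Because only the trap position is controlled, every
lengthening of the construct appears as a *drop* in force (the bead relaxes
toward the trap centre) and every shortening as a rise. Relative extensions
are measured as the difference in trap position between two conformational
branches at a fixed force.

No raw trajectories are publicly available for these experiments, so the
package pairs the analysis pipeline with a simulator whose ground truth makes
every analysis stage testable. The simulator's default parameters *are* the
study conditions above; they are read from plain-text configuration files
under `inst/extdata/configs/`.

## Polymer models and calibration

Each conformational state is a series of worm-like chains (WLC): B-form DNA
(persistence length 50 nm, rise 0.34 nm/bp, stretch modulus 1200 pN),
single strands (persistence length 0.75 nm, stretch modulus 800 pN -- at
these forces effectively a freely-jointed chain), the S-form (persistence
length 15 nm, stretch modulus 1500 pN) and a single effective single-stranded
handle (contour 120 nm; real handle lengths are unknown, so this is a
configurable choice). The extensible Marko--Siggia interpolation is inverted
by a vectorized Newton iteration on its cubic form; `solve_force()` closes
the construct--trap series `F = k (x_trap - x_construct(F))`.

Only *relative* extensions are reported for the real experiments, so
absolute single-strand contour lengths are **calibrated** rather than taken
from literature: at load time the single-stranded (or molten, or S-form)
contour per unit is solved so that the state-to-state branch separation
equals the reported value at the reported force -- 14.7 nm at 61.5 pN for
the 5'AT peel, 10.6 nm at 67.8 pN for the 3'5'AT midpoint, and 24.7 nm total
at 64.3 pN for ATGC. One consequence of using a single short-persistence
law per state: the 5'AT rezip contraction implied by the calibrated model is
~10 nm at 21.7 pN, smaller than the reported 13.4 nm -- a single WLC cannot
reproduce both printed numbers, and the calibration constraint at the melt
takes precedence. The ATGC intermediate is a composite ("split") state; its
branch carries an extra linear compliance of 4.8 nm spread between the two
crossing forces, which reproduces the reported smaller force-position
gradient of that branch.

## Kinetics

Abrupt transitions are Bell processes, `k(F) = k0 exp(F x / kBT)` with a
signed transition distance. Neither rates nor transition distances are
reported, so both are derived from printed numbers:

* the transition distance comes from the printed rupture-force standard
  deviation through the asymptotic Gumbel width of the Evans--Ritchie
  distribution, `x = (pi/sqrt(6)) kBT / sd`;
* `k0` comes from inverting the Evans--Ritchie mean rupture force
  `(kBT/x) e^a E1(a)`, `a = k0 kBT/(r x)`, at the nominal 7.8 pN/s ramp
  (`calibrate_k0()`), or the falling-ramp analogue for rezipping
  (`calibrate_rezip_k0()`).

For the peeling scheme the rupture hazard acts from whichever state the
molecule occupies, and the intermediate branch carries a slightly lower
force at the same trap position; with default kinetics the simulator
therefore refines `k0` against the full state machine, integrating the
two-state master equation for the intermediate occupancy along the actual
trap path, so that the mean rupture force of the simulated process matches
the configured target.

Bistable hopping (the 5'AT partial-peel intermediate and both ATGC ladders)
is sampled by Gillespie steps within each 1-ms sampling interval, with
detailed-balance rates
`k_up/k_down = exp((F - F_mid) dx / kBT)` around the configured midpoint.
The hopping loops run only inside the force window where the minority
population exceeds ~1e-3; outside it the dominant state is deterministic,
which bounds the rates without affecting the statistics. The 5'AT hopping
parameters (midpoint 60.5 pN, 4 nm extension, attempt rate 20 /s) are
order-of-magnitude choices -- the experiments show the intermediate exists,
hops reversibly at 1 kHz and rides on the B-form branch, but do not quantify
its kinetics.

The gradual internal melting of 3'5'AT at high salt is non-cooperative over
many base pairs, so its molten fraction is the deterministic equilibrium
value `phi(F) = 1/(1 + exp(-delta (F - F_tr)/kBT))` (cooperative length
`delta` = 2.6 nm, midpoint 67.8 pN); per-sample fluctuations of `phi` are
negligible at this bandwidth and the measurement noise dominates. The
hysteretic relax pathway is drawn per relax phase with probability 34/155;
its abrupt rezip force is not reported and defaults to 45 pN (below the
transition region, above the low-salt value). Salt enters only through the
parameter sets -- the experiments provide no electrostatic model.

Measurement noise is additive Gaussian on the force channel,
sigma = 0.3 pN at 1 kHz; this is not a reported number but is chosen so that
rips of >= 2 pN stand at more than 5 sigma. kBT is computed from the
temperature (4.086 pN nm at 22.8 °C).

## Detection conventions

`detect_rips()` compares leading and trailing window medians (default window
30 ms) after removing the loading ramp. Two robustness choices matter on
this kind of data: the local ramp slope is estimated from successive window
medians and clipped to a band around the phase-wide robust slope (a jump or
telegraph hopping would otherwise corrupt an ordinary trailing fit), and the
event force is the median of the trailing samples on the pre-event side of
the jump, projected along the ramp -- robust both to a few samples of
localization error and to hopping earlier in the window. The default
threshold of 1.5 pN is 5 sigma; the pipeline lowers it to 1.0 pN on pull
phases (the melt rip from the partially peeled intermediate is ~1.5 pN) and
0.8 pN on relax phases, which carry no hopping and where the jump statistic
averages the noise down by an order of magnitude.

`detect_hopping()` assigns samples to the nearer branch by position residual
after lightly smoothing the force (7 samples; dwells are much longer),
debounces single-sample flips, and reports alternation segments and dwell
counts. Branches closer than three (post-smoothing) sigma are declared
undetectable. `classify_hysteresis()` interpolates lightly smoothed pull and
relax curves on a common trap-position grid (clipping 3 % at each end, where
the phases share few samples) and calls a cycle hysteretic when the maximum
force gap exceeds 0.8 pN -- simulated hysteretic cycles sit near 1.6--2.3 pN
and reversible ones below ~0.6 pN.

## Equilibrium fits

`fit_branches()`/`branch_fit()` are ordinary least squares of force on trap
position over force windows, as in the standard analysis. Samples are
*selected* by a lightly smoothed force: selecting on the raw noisy force
truncates the response inside narrow windows and visibly attenuates the
fitted slope. `reaction_extent()` evaluates
`phi = (x - x_low(F)) / (x_high(F) - x_low(F))`, clamped to [0, 1], against
the smoothed force for both the branch positions and the abscissa -- the raw
noise enters the numerator and the force coordinate with correlated sign and
would flatten the fitted transition.

`analyze_internal_melting()` adds a self-consistent refinement: WLC branches
are curved, so straight lines fitted far from the midpoint misplace the
branch positions there (the single-stranded handle dominates this
curvature). After an initial fit, the fitted molten fraction is subtracted
from each sample to linearize the two branches, which are then refit on
windows adjacent to the midpoint and the extent recomputed. Two iterations
reduce the bias of the cooperative length from ~+0.4 nm to ~+0.2 nm under
the default conditions and leave the midpoint force essentially unbiased;
the residual bias is inherent to describing curved branches with the
method's straight lines. For the same reason the measured midpoint
extension comes out near 9.3 nm rather than the calibrated 10.6 nm -- the
branch-separation estimate at the midpoint inherits the line-vs-curve error.

The two-state form (logistic in force with slope `delta/kBT`) is an
assumption: it is the standard equilibrium two-state force law and
reproduces the consistency between `delta` = 2.6 nm and the observed
60--70 pN transition width (`F(0.95) - F(0.05) = 2 ln(19) kBT/delta`,
about 9.3 pN). The cooperative length converts to base pairs with the
measured midpoint extension per bp, 0.166 nm/bp, giving 16 bp.

The three-state fit models the populations as Boltzmann weights with
force-linear exponents, `w_i = exp(-(G_i - F x_i)/kBT)`, `G_B = 0`,
`x_B = 0` (compliance differences are absorbed by the branch fits).
Populations are computed in 0.5 pN bins (bins with fewer than 5 samples are
dropped) and the fit is weighted by per-bin binomial variance. Derived
forces: `F_tr^I = G_I/x_I` (B/intermediate crossing),
`F_tr^II = (G_S - G_I)/(x_S - x_I)` (intermediate/stretched crossing) and
`F_tr = (G_S + kBT log(x_I/(x_S - x_I)))/x_S` (intermediate-population
maximum); the numerically located crossings must and do agree with these
closed forms. The configured `F_tr^II` (65.92 pN) is itself derived: it is
the value at which the intermediate-population maximum of the model falls at
the reported 64.3 pN given `F_tr^I` = 62.1 pN, `x_I` = 8.0 nm and
`x_S - x_I` = 11.9 nm. State assignment breaks ties toward the
lower-extension state. Because a state change shifts the measured force by
`~k dx` at fixed trap position (1--2 pN, comparable to the population
widths), the population curves in *measured* force are broadened and the
recovered transition distances are smaller than the configured ones; the
crossing forces and their ordering are much less affected, which is what the
analysis reports.

## What the simulator does and does not emulate

It reproduces: the force-trap-position geometry of the series (so rips drop
and zips raise the force by stiffness times the extension change), abrupt
Bell ruptures with Evans--Ritchie statistics at the calibrated means and
dispersions, hysteretic rezipping, bistable hopping attached to the correct
branches, gradual non-cooperative melting, mixed reversible/hysteretic relax
populations, and white Gaussian force noise.

It does not emulate: baseline drift or 1/f noise, bead-size or stiffness
calibration errors, tether misalignment, sequence-level (nearest-neighbour)
energetics, secondary structure in peeled strands, glyoxal chemistry, or
laser heating. Passing tests therefore show that the analysis recovers known
ground truth under idealized stationary noise -- not that it is robust to
instrumental drift in real recordings.

## Problem sizes and reproducibility

The test suite and the acceptance script run reduced but statistically
meaningful ensembles, chosen so the whole suite completes in a couple of
minutes: 31 molecules x 5 cycles for the internal-melting recovery, 50
cycles for peeling, 1000 relax curves for the pathway fraction, and 6--8
cycle ensembles for the composite construct. Every simulation is
deterministic under its seed (identical seeds give bit-identical
trajectories), and the full pipeline
simulate -> detect -> fit -> aggregate writes byte-identical tables across
runs.

## Known limitations

* The analysis reproduces the *method* of the original experiments on
  synthetic data; the experimental means themselves enter only as
  calibration targets.
* A single calibrated single-strand elasticity cannot reproduce both the
  printed peel extension at high force and the printed rezip contraction at
  low force (see above); the simulator is calibrated at the melt.
* The straight-line branch convention biases midpoint branch separations by
  the local curvature of the WLC branches; the iterative linearization
  reduces but does not remove this (cooperative length recovers ~10 % high,
  midpoint extension ~10 % low under default conditions).
* Hopping kinetics (attempt rates, intermediate size) are order-of-magnitude
  choices; only their phenomenology is constrained by the experiments.
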