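---
title: "Modelling monolayer growth and radiotherapy–hyperthermia response with thermorad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling monolayer growth and radiotherapy–hyperthermia response with thermorad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorad)
```

## The model

`thermorad` simulates an adherent cell monolayer as a hybrid cellular
automaton: a circular two-dimensional lattice in which each voxel holds at
most one cell, coupled to closed-form clonogenic-survival models that decide
each cell's fate when a treatment fraction is delivered. It is designed for
in vitro questions — growth curves in well plates, single and fractionated
radiation (RT), hyperthermia (HT) and combined RT+HT courses — where the
population is large (10^5–10^7 cells) but the biology per cell can be kept
deliberately simple.

### Growth engine

Every cell owns a cycle clock and an individual cycle duration drawn from a
normal distribution around the population doubling time (default 19.5 h, the
calibrated HCT116 value) with a 5% standard deviation, truncated at three
SDs. The clock maps onto the four cycle stages by fixed fractions of the
duration — by default 40% G1, 35% S, 20% G2 and 5% M, in that order, with
half-open `[start, end)` stage intervals. G2 and M carry the standard
flow-cytometry split of the 25% G2/M pool; the G1/S split is the prominent
remaining degree of freedom and is exposed in `cycle_config()`.

When the clock reaches the duration the cell attempts to divide: its
neighbourhood is scanned for empty in-well voxels out to third-order
neighbours, the nearest non-empty shell is selected, and a voxel of that
shell is chosen uniformly at random for the daughter. Moore (Chebyshev) and
Von Neumann (Manhattan) neighbourhoods alternate per cell between successive
division attempts; this alternation compensates the anisotropy of either
neighbourhood alone and produces near-circular colonies (a property test
grows one founder to several thousand cells and checks the colony's aspect
ratio stays within 10% of unity). Both parent and daughter restart in G1
with clock zero; the daughter draws a fresh duration.

A cell with no free voxel up to third order enters G0, a reversible
quiescent state with a frozen clock; quiescent cells re-check for space every
step and divide as soon as a neighbour is vacated. This contact inhibition
alone produces the growth-curve plateau: for an untreated run the plateau
count equals the number of in-well voxels exactly, which is why the voxel
edge length (9.6 um for 24-well plates, 12 um for 6-well plates, giving
1625- and 2900-voxel grid diameters) is a calibration target of the plateau
rather than a free parameter.

Freshly seeded populations pass through a 2 h attachment lag during which
clocks are frozen but treatment can still kill. The lag models the
seeding-to-attachment delay of real cultures, so it is applied to the first
two simulated hours of a run and not to daughters born later.

### Survival models

Radiation survival uses the AlphaR family: below a threshold dose `D_T` the
linear-quadratic (LQ) arm

$$S(d) = \exp(-(\alpha_0-\alpha_R)\,d - \beta d^2),$$

and above it a single exponential, on the reading that `D_T` is the dose
beyond which repair is exhausted. With the derived threshold
`D_T = alphaR / beta` the repair term `(alphaR - beta d) d` vanishes exactly
at `D_T`, so the post-threshold arm is `exp(-alpha0 d)` and the curve is
continuous with no extra constant. When a threshold is supplied explicitly
in configuration, continuity is instead preserved by anchoring the
exponential at `S(D_T)`. For HCT116 radiation only the LQ arm is needed
(`alpha = 0.5` Gy^-1, `beta = 0.042` Gy^-2), which reproduces the printed
surviving fractions 0.31, 0.15 and 0.03 at 2, 3 and 5 Gy.

Heat exposures are reduced to a CEM43 thermal dose (cumulative equivalent
minutes at 43°C) with the standard two-case Sapareto–Dewey constants,
`R = 0.5` at or above 43°C and `R = 0.25` between 40 and 43°C; steps at or
below 40°C are inert. These constants reproduce the 5 min @ 46°C ↔ 40 CEM43
equivalence of the experimental heat treatment. HT survival evaluates the
AlphaR model in CEM43 units with `alpha0 = alphaR`, giving the
characteristic shoulder `exp(-beta t43^2)` followed by a single-exponential
tail.

Combined treatment multiplies heat-only survival by a sensitized LQ
radiation factor whose alpha grows linearly with thermal dose:

$$S_{RTHT}(d, t_{43}) = S_{HT}(t_{43})\,
  \exp(-(\alpha_{RT} + a\,t_{43})\,d - \beta_{RT} d^2).$$

With a non-negative slope `a` this never exceeds either single-modality
survival, which is asserted as a property test.

### Cycle-phase radiosensitivity

Radiation sensitivity differs between stages. Phase-specific survival is a
power of the population survival, `S_phase = S^gamma_phase`, with the gamma
map fixed by two conditions at the delivered dose: consecutive phase
survivals stand in a constant ratio of 1.5 in the resistance order
S > G1 > G2 > M, and the phase-fraction-weighted mean of the phase survivals
equals the unweighted survival. Because the second condition is linear in
the common scale of the phase survivals, the map has a closed form
(`phase_sensitivity()`); the solved map satisfies both conditions to below
1e-10 and orders the exponents `gamma_M > gamma_G2 > gamma_G1 > gamma_S`.
Quiescent cells default to the G1 exponent — their distinct sensitivity is
not established — and every gamma can be overridden in configuration.
Reported gamma ranges of roughly 0.85–1.39 for this rule are treated as a
regression reference only, since they depend on the reference dose and
population composition at solve time.

### Treatment decision tree and delayed death

At a fraction, every cell draws `N ~ Uniform(0,1)` once:

* heat only: `N > S_HT` removes the cell at once (heat kill is modelled as
  instantaneous, with no further cycle delay for survivors);
* radiation only: `N > S_RT` (phase-weighted) marks the cell *doomed* with
  an absolute death time `now + Exp(k_delay)`;
* combined: `N > S_HT` removes at once; `S_HT ≥ N > S_RTHT` dooms the cell
  as for radiation.

Doomed cells continue cycling and dividing; every descendant inherits the
ancestor's absolute death time, and the whole lineage is removed as each
cell's time elapses. At each M exit a doomed cell may instead undergo
mitotic catastrophe (probability `p_mitoticCat`), becoming senescent with
probability `p_senescence` — permanently viable, never divides, never dies
in-simulation — or otherwise a giant cell, which stops producing daughters,
increments a size counter at each further attempted division (it occupies a
single voxel throughout, keeping the occupancy bookkeeping bijective), and
dies at its scheduled time. The calibrated HCT116 values are
`k_delay = 0.009` h^-1 (mean delay ≈ 111 h), `p_mitoticCat = 0.2` and
`p_senescence = 0.05`.

Delayed death is the feature that separates this model from
instantaneous-kill automata: immediately after a fraction the population is
numerically unchanged, and the census only gradually approaches the
clonogenic prediction while doomed lineages keep occupying — and competing
for — space. `mode = "instantaneous"` removes failed cells at the moment of
treatment instead, and a paired-seed test confirms the delayed-kill curve
dominates the instantaneous-kill curve pointwise.

Two ambiguities were resolved as package policy. The catastrophe draw
happens exactly when the clock crosses the cycle duration (the canonical
"end of M"), not at the every-step space re-checks of crowded quiescent
doomed cells, which would otherwise multiply the number of draws by the
step rate. A doomed cell struck by a later fraction keeps the earlier of
its old and newly drawn death times (`refraction = "earliest"`), so
re-irradiation can only accelerate a lineage's death; `"ignore"` is
available for sensitivity checks.

## Numerical and implementation choices

* **Time step.** `dt = 0.5 h` by default, chosen to resolve the ~1 h
  M-phase; a convergence test halves it and requires growth to change by
  less than 10%.
* **Update order.** Cells are processed in a fresh seeded random
  permutation each step, so no lattice region systematically divides first.
  Daughters born within a step are not processed until the next step.
* **Determinism.** All randomness — seeding positions, clocks and
  durations, permutations, daughter placement, survival draws, death
  delays, catastrophe draws — flows through R's RNG, so `(configuration,
  seed)` reproduces a run bit for bit, including through the compiled core.
* **Compiled core.** The per-step loop (clock advance, division-space
  search, G0 bookkeeping, scheduled deaths) is C++ via Rcpp; a 1625-voxel
  grid with ~6×10^5 cells advances through 96 simulated hours in a couple
  of seconds. The R-level lattice functions are the reference
  implementation, and a dual-route test checks the compiled neighbourhood
  enumeration against them on random occupancy patterns.
* **Edge cases.** `S = 0` with any positive gamma yields zero survival;
  fractions with `S = 1` consume no randomness (so degenerate
  confidence-bound envelopes coincide exactly with untreated runs); the
  circular mask uses the voxel-centre convention, making in-well voxel
  counts reproducible from the diameter alone.

## Calibration

`fit_death_dynamics()` fits the two parameters that cannot be measured
directly, `k_delay` and `p_mitoticCat`, by maximizing the coefficient of
determination R² between a simulated ensemble-mean growth curve
(interpolated at the reference times) and a reference curve, over an
exhaustive grid, holding `p_senescence` fixed at 5%. A grid search is used
deliberately: the objective is a noisy stochastic-simulation output, and
with shared seeds across grid points the surface is smooth, deterministic
and inspectable (`$surface`). A flat surface — e.g. an untreated reference,
where the parameters are inert — is flagged rather than silently argmaxed.

`make_reference_fixture()` generates synthetic reference curves: an
ensemble mean sampled at experiment-like times (every 12–24 h from 24 h)
with multiplicative Gaussian noise, standing in for haemocytometer counts.
It emulates count-scale noise and replicate SDs, but not systematic
experimental effects — attachment-lag variability between treatments,
medium-renewal effects on the plateau, counting bias at low density — so
parameter-recovery tests demonstrate identifiability of the fitting
procedure, not accuracy against a wet laboratory.

## Problem sizes used in the tests

The package's own suite runs at desk scale, as its choice of problem size:
the doubling-time check uses the full 1625-voxel 24-well grid with 2.3×10^4
founders and 10 replicates to 96 h; structural property checks (plateau,
dominance, branch frequencies, conservation) use 41–121-voxel grids with
10^2–10^4 cells; calibration recovery uses a 101-voxel grid, 1500 founders,
a 5×4 parameter grid and 3 replicates per point. Ensembles elsewhere use
2–10 replicates where a production study would use hundreds; standard
deviations reported from such small ensembles are indicative only.

## Known limitations

* Two-dimensional monolayers only: no spheroid/3-D growth, and no nutrient
  or oxygen transport — the plateau is purely space-limited, so plateau
  densities that depend on medium renewal must be absorbed into the voxel
  size.
* No kinetics of sublethal-damage repair between fractions and no decay of
  heat-induced radiosensitization with the RT–HT interval; combined
  fractions are simultaneous events. Schedules with deliberate RT–HT gaps
  of hours are outside the model's validated scope.
* No dose-rate effects; a fraction is an instant.
* Giant cells occupy one voxel regardless of their size counter, so giant
  morphology affects reporting, not geometry.
* Survival parameters are inputs (from clonogenic assays), not fitted by
  this package; only the delayed-death parameters are calibrated here.

## A minimal example

```{r example, eval = FALSE}
library(thermorad)

rt <- alphar_params(alpha = 0.5, beta = 0.042)
cfg <- experiment_config(
  plate = "24-well", n0 = 2.4e4,
  schedule = treatment_schedule(24, dose_Gy = 2),
  rt_params = rt, t_end = 168)

ens <- run_ensemble(cfg, n_replicates = 5, seed = 1)
env <- envelope_runs(cfg, survival_ci = c(0.25, 0.37),
                     n_replicates = 5, seed = 1)
tail(ens[, c("time", "total_mean", "total_sd", "viable_mean")])
```
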