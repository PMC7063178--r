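---
title: "Methods: the ER-stress / insulin-signalling model and its controllers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ER-stress / insulin-signalling model and its controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`erins` represents the integrated unfolded-protein-response (UPR) and
insulin-signalling network of the liver as a deterministic, well-mixed,
single-compartment ODE system in arbitrary units (AU). The network is
declarative: a JSON document lists 32 species, their per-species rate
terms, the parameter set and the readout definitions, and the package
compiles it into a right-hand side. Nothing about the biology is
hard-coded; the bundled roster can be replaced file-for-file.

Every derivative is a sum of terms drawn from a three-shape grammar:

* **input drive** `+k·u`: an external input feeding a species. The
  unfolded-protein load obeys `dx1/dt = k1·u1 − k2·x1·x2`, with `x2` the
  chaperone (BiP) pool;
* **modulated activation** `+k·Πx_f·Π(1+F·x_a)`: mass action in the factor
  species with optional `(1+F·x)` accelerators;
* **modulated decay** `−k·x_d·Πx_f / Π(1+F·x_j)`: first-order consumption,
  optionally co-driven by extra factors (the "mixed decay" used by the load
  equation) and slowed by feedback divisors, as in the insulin receptor
  equation `dx26/dt = k53·u2 − k52·x26/((1+F3·x30)(1+F4·x32))` where the
  receptor's turnover is slowed by downstream pAKT (`x30`) and pFoxO1
  (`x32`).

Phosphoprotein pairs (PERK/pPERK, eIF2α/peIF2α, IRE1α/pIRE1α, JNK, IKKβ,
NF-κB, AKT, FoxO1) are modelled as interconverting pools, so each pair
conserves its total and the phospho/total ratio has a closed steady form:
`r = (k_basal + k_drive·d)/(k_basal + k_drive·d + k_dephos)` for drive
strength `d`. Mass is *not* conserved globally — synthesis and decay terms
create and destroy material, as the term grammar allows.

### The reconstructed roster

The complete published equation list for this network is not available
(only three example equations and the pathway diagram are), so the shipped
roster is a documented reconstruction: stress load → the three UPR sensor
branches; pIRE1α → TRAF2-ASK1 → JNK/IKKβ → (IκBα, NF-κB, IRS serine
phosphorylation); insulin → IR → IRpY → IRSpY → PI3K → PIP3 → AKT → FoxO1;
a PERK-arm brake on AKT activation (the TRB3-like route); ATF6 cleavage
inducing chaperone synthesis. Edge-level choices that were genuinely open
are listed under *Design choices* below.

## External inputs

The two drives are derived from equilibrium: `u1 = amplify1·k2·x1·x2/k1`
and `u2 = amplify2·(k52/((1+F3·x30)(1+F4·x32)))·x26/k53`. With
amplification 1 these nullify the driven species' derivative exactly (a
property the test suite checks to round-off on random states). The DIO
scenario re-derives `u1` continuously with `amplify1 = 1.3 > 1`, which
produces exponential growth of the load until it saturates at its upper
bound — the sustained stressed state. The NCD control sets `u1 = 0`.

`u2` is computed once at the initial state and **frozen** (`amplify2 = 1`):
a constant insulin drive. The schedule was left open by the design
contract; the frozen choice is deliberate, because continuous re-derivation
makes the receptor derivative identically zero (or uniformly exponential),
erasing the DIO-vs-NCD contrast in IRpY/IRSpY that the qualitative pattern
table requires strictly. With a frozen drive the receptor feels the
pAKT/pFoxO1 feedback, and stress lowers IRpY/IRSpY as observed.

## Time axis and solver

The canonical time axis is [0, 70000] AU — one AU per reported solver
iteration — with a 1401-point output grid (50 AU spacing), which makes the
published "near time 6000 AU" flux statement addressable. Rate constants
were calibrated on this axis and all lie inside the admissible sampling
interval [0, 5].

The integrator is an adaptive TR-BDF2 composite (trapezoidal stage to
`t+γh`, BDF2 stage to `t+h`, `γ = 2−√2`) — the same family as `ode23tb` —
with modified Newton iterations on a finite-difference Jacobian, an
embedded third-order error estimate smoothed through the stage-2 iteration
matrix, and L-stability appropriate for the ~10³ stiffness ratio between
the fast sensor pools and the slow load dynamics. Defaults:
`rel_tol = 1e-5`, `abs_tol = 1e-7`; halving both changes steady readouts by
well under 1% (tested). A pure-R twin of the C++ stepper ships in the
package and the two are cross-checked. State bounds ([0, 25] AU default,
per-species configurable) are applied by projection at every accepted step;
this is a projection, not a reflecting boundary, and is documented as such.

## Controllers

The controllers are discrete PID laws with zero-order hold, sampled at the
output-grid spacing. The error is signed (`r − o`) by default: the printed
absolute-value form cannot steer a readout downward, so it is retained only
as an option (`error_mode = "absolute"`) and is documented as
directionless. The derivative acts on the measurement (not the error) to
avoid reference kick; negative `kd` is honoured as printed. Outputs are
clamped (floored at 0 — a negative stress or insulin drive has no physical
meaning) with conditional-integration anti-windup.

Loop 1 (`ki = 0.0691`) senses pPERK/PERK and actuates `u1`; its integral is
preloaded with the open-loop DIO steady drive, so a thought experiment
starts from the drive level of the stressed system and the initial
unfolded-protein flux is nonzero (the Case I (iv) "flux falls to ~0 by
~6000 AU" statement needs that baseline). Loop 2
(`kp = 0.2134, ki = 0.10329, kd = −0.1082`) senses the case marker and
actuates `u2`, preloaded with the frozen open-loop insulin drive. With the
50-AU hold, discrete-loop stability requires `ki·Δt·G ≲ 2` for plant DC
gain `G`; the insulin-chain gains in the calibrated configuration keep
`G ≈ 0.3` at their largest (the low-stress conditions), which is why the
receptor drive constant `k53` is small relative to `k52`.

## Scenario battery, references and thresholds

The battery holds 14 scenarios: NCD, DIO, and 3 cases × 4 conditions, case
I/II/III pairing the pPERK loop with IRpY/IRSpY/pAkt-ratio respectively,
each at (high, low) × (high, low) references. Reference values are
calibration outputs stored explicitly in the battery file: the pPERK
references are the two printed ratio plateaus (0.8 high, 0.5 low — the low
reference sits just beneath the de-stressed plateau 0.505, so the loop
winds its drive down to zero and the flux collapses); the IRpY/IRSpY
references are the 25%/75% points of the open-loop NCD–DIO span; the
pAkt-ratio references are the printed steady values 1.7/4.7 (which are,
as the design contract anticipated, close to the 25%/75% points of the
calibrated span). Low/high verdicts compare steady values against the
NCD/DIO midpoint per readout. "Steady value" is operationally the mean of
the final 10% of the output grid, with the tail spread reported as a
settledness diagnostic.

The expected verdict table encodes: conditions (i)/(ii) — high ER stress,
high UPR ratios, low insulin sensitivity in cases I and II (high pPERK
blocks the insulin arm regardless of IRpY/IRSpY) but *high* sensitivity in
case III (ii), where pAKT itself is forced; condition (iii) — low stress,
low ratios, high sensitivity; condition (iv) — low stress, low ratios, and
insulin sensitivity classified low. The (iv) classification is the one
judgement call: the narrative calls sensitivity "increasing slowly" there,
and in case III prints 1.7 — below the calibrated NCD/DIO midpoint — so
steady-state classification labels all three (iv) conditions low, while
the improving trend relative to the (i)/(ii) conditions is asserted by the
monotonicity property test (lowering the pPERK reference never lowers the
steady sensitivity, in any pairing).

## Calibration

The published tuning was explicitly ad hoc. The package's reproducible
stand-in, `calibrate()`, scores a parameterization by the number of
satisfied constraints (12 pattern orderings + 36 verdict fields + 5
quantitative anchors) minus a small squared-relative-error tiebreak on the
anchors, evaluates the incumbent roster values first, and otherwise runs
seeded uniform sampling over [0, 5] with greedy ±10% coordinate
perturbation. Because the shipped configuration satisfies every
constraint, regeneration from the shipped seed accepts the incumbent at
trial 0 and is bit-identical — that is by construction, and the search
path itself is exercised in tests from deliberately broken starting
points. The anchors are the printed calibration targets: steady pAkt/Akt
1.7 and 4.7, UPR plateaus ≈0.8 and ≈0.5, flux below 1% of its initial
value from ≈6000 AU on (±15%).

## Synthetic densitometry data

`generate_synthetic_blots()` is the stand-in for the study's replicate
western-blot/qPCR measurements: for each encoded contrast it separates
condition means by a fold-change (default 2; the real effect sizes are
figure-only and never asserted), draws n = 4 positive replicates per
condition with mean-corrected lognormal noise (σ = 0.2 default — typical
densitometry-scale variability), and is fully seeded. It emulates the
replicate structure, positivity and orderings of the published panels; it
does **not** emulate band saturation, loading-control normalization
artifacts, inter-blot batch effects, or any absolute scale. A green
round-trip test (generated replicates satisfy their generating table at
σ ≤ 0.1 across seeds) therefore establishes self-consistency of the
generator and checker, not agreement with laboratory data.

## Numerical and design choices

* **Ultrasensitive edges.** Several reconstructed edges use third-order
  (cubic) kinetics in their driver: peIF2α activation by pPERK, the
  TRAF2→JNK/IKKβ and IKKβ→NF-κB activations, JNK-driven deactivation of
  IRpY/IRSpY, the PERK-arm brake on pAKT, and FoxO1 phosphorylation by
  pAKT. The anchors demand an odds swing of roughly 4× (ratio 0.5 → 0.8)
  downstream of drivers that themselves swing only ~1.6×; with nonnegative
  constants a first-order edge cannot produce that, whereas switch-like
  multi-site phosphorylation (standard in kinase-cascade modelling) can.
* **Insulin-sensitivity scale.** The sensitivity readout is the blot-style
  raw ratio pAKT/AKT (phospho over unphosphorylated band), which can
  exceed 1 and matches the printed steady values 1.7/4.7; the bounded
  phospho/(phospho+unphospho) primitive is used for the three UPR ratios
  and is available as `pAkt_total_ratio`.
* **Ratio guards.** Ratio readouts guard zero denominators with a
  configurable epsilon (default 1e-9) and a logged warning.
* **Degenerate inputs.** A zero drive constant makes the steady-state
  derivation undefined and is rejected as an invalid parameterization;
  zero-rate models integrate to constant trajectories and fail every
  strict pattern, by design.
* **Determinism.** The battery is deterministic; randomness exists only in
  the synthetic-data generator and the calibration search, both seeded,
  and both restore the caller's RNG state.

## Known limitations

* The roster is a reconstruction; parameter values are calibration
  outputs satisfying the qualitative table and the printed anchors, with
  no claim of identifiability or uniqueness.
* The ceramide/lipotoxicity arm and any spatial or stochastic effects are
  out of scope; the model is single-compartment and deterministic.
* Bound handling by projection can in principle shadow mass that an
  event-based treatment would preserve; at the shipped parameterization
  only the stressed load saturates its bound.
* The discrete controllers approximate a continuous (block-diagram) loop
  by zero-order hold at the grid spacing; gains are taken as printed, not
  re-tuned, so loop stability is a property of the calibrated plant gains.
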