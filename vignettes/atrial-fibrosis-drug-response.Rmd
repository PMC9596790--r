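---
title: "Simulating fibrosis and antiarrhythmic drug effects on atrial conduction"
author: "atriasim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fibrosis and antiarrhythmic drug effects on atrial conduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriasim)
```

## The problem

Diffuse atrial fibrosis replaces part of the working myocardium with
non-excitable fibroblasts. Fibroblasts do not fire action potentials, but
they are electrically coupled to neighbouring cardiomyocytes through gap
junctions, so they act simultaneously as diffusion obstacles and as resistive
current sinks that depolarize the myocytes around them. Both effects slow or
block the propagating electrical impulse, and both interact with
antiarrhythmic drugs whose action is to reduce specific ionic conductances.
`atriasim` provides an end-to-end in-silico workflow for this problem:

1. a 2D **monodomain** human atrial tissue model with seeded diffuse
   fibroblast infiltration and myocyte-fibroblast gap coupling;
2. a **population of models**: Latin-hypercube sampling of nine
   electrophysiological parameters, calibrated against action-potential
   biomarker ranges;
3. **single-pore-channel drug block** for amiodarone, dofetilide and sotalol;
4. biomarker extraction (APD90, conduction velocity, resting membrane
   potential, peak amplitude) and conduction/block labelling;
5. supervised classifiers (polynomial-kernel SVMs, decision tree, k-NN) that
   predict conduction from the profile, drug and fibrosis features.

## Cellular models

### Myocyte

The cardiomyocyte is a human atrial model in the Nygren formulation family
with AF-type remodelling and an added small-conductance Ca2+-activated K+
current (`IKCa`/SK), written by this package from the published formulation
lineage. Membrane currents: fast Na+ (`INa`, gates m, h1, h2), L-type Ca2+
(`ICaL`, d, f1, f2 with instantaneous Ca-dependent inactivation), transient
outward (`Ito`, r, s), ultrarapid delayed rectifier (`IKur`, with partial
steady-state inactivation), slow and rapid delayed rectifiers (`IKs`,
`IKr`), inward rectifier (`IK1`), SK current gated by cytosolic Ca2+
(Hill coefficient 2, EC50 0.7 uM), Na+/K+ pump, Na+/Ca2+ exchanger,
sarcolemmal Ca2+ pump and Na+/Ca2+ background leaks. Intracellular
Na+, K+ and Ca2+ are dynamic; Ca2+ handling uses two lumped compartments
(cytosol and SR) with SERCA uptake, a voltage-triggered, Ca-inactivated
release flux and a small constant SR leak, under instantaneous buffering
factors. This is a deliberate simplification of the four-compartment
spatial Ca2+ models in this lineage: it preserves a stable resting state, a
physiological Ca2+ transient driving `fCa`, `ISK` and `INaCa`, and the
drug/profile-sensitivity structure of the study, at a fraction of the state
count.

The canonical initial state is the one the tissue protocol assumes:
membrane potential -79.83 mV, [K+]i = 129.43 mM, [Na+]i = 8.5547 mM,
Cm = 66 pF, gates at steady state for the resting potential. The background
Na+ conductance is fixed (0.1516 nS) so that this resting potential is an
exact equilibrium of the model; the baseline conductances were calibrated
once so that the paced baseline lies inside the shipped biomarker bands
(APD90 about 175 ms, CV about 62 cm/s, amplitude about 133 mV on the
calibration strip) and were then frozen in
`inst/extdata/myocyte_baseline.json`.

### Fibroblast

The active fibroblast carries four currents (time- and voltage-dependent
`IKv` with activation/inactivation gates, inward-rectifier `IK1`, Na+/K+
pump, background Na+), Cm = 6.3 pF, fixed intracellular concentrations, and
rests at -47.75 mV; its background conductance is likewise balanced so that
value is an exact equilibrium. Fibroblasts are non-excitable: sustained
depolarizing input produces a monotone rise to a plateau with a
delayed-rectifier sag, never a regenerative spike.

### Gap coupling

Myocyte-fibroblast coupling is a species-resolved ohmic gap current,
`I_gap = G_gap (V_myo - V_fib)`, carried independently by Na+ and K+. The
total gap conductance is fixed at 0.5 nS per neighbour pair; the Na/K split
is not stated in the study design, so the package defaults to an even
0.25/0.25 nS split, exposed in configuration. Both species contribute to the
respective intracellular concentration balances of the myocyte.

## Tissue model

The monodomain reaction-diffusion equation

$$\partial_t V_m = \nabla\cdot(D\nabla V_m) - \frac{I_{ion}+I_{applied}}{C_m}$$

is solved on a square grid (default 200 x 200 nodes, 0.01 cm spacing, a 2 cm
plane) by forward Euler with Rush-Larsen exponential integration of all
Hodgkin-Huxley gates. The 5-point Laplacian enforces zero flux at the outer
boundary and at faces adjoining fibroblast nodes: masked nodes *replace*
myocytes and are excluded from diffusion (the cell-per-node reading of
"randomly located" fibroblasts), exchanging current with each von-Neumann
myocyte neighbour only through `I_gap`. Both the replacement choice and the
per-pair conductance are configuration-exposed.

Numerical choices:

* **Time step.** The default is 5 us. A coarser 10 us step is stable
  (`dt <= dx^2/4D` holds up to a +100% diffusion profile) and is used in
  direction-only checks, but it fails the package's own convergence gate for
  quantitative conduction velocity (halving the step changes CV by 1.5%;
  from 5 us the change is 0.6%, within the 1% gate). Gate lookup tables over
  membrane voltage (0.05 mV grid, linear interpolation) and periodically
  refreshed Nernst potentials keep the solver near 40 ns per node-step on
  one core.
* **Diffusion coefficient.** The study varies `D` as one of the nine profile
  parameters but never states its baseline. It was calibrated once so the
  unscaled profile conducts near the middle of the population CV band
  (62 cm/s at 0% fibrosis) while keeping the explicit stability bound
  satisfied for every admissible profile (up to +100% D) at the default
  step; the frozen value is `D = 1.25e-3` cm^2/ms.
* **Stimulus.** The S1 protocol is 4 pulses at 1 Hz, 3 ms each, applied at
  the left edge. A literal stimulus density of 4000 pA/pF would add about
  12 V in 3 ms and destabilizes any membrane model, so the package default
  is the same total current read per cell capacitance: 4000 pA over 66 pF =
  60.6 pA/pF, configuration-exposed. A single stimulated column cannot
  capture against the diffusive load at 0.01 cm spacing, so the default
  stimulus region is the three left-edge columns (also configurable).
* **Activation detection.** Per beat, activation is the time of maximum
  dV/dt, accepted only when the upstroke exceeds 1 mV/ms and the potential
  crosses -20 mV (rejecting subthreshold humps); APD90 runs from activation
  to the interpolated downward crossing of RMP + 0.1 x amplitude. Per-beat
  resting potential is the Vm minimum over the 100 ms before each stimulus.
  All thresholds live in `numerics_config()`.

Solver contracts verified in the test suite: discrete conservation of the
diffusion operator; conduction velocity scaling with the square root of D;
bit-identical reruns under fixed seeds; a numerical blow-up is reported as
an error naming the time and node.

## Population of models

Nine parameters are varied multiplicatively, each in [-50%, +100%] of
baseline: `gNa`, `INaK`, `gK1`, `gCaL`, `gKur`, `IKCa`, `D`, `Ko`, `Nao`
(the pump and SK modifiers act on the current magnitudes). `lhs_profiles()`
draws a Latin hypercube sample: exactly one draw per equal-width stratum per
parameter, deterministic under a seed. `calibrate_population()` then
simulates each candidate on a fibrosis-free strip (default 8 x 256 cells)
under the S1 protocol, measures plane-averaged biomarkers over the last two
beats, and accepts candidates whose APD90, CV, RMP and peak amplitude all
fall inside the shipped bands.

The acceptance bands live in `inst/extdata/biomarker_ranges.json` and are an
editable part of the versioned configuration. They were set from published
AF-remodelled human atrial values while the baseline was calibrated:
APD90 60-330 ms, CV 40-110 cm/s, RMP -92 to -65 mV, amplitude 70-140 mV.
With these bands roughly a fifth to a quarter of uniform Latin-hypercube
draws are accepted; rejections are dominated by non-conducting combinations
(typically high `Ko` with low `gK1`) and by out-of-band APD90.

## Drug model

Channel block follows the single-pore-channel equation
`G_i = G_0 / (1 + [C_d]/IC50)`: a pure conductance scaling, strictly
decreasing in concentration and equal to one half at the IC50. The shipped
drug library (`inst/extdata/drugs.json`) carries the simulated
concentration and the IC50 values for the three targeted channels (IKr,
ICaL, INa) of amiodarone, dofetilide and sotalol. Applying a drug multiplies
`g_Kr`, `g_CaL` and `g_Na` of the myocyte only (fibroblast currents are
untouched), and composes commutatively with profile scaling since both are
multiplicative. The package deliberately models no state-dependent binding
and no Hill coefficients other than 1.

At the defaults this yields the characteristic regimes: sotalol's INa factor
of about 0.024 abolishes propagation in most profiles, dofetilide's IKr
factor of 0.286 prolongs repolarization and slows conduction, amiodarone
produces a moderate CV decrease with preserved conduction.

## Biomarkers and conduction labelling

`tissue_biomarkers()` reports plane-averaged APD90, RMP and peak over
myocyte nodes and the last two beats; peak is reported as the AP *amplitude*
(Vmax - RMP), with the absolute maximum kept alongside. CV divides the probe
distance - probes sit at 2.5% and 97.5% of the x-extent, centred in y,
mapping the 0.5 mm/19.5 mm convention of the 2 cm plane - by the activation
delay, averaged over the last two beats. A run counts as conducting when the
right-probe cell both depolarizes and repolarizes after the final stimulus;
failure to be stimulated, to conduct, or to repolarize all label the run as
block. Drug-induced deltas (`biomarker_delta()`) are defined only for
profiles conducting in both conditions, so delta summaries have shrinking
denominators as block sets in. `group_tests()` wraps the t-test, one-way
ANOVA, Kruskal-Wallis and chi-square for condition comparisons.

## Classifiers

`assemble_features()` builds one row per (profile, fibrosis, drug) run: the
nine profile modifiers, the three drug conductance factors (1.0 without
drug), the fibrosis percentage, and the block/conduct label.
`train_conduction_models()` applies a stratified 80:20 split (test size
`floor(0.2 n)`, remainder to train, class ratio preserved within one row),
selects hyperparameters (SVM cost; tree complexity; k) by stratified
10-fold cross-validation inside the training portion, and reports held-out
metrics: the five confusion-matrix ratios with Wilson score intervals (the
interval method is a package choice), plus AUC over the models' decision
values without probability calibration. Ratios with empty denominators are
reported as missing, never as zero. `rank_features()` reports two rankings -
a kernel-gradient aggregation of the dual-coefficient-weighted support
vector contributions, and seeded permutation importance - because the
single "support vector magnitude" notion is ambiguous; disagreement between
the two is flagged rather than hidden.

## Synthetic fixtures

Every analysis-side operation is testable without tissue simulation:

* `synthetic_ap_trace()` builds an AP-like waveform whose APD90, RMP and
  amplitude are analytically exact (half-cosine upstroke, linear
  repolarization with the 90% crossing planted at the requested duration),
  with optional seeded noise;
* `surrogate_ml_dataset()` emits feature tables in the study's exact schema
  with labels from a known rule - either the sodium-availability product
  `(1 + gNa/100) f_INa` or a single-feature `gNa` rule - with an excluded
  boundary margin and a stated label-flip rate, so the Bayes accuracy is
  known in closed form;
* `toy_plane()` bundles a small geometry with proportionally rescaled probes
  for solver tests.

These fixtures emulate waveform shape, schema and decision structure; they
do not emulate AP morphology details (notch, restitution), realistic
fibrosis textures (only diffuse random masks are modelled, as in the study
design), or correlated profile parameters. Tests passing on fixtures
therefore validate the measurement and learning machinery, not the
physiology, which is covered separately by the single-cell and tissue
property tests.

## Problem sizes used by the shipped analyses

The package's own test suite and the reproduction script
(`scripts/acceptance.R`) run everything at desk scale, chosen so the full
pipeline exercises every stage on a single core: toy planes of 20 x 20 to
30 x 30 nodes with 2 beats for solver properties; a 64 x 3 to 128 x 4
calibration strip with 3 beats for population work (the package default
remains the 8 x 256 strip with 4 beats); 32 Latin-hypercube candidates with
at most 6 accepted profiles carried into the 2D study on 20 x 20 planes;
and surrogate datasets of 400-1000 rows for the classifiers. Full-scale
200 x 200 planes with the complete 4-beat protocol run with the same code
by using the default `tissue_geometry()` and `stimulus_protocol()`.

## Known limitations

* The cellular models are this package's own implementation of the cited
  formulation lineage with a lumped Ca2+ subsystem; rate constants and
  conductances were calibrated to the stated initial conditions and
  physiological biomarker bands, not fitted to the original models'
  trajectories.
* Fibroblast parameters are fixed (no fibroblast-side variability), and the
  fibrosis texture is diffuse-random only.
* The monodomain sheet is isotropic; no fibre orientation, 3D anatomy or
  pulmonary-vein structures.
* Drug block is concentration-static with Hill coefficient 1 on three
  channels; no use-dependence.
* At desk scale the classifier test sets are small, so reported intervals
  are wide; the machinery is identical at full scale.

## A minimal session

```{r example, eval = FALSE}
tp <- toy_plane(30, 30, fraction = 0.05, seed = 1, n_pulses = 2)
basal <- run_simulation(tp$geometry, protocol = tp$protocol,
                        numerics = tp$numerics)
drugged <- run_simulation(tp$geometry, drug = drug_spec("amiodarone"),
                          protocol = tp$protocol, numerics = tp$numerics)
tissue_biomarkers(basal)
biomarker_delta(tissue_biomarkers(drugged), tissue_biomarkers(basal))
```
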