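---
title: "MRI-only mass density and RSP estimation: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-only mass density and RSP estimation: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Proton treatment planning converts a volumetric image into per-voxel mass
density or relative stopping power (RSP). MRI cannot supply either directly,
so `mrirsp` models a *voxel-wise* regression from multi-sequence MR
intensities to these quantities: each voxel contributes one row of
water-normalized channel intensities (T1-Dixon water, T1-Dixon fat, T2-STIR,
optionally ZTE, optionally DECT-surrogate parametric channels) and one
density and/or RSP target. The regressor is a fully connected network: the
input row passes through 9 hidden blocks of 80 nodes, each
linear → layer normalization → ReLU, followed by a single linear output. One
network is trained per target (density and RSP are separate losses, so
separate single-output networks; a two-output variant would couple their
gradients and is intentionally not the default). Training minimizes the mean
squared error with mini-batch Adam.

The key modeling assumption is that tissue identity — and through it density
and RSP — is a function of the *contrast signature* across sequences at a
voxel, not of spatial context. That is why a 1-D (per-voxel) network
suffices and why water normalization matters: dividing each channel by its
mean pure-water signal removes scanner gain so that signatures are
comparable across acquisitions.

Two reference models are implemented for comparison. The DECT empirical
conversions map a dual-energy material decomposition (relative electron
density $\rho_e$, effective atomic number $Z_{eff}$) to density,
$\rho = -0.1746 + 1.176\rho_e$, and to RSP through a four-branch piecewise
law in $Z_{eff}$ with half-open intervals $[0,0.5)$, $[0.5,8.5)$, $[8.5,10)$,
$[10,\infty)$. The half-open convention fixes behavior exactly at the
breakpoints (a boundary voxel takes the right-hand branch); the vectorized
implementation is tested against a scalar branch-by-branch oracle. The
second reference is ordinary least squares of the target on the single
T1-Dixon-water channel — deliberately underpowered, to show that one
sequence cannot separate the materials.

## Supporting physics

The phantom table carries measured density, RSP at 150 MeV, mean excitation
energy and elemental compositions; the package cross-checks them with
standard stopping-power physics: mean $Z/A$ and relative electron density,
Bragg-additivity $I$-values (log-weighted mean of elemental $I$), and the
Bethe stopping-power ratio at the 150 MeV measurement energy (proton rest
energy 938.272 MeV, electron rest energy 0.511 MeV; water reference
$I_w = 75$ eV with $Z/A$ computed from the H 11.19% / O 88.81% composition,
both overridable in `beam_spec()`).

Elemental $I$-values default to the ICRU condensed-phase recommendations
(H 19.2, C 81, N 82, O 106, Na 149, P 173, S 180, Ca 191 eV) but live in a
swappable `element_table()`. Measured compound $I$-values are not exactly
reproducible under any single elemental convention — straightforward Bragg
additivity lands 2–4% below the measured soft-tissue values and ~8% below
the mineralized 45%-hydroxyapatite value (the measured values likely treat
bound water as a compound with its own $I$). The package therefore treats
$I$ agreement as tolerance-based (5% soft tissues, 10% mineralized) rather
than exact; the Bethe-ratio RSP computed from the printed composition,
density and $I$ agrees with the measured RSP within 5% for all seven
phantoms, and within 0.5% for most soft tissues.

Trace-element column assignment in the packaged composition table follows
the chemistry of the recipes: SDS contributes Na and S, gelatin S; the
sub-0.3% trace entries for muscle, brain and liver are assigned to Na/S
accordingly. These choices move $I$ and $Z/A$ at far below the stated
tolerances.

## What the simulator emulates — and what it does not

`build_scene()` voxelizes the measurement geometry: a water cylinder of
84.1 mm radius and 254 mm height holding 57 × 57 × 129 mm³ inserts, on a
default 1 mm isotropic grid (axis order slice/row/column, voxel centers at
integer coordinates; the acquisition-protocol spacings are available by
setting `voxel_spacing_mm`). All channels are born on a common grid —
registration and resampling are out of scope.

Per-tissue nominal MR signals are *not* published for these phantoms, so the
default `signal_table()` encodes the qualitative contrasts reported for the
acquisitions — adipose bright on the Dixon fat channel and suppressed on
T2-STIR; the 45% HA phantom bright on T1-Dixon and ZTE but dark on T2-STIR;
spongiosa and mineral phantoms bright on ZTE — with numeric values chosen
once so that signatures are distinct at the SNR-30 noise scale (minimum
pairwise separation several times the per-channel noise sd). Water is 1.0 in
every sequence by construction. Noise defaults to additive Gaussian with
sd = water-signal/SNR and SNR 30, the floor observed on the real scans
(at which degradation of contrast is negligible); a Rician option exists for
magnitude-image realism. DECT-surrogate parametric maps are generated
directly from composition ($\rho_e$ from density and $Z/A$; $Z_{eff}$ from
the power law with $m = 3.1$, a common spectral-CT convention — the clinical
decomposition software does not publish its exponent) with multiplicative
noise at the decomposition's characteristic 0.8% / 2.9% errors.

Consequences for interpretation: passing tests show that the *pipeline and
models* behave correctly on data whose generative process matches the
modeling assumption (piecewise-constant signatures plus voxel-independent
noise). They do not show accuracy on real scans, where partial volume,
bias fields, relaxation-time differences between phantom and human tissue,
and registration error all exist and are deliberately not simulated (no
Bloch simulation, no k-space artifacts, no CT beam hardening, no
inter-sequence misregistration).

## Protocol and numerical choices

- **Half-and-half separation.** Slices $[0, \lfloor S/2 \rfloor)$ are the
  training pool, $[\lfloor S/2 \rfloor, S)$ the application set; an odd
  slice count gives the extra slice to the application half (the midpoint
  convention is otherwise arbitrary). Training and application voxel sets
  are provably disjoint, and the test suite asserts it.
- **Voxel counts.** The per-phantom extraction count is a total across the
  allowed slices (24,000 per phantom at acquisition scale, drawn uniformly without
  replacement within the radius-15 VOI), because only that reading
  reproduces the reference 168,000 × 3 and 120,000 × 4 matrix sizes;
  patient-style assembly uses all slices (48,000 per phantom → 336,000
  rows).
- **75/25 split.** Random, stratified by phantom so per-phantom proportions
  are preserved within rounding; validation rows are used for monitoring
  only and never influence the weights (asserted by an identical-weights
  test). Early stopping on validation loss is intentionally not performed;
  training runs to `max_epochs` and prediction uses the `epochs_used`
  checkpoint (defaults 500/300, the train-long-use-earlier pattern that
  avoids overfitting on small phantom datasets).
- **Layer ordering.** Linear → layer-norm → ReLU per block, final layer
  linear without activation or normalization; the architecture annotation
  alone does not fix this order, so it is pinned here and documented.
  Layer-norm $\epsilon = 10^{-5}$.
- **Initialization and determinism.** Uniform fan-in initialization
  (PyTorch convention) from R's RNG; batch shuffles are drawn in R per
  epoch; the compiled Armadillo training core is deterministic given both,
  so identical seed + data give identical loss histories and predictions
  down to the byte.
- **No output clipping.** The affine density conversion itself can go
  negative at very low $\rho_e$; the FCNN could, in principle, too.
  Predictions are reported as produced and surfaced by the error reports
  rather than silently truncated.
- **Report spread.** The ± column is the population SD of the per-voxel
  APE within a phantom (a per-voxel rather than per-slice spread), which is
  the finest-grained and most conservative reading of a ± column.
- **Line profiles** use nearest-voxel lookup, not interpolation — profiles
  are voxel-indexed.
- **Model C channels.** The patient-style two-channel schema defaults to
  T1-Dixon-water + T2-STIR but the pair is an explicit, overridable field of
  `model_schema()`, since a two-MR-channel model is meaningful for several
  channel pairs.

## Problem sizes used by the shipped tests

Matrix-size checks run at full scale (24,000/48,000 voxels per phantom).
The learning-performance checks run the complete pipeline at the full
acquisition geometry but with 1,600 extracted voxels per phantom and 100 training
epochs — sizes chosen once as a package default for a thorough-but-compact
regression study; at these sizes the held-out per-phantom MAPE is far below
the stated bounds (< 0.5% noise-free, < 2% at SNR 30) for both density
and RSP under Models A and B, and the qualitative ordering
linear ≫ DECT-empirical > FCNN holds on every soft-tissue phantom.

## Known limitations

The simulator's nominal signatures are stand-ins; no claim is made about
real-scan accuracy. The phantom set spans only 0.94–1.42 g/cm³ — no lung- or
cortical-bone-like materials — so any regression trained on it extrapolates
poorly outside that range. The DECT-surrogate channels bypass an actual
material decomposition; their error model is a calibrated scalar noise
level, not a physical reconstruction. Dosimetric evaluation (DVH, dose
differences) is out of scope.
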