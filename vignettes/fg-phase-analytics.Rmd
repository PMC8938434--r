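---
title: "Quantifying FG-domain phase separation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FG-domain phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgphase)
```

`fgphase` bundles the quantitative analyses used to characterise
liquid–liquid phase separation of engineered FG-repeat proteins:
perfectly repetitive Nup98-like sequences such as the 52-fold
concatenation of the 12-mer GGLFGGNTQPAT, whose repeats are
indistinguishable by NMR and therefore give one resonance per repeat
position. This vignette explains the models behind each module, the
tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the design decisions taken where
the methods literature leaves the choice open.

## Hydrodynamic reference calculations

The sequence module supplies closed-form reference quantities: average
molecular mass (average, not monoisotopic, residue masses, because
protein is quantified by dry weight), molarity/mass-concentration
conversions, motif molarities, and the concentration of motifs confined
to a sphere (used to estimate the local FG-motif concentration inside a
single ~5 nm chain, about 0.17 M for 52 motifs).

The rigid-sphere references come from the Stokes–Einstein(–Debye)
relations. The bare radius follows from the partial specific volume
(default v̄ = 0.73 cm³/g, the standard protein value; configurable) and
a hydration shell is added (default 3.2 Å). Solvent viscosity defaults
to pure water from a Vogel-type correlation
η(T) = 2.414·10⁻⁵·10^{247.8/(T−140)} Pa·s, which agrees with handbook
values to well under 1% between 0 and 40 °C; buffer additives are
ignored, since at ≤600 mM NaCl they perturb viscosity by only a few
percent. Temperatures are accepted in °C at every interface and
converted internally. These choices reproduce the expected rigid-sphere
correlation times for the 52- and 7-repeat constructs (≈22 and ≈4 ns at
24 °C) to within a few percent, and the two relations obey
D·τ_c = (2/9)r² identically, which the suite asserts.

A deliberate non-goal: no disordered-chain R_h scaling laws or shape
corrections. The rigid-sphere numbers are reference values whose whole
point is the contrast with the much shorter measured per-residue
correlation times.

## TRACT: rotational correlation times with uncertainties

Each residue contributes two relaxation series (TROSY-selected α and
anti-TROSY β ¹⁵N doublet components). The pipeline is:

1. Unweighted nonlinear least squares of I(t) = I₀e^{−Rt} per series
   (Levenberg–Marquardt), no baseline offset — the difference data are
   assumed baseline-corrected. Rate uncertainties come from the fit
   covariance. Non-decaying series yield a near-zero rate with a flag,
   not an error.
2. η_xy = (R_β − R_α)/2, with β the faster-relaxing component.
3. τ_c from inverting the cross-correlated-rate expression
   η_xy = 2pδ_N(3cos²θ−1)(4J(0)+3J(ω_N)) with J(ω) = 0.4τ/(1+ω²τ²).
   The expression is strictly increasing in τ_c, so the root is unique;
   it is found by bisection in log τ over [1 ps, 10 μs] to 1e-9
   relative tolerance in η (the floor extends automatically for
   arbitrarily small rates). The inversion is vectorised, which makes
   the full 10000-draw Monte Carlo cheap.
4. Monte Carlo SDs: both rates are resampled from normal distributions
   with the fitted SDs (default N = 10000, seeded). Draws with
   R_β ≤ R_α have no physical solution; they are discarded and counted,
   and a residue whose draws are majority-unphysical — or whose rate
   difference is within its combined error — is reported indeterminate
   (τ_c missing; plots conventionally render such residues as 0).

Constants that the relaxation data cannot determine are isolated in
`spin_parameters()`: r_NH = 1.02 Å, Δδ_N = 160 ppm, θ = 17°, standard
values in the TRACT literature, all configurable. Absolute τ_c values
from real spectra can shift by a few percent with these choices; the
package guarantees forward/inverse self-consistency, which is what the
recovery tests exercise.

### Why the coverage tests use a t-multiplier

Each decay fit has 7 points and 2 parameters, so its residual variance
estimate carries 5 degrees of freedom. Intervals built from such an
estimate are calibrated by the t distribution, not the normal: the
suite therefore checks that τ̂ ± t₀.₉₇₅,₅·SD_MC covers the truth in at
least 90% of simulated replicates (measured ≈95%). The Monte Carlo
itself resamples from normal distributions, as is conventional.

## FRAP: translational diffusion in the condensed phase

Normalization divides the bleached-ROI trace by a user-supplied
unbleached reference ROI (rescaled to its initial value) to remove
acquisition photobleaching, then maps the corrected prebleach level to
1; the first postbleach value then reflects bleach depth. If no
reference exists the correction is skipped with a warning — no decay
model is invented. The recovered fraction is fitted to
C(t) = A(1 − e^{−t/τ}) with t = 0 at the first postbleach frame, so A
measures the mobile fraction (1 − A the immobile fraction). Traces
recovering less than 10% of the bleach depth are classified immobile,
the behaviour of strongly cohesive wild-type condensates. The half-time
and diffusion coefficient are algebraic: t₁/₂ = −ln(0.5)·τ,
D = 0.224·R²/t₁/₂.

The effective bleach radius R is measured from the postbleach radial
profile as the half-width at 86% of bleach depth, i.e. where the
profile crosses baseline − 0.14·depth, with linear interpolation. For a
Gaussian dip this equals σ√(2 ln(1/0.14)) — the analytic oracle in the
tests — and it turns a nominal ~1.5 μm spot into the realistic
effective 2–3 μm radius produced by diffusion during bleaching.
Replicates (typically n = 5 particles) are fitted independently and D
is reported as mean ± SD. Whether R should enter per replicate or as a
fixed value is not settled by the methods literature; `run_frap()`
applies one radius to all replicates, which matches how a single
calibrated bleach geometry is used in practice.

Non-goals: reaction–diffusion models and the Bessel-function
(uniform-disk) solution; the simple exponential model is the one used
for condensate FRAP here, and the generator inverts exactly that model.

## DLS: transition temperatures and the LCST phase diagram

A ramp (default 1 °C/min, radii acquired continuously) crosses the
transition when the apparent radius jumps from ~5 nm to ~1000 nm. The
detector takes the baseline as the median radius over the first
quartile of the ramp and reports the first temperature at which the
radius exceeds `threshold_factor` × baseline (default 10×) and stays
above for `persistence` points (default 3) — both invented,
configurable operationalisations of a "sharp increase". The raw
crossing is interpolated between samples and rounded *up* to 0.1 °C,
so the reported T_p is never below the crossing and differs from it by
less than 0.1 °C. Replicates (three per condition) aggregate to
mean ± sample SD. The phase-diagram builder orders points per salt
series and flags LCST consistency (T_p decreasing with concentration)
and salt enhancement (every T_p lower at higher NaCl).

Correlogram support is a first-cumulant analysis:
g₂ − 1 = βe^{−2Γτ}, D = Γ/q², R_h = kT/6πηD, with the scattering
vector from configurable optics (defaults 658 nm, 90°, n = 1.33 —
instrument constants, not derivable from the data). Polydispersity
inversion is out of scope.

## Critical concentrations and partitioning

After phase separation the dilute phase sits at the critical
(saturation) concentration, so supernatant concentrations from
centrifugation assays estimate c_crit directly: points with
supernatant < (1 − 0.05) × total are classified as separated and their
supernatants averaged; if nothing separated, the largest load is
returned as a lower bound with a flag (the behaviour of non-cohesive
variants re-tested at 100 μM). The estimator is scale-equivariant and,
on `sup = min(total, c*)` data, recovers c* to within the noise level.
Partition coefficients are simple in/out signal ratios; a zero outside
signal reports a lower bound at a configurable detection floor
(default 0.001 of the inside signal). Gel densitometry itself is out of
scope — inputs are already-quantified concentrations.

## Synthetic data: what it does and does not emulate

Every generator is the exact inverse image of its analyzer at zero
noise, is deterministic under a seed, and encodes the acquisition
design of the corresponding experiment:

- `gen_tract()`: 7 delays per state, each state sampled to ~30%
  residual signal of its own first increment, multiplicative Gaussian
  intensity noise (default 2%), rates split symmetrically about a base
  rate (default 30 s⁻¹). The condensed-phase preset profile spans
  6–11 ns with maxima at L3/F4 and Q9/A11; the soluble preset is flat
  at 2 ns.
- `gen_frap()`: 2 s frames over 300 s, exponential recovery with
  bleach depth 0.8 and immobile fraction 0.05 by default, optional
  acquisition-bleach decay shared by ROI and reference, additive noise
  on the normalized signal.
- `gen_dls_ramp()`: logistic radius jump 5 → 1000 nm with a 0.1 °C
  scale (sharp), 0.5 °C sampling over 2–40 °C, optional programmable
  hysteresis for cooling ramps.
- `gen_shift_tables()` / `gen_noesy_peaks()`: built on a synthetic
  shift table for the repeat unit (random-coil-like placeholder values,
  clearly not experimental); degenerate shifts can be injected to force
  ambiguity.
- `gen_assay()`: supernatant = min(total, c_crit) with multiplicative
  noise.

Gaussian noise (multiplicative for intensities and concentrations,
additive for normalized FRAP signals) is the simplest model consistent
with least-squares fitting; real instruments have heavier-tailed and
correlated noise, baseline drifts, and in the NMR case peak overlap and
lineshape effects that the generators do not attempt. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated designs, not robustness to every pathology of real spectra.

## Spectral bookkeeping conventions

- Expected amide peaks = non-proline residues of the repeat unit (11
  for GGLFGGNTQPAT).
- Phenylalanine under fast ring flips shows three aromatic CH
  environments at 2:2:1 (δ, ε, ζ); tyrosine 2:2.
- CSP combines amide shifts as √(Δδ_H² + (0.2·Δδ_N)²) — the common
  Δδ_N/5 convention, configurable — and flags residues above the
  profile mean.
- NOE classification treats the repeat as circular (position 12
  adjoins position 1 of the next repeat) because the repeats are
  indistinguishable by NMR: sequential means circular separation 1,
  long-range ≥ 2. Matching tolerances default to 0.03 ppm (¹H) with a
  0.05 ppm diagonal band; diagonal peaks are excluded from contact
  categories since they stem mostly from untransferred magnetization
  (which also hides contacts between equivalent groups, e.g. Phe–Phe).
  Ambiguous matches are listed in full, never resolved, and contacts
  are categorical only — NOE intensities are not converted to
  distances, which is unreliable for such a dynamic system.

## Problem sizes and numerical choices

The simulation studies in the test suite use 200 replicates of the
11-residue profile at 1.5% noise with the Monte Carlo reduced to 2000
draws per residue (the package default remains 10000); bisection uses
80 iterations in log τ; decay and recovery fits start from log-linear
estimates and run Levenberg–Marquardt, which is robust on zero-residual
(noise-free) data. Degenerate inputs are policy, not accidents:
non-decaying relaxation series flag rather than fail, flat FRAP traces
classify as immobile, ramps that never cross threshold return no
transition, and assay tables where nothing separated return bounds.

## Known limitations

- Absolute τ_c from real TRACT data depends on the CSA/geometry
  constants; only self-consistency is guaranteed.
- The exponential FRAP model ignores diffusion during bleaching except
  through the effective radius, and assumes a single mobile species.
- Transition detection needs a baseline quartile free of the
  transition; transitions in the first quarter of a ramp bias the
  baseline.
- The synthetic shift table is a placeholder; real CSP/NOE analyses
  require user-supplied assignments.
- LCST thermodynamics are deliberately not modelled; the phase diagram
  is assembled from measurements, not fitted to a theory.
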