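---
title: "Measuring Httex1 aggregation flux: models, gates and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Httex1 aggregation flux: models, gates and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggflux)
```

# The measurement problem

Httex1 with an expanded polyglutamine tract flows through three molecular
states inside a cell — dispersed monomer, diffuse oligomer, micrometre-scale
inclusion — and the relationship between that flux and cell death cannot be
read from any single assay. The platform implemented here triangulates it
from three measurement modalities: flow-cytometry pulse shapes classify
*cells* by the localisation of their Httex1; gel filtration and low-speed
sedimentation velocity classify *molecules* in the pooled lysate; and a
bicistronic membrane reporter plus a permeability stain make dead and even
disintegrated cells countable. Because the populations, gates and fits
interlock, the package treats the whole chain — population simulation,
instrument simulation, gating, metrics, fitting, partitioning — as one
tested pipeline with ground truth at every stage.

# The cell-population model

`simulate_population()` steps each cell through discrete time (default
`dt = 0.5` h) with four competing hazards:

* **Inclusion nucleation**
  `λ = k_nuc · min((E/E_ref)^h_exp, exp_cap) · q_gain(Q) · mod_nuc(arm)`,
  where `E` is the cell's Httex1 abundance, `E_ref` the median of the
  expression law, `h_exp = 2` a cooperativity exponent, and
  `q_gain(Q) = max(0, (Q−36)/10)^1.5` a polyQ gain that vanishes for
  non-pathogenic lengths and is normalised to 1 at 46Q. Only the *ordering*
  of aggregation propensity with repeat length is established biology; the
  functional form is a package choice. The saturation `exp_cap = 16` caps
  the per-step probability at extreme supersaturation — both the physically
  sensible behaviour and what keeps the stepping guard (error if any
  per-step probability exceeds 0.2) meaningful at 97Q.
* **Death** at `mu_ni = 0.005 h⁻¹` without an inclusion and
  `mu_i = 0.09 h⁻¹` with one, times per-arm modifiers. A dying cell stays
  intact, leaches its cytosol (probability 0.25), or — only if it carries an
  inclusion — lyses to a free inclusion with debris (probability 0.35).
* **Division** at `growth_rate = 0.03 h⁻¹` (≈23 h doubling); daughters
  duplicate the parent state.
* **Oligomer enrichment** at `k_olig = 3e-5 h⁻¹ · q_gain(Q)`: a rare
  transition of cells without inclusions into a state whose monomer fraction
  converts first-order into oligomer, producing the poor-FlAsH-reactive
  intermediates.

After nucleation the monomer and oligomer fractions convert first-order
(`k_conv = 0.8 h⁻¹`) into the inclusion fraction; inclusion formation is
absorbing. Whether cells ever dissolve inclusions is not established; the
simulator deliberately has no reverse flux, and conclusions that depend on
reversibility are outside what these simulations can show. Httex1 decays at
`k_deg = 0.002 h⁻¹` in live cells; the membrane reporter is drawn once per
cell as `0.5 · E₀ · lognormal(0.25)` and is not degraded, which is what
makes the reporter ratio sensitive to arm-dependent clearance.

Defaults were tuned once (script shipped as `scripts/tune_defaults.R`)
against the qualitative bands the platform is designed to exhibit —
i-population death 50–75% and ni-population 15–30% at 46 h, an hsp40 arm
suppressing the all-cell inclusion fraction by 20–30% relative, an hsp70 arm
protecting inclusion-bearing cells by about 15 points, a combined arm that
raises ni death by 5–10 points while boosting growth and turnover, and an
oligomer-intermediate (PFR,ni) fraction near 0.5% at 46Q — then frozen in
`R/defaults.R`. They are conditions of the simulated study, not free dials.

# Instrument models

**Cytometer pulses.** A cell's transit profile is a centred Gaussian whose
sd is `0.25 ×` its diameter (diffuse fluorophore) plus a near-point Gaussian
(sd 0.3) carrying the inclusion's signal, convolved with a Gaussian beam —
all Gaussian, so `synthesize_pulse()` evaluates the convolution in closed
form, and the tests check it against a numeric convolution oracle. Height is
the profile maximum, area the integral, and width the duration above a fixed
detector floor (2 a.u.). Real cytometers do not publish their width
algorithm; an absolute-threshold duration is instrument-style, and every
width-based gate is therefore defined *relative to a simulated calibration
control*, never in absolute units. Channel noise is multiplicative
log-normal (8% CV) plus additive detector noise.

**Measurement rules per cell state.** Live and intact dead cells: Cerulean ∝
Httex1 with punctate share `f_inc`; mKate2 ∝ reporter; FlAsH ∝ monomeric
Httex1 only. Leached ghosts retain membrane mKate2 but only 0.3% of
cytosolic signal. Debris events carry the free inclusion's punctate Cerulean
with 2% of the reporter. SYTOX responds with probability 0.995 in intact
dead cells, 0.4 in leached and debris events (they have lost nucleic acids;
the 60% miss rate is configurable), and 0.001 in live cells. An unstained
tube is simulated with `stain_sytox = FALSE`; using a stained control as the
SYTOX reference is a protocol error the package surfaced during testing —
a handful of true positives in the control can push the 99.9th-percentile
threshold into the positive population.

**Ultracentrifuge scans.** Non-diffusing species: boundary at
`r_m·exp(ω²st)`, plateau diluted by `exp(−2ω²st)`. A logistic edge of width
0.005 cm stands in for diffusional spreading so that fitting is
non-degenerate; truly non-sedimenting species are rendered exactly flat. A
species pelleting within the scan window is reported with a warning, never
silently.

**Chromatograms.** Monomer: narrow Gaussian at its calibrated elution
volume; oligomer: earlier peak, three times wider; inclusions: occluded, so
the loaded signal is `(1 − p_inc) ·` total.

# The gating tree

Hand-drawn gates are replaced by quantile rules with recorded provenance,
making `apply_gates()` a pure function of (events, gate set):

1. scatter floor and doublet bound (derived from the event cloud);
2. transfection threshold = 99.9th percentile of the untransfected control's
   max reporter signal, passed on *either* channel so leached cells survive;
3. M/D/L: a Theil–Sen line through log-Cerulean × log-mKate2 (deterministic
   half-split pairing, so no RNG enters gate derivation); D = Cerulean
   excess beyond `k·MAD` of the residuals, L = Cerulean below the
   transfection threshold with mKate2 above it, M = the rest. The band
   half-width is `k = 5` MAD ≈ 3.4 σ for Gaussian residuals: a 3-MAD band
   (≈2 σ) would misassign ~2% of genuinely intact cells to D, which the
   death-rate statistic would then count as dead — a systematic bias far
   exceeding the estimator's sampling error.
4. SYTOX threshold = 99.9th percentile of the unstained control;
5. PulSA: per height-decile 0.5th-percentile width envelope of a 25Q-like
   diffuse calibration; below the envelope ⇒ `i`. One calibration is reused
   across constructs within a run and recorded in the gate set.
6. FlAsH: per Cerulean-decile 0.2nd-percentile envelope of the
   log(FlAsH/Cerulean) ratio of the monomeric control; below ⇒ PFR. The
   envelope quantile is the one place where the false-positive rate directly
   enters a headline quantity (the PFR,ni fraction), and 0.002 keeps that
   floor (~0.15% of transfected) well below the signal it measures.

Every level is an exact partition of its parent, which the tests assert as
count identities.

# Estimators

**Death rate.** `(|SYTOX+| + |SYTOX−∩L| + |SYTOX−∩D|) / (|M|+|L|+|D|)`,
each D event counting as one cell's remnant. The subpopulation scopes
attribute D to the inclusion-bearing scope (free inclusions come from i
cells) and L to the no-inclusion scope; this attribution is an inference
from the populations' provenance, documented here and switchable, since the
denominators are not uniquely dictated by the gating alone. Monte-Carlo
calibration (200 replicates in the acceptance suite) shows the estimator
unbiased to within twice its standard error under the default measurement
model; its residual error budget is the 0.5% SYTOX miss on intact dead
cells, the 0.1% live false-positive rate, and the ~0.04% leak of live cells
past the 5-MAD D bound.

**ls-g\*(s).** The design matrix evaluates every grid point's step boundary
at every (radius, time) sample; amplitudes are solved by non-negative least
squares (`pracma::lsqnonneg`) with a second-difference penalty on `g = c/Δs`
and an unpenalised flat baseline. The penalty weight is chosen by a
discrepancy rule — the largest weight on a geometric ladder whose RMSD stays
within 10% of the unpenalised fit — because no selection criterion is
canonical for this model class. The default grid is 50 log-spaced points
over 1–5000 S; a grid whose boundary displacements are all below the radial
spacing is rejected as ill-conditioned. The integral `Σc` equals the loading
signal by construction of the dilution columns, giving the 1%-level
conservation checks in the tests. Oracle equivalence against a 10×-finer
brute-force NNLS fit is part of the acceptance suite.

**Inclusion fraction in 2 M sucrose.** A two-component decomposition:
unpenalised NNLS over a flat column plus boundary columns whose apparent s
spans, adaptively, the slowest boundary that traverses ≥10% of the solution
column by the last scan up to the fastest still inside the cell at the first
scan. Slower grid points are indistinguishable from the flat component and
would split arbitrarily with it; excluding them is what makes the `p_inc = 0`
pole stable (worst-case noise leakage ~1–3%, within the ±0.03 the estimator
is specified to). The solvent correction
`s20w = s_obs · (η/η₂₀,w) · (1 − v̄ρ₂₀,w)/(1 − v̄ρ)` ships with tabulated 2 M
sucrose conditions (ρ = 1.25 g/ml, η = 15 cP near 11 °C, standard sucrose
tables); all corrected outputs carry the conditions used, since the solvent
properties are inputs, not measurements.

**Pools and partition.** The chromatogram is decomposed by a two-Gaussian +
baseline fit (`minpack.lm::nlsLM`) initialised at the calibration centres,
falling back to a recorded valley split when the fit fails or the fitted
peaks overlap beyond half their combined widths; residual signal is reported
as `unassigned`, never dropped, so the three amounts always reproduce the
chromatogram integral exactly. The partition rule
`p_mono = (1−p_inc)·m/(m+o)` applies the gel-filtration ratio to the
non-inclusion share from sedimentation; it is the only arithmetic consistent
with the two assays' blind spots (the column cannot see inclusions, the
low-speed run cannot resolve monomer from oligomer) and is scale-invariant
in the pool signals, so no cross-normalisation between the two instruments
is needed beyond the shared loading signal.

**Statistics.** One- and three-way fixed-effects ANOVA use `stats::aov`;
pairwise arm-vs-control comparisons use marginal means with the pooled
residual variance, then the Holm–Šidák step-down
`adj_p(j) = max_{j'≤j} 1 − (1−p(j'))^{k−j'+1}`, implemented here and checked
against its closed form.

# What the simulations do and do not show

The simulator reproduces the platform's *structure*: correlated
reporter expression with leaching and debris, expression/time/polyQ-ordered
inclusion kinetics, pulse-shape separability, stain imperfection, occlusion
and sedimentation physics, and chaperone-arm effects of realistic sign and
size. It deliberately omits spectral spillover and compensation, doublet
physics beyond a size surrogate, cell-cycle structure, diffusion in the
ultracentrifuge (no Lamm equation), mechanistic polymerisation rate laws,
and any reverse flux out of inclusions. Passing tests therefore demonstrate
that the estimators are correct and calibrated *given* this measurement
model — not that real Neuro2a data would yield the same numbers. Gate
placements on real data would still need instrument-specific controls, and
the chaperone-arm magnitudes are tuned emulations of reported bands, not
predictions.

# Problem sizes and numerics

The shipped tests run on 1,000–10,000-cell populations, 8–10 radial scans of
240–2,000 points, and 30–200 replicate simulations; these sizes were chosen
so the full suite exercises every estimator at its stated tolerance in a few
minutes on a single core. Degenerate inputs are errors, not guesses:
zero-variance ANOVA, empty populations, all-zero abundances, boundaries
beyond the cell base, unresolvable s-grids, reference controls overlapping
their sample. Ties and floating-point drift are handled where they matter —
per-cell state fractions are renormalised each conversion step, and events
failing the log transform are clamped to zero and counted in the gate set.
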