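---
title: "Methods: population mechanistic modelling of month-one CAR T-cell dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population mechanistic modelling of month-one CAR T-cell dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartpop)
```

## Scope and rationale

`cartpop` models the first 30 days after infusion of an anti-CD19 CAR
T-cell product in lymphoma: the initial expansion driven jointly by
lymphodepletion (antigen-independent) and tumour antigen
(antigen-dependent), the contraction that follows, the drift of
T-cell differentiation phenotypes, and the shrinkage of CD19⁺ lesions.
The horizon stops at day 30 deliberately: the long-term biphasic decline
of CAR counts and the return of endogenous homeostasis happen on a slower
time scale and are out of scope, so late-time endogenous counts are
allowed to decay toward zero without a homeostatic floor.

## Model hierarchy and assumptions

The five layers are strictly nested. Structural assumptions, each of
which the code enforces or the tests check:

* **Shared kinetics.** Endogenous and CAR T-cells share the
  antigen-independent proliferation rate ρ_e(t) = ρ₀e^(−γt) and the death
  rate δ. CAR-specific processes never feed back on endogenous cells, so
  every layer reproduces layer 1's endogenous totals exactly (tested to
  relative 10⁻⁶ against the closed form and across layers).
* **Constant partition.** The lesion CAR pool is a fixed multiple φ of
  the blood pool (fast extravasation relative to proliferation, killing
  and death). One total-CAR state is integrated and partitioned
  algebraically, which makes the constraint exact by construction.
* **Saturating antigen drive.** Antigen stimulation enters as
  ρ_a·B/(B + K_half), the simplest one-constant saturation. Whether CAR
  exhaustion should modulate this is unknown; the package implements
  depletion-only feedback (killing lowers B, which lowers the drive).
* **Phenotype-uniform rates.** The four phenotypes (naive, CM, EM,
  terminal effector) differentiate along an irreversible chain with rates
  α₁..α₃ but proliferate and die at identical rates. Proportions then
  evolve independently of totals, which is what keeps the hierarchy
  conservative, and initial phenotype proportions are forgotten over
  time (tested as a contraction property). The cost is that phenotype
  composition can only influence outcomes through killing.
* **Effector-weighted killing.** Killing rates default to zero for naive
  and CM cells. The EM rate is supported but not fitted by default
  because EM and effector proportions are nearly collinear over one
  month, making the pair practically unidentifiable; lesion kill then
  defaults to the terminal-effector channel alone.
* **Lesion geometry.** Equal-volume spherical lesions, even elimination,
  T-cells excluded from lesion volume: diameter d = (6V/(nπ))^(1/3),
  SPD = Σd². Blood CD19⁺ cells sit at the limit of quantitation and are
  inert.

Model 3 has no phenotype states of its own, but its lesion killing uses
the phenotype-weighted κ computed from the (independently evolving)
proportion chain; this is what makes model 5's CAR totals equal model 3's
for the same parameter set, a property the acceptance suite checks over
100 random parameter draws.

## Parameters

All rates are per day, blood counts per 5.3 L (average adult blood
volume), lesion counts absolute. Defaults describe a plausible large-ish
B-cell lymphoma patient after lymphodepleting chemotherapy and are the
generator's population medians:

| parameter | default | meaning |
|---|---|---|
| ρ₀ (`rho0`) | 0.6 /day | initial antigen-independent proliferation |
| γ (`gamma`) | 0.12 /day | decay of that proliferation (~week time scale) |
| δ (`delta`) | 0.3 /day | shared T-cell death rate |
| ρ_a (`rho_a`) | 0.4 /day | maximal antigen-driven CAR proliferation |
| K_half | 10¹⁰ cells | half-maximal antigen stimulation |
| g (`g_tumour`) | 0.02 /day | net lesion growth without killing |
| κ (`kappa_p`) | (0, 0, 0, 10⁻⁸) /(cell·day) | per-phenotype killing |
| φ (`phi`) | 0.5 | lesion:blood CAR partition ratio |
| α₁..α₃ | 0.03, 0.05, 0.08 /day | differentiation chain rates |
| E₀, C₀ | 3×10⁸, 7×10⁷ | initial blood endogenous / CAR counts |
| B₀ | 5×10¹⁰ cells | initial lesion CD19⁺ burden (~47 cm³, SPD ≈ 21 cm²) |
| v_cell | 10⁻⁹ cm³ | tumour cell volume (1000 µm³) |
| LOQ (`B_blood_loq`) | 5.3×10⁶ | blood CD19⁺ floor (1 cell/µL) |

With these values the default patient peaks near 3×10⁸ blood CAR cells
around day 8 and clears ~99% of the lesion — the order of magnitude seen
in responding large-B-cell-lymphoma patients. K_half sits below B₀ so
that the antigen drive de-saturates as the lesion clears; this is also
what makes K_half identifiable from time-course data at all.

## Population model and virtual patients

Marginal families follow the usual pharmacometric conventions: log-normal
for positive rates and counts (locations are log-medians), Gaussian for
the death rate, logit-normal for proportions, with an optional
correlation matrix on the latent Gaussian scale (applied through the
Cholesky factor). Phenotype proportion vectors are renormalized onto the
simplex after their marginal draws; default locations are chosen so their
natural-scale values already sum to one and zero-scale draws are
therefore exactly the locations. Gaussian-family rates are floored at
zero (an event with negligible probability at the default scales).
Observation-error models are per observable: multiplicative log-normal
for counts and SPD, additive for LDH and cytokines, additive-on-logit
(then renormalized) for flow proportions.

Quantile bands (median, IQR, 5th–95th) use linear interpolation between
order statistics (R type 7) everywhere; the convention matters because
the bands are comparison surfaces.

Parameter-alteration experiments multiply or add a constant to one flat
parameter across the whole virtual population. Altered proportions are
capped at 1 and the vector renormalized — the generator's `×10 naive`
experiment intends "ten times as much of the naive pool", and
renormalization is the only way to keep the simplex valid; the
alternative (clipping without renormalizing) was rejected because it
silently changes the other three proportions' ratios.

## Fitting

Population inference is deliberately two-stage: per-patient weighted
least squares on transformed scales (log for counts and SPD, logit for
proportions), then Gaussian maximum likelihood per parameter on the
family's latent scale across the individual optima, with latent-scale
correlations and pooled-residual error models. Stochastic-approximation
EM machinery is out of scope; two-stage estimation is transparent,
deterministic, and adequate for cohorts where every patient has usable
blood data.

Layers are fitted sequentially, each freezing its predecessors'
parameters — in the order 1, 2, 4, 3, 5 rather than 1–5. The phenotype
chain (layer 4) is independent of tumour dynamics, while lesion killing
(layer 3) is phenotype-weighted, so estimating the chain first lets the
lesion layer use it; the freezing contract is unchanged and a missing
lesion stream still skips exactly layers 3 and 5.

Initial conditions are anchored at baseline measurements when a day-≤1
visit exists: C₀ at the measured baseline CAR count, B₀ at the baseline
SPD, both phenotype vectors at the baseline flow panel. Layer 2 contains
no antigen term, so a least-squares fit of C₀ against data generated by
the full model would absorb the whole antigen-driven expansion into the
initial condition; the baseline count is a direct measurement of C₀ and
is used as such. φ is a structural constant, never fitted: without lesion
CAR counts it enters only through κφ and φ/(1+φ) and is unidentifiable.

Between the first and last imaging visits the SPD series is densified by
LDH interpolation. The interpolation used for fitting is affine in LDH on
the **volume** scale (endpoint SPDs converted to sphere volumes,
interpolated, converted back): LDH tracks total burden, which is
proportional to volume, whereas SPD scales as V^(2/3) — interpolating
affinely on the SPD scale distorts the interior of the series and
measurably biases the lesion growth and killing rates. The plain
SPD-scale map remains available (and is the `interpolate_tumour_burden()`
default) for burden summaries where the V^(2/3) distinction is
irrelevant.

### Numerical choices

* Integration: `lsoda` (stiff-capable, adaptive) at rtol 10⁻⁸ /
  atol 10⁻¹⁰; tiny solver-noise negatives (below 100·atol) are clamped to
  zero, anything larger is an error with the offending parameters
  reported.
* Optimization: `nlminb` box-bounded on log/logit-transformed parameters,
  5 jittered restarts by default (restart seeds derived from the control
  seed), best optimum kept.
* A weak quadratic ridge (10⁻⁴, transformed scale, toward the starting
  values) breaks flat likelihood ridges deterministically — the
  motivating case is γ→0, where model 1 degenerates to a pure exponential
  and only ρ₀ − δ is identified, sending unpenalized optima to the box
  bounds. The weight was chosen as the largest of 10⁻³/10⁻⁴/10⁻⁵ that
  leaves noise-free single-patient recovery below 1% relative error; it
  is orders of magnitude below the data term for identified parameters.
* Degenerate inputs: all-missing observables are dropped with a warning;
  an all-zero CAR series yields Cmax = 0 at tmax = 0; zero baseline SPD
  makes the Lugano relative change undefined and is rejected.

## Sensitivity suite

Five families over the outputs Cmax, tmax, AUC, the ordinal-coded Lugano
class (CR=0 … PD=3) and the proportional tumour-size change:

1. **eFAST** (own implementation — no extended-FAST implementation exists
   in the dependency stack): classic search-curve sampling with
   interference factor 4, N points per curve, M random-phase resample
   curves per factor, first-order indices from the harmonics of the
   driving frequency and total indices from the complementary spectrum.
   The estimator reproduces the analytic 0.5/0.5 variance shares of an
   additive two-factor function within 0.05 at N = 1000 (acceptance
   suite). The minimum N for the frequency selection (65 at Mi = 4) is
   reported when violated.
2. **Random forest importance**, 100 trees, trained on all rows (the
   forest never predicts), node-impurity importances normalized to sum
   to 1. All features are candidates at every split so importance
   concentrates on true drivers.
3. **Spearman rank correlation** between parameters and outputs
   (mid-ranks on ties), on either virtual-patient draws or fitted optima.
4. **Local 1% one-at-a-time** around fitted optima: mean absolute
   relative output change over both directions and all patients,
   validated against central finite differences within 5%.
5. A **dummy parameter** rides along in every global design; heatmap
   normalization subtracts its apparent sensitivity where applicable,
   floors at zero, and rescales each method-output row to max 1.

Global bounds come from the population model: location ± 3 latent
standard deviations mapped to the natural scale, proportions truncated to
(0, 1), zero-spread structural parameters dropped. Failed simulations
inside global sweeps are median-imputed and counted; above 5% the run
aborts rather than report indices from a broken design.

## Synthetic cohorts: what they do and do not emulate

The generator draws truth parameters from the default population above,
simulates the full model, and emits trial-like tables: blood counts on a
tapering visit schedule, weekly flow panels renormalized after noise,
SPD at only the first and last visits (lesion data really are that
sparse), blood CD19⁺ pinned at the LOQ, LDH affine in lesion volume, and
IL-7/IL-15 as noisy decaying exponentials sharing each patient's γ — so
the cytokine–proliferation correlation that motivates the
lymphodepletion interpretation exists by construction and the
correlation machinery can be exercised against a known answer. A
responder mode raises ρ_a for half the cohort to give the ranking and
decomposition tools a known good/poor contrast, and `degrade()` adds
uniform missingness that never removes a baseline visit.

Not emulated: real assay artefacts (detection limits other than the
CD19⁺ floor, batch effects), informative dropout, multi-lesion imaging,
inter-occasion variability, and any pharmacology of the conditioning
regimen itself. Passing the recovery tests therefore shows the pipeline
is self-consistent — that the estimator recovers the generator's truth
under the stated noise — not that the model is correct for any real
cohort.

Default problem sizes keep the whole test suite desk-scale: cohorts of
2–20 patients in the fitting tests, 100 draws for the hierarchy
property, 200 virtual patients for the parameter-alteration contrast,
N = 1000 per curve for the eFAST oracle.

## Known limitations

* Everything downstream of day 30 — persistence, late relapse, memory
  re-expansion — is outside the model by design.
* The phenotype-uniform proliferation assumption nullifies phenotype
  effects on total counts; only killing feels composition. A model
  relaxing this would need a regulation mechanism to keep proportions
  bounded.
* Two-stage population estimation understates uncertainty relative to
  full nonlinear mixed-effects inference, particularly for patients with
  sparse data.
* Medians of heavy-tailed simulated outputs at cohort sizes around 10³
  carry Monte-Carlo noise of a few percent; conclusions should rest on
  ordering and contrasts (as in the alteration experiment) rather than
  on tight numeric equality between independent cohorts.
* The κ_EM/κ_EFF pair, φ, and K_half in the always-saturated regime are
  structurally or practically unidentifiable from blood-plus-sparse-SPD
  data; the package fixes or anchors them rather than pretending to
  estimate them.
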