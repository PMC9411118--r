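---
title: "Methods: phosphorus limits on photosynthetic capacity, leaf to canopy"
author: "phoslim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphorus limits on photosynthetic capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoslim)
```

## The scientific problem

Leaf nitrogen has long been treated as *the* nutrient that sets
photosynthetic capacity: most of a leaf's N sits in Rubisco and the
thylakoid proteins, so carboxylation capacity (`Vcmax`) and
electron-transport capacity (`Jmax`) rise with leaf N, and terrestrial
biosphere models encode exactly that. On the old, highly weathered soils
that carry most tropical and subtropical forest, however, phosphorus is
chronically scarce, and P has its own biochemical roles — ATP, RuBP
regeneration, sugar phosphates — that are distinct from N's. The
pattern this package quantifies is that at low leaf P the V–N and J–N
relationships flatten: P-starved leaves gain much less photosynthetic
capacity per unit of extra N. `phoslim` implements the full chain needed
to estimate, test and apply that interaction: A–Ci curve inversion with
temperature normalisation, quality control and species-at-site
aggregation, a log–log regression framework with class and interaction
tests, forward predictor equations `Vcmax/Jmax = f(N, P)`, and a
simplified canopy scenario contrast.

## The FvCB model and its temperature machinery

Net assimilation is `min(Ac, Aj) − Rd` with

* `Ac = Vcmax (Ci − Γ*) / (Ci + Km)`, `Km = Kc (1 + O / Ko)`
* `Aj = J (Ci − Γ*) / (4 Ci + 8 Γ*)`, and `J = Jmax` at saturating light.

Assumptions worth stating explicitly:

* **Saturating light for curve fitting.** Compiled A–Ci curves are
  measured light-saturated, so no light-response function enters the
  inversion. The canopy module *does* use a light response (below).
* **Infinite mesophyll conductance.** `Ci` stands for the chloroplast
  CO2 mole fraction; all rates are "apparent". A finite-gm analysis would
  rescale parameters but not the log–log slope structure downstream.
* **Two limitations only.** Triose-phosphate-utilisation limitation is
  not modelled; curves are fitted with the Rubisco and RuBP-regeneration
  states alone, taking the hard minimum (no smoothing). The hard minimum
  keeps the objective piecewise smooth and matches standard fitting
  practice.

Kinetic constants default to the tobacco-derived set
(`Kc25 = 404.9 µmol mol⁻¹`, `Ko25 = 278.4 mmol mol⁻¹`,
`Γ*25 = 42.75 µmol mol⁻¹`, `O = 210 mmol mol⁻¹`, activation energies
79 430 / 36 380 / 37 830 J mol⁻¹) and are fully overridable through
`kinetic_constants()` or a YAML file read by `read_kinetics()`. The
choice of kinetic set rescales fitted values multiplicatively and leaves
every log–log slope invariant (a property the test suite checks), so
none of the regression conclusions hinge on it.

Temperature responses: `Kc`, `Ko`, `Γ*` and `Rd` follow Arrhenius
scaling; `Vcmax` and `Jmax` follow the peaked (deactivating) form with
`Hd = 200 000 J mol⁻¹`, `Ha_V = 71 513`, `Ha_J = 49 884 J mol⁻¹` and
entropy terms that acclimate linearly to growth temperature
(`ΔS_V = 668.39 − 1.07 Tgrowth`, `ΔS_J = 659.70 − 0.75 Tgrowth`
J mol⁻¹ K⁻¹). `normalize_to_25()` is the exact algebraic inverse of
`scale_to_leaf_temperature()`; the round trip is identity to < 1e-10
relative. Whether day respiration should itself be
temperature-corrected before normalisation is genuinely open; we apply
Arrhenius with `Ea_Rd = 46 390 J mol⁻¹` and flag it as an assumption —
`Rd` is a nuisance parameter for every downstream analysis here.

## A–Ci inversion and quality control

`fit_aci()` minimises the sum of squared residuals of the forward model
over `(Vcmax25, Jmax25, Rd25)` with bounded Levenberg–Marquardt from
three deterministic starts (spread across the plausible range so the
fit is seed-free and insensitive to a single bad basin). Because each
point is forward-scaled to its own leaf temperature, the estimates are
normalised to 25 °C by construction: a curve measured at 30 °C returns
the 25 °C parameters.

The curve-fit CV is defined as `100 · SE(Vcmax25) / Vcmax25` with the SE
taken from the Jacobian-based covariance at the optimum. The historical
criterion was phrased against "the initial slope" of the curve, which in
the FvCB parameterisation *is* the Vcmax-controlled region; applying it
to the fitted parameter's relative SE is the cleanest computable form,
and it naturally flags curves whose Ci range never expresses one of the
two limitations (the parameter then has a huge SE). Identifiability is
also checked directly: a warning fires unless the Ci range spans below
250 and above 400 µmol mol⁻¹.

`qc_filter()` applies three removal rules — mean
`gsw < 30 mmol H2O m⁻² s⁻¹`, `Amass ≤ 20 nmol g⁻¹ s⁻¹`, CV ≥ 30 % — and
tags each removed record with *every* rule it fails; records missing a
QC field are removed with a `MISSING_FIELD` tag rather than silently
kept. A fourth historical filter (dropping drought-period measurements
"as much as possible") has no computable definition and is not
implemented. `species_site_means()` averages leaves arithmetically
within species × site on each basis (mass-based and area-based fields
averaged directly, not as ratios of means — the averaging order is
otherwise arbitrary and this choice keeps each basis internally
consistent); the mass/area identity `X_mass = 1000 X_area / Ma` is
enforced per leaf, not on group means.

## The regression framework

All trait regressions are on natural logs: power-law relationships
become straight lines and a slope is an elasticity. `log_ols()` is
plain OLS; `sma_fit()` is the standardised major axis
(`slope = sign(r) · sd(ln y)/sd(ln x)`), the symmetric estimator used as
a supporting approach because OLS attenuates slopes when x carries
error. The identity `|b_SMA| = |b_OLS| / |r|` holds on every dataset and
is tested to 1e-10.

Class structure is tested with `separate_slopes_test()`: fit
`ln y ~ ln x × group` and read the F-test of the interaction term — a
significant interaction means separate rather than parallel slopes. The
leaf-P classing boundary defaults to 0.92 mg g⁻¹ (dataset-median
convention; `P ≥ 0.92` is "moderate"), and `threshold_sweep()` refits
the class slopes across a grid of alternative thresholds to show the
conclusion is not an artefact of the boundary. No multiple-testing
correction is applied across continent-vs-remainder tests: raw p-values
mirror standard reporting practice for these tables, and the null
finding (no continent effect) is not sensitive to it.

`np_interaction_model()` fits `ln y ~ ln N + ln P + ln N · ln P`
(optionally `+ ln Ma`). A positive interaction coefficient is the
quantitative statement of the P constraint: the N-elasticity of capacity
grows with leaf P. The squared lnN–lnP correlation is reported alongside
as a collinearity diagnostic. Derived contrasts are closed forms:
`fold_change(b, k) = k^b`, and `class_contrast_at()` evaluates two class
lines at a reference N and returns the percent gap,
`100 (exp(Δ) − 1)`.

Residual diagnostics are a human-inspection step (Q-Q and
residual-vs-fitted plots via the returned `lm` objects), not automated
gates.

## Predictor equations and the P-acquisition scalar

Two coefficient sets ship as data
(`inst/extdata/np_coefficients.yaml`), selectable by name and never
mixed silently:

* `"methods"` — the equations used inside the land-surface experiment,
  without the N × P interaction, on both mass and area bases (the
  area-based set is an independent fit to area-based data, *not* a
  conversion of the mass-based set);
* `"table2"` — the full-dataset interaction models (the recommended set
  for biosphere models; it yields a leaf-P effect on canopy GPP roughly
  15 % stronger than the `"methods"` set).

Because the mass- and area-based equations were fitted independently,
chaining the mass equations through the `Ma = f(N, P)` model only
*approximately* reproduces the area equations; the package checks rank
agreement (Spearman > 0.95 over the core trait range) and exposes both
routes explicitly.

`p_acquisition_scalar()` is the sigmoid `1/(1 + exp(−(N:P)/2 + 10))`:
0.5 exactly at N:P = 20, rising steeply between 15 and 25 — the range
where plant communities shift from N- to P-limitation. N:P is always a
mass ratio (g N per g P). `unlimited_p_leaf()` encodes the P-unlimited
diagnostic: leaf P raised to `Nmass / 5`, the minimum observed N:P.

## The canopy scenario engine

`big_leaf_gpp()` is deliberately simple plumbing, not a land-surface
model: leaf `Vcmax_mass`/`Jmax_mass` from the predictor equations →
area basis via the cell's `Ma` → big-leaf canopy capacity with Beer-law
absorption (`(1 − e^{−kL})/k`, `k = 0.5`) → gross `min(Ac, Aj)`
integrated over a sinusoidal 12-h photoperiod (non-rectangular
hyperbola light response for `J`, curvature `θ = 0.7`, quantum yield
`α = 0.3 e⁻ photon⁻¹`) at fixed `Ci/Ca = 0.7` and leaf temperature equal
to growth temperature, × 365 days, converted at 12.011 µg C µmol⁻¹. GPP
is gross: `Rd` is never subtracted. Every constant is an argument;
none is a published value. `scenario_compare()` runs each cell twice
(observed P, and P clamped up to `Nmass/5`) and `zonal_aggregate()`
produces cosine-weighted 2° band means. The module is deterministic and
bit-reproducible.

What this module can and cannot show: it verifies *structure and
direction* — unlimited-P GPP ≥ limited-P GPP cell-wise, zero contrast at
N:P = 5, reductions largest where P is lowest. The published
whole-tropics magnitudes (a 36 % GPP reduction, a ~70 Pg C difference,
zonal means near 1800 vs ~3000 g C m⁻² y⁻¹) come from a full
land-surface model with historical climate forcing, land cover and
nutrient-deposition history, and spin-up; they are explicitly not
reproduction targets for a desk-scale big-leaf engine.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their arguments plus a mandatory
seed, and they restore the caller's RNG state.

`gen_leaf_traits()` draws `(ln N, ln P)` bivariate normal with target
squared correlation 0.39. Defaults place the medians at the dataset
conventions — `Nmass` at 20 mg g⁻¹, `Pmass` at 0.92 mg g⁻¹ — with
log-sds 0.35 and 0.63; the P sd is set so a sample of ~450 spans
roughly 50-fold in P (range ≈ 6.2 sd at that n), matching the spread
that makes the P signal detectable at all. Responses come from a chosen
coefficient set plus Gaussian log-scale residuals whose sd is calibrated
to the printed r² by the closed form
`sd² = var(linear predictor) · (1 − r²)/r²`. Noise is Gaussian on the
log scale for traits (consistent with the log-transformed analyses) and
on the linear scale for A–Ci curves (instrument noise). Continent labels
are assigned uniformly at random with no continent effect — matching
the empirical null finding — so continent-covariate tests are calibrated
against a true null. Residual sds are nowhere published; calibrating
them to printed r² values is a reconstruction, and generated datasets
are labelled as synthetic wherever they are written.

`gen_jv_dataset()` uses the analytic uniform-x version of the same
calibration (`var(fitted) = slope² · width²/12`); an independent
grid-search oracle in the test suite confirms the closed form. What the
generators do *not* emulate: phylogenetic structure, site climate
gradients, family composition, or any dependence between the residuals
of different responses. Passing parameter-recovery tests therefore
demonstrates that the estimators are unbiased and calibrated under the
assumed error model — not that the field data satisfy that model.

## Numerical choices and problem sizes

* Optimiser bounds `[1, 1000] × [2, 2000] × [0, 50]`; three fixed
  starts; convergence tolerances 1e-12; non-convergence returns a
  flagged fit, never an error or a silent value.
* Ties between `Ac` and `Aj` resolve by value equality (hard `pmin`).
* Temperatures are Kelvin internally, Celsius at every interface.
* Monte-Carlo checks in the tests and acceptance script use 100–500
  replicates at the study's sample sizes (n = 111 for the J–V line,
  n = 446 for trait tables, n = 10 000 for the correlation
  calibration) — large enough that Monte-Carlo error is well inside
  each assertion's tolerance, and small enough that the full suite runs
  in well under a minute.
* The power of the separate-slopes test under the documented class
  structure (slopes 0.736 vs 0.367 with r² 0.26/0.08 at n = 231/212) is
  analytically ≈ 0.88 at α = 0.05 — each slope's SE,
  `b·√((1−r²)/r²)/√n`, is independent of the x spread — and the test
  suite asserts the corresponding empirical rate, not a higher one.

## Known limitations

* C4 photosynthesis, stomatal models, energy balance, TPU limitation
  and mesophyll conductance fitting are out of scope.
* The canopy engine has no P biogeochemistry: observed (or synthetic)
  leaf P is taken as given, where a full model would compute it from a
  P cycle; the P-acquisition scalar is reported as a diagnostic only and
  feeds back on nothing.
* The Jmax–N "all data" single-factor line in the historical table set
  is internally inconsistent with its class-wise counterparts and is not
  used or verified anywhere in this package.
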