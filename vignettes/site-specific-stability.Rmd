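---
title: "Site-specific fold stability curves from 2D NMR peak volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific fold stability curves from 2D NMR peak volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldstab)
```

## The problem

Most probes of protein stability (CD, calorimetry, fluorescence) report a
single, global denaturation curve: the protein is modelled as collapsing
from folded to unfolded in one cooperative, all-or-none event. A 2D
^15^N-HSQC spectrum instead gives one peak per backbone amide, so a
temperature series of HSQC spectra yields one melting curve *per residue*.
For a protein that unfolds both on heating and on cooling above 0 °C —
yeast frataxin (Yfh1) at low ionic strength is the canonical example — each
residue's peak-volume series can be converted to a per-residue *stability
curve* ΔG(T), covering both the cold- and heat-denaturation transitions.

`foldstab` implements that analysis end to end: volume normalisation,
population anchoring, Gibbs–Helmholtz fitting with covariance-based error
bands, a structure-based burial score (RAD) to select the buried
hydrophobic-core reporters that define the reference behaviour,
classification of all other residues against that reference, and a
synthetic-data generator that emulates the NMR artefacts capable of
distorting apparent stability.

## The two-state model

Unfolding is treated as a two-state equilibrium F ⇌ U with a
temperature-independent heat-capacity difference ΔC~p~. The free energy of
unfolding (sign convention ΔG = G~U~ − G~F~, positive when folded is
stable) follows the modified Gibbs–Helmholtz form

$$\Delta G(T) = \Delta H_m\left(1 - \frac{T}{T_m}\right) +
  \Delta C_p\left[(T - T_m) - T\ln\frac{T}{T_m}\right],$$

an inverted-parabola-like curve with zeros at the cold-denaturation
temperature T~c~ and the melting temperature T~m~, maximum at the
zero-entropy temperature

$$T_s = T_m\,\exp\!\left[-\frac{\Delta H_m}{T_m\,\Delta C_p}\right],$$

and curvature ∂²ΔG/∂T² = −ΔC~p~/T. Populations are Boltzmann:
f~U~(T) = e^−ΔG/RT^/(1 + e^−ΔG/RT^) with R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹;
the package works exclusively in kcal and absolute Kelvin (Celsius never
enters the data model, which avoids the unit ambiguity common in the
melting literature).

Derived quantities reported with every fit: ΔS~m~ = ΔH~m~/T~m~, T~s~,
T~c~ (bracketed root search on (150 K, T~s~), polished to
|ΔG| < 10⁻⁹ kcal/mol), and ΔH~s~ = ΔH~m~ + ΔC~p~(T~s~ − T~m~), the
enthalpy at maximum stability, which equals the peak free energy because
the entropy change vanishes at T~s~.

```{r}
p <- thermo_params(28.5, 298.2, 3.73)  # a buried leucine of Yfh1
p
```

## From peak volumes to populations

Raw per-residue peak volumes are normalised by a reference peak recorded at
the same temperature (an internal standard that cancels instrumental
non-linearities). The apparent folded fraction is

$$a(T) = \frac{V(T) - V_U}{V_F - V_U},$$

with V~F~ the maximum normalised volume and V~U~ the unfolded-state
baseline. Two baseline rules are provided:

* `"top"` (default): V~U~ is the volume at the highest measured
  temperature, where the protein is assumed fully unfolded. This is the
  standard analysis choice; the same top-temperature point is excluded from
  the fit, because there f~U~ = 1 holds by assumption rather than
  measurement.
* `"zero"`: V~U~ = 0, appropriate when the folded-peak signal carries no
  unfolded-state contribution — exactly the situation for synthetic data
  generated proportional to f~F~(T). Under the `"top"` rule such data
  cannot round-trip exactly, because f~F~ at the top temperature is small
  but not zero; the residual is an affine distortion of the populations
  that barely moves T~m~ and T~c~ (the curve's zeros sit at f~U~ = 0.5,
  which an affine map leaves almost fixed) but is visible in ΔH~m~.

The apparent fractions are then *anchored*: scaled so the folded population
at the measured temperature nearest the anchor (298.15 K by default)
equals a stated value — 70% for real Yfh1 data, where that population is
known independently from CD. The published procedure states the 70%
assumption but not the algebra; multiplying the apparent folded fraction by
`anchor_fraction / a(anchor_T)` is one consistent choice, applied here,
logged in every run, and switchable off (`anchor_fraction = NA`).
Populations are clipped to [0, 1] after anchoring and the clipped count is
reported, never hidden.

## Fitting

`fit_stability()` estimates (ΔH~m~, T~m~, ΔC~p~) by Levenberg–Marquardt
least squares on the unfolded fractions (uniform weights — no weighting
scheme is part of the published procedure; populations are fitted on their
natural scale, not log-transformed). Start values are ΔH~m~ = 25 kcal/mol
and ΔC~p~ = 2.5 kcal/mol/K (the centre of the published per-residue
ranges) with T~m~ at the steepest high-temperature population drop; on
failure the fit restarts from five deterministically jittered points. At
least six distinct temperatures are required for a three-parameter fit
with redundancy. Fits that do not converge, or converge to unphysical
optima (ΔH~m~ ≤ 0, ΔC~p~ ≤ 0, T~m~ outside 250–400 K), are *flagged* and
carried through every downstream table with their flag — unrealistic
numbers are how wrong model assumptions manifest, so they must stay
visible.

The parameter covariance comes from the final Jacobian
(σ² (JᵀJ)⁻¹), and uncertainty is propagated onto the free-energy scale by
the covariance (delta) method with the closed-form gradient

$$g(T) = \left(1 - \tfrac{T}{T_m},\;
  \Delta H_m \tfrac{T}{T_m^2} + \Delta C_p(\tfrac{T}{T_m} - 1),\;
  (T - T_m) - T\ln\tfrac{T}{T_m}\right),$$

giving σ~ΔG~(T)² = g(T)ᵀ Σ g(T) — the grey bands drawn by
`plot.stab_fit()`. The tests verify this band against a 10⁵-draw
Monte-Carlo sample to within 2%.

```{r}
T <- seq(278, 313, by = 2.5)
pop <- population_series("70 Leu", T, folded_fraction(T, gibbs_helmholtz(T, p)))
fit <- fit_stability(pop)
summary(fit)
```

## Selecting buried-core reporters: the RAD score

A residue reports faithfully on global unfolding only if it is buried in
the hydrophobic core. The RAD score of a backbone amide nitrogen is

$$\mathrm{RAD} = D \times RA \times 100,$$

where *RA* is the nitrogen's solvent-accessible surface area as a fraction
of its whole residue's SASA (sphere-sampling with a 1.4 Å probe and ≥960
quasi-uniform test points per atom), and *D* is an exteriority index in
[0, 1]: the fraction of test points on a 4 Å probe sphere around the atom
that fall outside the protein's occupied volume (van der Waals spheres
expanded by 1.4 Å so interstitial packing gaps count as interior). An
isolated atom has D = 1; a deeply buried one tends to 0. Heavy atoms only,
with fixed van der Waals radii (N 1.55, C 1.70, O 1.52, S 1.80 Å) — no
hydrogens are added, matching the convention used for crystallographic
input.

Two deliberate design points. First, although the original description
calls D a "distance", published RAD values only make sense if large RAD
means *exposed* (buried-core residues have RAD < 0.1 while a fully exposed
valine scores 48.2), so D is implemented as a normalised exteriority, not
a Euclidean depth in Å. Second, the exact indices of the external
depth/accessibility programs used originally are not replicated; a
precomputed D/RA (or RAD) table can be supplied instead
(`read_rad_table()`), and that path reproduces published selections
exactly. The 4 Å probe radius is configurable; it must exceed van der
Waals contact distances to sense burial at all.

```{r}
tab <- yfh1_thermo_table()
select_by_rad(tab, 0.1)   # the 11 buried-core reporters of Yfh1
```

## Reference curve and outlier classification

The residues with RAD < 0.1 define the reference: their folded populations
are averaged per temperature (arithmetic mean over members measured at that
temperature) and the average series is fitted once. Averaging populations,
not parameters, is the default because it weighs every temperature point;
a parameter-averaging mode exists for comparison. Members whose own fits
are flagged are dropped from the reference.

Each residue is then compared with the reference through
ΔT~m~ = T~m~ − T~m~^ref^ and ΔT~c~ = T~c~ − T~c~^ref^. "Differs on
average" is implemented as the mean of the absolute shifts,
(|ΔT~m~| + |ΔT~c~|)/2: below 1.5 K the residue is *consistent* with the
global transition, above 3 K it is an *outlier*; the band in between —
which the published analysis leaves unassigned — is an explicit
*intermediate* category rather than a silent gap. Flagged fits are
*unclassifiable*. Both thresholds are configurable.

Differences are decomposed into the classic three mechanisms of
thermostability change:

* **I** — ΔH~s~ changes: the curve lifts or drops, shape and T~s~ intact;
* **II** — ΔC~p~ changes: the curve broadens or sharpens around an
  unchanged maximum (curvature −ΔC~p~/T);
* **III** — the whole curve translates along T (a T~s~ shift, entropy
  driven).

Real curves are mixtures, so every component exceeding 10% (configurable)
of its reference scale is labelled. The scales are |ΔH~s~^ref^| for I and
ΔC~p~^ref^ for II; for III, a fraction of an absolute Kelvin temperature
would be meaningless, so the T~s~ shift is scaled against the reference
stability width T~m~^ref^ − T~c~^ref^ (≈18 K for Yfh1, making the default
label threshold ≈1.8 K).

A useful identity behind the mechanism constructions: with ΔC~p~ fixed,
the Gibbs–Helmholtz family is *linear* in the reparameterisation
ΔG(T) = c₀ + c₁T − ΔC~p~ T ln T (`gh_linear_coefs()` /
`gh_from_linear()`). A constant lift (mechanism I) stays in the family and
leaves T~s~ = exp(c₁/ΔC~p~ − 1) untouched; an exact least-squares
projection of any target curve onto the family is ordinary linear
regression (`fit_gibbs_helmholtz_dg()`), which is also how the package
fits naive intensity-derived ΔG̃ values and how the tests construct pure
mechanism-III translates.

Applied to the published Yfh1 table with a mean-of-core reference
(T~m~ ≈ 300.3 K, T~c~ ≈ 282.4 K), the reported ill-behaved residues show
the signature this analysis was built to detect: a moderate mean ΔT~m~
(≈ −2.7 K) and a much larger mean ΔT~c~ (≈ −4.0 K) — cold denaturation
shifts far more than heat denaturation, consistent with cold unfolding
being driven by hydration of the core rather than by conformational
entropy. The exact published 18/21-residue well-/ill-behaved lists are
*not* reproducible from the printed table alone (the reference curve's
fitted parameters were never printed, and one RAD < 0.1 member is itself
listed ill-behaved, which no parameter-mean reference can reproduce); the
package therefore asserts the qualitative geometry, not the membership.

## The synthetic-data generator

`generate_series()` emulates the measurement: folded-peak volumes exactly
proportional to f~F~(T) on the standard 278–313 K grid in 2.5 K steps,
reference volumes of 1 (or a smooth polynomial drift, so normalisation has
something to correct), multiplicative log-normal noise
(V·e^σZ^, median-unbiased; default σ = 3%, the typical volume
reproducibility of well-resolved HSQC peaks), and three optional artefact
attenuations applied multiplicatively to the folded peak:

* **exchange broadening** during the INEPT transfers, in the fast-exchange
  limit: e^−R_ex τ^ with R~ex~ = f~F~f~U~Δω²/k~ex~(T), τ = 5.4 ms
  (≈ 1/(2·93 Hz)); k~ex~ = 0 with Δω > 0 is the slow-exchange branch where
  the folded peak is separate and unbroadened;
* **differential relaxation**: Bloch decay e^−R₂(T)·t^ with per-state,
  linear-in-T rates;
* **solvent hydrogen exchange**: e^−k_hx(T)·w·t^ with the rate doubling or
  tripling per 10 K and an exposure weight w ∈ [0, 1].

These are deliberately standard first-order attenuation models with every
constant configurable — not a full Bloch–McConnell evolution through the
pulse sequence, and not a replication of any particular published
simulation's equations or values. What the generator supports is the
qualitative, testable claim: artefacts of this kind distort the apparent
ΔH~m~, T~m~ and T~c~, yet the temperature of maximum stability T~s~ is
well reproduced. `ts_robustness_experiment()` runs that experiment both
through the full pipeline and through the "naive" route
ΔG̃(T) = −RT ln((1 − I~f~)/I~f~) applied directly to observed intensity
fractions. Under moderate attenuation (all factors ≥ 0.7) the naive
route's median T~s~ error stays ≈0.3 K while its T~m~/T~c~ errors reach
several Kelvin.

For synthetic data the anchoring fraction defaults to the *true*
f~F~(anchor T) of the generating parameters — ground truth is known, so
recovery experiments measure the estimator, not an anchoring mismatch. The
anchor temperature snaps to the nearest grid point, matching the
downstream transform. All randomness flows through the spec's single seed
(restoring the caller's RNG state afterwards); identical spec + seed gives
bit-identical data.

What the generator does *not* emulate — intermediate-exchange lineshapes,
three-state or downhill unfolding, field-dependent effects, peak overlap,
baseline distortions — bounds what passing tests show: parameter recovery
and T~s~ robustness hold for well-resolved two-state reporters, which is
precisely the regime the RAD selection is designed to find.

## Numerical choices and problem sizes

* Gas constant 1.987×10⁻³ kcal mol⁻¹ K⁻¹ (the table units of the field).
* T~c~: `uniroot` on (150 K, T~s~) plus Newton polish; below 150 K cold
  denaturation is reported as unobservable (`NA` with a warning), and
  ΔC~p~ ≤ 0 is an error (the linear-limit curve has a single root at T~m~).
* Recovery experiments: 100 replicates at 3% noise on the 15-point grid
  (median |T̂~m~ − T~m~| ≈ 0.25 K, median |T̂~c~ − T~c~| ≈ 0.27 K);
  robustness: 4 perturbation settings × 25 replicates. These sizes give
  stable medians in seconds on one core.
* SASA/exteriority use 960 deterministic golden-spiral points per atom;
  the test oracle is independent 10⁴-point rejection sampling.
* Property tests sweep 1000 random parameter draws
  (ΔH~m~ ∈ [5, 50], T~m~ ∈ [280, 320], ΔC~p~ ∈ [0.5, 5]) for the curve's
  sign structure and 50 draws for end-to-end noiseless recovery to 10⁻⁶.

## Known limitations

* The printed per-residue table is internally rounded; quantities derived
  from it (e.g. ΔS~m~ = ΔH~m~/T~m~) agree with printed values to one unit
  in the last printed decimal, not to half an ulp, and counts at RAD
  thresholds can differ by one where printed scores sit exactly on the
  boundary (two residues print RAD = 0.20).
* The anchoring algebra (multiplicative rescale at one temperature) is one
  consistent reading of the published 70% assumption, not a verified
  replication of the original scripts.
* A residue whose true curve is strongly shifted relative to the global
  anchor assumption can saturate at f~F~ = 1 after anchoring and lose its
  cold limb; such fits come back flagged rather than wrong, which is the
  intended behaviour but does mean strongly divergent outliers may be
  unclassifiable instead of quantified.
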