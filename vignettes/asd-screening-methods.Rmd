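---
title: "Methods: screening and evaluating amorphous solid dispersions with asdtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and evaluating amorphous solid dispersions with asdtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdtools)
```

## The problem

Poorly water-soluble drugs (BCS Class II) dissolve too slowly to be
absorbed reliably, even though they permeate well. A standard remedy is
the amorphous solid dispersion (ASD), ideally a *glassy solution*: the
drug molecularly dissolved in an amorphous polymer, so no crystal lattice
has to be broken on dissolution. Developing one raises a chain of
quantitative questions that this package answers in order:

1. Which polymers are *miscible* with the drug? (Hansen solubility
   parameters, Flory–Huggins interaction parameter)
2. Did processing actually produce *one* amorphous phase?
   (Gordon–Taylor prediction vs the measured glass transition)
3. Do the milled granules *flow* well enough to tablet, and do the
   tablets pass QC? (Carr's index, USP <1174>; friability,
   disintegration, content)
4. Is the dissolution profile *different from* (better than) the
   reference product? (similarity factor f2, release-kinetics models)
5. Does the improvement survive *in vivo*? (non-compartmental PK,
   relative bioavailability, ANOVA)

The bundled `material_library()` carries literature constants for
glibenclamide (GLB, an antidiabetic sulfonylurea) and three carriers
(PVP K25, PVP VA64, Soluplus), which also serve as the worked example
throughout.

## Miscibility screening

The total solubility parameter combines Hansen's dispersion, polar and
hydrogen-bonding contributions, \(\delta_t = (\delta_d^2 + \delta_p^2 +
\delta_h^2)^{1/2}\) (MPa^1/2). Two materials with similar cohesive energy
density — small \(\Delta\delta = |\delta_{drug} - \delta_{poly}|\) — are
likely miscible. The conventional screening thresholds are
\(\Delta\delta < 7\) MPa^1/2 (miscible) and \(> 10\) (immiscible); both
are stated as strict inequalities, so a value exactly on a threshold is
classed into the intermediate band. The thresholds are heuristics, not
thermodynamics: they rank candidate carriers, nothing more.

The Flory–Huggins parameter sharpens the same information into a
free-energy statement:
\[\chi = \frac{V_d\,(\Delta\delta)^2}{R\,T},\]
with \(V_d\) the drug's molar volume (molar mass over amorphous true
density, cm³/mol), \(R = 8.314\) J mol⁻¹ K⁻¹ and \(T = 298\) K by
default. Unit handling is exact rather than approximate: \(V_d\) in
m³/mol is the cm³ figure × 10⁻⁶ and \((\Delta\delta)^2\) in J/m³ is the
MPa figure × 10⁶, so the two factors cancel and the cm³/MPa arithmetic is
already dimensionless. \(\chi \le 0.5\) is classed favourable
(the criterion in use is "\(\chi > 0.5\) implies limited miscibility",
so the boundary itself is favourable). A unit-careful SI recomputation is
kept as an independent oracle in the test suite (agreement to 1e-12
relative over random inputs).

For GLB the library's constants give \(\Delta\delta\) of 1.6 / 0.1 / 1.7
MPa^1/2 and \(\chi\) of 0.373 / 0.0015 / 0.421 against PVP K25 /
PVP VA64 / SOL — all miscible, VA64 near-ideally so. The GLB molar mass
(494.0 g/mol) is the standard chemical constant; the molar volume it
implies (360.6 cm³/mol) is consistent with all three published \(\chi\)
values simultaneously.

## Glass-transition prediction

A single Tg between the component Tgs is the accepted evidence of one
mixed amorphous phase. The Gordon–Taylor equation predicts it for ideal
mixing:
\[T_g = \frac{W_1 T_{g1} + K\,W_2 T_{g2}}{W_1 + K\,W_2},\qquad
K = \frac{\rho_1 T_{g1}}{\rho_2 T_{g2}}\ \text{(Simha–Boyer)},\]
with subscript 1 the lower-Tg component. The implementation resolves the
ordering itself, so callers pass drug, polymer and the drug weight
fraction.

**Temperature scale.** Thermodynamic convention evaluates both formulas
in kelvin. The literature predictions this package reproduces for the
GLB systems (129.90 / 95.85 / 70.25 °C at 10% drug load), however, only
emerge when Tg enters both equations in °C; kelvin mode gives, e.g.,
≈136 °C for the PVP K25 system. Both modes are provided:
`scale = "celsius"` is the default because it matches the published
convention for these constants, and `scale = "kelvin"` is the
conventional alternative. In kelvin mode, forcing
`k = Tg1/Tg2` (kelvin) reduces Gordon–Taylor exactly to the Fox
equation, which the tests use as an internal oracle.

The prediction is compared to the DSC-measured Tg with
`compare_tg()`; \(|\Delta T_g| \le 4\) °C (user-overridable) flags a
single-phase glassy solution, the sign convention being experimental
minus predicted. Physical mixtures typically miss by tens of degrees;
well-processed glassy solutions land within a few.

## Powder flow and tablet QC

Carr's index \(CI = (\rho_t - \rho_b)/\rho_t \times 100\) is
scale-invariant in the densities, so bulk/tapped may be in any common
unit. The USP <1174> verbal scale is published with small gaps between
bands (10–11, 15–16, …, and "extremely poor" starting at 38 while "very
poor" ends at 37); `classify_flow()` closes them with contiguous
half-open intervals (≤10, (10,15], (15,20], (20,25], (25,31], (31,37],
>37) so that classification is total and single-valued. Published CI
values for the GLB granules (18.1–18.9%) sit safely inside the "fair"
band under any convention.

Note that published CI values may be computed from unrounded density
replicates; `carrs_index()` always returns the value implied by the
densities it is given (e.g. 0.48/0.59 gives 18.6, whatever a rounded
table may print alongside).

Tablet acceptance uses strict upper bounds for friability (< 0.5%) and
disintegration (< 60 s) and an inclusive 90–110% band for content — the
boundary behaviours are tested explicitly.

## Dissolution similarity and release kinetics

The similarity factor
\[f_2 = 50\log_{10}\!\Big(100\,\big[1 + \tfrac1n\textstyle\sum_t (R_t -
T_t)^2\big]^{-1/2}\Big)\]
is 100 for identical profiles and falls as they separate; \(f_2 > 50\)
(≈ average 10% pointwise difference) declares similarity. Decisions made
here:

* **No interpolation inside f2.** Profiles must share a time grid;
  mismatched grids raise an error rather than being silently aligned.
* **Rapid-dissolution exemption.** When both profiles exceed 85%
  dissolved by 15 min, they are similar without an f2 value (the
  statistic is uninformative there). Since the standard 6-point grid
  (10/20/30/45/60/120 min) has no 15-min sample, the cumulative curves
  are linearly interpolated onto 15 min, anchored at the (0, 0) origin —
  the only interpolation in the module.
* **Truncation above 85% is available but off by default**
  (`truncate_85 = TRUE` keeps at most one point past joint 85%
  dissolution); published f2 values for these systems are consistent
  with full-profile sums.

Release kinetics are fitted by ordinary least squares on the four
standard linearisations — zero order (Q vs t), first order (ln(100−Q)
vs t, k reported positive in min⁻¹; natural log, so divide by 2.303 for
the log₁₀ variant), Higuchi (Q vs √t) and Hixson–Crowell
(100^{1/3} − (100−Q)^{1/3} vs t) — and ranked by the R² of the
linearised fit (the convention in the formulation literature; R² on the
back-transformed scale would differ). Intercepts are free by default;
strict Higuchi theory pins the intercept at zero and a
`through_origin` option imposes that. Points at ≥ 99.95% dissolved are
excluded from the log/cube-root transforms with a warning. Exact R² ties
resolve deterministically in the fixed model order with a warning.

A conditioning caveat worth knowing: the first-order linearisation
amplifies noise without bound as Q approaches 100, because the remaining
fraction under the log goes to zero. Recovery properties are therefore
demonstrated on curves that stay below ~90% at the last sample; fits to
essentially complete profiles should rest on the early points.

## Non-compartmental pharmacokinetics

Cmax and Tmax are read directly from the observations (ties on the
maximum break to the earliest time); AUC from 0 to the last sample is
the linear trapezoid (via `pracma::trapz`), with a (0, 0) anchor
prepended when sampling starts after dosing — an oral dose starts at
zero plasma concentration. No extrapolation to infinity is performed:
the quantity reported is AUC0–t. Relative bioavailability is the ratio
of *group-mean* AUCs × 100 (per-subject ratio averaging would require
paired designs). Group comparison uses the classical one-way ANOVA
(between/within mean squares on k−1, N−k df, via `stats::aov`),
significance at p < 0.05; the degenerate zero-within-variance case with
unequal means reports F = ∞, p = 0 with a flag instead of failing.
An optional LOQ (e.g. 0.01 µg/mL, a typical plasma assay lower bound)
zeroes sub-LOQ values before analysis; it is off by default.

## The synthetic-data generator

Laboratory dissolution and plasma curves are rarely published as data,
so the package generates inputs with the statistical structure the
analysis assumes:

* **Dissolution**: the chosen model's closed form on the 6-point grid,
  plus additive Gaussian vessel noise (truncated to [0, 100]), vessel
  count and seed in the spec. Defaults: the standard 6-point grid, 2%
  noise SD and 6 vessels in the study bundle — the shape of a USP
  apparatus-2 run.
* **Plasma**: the Bateman one-compartment oral-absorption curve
  \(C(t) = S\,\frac{k_a}{k_a-k_e}(e^{-k_e t} - e^{-k_a t})\) on the
  standard rat sampling grid (0.25–24 h), with independent lognormal
  between-subject factors (mean 1, CV as configured) on \(k_a\), \(k_e\)
  and the scale \(S = FD/V\). Defaults \(k_a = 1.5\)/h, \(k_e = 0.2\)/h
  put Tmax near 1.5 h, inside the sampling grid, and n = 5 subjects per
  group at 10% CV mirror a typical small-rodent bioavailability study.
  The confluent \(k_a = k_e\) limit is deliberately not implemented —
  callers perturb a rate instead.
* **Study bundle** (`make_study()`): four dissolution arms (slow and
  moderate Higuchi arms, two fast first-order arms) and four plasma
  cohorts whose group-mean AUC ratios are configured through the scale
  (AUC is linear in \(FD/V\)); defaults 1 / 0.95 / 1.25 / 2.5 give one
  reference-like, one equivalent, one moderately and one strongly
  enhanced group. One study seed derives per-stream sub-seeds, so every
  component is independently reproducible; generation saves and restores
  the caller's RNG state.

What the generator does **not** emulate: supersaturation/precipitation
kinetics, biphasic release mechanisms, correlated vessel effects,
assay-specific error structure, or the actual curves of any published
figure. Passing tests therefore demonstrate that the estimators recover
known generating parameters under idealised noise — not that any real
formulation behaves this way.

**Calibration.** With n = 5 and 10% CV, a single simulated study's
pipeline F% for a configured 2.5× exposure ratio scatters with SD ≈ 8.6%
of the target (500-seed calibration; mean 251.5%). End-to-end recovery
checks therefore average 25 studies (SE ≈ 1.7%) and allow three standard
errors. Kinetic-constant recovery at 2% noise uses 200 seeds per model
with the 6-vessel mean profile.

## Problem sizes and determinism

Everything in the package is desk-scale: the screening chain is closed
form, the fits are 4–6-point linear regressions, and the largest test
computations are 200–500 short simulations, so the full suite runs in
seconds on one CPU. All simulation is seed-deterministic; reports
serialised twice from the same inputs are byte-identical (numbers are
written at full precision, rounding happens only in text rendering).

## Known limitations

* The Hansen/Flory–Huggins screen uses literature total parameters; no
  group-contribution estimation of components is provided.
* Gordon–Taylor assumes ideal volume additivity; systems with strong
  specific interactions (e.g. hydrogen-bond networks) deviate, which is
  exactly what the ΔTg comparison is for.
* f2 comparisons use mean profiles; vessel-wise bootstrap variants are
  out of scope.
* No Korsmeyer–Peppas/Weibull release models, no melting-point
  depression phase diagrams, no bioequivalence confidence intervals, no
  terminal half-life estimation.
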