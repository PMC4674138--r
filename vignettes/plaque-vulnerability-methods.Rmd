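---
title: "Methods: morphological and stress-based plaque vulnerability indices"
author: "plaquevuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphological and stress-based plaque vulnerability indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquevuln)
```

## The problem

Rupture of an atherosclerotic coronary plaque is the precipitating event of
most acute coronary syndromes, and the morphology of the lesion — a large
lipid-rich necrotic core covered by a thin fibrous cap — is the strongest
anatomical predictor of rupture.  Intravascular ultrasound (IVUS) with
virtual-histology tissue classification yields, for every imaged
cross-section, segmented contours of the lumen, the outer vessel wall, and
any necrotic-core or calcification regions.  `plaquevuln` turns such
contour sets into quantitative vulnerability assessments: per-slice
morphological measurements, ordinal 0–4 vulnerability indices, a
mechanically motivated stress index, and cohort-level correlation and
agreement statistics that respect the clustering of slices within patients.

Because clinical IVUS pullbacks are rarely shareable, the package also
ships a seeded synthetic-cohort generator that emulates a multi-patient
cross-section cohort with controlled cap thickness and lipid burden, and a
closed-form mechanical surrogate that stands in for a full fluid–structure
interaction (FSI) solution.  Everything downstream of the contours — the
measurement procedure, the index rules, the calibration optimizer, the
statistics — is exactly the analysis one would run on real segmented data.

## Per-slice measurement procedure

Each slice is measured at 100 nodal points on the lumen boundary, evenly
spaced by arc length and grouped into four quarters of 25 points each.  The
arc-length origin is fixed at the lumen vertex of maximum x (ties broken by
maximum y); the convention is arbitrary but deterministic, so repeated runs
and reversed-orientation inputs give identical results.

At each nodal point a *connecting line* is cast from the lumen centroid
through the point to its first crossing of the outer boundary.  The segment
length is the **wall thickness**.  If the segment crosses a lipid core, the
distance from the lumen point to the first crossing is the **cap
thickness**; otherwise cap thickness equals wall thickness.  Calcifications
never shorten the measurement.  The slice summary records

* the **minimum cap thickness** over the 100 nodes, and
* the **lipid percentage**, total lipid-core area divided by the wall
  area (outer area − lumen area), with all areas from the shoelace formula.

Two conventions in this procedure are genuinely open and were fixed as
design choices: the lumen-to-outer correspondence is realized as
centroid-ray casting (well defined for star-shaped walls and matching the
radial measurement sketched in the source imagery conventions), and the
quarters are arc-length quarters rather than angular quarters.  For a
non-star-shaped lumen the farthest lumen crossing along the ray is used and
the profile flags the node count in an attribute.

```{r measurement-example}
th <- seq(0, 2 * pi, length.out = 129)[-129]
geom <- slice_geometry(cbind(1.5 * cos(th), 1.5 * sin(th)),
                       cbind(2.5 * cos(th), 2.5 * sin(th)))
profile <- nodal_profile(geom)
range(profile$wall_mm)   # concentric circles: 1 mm everywhere
```

## Vulnerability indices

The **cap index** and **lipid index** are ordinal 0–4 scores aligned with
AHA plaque types; all bin boundaries are right-closed, exactly as the
classification tables state them:

| index | min cap thickness (mm) | lipid percentage |
|------:|------------------------|------------------|
| 0 | no lipid component | no lipid |
| 1 | > 0.2 | (0, 5)% |
| 2 | (0.15, 0.2] | [5, 30)% |
| 3 | (0.065, 0.15] | [30, 40)% |
| 4 | ≤ 0.065 | ≥ 40% |

The **morphological index** is the maximum of the two.  Index 0 is reserved
for slices without a lipid core; a lipid-bearing slice always receives cap
index ≥ 1.  The lower bound of lipid index 1 is strict (a slice with
exactly zero lipid is index 0).

The **stress index** maps the slice's critical plaque wall stress (CPWS,
kPa) through five half-open intervals `(0,t1], (t1,t2], (t2,t3], (t3,t4],
(t4,∞)`; the default cuts are 35/55/89/140 kPa, the values calibrated on
the 617-slice coronary cohort the method was developed on.

### Calibrating the stress intervals

`calibrate_stress_intervals()` finds the four cut-points maximizing the
exact agreement (match) rate with the morphological index.  The match count
only changes when a cut crosses a data value, so the continuous problem is
equivalent to a monotone non-decreasing assignment of index levels to the
sorted unique CPWS values.  That assignment is solved exactly by dynamic
programming in O(5·n); index levels may be empty (two cuts can share a gap
or sit below the data minimum), which is what makes degenerate labelings
— e.g. every slice at morphological index 2 — achieve a perfect match
rate.  Ties are resolved toward the earliest possible boundary positions,
and cut values are placed at gap midpoints (equally spaced when a gap
hosts several cuts, unit-spaced above the data maximum), so calibration is
deterministic and invariant to slice order.  The test suite checks the
dynamic program against exhaustive enumeration of all boundary multisets
on instances up to 50 slices.

The calibration objective is the exact-match rate only — no partial credit
for adjacent indices — mirroring how the published agreement rates are
defined.

## Constitutive model and mechanical surrogate

The vessel wall is modeled with the anisotropic modified Mooney–Rivlin
strain-energy density

$$W = c_1(I_1-3) + c_2(I_2-3) + D_1\left[e^{D_2(I_1-3)}-1\right] +
\frac{K_1}{2K_2}\left\{e^{K_2(I_4-1)^2}-1\right\},$$

with $I_1, I_2$ the isotropic invariants of the right Cauchy–Green tensor
and $I_4 = \mathbf{n}_c^\top C\,\mathbf{n}_c$ the squared circumferential
stretch.  Default constants (biaxial fits for human coronary media):
$c_1 = -1312.9$, $c_2 = 114.7$, $D_1 = 629.7$, $K_1 = 35.9$ kPa,
$D_2 = 2.0$, $K_2 = 23.5$.  The anisotropic bracket is normalized so that
$W = 0$ at the identity — a physically required stress-free reference; the
typographically ambiguous unnormalized variant (which carries a constant
offset $\tfrac{K_1}{2K_2}e^{-1}$ at the identity) is available behind
`printed_form = TRUE` for comparison only.  Incompressibility is handled
by parameterized stretches rather than a bulk penalty (no penalty constant
is published for this tissue).  Analytic stress derivatives are verified
against central finite differences of the energy to 1e-6 relative over
stretches 0.9–1.3.

The per-node surrogate replaces the FSI solution with closed forms chosen
for their couplings, not their magnitudes:

* **PWS** (plaque wall stress): thin-wall Laplace hoop stress
  $a + b\,p\,r/h$, with $p$ the transmural pressure (default 13.3 kPa
  ≈ 100 mmHg), $r$ the centroid-to-lumen distance and $h$ the cap
  thickness at lipid-hit nodes, the wall thickness elsewhere.  This builds
  in the inverse stress–cap-thickness coupling with tunable strength
  $(a, b)$.
* **PWSn** (wall strain): the Green–Lagrange strain at which the
  equibiaxial Mooney–Rivlin membrane response equals the nodal PWS,
  obtained by monotone inversion of the analytic stress–stretch curve on a
  600-point grid and clipped to [0, 0.5].  Reusing the constitutive model
  keeps strain consistent with stress.
* **FSS** (flow shear stress): Poiseuille wall shear
  $4\mu Q/(\pi r^3)$ (blood viscosity 0.0035 Pa·s, flow 1 ml/s),
  reported in dyn/cm².  FSS depends on lumen caliber only, so it is
  generated *uncoupled* from cap thickness — the null the correlation
  analysis should, and does, report as non-significant.

Optional noise is multiplicative lognormal, $\exp N(0, \sigma)$ — Gaussian
on the log scale — which preserves the positivity of stresses exactly;
PWSn is recomputed from the perturbed PWS so the two remain consistent.

Slice-level **critical values** (CPWS, CPWSn, CFSS) are the maxima of each
factor over the thin-cap region: the lipid-hit nodes dilated by 2 nodes
(~7.2°) on each side, the *shoulder*.  The shoulder width is a
documented interpretation — no quantitative definition is published — and
is configurable.  Restricting to this region makes the reported value the
largest of the region's local maxima; when several lipid arcs are present
the largest per-arc peak wins.  Slices without lipid still receive
critical values (global maxima), since every slice of a cohort is scored.
The surrogate magnitudes are deliberately **not** calibrated to any FSI
solver output; the published stress intervals are used only as fixed
lookup values, never as surrogate validation.

## The synthetic cohort generator

`generate_cohort()` emulates a diseased multi-patient coronary cohort at
the contour level:

* **Contours**: lumen radius drawn from a truncated normal (mean 1.5 mm,
  sd 0.3, bounds 0.8–2.5) with a low-order Fourier radius perturbation
  (orders 2–4, amplitudes up to 4%) discretized to 128 vertices; the outer
  boundary is a radial offset by a smoothly varying wall thickness
  (mean 1.0 mm, sd 0.2, bounds 0.5–2.0).
* **Lipid cores** (prevalence 0.85, second opposite-side core with
  probability 0.3): annular sectors built in polar coordinates around the
  lumen centroid — arc 40–280°, radial cap offset drawn uniformly from
  (0.02, 0.30] mm, radial thickness a 0.35–0.95 fraction of the wall
  available beyond the cap.  Because the sector's inner edge is the lumen
  boundary offset by the sampled cap value along the same centroid rays
  the measurement uses, the downstream minimum cap thickness is controlled
  by construction; recovery tests confirm agreement within 0.01 mm
  (contour-chord discretization).
* **Calcifications** (prevalence 0.3): similar sectors placed deeper in
  the wall.
* **Mechanics**: attached per slice through the surrogate with the
  configured stress coupling (default noise sd 0.1 on the log scale).

Patient counts (14) and slice counts per patient (34–57) default to the
scale of the cohort the method was reported on.  No per-slice morphology
distributions are published for that cohort; the distribution choices
above are free parameters selected once to give realistic diseased
vessels whose cap thicknesses populate all four cap-index bins and whose
lipid percentages span all lipid-index bins, and they are documented here
as such.

One RNG stream per cohort is split hierarchically into per-patient and
per-slice seeds, so per-slice draws are independent of generation order;
the same configuration and seed reproduce a byte-identical cohort, and
the caller's RNG state is restored afterwards.

What the generator does **not** emulate: IVUS speckle, virtual-histology
pixel classification, segmentation error, along-vessel (3D) continuity of
plaque between slices, component clustering/merging, or realistic
correlation between lipid burden and cap thickness beyond what the
geometry imposes.  Passing tests therefore demonstrate that the analysis
machinery is correct and that the statistical pipeline recovers
engineered couplings at realistic sizes — not that the surrogate
reproduces patient-level stress magnitudes or that published correlation
values would be reproduced on clinical data.

## Clustered correlation analysis

Slices within a patient are correlated, so pooled Pearson correlations
overstate the evidence.  `lme_correlation()` fits the random-intercept
model $y_{ij} = \beta_0 + \beta_1 x_{ij} + u_i + \epsilon_{ij}$,
$u_i \sim N(0, \sigma_u^2)$, by maximum likelihood (ML rather than REML so
nested-model comparisons remain coherent) and reports the Wald p-value
for $\beta_1$.  How a correlation coefficient should be derived from such
a fit is not standardized; the package reports the **standardized slope**
$r = \beta_1\,\mathrm{sd}(x)/\mathrm{sd}(y)$, clipped to [−1, 1].  This
choice is sign-consistent with the fitted association and reduces exactly
to the Pearson correlation when clustering is absent (a single patient is
handled as pooled Pearson, and the two agree to 1e-6 in that limit).  It
is an interpretation, flagged as such: with strong between-patient
intercept spread the standardized slope is attenuated by the patient-level
variance in sd(y), which is exactly the clustering penalty the model is
meant to express.  The random-effects structure (random intercept only, no
random slope) is likewise a documented choice.  Monte-Carlo calibration in
the acceptance suite verifies the nominal type-I error: over 1000 null
replicates at 14 patients × 40 slices, the rejection rate at α = 0.05
must fall in (0.03, 0.07).

Per-patient correlations are plain Pearson with a two-sided test (a
single-group mixed model would be degenerate); patients with fewer than 3
usable slices are skipped with a warning, and within-patient constant
variables yield a missing `r`, never a zero.  Raw p-values are reported
throughout — no multiple-testing correction — with α = 0.05 as the
significance convention.  Agreement between the stress index and each
morphological index is the exact match rate with matched/unmatched counts.

## Numerical choices

* Contours are normalized counterclockwise on construction; reversing the
  vertex order of any input changes no output.
* Ray–edge intersections use a half-open edge-parameter range with a 1e-9
  tolerance so a ray through a shared polygon vertex is counted once;
  1e-9 mm is far below the ~20 µm displayed resolution of IVUS.
* Polygon areas (shoelace) match analytic circle/ellipse areas within
  0.5% at ≥ 128 vertices, the default discretization.
* Component placement that cannot fit inside the wall is resampled up to
  20 times, then fails with a diagnostic naming the slice.
* Degenerate statistics (zero residual variance, constant inputs) raise
  errors with diagnostics; a pooled-Pearson fallback exists but only on an
  explicit flag.

## Validation problem sizes

The test suite validates the geometry kernel against a brute-force
segment-intersection oracle on 200 generated slices (20,000 nodal
measurements), the calibration DP against exhaustive enumeration on
instances up to 50 slices, constitutive derivatives against finite
differences on an 81-point stretch grid, the type-I error of the
clustered correlation on 1000 null replicates, and the qualitative
stress–morphology correlation pattern (positive with cap index, negative
with min cap thickness, lipid correlations weaker, shear–cap null) on 20
seeded cohorts of 14 × 40 slices.  These sizes were chosen as the package's
own validation design: large enough for the binomial and Monte-Carlo bands
asserted, small enough to run routinely.

## Known limitations

* The mechanical surrogate is a physically motivated stand-in: Laplace and
  Poiseuille closed forms at a single loading state, with no
  fluid–structure coupling, no pulsatile cycle, no cyclic bending, no
  residual stress/pre-shrink.  Its magnitudes must not be compared with
  solver outputs.
* Centroid-ray measurement assumes an approximately star-shaped wall;
  strongly concave lumens are handled by a documented fallback but the
  measurement convention itself becomes questionable there.
* The lipid percentage uses contour areas; overlap between lipid and
  calcification polygons is not subtracted (the definition references
  lipid area only).
* Isotropic constants for plaque components (lipid, calcification) are
  not published and are not invented; the surrogate does not require them.
* Cross-slice (3D) structure is out of scope; every slice is analyzed as
  an independent planar section, and correlation analysis accounts for
  patient clustering only.
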