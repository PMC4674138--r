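# plaquevuln

Quantitative vulnerability assessment of atherosclerotic coronary plaque
from segmented cross-sectional contours.

Plaque rupture risk is driven by lesion morphology — a large lipid-rich
necrotic core under a thin fibrous cap — and by the mechanical load on
that cap. Starting from segmented IVUS-style contours (lumen, outer wall,
lipid cores, calcifications; slice-local coordinates in mm), `plaquevuln`

* measures each slice at **100 nodal points in 4 quarters**: wall
  thickness and fibrous-cap thickness along centroid rays (calcifications
  never shorten the cap measurement), minimum cap thickness, and the
  lipid percentage `lipid area / (outer area − lumen area)`;
* assigns ordinal **0–4 vulnerability indices**: a cap index from minimum
  cap thickness (cuts 0.065 / 0.15 / 0.2 mm, right-closed), a lipid index
  from lipid percentage (cuts 5 / 30 / 40%), the **morphological index**
  `max(cap index, lipid index)`, and a **stress index** from the critical
  plaque wall stress via five half-open kPa intervals
  (default cuts 35 / 55 / 89 / 140);
* **calibrates** the stress intervals by exactly maximizing the match
  rate with the morphological index (dynamic programming, provably equal
  to exhaustive search);
* computes a closed-form **mechanical surrogate** per node — Laplace hoop
  stress `p·r/h`, wall strain by inversion of an anisotropic modified
  Mooney–Rivlin equibiaxial response
  (`W = c1(I1−3) + c2(I2−3) + D1[exp(D2(I1−3))−1] +
  K1/(2K2){exp[K2(I4−1)²]−1}`), and Poiseuille shear `4μQ/(πr³)` — and
  extracts slice-level critical values (CPWS, CPWSn, CFSS) from the
  thin-cap-plus-shoulder region;
* runs **clustered correlation analysis** with linear mixed-effects
  models (random intercept per patient, ML, Wald tests; the reported r is
  the standardized slope `β₁·sd(x)/sd(y)`), per-patient Pearson
  correlations, and index agreement tables;
* generates seeded **synthetic multi-patient cohorts** with cap thickness
  and lipid burden controlled by construction, for method validation and
  power exploration.

## Worked example

One slice: concentric lumen/outer circles (radii 1.5 / 2.5 mm) with a
lipid core whose cap is 0.12 mm thick over a quarter-circle arc.

```r
library(plaquevuln)

th    <- seq(0, 2 * pi, length.out = 129)[-129]
lumen <- cbind(1.5 * cos(th), 1.5 * sin(th))
outer <- cbind(2.5 * cos(th), 2.5 * sin(th))
ang   <- seq(0.1, pi / 2, length.out = 40)
core  <- rbind(cbind(1.62 * cos(ang), 1.62 * sin(ang)),
               cbind(2.10 * cos(rev(ang)), 2.10 * sin(rev(ang))))
geom  <- slice_geometry(lumen, outer, list(core))

profile <- nodal_profile(geom)
morph   <- slice_morphology(geom, profile)
round(c(min_cap_mm = morph$min_cap_thickness_mm,
        lipid_pct  = 100 * morph$lipid_fraction), 3)
#> min_cap_mm  lipid_pct
#>      0.120     10.451

cap_i <- assign_cap_index(morph$min_cap_thickness_mm, morph$has_lipid)  # 3
lip_i <- assign_lipid_index(100 * morph$lipid_fraction)                 # 2
morphological_index(cap_i, lip_i)
#> [1] 3

mech <- nodal_mechanics(profile, geom, surrogate_params())
crit <- extract_critical(mech, profile)
round(c(CPWS_kPa = crit$cpws_kPa, CPWSn = crit$cpwsn,
        CFSS_dyn_cm2 = crit$cfss_dyn_cm2), 3)
#>     CPWS_kPa        CPWSn CFSS_dyn_cm2
#>      166.503        0.071       13.216
assign_stress_index(crit$cpws_kPa)
#> [1] 4
```

A 0.12 mm cap under a lipid core is "moderately unstable" (cap index 3);
the modest lipid burden (10.5%) gives lipid index 2, so the morphological
index is 3. The Laplace stress concentrates at the thin cap
(13.3 kPa × 1.5 mm / 0.12 mm ≈ 166 kPa), which the default intervals map
to stress index 4.

End to end on a simulated cohort, with stress-interval calibration:

```r
res <- run_pipeline(run_config(
  cohort = cohort_config(n_patients = 14, slices_per_patient = c(34, 57)),
  intervals = "calibrate", seed = 1))
res
#> <plaque_results> 597 slices, 14 patients
#>   stress cuts (kPa): 42.64, 46.33, 147.76, 374.27 (calibrated)
#>   stress/morph agreement rate: 0.8191

subset(res$correlations, mechanical == "cpws_kPa")[, 1:4]
#>   mechanical morphological          r       p_value
#> 1   cpws_kPa    min_cap_mm -0.4960034  2.852288e-44
#> 2   cpws_kPa     cap_index  0.7425748 1.750257e-161
#> 3   cpws_kPa     lipid_pct  0.3149494  5.147277e-16
#> 4   cpws_kPa   lipid_index  0.3606168  3.493613e-21
#> 5   cpws_kPa   morph_index  0.6609445 1.795001e-102
```

Wall stress correlates positively with the cap index and negatively with
minimum cap thickness (thinner caps score higher and bear more stress),
while the lipid correlations are weaker — the qualitative pattern expected
when stress is driven primarily by cap thinning. The calibrated cuts and
agreement rates describe this synthetic cohort, not any clinical dataset.

See `vignettes/plaque-vulnerability-methods.Rmd` for the model details,
conventions, and limitations.

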