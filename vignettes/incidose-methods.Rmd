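---
title: "Incidental nodal dose, EUD and TCP: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incidental nodal dose, EUD and TCP: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incidose)
```

## The problem

Involved-field radiotherapy (IF-RT) of non-small-cell lung cancer irradiates
only PET-positive disease and relies on *incidental* dose — dose the beams
deposit on their way to the target — to control microscopic disease in
elective (uninvolved) hilar and mediastinal lymph node stations.  Highly
conformal techniques such as IMRT produce steeper dose gradients around the
PTV than 3D-conformal plans, so they deposit less incidental dose in those
stations.  `incidose` quantifies that trade-off for paired plans: it scores
out-of-field nodal volumes by equivalent uniform dose (EUD) and a logistic
tumour control probability (TCP) for microscopic disease, and compares
techniques at matched prescriptions across a cohort.

Three plans are compared per patient: the escalated IMRT plan, the escalated
3D-CRT plan, and `IMRT_norm` — the IMRT plan rescaled (by fraction matching
at 2 Gy/fraction) to the 3D-CRT prescription, which isolates the effect of
dose *distribution* from that of dose *level*.

## Models

### DVHs and metrics

A DVH is stored as a discrete distribution: fractional volumes at tabulated
doses.  `compute_dvh()` histograms masked voxels into left-closed,
right-open bins (`[k·w, (k+1)·w)`, default `w = 0.1` Gy) and anchors each
bin at its midpoint; `dvh_from_points()` represents exact dose points
without binning.  Mean dose is `Σ vᵢ dᵢ`; histogram metrics therefore carry
a quantisation error of at most half a bin (the 0.1 Gy default keeps
DVH-based and voxel-based EUD within tolerance for doses above ~10 Gy; see
below).

`metric_Vx()`/`metric_Dx()` read the cumulative curve.  The default
evaluation is the *step* (staircase) form of the tabulated distribution —
exact for the histogram the DVH actually is — with linear interpolation
between tabulated points available via `interp = "linear"`.  The step
convention was chosen because it reproduces hand-computable results on
exact-point DVHs (e.g. a {25% @ 20 Gy, 75% @ 60 Gy} structure has
V(35 Gy) = 75% and D90 = 20 Gy); for fine-binned histogram DVHs the two
conventions differ by less than one bin.

The conformity of a reference isodose to the PTV is reported as the van't
Riet/Paddick conformation number `CN = TV_PIV² / (TV·PIV)` (in [0, 1], 1 is
perfect, penalising both under-coverage and spill).  Vendor "CI" values in
the literature are not always this quantity, so the simpler RTOG ratio
`PIV/TV` is also exported under its own name.

### EUD

The generalized EUD is the power mean
`EUD = (Σᵢ vᵢ Dᵢᵃ)^(1/a)` with the volume-effect exponent `a`.  `a = 1` is
the mean dose; large positive `a` approaches the maximum (serial-organ
behaviour), negative `a` approaches the minimum (target behaviour, punishing
cold spots).  EUD is positively homogeneous of degree 1 in dose — the
property that makes fraction-matched normalization a pure rescaling of all
derived quantities.  Numerically the power mean is evaluated after rescaling
doses by the maximum (for `a > 0`) or minimum occupied dose (for `a < 0`),
so `|a|` up to ±50 is safe from overflow.  For `a < 0`, any zero-dose
volume drives the limit to 0 Gy; that limit is returned with a warning
rather than a numerical fault.  `a = 0` is a domain error.

No published value of `a` exists for elective nodal target tissue in this
setting.  The package default is `a = -8`, a conventional target-type
exponent; it is a modelling default to be set explicitly by the user when it
matters, not a literature value.

### TCP

The dose–response model is the logistic curve
`TCP(D) = 1 / (1 + (D50/D)^(4γ))` evaluated at `D = EUD`, with microscopic-
disease parameters `D50 = 36.5` Gy and `γ = 0.72`.  The exponent `4γ` makes
`γ` the *normalized slope*: `D50 · dTCP/dD` at `D50` equals `γ` exactly, and
`TCP(D50) = 1/2`.  No fractionation (LQ/EQD2) correction is applied; the
model acts on the physical EUD.  Cohort TCP is always summarised as the mean
of per-patient TCPs — by Jensen's inequality this is *not* the TCP of the
mean EUD, so the EUD and TCP columns of a cohort summary cannot be derived
from one another.

### Constraints, escalation and normalization

`default_constraints()` encodes the normal-tissue gate: lung (GTV
subtracted) V20 ≤ 35% and mean ≤ 20 Gy; spinal cord Dmax ≤ 45 Gy; esophagus
(V50 ≤ 50% *or* mean ≤ 34 Gy) and Dmax ≤ 70 Gy; heart V45 ≤ 67% and
V60 ≤ 33% — seven rules over four organs, the esophageal OR-pair counting as
one rule.  Comparisons are inclusive (`V20 = 35.0%` passes).  The tighter
IMRT planning objectives (`imrt_objectives()`) are carried as data for
generator use, not as a feasibility gate, because inverse optimisation is
out of scope.

`escalate_prescription()` assumes the dose distribution is linear in the
prescription (true by construction for the synthetic cohort) and returns the
*maximal* feasible multiple of 2 Gy in [2, 110].  The search sweeps the
whole lattice rather than walking from the 70 Gy start: "escalate until the
constraints are surpassed" is ambiguous for non-monotone feasibility, and
the sweep guarantees the argmax; non-monotone feasibility triggers a
warning, as does a result below the 60 Gy aspiration level.

`normalize_plan()` implements fraction matching at a fixed fraction size,
which with identical 2 Gy fractions is exactly linear rescaling of every
dose in the plan.  This is stated explicitly because "normalized to the same
maximum dose level" phrasing in the planning literature could be misread as
point-dose matching.

### Nodal grouping

The station vocabulary is the 13 AJCC hilar/mediastinal labels with levels
10/11 merged per side.  `all_elective()` is the complement of the involved
set.  `adjacent_elective()` is `({7} ∪ {ipsilateral 10/11} ∪
neighbours(involved)) \ involved`.  The shipped adjacency graph follows the
cranio-caudal ordering of a CT-based atlas (paratracheal chains 1–2–4 per
side, prevascular 3 against 2R/2L, subcarinal 7 as the hub to 4R/4L and both
hila, aortopulmonary 5–6 on the left, paraesophageal 7–8–9) and is a
*modelling choice*: individual anatomy varies, the graph is replaceable via
`read_adjacency_json()`, and it is deliberately not mirror-symmetric
(stations 5 and 6 exist only on the left).  Whether a contralateral hilum
can ever be "adjacent" is left to the user's map; the default says no.
Grouped volumes are scored on the voxelwise union of the station masks,
never on volume-weighted averages of per-station DVHs, so overlapping
contours are not double counted.

### Paired statistics

`paired_compare()` gates on a Shapiro–Wilk test of the paired differences at
α = 0.05 (per endpoint): normal-looking differences get the paired t-test,
anything else the two-sided Wilcoxon signed-rank test (exact null
distribution up to 25 nonzero differences, normal approximation with
continuity correction above).  All-zero differences return p = 1 with a
degeneracy flag.  No multiple-testing correction is applied, matching
per-endpoint reporting conventions for this kind of planning comparison.
Simulation (10,000 null replicates at n = 41, in the test suite) confirms
the routed procedure holds its nominal 5% type-I error.

## The synthetic cohort

The generator emulates the *conditions* of a paired planning comparison, not
beam physics.  Each patient (default 41 per cohort, the scale of the study
design being emulated) is a 64³ grid at 4 mm spacing — 256 mm of thorax,
desk-scale while leaving nodal stations (12 mm radius spheres) over a
hundred voxels each.  Geometry: a spherical tumour in the ipsilateral lung
(GTV radius 12–26 mm, plus 3 mm CTV and 7 mm PTV margins), 13 stations at
jittered template positions consistent with the adjacency graph, and OAR
surrogates (lung ellipsoids minus GTV, cord and esophagus tubes, heart
ellipsoid).

Normalized dose is 1 inside the PTV and falls off as a Gaussian of the
distance to the PTV surface, with σ = 12 mm for IMRT and 20 mm for 3D-CRT
(the steeper-IMRT-gradient mechanism).  The 3D-CRT plan adds three straight
beam corridors through the tumour at 30% of prescription; the IMRT plan uses
the same corridors modulated down by a factor 0.85.  Using the *same*
corridor geometry at a lower amplitude makes the IMRT normalized field
voxelwise ≤ the 3D-CRT field, which guarantees — by construction, for every
patient — the directional findings the pipeline is meant to detect (lower
out-of-field EUD/TCP for IMRT at matched prescription) while the corridors
still deposit the extra incidental mediastinal dose that makes 3D-CRT bind
its lung constraints earlier.  A 3% scatter floor keeps far-field doses
positive.  Involvement: count = 1 + Binomial(6, 0.25) (mean 2.5 stations),
grown contiguously along the adjacency graph from a seed station weighted
towards the ipsilateral lower paratracheal level, the subcarinal station and
the ipsilateral hilum.  Every patient has at least one involved station; in
the rare draw whose adjacent-elective volume would be empty the involvement
is redrawn.

Prescriptions default to the escalation loop against the synthetic OARs
(`prescription_mode = "escalate"`), which exercises the whole plan-ops
module and lands 3D-CRT around 70 Gy; `"sample"` mode draws instead from
N(74.3, 9.1²) for IMRT and N(70.1, 7.9²) for 3D-CRT, rounded to the 2 Gy
lattice and clamped to [2, 110] Gy.

What the generator does **not** reproduce, and what passing tests therefore
do not show about real data:

* **Absolute magnitudes.**  In escalation mode the synthetic IMRT plans bind
  their constraints late (often only at the 110 Gy cap), so the simulated
  IMRT prescription mean sits well above clinical values; the *ordering*
  (IMRT > 3D-CRT, per patient and in the mean) is the reproduced feature.
* **Elective-volume dose levels.**  The merged all-elective volume includes
  stations far from the PTV that receive almost nothing beyond the scatter
  floor in this geometry.  Under `a = -8` the EUD of such a volume collapses
  towards its coldest station, so synthetic LN_all EUD/TCP values are much
  lower than clinically reported ones; orderings across plans and volumes
  are preserved.
* Real beam physics, tissue heterogeneity, breathing motion, contour
  variability and non-spherical targets.

## Numerical choices and degenerate inputs

* DVH invariants are enforced to 1e-9 (differential sums to 1; cumulative
  monotone with value 1 at 0 Gy); conversions round-trip to 1e-12.
* Differential DVHs always carry a 0 Gy anchor (possibly zero mass), so both
  forms share dose coordinates and interconvert losslessly.
* Empty masks, shape mismatches, missing structures and malformed adjacency
  maps raise typed errors (`structure-empty`, `geometry error`,
  `configuration error`) rather than producing NaNs.
* Constraint comparisons and Vx/Dx thresholds use a 1e-12..1e-9 tolerance so
  boundary cases (`V20 = 35%`) behave inclusively under float rounding.
* All randomness flows from one master seed: `generate_cohort()` draws
  per-patient seeds in a single documented `sample.int()` call and each case
  is generated under its own restored-afterwards RNG stream, so cohorts are
  bit-identical under the same config and invariant to generation order.

## Problem sizes used by the shipped checks

The test suite exercises the full default cohort (41 patients at 64³) once,
property suites on small randomized fixtures, an exhaustive sweep of all
2¹³ involvement sets for the grouping rules, and 10,000 null replicates at
n = 41 for the type-I error of the routed paired test; the whole suite runs
in well under a minute on one core.
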