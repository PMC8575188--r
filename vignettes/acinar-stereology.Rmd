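---
title: "Design-based stereology of pulmonary acini: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology of pulmonary acini}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acinostereo)
```

## The problem

Pulmonary acini — the gas-exchanging units distal of the terminal
bronchioles — cannot be delineated on single 2D sections: whether two air
profiles belong to the same acinus is a 3D question. Given high-resolution
3D image stacks (tomographic data at ~1.48 µm isotropic voxels), individual
acini can be isolated by closing the airway at the bronchioalveolar duct
junction with a disk-shaped *segmentation stopper* and flooding the distal
air space with a threshold region grower. Each extracted acinus is then
assessed by virtual stereology:

* **Volume** by the Cavalieri principle on a systematic uniform random
  (SURS) set of sections: $V = t \cdot a_p \cdot \Sigma P$, with section
  separation $t$, area per test point $a_p$, and total point count
  $\Sigma P$.
* **Alveolar number** by the physical disector on paired sections: an
  alveolar entrance ring appears or disappears exactly once between
  consecutive sections, so the bidirectional event count
  $(Q^+ + Q^-)/2$ over all pairs equals the number of alveoli.

From per-acinus records the package derives the quantities a developmental
morphometry study reports: per-animal summary tables, acini-weighted day
means, coefficients of variation, size-quintile ratios, normalized volume
distributions, acini per lung, total alveoli per lung, and
sphere-equivalent alveolar diameters, with rank-based group statistics
under Šidák correction.

Because raw tomographic stacks are not shippable, the package is built
around a synthetic-phantom module with *exact* voxel-level ground truth:
every estimator is verified against phantoms, and the derived layer is
verified against the packaged per-animal tables of a postnatal rat cohort
(days 4, 10, 21, 60; 12 animals; 268 assessed acini).

## The phantom generator

`build_duct_tree()` grows a binary-branching tree of tapering capsules
(root along +z, daughters at ~38° polar angle with random azimuth);
`synthesize_acinus()` rasterizes it and attaches spherical alveoli to the
duct walls by rejection sampling. The construction enforces, voxel by
voxel, the assumptions the estimators rely on:

* each alveolus opens into the lumen through a single mouth (candidate
  spheres whose lumen overlap strays from the attachment point are
  rejected), mirroring the counting assumption that wall interruptions
  occur only at alveolar mouths;
* alveoli never merge (a one-voxel septum is guaranteed by a dilated
  exclusion test), so labels are well defined;
* the whole air space is one 6-connected component (one ventilatory unit,
  asserted by connected-component labelling);
* each alveolar profile occupies a contiguous run of sections, so the
  exhaustive disector is exact by construction — this is a property of
  real entrance rings the phantom reproduces, not a convenience;
* the manifest is exact: `true_volume_mm3` *is* the nonzero-label voxel
  count times the voxel volume, and `n_alveoli` the number of labels ≥ 2.
  A placement that cannot complete errors out rather than silently
  truncating truth.

`synthesize_cohort()` draws target volumes from a log-normal law
moment-matched to a day profile's (mean, CV). The within-day distribution
family is not identifiable from published day aggregates; log-normal is a
modelling choice, made once, because it has positive support and
reproduces the reported right skew at days 4–21 (median of normalized
volumes ≪ 0.5) while being near-symmetric at the adult CV of 0.49.
Alveolar counts co-vary with volume as
$n_i \propto (v_i/\bar v)^{0.8} e^{\varepsilon}$, $\varepsilon \sim
N(0, 0.25^2)$, which yields within-day density CVs of roughly 0.3–0.5,
the range seen in the per-animal density table.

Phantom geometry is built in voxel units at desk scale (tens to a couple
hundred voxels across) and the voxel edge length is then set so the
realized distal air volume equals the drawn target exactly. All
estimators are scale-free, so this loses no generality; it is what makes
ground-truth-exact cohorts affordable. The default day profiles are the
cohort's own aggregates (mean volumes 0.03/0.04/0.10/0.74 mm³, volume CVs
1.33/1.25/0.90/0.50, mean counts 48/89/233/702, cohort sizes
125/58/42/43). For end-to-end runs the `alveoli_scale` knob realizes
phantoms at proportionally reduced alveolar counts: disector counting is
exact at any count, so scaled counts trade no validity for speed. The
shipped demo configuration uses 4 days × 6 acini at `alveoli_scale = 10`;
the test suite and acceptance script use 4 × 4.

What the phantoms do **not** emulate: anatomically faithful septal
thickness, capillary networks, tomographic artifacts (rings, phase
fringes), or developmental remodelling. Passing phantom tests therefore
demonstrates estimator correctness under the stated geometric assumptions,
not robustness to real-data artifacts — on real stacks, threshold choice
and stopper placement remain operator responsibilities.

## Segmentation

Region growing uses 6-connectivity: diagonal adjacency could leak air
through one-voxel septal gaps, and a 6-connected flood is the strictest
choice consistent with a plugged entrance. Stoppers are solid oriented
disks with a default thickness of 3 voxels — at least 2 is required, which
makes the plug airtight under 6-connectivity by construction. The disk
slab is half-open along its normal, $(-t/2, t/2]$, so an integer thickness
covers exactly $t$ sections. The default threshold is Otsu's on the whole
stack, with a per-acinus override because gray-value variation is known to
bias automatic thresholds on real tomograms. The automatic seed helper
steps one stopper thickness along the stopper normal (the distal
direction).

No rule can validate a stopper radius against the local airway caliber
from inside this module; an undersized stopper leaks silently. As a
post-hoc heuristic, a grown mask that touches the stack boundary triggers
a warning (extracted-acinus stacks should contain their acinus with
margin), not an error.

## Stereology

Section designs are 1-based: SURS offsets are uniform on
`{1, …, interval}` and indices are `seq(offset, depth, interval)`, so the
designs over all offsets partition the sections — the discrete form of the
unbiasedness argument. Point grids place nodes at
`origin + k · spacing` with the origin uniform in `[0, spacing)²`; node
membership uses the half-open voxel convention with a relative epsilon so
conceptually aligned designs (e.g. a grid aligned to a cuboid) are exact
rather than float-fragile. Averaged over the exhaustive offset × origin
design, the Cavalieri estimate equals the voxel-counted volume to machine
precision; the test suite asserts < 0.5 %.

The disector counts both appearances and disappearances and divides by
two. Published protocols often leave the direction convention implicit;
the bidirectional rule is symmetric (reversing the stack swaps $Q^+$ and
$Q^-$ and leaves the estimate unchanged) and exact on exhaustive pairs.
Fractional pair sampling scales by `pairs_total / pairs_examined` and is
unbiased over starts. The Gundersen–Jensen CE is computed in its
smoothness-class-0 form without a nugget term,
$\mathrm{CE} = \sqrt{(3A - 4B + C)/12} \,/\, \Sigma P$; it reflects
between-section variance only and is reported as auxiliary output. On
small phantoms the realized estimator scatter can exceed the nominal CE
because within-section point noise is not in the formula.

Shrinkage correction is the ratio of fresh (fluid displacement) to
processed (Cavalieri) lobe volume, applied multiplicatively per animal —
the simplest estimator consistent with a global linear correction; a
per-day variant would only pool the same ratios.

`detect_interruptions()` is a best-effort 2D heuristic (erosion severs
mouth necks; the component-count increase estimates openings) for
grayscale-only data. It is documented as approximate and sits on no
verification path; exact counting uses label volumes.

## Derived metrics

Day means are acini-weighted: $\sum n_i m_i / \sum n_i$, identical to the
pooled per-acinus mean. Pooled CVs from per-animal tables use
$s^2_{\mathrm{pooled}} = [\sum (n_i - 1) s_i^2 + \sum n_i (m_i - \bar
m)^2] / (\sum n_i - 1)$. Recomputed from the display-rounded volume table
this gives 1.28 and 0.50 for days 4 and 60 against the published 1.26 and
0.49 — the drift is table rounding, the raw per-acinus values being
unavailable, and the tests assert agreement to 0.03.

Quintile tails round to the nearest integer (20 % of 125 → 25, of 43 → 9,
matching the published tail sizes). The alveolar-duct volume fractions
(0.733/0.739/0.689/0.771 for days 4/10/21/60) are not measured here: they
are back-solved from the published mean alveolar volumes against the exact
table day means, shipped as configuration, and flagged as
reverse-engineered. With them, the chain *table means → alveolar volume →
sphere-equivalent diameter* reproduces 98/86/84/116 µm.

## Group statistics

Pairwise two-sided Mann–Whitney tests use exact enumeration when both
groups have ≤ 8 observations and no ties, else the tie-corrected normal
approximation with continuity correction (the original software's variant
is unknown; the switch point is configurable). The Šidák threshold
$1 - (1 - \alpha)^{1/m}$ with family $\alpha = 0.01$ and $m = 6$ day pairs
gives 0.00167, the published per-comparison level — the published report
states the threshold but not ($\alpha$, m); this pair is the back-solve.
The normality screen is advisory, matching the original analysis flow.
Acini are pooled across animals within a day, as published; this is
pseudo-replication (acini within an animal are not independent), kept
deliberately for comparability and noted here as a caveat.

## Numerical choices and degenerate inputs

* Indexing is 1-based `(z, y, x)` throughout, the native R convention.
* 16-bit TIFF I/O round-trips integer gray values exactly; the voxel size
  lives in a JSON sidecar and is mandatory on read — refusal over
  guessing. DICOM is out of scope for this implementation (no R-side
  reader in the supported stack); the TIFF path carries all contracts.
* Constant stacks cannot be thresholded (error); seeds in tissue or
  inside a stopper are errors; empty slice designs are errors; an empty
  acinus list subsamples to an empty list (not an error).
* A single-acinus animal reports SD 0 with an explicit `sd_defined =
  FALSE` flag.
* All internal math is double precision; rounding is display-only.

## Problem sizes

The shipped tests and the acceptance script run phantoms of roughly
60–130 voxels per edge, cohorts of 2–4 acini per day with counts scaled
by 10, 20 phantom seeds for disector exactness, a 3 × 3 × 3 exhaustive
Cavalieri design, and 2000 null simulations for the rank-test
calibration. These sizes were chosen so a full run completes in a few
minutes on one core; every check is size-free in its logic and can be
rerun at larger sizes by changing the corresponding arguments.

## Known limitations

* The ductal fractions and the (α, m) behind the Šidák threshold are
  reverse-engineered from published values, not independent measurements.
* The grayscale interruption detector is heuristic and unvalidated
  against operator counts.
* Phantom alveoli are spherical caps; real alveoli are polyhedral with
  shared septa, so surface-dependent quantities (deliberately out of
  scope) must not be read off these phantoms.
* The CE formula underestimates total estimator variance on small masks
  (no nugget term).
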