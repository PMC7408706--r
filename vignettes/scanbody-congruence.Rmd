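---
title: "Scanbody mesh congruence: models, registration, and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanbody mesh congruence: models, registration, and the statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanbody)
```

## The problem

In digital implant prosthodontics, the 3D pose of an implant is captured by
scanning a *scanbody* — a transfer post screwed onto the fixture — with an
intraoral scanner (IOS). During CAD modelling, the technician replaces the
scanned surface reconstruction (the *mesh*, ME) with the manufacturer's exact
CAD model of the part (the *library file*, LF) via a best-fit superimposition.
If the scanned mesh and the library file are not dimensionally congruent, the
best-fit is pulled toward whatever surface dominates it — typically the flat
reference face — and the substituted library lands in a slightly wrong pose.
Over a full-arch restoration on six implants those errors accumulate into
clinically relevant misfit.

`scanbody` implements the complete measurement pipeline used to quantify this
congruence, exercised on synthetic scan meshes with controlled error models:

1. **mesh I/O** — STL (binary + ASCII), ASCII PLY, OBJ; validation; trimming;
2. **synthetic scanbody generation** — a parametric reference mesh and
   per-scanner error models standing in for real scans;
3. **registration** — three-point landmark alignment followed by robust
   point-to-plane ICP with at least 100 iterations per case;
4. **deviation analysis** — signed point-to-surface distances in µm,
   colorimetric banding (±50 µm scale, ±1 µm green band), three-region
   qualitative direction labels;
5. **study statistics** — per-cell descriptives, balanced scanner estimates
   with Tukey-adjusted contrasts, within-scanner scanbody contrasts, Friedman
   rank tests with Holm correction, agglomerative biclustering, all at
   α = 0.01.

## The synthetic scanbody and what it stands in for

No scan meshes are publicly deposited for studies of this kind, so the
package generates its own study material. `scanbody_spec()` describes a
13 mm tall cylindrical scanbody (shaft radius 2.5 mm) with one flat scanning
face (chord width 3.5 mm), a 0.5 mm chamfered top, and a target triangle edge
length of 0.3 mm. Only the *relative* geometry matters for congruence
analysis — a planar reference face against a cylindrical "back" — so every
dimension is a parameter. The tessellation subdivides the flat face into
3k equal columns so that the central-third band boundary falls exactly on
vertex columns, which keeps the `flat_central` / `flat_lateral` /
`back` face partition of `label_regions()` exact rather than approximate.

`error_model()` applies, in a fixed documented order:

1. a **manufacturing scale offset** drawn uniformly within the production
   tolerance (±20 µm) and applied along vertex normals — the physical part is
   not the CAD ideal;
2. a **region-dependent mean normal offset** (µm; positive = outward growth,
   negative = inward shrinkage);
3. optional **Laplacian smoothing** — a surrogate for the mesh
   post-processing suspected of biasing reconstructions inward;
4. per-vertex **Gaussian noise** along normals;
5. a random **rigid pose** (the scan's arbitrary frame).

The order is fixed for reproducibility; each stage's random draws come from a
seed split deterministically per (scanner, model, scanbody), so adding a
replicate never perturbs earlier ones. In `generate_study()` and
`run_study()` the six per-part manufacturing offsets are drawn **once** and
shared across scanners, because the same six physical parts are scanned by
every device — this is what makes "scanbody position" a real blocking factor,
and it is the generative source of the between-position differences the
statistics then detect.

The five shipped profiles (`default_scanner_profiles()`) span the deviation
signatures reported across commercial IOSs: outward-dominant growth
(+26 µm, "CS 3700-like"), inward-dominant shrinkage at three severities
(−24, −32, −36 µm), and a mixed profile with opposite-signed regional offsets
(+18 µm flat-central, −18 µm flat-lateral, 0 back, noise 40 µm). The mixed
signature is deliberately *regional* rather than pure zero-mean noise: a
pure-noise profile's per-superimposition majority label is a near coin flip,
and the predominance table amplifies any microscopic bias into a spuriously
stable direction; opposite-signed regions reproduce the scan/reference
interpenetration pattern robustly. Offsets and noise levels were chosen once
so per-cell mean absolute deviations land in the 20–50 µm range typical of
scanbody congruence studies.

**What the generator does not emulate:** optics, reflectance, stitching
drift across the arch, partial coverage, holes, or topology changes. Passing
tests therefore demonstrate that the *measurement chain* (registration,
signed deviation, statistics) recovers known ground truth, not that any
particular commercial scanner behaves like a profile.

## Registration

`landmark_align()` is the closed-form orthogonal Procrustes solution (SVD
with determinant correction): the global least-squares rigid transform for
the operator's three picked points, used only to initialise.

`icp_point_to_plane()` then minimises
$\sum_i w_i \left( n_i \cdot (R s_i + t - q_i) \right)^2$
over rigid $(R, t)$, where $q_i$ is the *exact* nearest point on the
reference surface to the moved sample $s_i$ and $n_i$ the normal of its
nearest face. Each iteration solves the small-angle 6×6 normal equations and
re-orthonormalises the rotation (polar factor). Nearest-surface queries use a
uniform-grid index whose expanding shell search stops only when no unvisited
cell can beat the current best — accelerated results equal brute force
exactly, which the tests assert against an independent all-faces oracle.

Numerical choices worth knowing:

* **Correspondence source.** Correspondences are the source mesh's *face
  centroids carrying their face areas as weights*; when the tessellation
  exceeds `sample_count` (default 20 000) a seeded *uniform* face subset is
  used, with areas retained as weights. Two measured properties drive this:
  for a closed mesh $\sum_f A_f n_f = 0$ and $\sum_f A_f (c_f \times n_f) = 0$
  *exactly*, so a normal-symmetric surface offset (a uniformly grown or
  shrunken part) cannot masquerade as a rigid motion — with random point
  sampling the residual Monte-Carlo imbalance of order
  $\text{offset}/\sqrt{n}$ leaks into translation and axial rotation.
  And the subset must be uniform rather than area-biased, because gross
  vertex outliers *inflate* the areas of the faces they touch; area-biased
  sampling would preferentially sample exactly the corrupted geometry the
  robust weights are meant to reject.
* **Robust weights.** Tukey biweight (c = 4.685 by default) with the scale
  estimated as 1.4826 × the median absolute residual **about zero**. The
  residual's natural target is the surface itself: centring the MAD at the
  median residual makes the scale collapse when the whole surface sits at a
  uniform offset (every residual ≈ +26 µm, spread ≈ noise), classifying the
  bulk as outliers and producing singular normal equations. The scale is
  clamped below at 1 nm so exactly-converged data (all residuals at machine
  precision) keeps unit weights while gross outliers still reach weight 0.
* **Iterations.** At least `min_iterations = 100` per case, so every
  superimposition in a study is comparable; afterwards the loop stops when
  the RMS residual changes by less than `convergence_tol_um` (10⁻⁴ µm),
  capped at `max_iterations = 500`.
* **Direction.** The scan moves onto the fixed library frame (the library is
  the reference); `signed_deviation()` offers the reverse sampling direction
  behind a flag for sensitivity checks.
* **Degeneracy.** A source that leaves any of the six degrees of freedom
  unconstrained (e.g. a plane) produces rank-deficient normal equations and a
  clear error rather than a silent drift.

## Deviation quantification and classification

`signed_deviation()` samples the scan surface (area-weighted, seeded),
transforms the samples into the reference frame, and reports exact distances
to the reference surface in µm, signed by the side of the nearest reference
face's outward normal: positive = outward excess, negative = inward defect.
`summarize_congruence()` reports the headline statistics on *absolute*
deviations (mean, SD with n−1, median, quartiles by linear interpolation,
range, normal-approximation 95% CI) while retaining the signed mean for
directionality — congruence tables in this field are tabulated as absolute
deviations, but the sign carries the clinically interesting direction.
The normal-approximation CI is the simplest defensible choice at thousands
of samples per superimposition.

`classify_bins()` reproduces the colorimetric convention: a ±1 µm green
band ("no deviation"), outward above, inward below, saturation at ±50 µm
affecting rendering only. `direction_label()` takes the per-region majority
class, with ties resolved to "no deviation". The three regions are the flat
face's central third, the flat remainder, and the cylindrical back; the
central band is defined as the middle third of the flat-face width — the
boundary is a package convention (no standard exists) and is exact by
construction of the tessellation.

## Study statistics

All statistics consume a long-format `deviation_table` (scanner × scanbody ×
model replicate → mean absolute deviation, µm).

* **Balanced estimators.** Under the balanced two-level design each
  scanner's estimate is the unweighted mean of its six cell means — the
  mixed-model point estimate coincides with this closed form under balance,
  which is why a full REML fit is deliberately out of scope. Contrast
  estimates are differences of these means; CIs and p-values come from the
  studentized-range distribution with the between-scanbody variance of cell
  means (pooled across scanners) as the error term. With one replicate per
  cell the point estimates are still exact; with full data the p-values are
  approximate relative to an observation-level mixed model, which is
  documented rather than hidden.
* **Scanbody contrasts.** All 15 position pairs per scanner, estimated as
  cell-mean differences, Tukey-adjusted within the 6-mean family using the
  pooled within-cell residual of the two-way layout with interaction.
* **Outliers.** The default rule flags observations whose *leave-one-out*
  z-score within the cell exceeds 3. A plain within-cell z-score is bounded
  by $(n-1)/\sqrt{n} \approx 2.85$ at $n = 10$ and would mask precisely the
  gross outliers the rule exists for. Flags exclude rows from parametric
  estimation only; descriptives and rank tests keep them.
* **Friedman / Holm.** `stats::friedman.test` per scanner (models as
  treatments, scanbody as block; average-rank ties), Holm across the scanner
  family via `p.adjust`. Fully tied blocks (a NaN from the tie-correction
  denominator) are reported as statistic 0, p = 1.
* **Biclustering.** Independent `hclust` trees over rows and columns of the
  cell-mean (or cell-SD) matrix; Euclidean distance with average linkage by
  default — common heatmap defaults, configurable, since no canonical choice
  exists for this analysis.
* **Type-I audit.** `simulate_null_table()` draws every (scanner, scanbody)
  cell level from one common distribution (a cell-level effect standing for
  scanner × scanbody interaction variability plus replicate noise), so any
  significant scanner pair is a false positive. The audit runs at the table
  level: under identical scanner profiles the per-cell summaries are
  exchangeable across scanners, so simulating tables directly is the
  faithful null for the contrast machinery, at a millionth of the cost of
  re-running the mesh pipeline 500 times. The measured rate of
  Tukey-significant pairs at α = 0.01 is ≈ 0.005 over 500 studies of
  3 scanners × 5 models.

## Problem sizes and reproducibility

The default study configuration (`study_config()`) runs 5 profiles ×
10 models × 6 scanbodies = 300 superimpositions at a reduced ICP budget of
1500 correspondences per iteration and 4000 deviation samples per
superimposition — registration errors at this budget are well below a
micrometre, two orders under the 20–50 µm deviations of interest, and a full
study completes in a couple of minutes on one core. Precision-critical
checks (known-transform recovery, symmetric-offset invariance) use dense
meshes and full centroid sets instead. Everything is deterministic given the
master seed: same configuration and seed, byte-identical tables.

## Known limitations

* One-directional point-to-plane registration (scan → library); symmetric
  formulations are not implemented.
* The trim template is an axis-aligned box or cylinder, with whole-face
  keep/drop by centroid — no re-triangulation at the cut.
* The error models are phenomenological. In particular the smoothing stage
  is a plausible surrogate for scanner post-processing, not a claim about
  any vendor's algorithm.
* PLY support is ASCII-only and geometry-only; OBJ materials are ignored.
* CIs for scanner estimates derive from six cell means (5 df); they are
  honest but wide, and p-values from cell means are conservative relative to
  an observation-level mixed model.
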