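---
title: "Methods: Voronoi myocardial territories and the MMAR/MLD index"
author: "mmarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Voronoi myocardial territories and the MMAR/MLD index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmarisk)
```

## The problem

Fractional flow reserve (FFR) — distal coronary pressure over aortic
pressure under maximal hyperemia — is the reference standard for deciding
whether a coronary stenosis is functionally significant (FFR ≤ 0.8), but it
requires an invasive pressure wire. Anatomical severity alone predicts FFR
poorly, because ischemia depends not only on how narrow a lesion is but on
how much myocardium lies downstream of it: a lesion feeding a large
territory must carry a large hyperemic flow, and the same anatomical
narrowing then produces a larger pressure loss.

`mmarisk` implements the computational chain behind a non-invasive
surrogate built on that observation: the **myocardial mass at risk (MMAR)**
subtended by a lesion, divided by the **minimal lumen diameter (MLD)** from
quantitative coronary angiography. The MMAR/MLD ratio is a
demand-to-supply index; high values predict FFR ≤ 0.8.

## Territory computation

The geometric core assigns every voxel of a binary left-ventricular
myocardium mask to its nearest point on the coronary centerline tree
(a Voronoi tessellation with the arteries as seeds), then sums the volume
of all voxels whose nearest point lies at or downstream of the lesion.

Concretely:

1. **Densification.** The polyline tree is resampled so consecutive
   samples are at most `max_spacing` apart (default: half the smallest
   voxel spacing). Seeding the tessellation with sparse polyline vertices
   would bias territories toward long edges; sampling below grid
   resolution makes the discrete seed set behave like the continuous
   curve. On the built-in fixtures, halving `max_spacing` further changes
   MMAR by well under 1%.
2. **Distal set.** Distality is along-tree reachability, not Euclidean
   position: the lesion sample plus everything reachable moving away from
   the ostium, into all daughter branches. Lesion anchors given as
   (branch, arc length) are snapped to the nearest densified sample at or
   beyond that arc length, which makes the distal set well defined on the
   sampled tree.
3. **Assignment.** Each foreground voxel center (world mm, voxel-center
   convention, 0-based indices) is labeled with the sample minimizing
   Euclidean distance. Ties break to the lowest sample id — a
   determinism device with measure-zero effect at float precision.
   Background voxels carry the sentinel label 0 and are never claimed.
4. **Summary.** `MMAR` is the labeled-distal voxel count times the voxel
   volume (ml); `%MMAR` is its percentage of the total foreground volume.
   Volumes are reported in ml to match common clinical software output;
   a mass in grams is available via an explicit density argument
   (1.05 g/ml is conventional) but is off by default.

Because every foreground voxel receives exactly one label, territory
volumes are conserved exactly at the integer-count level: the three
ostial territories of an RCA/LAD/LCx tree partition the LV and their
`%MMAR` values sum to 100, and moving a lesion distally can only shrink
its distal set (the package's tests sweep every branch to confirm
monotonicity).

Distances are Euclidean in world millimetres. The NIfTI loader accepts
axis-aligned, positively oriented transforms only; oblique volumes must be
resampled upstream rather than silently reinterpreted.

## The statistical battery

- **ROC / AUC.** The AUC is computed as the tie-adjusted Mann–Whitney
  statistic (midranks). Variance comes from DeLong's structural
  components; the 95% CI is built on the logit scale and back-transformed
  so bounds stay inside [0, 1]. Degenerate zero-variance cases (AUC
  exactly 1) return a point interval with a warning. Correlated AUCs on
  the same cases are compared with the DeLong z test.
- **Operating point.** The reference studies report a cut-off without
  stating the criterion; the package uses Youden's J (the default in the
  common clinical GUI front ends to R), with closest-to-(0,1) available
  behind a flag. Ties resolve to the lowest cut-off, and positivity is
  inclusive (`value ≥ cutoff`) everywhere — classification, threshold
  tables, and diagnostic metrics use one convention.
- **Reclassification.** Risk models are logistic: base = diameter
  stenosis, extended = diameter stenosis + MMAR/MLD, outcome = FFR ≤ 0.8.
  The NRI is the continuous (category-free) variant — no risk categories
  are published for this problem — with an asymptotic CI from the
  multinomial variance of the up/down proportions; a categorical NRI is
  computed when the user supplies thresholds. The IDI is computed as the
  difference of discrimination slopes, which makes the defining identity
  exact rather than approximate in floating point.
- **Simple tests.** Pearson correlation, Mann–Whitney U (exact for small
  tie-free samples, tie-corrected normal approximation otherwise, no
  continuity correction), Pearson chi-squared without continuity
  correction, and median (Q1–Q3) summaries with type-7 quantiles. These
  delegate to base R's implementations; the package fixes and documents
  the conventions so reported tables are reproducible.

All p-values are two-sided.

## The synthetic cohort generator

No patient images or lesion tables are distributable, so the package
generates cohorts with the statistical and geometric structure the
analysis assumes. The generator is first-class, tested code — every
downstream stage is exercised against it.

**LV shell.** A truncated half-ellipsoid shell: outer semi-axes
(35, 35, 55) mm, 10 mm wall, truncation 0.85 (base plane at 0.7·c),
1 mm isotropic grid — about 150 ml of myocardium, a plausible adult LV,
and small enough that a full tessellation takes well under a second. The
voxelized volume agrees with the closed-form ellipsoid-difference volume
to better than 2%.

**Coronary tree.** Three arteries run from base toward apex on the outer
(epicardial) surface at separated azimuths with a gentle azimuthal drift,
each with 2–3 side branches leaving at spaced, jittered positions. All
nodes lie exactly on the implicit surface, so the generated geometry can
be verified against the surface equation directly.

**Lesion geometry.** MLD, reference diameter and length are log-normal,
with medians (1.39, 2.65, 12.0) and log-scale spreads (0.360, 0.235,
0.542) chosen so the quartiles match a published intermediate-stenosis
cohort; the spreads come from the identity sdlog = log(Q3/Q1)/1.349. The
log-scale MLD–RD correlation of 0.78 is derived the same way from the
diameter-stenosis quartiles (40–56%), and pairs violating MLD < RD are
re-drawn. Arteries are sampled with the study mix (RCA 18%, LAD 60%,
LCx 21%); lesions sit at a proximal-weighted Beta(1.0, 3.2) arc-length
fraction of their branch, 12% on side branches, with "proximal" defined
as the first 15% of the main branch — together this reproduces a ~35%
proximal share and a median MMAR inside the published interquartile band
(21.9–44.3 ml).

**FFR model.** Hyperemic flow is proportional to subtended volume,
Q = q·MMAR, and the trans-stenotic gradient follows classic stenosis
fluid mechanics — a viscous term linear in flow and an expansion term
quadratic in flow:

$$\Delta P = K_v \frac{L}{\mathrm{MLD}^4} Q
           + K_e \left(\frac{1}{\mathrm{MLD}^2}
                      - \frac{1}{\mathrm{RD}^2}\right)^{\!2} Q^2,
\qquad \mathrm{FFR} = \frac{P_a - \Delta P}{P_a} + \varepsilon$$

clamped to (0, 1], with ε ~ N(0, 0.04) emulating measurement
repeatability. Defaults are Pa = 90 mmHg, q = 2.5 ml/min per ml,
Kv = 0.031, Ke = 0.0073, calibrated once so that ~38% of default-cohort
lesions fall at FFR ≤ 0.8 (the prevalence of the reference cohort) with
the viscous and expansion terms contributing roughly 60/40 at the median
lesion. Noiseless mode (sd = 0) makes FFR a deterministic, strictly
monotone function of (MMAR, MLD), which the tests exploit.

**What the generator does and does not emulate.** It reproduces the
marginal geometry distributions, artery mix, prevalence, and — most
importantly — the *direction and ordering* of the correlation structure:
MMAR/MLD correlates with FFR more strongly (and negatively) than either
diameter stenosis or MMAR alone, and adding MMAR/MLD to a
diameter-stenosis risk model improves discrimination. It does **not**
reproduce clinical FFR marginals faithfully: the MLD⁻⁴ tail and the
absence of hyperemic flow autoregulation make the synthetic FFR
distribution wider than clinical quartiles, and the synthetic
correlations are stronger than clinical ones (a phantom has no
anatomical-variant noise, no papillary-muscle exclusions, no
imaging error). Passing tests therefore demonstrate correctness of the
computations and qualitative replication of the effect, not quantitative
agreement with any patient cohort.

## Numerical and design choices

- One RNG stream per cohort, seeded from the run seed, with a fixed
  documented draw order (arteries, branch choices, arc fractions,
  geometry, FFR noise) — cohorts and full study reports are
  byte-reproducible.
- `run_study` flags rather than fails on degenerate inputs: subgroup ROC
  rows need at least 5 positives and 5 negatives (small subgroups produce
  unstable AUCs and absurd CIs), and a single-class cohort still yields
  the group table with the ROC/reclassification marked unavailable.
- Zero-length centerline edges are tolerated (skipped with a warning);
  an empty tree or mask is an error.
- Supplied diameter-stenosis columns are recomputed from MLD and RD;
  disagreement beyond one percentage point warns rather than errors,
  since rounded published values need not compose exactly.
- Problem sizes used by the test-suite and the acceptance script — a
  150 ml shell at 1 mm, 300-lesion cohorts, 20 replicate seeds, 500
  coverage simulations — were chosen as the smallest sizes at which the
  stochastic checks are stable.

## Known limitations

- Tessellation is against centerlines, not lumen surfaces; very proximal
  voxels between parallel branches can flip ownership with centerline
  tracing noise.
- The NIfTI interface requires axis-aligned orientation.
- The logistic risk models are unpenalized; near-separable cohorts (easy
  to produce synthetically at small n with low noise) are flagged, not
  regularized.
- Right-ventricular and whole-heart territories, transmural subdivision,
  and segmentation itself are out of scope: the mask and tree are inputs.
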