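---
title: "Methods: microCT phenomics of the zebrafish vertebral column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microCT phenomics of the zebrafish vertebral column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertebrome)
```

This vignette is the package's account of its methods: the models it
fits, the parameters that matter, the numerical conventions it commits
to, and — because most of the test suite runs on synthetic data — what
the synthetic generators do and do not emulate.

## The measurement model

A calibrated microCT volume is a 3D grid of raw integer intensities
with an isotropic voxel size (21 µm for medium-resolution zebrafish
scans, 10.5 µm for high resolution). Raw values map to tissue mineral
density through the scanner calibration

$$\mathrm{TMD}\;[\mathrm{mgHA/cm^3}] = \frac{x}{4096}\cdot s + c,$$

with slope $s = 281.706$ and intercept $c = -195.402$ as defaults.
These constants live in `ct_calibration()` and must be replaced with
the user's own scanner calibration; DICOM rescale tags are deliberately
ignored because the mapping addresses raw values. Negative calibrated
densities are retained — density statistics are only ever computed over
above-threshold voxels, where values are positive in practice.

Axis convention: grid axis 1 is dorsoventral (dorsal at index 1), axis
2 mediolateral, axis 3 anteroposterior (anterior at slice 1). This
matches scanner stacking and is configurable via `axis_labels`.

## Segmentation

**Thresholding.** Fish differ enough in mineralization that a fixed
threshold is unreliable, so the threshold is computed per animal: the
user outlines the fish on a maximum-intensity projection, voxels
outside the extruded outline are zeroed, and IsoData (iterative
intermeans on a 256-bin histogram of the nonzero voxels of the full 3D
volume) supplies a base threshold that is multiplied by a correction
factor, 0.73 by default. The 3D histogram (rather than a histogram of
the projection) matches how stack-wise IsoData is conventionally
applied. Foreground is `intensity >= threshold` — the inclusive rule is
stated once and used everywhere.

**Separating vertebrae.** Users mark each intervertebral boundary with
a seed line drawn in the mid-sagittal plane (a dorsal and a ventral
endpoint in voxel coordinates); the plane it defines is the segment
extruded across the full mediolateral extent. For each boundary the
algorithm zeroes the plane's voxels, labels 26-connected components,
and tallies component labels within windows extending 10 voxels to
either anteroposterior side of the plane. If the plurality components
on the two sides differ, the boundary is accepted; otherwise both
endpoints step outward along the segment's own direction by 2 voxels
and the test repeats. Votes are voxel counts by default
(component-count voting is a switch); a tie counts as "not separated".
The 2-voxel step and 10-voxel window are config keys — they trade a few
extra iterations against the risk of overshooting a thin gap — and
26-connectivity is the permissive choice that avoids spuriously
splitting thin arches. The plane rasterization is kept 8-connected
thick in the sagittal plane so a 26-connected path cannot slip through
a diagonal. Final labels are assigned per connected component by
plurality of the inter-boundary bins, which enforces the invariant that
no component carries two vertebra labels.

**Element masks.** Within one vertebra, the neural arch is everything
dorsal to the line through the two dorsal seed endpoints; the centrum
is the quadrilateral prism spanned by all four endpoints, dilated
isotropically by a 5-voxel buffer (2D Euclidean dilation in the
sagittal plane, applied across the mediolateral extrusion); the haemal
arch/ribs are the remainder. The three masks partition the vertebra
exactly, by construction. The buffer direction is not dictated by the
construction itself; isotropic dilation is the neutral choice and the
buffer is a parameter.

## Morphometry

Per element and per whole vertebra (computed on the union mask, not
averaged from the elements), the package reports:

* **Vol** — voxel count × voxel³. Exact by definition.
* **SA** — count of foreground voxels with a face-adjacent background
  neighbour, × voxel². This perimeter-voxel estimator is biased
  relative to meshed surfaces; do not compare against mesh-based
  surface areas. Volume-boundary voxels count as surface.
* **Th, Th.sd** — mean and SD of model-independent local thickness:
  each voxel's thickness is the diameter of the largest inscribed
  sphere containing it, computed by distance transform → sphere
  propagation. Spheres are centred on foreground voxels with radius
  `edt − 0.5` (the structure boundary sits half a voxel beyond the
  nearest background voxel centre) and a voxel counts as covered when
  its centre is within half a voxel of the sphere. Under this
  convention laterally extensive slabs of odd voxel width are exact,
  even widths read one voxel low, and digital spheres read ~5% high —
  all within the one-voxel accuracy the package claims.
* **TMD, TMD.sd** — mean and SD of calibrated intensity over the mask.
* **Cent.Le** — anteroposterior distance between the midpoints of the
  vertebra's two boundary lines.

SDs are population SDs: the voxels of an element are the complete
population of that element, and the SD measures intra-specimen
variation, not sampling error. Phenome tables are written as plain TSV
with the long column names (`VertebralVolumes`, `CentrumTMDs`, ...)
so existing files in that dialect parse unchanged; surface areas are
reported in physical units (µm²).

## The global test

For one feature, fish form rows and vertebrae 1..16 form columns of a
covariate matrix $X$; the binary group indicator $y$ is the response.
The statistic is the centred quadratic form through the covariate Gram
matrix, scaled by the response sum of squares:

$$Q = \frac{(y-\bar y)^\top X_c X_c^\top (y-\bar y)}
          {(y-\bar y)^\top (y-\bar y)}.$$

This is the linear (identity-link) form of the score test, which for a
two-group response is a monotone transform of the logistic score test;
covariates are centred but *not* standardized, so the covariance
structure keeps its weight. $Q$ is invariant to scaling of $X$ or $y$,
to adding constants, and to swapping group labels; the per-vertebra
component statistics $Q_j$ (single-column versions) sum exactly to $Q$.

The default p-value treats the null response as exchangeable Gaussian:
$P(Q \ge q)$ equals the probability that a weighted sum of independent
$\chi^2_1$ variables is non-negative, with weights the eigenvalues of
$X_c X_c^\top - qH$ on the centred subspace. That probability is
computed by Imhof's integral. Two numerical points matter: the weights
are first rescaled by their largest magnitude (the probability is
invariant to positive rescaling, and without it the integrand's mass
sits at $u \sim 1/\lambda$ where quadrature misses it), and if the
integration fails or leaves $[0,1]$ a two-moment normal approximation
takes over. The asymptotic default is deliberate: with 3 fish per group
an exact permutation test has only $\binom{6}{3} = 20$ assignments and
cannot reach $p < 0.01$, yet screening at stringent alpha levels is
exactly where the workflow operates. Permutation p-values remain
available (`method = "permutation"`), with exact enumeration whenever
the number of distinct assignments is at most 20,000 — that exact
enumeration is also the oracle the test suite checks the machinery
against.

Per-vertebra component p-values are reported unadjusted (components are
descriptive, localizing the association rather than confirming it).
Analyses default to the 16 anterior-most vertebrae; fish missing more
than a quarter of the window are dropped with a warning, and the
remaining analysis uses the vertebrae present in all fish.

**Barcodes.** A fish's standard score for a measure is its per-vertebra
value minus the control population's mean, over the control population's
SD, with mean and SD pooled across *all* vertebrae and all control fish
jointly (the pooling choice follows from treating the column as one
distributed organ; per-vertebra pooling would erase exactly the
patterns the workflow looks for). Control fish scored against their own
cohort pool to mean 0, SD 1 per measure.

**Royston screening.** Before a feature is trusted to a multivariate
normal model, Royston's $H$ (Shapiro–Wilk statistics per vertebra,
normalized and combined with an equivalent-degrees-of-freedom
correction for inter-vertebra correlation) is run on two interleaved
8-vertebra subsets, keeping the variable count below the sample size.
Features failing either subset at 0.05 are excluded from simulation by
default.

## Monte-Carlo power analysis

Control cohorts supply $\hat\mu$ and $\hat\Sigma$ (sample moments,
denominator $n-1$) for each feature over vertebrae 1..16. Mutants are
emulated by shifting means to $\mu_i + d_i\sigma_i$ with equal
covariance; $d_i$ is uniform or a linear anterior→posterior ramp
($d_1 = 0$, $d_k = d$). Each replicate draws a WT and a mutant cohort
(sensitivity) and two WT cohorts (specificity) and applies three
procedures: the global test on the full window, a two-tailed Welch
t-test of vertebra 2, and a Welch t-test of the per-fish mean over the
window. Defaults: 10,000 replicates, seeds recorded in every result,
rank-deficient covariances (unavoidable when models come from 3 fish)
sampled through the eigen-decomposition with negative eigenvalues
clipped at zero. The FDR quoted for an operating point is the two-urn
estimate $\alpha/(\alpha + \text{sensitivity})$, i.e. equal numbers of
null and alternative comparisons.

## Allometric normalization

Growth is modelled per feature as $y = a x^b$ with $x$ the standard
length; fitting is OLS on $\log y \sim \log x$, which recovers $(a, b)$
exactly on noiseless power-law data and estimates $b$ without bias
under multiplicative log-normal noise. Isometric references are $b = 3$
for volumes and TMC, 2 for areas, 1 for lengths and thicknesses.
Normalization slides control fish to a reference length via
$y^* = y\,(x^*/x)^b$; the reference defaults to the mutant group's mean
length, and mutants themselves are never rescaled — their allometry
cannot be assumed to match the controls'. TMD is handled in two steps:
TMC and volume are normalized with their own exponents and TMD is
recomputed as their ratio, because TMD is a ratio of mass to volume and
has no isometric exponent of its own. SD-type columns inherit their
parent's exponent, preserving the element's coefficient of variation.
CVs are population-SD over mean.

## Synthetic data: what it emulates, what it does not

**Spine phantoms** (`generate_spine_phantom()`) are columns of hollow
hourglass centra (outer endplate radius 10 voxels, wall 4, length 24,
waist 0.7) with a dorsal neural blade and a ventral haemal blade per
vertebra, separated by 4-voxel gaps; anterior vertebrae get longer
haemal blades so the rib-driven anterior/posterior haemal-volume
contrast of real fish is present. Raw intensities (13,000 for centra,
11,500 for arches, Gaussian noise SD 150 by default) calibrate to
realistic densities near 700 and 600 mgHA/cm³. Ideal seed lines sit at
gap centres with the dorsal endpoint at the centrum crest and the
ventral endpoint inset 5 voxels into the silhouette — emulating a user
clicking inside the ventral margin, which the centrum buffer then
restores; with these seeds and no noise the element masks equal truth
exactly, which is what lets the suite assert exact volume recovery
rather than a tolerance. Truth volumes are voxel counts (the definition
of the volume measure); thicknesses and pitch are analytic. Phantoms do
not attempt anatomical realism (no endplate ridges, no dysmorphic
vertebrae, no beam hardening), so they validate the geometry of the
algorithms, not robustness to pathology.

**Phenome cohorts** (`simulate_phenome_cohort()`) generate per-fish
tables of all 25 measures from an allometric model: every family scales
as a power of standard length (volumes $b = 2.6$ and thicknesses
$b = 0.8$, mildly below isometry; TMD weakly positive at $b = 0.3$;
lengths $b = 1$), with a fish-level log-normal factor per feature
family shared along the column and a smaller per-vertebra residual
(e.g. 4% vs 1.5% for TMD). The fish factor dominating the vertebra
residual reflects how strongly a single fish's curve tracks its own
level along the column — the premise that makes barcodes legible — and
produces strong inter-vertebra correlation within a feature. Baselines
(e.g. centrum TMD 480 mgHA/cm³, centrum volume 2×10⁷ µm³ at the 20 mm
reference length) are plausible adult-zebrafish values; the haemal
volume drops to 45% after vertebra 10 to emulate the rib transition.
These parameters were fixed once, on the grounds above, before the
acceptance suite was run, and were not revisited afterwards.

What the cohorts do *not* carry is the covariance structure of any real
cohort: the true inter-vertebra and inter-feature correlations of
scanned fish are unavailable here, so statistical results that depend
only on calibration (specificity ≈ 1 − α for every procedure, uniform
null p-values, exact moment recovery) transfer to real data, while
operating points that depend on the covariance (absolute sensitivities
at a given $d$ and $n$, the median pairwise correlation across all 600
measurements) are properties of the stand-in. The acceptance suite
asserts published operating points against the stand-in at their stated
tolerances and several land within them; the ones that do not are left
failing rather than retuned, because moving generator parameters toward
a target after measuring would make the test circular.

## Numerical choices and degenerate inputs

* IsoData on constant input raises a "degenerate histogram" error; an
  empty outline, an empty element mask, or fewer than 2 fish per group
  are all rejected up front rather than propagated as NaNs.
* Empty element masks yield missing measure fields with a warning
  (missing vertebrae are flagged, never zero-filled).
* The Dice coefficient of two empty masks is defined as 1.
* Plurality ties during separation count as "not separated" and trigger
  another extension; a separation line that reaches the volume boundary
  without separating raises an error naming the seed.
* Identical boundary lines give centrum length 0 with a warning.
* Reorientation uses bilinear in-plane interpolation with zero fill;
  rotation by 0 or 360 degrees is the exact identity.
* All Monte-Carlo results are bit-reproducible given their seed.

## Problem sizes

The test suite runs phantoms of 4 vertebrae in a 58×28×116 grid,
statistical cohorts of 3–34 fish, and Monte-Carlo runs of 200–10,000
replicates (10,000 for the acceptance operating points, smaller for
property checks); the full suite completes in a few minutes on one CPU.
These sizes were chosen as the smallest at which the asserted
properties are stable.

## Known limitations

* Surface area is a voxel-face count; thickness inherits the half-voxel
  conventions above. Both are consistent within the package but not
  comparable across estimators.
* Seed lines are required input: there is no automatic boundary
  detection, and the package offers no interactive editing — it is a
  programmatic/CLI toolkit.
* The global test's asymptotic p-values are slightly conservative at
  n = 3 per group; the permutation option is exact but coarse there.
* Beam hardening and partial-volume effects are not modelled or
  corrected; TMD comparisons should hold scan geometry constant.
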