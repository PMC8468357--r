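---
title: "Assessing radiomic feature reproducibility under manual and semi-automatic tumour segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing radiomic feature reproducibility under manual and semi-automatic tumour segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrepro)
```

## The problem

Radiomics turns a segmented tumour on a medical image into hundreds of
quantitative descriptors — intensity statistics, 3D shape measures,
gray-level texture matrices, and the same statistics recomputed on
wavelet-filtered versions of the image. Before such features can feed a
prognostic model, they must be *reproducible*: a feature that changes
substantially when a different observer draws the tumour outline, or when
the same observer repeats the segmentation weeks later, carries more
delineation noise than biology.

`radrepro` implements the full computational chain for studying this
question on hepatocellular carcinoma (HCC)-like MR volumes:

1. a **synthetic study generator** producing phantom T1-weighted-like
   volumes with ellipsoidal tumours and simulated observers — several
   independent manual delineations per subject plus repeated
   semi-automatic (flood-fill) segmentations;
2. a **seeded flood-fill segmenter** with intensity tolerance,
   configurable connectivity and a neighbourhood-mean leak check;
3. a **662-feature radiomic extractor** (18 first-order + 14 shape + 54
   texture features on the original image, and 18 + 54 on each of eight
   undecimated wavelet channels);
4. an **ANOVA-based intraclass correlation (ICC) analysis** that bands
   every feature into high / medium / low reproducibility and compares
   the two segmentation strategies.

Because every stage is seeded, an entire study — volumes, masks, feature
table, report — is reproducible byte-for-byte from a configuration object
and one integer.

## The synthetic study

The default `study_design()` emulates a two-arm segmentation experiment
on 30 subjects split evenly between two disease-stage groups. Tumour
diameters are drawn per group from Gaussian distributions, 3.7 ± 0.7 cm
(Stages I–II) and 8.9 ± 3.4 cm (Stages III–IV), values representative of
early- versus late-stage HCC. Each subject receives 4 independent manual
delineations and 2 semi-automatic observers × 2 sessions, i.e. 120 + 120
= 240 masks in total.

The phantom itself is deliberately simple: an ellipsoid (axis ratios
uniform in [0.7, 1.0], random orientation) of fixed intensity contrast
(+50 by default) over a background of 100, overlaid with two stochastic
components — a Gaussian-smoothed random field (SD 8, correlation length
~3 voxels) that gives the texture matrices something non-trivial to
measure, and white Gaussian voxel noise (SD 5). The default grid is 64³
voxels at 1.5 mm isotropic spacing. Diameters whose rasterization would
not fit the 9.6 cm field of view are truncated at rasterization time
(with a warning); the *sampled* diameter is what the study manifest
records, so the cohort statistics remain recoverable. At this default
grid most Stage III–IV draws hit the cap — the phantom cohort is a
scaled-down emulation, not an attempt to image 9 cm lesions in a 9.6 cm
box.

### Observer models

The two arms are driven by different noise mechanisms, mirroring how the
two segmentation styles actually err:

* **Manual observers** deform the true boundary by a smooth random radial
  displacement field: a degree ≤ 2 real spherical-harmonic expansion
  evaluated on the direction from the tumour centre, with coefficients
  scaled so the pointwise displacement SD equals `manual_boundary_sd`
  (default 2 mm). Half of the variance is an observer-specific *bias
  field*, fixed across subjects and sessions (a person who systematically
  over-segments anteriorly keeps doing so); the other half is fresh
  per-session noise. Smooth fields produce spatially correlated boundary
  errors — the realistic failure mode — rather than voxel salt-and-pepper.
* **Semi-automatic observers** place a handful of seed voxels near the
  tumour centroid — jittered by an observer bias offset plus per-session
  noise with total SD `semiauto_seed_jitter_sd` (default 1 mm), clamped
  inside the tumour — and run the flood fill on the noisy image. Their
  variability is therefore *induced* through the algorithm: a different
  seed set shifts the reference intensity and the accepted region, but
  the underlying image evidence anchors the boundary.

This asymmetry — large direct boundary noise in the manual arm, small
indirect noise in the semi-automatic arm — is the structural driver of
the study's expected finding: higher feature ICCs for the flood-fill arm.
The magnitudes themselves are configuration, not measurements; no
observer noise magnitudes are available to calibrate against, so the
defaults were chosen once as plausible for liver MR delineation and left
alone. Note that the seed jitter is below the voxel pitch, so two
sessions occasionally land on identical seed voxels and produce identical
masks — a faithful consequence of working on a discrete grid.

For *null-calibration* experiments (checking the analysis under "no
method difference"), the flood-fill mechanism is a confounder: no
parameter equates its error distribution with the manual model's. Setting
`semiauto_model = "displacement"` therefore runs the semi-automatic arm
under the same displacement observer model with its own
`semiauto_boundary_sd`, making the two arms statistically exchangeable
when the design is otherwise symmetric.

## Flood-fill segmentation

`flood_fill()` grows a region from seed voxels. A candidate voxel is
accepted iff

* it is connected to an accepted voxel under the configured connectivity
  (faces-6 by default — the direct 3D analogue of 4-connectivity in 2D —
  with 18 and 26 available),
* its intensity lies within `tolerance` of the reference intensity (the
  mean over the seed voxels by default, robust to one noisy seed), and
* when `neighborhood_size > 0`, the mean intensity of the cubic
  neighbourhood of that radius also lies within tolerance.

The last clause is the leak guard: a one-voxel bridge between the tumour
and an adjacent structure passes the per-voxel test but fails the
neighbourhood-mean test, so growth stops at the bridge. Acceptance is a
property of the voxel alone, which makes the result the connected
component of the acceptable set containing the seeds — independent of
traversal order by construction, with the seeds always included.

Interactive post-editing has no place in a fully automatic pipeline, so
`finalize_mask()` replaces it with a deterministic cleanup: keep the
largest face-connected component and fill fully enclosed holes. It is
idempotent, and it is applied to every simulated mask in both arms.

There is no principled universal default for the intensity tolerance; the
study generator uses half the tumour-background contrast (which its
phantoms know), and for unknown volumes a sensible starting point is
about twice the background noise SD.

## Feature extraction

`extract_all()` produces 662 named values:
14 shape + 72 (first-order + texture) on the original image + 8 × 72 on
the wavelet channels, under the naming scheme
`<channel>_<family>_<feature>`.

**Discretization.** All texture matrices (and the first-order Entropy and
Uniformity) operate on gray levels obtained by `fixed-bin-count`
discretization of the masked intensity range into 32 bins by default
(`fixed-bin-width` is also available). Texture values depend materially
on this choice, which is why it is an explicit, recorded parameter.
Every channel is re-discretized on its own range, so wavelet channels
with small dynamic range still use the full level set, and adding a
constant to the image changes no texture feature.

**Texture matrices.** GLCM co-occurrences are counted symmetrically at
distance 1 along the 13 unique 3D directions (the 26 neighbours modulo
sign, in a fixed documented order), each direction normalized and the 13
matrices averaged. GLRLM decomposes the masked voxels into maximal
constant-level runs per direction; features are computed on the
direction-summed aggregate, whose voxel-count conservation
(`sum of l * r(i,l)` = masked voxels × directions) is tested per
direction. GLDM counts, for each masked voxel, neighbours within
Chebyshev distance 1 whose level differs by at most 0 (`alpha`); the
dependence index in the feature formulas is the count plus one, so the
small-dependence emphases stay finite. Pairs, runs and neighbourhoods
never cross the mask boundary, and direction offsets live on the voxel
lattice (anisotropic spacing is ignored for offsets — a known limitation
shared with common practice).

**First-order conventions.** Percentiles interpolate linearly between
order statistics (R type 7); Variance and the standardized moments use
population (divide-by-N) normalization; Kurtosis is non-excess, so a
Gaussian sample sits near 3; Total Energy multiplies Energy by the voxel
volume in mm³; Entropy uses a guard constant `eps = 2.2e-16` inside the
logarithm.

**GLCM degenerate cases.** With a single occupied level the marginal
deviations vanish; Correlation and the maximal correlation coefficient
return 1 (the perfectly-dependent limit), the information measures fall
back to 0, and the Imc2 radicand is clamped at zero.

**Wavelet channels.** A single-level undecimated (stationary) transform
with the Coiflet-1 filter bank: the low- or high-pass analysis filter is
applied by circular convolution along each axis; channel labels such as
`HLL` give the filter per axis in X, Y, Z order. No downsampling occurs,
so the original mask applies unchanged. Axes shorter than the 6-tap
filter support are symmetrically extended first (with a warning). A
constant image has exactly zero response in every channel containing a
high-pass axis — a property the tests assert.

**Shape.** Shape descriptors are geometric, computed once on the original
mask. Mesh Volume and Surface Area come from a triangulated isosurface:
marching tetrahedra on a body-centred 24-tetrahedra cell decomposition,
with vertices linearly interpolated at the half level of a *lightly
anti-aliased* indicator (Gaussian, sigma 0.6 voxel). The smoothing step
deserves a word: an isosurface of the raw binary mask is a beveled
staircase whose area overestimates that of the underlying smooth object
by 10–27% depending on the triangulation — enough to bias Sphericity for
every realistic tumour. Validating the estimator against closed-form
solids fixes the scale: with sigma = 0.6 the surface area of a rasterized
radius-15 ball is recovered to ~2% (Sphericity 0.973) while flat faces
stay put (an axis-aligned cube of side 20 keeps its volume to 1% and its
area to 5%, the residual coming from genuinely rounded edges and
corners). Mesh volume follows exactly from the divergence theorem over
the oriented triangles. The maximum 3D diameter is the exact largest
distance between corners of boundary voxels (convex-hull pruned), and
the 2D diameters take per-slice hulls in the axial (Slice), coronal
(Column) and sagittal (Row) planes. Axis lengths are `4 * sqrt(lambda)`
for the ordered eigenvalues of the physical-coordinate covariance
(population normalization) of the masked voxel centres; Elongation and
Flatness are ratios of these and need at least 4 voxels to be
well-posed.

Everything runs on a bounding-box crop padded past the wavelet filter
radius; since every feature reads only masked voxels, cropping changes
nothing (whole-voxel translation invariance is among the tested
properties).

## ICC analysis

For every feature and segmentation method the analysis forms an
`n subjects × k raters` matrix — by default all of a method's
observer/session combinations jointly act as raters — and estimates the
two-way single-rater **agreement** ICC,

\[
\mathrm{ICC}(A,1) \;=\;
\frac{MS_R - MS_E}{\,MS_R + (k-1)\,MS_E + \tfrac{k}{n}\,(MS_C - MS_E)\,},
\]

where \(MS_R\), \(MS_C\) and \(MS_E\) are the subject, rater and residual
mean squares. Rater offsets count against agreement: a systematically
generous observer lowers \(\mathrm{ICC}(A,1)\) through \(MS_C\). For
intra-observer (session) reproducibility the **consistency** form

\[
\mathrm{ICC}(C,1) \;=\; \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E}
\]

is used instead, which is invariant to per-rater constants — repeating a
segmentation with a constant offset is perfectly *consistent* though not
in perfect *agreement*. Both formulas use the two-way residual; the
one-way within-subject mean square is also exposed by
`anova_decompose()` for the one-way variant. Negative estimates are
reported as-is (they occur when rater noise swamps subject variance), a
zero denominator yields a logged not-a-value that summaries exclude, and
the banding rule is exact: high for ICC ≥ 0.8, medium for 0.5 ≤ ICC <
0.8, low below 0.5 — three bands partitioning \((-\infty, 1]\).

The two methods' per-feature ICC vectors are compared with a two-sided
Wilcoxon rank-sum test (midranks; continuity-corrected normal
approximation; exact enumeration when the pooled sample is at most 12
without ties; all-values-tied returns p = 1).

### A calibration caveat

Treating the per-feature ICCs as independent samples is questionable, and
the package's own null-calibration experiment (part of the acceptance
suite, using the exchangeable `displacement` configuration for both arms)
shows why: features extracted from the same handful of masks have
strongly correlated ICC estimates, the effective sample size is far below
the feature count, and the rank-sum test rejects a true null far more
often than its nominal level. The directional conclusion under a genuine
method difference is unaffected — the power experiment rejects in
essentially every replicate with the correct sign — but the p-value
attached to the method comparison should be read as descriptive, not as a
calibrated error rate. This is a limitation of the analysis design the
pipeline reproduces, not of the implementation.

## Numerical and testing choices

* Every stochastic quantity derives from `rng_seed` through a
  deterministic Lehmer-style mixer (`derive_seed()`), giving each
  (subject, observer, session) its own stream below 2³¹; regenerating a
  study under one seed reproduces every mask checksum and every CSV byte.
* Feature tables are written at full `%.17g` precision, so CSV
  round-trips are lossless and byte-comparisons are meaningful.
* The test suite works at reduced problem sizes chosen to exercise every
  code path: oracle equivalence on ≤ 6³ random volumes against scalar
  brute-force enumerations (flood fill, all three texture matrices,
  first-order sums, naive separable convolutions, `aov()`-based mean
  squares); observer-model Monte-Carlo on 24³ phantom studies of 8–10
  subjects; power and null-calibration experiments over 50 seeded
  replicates with original-channel texture features; parameter recovery
  for ICC(A,1) from 1000 simulated 50 × 4 rating matrices; and the full
  240-mask, 64³, 662-feature study run twice for end-to-end
  byte-determinism.
* Phantom tumours are ellipsoids, not irregular lesions; intensity noise
  is Gaussian, not Rician; no MR physics (TR/TE, bias fields, partial
  volume) is modelled. Passing tests therefore demonstrate correctness
  of the computational chain and the *direction* of the
  segmentation-reproducibility effect under controlled conditions — they
  do not certify the magnitudes one would obtain on clinical images.

## Known limitations

* Direction offsets ignore anisotropic spacing (lattice-unit offsets).
* The surface estimator's anti-aliasing slightly rounds sharp edges, so
  very small or thin structures (a few voxels across) lose a few percent
  of mesh volume and area.
* The exact feature subsets of other radiomics tools differ in
  conventions (bin policy, aggregation, kurtosis offset); comparisons
  across tools require aligning those conventions first.
* The method-comparison p-value is anticonservative under cross-feature
  dependence, as discussed above.
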