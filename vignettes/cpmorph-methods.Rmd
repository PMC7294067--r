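---
title: "Injury-robust brain morphometry and structure-function modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Injury-robust brain morphometry and structure-function modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In unilateral cerebral palsy the brain injury behind a one-sided motor
impairment is often severe and, in a third to a half of children, present in
*both* hemispheres. Standard morphometry pipelines assume roughly normal
anatomy: atlas priors, tissue intensity models and cortical surface
extraction all fail when the lateral ventricles are grossly enlarged, large
periventricular lesions replace white matter, or whole cortical territories
are atrophic. `cpmorph` implements a quantification pipeline designed to
keep working under exactly those conditions, and the statistical machinery
that relates the resulting structural measures to hand-function scores (AHA,
0-100, bimanual; MUUL, reported as a percentage, unimanual), including
interaction terms that let the structure-function relationship differ
between children with unilateral and bilateral injury.

Because the clinical MRI cohorts this class of pipeline is built for cannot
be redistributed, the package ships a synthetic phantom generator with
analytic ground truth, and every claim the test suite makes is a claim about
recovery of known truth on those phantoms.

# The synthetic phantom and what it does (not) emulate

`make_atlas_phantom()` builds a canonical "brain": a three-compartment
ellipsoidal head (white matter core, 6 mm cortical gray shell divided into 8
angular parcels per hemisphere, 3 mm outer CSF rim) containing left/right
lateral ventricles, caudate, lenticular nucleus and thalamus (ellipsoids),
anterior/posterior internal-capsule limbs (boxes carved from WM), and a
corpus callosum sheet superior to the ventricles split into genu, body and
splenium. The layout is specified in field-of-view-normalised coordinates,
so any grid of at least 48 voxels per axis hosts all structures; the
uninjured atlas is exactly mirror-symmetric. Geometric primitives were
chosen deliberately over realistic anatomy: every downstream measure
(volumes, thickness, curvature, overlap) then has a closed-form or
voxel-count oracle.

`apply_injury()` plants the three injury processes the pipeline must
survive:

* **ventricular enlargement** - the nearest same-hemisphere WM voxels are
  converted to ventricle until a target volume ratio is reached, so the
  realised ratio is exact by construction;
* **periventricular lesions** - spheres (default radius 5 mm) carved from WM
  2-12 mm from the ventricle, carrying a dedicated ground-truth label so
  lesion segmentation is scoreable; rendered mildly hypointense on T1 and
  hyperintense on T2, as white-matter injury appears on T2-TIRM;
* **cortical atrophy** - removal of the outer fraction of the GM shell on
  the affected side(s).

Laterality `"none"` forces the identity; `"unilateral"` confines all
non-identity factors to one hemisphere. `render_intensities()` maps tissue
classes to channel means (T1: WM 100, GM 70, CSF 30, lesion 60; T2: WM 60,
GM 80, CSF 130, lesion 140 - arbitrary units, chosen to mimic the relative
contrasts of MPRAGE and T2-TIRM), then applies partial-volume Gaussian
smoothing (default 1 mm), a smooth multiplicative bias field
(`1 + amplitude * S`, `S` unit-normalised smoothed noise; default amplitude
0.15, correlation length 40 mm) and additive Gaussian noise (default sd 3,
i.e. 10% of the 30-unit WM-GM contrast).

What the phantom does **not** emulate: MR physics (no k-space, no Rician
noise), gyrification (the cortex is a smooth shell, so sulcal depth is
exercised on separate groove phantoms), anatomical variability of the deep
gray nuclei (their volumes are constant across subjects), lesion texture
heterogeneity, and motion or slice-thickness artefacts. Passing tests
therefore demonstrate algorithmic correctness and injury robustness in the
planted sense, not clinical-grade accuracy on real MRI.

`simulate_cohort()` generates whole cohorts (defaults 44 controls / 37
unilateral / 54 bilateral, the study design the package mirrors; the
generator takes the sizes as parameters). Every subject receives benign
anatomical jitter (ventricle volume x U(1, 1.15) per side, cortical
thinning U(0, 0.08)) so control groups have within-group variance; injured
subjects then draw group-specific injury (unilateral: dilation U(1.3, 2.2),
0-3 lesions, atrophy U(0, 0.3) on one side; bilateral: per-side dilation
U(1.2, 2.0), 0-2 lesions, atrophy U(0, 0.25)). Motor scores follow
`score = clamp(60 + 15 * (beta . z + gamma . z * 1[group] + eps), 0, 100)`
with `z` the cohort-standardised ground-truth features; the default planted
effects sit on contralateral ventricular volume (-0.8) and contralateral
mean cortical thickness (+0.8), the two axes the injury model actually
varies. (A thalamic effect would be unrecoverable by construction, since
phantom DGM volumes do not vary.) About 23% of subjects are simulated
without a T2 volume, mirroring the partial T2 coverage of such cohorts;
their lesion features are missing, not zero. Controls carry no motor
scores.

# The quantification pipeline

`quantify_subject()` chains the following stages. All spatial operations
use a centred world frame with the `+x` axis pointing right.

**Bias correction.** The multiplicative bias is modelled as a low-order
polynomial in space (default order 2 plus pairwise cross terms) fitted to
log-intensities. The fit is restricted to bright, WM-like voxels (within
15% of the 85th foreground percentile) and iterated twice; an unrestricted
fit absorbs anatomy - the dark ventricles drag the polynomial down and the
"correction" then destroys class contrast. On phantoms with a planted 0.3
amplitude field the estimate correlates > 0.95 with truth.

**Histogram matching** is monotone quantile mapping (1001 quantiles, linear
interpolation), which preserves intensity rank order. In the pipeline it is
applied *brain-to-brain* (subject brain mask to atlas brain mask)
immediately before the patch comparison, not whole-volume: the atlas
rendering has a nearly discrete histogram, and whole-volume matching of an
injured subject (whose class proportions differ - more CSF, less WM) maps
entire classes onto the wrong plateaus.

**Denoising** is explicit 3D Perona-Malik diffusion with exponential
conductance `g = exp(-(|grad I|/kappa)^2)` on face-centred differences and
zero-flux boundaries, written in flux form so the global mean is conserved
to machine precision; the step size is capped at the 3D stability bound
1/7. Defaults: 2 iterations, kappa = 10 (a third of the WM-GM contrast) -
enough to help the lesion class without eroding the thin atrophic cortex.

**Affine atlas alignment** (optional in the pipeline, since simulated
subjects already share the atlas grid) minimises mean-squared intensity
over the fixed foreground with a 12-parameter transform, coarse-to-fine
over 2-3 resolution levels. The 12-D Nelder-Mead search is staged - rigid,
then rigid+scale, then full affine - which recovers a synthetic 10 deg /
1.1x / 5 mm transform within 1 deg / 1% / 1 mm. As in the original design
the alignment doubles as intracranial-volume normalisation.

**Skull stripping** estimates a naive WM intensity as the 80th percentile
within 25 mm of the intensity-weighted centre of gravity, thresholds at
+/-20% of it, keeps the largest component, and grows it by geodesic
dilation accepting voxels whose intensity exceeds 25% of the naive WM
intensity (`csf_fraction`), so growth stops at dark intradural CSF. The
final mask is the largest 26-connected component with interior holes
filled. Because acceptance is purely intensity-relative-to-WM, large
lesions stay inside the mask.

**Tissue segmentation** is diagonal-covariance Gaussian-mixture EM inside
the brain mask: 3 classes on T1 alone, or 4 classes on the (T1, T2) pair
when T2 exists. The lesion class's per-voxel prior is multiplied by
`2 * plogis(slope * (z - 2))` with `z` the within-brain T2 z-score (slope =
`lesion_weighting`, default 4) and the priors renormalised - a monotone
push of T2-hyperintense voxels towards the lesion class that is exactly
neutral (multiplier 1) at slope 0. The factor 2 makes the slope-0 case an
exact no-op; a bare logistic would rescale every prior by 0.5. EM with
fixed per-voxel prior multipliers retains the log-likelihood monotonicity
guarantee, which the tests assert on every fit. Initialisation: k-means on
a 10^4-voxel subsample for the tissue classes, plus a lesion class seeded
from voxels with z > 2 that are brighter than CSF on T1; class identities
are resolved after fitting (CSF = lowest T1 mean among surviving classes,
lesion = highest T2 mean of the rest), with variances floored at 1e-4 of
the channel variance. Partial-volume voxels are assigned by maximum
posterior; there is no explicit PV class.

**Ventricle extraction** assigns CSF-labelled 26-connected components that
overlap the 6 mm-dilated side-specific atlas ventricle priors; a component
touching both priors is split at the mid-sagittal plane. The lesion mask
is forced disjoint from the ventricle masks.

**Deep-structure labelling** is the heart of the injury robustness. The
atlas labels are first *rigidly aligned to the ventricles*, not the skull -
severe tissue loss moves the ventricles off-centre: the corpus-callosum
group to the superior ventricle faces, the DGM/internal-capsule group to
the lateral faces (6-parameter fit of transformed atlas face points against
a distance transform of the subject face points, initialised at the
centroid offset and kept only if it reduces the mean distance). Then every
stride-sampled 15x15x15 atlas patch containing part of a structure label is
compared against the subject image at every displacement within a 6-voxel
search radius using the sum of squared differences, with CSF-labelled
voxels *on either side* masked out of the sum and the SSD normalised by
the number of contributing pairs - without the normalisation, displacements
that hide more voxels behind the mask win spuriously. The pipeline also
masks the segmented lesion voxels on the subject side; lesions are
tissue-loss signal absent from the atlas, and with them left in, a lesion
abutting a small structure (the caudate is ~40 voxels) can drag its patches
several voxels off target. Ties in the SSD minimum resolve to the smallest
squared displacement, then lexicographically, which makes identity
propagation bit-exact. Label voxels are copied at the winning displacement;
votes are divided by each voxel's patch coverage (the vote count identity
propagation would deliver, i.e. the maximum attainable given the stride)
and clipped to [0, 1]. Thresholding at 0.5, largest-component selection,
lesion-voxel removal and higher-probability conflict resolution produce the
final labels. Stride defaults to 3 (the dense stride-1 search is available
and used by the identity test); the implementation computes the SSD field
once for all structures with a box-filter decomposition (O(N) per
displacement), and `patch_ssd_reference()` is a deliberately independent
brute-force implementation used to validate the argmin displacements
exactly.

**Cortical measures.** Thickness is the symmetric distance-transform
definition: distance to WM plus distance to non-brain, minus one voxel
spacing (the two centre-to-centre transforms jointly overcount by exactly
one voxel; a 4 mm slab at 1 mm then reads 4.0 mm). Sulcal depth is the
distance to the complement of the 10 mm morphological closing of the brain
mask *minus* the distance to the complement of the mask itself - the
difference cancels the discretisation of the closing, making convex
surfaces read exactly 0; the closing is computed on a padded grid because
a dilation clipped at the volume faces cannot be undone by the erosion.
Curvature is half the negative divergence of the normalised gradient of
the Gaussian-smoothed (sd 1 voxel) mask, so spheres read +1/R within 15%
at R = 20 mm. Cortical parcels are propagated to every GM voxel by nearest
atlas-parcel distance with no cap, so even severely displaced or atrophic
cortex is fully labelled; equidistant ties go to the lower parcel code.
Regional summaries report mean/sd/voxel count per parcel and flag parcels
under 10 voxels. The visual-inspection step of the original workflow is
replaced by automatic QC (brain-mask component count, empty-structure
flags).

# The statistical methodology

`assemble_features()` relabels hemispheres relative to the impaired body
side: the *contralateral* hemisphere is the one opposite the impaired hand,
i.e. the (more) injured one; controls use ipsi = left, contra = right.
Volumes are ICV-normalised by default (fractions of the brain-mask volume).
Missing lesion volumes (no T2) stay `NA` and the rows stay in. Interaction
columns `int_<feature> = feature x 1[bilateral]` are appended for every
structural feature, hence exactly zero for the unilateral group. Controls
are excluded from all regression models (they have no motor scores).

Two feature-reduction arms feed a 500-tree random forest
(`mtry = sqrt(p)`, fixed seed, ranger) evaluated on a single 75/25 split
stratified by laterality group:

* **data-driven**: the training table is augmented with *shadow features*
  (independently permuted copies, which carry no signal by construction);
  features whose permutation importance exceeds the 95th percentile of the
  shadow importances are retained. If nothing survives, the top 5 are kept
  and flagged.
* **PCA**: structural measures *including the interaction columns* are
  standardised (missing lesion volumes median-imputed within laterality
  group) and the top 10 components retained; age, gender and the laterality
  indicator pass through unreduced, and the share of variance captured is
  reported, not enforced. Interactions are included in the reduction
  because the retained-component account of the original analysis lists
  interaction terms among the leading loadings.

Reports carry training R^2, test Pearson r with p-value, test RMSE, the
split indices and predictions. Group contrasts use Welch t-tests for the
three pairwise group comparisons per feature (the group variances are
plainly unequal, so the unequal-variance variant is the defensible choice),
a Shapiro-Wilk normality flag per feature per group, and Bonferroni
correction over the total number of computed tests.

Design choices on points the methodology leaves open: the 75/25 split is a
single stratified split (not repeated, not cross-validated); missing lesion
volumes enter forests as a -1 surrogate plus a missingness indicator
column rather than dropping rows; significance stars follow the usual
.05/.01/.001 convention.

# Problem sizes and verification

The test suite and the acceptance script run everything on phantoms of
48^3 (2.5 mm) and 64^3 (2 mm) voxels and cohorts of 90 patients - sizes
chosen so the full suite completes on a single desk-scale core while every
structure still spans multiple voxels. Key verified properties: exact
agreement of the patch search with its brute-force reference across radii
{0, 2, 6} and strides {1, 3}; bit-exact identity propagation; bitwise
invariance to intensity changes under the CSF masks; Dice >= 0.9 (tissues,
within the brain mask), >= 0.85 (ventricles per side) and >= 0.7 (lesions
and all thirteen deep structures) on the standard injured phantom across
five seeds; skull-strip Dice >= 0.9 under severe unilateral and bilateral
injury; slab/sphere/groove morphometry analytics; EM monotonicity and
recovery; both statistical arms reaching test r >= 0.5 in at least 80% of
20 planted-effect cohorts with the planted interaction retained at the
same rate; and end-to-end bit-level determinism. The headline numbers of
the clinical study this pipeline emulates depend on a private cohort and
are deliberately *not* targets: the synthetic cohorts establish that the
machinery recovers known truth, nothing more.

# Known limitations

* The phantom cortex has no gyri; sulcal depth and curvature are validated
  on geometric phantoms only.
* Deep gray structures neither vary across subjects nor deform under
  injury, so structure-function effects on DGM volumes cannot be planted.
* The EM has no spatial regularisation (no MRF), matching the scope of the
  emulated pipeline.
* The bias model is a low-order polynomial, a stand-in for spline-based N4
  - adequate for smooth fields, not for fast-varying coil profiles.
* Single-atlas propagation only; no multi-atlas fusion.
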