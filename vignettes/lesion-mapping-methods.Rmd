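---
title: "Methods: whole-body lesion mapping to template space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body lesion mapping to template space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the method

Whole-body FDG-PET–CT is acquired routinely for patients with metastatic
cancer, and each study comes (after segmentation) with a binary mask of the
metabolically active tumor lesions. Individually these masks live in each
patient's own anatomy, so lesion locations cannot be compared or aggregated
across a cohort. `lesionmapr` implements the standard solution from
neuroimaging lesion-symptom mapping, extended to the whole body: spatially
normalize every subject into a common *template space* and analyze the
lesion masks voxel-wise there.

The pipeline is:

1. **Template selection.** One negative-control subject per sex defines the
   template space. Selection is by *image body-fat percentage*: the share of
   torso voxels in the adipose CT band (−190 to −30 HU, endpoints
   inclusive). The subject nearest the subset median (within ±2 percentage
   points) is chosen, so the template is metrically "typical" for its sex.
   The torso — an inferior–superior slab between pelvic floor and shoulder
   level — is used instead of the whole image because scanner fields of
   view differ between studies. Female and male subsets are processed
   entirely separately; their template spaces are never pooled voxel-wise.
2. **Registration.** Each positive subject's CT (harmonized to 3 mm slice
   thickness by linear interpolation; in-plane spacing untouched) is
   deformably registered to the sex-matched template CT. Voxels inside the
   subject's lesion mask, dilated by one voxel, are excluded from the
   similarity cost (*cost-function masking*) so that abnormal tissue does
   not drive the deformation and lesion shapes are preserved.
3. **Feature maps.** The lesion mask is labeled into connected components
   (3D connectivity 2) and three feature maps are built in subject space:
   voxel-level PET SUV over the lesion support, the per-lesion metabolic
   volume (ml) painted as a constant over each lesion, and a subject-level
   scalar (total lesion count scaled to 0–1 by the subset maximum) painted
   over all lesions. Each lesion is then transferred to the template grid
   individually with nearest-neighbor sampling.
4. **Aggregation.** Per subset (sex × diagnosis), the package counts
   lesion occurrences voxel-wise (frequency and percentage-frequency maps)
   and computes the voxel-wise mean and coefficient of variation of each
   feature over the lesions sampled at each location, restricted to voxels
   with at least `min_occurrences = 2` lesion occurrences.
5. **Evaluation.** Because the mapping may distort masks, lesion volume,
   total metabolic volume, all pairwise center-of-mass distances, and the
   maximum within-patient lesion distance are measured in both spaces and
   compared (Pearson correlation, mean/median/SD of change). Lesion
   identity across spaces is carried by the per-lesion transfer.

# Data model and conventions

All volumes are `scalar_volume` objects: a 3D array plus spacing (mm),
origin (mm) and an orthonormal direction matrix. Voxel indices are 0-based;
the world coordinate of index $i$ is $origin + R\,(s \circ i)$. All
distances are computed in world mm and converted to cm only at reporting
time. Out-of-volume samples take fill value 0 in every modality, matching
the background semantics of masks and of SUV outside the body. NIfTI files
carry the full geometry in the sform affine, so oblique orientations
round-trip and resample correctly even though the synthetic cohort is
axis-aligned.

"Connectivity 2" labeling uses the 18-neighborhood: face- and edge-adjacent
voxels connect, corner-only contact does not — the standard reading of a
rank-2 structuring element in 3D. It is configurable (1 = 6, 3 = 26).

# The synthetic cohort

Real whole-body collections are large downloads with manual segmentations,
so the package ships a generator that emulates their structure at desk
scale. The canonical body of each sex is an *analytic* function of world
coordinates: leg cylinders, a torso with elliptical cross-section whose
half-widths interpolate linearly from hips to shoulders (females wider at
the hips, males at the shoulders), two lung ellipsoids, a spine cylinder, a
neck and a head. Subcutaneous fat is a ring between the torso ellipse and
the same ellipse scaled by $\sqrt{1-f}$, so the adipose area fraction of
each torso cross-section equals the configured fat fraction $f$ exactly in
the continuum; each subject draws $f$ uniformly from a sex-independent
range (default 0.25–0.50).

Per-subject anatomy is a smooth warp of the canonical body: a sum of
Gaussian radial-basis displacements with control points on a jittered
coarse grid (default spacing 64 mm, kernel SD 32 mm), amplitudes rescaled
so the maximum displacement magnitude equals `warp_max_displacement_mm`
(default 8 mm). Keeping the maximum displacement below half the
control-point spacing makes the warp a contraction perturbation, so the
inverse exists and is computed by per-voxel fixed-point iteration
(tolerance 0.05 mm downstream, 0.01 mm during rendering). Because the
canonical body is analytic, a subject's CT is rendered by evaluating the
canonical intensity at inverse-warped voxel coordinates — there is no
resampling error in the ground truth itself. CT tissue classes sit at
conventional HU (air −1000, lung −750, adipose −100, soft 40, bone 700,
tumor 55) with additive Gaussian noise (SD 15 HU); PET is background SUV
1.0 ± 0.1 inside the body with focal uptake (SUV 4–10) in ellipsoidal
lesions.

Lesions are placed by per-diagnosis spatial priors in canonical
coordinates and mapped through the subject's warp: lung cancer in the lung
fields with right:left weight 60:40; lymphoma in mediastinal, cervical and
abdominal/para-aortic nodal regions; melanoma scattered uniformly through
the body; negative controls have none. Lesion counts are 1 + Poisson with
per-diagnosis means 4.5 / 10 / 8.5 — the per-subject lesion counts of the
cancer-type subsets this cohort emulates (roughly 11, 22 and 19 lesions
per subject), halved because at a 4 mm grid a whole-body phantom cannot
hold the full counts without the ellipsoids merging into one another.
Ellipsoid semi-axes draw from 8–16 mm (lower bound fixed at twice the
voxel size so every lesion survives nearest-neighbor resampling; the upper
end is shrunk per diagnosis). Overlapping lesions merge in the mask, and
the labeling step decides what counts as one lesion, exactly as it would
on real data.

What the phantom deliberately does *not* emulate: organ-level anatomical
realism (XCAT-class models), PET point-spread/partial-volume effects,
respiratory motion, arms-down positioning, scoliosis, or non-metabolic CT
lesions. Tests passing on this cohort therefore validate the *mapping and
aggregation machinery* — geometry, interpolation, labeling, statistics —
not registration accuracy on real anatomy, which must be established
separately on real data.

# Registration

The baseline estimator is a multiresolution demons-style scheme on CT
intensities (anatomy drives the alignment; PET is carried along). The
initial alignment translates the subject so the centers of mass of the two
body masks coincide; the body mask is the complement of border-connected
air, so enclosed air spaces (lungs) stay inside the body. At each level
(shrink factors 4 then 2) the update force is
$\delta = (F - M\circ\phi)\,\nabla F / (\|\nabla F\|^2 + (F - M\circ\phi)^2/s^2)$,
capped at 2 mm per iteration, smoothed with a fluid kernel (SD 1 voxel),
added to the field, and the field re-smoothed with an elastic kernel (SD
1.5 voxels); iterations stop when the mean update falls below 0.01 mm.
With cost-function masking on (the default), the force is zeroed wherever
the warped sample falls inside the dilated lesion mask; the dilation margin
is 1 voxel by default and configurable, since the margin is a free
parameter of the approach. The result is a dense displacement field on the
template grid, deterministic given inputs and spec, with the inverse
obtained by fixed-point iteration on the interpolated field.

The pipeline also accepts ground-truth transforms
(`provenance = "synthetic_ground_truth"`), in which case the template space
is the canonical body of the sex and every downstream module can be
validated independently of registration quality. This decoupling is the
main design device of the package's test suite.

# Numerical and design choices

* **Median convention.** The median of an even-sized subset is the midpoint
  of the two central values; template candidates are those within ±2
  percentage points of it. Within the window the choice on real cohorts is
  a manual screening step; the package defaults to nearest-to-median with
  ties broken by smallest subject id, and exposes an `override` argument as
  the manual escape hatch.
* **Per-lesion transfer.** Transferring each lesion separately (rather than
  one nearest-neighbor pass over the whole label map) preserves lesion
  identity when warped lesions touch in template space. A template voxel
  claimed by two lesions of one subject goes to the lesion whose
  transformed center of mass is nearer — such overlap cannot exist in
  subject space, so the rule is our construction.
* **Field-of-view truncation.** Lesions partially inside the template grid
  keep their inside voxels; only lesions with no voxel in the template
  field of view are dropped, and every drop is reported in an exclusion
  table. Partial retention loses the least data.
* **Lesion-level features** are measured in subject space and carried as
  constants; template-space re-measurement happens only in the evaluation
  module, where the comparison is the point.
* **Aggregation statistics** use the sample (n−1) standard deviation, since
  the lesions at a voxel are a sample of the subset; the CV at voxels with
  zero mean is stored as `NA` and excluded from rendering. One subject
  contributes at most one value per voxel (overlap resolved upstream).
* **Centers of mass** are unweighted voxel means (SUV weighting is a
  documented alternative); correlations are computed on raw values even
  where figures would use log axes for display.
* **Evaluation pairing** excludes, at the pair level, any pair whose member
  was dropped at the field-of-view boundary, so only defined comparisons
  enter the tables.

# Problem sizes

The default phantom grid is 64 × 64 × 160 voxels at 4 mm isotropic
spacing — a whole-body aspect ratio that generates in about 2 s per subject.
The package's own validation runs use cohorts of 16 subjects (identity
checks), 20 positive subjects per sex (known-warp recovery), and 50
subjects (frequency-contrast checks), with registration exercised on the
full default grid through shrink factors 4 and 2. Unit tests use a
48 × 48 × 120 grid.

# Known limitations

The baseline registration is a generic intensity demons; it honors the
contract (masked cost, smooth deterministic field) but is not tuned for
inter-subject whole-body alignment quality, and no claim is made that it
matches purpose-built whole-body methods. The torso slab is parameterized
by axial landmark indices (anatomical landmark detection is out of scope);
on synthetic data the generator supplies them. DICOM ingestion and SUV
computation from raw PET counts are out of scope: inputs are NIfTI volumes
already in HU and SUV.
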