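---
title: "Counting nanoparticles in a cell from FIB/SEM slice-and-view stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting nanoparticles in a cell from FIB/SEM slice-and-view stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A focused ion beam / scanning electron microscope (FIB/SEM) can consume a
whole resin-embedded cell in serial slices — mill away a thin layer
(typically 40 nm), image the freshly cut face with the SEM, repeat — and
so produce an ordered stack of cross-section images spanning the entire
cell volume. Metallic nanoparticles (NPs) inside the cell appear bright
without any staining because their secondary-electron yield is roughly
twice that of the organic matrix. In principle the stack therefore
contains the *absolute* number of particles in that one cell, a quantity
that bulk techniques (which average over thousands of cells) and single
2D sections (which sample a sliver of the volume) cannot deliver.

Two properties of the image formation stand between the raw stack and
that number:

1. **Subsurface glow.** Secondary electrons escape from a characteristic
   depth $l$ below the cut face (tens of nanometres in organic material).
   A particle that is still buried glows through the matrix before the
   beam ever exposes it, with intensity decaying as $e^{-z/l}$ in the
   distance $z$ between the cut face and the particle surface. Summed
   over slices, every particle therefore carries a spurious *offset
   volume* in addition to its actual volume.
2. **Shading.** Electrons from a particle that lies *behind* another
   particle (along the slicing axis) are absorbed by the anterior one —
   the escape depth inside the metal is negligible compared to the
   matrix. A posterior particle only becomes visible once its anterior
   neighbour has been milled away, so the glow offset is incurred once
   per *projected footprint*, not once per particle.

`fibcount` implements the resulting quantification model. Writing $V_c$
for the accumulated, background-normalized intensity of a detected
cluster (its *detected volume*), $A_c$ for its projected area along the
slicing axis, and $V_{s0}$, $V_s'$, $A_s$ for the actual volume, offset
volume and projected area of a calibrated single particle, the number of
particles in the cluster is

$$ n_c \;=\; \frac{V_c - V_s'\, A_c / A_s}{V_{s0}}. $$

The offset is subtracted once per single-particle footprint contained in
the cluster's projection ($n_p = A_c/A_s$): side-by-side particles each
glow, stacked particles shade each other. The whole-cell dose is the sum
of per-cluster counts. All three calibration constants are measured from
isolated single particles found in the same stack, so no external
calibration standard is needed.

## Arbitrary intensity units

Detector settings are fixed during an acquisition, so pixel intensity is
proportional to the secondary-electron signal with one unknown gain for
the whole stack. All quantification happens in background-referenced
units ("a.i.u."): per slice, the cell-matrix median is subtracted and the
result divided by the robust matrix spread (`normalize_to_background()`).
The matrix maps to 0 with unit noise, and every downstream threshold is
expressed in these units — which makes detection provably invariant under
affine rescaling of the raw data (a property the test suite checks). The
background statistics are taken on the segmentation mask *eroded* by the
deliberate boundary extension, so the resin ring around the cell does not
contaminate them.

## Pipeline stages and their parameters

`run_pipeline()` chains the stages below; each is also exported on its
own. Defaults are listed with units.

**Registration** (`estimate_drift`, `apply_drift_correction`). Pairwise
integer-pixel shifts from the FFT cross-correlation of mean-subtracted
consecutive slices, accumulated into a trace anchored at the first slice.
Two guards matter in practice: a pair with peak correlation below
`min_ncc = 0.2` is unregistrable (featureless slices) and contributes a
zero shift; and a peak further than `max_step = 10` px away is treated as
a degenerate ridge — an image dominated by structure that is invariant
along one axis (the substrate edge) correlates equally well at every
lateral lag, and the smallest near-maximal shift is the only sensible
choice there. Subpixel refinement of the peak is available behind a flag
but shifts are applied as integers to keep segmentation crisp.

**Tilt correction** (`correct_view_angle`). The SEM views the cut face at
an angle to its normal (by construction of the instrument), so the
vertical image axis is foreshortened by $\cos\theta$. The correction
rescales rows by $1/\cos\theta$ with linear interpolation and updates the
vertical pixel size so physical heights are preserved. Because usage of
the angle convention varies between instruments, the alternative
$1/\sin\theta$ reading is selectable (`view_angle.convention`), as is
disabling the correction. Whether a quoted pixel size refers to the
raster before or after correction is a matter of bookkeeping: geometry in
this package always describes the *current* raster, and the synthetic
generator emits post-correction geometry by default.

**Denoising** (`denoise_wiener`, 5×5 window). A local-statistics adaptive
filter: windows whose variance is at the noise level collapse to their
mean, structured windows pass through. Used before thresholding; the
a.i.u. normalization deliberately uses the *unfiltered* data so that
"unit noise" means the acquisition's actual noise.

**Cell segmentation** (`segment_cell_stack`). The milling process digs a
trench into the substrate which travels with the slicing plane; its dark
edge anchors the lower cell boundary in every slice
(`detect_trench`). Above the trench, a 2-class Otsu threshold separates
resin from the homogeneous cell matrix. Several gates reject slices that
cannot be segmented: the threshold must explain a minimal variance
fraction *and* separate the class means by `contrast_sep = 4` pooled
within-class spreads (Otsu happily "splits" unimodal noise, reaching a
separation near 3); the pre-extension mask must cover at least
`min_area_px = 400` px (a sliver cross-section has too few matrix pixels
for reliable statistics); and the masked median must agree with the
stack-wide masked median within 25% (`level_consistency`) — constant
detector settings mean a slice whose "matrix" level suddenly looks like
resin has locked onto the wrong material. Bright particle-level blobs at
the mask boundary are absorbed by stepwise local growth until the
boundary neighborhood is back at the matrix level (notch repair), the
mask is extended by `extension_px = 10` px (the upper cell boundary has
no sharp edge, so the mask deliberately overshoots) and smoothed by
convolution with a normalized disc of radius 5 px re-thresholded at 0.5.
Flagged slices are reported as a fraction; particles in them are not
counted, mirroring how unsegmentable rear-of-cell slices are treated in
practice.

**Particle detection** (`detect_np_clusters`). Candidate pixels come from
Roberts edge detection on the Gaussian low-pass filtered
(`lowpass.sigma = 1.5` px) a.i.u. image, thresholded at 3 robust standard
deviations of the in-cell gradient, with edge rings filled to solid
blobs. Two guards make this specific: edges must sit on intensity above
1 a.i.u. (particle edges rise out of the matrix; the cell outline falls
toward the resin and would otherwise be hole-filled into one giant false
candidate), and a filled blob must enclose signal above 3 a.i.u.
Candidates are grouped into rough clusters by 26-connected component
labeling across the voxel grid, so an agglomerate is one object no matter
how many slices it spans. Each rough cluster is then re-thresholded
individually in its padded bounding box (5 px in-plane, 3 slices axially)
with a 2-threshold (3-class) Otsu: intensity levels fluctuate with
position in the cell, and the local threshold adapts. Classes whose mean
is consistent with the matrix (≤ 2 a.i.u.) count as background; voxels
above the boundary over the highest background class — subsurface glow
and exposed particle together — form the refined cluster. The glow
belongs in the detected volume: it is exactly what the calibration
decomposes, and the full projected footprint (which the counting formula
divides by) only exists because of it. Refined voxel sets are merged by a
final connected-component pass, since the glow of one particle may have
seeded several rough clusters.

**Calibration** (`select_single_nps`, `calibrate`). Reference singles are
screened automatically: projected area within 30% of the nominal
single-particle footprint, a single maximal plateau in the intensity
profile, and a plateau no longer than one particle diameter of slices
(stacked pairs share a single's footprint but stay bright twice as
long). A manual id list can override the screen. Per single:

* $V_s$ is the accumulated a.i.u. over the cluster.
* The *offset* $V_s'$ is measured per footprint pixel: a pixel's first
  exposure is the first slice whose intensity reaches the particle's
  exposed level (the median over per-pixel maxima) within the noise
  floor; everything before that is glow. A rim pixel whose chord fell
  between two cut faces never reaches the exposed level and is glow
  throughout. $V_{s0} = V_s - V_s'$, so the decomposition is exact by
  construction.
* The escape depth $l$ is a log-linear least-squares fit of the rising
  branch of the intensity profile, $I_k = I_0 e^{-z_k/l}$. The profile
  statistic is the median over the central half-radius of the footprint
  (noise-averaging over a fixed pixel set; the plain maximum rides on the
  noise extreme of a hundred pixels and flattens the slope). The
  first-exposure slice is determined from the max-statistic profile —
  once any pixel is exposed, the median mixes glow with exposed levels.
  Only strictly pre-exposure points enter the fit: the profile maximum is
  clipped at the exposed level and would bias the slope by the slice
  phase. Leading points that fall off the common exponential are trimmed;
  the deepest glow of a particle close to the cell surface travels partly
  through resin and undershoots the matrix decay. Two usable points
  suffice for the noiseless fit to be exact; in the targeted slicing
  regime (40 nm slices, $l \approx 90$ nm, 10:1 contrast) 2–3 glow slices
  clear the floor, and the estimate is averaged over all reference
  singles.
* $A_s$ is the footprint pixel count; dividing $V_{s0}$ by the exposed
  level gives an equivalent voxel count, which times the voxel volume
  estimates the physical particle volume — on noiseless phantoms this
  reproduces the analytic sphere volume within a few percent, and the
  equivalent-circle diameter of $A_s$ reproduces the generator's sphere
  diameter within 5%.

The classic closed-form offset $V_s' = V_s\,(1 - e^{-\Delta z/l})$ — the
glow fraction of a geometric series with per-slice attenuation
$e^{-\Delta z/l}$ — is reported alongside (`estimator = "closed_form"`)
for comparison with the empirical decomposition.

**Quantification** (`count_particles`, `total_dose`,
`size_distribution`). The formula above, clamped at zero, with
first-order uncertainty propagation over the calibration constants.
Per-cluster counts are rounded to the nearest integer for the total
(clusters with $n_c > 0.5$ count at least one particle); the fractional
total is reported alongside, since it is not knowable whether a published
integer total was rounded per cluster or once. For the total's
uncertainty the calibration constants are treated as fully correlated
across clusters — they come from one calibration — which makes the
relative uncertainty of $N$ at least that of $V_{s0}$. No tilt correction
is applied to $A_c$: electron escape is governed by the shortest path to
the cut face, which is normal to the cross-section plane. The cluster
size distribution is a fixed-bin histogram (width 10 particles) plus the
particle-weighted cumulative distribution — the fraction of all
*particles* in clusters up to a given size — together with the fractions
in small (1–5) and large (≥ 20) clusters. The small-cluster fraction is
particle-weighted, consistent with reporting the large-agglomerate
fraction as a share of all particles. `icpms_mass_to_count()` converts a
bulk mass-per-cell measurement into particles per cell
($m / (\rho\,\pi d^3/6)$) for cross-checking against elemental analysis.

## The synthetic phantom

Because no public reference stack exists, every stage is validated
against `generate_phantom()` + `render_stack()`: an ellipsoidal cell
resting on a substrate plane (clipped by it, as a spread cell is), with
spherical particles grouped into agglomerates of touching spheres —
in-plane rows, axial stacks, or random touching clumps — placed with a
150 nm clearance between agglomerates so that ground-truth cluster
identity is unambiguous. Defaults mirror the targeted acquisition: 74 nm
monodisperse particles, 6.3 nm pixels, 40 nm slices, escape depth 89 nm,
matrix at 0.5, particles at 1.0 (the factor-two yield of metal over
organic material), resin 0.2, substrate 0.1, additive Gaussian noise with
standard deviation 10% of the matrix level, and an optional ±1 px
random-walk drift script.

The renderer implements the imaging model per pixel: if the cut face
intersects the sphere's chord at that pixel, the pixel is at the particle
level; if the surface is still $z$ below the face, the pixel shows the
local base level plus the attenuated excess $(I_{np}-I_{base})e^{-z/l}$
— riding on matrix inside the cell and on resin outside it. Occlusion is
binary: at each pixel only the particle with the shallowest remaining
surface is visible, so a posterior particle glows only after all
anterior material above that pixel is milled away. A no-shading variant
adds the excesses instead, which brackets the shading model from above.
Under a fixed seed, generation and rendering are byte-identical.

What the phantom deliberately does *not* emulate: curtaining and charging
artifacts, beam damage, nonuniform matrix texture, diffusion blur of the
glow footprint (the glow is the full projected disc of the unexposed
part, which is what makes the offset proportional to projected area, as
the counting formula assumes), and any lateral escape of electrons around
an anterior particle (negligible, as the escape probability decays
exponentially with path length). Passing the phantom recovery tests
therefore demonstrates that the *algorithmic chain inverts the stated
imaging model*, not that the model captures every artifact of a real
instrument.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on a 128-bin histogram; with
  well-separated discrete classes the between-class variance has a flat
  plateau and the *middle* of the plateau is taken (its first bin would
  hug the lower class).
* 3D connected components use 26-connectivity and a padded flood fill;
  per-slice operations use the 8-connected `EBImage::bwlabel`.
* Surface meshes are extracted per voxel face with greedy rectangle
  merging: a solid box reduces to 12 triangles and the signed mesh volume
  equals the voxel volume exactly.
* TIFF export uses 32-bit samples on a uniform [0, 1] grid; integer
  rasters are placed exactly on that grid and survive a round trip
  bit-exactly up to the returned power scale.
* A constant or featureless slice cannot be registered and contributes a
  zero shift with a flag; a flat image has no trench and raises an error;
  an empty label volume cannot be meshed; a cluster visible in fewer than
  3 slices has no usable profile; unimodal refinement boxes leave the
  rough cluster with a `degenerate` flag.
* Problem sizes used in the tests and the acceptance script — a
  70-particle phantom on a 288×480×64 grid, a 12-particle phantom on
  160×240×40, 16-profile Monte-Carlo ensembles — were chosen as the
  smallest scenes that exercise every packing configuration with
  comfortable statistics.

## Known limitations

* With noisy data, the per-pixel glow/exposure split cannot distinguish
  glow within the noise tolerance of the exposed level from exposure
  itself, so $V_s'$ is biased low (and $V_{s0}$ high) by the near-surface
  glow annulus. The *dose* is insensitive to this: the same bias enters
  the cluster volumes, and the counting formula is exactly invariant to
  the split for singles and in-plane clusters ($A_c/A_s$ equals the
  particle count there), with only a small residual for stacked
  configurations. The split itself is exact in the low-noise limit.
* Counting relies on the linear $A_c/A_s$ offset correction for all
  cluster sizes, exactly as the formula states; no higher-order occlusion
  model is attempted. Gaps inside loosely packed agglomerates glow
  briefly once the anterior particle is milled, which the linear model
  does not capture; per-cluster rounding absorbs most of it, and
  end-to-end recovery on mixed phantoms stays within a few percent.
* Organelle-level localization is out of reach by design: chemical
  fixation with drying destroys the compartments, which is also what
  makes the cell matrix homogeneous enough to threshold.
* Particles in slices flagged as unsegmentable are not counted. The
  flagged fraction is reported, and on phantoms it corresponds to
  cell-free lead-in/lead-out slices.

## A minimal session

```{r, eval = FALSE}
library(fibcount)

# simulate: 20 particles in mixed agglomerates, rendered and written as TIFF
ph <- generate_phantom(
  agglomerates = data.frame(n = c(rep(1, 10), 2, 3, 5),
                            packing = c(rep("random", 10), "stacked",
                                        "in-plane", "random")),
  shape = c(288, 480, 64), seed = 1)
r <- render_stack(ph)
write_stack(r$stack, "stack.tif")

# quantify
cfg <- pipeline_config(input = "stack.tif", out_dir = "run")
res <- run_pipeline(cfg)
print(res)
plot(res$dose)          # cluster-size histogram + cumulative distribution
summary(res$calibration)
```
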