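---
title: "Measuring glioblastoma growth direction against white-matter fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring glioblastoma growth direction against white-matter fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmGrowth)
```

## The question and the measurement

Glioblastoma is widely believed to infiltrate preferentially along
white-matter tracts. `gbmGrowth` operationalizes that hypothesis as a
voxel-wise angular comparison between two vector fields:

1. a **growth field** `u`: the displacement that carries the tumor
   configuration seen on a diagnostic MRI onto the configuration seen on a
   later pre-operative MRI of the same patient, estimated by non-linear
   registration of the tumor region after affine intra-patient alignment;
2. a **fiber field** `v`: the principal eigenvector of a diffusion-tensor
   white-matter atlas, a proxy for local fiber orientation, defined only up
   to sign.

At each atlas voxel the two are compared through the folded angle

$$\theta = \cos^{-1}\!\left(\frac{|u \cdot v|}{\lVert u\rVert\,\lVert v\rVert}\right) \in [0^\circ, 90^\circ],$$

where the absolute value folds the sign ambiguity of `v` (and of the
registration's direction convention) away. Growth at a voxel is called
*parallel* when $\theta < 20^\circ$ and *perpendicular* when
$\theta > 70^\circ$; nested fractions at $10^\circ$ and $80^\circ$ and a
9-bin histogram over $[0^\circ, 90^\circ]$ are also reported. At cohort
level, per-patient parallel and perpendicular fractions are compared with a
Wilcoxon signed-rank test.

Under the null of no preferred orientation — independent uniformly random
directions on the sphere — the folded angle has CDF $1-\cos\theta$, so the
expected parallel fraction is $1-\cos 20^\circ \approx 0.0603$ and the
expected perpendicular fraction is $\cos 70^\circ \approx 0.3420$. These two
constants anchor most of the package's validation: any correct
implementation of the folding and classification must reproduce them, and
the asymmetry between them (6% vs 34%) is worth keeping in mind when
interpreting the paired test.

## Pipeline stages and their parameters

`runPipeline()` executes, per patient:

1. **Isotropic resampling and intra-patient affine.** Both images are
   resampled to a common isotropic grid (linear interpolation for images,
   nearest-neighbour for masks), then the diagnostic image is affinely
   registered to the pre-operative one (multi-resolution, mean-squared
   error, bounded L-BFGS-B with a Nelder–Mead polish). The tumor region —
   the pre-operative mask dilated by 8 mm — is excluded from the similarity
   metric. This cost-function masking matters: tumor growth between the two
   timepoints is exactly the signal the later stages quantify, and without
   masking an affine fit absorbs part of the anisotropic expansion into
   global scales and shears, silently subtracting fiber-aligned displacement
   from the non-linear field.
2. **Tumor-region non-linear registration** (`registerGrowth()`): a
   Gaussian-regularized demons scheme, multi-resolution (factors 4/2/1) on
   a crop around the dilated union of both tumor masks, with the update
   force restricted to that support. Defaults: 5 mm mask dilation, force
   and field smoothing of 1.3 and 0.8 voxels, per-level iteration caps
   80/60/60 with early stopping at a relative metric improvement below
   1e-5 over 10 iterations, per-iteration step capped at one voxel. The
   output field lives on the pre-operative grid in world mm and points from
   the diagnostic toward the pre-operative configuration; the folding in
   $\theta$ makes the analysis insensitive to this sign choice.
3. **Template normalization.** An affine from pre-operative to template
   space (again with the tumor masked from the metric, since the template
   has no tumor), applied to images and masks, and to the growth field with
   **finite-strain reorientation**: vectors are rotated by the orthogonal
   factor $R$ of the polar decomposition $A = RS$ of the affine's linear
   part. $R$ is computed via SVD and equals $A(A^\top A)^{-1/2}$; rigid
   transforms rotate vectors exactly and preserve norms, pure anisotropic
   scalings leave directions untouched. We chose finite-strain over
   preservation-of-principal-direction because it is the standard for
   transporting orientation data under affines and requires no local
   Jacobian model.
4. **Atlas-grid analysis.** The field is down-sampled to the atlas grid
   (per-component trilinear; support by majority vote), fiber directions
   are extracted from the tensor atlas (`principalDirections()`), the angle
   map is computed and classified.

Tunable thresholds, with defaults and rationale:

* `faMin = 0.2` — fractional anisotropy cutoff defining usable white-matter
  voxels of the atlas. FA below ~0.2 means the principal eigenvector is a
  poor fiber proxy. Voxels additionally need all eigenvalues nonnegative
  and a relative eigenvalue gap $(\lambda_1-\lambda_2)/\lambda_1 \ge 10^{-3}$,
  so numerically degenerate directions never enter the statistics.
* `magMinMM = 0.5` — "detectable vector" magnitude threshold in mm.
  Displacements below half a millimetre are dominated by registration
  noise; they are marked invalid rather than contributing near-random
  angles. The denominator of every reported fraction is the count of valid
  voxels (detectable vector on a valid fiber voxel), not all brain voxels.
* `tPar = 20`, `tPerp = 70` degrees — classification thresholds, strict
  inequalities. Ties sit on a measure-zero set in floating point.
* Pooling: cohort fractions are reported both voxel-pooled across patients
  and as means of per-patient fractions, since either reading of a
  cohort-level percentage is defensible; the signed-rank test always uses
  per-patient fractions.

The Wilcoxon signed-rank test drops zero differences (Pratt's
rank-then-drop variant is available), mid-ranks ties, and computes the
two-sided p exactly — by convolution over the distribution of the rank sum
across all $2^n$ sign assignments — for $n \le 20$ effective pairs, else by
normal approximation with tie-corrected variance and continuity correction.
The n = 20 cutoff keeps exact computation instant while covering every
cohort size where the approximation is questionable.

## The phantom generator

No patient images ship with (or are downloadable by) the package; all
validation runs on synthetic two-timepoint phantoms with analytically known
growth. A phantom brain is a sphere (default radius 40 mm in a 96 mm field
of view) containing fixed internal anatomy — two ventricle-like CSF spaces
and one deep-gray nucleus — and a smooth two-octave harmonic intensity
texture standing in for gyral/vascular structure. The tumor is a sphere
(default radius 8 mm, jittered center across a cohort) with intensity well
above tissue; an optional central non-enhancing core emulates necrosis
enclosed by the contrast-enhancing rim. Images at the two timepoints may
live on different grids (default: 1.5 mm isotropic pre-operative,
1.5 × 1.5 × 3 mm diagnostic) and carry independent Gaussian noise.

Growth is modelled as a radial expansion whose direction couples to the
local fiber field. For a surface point with radial direction $\hat r$ and
fiber axis $v$, the folded cosine $t = |\hat r \cdot v|$ is pushed through
the folded von Mises–Fisher CDF map
$t' = \operatorname{asinh}(t \sinh\kappa)/\kappa$ and the direction is
tilted toward $\pm v$ accordingly (keeping its azimuth about $v$). Because
the map is the exact CDF transport, the growth-direction law over a
uniformly sampled surface is exactly folded-vMF($\kappa$): $\kappa = 0$
gives purely radial growth whose folded angles against a uniform fiber
field follow the $1-\cos\theta$ null law, and $\kappa \to \infty$ gives
fiber-parallel growth. We deliberately made this transport deterministic
rather than literally sampling a random direction per voxel: a per-voxel
random field is nowhere-smooth, hence unrecoverable in principle by any
regularized registration, while the transport preserves exactly the
marginal law that the validation statistics test. The displacement
magnitude uses a direction-dependent gain
$g = g_\perp + (g_\parallel - g_\perp)\,t'^2$, scales linearly inside the
tumor and tapers linearly to zero 5 mm beyond the maximal grown radius, so
the truth field has bounded support. The later-timepoint image, mask and
truth field are produced from the exact inverse of this growth map
(damped Picard iteration, residual tolerance 0.01 mm — damping is needed
because the CDF transport is steep where $\hat r$ crosses the fiber
equator).

Default condition. Growth gains default to $g_\parallel = 1.54$,
$g_\perp = 1.1$ with $\kappa = 6$. Two considerations fixed these numbers
once. First, *fiber-aligned growth must be observable*: an intensity-driven
registration can only see motion along intensity gradients, so on a
uniform tumor only boundary-normal motion is recoverable (the aperture
problem). The published effect is physically carried by growth being
concentrated along fibers — detectable displacement arises mostly at
fiber-facing poles, where the boundary normal coincides with the fiber
direction — so the perpendicular gain is kept near 1. A configuration with
substantial isotropic expansion plus a directional tilt has the same
nominal "alignment" but its direction statistics are invisible to any
registration, ours or anyone else's. Second, with $\kappa = 6$ the
generated pre-operative/diagnostic tumor volume ratio equals 2.5, the
cohort mean reported for clinical glioblastoma between diagnosis and
surgery (the naive product $g_\parallel g_\perp^2$ only predicts the
volume ratio for uncoupled, $\kappa = 0$ growth).

The matching tensor atlas assigns every in-brain voxel an anisotropic
tensor (FA ≈ 0.46) whose principal eigenvector follows the configured
geometry — uniform, circular (tangents about an axis), or fanning
(direction rotating linearly with position) — and near-isotropic tensors
outside; it lives on its own coarser grid (default 1.75 × 1.75 × 2.25 mm).

What the phantom does *not* emulate: MRI bias fields, skull and scalp,
partial-volume and susceptibility artifacts, mass effect on surrounding
anatomy beyond the growth map itself, infiltrative (non-displacing) tumor
progression, and real gyral geometry. Consequently, passing phantom tests
demonstrates that the estimator chain is correct and that genuinely
fiber-aligned displacement is recovered as such — it does not certify
performance on clinical data, where bias correction and skull stripping
must be applied upstream and where growth is partly infiltration rather
than displacement.

## Numerical choices and degenerate inputs

* World geometry follows the NIfTI sform convention (0-based voxel indices
  to mm, RAS+); all resampling is done by pull-back through exact affine
  inverses, trilinear for intensities and vector components,
  nearest-neighbour for masks (which therefore stay exactly binary).
* The folded-angle cosine is clamped to $[-1, 1]$ before the arccosine;
  near-collinear vector pairs with accumulated rounding cannot produce NaN.
* Invalid angle-map voxels carry NA in memory and $-1$ on disk — never 0,
  which is a meaningful angle.
* Zero-length growth vectors are excluded by the magnitude threshold before
  the angle computation; `foldAngle()` itself rejects zero vectors.
* An empty segmentation, an all-zero difference vector in the signed-rank
  test, non-overlapping grids in `downsampleField()`, and singular affine
  transforms are all hard errors with explicit messages, not silent NAs.
* Tensor voxels with non-finite entries, negative eigenvalues, or a
  degenerate leading eigenpair are marked invalid rather than aborting the
  atlas.
* Segmentation uses 26-connectivity for the largest component and
  6-connectivity flood fill (from the volume faces) for hole filling, the
  common morphology defaults; both are stated so results are reproducible.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
64-voxel cubic pre-operative grids at 1.5 mm (10-patient cohorts for the
cohort-level checks, with the non-linear stage cropped to the tumor
neighborhood), 32-voxel grids at 3 mm for unit tests, and Monte-Carlo
sample sizes of $10^4$–$10^5$ for the distributional checks. These sizes
are the package's chosen validation scale; all algorithms accept
clinical-resolution inputs unchanged.

## Known limitations

* The demons engine assumes monomodal, bias-free intensity pairs (the
  normalized-correlation metric option in `registerAffine()` relaxes the
  affine stage only). Multimodal registration is out of scope.
* Template normalization is affine, as in the original analysis; residual
  anatomical misalignment between patients is absorbed only by the atlas's
  coarse voxel size.
* The recovered angle distribution is a *blurred* version of the truth:
  even on phantoms, registration regularization pulls extreme angles toward
  the middle, so recovered parallel fractions under-estimate the truth
  (truth ≈ 0.25 → recovered ≈ 0.16 at default settings) and recovered
  perpendicular fractions over-estimate it. The cohort-level ordering of
  parallel vs perpendicular fractions is what the method is designed to
  detect robustly.
* Atlas tensors are reoriented with the same finite-strain rule when
  transported; whether the original analysis did so is unstated, and any
  difference is confined to the atlas-alignment step.
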