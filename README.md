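# gbmGrowth

Glioblastoma grows — between a diagnostic MRI and the pre-operative MRI a
few weeks later, the contrast-enhancing tumor typically expands severalfold.
A long-standing hypothesis holds that this growth runs preferentially
*along* white-matter fiber tracts rather than across them. `gbmGrowth` is an
R package for testing that hypothesis on longitudinal imaging: it estimates
a voxel-wise tumor growth vector field from two timepoints, transports it to
a common template space, and compares it against the principal fiber
directions of a diffusion-tensor white-matter atlas.

The core quantity is the folded angle between the growth vector *u* and the
fiber axis *v* at each atlas voxel,

    theta = arccos( |u . v| / (||u|| ||v||) )  in  [0, 90] degrees,

folded because fiber directions are sign-ambiguous. Growth at a voxel is
classified *parallel* (theta < 20 deg) or *perpendicular* (theta > 70 deg),
per-patient category fractions are summarized, and parallel-vs-perpendicular
dominance is tested across the cohort with an exact Wilcoxon signed-rank
test. Under the no-preference null (uniform random directions) the folded
angle has CDF 1 − cos(theta): 6.03% of voxels fall below 20 degrees and
34.20% above 70 degrees — the package's validation suite leans on these
closed forms throughout.

The pipeline (four stages, mirroring standard longitudinal tumor-imaging
practice):

1. affine intra-patient alignment of the diagnostic to the pre-operative
   image (tumor region masked out of the similarity metric);
2. non-linear registration of the tumor region (Gaussian-regularized
   demons, multi-resolution, restricted to the dilated mask union) yielding
   the localized growth displacement field;
3. affine normalization to a template, applied to images, masks, and — with
   finite-strain (polar-decomposition) reorientation — to the field;
4. down-sampling to the atlas grid, folded-angle maps, classification,
   cohort statistics (Wilcoxon test, tumor frequency map, volume growth
   ratios with slice-gap-corrected volumetry).

Because clinical MRIs cannot ship with a package, `gbmGrowth` includes a
first-class synthetic cohort generator (`phantomSpec()`, `makePatient()`,
`makeCohort()`): two-timepoint brain phantoms with known analytic growth
fields whose direction law couples to a configurable fiber geometry with
exact folded-von-Mises–Fisher statistics, plus a matching tensor atlas.
Every stage of the pipeline is validated against this ground truth.

## Worked example

```r
library(gbmGrowth)

cfg <- pipelineConfig(phantom = phantomSpec(), nPatients = 3, seed = 5,
                      outDir = "growth-demo")
res <- runPipeline(cfg)

res$pooled$pooled
#>       lt10       lt20       gt70       gt80      other
#> 0.04587421 0.16762839 0.14353722 0.07054241 0.68883439

res$wilcoxon
#> Wilcoxon signed-rank: W = 5, n = 3, p = 0.5 (exact)

res$volumeSummary
#>       mean         sd
#> 2.46602906 0.05134101
```

Reading the output: on a 3-patient phantom cohort with fiber-aligned growth,
16.8% of detectable growth vectors lie within 20 degrees of the local fiber
axis against 14.4% beyond 70 degrees. Three patients are far too few for the
signed-rank test (its smallest attainable two-sided p is 0.25); at the
10-patient scale used by the validation suite the parallel dominance is
significant. The tumors grew 2.47 ± 0.05 times in volume between the
timepoints, matching the generator's configured 2.5x growth condition. `growth-demo/` now holds the
per-patient angle summaries (CSV), cohort statistics (JSON), the tumor
frequency map (NIfTI), a structured log, and a manifest listing every
artifact with the parameters and seed that produced it.

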