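# Tumor segmentation (threshold-within-ROI) and volumetry with the
# slice-gap voxel-volume correction.

#' Segment a tumor inside a region of interest
#'
#' Stand-in for semi-automatic segmentation: voxels inside the ROI with
#' intensity at or above the threshold are kept, interior holes are filled
#' (6-connectivity flood from the volume faces) so that a central
#' non-enhancing core enclosed by the contrast rim is included, and the
#' result is restricted to the largest 26-connected component.
#'
#' @param image a [ScalarVolume-class].
#' @param roi binary [ScalarVolume-class] on the same grid.
#' @param threshold intensity cutoff; must lie within the image range.
#' @return binary [ScalarVolume-class] (values 0/1). The mask is always a
#'   subset of the ROI except for filled interior holes.
#' @export
segmentTumour <- function(image, roi, threshold) {
  stopifnot(is(image, "ScalarVolume"), is(roi, "ScalarVolume"))
  if (!.sameGrid(image@affine, volDim(image), roi@affine, volDim(roi)))
    stop("segmentTumour: image and ROI must share one grid")
  rng <- range(image@data)
  if (threshold < rng[1] || threshold > rng[2])
    stop(sprintf("threshold %g outside image intensity range [%g, %g]",
                 threshold, rng[1], rng[2]))
  m <- image@data >= threshold & roi@data != 0
  if (!any(m)) stop("no tumor found: empty mask after thresholding")
  m <- .fillHoles(m)
  m <- .largestComponent(m, 26L)
  scalarVolume(array(as.numeric(m), volDim(image)), image@affine)
}

#' Tumor volume with slice-gap correction
#'
#' Implements the voxel-volume convention for gapped acquisitions: volume =
#' voxel count x in-plane resolution x (slice thickness + gap thickness).
#' With zero gap this is the plain voxel volume.
#'
#' @param mask binary [ScalarVolume-class], or a voxel count.
#' @param inPlaneMM in-plane resolution, mm, length 2 (a, b).
#' @param sliceMM slice thickness, mm.
#' @param gapMM inter-slice gap, mm (>= 0).
#' @return volume in mm^3.
#' @examples
#' tumourVolume(100, c(0.5, 0.5), 5, 1) # 150 mm^3
#' @export
tumourVolume <- function(mask, inPlaneMM, sliceMM, gapMM = 0) {
  count <- if (is(mask, "ScalarVolume")) sum(mask@data != 0) else mask
  inPlaneMM <- rep(inPlaneMM, length.out = 2)
  if (any(inPlaneMM <= 0) || sliceMM <= 0)
    stop("in-plane resolution and slice thickness must be positive")
  if (gapMM < 0) stop("slice gap must be non-negative")
  count * inPlaneMM[1] * inPlaneMM[2] * (sliceMM + gapMM)
}

#' Build one patient's volume report
#'
#' @param patientId identifier.
#' @param volumeDiagnosticMM3,volumePreoperativeMM3 tumor volumes in mm^3.
#' @return one-row data.frame with the growth ratio
#'   (pre-operative / diagnostic).
#' @export
volumeReport <- function(patientId, volumeDiagnosticMM3,
                         volumePreoperativeMM3) {
  if (volumeDiagnosticMM3 <= 0 || volumePreoperativeMM3 <= 0)
    stop("volumes must be positive")
  data.frame(patient_id = patientId,
             volume_diagnostic_mm3 = volumeDiagnosticMM3,
             volume_preoperative_mm3 = volumePreoperativeMM3,
             ratio = volumePreoperativeMM3 / volumeDiagnosticMM3)
}

#' Cohort growth-ratio summary
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-patient pre-operative / diagnostic volume ratios.
#'
#' @param reports data.frame with a `ratio` column (rows from
#'   [volumeReport()]), or a list of such data.frames.
#' @return named numeric c(mean, sd).
#' @export
cohortGrowthSummary <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  r <- reports$ratio
  if (length(r) < 2) stop("cohort growth summary needs at least 2 reports")
  c(mean = mean(r), sd = stats::sd(r))
}
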