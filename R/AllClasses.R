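#' @import methods
NULL

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (!all(is.finite(affine)))
    return("affine must be finite")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    return("affine linear part must be invertible")
  if (!isTRUE(all.equal(affine[4, ], c(0, 0, 0, 1))))
    return("affine last row must be (0, 0, 0, 1)")
  NULL
}

#' 3D scalar volume with voxel-to-world geometry
#'
#' Carrier for images, binary masks and count maps: a 3D numeric array plus a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm
#' (NIfTI convention, RAS+).
#'
#' @slot data 3D numeric array of voxel values.
#' @slot affine 4x4 voxel(0-based)-to-world matrix, mm.
#' @export
setClass("ScalarVolume", representation(data = "array", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    .checkAffine(object@affine)
  })

#' 4x4 homogeneous world-to-world transform (mm)
#'
#' @slot matrix 4x4 homogeneous matrix mapping moving-space world coordinates
#'   to fixed-space world coordinates.
#' @slot converged logical; FALSE when the estimating optimizer stopped at its
#'   iteration cap without meeting tolerance.
#' @slot metric final similarity metric value (NA when constructed directly).
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", converged = "logical", metric = "numeric"),
  prototype(converged = TRUE, metric = NA_real_),
  validity = function(object) .checkAffine(object@matrix))

#' Dense displacement field (world mm) on a voxel grid
#'
#' Vectors map earlier-timepoint (diagnostic) tumor positions toward the
#' later (pre-operative) configuration, i.e. they point along growth; the
#' folded-angle analysis is insensitive to this sign convention.
#'
#' @slot vectors 4D array, dims (nx, ny, nz, 3), world-mm displacement
#'   components in x, y, z order.
#' @slot affine 4x4 voxel-to-world matrix of the carrying grid.
#' @slot support logical 3D array; vectors are zero outside the support.
#' @export
setClass("DisplacementField",
  representation(vectors = "array", affine = "matrix", support = "array"),
  validity = function(object) {
    d <- dim(object@vectors)
    if (length(d) != 4L || d[4] != 3L)
      return("vectors must be a 4D array with 3 components")
    if (!identical(dim(object@support), d[1:3]))
      return("support must match the vector grid")
    if (!is.logical(object@support)) return("support must be logical")
    if (!all(is.finite(object@vectors))) return("vector components must be finite")
    n <- prod(d[1:3])
    mag <- abs(object@vectors[seq_len(n)]) +
      abs(object@vectors[n + seq_len(n)]) +
      abs(object@vectors[2L * n + seq_len(n)])
    if (any(mag[!object@support] > 0))
      return("vectors must be zero outside the support mask")
    .checkAffine(object@affine)
  })

#' Per-voxel unit fiber directions (defined up to sign) with FA
#'
#' @slot vectors 4D array (nx, ny, nz, 3); unit vectors at valid voxels,
#'   zeros at invalid voxels.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot valid logical 3D array marking voxels with a well-defined direction.
#' @slot fa 3D array of fractional anisotropy in [0, 1] (NA where undefined).
#' @export
setClass("DirectionField",
  representation(vectors = "array", affine = "matrix", valid = "array",
                 fa = "array"),
  validity = function(object) {
    d <- dim(object@vectors)
    if (length(d) != 4L || d[4] != 3L)
      return("vectors must be a 4D array with 3 components")
    if (!identical(dim(object@valid), d[1:3]) ||
        !identical(dim(object@fa), d[1:3]))
      return("valid and fa must match the vector grid")
    if (!is.logical(object@valid)) return("valid must be logical")
    nv <- sum(object@valid)
    if (nv > 0) {
      idx <- which(object@valid)
      n <- prod(d[1:3])
      nrm <- sqrt(object@vectors[idx]^2 + object@vectors[idx + n]^2 +
                  object@vectors[idx + 2 * n]^2)
      if (any(abs(nrm - 1) > 1e-6))
        return("valid direction vectors must have unit norm (tol 1e-6)")
    }
    fa <- object@fa[is.finite(object@fa)]
    if (length(fa) && (min(fa) < -1e-9 || max(fa) > 1 + 1e-9))
      return("FA must lie in [0, 1]")
    .checkAffine(object@affine)
  })

#' Voxel-wise folded angle map, degrees in [0, 90]
#'
#' Invalid voxels carry NA (never 0, which is a meaningful angle); on disk
#' they are written as -1.
#'
#' @slot theta 3D array of folded angles in degrees; NA at invalid voxels.
#' @slot affine 4x4 voxel-to-world matrix (atlas grid).
#' @slot valid logical 3D array.
#' @export
setClass("AngleMap",
  representation(theta = "array", affine = "matrix", valid = "array"),
  validity = function(object) {
    if (!identical(dim(object@theta), dim(object@valid)))
      return("theta and valid must share dimensions")
    th <- object@theta[object@valid]
    if (any(!is.finite(th))) return("valid voxels must carry finite angles")
    if (length(th) && (min(th) < 0 || max(th) > 90))
      return("angles must lie in [0, 90] degrees")
    if (any(is.finite(object@theta[!object@valid])))
      return("invalid voxels must carry NA")
    .checkAffine(object@affine)
  })

#' Symmetric diffusion tensor volume
#'
#' Six unique tensor components per voxel in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#'
#' @slot data 4D array (nx, ny, nz, 6).
#' @slot affine 4x4 voxel-to-world matrix.
#' @export
setClass("TensorVolume", representation(data = "array", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L || d[4] != 6L)
      return("data must be a 4D array with 6 tensor components")
    .checkAffine(object@affine)
  })

#' Per-patient angle-category summary
#'
#' Voxel counts and fractions of the folded-angle map by alignment category,
#' plus a 9-bin histogram over [0, 90] degrees (10-degree bins, left-closed,
#' final bin right-closed).
#'
#' @slot patientId character identifier.
#' @slot nValid number of voxels with detectable vectors on valid fiber voxels.
#' @slot fractions named numeric: lt10, lt20, gt70, gt80, other. NA (with
#'   empty = TRUE) when nValid is 0.
#' @slot histogram integer counts per 10-degree bin, length 9.
#' @slot thresholds numeric c(parallel, perpendicular) degrees used.
#' @slot empty logical flag raised when no valid voxels existed.
#' @export
setClass("AlignmentSummary",
  representation(patientId = "character", nValid = "numeric",
                 fractions = "numeric", histogram = "numeric",
                 thresholds = "numeric", empty = "logical"),
  validity = function(object) {
    need <- c("lt10", "lt20", "gt70", "gt80", "other")
    if (!identical(names(object@fractions), need))
      return("fractions must be named lt10, lt20, gt70, gt80, other")
    if (length(object@histogram) != 9L) return("histogram must have 9 bins")
    if (!object@empty) {
      f <- object@fractions
      if (f[["lt10"]] > f[["lt20"]] + 1e-12 || f[["gt80"]] > f[["gt70"]] + 1e-12)
        return("nested fractions must not exceed their enclosing category")
      if (abs(f[["lt20"]] + f[["gt70"]] + f[["other"]] - 1) > 1e-9)
        return("lt20 + gt70 + other must sum to 1")
      if (sum(object@histogram) != object@nValid)
        return("histogram counts must sum to nValid")
    }
    NULL
  })

#' Wilcoxon signed-rank test result
#'
#' @slot nEffective pairs remaining after zero-difference handling.
#' @slot nZero zero differences encountered (ranked but discarded under the
#'   Pratt policy, dropped before ranking under the default policy).
#' @slot statistic signed-rank statistic W (sum of positive-difference ranks).
#' @slot pValue two-sided p-value.
#' @slot method "exact" (full sign-assignment distribution) or
#'   "normal_approximation" (tie-corrected, continuity-corrected).
#' @export
setClass("WilcoxonResult",
  representation(nEffective = "numeric", nZero = "numeric",
                 statistic = "numeric", pValue = "numeric",
                 method = "character"),
  prototype(nZero = 0),
  validity = function(object) {
    n <- object@nEffective
    # under Pratt ranking the largest attainable rank is n + nZero
    wMax <- n * (n + 1) / 2 + n * object@nZero
    if (object@statistic < -1e-9 || object@statistic > wMax + 1e-9)
      return("W must lie in [0, max attainable rank sum]")
    if (object@pValue <= 0 || object@pValue > 1)
      return("p must lie in (0, 1]")
    NULL
  })

#' Tumor occurrence frequency map
#'
#' @slot counts ScalarVolume of non-negative integer patient counts on the
#'   template grid.
#' @slot nPatients number of masks summed.
#' @export
setClass("FrequencyMap",
  representation(counts = "ScalarVolume", nPatients = "numeric"),
  validity = function(object) {
    x <- object@counts@data
    if (any(x < 0) || any(x != round(x))) return("counts must be non-negative integers")
    if (max(x) > object@nPatients) return("counts cannot exceed nPatients")
    NULL
  })

#' Synthetic cohort configuration
#'
#' Defines one family of two-timepoint phantom patients: grid geometry at
#' both timepoints, fiber-field geometry, tumor placement and size,
#' direction-dependent growth gains, the concentration of growth-direction
#' coupling to the fibers, and the intensity model.
#'
#' @slot gridShape integer voxels per axis of the pre-operative (t2) grid.
#' @slot voxelSizeT1,voxelSizeT2 mm per axis at each timepoint (may differ).
#' @slot fiberGeometry "uniform", "circular" or "fanning".
#' @slot fiberParams geometry parameters (e.g. `direction` unit 3-vector for
#'   uniform; `center`/`axis` for circular; `direction`/`axis`/`rate` for
#'   fanning, rate in radians/mm).
#' @slot tumorCenter world mm.
#' @slot tumorRadiusT1 mm.
#' @slot gainParallel,gainPerpendicular unitless radial expansion factors
#'   along/across the local fiber direction (>= 1 unless allowShrink).
#' @slot alignmentKappa concentration of the growth-direction coupling to the
#'   fibers; 0 = isotropic radial growth.
#' @slot noiseSigma additive Gaussian intensity noise SD.
#' @slot tissueContrast named intensities: background, tumor, necrosis.
#' @slot necroticFraction radius fraction of the central non-enhancing core
#'   (0 disables it).
#' @slot brainRadius mm of the spherical brain (= designated white matter
#'   region of the matching atlas).
#' @slot atlasVoxelSize mm per axis of the tensor atlas grid.
#' @slot allowShrink logical; gains < 1 are rejected unless TRUE.
#' @slot seed base RNG seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSizeT1 = "numeric",
                 voxelSizeT2 = "numeric", fiberGeometry = "character",
                 fiberParams = "list", tumorCenter = "numeric",
                 tumorRadiusT1 = "numeric", gainParallel = "numeric",
                 gainPerpendicular = "numeric", alignmentKappa = "numeric",
                 noiseSigma = "numeric", tissueContrast = "numeric",
                 necroticFraction = "numeric", brainRadius = "numeric",
                 atlasVoxelSize = "numeric", allowShrink = "logical",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
      return("gridShape must be three integers >= 16")
    if (any(object@voxelSizeT1 <= 0) || any(object@voxelSizeT2 <= 0))
      return("voxel sizes must be positive")
    if (!object@fiberGeometry %in% c("uniform", "circular", "fanning"))
      return("fiberGeometry must be uniform, circular or fanning")
    if (!object@allowShrink &&
        (object@gainParallel < 1 || object@gainPerpendicular < 1))
      return("growth gains must be >= 1 unless allowShrink = TRUE")
    if (object@alignmentKappa < 0) return("alignmentKappa must be >= 0")
    if (object@tumorRadiusT1 <= 0) return("tumorRadiusT1 must be positive")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    need <- c("background", "tumor", "necrosis")
    if (!all(need %in% names(object@tissueContrast)))
      return("tissueContrast needs background, tumor and necrosis levels")
    if (object@necroticFraction < 0 || object@necroticFraction >= 1)
      return("necroticFraction must lie in [0, 1)")
    NULL
  })

#' One synthetic two-timepoint patient
#'
#' @slot id patient identifier.
#' @slot imageT1,imageT2 ScalarVolume intensity images (diagnostic /
#'   pre-operative timepoints, possibly on different grids).
#' @slot maskT1,maskT2 binary ScalarVolume tumor masks.
#' @slot truthField DisplacementField: the analytic growth displacement on
#'   the t2 grid (world mm), zero outside a bounded tumor neighborhood.
#' @slot truthMeanAngle expected folded angle (degrees) of growth vs fibers
#'   over the tumor surface.
#' @export
setClass("PhantomPatient",
  representation(id = "character", imageT1 = "ScalarVolume",
                 imageT2 = "ScalarVolume", maskT1 = "ScalarVolume",
                 maskT2 = "ScalarVolume", truthField = "DisplacementField",
                 truthMeanAngle = "numeric"))
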