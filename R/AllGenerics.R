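#' @include AllClasses.R
NULL

#' Construct a ScalarVolume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel(0-based)-to-world matrix in mm.
#' @return A [ScalarVolume-class].
#' @export
scalarVolume <- function(data, affine) {
  new("ScalarVolume", data = data, affine = affine)
}

#' Construct a DisplacementField
#'
#' @param vectors 4D array (nx, ny, nz, 3), world-mm components.
#' @param affine 4x4 voxel-to-world matrix.
#' @param support logical 3D array; vectors are forced to zero outside it.
#' @return A [DisplacementField-class].
#' @export
displacementField <- function(vectors, affine, support = NULL) {
  d <- dim(vectors)
  if (is.null(support)) {
    n <- prod(d[1:3])
    mag <- abs(vectors[seq_len(n)]) + abs(vectors[n + seq_len(n)]) +
      abs(vectors[2L * n + seq_len(n)])
    support <- array(mag > 0, dim = d[1:3])
  } else {
    vectors <- vectors * as.numeric(support)  # recycles over 4th dim
  }
  new("DisplacementField", vectors = vectors, affine = affine,
      support = support)
}

#' Construct an AffineTransform
#'
#' @param matrix 4x4 homogeneous world-to-world matrix (mm).
#' @param converged logical optimizer status.
#' @param metric final metric value.
#' @return An [AffineTransform-class].
#' @export
affineTransform <- function(matrix, converged = TRUE, metric = NA_real_) {
  new("AffineTransform", matrix = matrix, converged = converged,
      metric = metric)
}

#' @rdname accessors
#' @param object a gbmGrowth data object.
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volAffine", function(object) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setGeneric("volDim", function(object) standardGeneric("volDim"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' Accessors for grid-carrying objects
#'
#' `volData` returns the voxel data array (scalar, vector, or tensor),
#' `volAffine` the 4x4 voxel-to-world matrix, `volDim` the grid dimensions
#' and `voxelSize` the voxel edge lengths in mm.
#'
#' @name accessors
#' @aliases volData,ScalarVolume-method
NULL

.gridClasses <- c("ScalarVolume", "DisplacementField", "DirectionField",
                  "AngleMap", "TensorVolume")

setMethod("volData", "ScalarVolume", function(object) object@data)
setMethod("volData", "TensorVolume", function(object) object@data)
setMethod("volData", "DisplacementField", function(object) object@vectors)
setMethod("volData", "DirectionField", function(object) object@vectors)
setMethod("volData", "AngleMap", function(object) object@theta)

for (cl in .gridClasses) {
  setMethod("volAffine", cl, function(object) object@affine)
}
setMethod("volDim", "ScalarVolume", function(object) dim(object@data))
setMethod("volDim", "TensorVolume", function(object) dim(object@data)[1:3])
setMethod("volDim", "DisplacementField",
          function(object) dim(object@vectors)[1:3])
setMethod("volDim", "DirectionField",
          function(object) dim(object@vectors)[1:3])
setMethod("volDim", "AngleMap", function(object) dim(object@theta))
for (cl in .gridClasses) {
  setMethod("voxelSize", cl, function(object)
    sqrt(colSums(object@affine[1:3, 1:3]^2)))
}

#' @rdname fieldAccessors
#' @param object a DisplacementField or DirectionField.
#' @export
setGeneric("fieldSupport", function(object) standardGeneric("fieldSupport"))
#' @rdname fieldAccessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname fieldAccessors
#' @export
setGeneric("faValues", function(object) standardGeneric("faValues"))

#' Field-specific accessors
#'
#' `fieldSupport` returns a DisplacementField's support mask, `validMask` a
#' DirectionField's or AngleMap's validity mask, `faValues` a
#' DirectionField's fractional anisotropy array.
#'
#' @name fieldAccessors
NULL

setMethod("fieldSupport", "DisplacementField", function(object) object@support)
setMethod("validMask", "DirectionField", function(object) object@valid)
setMethod("validMask", "AngleMap", function(object) object@valid)
setMethod("faValues", "DirectionField", function(object) object@fa)

#' @rdname summaryAccessors
#' @param object an AlignmentSummary or WilcoxonResult.
#' @export
setGeneric("alignmentFractions",
           function(object) standardGeneric("alignmentFractions"))
setMethod("alignmentFractions", "AlignmentSummary",
          function(object) object@fractions)
#' @rdname summaryAccessors
#' @export
setGeneric("angleHistogram", function(object) standardGeneric("angleHistogram"))
setMethod("angleHistogram", "AlignmentSummary", function(object) object@histogram)
#' @rdname summaryAccessors
#' @export
setGeneric("nValid", function(object) standardGeneric("nValid"))
setMethod("nValid", "AlignmentSummary", function(object) object@nValid)
#' @rdname summaryAccessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
setMethod("pValue", "WilcoxonResult", function(object) object@pValue)
#' @rdname summaryAccessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
setMethod("statistic", "WilcoxonResult", function(object) object@statistic)

#' Result accessors
#'
#' Accessors for [AlignmentSummary-class] (category fractions, 10-degree
#' histogram, valid voxel count) and [WilcoxonResult-class] (W statistic,
#' two-sided p).
#'
#' @name summaryAccessors
NULL

setMethod("show", "ScalarVolume", function(object) {
  cat("ScalarVolume:", paste(volDim(object), collapse = " x "),
      "voxels,", paste(signif(voxelSize(object), 4), collapse = " x "),
      "mm\n  intensity range:",
      paste(signif(range(object@data), 5), collapse = " .. "), "\n")
})

setMethod("show", "DisplacementField", function(object) {
  n <- prod(volDim(object))
  mag <- sqrt(rowSums(matrix(object@vectors, n, 3)^2))
  cat("DisplacementField:", paste(volDim(object), collapse = " x "),
      "voxels,", sum(object@support), "supported\n  |u| max:",
      signif(max(mag), 4), "mm\n")
})

setMethod("show", "DirectionField", function(object) {
  cat("DirectionField:", paste(volDim(object), collapse = " x "),
      "voxels,", sum(object@valid), "valid;  FA range:",
      paste(signif(range(object@fa, na.rm = TRUE), 3), collapse = " .. "),
      "\n")
})

setMethod("show", "AngleMap", function(object) {
  th <- object@theta[object@valid]
  cat("AngleMap:", sum(object@valid), "valid voxels")
  if (length(th))
    cat(";  median theta:", signif(stats::median(th), 4), "deg")
  cat("\n")
})

setMethod("show", "AlignmentSummary", function(object) {
  cat("AlignmentSummary [", object@patientId, "]  n_valid =",
      object@nValid, "\n")
  if (object@empty) {
    cat("  no detectable growth vectors\n")
  } else {
    f <- signif(object@fractions, 4)
    cat(sprintf("  <10deg %.4f | <20deg %.4f | >70deg %.4f | >80deg %.4f | other %.4f\n",
                f[["lt10"]], f[["lt20"]], f[["gt70"]], f[["gt80"]],
                f[["other"]]))
  }
})

setMethod("show", "WilcoxonResult", function(object) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.5g (%s)\n",
              object@statistic, as.integer(object@nEffective),
              object@pValue, object@method))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (world mm):\n")
  print(signif(object@matrix, 6))
  if (!object@converged) cat("  warning: optimizer did not converge\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = "x"), "t2 grid,",
      object@fiberGeometry, "fibers, kappa =", object@alignmentKappa,
      ", gains", object@gainParallel, "/", object@gainPerpendicular, "\n")
})

setMethod("show", "PhantomPatient", function(object) {
  cat("PhantomPatient", object@id, "- truth mean angle",
      signif(object@truthMeanAngle, 4), "deg\n")
})
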