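# File formats: NIfTI-1 volumes/fields/tensors (via RNifti), 4x4 plain-text
# affine matrices, CSV summaries and JSON statistics/manifests.
#
# Conventions: voxel-to-world affines follow the NIfTI sform (0-based voxel
# indices, world mm, RAS+); displacement fields are 4D NIfTI with 3
# components holding x/y/z world-mm displacements; tensors are 4D NIfTI with
# 6 components in lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz);
# angle maps are scalar NIfTI in degrees with -1 marking invalid voxels.

.asNiftiWithAffine <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

.affineFromNifti <- function(img) {
  m <- unclass(RNifti::xform(img))
  attributes(m) <- list(dim = dim(m))
  m
}

# strip niftiImage class/attributes down to a plain numeric array
.plainArray <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim(a))
}

#' Read / write scalar volumes
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @return `readVolume` returns a [ScalarVolume-class].
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- .plainArray(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L)
    stop("expected a 3D scalar volume, found ", length(dim(a)),
         " dimensions in ", path)
  scalarVolume(a * 1.0, .affineFromNifti(img))
}

#' @rdname readVolume
#' @param vol a [ScalarVolume-class].
#' @param binary write as int8 0/1 (for masks).
#' @export
writeVolume <- function(vol, path, binary = FALSE) {
  stopifnot(is(vol, "ScalarVolume"))
  data <- vol@data
  if (binary) {
    data <- array(as.integer(data != 0), dim(data))
    img <- .asNiftiWithAffine(data, vol@affine)
    img <- RNifti::asNifti(img, datatype = "int8")
  } else {
    img <- .asNiftiWithAffine(data, vol@affine)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write displacement fields
#'
#' Stored as 4D NIfTI with three components (x, y, z world-mm
#' displacement); the description header field records the convention.
#'
#' @param path NIfTI-1 file.
#' @return `readField` returns a [DisplacementField-class] (support =
#'   non-zero vectors).
#' @export
readField <- function(path) {
  img <- RNifti::readNifti(path)
  a <- .plainArray(img)
  if (length(dim(a)) == 5L) a <- array(a, dim(a)[c(1:3, 5)])
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("expected a 4D displacement field with 3 components in ", path,
         " (found dims ", paste(dim(a), collapse = "x"), ")")
  displacementField(a * 1.0, .affineFromNifti(img))
}

#' @rdname readField
#' @param field a [DisplacementField-class].
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "DisplacementField"))
  img <- .asNiftiWithAffine(field@vectors, field@affine)
  img$descrip <- "growth displacement, world mm, x/y/z components"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write diffusion tensor volumes
#'
#' 4D NIfTI with six components in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#'
#' @param path NIfTI-1 file.
#' @return `readTensorVolume` returns a [TensorVolume-class].
#' @export
readTensorVolume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- .plainArray(img)
  if (length(dim(a)) == 5L) a <- array(a, dim(a)[c(1:3, 5)])
  if (length(dim(a)) != 4L || dim(a)[4] != 6L)
    stop("expected a 4D tensor volume with 6 components in ", path,
         " (found dims ", paste(dim(a), collapse = "x"), ")")
  new("TensorVolume", data = a * 1.0, affine = .affineFromNifti(img))
}

#' @rdname readTensorVolume
#' @param tensors a [TensorVolume-class].
#' @export
writeTensorVolume <- function(tensors, path) {
  stopifnot(is(tensors, "TensorVolume"))
  img <- .asNiftiWithAffine(tensors@data, tensors@affine)
  img$descrip <- "symmetric tensor, lower-triangular Dxx Dxy Dyy Dxz Dyz Dzz"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a direction field as vector + FA NIfTI pair
#'
#' @param dirs a [DirectionField-class].
#' @param pathVectors,pathFA output NIfTI paths.
#' @export
writeDirectionField <- function(dirs, pathVectors, pathFA) {
  stopifnot(is(dirs, "DirectionField"))
  img <- .asNiftiWithAffine(dirs@vectors, dirs@affine)
  img$descrip <- "principal fiber direction (unit, sign-arbitrary)"
  RNifti::writeNifti(img, pathVectors)
  fa <- dirs@fa
  fa[!is.finite(fa)] <- 0
  RNifti::writeNifti(.asNiftiWithAffine(fa, dirs@affine), pathFA)
  invisible(pathVectors)
}

#' Write an angle map (degrees; invalid voxels as -1)
#'
#' @param map an [AngleMap-class].
#' @param path output NIfTI path.
#' @export
writeAngleMap <- function(map, path) {
  stopifnot(is(map, "AngleMap"))
  th <- map@theta
  th[!map@valid] <- -1
  img <- .asNiftiWithAffine(th, map@affine)
  img$descrip <- "folded angle, degrees in [0,90]; -1 = invalid"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an angle map written by [writeAngleMap()]
#'
#' @param path NIfTI file.
#' @return An [AngleMap-class].
#' @export
readAngleMap <- function(path) {
  vol <- readVolume(path)
  th <- vol@data
  valid <- th >= 0
  th[!valid] <- NA_real_
  new("AngleMap", theta = th, affine = vol@affine, valid = valid)
}

#' Read / write 4x4 affine transforms as plain text
#'
#' @param path text file holding a whitespace-separated 4x4 matrix.
#' @return `readAffineTransform` returns an
#'   [AffineTransform-class].
#' @export
readAffineTransform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  affineTransform(m)
}

#' @rdname readAffineTransform
#' @param transform an [AffineTransform-class].
#' @export
writeAffineTransform <- function(transform, path) {
  stopifnot(is(transform, "AffineTransform"))
  utils::write.table(format(transform@matrix, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a frequency map as int16 NIfTI
#'
#' @param fmap a [FrequencyMap-class].
#' @param path output path.
#' @export
writeFrequencyMap <- function(fmap, path) {
  stopifnot(is(fmap, "FrequencyMap"))
  img <- .asNiftiWithAffine(fmap@counts@data, fmap@counts@affine)
  img <- RNifti::asNifti(img, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}
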