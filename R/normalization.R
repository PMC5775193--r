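# Template-space normalization: affine registration to a template,
# finite-strain vector reorientation, field down-sampling to the atlas grid,
# and principal fiber directions from the diffusion tensor atlas.

#' Affine registration of the pre-operative image to a template
#'
#' Thin wrapper around [registerAffine()]; the returned transform is
#' applied downstream to the pre-operative image, both tumor masks, the
#' diagnostic image and the growth field (vectors reoriented by the
#' finite-strain rotation factor).
#'
#' @param preop pre-operative [ScalarVolume-class].
#' @param template template [ScalarVolume-class].
#' @param ... passed to [registerAffine()].
#' @return An [AffineTransform-class] mapping pre-operative world
#'   to template world coordinates.
#' @export
registerToTemplate <- function(preop, template, ...) {
  registerAffine(preop, template, ...)
}

#' Finite-strain reorientation of displacement vectors
#'
#' Rotates every vector by the rotation factor R of the polar decomposition
#' A = R S of the transform's linear part. Under a rigid transform this is
#' the rotation itself and vector norms are preserved; under pure
#' (anisotropic) scaling R is the identity and directions are unchanged.
#' Positions are not moved; pair with [applyTransform()] for full
#' transport of a field (which calls this rotation internally).
#'
#' @param field a [DisplacementField-class].
#' @param transform an [AffineTransform-class].
#' @return A [DisplacementField-class] with rotated vectors on the
#'   unchanged grid.
#' @export
reorientVectors <- function(field, transform) {
  stopifnot(is(field, "DisplacementField"), is(transform, "AffineTransform"))
  A <- transform@matrix[1:3, 1:3]
  if (abs(det(A)) < 1e-12) stop("singular linear part")
  R <- .polarRotation(A)
  m <- .fieldAsMatrix(field@vectors) %*% t(R)
  m[!as.vector(field@support), ] <- 0
  new("DisplacementField", vectors = array(m, dim(field@vectors)),
      affine = field@affine, support = field@support)
}

#' Down-sample a displacement field onto the atlas grid
#'
#' Per-component trilinear resampling onto the atlas grid; the support mask
#' is carried over by majority vote (fractional support >= 0.5). Atlas
#' voxels receiving no source support are marked unsupported.
#'
#' @param field a [DisplacementField-class].
#' @param atlasGrid grid-carrying object (e.g. the
#'   [TensorVolume-class] atlas or a [DirectionField-class])
#'   or `list(dim, affine)`.
#' @return A [DisplacementField-class] on the atlas grid.
#' @export
downsampleField <- function(field, atlasGrid) {
  stopifnot(is(field, "DisplacementField"))
  tg <- .targetGridOf(atlasGrid)
  w <- .gridWorld(tg$affine, tg$dim)
  vox <- .worldToVoxel(field@affine, w)
  suppFrac <- .interpTrilinear(array(as.numeric(field@support),
                                     volDim(field)), vox)
  supp <- suppFrac >= 0.5
  if (!any(supp)) {
    dm <- volDim(field)
    anyOverlap <- any(vox[, 1] > -0.5 & vox[, 1] < dm[1] - 0.5 &
                      vox[, 2] > -0.5 & vox[, 2] < dm[2] - 0.5 &
                      vox[, 3] > -0.5 & vox[, 3] < dm[3] - 0.5)
    if (!anyOverlap)
      stop("downsampleField: atlas grid does not overlap the field grid")
  }
  comp <- vapply(1:3, function(k)
    .interpTrilinear(field@vectors[, , , k], vox), numeric(nrow(vox)))
  comp[!supp, ] <- 0
  new("DisplacementField", vectors = array(comp, c(tg$dim, 3L)),
      affine = tg$affine, support = array(supp, tg$dim))
}

# vectorized FA from tensor invariants: FA^2 = 3/2 * ||D - tr/3 I||^2 / ||D||^2
.faFromTensors <- function(tm) {
  # tm: n x 6 in order Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
  tr <- tm[, 1] + tm[, 3] + tm[, 6]
  norm2 <- tm[, 1]^2 + tm[, 3]^2 + tm[, 6]^2 +
    2 * (tm[, 2]^2 + tm[, 4]^2 + tm[, 5]^2)
  dev2 <- norm2 - tr^2 / 3
  fa2 <- ifelse(norm2 > 0, 1.5 * dev2 / norm2, NA_real_)
  sqrt(pmin(pmax(fa2, 0), 1))
}

#' Principal fiber directions of a diffusion tensor volume
#'
#' Per-voxel eigen-decomposition of the symmetric tensor: the direction is
#' the eigenvector of the largest eigenvalue (defined up to sign), and
#' FA = sqrt(1/2) sqrt((l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2) /
#' sqrt(l1^2 + l2^2 + l3^2). A voxel is valid when FA >= `faMin`, all
#' eigenvalues are non-negative, and the two leading eigenvalues are
#' separated by a relative margin (l1 - l2)/l1 >= 1e-3 so the principal
#' direction is numerically well defined. Non-finite tensor entries mark
#' the voxel invalid rather than failing.
#'
#' @param tensors a [TensorVolume-class] (components in
#'   lower-triangular order Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#' @param faMin white-matter FA cutoff (default 0.2).
#' @return A [DirectionField-class].
#' @export
principalDirections <- function(tensors, faMin = 0.2) {
  stopifnot(is(tensors, "TensorVolume"))
  dm <- volDim(tensors)
  n <- prod(dm)
  tm <- matrix(tensors@data, n, 6)
  finite <- rowSums(is.finite(tm)) == 6L
  fa <- rep(NA_real_, n)
  fa[finite] <- .faFromTensors(tm[finite, , drop = FALSE])
  cand <- which(finite & !is.na(fa) & fa >= faMin)
  vecs <- matrix(0, n, 3)
  valid <- logical(n)
  for (i in cand) {
    D <- matrix(c(tm[i, 1], tm[i, 2], tm[i, 4],
                  tm[i, 2], tm[i, 3], tm[i, 5],
                  tm[i, 4], tm[i, 5], tm[i, 6]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    l <- e$values
    if (any(l < -1e-12 * max(abs(l), 1))) next
    if (l[1] <= 0 || (l[1] - l[2]) / l[1] < 1e-3) next
    v <- e$vectors[, 1]
    # canonical sign: first non-zero component positive
    nz <- which(abs(v) > 1e-12)[1]
    if (v[nz] < 0) v <- -v
    vecs[i, ] <- v
    valid[i] <- TRUE
  }
  new("DirectionField", vectors = array(vecs, c(dm, 3L)),
      affine = tensors@affine, valid = array(valid, dm),
      fa = array(fa, dm))
}
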