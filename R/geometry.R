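# Grid geometry, interpolation, resampling and 3D morphology primitives.
# All voxel indices handled here are 0-based (NIfTI convention); world
# coordinates are mm. Points travel as n x 3 matrices.

.voxelToWorld <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine[1:3, 1:3] %*% t(ijk)) +
    matrix(affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
}

.worldToVoxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz)) +
    matrix(inv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
}

# 0-based voxel coordinates of every voxel of a grid, in array order
.gridVoxels <- function(dm) {
  cbind(rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
        rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3]),
        rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]))
}

.gridWorld <- function(affine, dm) .voxelToWorld(affine, .gridVoxels(dm))

# default world frame: axis-aligned grid centered on the world origin
.centeredAffine <- function(dm, voxel) {
  a <- diag(4)
  diag(a)[1:3] <- voxel
  a[1:3, 4] <- -voxel * (dm - 1) / 2
  a
}

# Trilinear interpolation of a 3D array at continuous 0-based voxel points.
# Points outside the grid get `outside` (default 0, background).
.interpTrilinear <- function(arr, pts, outside = 0) {
  dm <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x > -0.5 & x < dm[1] - 0.5 & y > -0.5 & y < dm[2] - 0.5 &
    z > -0.5 & z < dm[3] - 0.5
  out <- rep(outside, nrow(pts))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(pmax(floor(x), 0), dm[1] - 1)
  y0 <- pmin(pmax(floor(y), 0), dm[2] - 1)
  z0 <- pmin(pmax(floor(z), 0), dm[3] - 1)
  fx <- pmin(pmax(x - x0, 0), 1)
  fy <- pmin(pmax(y - y0, 0), 1)
  fz <- pmin(pmax(z - z0, 0), 1)
  x1 <- pmin(x0 + 1, dm[1] - 1)
  y1 <- pmin(y0 + 1, dm[2] - 1)
  z1 <- pmin(z0 + 1, dm[3] - 1)
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  i000 <- 1 + x0 + nx * y0 + nxy * z0
  dx <- x1 - x0; dy <- nx * (y1 - y0); dz <- nxy * (z1 - z0)
  v <- (arr[i000]            * (1 - fx) + arr[i000 + dx]           * fx) *
         (1 - fy) * (1 - fz) +
       (arr[i000 + dy]       * (1 - fx) + arr[i000 + dx + dy]      * fx) *
         fy * (1 - fz) +
       (arr[i000 + dz]       * (1 - fx) + arr[i000 + dx + dz]      * fx) *
         (1 - fy) * fz +
       (arr[i000 + dy + dz]  * (1 - fx) + arr[i000 + dx + dy + dz] * fx) *
         fy * fz
  out[inside] <- v
  out
}

.interpNearest <- function(arr, pts, outside = 0) {
  dm <- dim(arr)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  inside <- i >= 0 & i <= dm[1] - 1 & j >= 0 & j <= dm[2] - 1 &
    k >= 0 & k <= dm[3] - 1
  out <- rep(outside, nrow(pts))
  out[inside] <- arr[1 + i[inside] + dm[1] * (j[inside] + dm[2] * k[inside])]
  out
}

.interpAt <- function(arr, pts, interp, outside = 0) {
  if (interp == "nearest") .interpNearest(arr, pts, outside)
  else .interpTrilinear(arr, pts, outside)
}

# Resample a 3D array from (srcAffine) onto a target grid (dstAffine, dstDim).
.resampleArray <- function(arr, srcAffine, dstAffine, dstDim,
                           interp = "linear", outside = 0) {
  w <- .gridWorld(dstAffine, dstDim)
  v <- .worldToVoxel(srcAffine, w)
  array(.interpAt(arr, v, interp, outside), dim = dstDim)
}

# Separable Gaussian smoothing; sigma in voxels per axis (length 1 or 3).
.gaussianKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

.convAxis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  dm <- dim(arr)
  n <- dm[axis]
  r <- (length(k) - 1L) / 2L
  # band matrix with replicated-edge boundary handling
  cm <- matrix(0, n, n)
  for (o in seq_along(k)) {
    idx <- seq_len(n) + (o - 1L - r)
    idx <- pmin(pmax(idx, 1L), n)
    cm[cbind(seq_len(n), idx)] <- cm[cbind(seq_len(n), idx)] + k[o]
  }
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  a <- cm %*% matrix(a, da[1], da[2] * da[3])
  dim(a) <- da
  aperm(a, order(perm))
}

.gaussianSmooth <- function(arr, sigmaVox) {
  sigmaVox <- rep(sigmaVox, length.out = 3)
  for (ax in 1:3) arr <- .convAxis(arr, .gaussianKernel(sigmaVox[ax]), ax)
  arr
}

.shiftArray <- function(arr, d, fill = 0) {
  dm <- dim(arr)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- seq_len(dm[ax] - d[ax]) + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

.neighborOffsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  offs
}

# Binary dilation by `iter` steps of 6-neighborhood growth (chamfer ball).
.dilate6 <- function(mask, iter) {
  offs <- .neighborOffsets(6L)
  m <- mask
  for (i in seq_len(iter)) {
    acc <- m
    for (r in seq_len(nrow(offs)))
      acc <- acc | .shiftArray(m, offs[r, ], FALSE)
    m <- acc
  }
  m
}

# Connected-component labelling by iterative minimum-label propagation.
.labelComponents <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lbl <- array(0, dm)
  lbl[mask] <- which(mask)
  offs <- .neighborOffsets(connectivity)
  big <- prod(dm) + 1
  repeat {
    cur <- lbl
    cur[!mask] <- big
    best <- cur
    for (r in seq_len(nrow(offs))) {
      s <- .shiftArray(cur, offs[r, ], big)
      best <- pmin(best, s)
    }
    best[!mask] <- 0
    if (identical(best, lbl)) break
    lbl <- best
  }
  lbl
}

.largestComponent <- function(mask, connectivity = 26L) {
  lbl <- .labelComponents(mask, connectivity)
  tab <- table(lbl[lbl > 0])
  keep <- as.numeric(names(tab)[which.max(tab)])
  lbl == keep
}

# Fill interior holes: flood the complement from the volume faces with
# 6-connectivity; anything not reached is an enclosed hole.
.fillHoles <- function(mask) {
  dm <- dim(mask)
  bg <- !mask
  reached <- array(FALSE, dm)
  reached[1, , ] <- bg[1, , ]; reached[dm[1], , ] <- bg[dm[1], , ]
  reached[, 1, ] <- reached[, 1, ] | bg[, 1, ]
  reached[, dm[2], ] <- reached[, dm[2], ] | bg[, dm[2], ]
  reached[, , 1] <- reached[, , 1] | bg[, , 1]
  reached[, , dm[3]] <- reached[, , dm[3]] | bg[, , dm[3]]
  offs <- .neighborOffsets(6L)
  repeat {
    acc <- reached
    for (r in seq_len(nrow(offs)))
      acc <- acc | (.shiftArray(reached, offs[r, ], FALSE) & bg)
    if (identical(acc, reached)) break
    reached <- acc
  }
  mask | (bg & !reached)
}

.maskBoundingBox <- function(mask, marginVox = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  dm <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - marginVox, 1L)
  hi <- pmin(apply(idx, 2, max) + marginVox, dm)
  list(lo = lo, hi = hi)
}

# Orthogonal factor of the polar decomposition A = R S (finite strain);
# equals A (A^T A)^(-1/2). For orientation-reversing A (det < 0) the factor
# is itself a reflection and is passed through unchanged.
.polarRotation <- function(A) {
  s <- svd(A)
  s$u %*% t(s$v)
}

.rowNorms <- function(m) sqrt(rowSums(m^2))

.normalizeRows <- function(m) {
  n <- .rowNorms(m)
  n[n == 0] <- 1
  m / n
}

.sameGrid <- function(a1, d1, a2, d2, tol = 1e-4) {
  identical(as.integer(d1), as.integer(d2)) && max(abs(a1 - a2)) < tol
}

.fieldAsMatrix <- function(vectors) {
  d <- dim(vectors)
  matrix(vectors, prod(d[1:3]), 3)
}

# Run code with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-index child seed (31-bit), independent of the global RNG.
.childSeed <- function(master, index) {
  as.integer((as.double(master %% 2147483647L) * 48271 +
              as.double(index) * 1299721) %% 2147483647)
}
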