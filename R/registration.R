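# Intra-patient registration: isotropic resampling, multi-resolution affine
# alignment, transform application, and non-linear tumor-region registration
# yielding the localized growth deformation field.

#' Resample a volume to isotropic (or stated) spacing
#'
#' Builds an axis-aligned grid with the requested spacing covering the input
#' field of view; world coordinates are preserved. Use nearest-neighbour
#' interpolation for masks.
#'
#' @param image a [ScalarVolume-class].
#' @param spacingMM target voxel size in mm (scalar or length 3).
#' @param interp "linear" or "nearest".
#' @return A [ScalarVolume-class] on the new grid.
#' @export
resampleIsotropic <- function(image, spacingMM = 1, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is(image, "ScalarVolume"), all(spacingMM > 0))
  spacing <- rep(spacingMM, length.out = 3)
  dm <- volDim(image)
  corners <- as.matrix(expand.grid(c(-0.5, dm[1] - 0.5),
                                   c(-0.5, dm[2] - 0.5),
                                   c(-0.5, dm[3] - 0.5)))
  w <- .voxelToWorld(image@affine, corners)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  newDim <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)))
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- lo + spacing / 2
  out <- .resampleArray(image@data, image@affine, aff, newDim, interp)
  scalarVolume(out, aff)
}

# transform parameters -> 4x4 world matrix, rotations about `center`
.paramsToMatrix <- function(par, type, center) {
  tr <- par[1:3]
  ang <- if (type == "translation") c(0, 0, 0) else par[4:6]
  sc <- switch(type,
               translation = , rigid = c(1, 1, 1),
               similarity = rep(exp(par[7]), 3),
               affine = exp(par[7:9]))
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  A <- Rz %*% Ry %*% Rx %*% diag(sc)
  if (type == "affine" && length(par) >= 12) {
    sh <- diag(3)
    sh[1, 2] <- par[10]; sh[1, 3] <- par[11]; sh[2, 3] <- par[12]
    A <- A %*% sh
  }
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- center - A %*% center + tr
  m
}

.nParams <- function(type) switch(type, translation = 3L, rigid = 6L,
                                  similarity = 7L, affine = 12L)

.intensityCentroid <- function(vol) {
  x <- vol@data - min(vol@data)
  s <- sum(x)
  if (s <= 0) return(c(0, 0, 0))
  w <- .gridWorld(vol@affine, volDim(vol))
  colSums(w * as.vector(x)) / s
}

# mean-squared error / negative NCC of moving resampled through M onto the
# fixed sample points
.affineMetric <- function(par, type, center, movData, movAffine, fixVals,
                          fixWorld, metric) {
  M <- .paramsToMatrix(par, type, center)
  if (!all(is.finite(M)) || abs(det(M[1:3, 1:3])) < 1e-6)
    return(1e10) # degenerate transform: reject

  vox <- .worldToVoxel(movAffine, t(solve(M, t(cbind(fixWorld, 1))))[, 1:3])
  mv <- .interpTrilinear(movData, vox)
  if (metric == "ncc") {
    s <- stats::sd(mv)
    if (s == 0) return(1)
    1 - abs(stats::cor(mv, fixVals))
  } else {
    mean((mv - fixVals)^2)
  }
}

# coarse pyramid copy of a volume at roughly `spacing` mm
.pyramidLevel <- function(vol, spacing) {
  vs <- voxelSize(vol)
  if (all(spacing <= vs + 1e-9)) return(vol)
  sigma <- pmax(0, spacing / vs / 2 - 0.4)
  sm <- scalarVolume(.gaussianSmooth(vol@data, sigma), vol@affine)
  resampleIsotropic(sm, spacing)
}

#' Affine registration of two volumes
#'
#' Multi-resolution (coarse-to-fine) minimization of the mean-squared
#' intensity error (or 1 - |normalized correlation|) over a parameterized
#' world-to-world transform, initialized from the intensity centroid offset.
#' Suited to monomodal longitudinal pairs.
#'
#' @param moving,fixed [ScalarVolume-class]s; both must be
#'   non-constant.
#' @param type "translation", "rigid", "similarity" or "affine".
#' @param metric "mse" or "ncc".
#' @param levels pyramid spacings in mm, coarse to fine; default
#'   `c(4, 2) * min(voxel size)`.
#' @param maxIter optimizer iteration cap per level.
#' @param maxPoints fixed-image sample cap per level.
#' @param excludeMask optional binary [ScalarVolume-class] on the
#'   fixed grid; voxels inside it are excluded from the similarity metric
#'   (cost-function masking, e.g. to keep a growing tumor from leaking into
#'   the global transform).
#' @return An [AffineTransform-class] mapping moving world
#'   coordinates to fixed world coordinates; `converged = FALSE` (with a
#'   warning) when the optimizer hit its iteration cap.
#' @export
registerAffine <- function(moving, fixed, type = c("affine", "rigid",
                                                   "similarity",
                                                   "translation"),
                           metric = c("mse", "ncc"), levels = NULL,
                           maxIter = 100L, maxPoints = 15000L,
                           excludeMask = NULL) {
  type <- match.arg(type)
  metric <- match.arg(metric)
  stopifnot(is(moving, "ScalarVolume"), is(fixed, "ScalarVolume"))
  if (stats::sd(moving@data) == 0 || stats::sd(fixed@data) == 0)
    stop("registerAffine needs non-constant images")
  if (is.null(levels)) {
    base <- min(voxelSize(fixed))
    levels <- base * c(4, 2, 1)
  }
  center <- .intensityCentroid(fixed)
  par <- numeric(.nParams(type))
  par[1:3] <- .intensityCentroid(fixed) - .intensityCentroid(moving)
  scales <- c(rep(1, 3), rep(50, .nParams(type) - 3))  # mm vs rad/log units
  converged <- TRUE
  value <- NA_real_
  for (lv in levels) {
    fl <- .pyramidLevel(fixed, rep(lv, 3))
    ml <- .pyramidLevel(moving, rep(lv, 3))
    w <- .gridWorld(fl@affine, volDim(fl))
    vals <- as.vector(fl@data)
    if (!is.null(excludeMask)) {
      exVox <- .worldToVoxel(excludeMask@affine, w)
      keepEx <- .interpNearest(excludeMask@data, exVox) == 0
      w <- w[keepEx, , drop = FALSE]
      vals <- vals[keepEx]
    }
    if (length(vals) > maxPoints) {
      keep <- round(seq(1, length(vals), length.out = maxPoints))
      w <- w[keep, , drop = FALSE]
      vals <- vals[keep]
    }
    fn <- function(p)
      .affineMetric(p / scales, type, center, ml@data, ml@affine,
                    vals, w, metric)
    # box constraints (scaled units): 60 mm translation, ~0.5 rad rotation,
    # |log scale| and shear up to 0.3
    bound <- c(rep(60, 3), rep(25, .nParams(type) - 3))
    opt <- stats::optim(par * scales, fn, method = "L-BFGS-B",
                        lower = pmin(par * scales - 1, -bound),
                        upper = pmax(par * scales + 1, bound),
                        control = list(maxit = maxIter, factr = 1e4))
    converged <- converged && opt$convergence == 0L
    # simplex polish: robust to the piecewise-linear kinks of the
    # trilinear-interpolated metric that blunt finite-difference gradients
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 2L * maxIter,
                                        reltol = 1e-10))
    if (opt2$value <= opt$value) opt <- opt2
    par <- opt$par / scales
    value <- opt$value
  }
  if (!converged)
    warning("registerAffine: optimizer stopped at iteration cap; ",
            "returning best transform found")
  affineTransform(.paramsToMatrix(par, type, center),
                  converged = converged, metric = value)
}

.targetGridOf <- function(targetGrid) {
  if (is(targetGrid, "ScalarVolume") || is(targetGrid, "DisplacementField") ||
      is(targetGrid, "DirectionField") || is(targetGrid, "TensorVolume"))
    list(dim = volDim(targetGrid), affine = volAffine(targetGrid))
  else if (is.list(targetGrid) && !is.null(targetGrid$dim) &&
           !is.null(targetGrid$affine))
    targetGrid
  else stop("targetGrid must be a grid-carrying object or list(dim, affine)")
}

#' Apply a world-to-world affine transform
#'
#' Resamples a volume or displacement field onto a target grid through the
#' inverse transform. Masks should use `interp = "nearest"` and then remain
#' exactly binary. Displacement-field vectors are additionally reoriented by
#' the rotation factor of the transform's polar decomposition
#' (finite-strain reorientation, see [reorientVectors()]).
#'
#' @param x a [ScalarVolume-class] or [DisplacementField-class].
#' @param transform an [AffineTransform-class] mapping x's world to the
#'   target world.
#' @param targetGrid grid-carrying object or `list(dim, affine)`.
#' @param interp "linear" or "nearest".
#' @return object of the same class as `x` on the target grid.
#' @export
applyTransform <- function(x, transform, targetGrid,
                           interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is(transform, "AffineTransform"))
  M <- transform@matrix
  if (abs(det(M[1:3, 1:3])) < 1e-12) stop("singular transform")
  tg <- .targetGridOf(targetGrid)
  w <- .gridWorld(tg$affine, tg$dim)
  srcWorld <- t(solve(M, t(cbind(w, 1))))[, 1:3]
  if (is(x, "ScalarVolume")) {
    vox <- .worldToVoxel(x@affine, srcWorld)
    out <- array(.interpAt(x@data, vox, interp), dim = tg$dim)
    if (interp == "nearest") out <- array(as.numeric(out != 0), dim = tg$dim)
    return(scalarVolume(out, tg$affine))
  }
  if (is(x, "DisplacementField")) {
    vox <- .worldToVoxel(x@affine, srcWorld)
    comp <- vapply(1:3, function(k)
      .interpTrilinear(x@vectors[, , , k], vox), numeric(nrow(vox)))
    supp <- .interpNearest(array(as.numeric(x@support), volDim(x)), vox) > 0
    R <- .polarRotation(M[1:3, 1:3])
    comp <- comp %*% t(R)
    comp[!supp, ] <- 0
    return(new("DisplacementField",
               vectors = array(comp, c(tg$dim, 3L)),
               affine = tg$affine, support = array(supp, tg$dim)))
  }
  stop("applyTransform supports ScalarVolume and DisplacementField inputs")
}

# crop helper: subvolume array + adjusted affine
.cropGrid <- function(affine, lo, hi) {
  a <- affine
  a[1:3, 4] <- .voxelToWorld(affine, matrix(lo - 1, 1, 3))
  a
}

#' Non-linear tumor-region registration (growth field estimation)
#'
#' Estimates the dense displacement field carrying the diagnostic-timepoint
#' tumor configuration onto the pre-operative one, on the pre-operative
#' grid. The similarity (mean-squared error) is driven only inside the
#' dilated union of the two tumor masks; the field is regularized by
#' Gaussian smoothing of both the update force and the accumulated field
#' (demons-style), run over a multi-resolution pyramid on a crop around the
#' tumor neighborhood. Returned vectors point from the diagnostic toward
#' the pre-operative configuration (growth), in world mm; the support mask
#' is the dilated mask union.
#'
#' @param diag,preop [ScalarVolume-class]s in the pre-operative
#'   space (intra-patient affine already applied), same grid.
#' @param diagMask,preopMask binary [ScalarVolume-class]s on that grid.
#' @param dilateMM dilation radius of the mask union, mm (default 5).
#' @param levels downsampling factors, coarse to fine (default c(4, 2, 1)).
#' @param iterations demons iterations per level.
#' @param sigmaFluidVox,sigmaDiffVox Gaussian sigmas (voxels at each level)
#'   for the force and field smoothing.
#' @param tol relative metric improvement below which a level stops early.
#' @return A [DisplacementField-class] on the pre-operative grid.
#' @export
registerGrowth <- function(diag, preop, diagMask, preopMask,
                           dilateMM = 5, levels = c(4L, 2L, 1L),
                           iterations = c(80L, 60L, 60L),
                           sigmaFluidVox = 1.3, sigmaDiffVox = 0.8,
                           tol = 1e-5) {
  stopifnot(is(diag, "ScalarVolume"), is(preop, "ScalarVolume"))
  for (m in list(diagMask, preopMask))
    if (sum(m@data != 0) == 0) stop("registerGrowth: empty tumor mask")
  if (!.sameGrid(diag@affine, volDim(diag), preop@affine, volDim(preop)) ||
      !.sameGrid(diagMask@affine, volDim(diagMask), preop@affine,
                 volDim(preop)) ||
      !.sameGrid(preopMask@affine, volDim(preopMask), preop@affine,
                 volDim(preop)))
    stop("registerGrowth: all inputs must share the pre-operative grid")
  vs <- voxelSize(preop)
  both <- diagMask@data != 0 & preopMask@data != 0
  union <- diagMask@data != 0 | preopMask@data != 0
  if (!any(both)) {
    warning("tumor masks do not overlap after affine alignment; ",
            "enlarging the registration support")
    dilateMM <- dilateMM * 2
  }
  support <- .dilate6(union, max(1L, ceiling(dilateMM / min(vs))))
  bb <- .maskBoundingBox(support, marginVox = 4L)
  sel <- list(seq(bb$lo[1], bb$hi[1]), seq(bb$lo[2], bb$hi[2]),
              seq(bb$lo[3], bb$hi[3]))
  F0 <- preop@data[sel[[1]], sel[[2]], sel[[3]]]
  M0 <- diag@data[sel[[1]], sel[[2]], sel[[3]]]
  S0 <- support[sel[[1]], sel[[2]], sel[[3]]]
  cropAff <- .cropGrid(preop@affine, bb$lo, bb$hi)
  cropDim <- dim(F0)
  u <- NULL # displacement in world mm, on the current level grid
  for (li in seq_along(levels)) {
    f <- levels[li]
    lvDim <- pmax(4L, as.integer(ceiling(cropDim / f)))
    lvAff <- cropAff
    lvAff[1:3, 1:3] <- cropAff[1:3, 1:3] * f
    sig <- if (f > 1) rep(f / 2, 3) else c(0, 0, 0)
    Fl <- .resampleArray(.gaussianSmooth(F0, sig), cropAff, lvAff, lvDim)
    Ml <- .gaussianSmooth(M0, sig)
    Sl <- .resampleArray(array(as.numeric(S0), cropDim), cropAff, lvAff,
                         lvDim, "nearest") > 0
    u <- if (is.null(u)) {
      array(0, c(lvDim, 3L))
    } else {
      upC <- vapply(1:3, function(k)
        .resampleArray(u[, , , k], prevAff, lvAff, lvDim),
        numeric(prod(lvDim)))
      array(upC, c(lvDim, 3L))
    }
    u <- .demonsLevel(Fl, Ml, cropAff, lvAff, lvDim, Sl, u,
                      iterations[min(li, length(iterations))],
                      sigmaFluidVox, sigmaDiffVox, tol)
    prevAff <- lvAff
  }
  # embed at full resolution into the preop grid; vectors = -u (growth)
  full <- array(0, c(volDim(preop), 3L))
  for (k in 1:3) {
    embedded <- array(0, volDim(preop))
    embedded[sel[[1]], sel[[2]], sel[[3]]] <- u[, , , k]
    full[, , , k] <- -embedded * as.numeric(support)
  }
  new("DisplacementField", vectors = full, affine = preop@affine,
      support = support)
}

# One pyramid level of Gaussian-regularized demons. F on the level grid,
# M on the crop grid (sampled through the composed displacement), u in mm.
.demonsLevel <- function(Fl, M0, cropAff, lvAff, lvDim, Sl, u, iters,
                         sigmaFluid, sigmaDiff, tol) {
  vs <- sqrt(colSums(lvAff[1:3, 1:3]^2))
  w <- .gridWorld(lvAff, lvDim)
  kappa2 <- mean(vs)^2
  grad <- list(.centralDiff(M0, cropAff, 1), .centralDiff(M0, cropAff, 2),
               .centralDiff(M0, cropAff, 3))
  best <- Inf
  stall <- 0L
  n <- prod(lvDim)
  sMask <- as.vector(Sl)
  for (it in seq_len(iters)) {
    pos <- w + matrix(u, n, 3)
    vox <- .worldToVoxel(cropAff, pos)
    mv <- .interpTrilinear(M0, vox)
    gx <- .interpTrilinear(grad[[1]], vox)
    gy <- .interpTrilinear(grad[[2]], vox)
    gz <- .interpTrilinear(grad[[3]], vox)
    diffv <- as.vector(Fl) - mv
    g2 <- gx^2 + gy^2 + gz^2
    den <- g2 + diffv^2 / kappa2
    fac <- ifelse(den > 1e-12, diffv / den, 0) * sMask
    step <- cbind(fac * gx, fac * gy, fac * gz)
    # cap the per-iteration step at one voxel
    sn <- .rowNorms(step)
    cap <- mean(vs)
    over <- sn > cap
    step[over, ] <- step[over, , drop = FALSE] * (cap / sn[over])
    du <- array(step, c(lvDim, 3L))
    for (k in 1:3) du[, , , k] <- .gaussianSmooth(du[, , , k], sigmaFluid)
    u <- u + du
    for (k in 1:3) u[, , , k] <- .gaussianSmooth(u[, , , k], sigmaDiff)
    mse <- mean(diffv[sMask]^2)
    if (mse < best * (1 - tol)) {
      best <- mse
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 10L) break
    }
  }
  u
}

# central difference gradient in world units (per mm) along world axis k,
# assuming an axis-aligned grid
.centralDiff <- function(arr, affine, k) {
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  d <- c(0L, 0L, 0L)
  d[k] <- 1L
  (.shiftArray(arr, -d, 0) - .shiftArray(arr, d, 0)) / (2 * vs[k])
}
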