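# Synthetic two-timepoint glioma phantoms with known growth directions.
#
# The growth model is a radial expansion of a spherical tumor whose
# direction at each point is coupled to the local white-matter fiber
# orientation. The coupling is a deterministic measure transport: the folded
# cosine t = |r_hat . v| between the radial direction and the fiber axis is
# pushed through the folded von Mises-Fisher CDF map
#     t' = asinh(t * sinh(kappa)) / kappa,
# so that over a uniformly sampled tumor surface the growth direction has
# exactly the folded-vMF(kappa) law around the fiber axis: kappa = 0 leaves
# growth purely radial (folded angles follow the uniform-sphere law
# CDF(theta) = 1 - cos theta), kappa -> Inf makes growth fiber-parallel.
# Keeping the transport deterministic makes the truth field smooth, hence
# recoverable by a regularized registration, while preserving the marginal
# direction law that the validation statistics test.

#' Create a phantom cohort specification
#'
#' Defaults describe a fiber-aligned growth condition scaled to a desk-size
#' phantom: a 96 mm field of view holding a spherical brain with fixed
#' internal anatomy and smooth parenchymal texture, an 8 mm tumor, and
#' growth concentrated along the local fiber direction
#' (`gainParallel = 1.54`, `gainPerpendicular = 1.1`): together with the
#' `alignmentKappa = 6` coupling these produce a generated tumor volume
#' ratio of 2.5x, the mean pre-operative / diagnostic ratio reported for
#' clinical cohorts. The
#' diagnostic (t1) grid is deliberately coarser along z than the
#' pre-operative (t2) grid to exercise the resampling path.
#'
#' @param gridShape t2 grid, voxels per axis.
#' @param voxelSizeT1,voxelSizeT2 mm per axis.
#' @param fiberGeometry "uniform", "circular" or "fanning".
#' @param fiberParams list of geometry parameters; see
#'   [PhantomSpec-class].
#' @param tumorCenter world mm (origin = grid center).
#' @param tumorRadiusT1 mm.
#' @param gainParallel,gainPerpendicular radial expansion factors.
#' @param alignmentKappa fiber-coupling concentration (0 = isotropic).
#' @param noiseSigma intensity noise SD.
#' @param tissueContrast named background/tumor/necrosis intensities.
#' @param necroticFraction central non-enhancing core radius fraction.
#' @param brainRadius mm.
#' @param atlasVoxelSize tensor atlas voxel size, mm.
#' @param allowShrink permit gains below 1.
#' @param seed base RNG seed.
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 64L),
                        voxelSizeT1 = c(1.5, 1.5, 3.0),
                        voxelSizeT2 = c(1.5, 1.5, 1.5),
                        fiberGeometry = "uniform",
                        fiberParams = list(direction = c(1, 0, 0)),
                        tumorCenter = c(0, 0, 0),
                        tumorRadiusT1 = 8,
                        gainParallel = 1.54,
                        gainPerpendicular = 1.1,
                        alignmentKappa = 6,
                        noiseSigma = 10,
                        tissueContrast = c(background = 100, tumor = 300,
                                           necrosis = 150),
                        necroticFraction = 0,
                        brainRadius = 40,
                        atlasVoxelSize = c(1.75, 1.75, 2.25),
                        allowShrink = FALSE,
                        seed = 1L) {
  spec <- new("PhantomSpec",
              gridShape = as.integer(gridShape),
              voxelSizeT1 = rep(as.numeric(voxelSizeT1), length.out = 3),
              voxelSizeT2 = rep(as.numeric(voxelSizeT2), length.out = 3),
              fiberGeometry = fiberGeometry, fiberParams = fiberParams,
              tumorCenter = as.numeric(tumorCenter),
              tumorRadiusT1 = tumorRadiusT1,
              gainParallel = gainParallel,
              gainPerpendicular = gainPerpendicular,
              alignmentKappa = alignmentKappa, noiseSigma = noiseSigma,
              tissueContrast = tissueContrast,
              necroticFraction = necroticFraction,
              brainRadius = brainRadius,
              atlasVoxelSize = rep(as.numeric(atlasVoxelSize),
                                   length.out = 3),
              allowShrink = allowShrink, seed = as.integer(seed))
  .checkFiberParams(spec)
  spec
}

.checkFiberParams <- function(spec) {
  p <- spec@fiberParams
  if (spec@fiberGeometry == "uniform") {
    if (is.null(p$direction) || length(p$direction) != 3 ||
        sqrt(sum(p$direction^2)) < 1e-12)
      stop("uniform fiber geometry needs a non-zero 'direction' 3-vector")
  } else if (spec@fiberGeometry == "circular") {
    ax <- if (is.null(p$axis)) c(0, 0, 1) else p$axis
    if (length(ax) != 3 || sqrt(sum(ax^2)) < 1e-12)
      stop("circular fiber geometry needs a non-zero 'axis' 3-vector")
  } else if (spec@fiberGeometry == "fanning") {
    if (is.null(p$direction) || sqrt(sum(p$direction^2)) < 1e-12)
      stop("fanning fiber geometry needs a non-zero 'direction' 3-vector")
  }
  invisible(TRUE)
}

# world extent of the t2 grid (mm per axis)
.fovMM <- function(spec) spec@gridShape * spec@voxelSizeT2

.t2Affine <- function(spec) .centeredAffine(spec@gridShape, spec@voxelSizeT2)

.t1Dim <- function(spec) {
  pmax(16L, as.integer(round(.fovMM(spec) / spec@voxelSizeT1)))
}

.t1Affine <- function(spec) .centeredAffine(.t1Dim(spec), spec@voxelSizeT1)

# Unit fiber direction at world points (n x 3). Sign is arbitrary.
.fiberDirection <- function(spec, pts) {
  pts <- matrix(pts, ncol = 3)
  p <- spec@fiberParams
  if (spec@fiberGeometry == "uniform") {
    d <- p$direction / sqrt(sum(p$direction^2))
    matrix(d, nrow(pts), 3, byrow = TRUE)
  } else if (spec@fiberGeometry == "circular") {
    ax <- if (is.null(p$axis)) c(0, 0, 1) else p$axis
    ax <- ax / sqrt(sum(ax^2))
    ctr <- if (is.null(p$center)) c(0, 0, 0) else p$center
    rel <- pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)
    # tangent of the circle about the axis: axis x radial offset
    tg <- cbind(ax[2] * rel[, 3] - ax[3] * rel[, 2],
                ax[3] * rel[, 1] - ax[1] * rel[, 3],
                ax[1] * rel[, 2] - ax[2] * rel[, 1])
    n <- .rowNorms(tg)
    deg <- n < 1e-9
    if (any(deg)) {
      # on the axis the tangent is undefined; pick a fixed perpendicular
      perp <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * ax) * ax
      perp <- perp / sqrt(sum(perp^2))
      tg[deg, ] <- matrix(perp, sum(deg), 3, byrow = TRUE)
    }
    .normalizeRows(tg)
  } else { # fanning: base direction rotated about an axis, linearly in
    # position along that axis's first perpendicular
    d0 <- p$direction / sqrt(sum(p$direction^2))
    ax <- if (is.null(p$axis)) c(0, 0, 1) else p$axis
    ax <- ax / sqrt(sum(ax^2))
    rate <- if (is.null(p$rate)) 0.02 else p$rate # rad/mm
    ctr <- if (is.null(p$center)) c(0, 0, 0) else p$center
    e1 <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * ax) * ax
    e1 <- e1 / sqrt(sum(e1^2))
    s <- (pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% e1
    ang <- rate * as.numeric(s)
    # Rodrigues rotation of d0 about ax by ang (vectorized over points)
    ca <- cos(ang); sa <- sin(ang)
    k <- ax
    kxd <- c(k[2] * d0[3] - k[3] * d0[2],
             k[3] * d0[1] - k[1] * d0[3],
             k[1] * d0[2] - k[2] * d0[1])
    kd <- sum(k * d0)
    outer(ca, d0) + outer(sa, kxd) + outer((1 - ca) * kd, k)
  }
}

# Stable folded-vMF CDF transport of t = |cos| in [0,1].
.vmfFoldTransport <- function(t, kappa) {
  if (kappa <= 0) return(t)
  # t' = asinh(t * sinh(kappa)) / kappa, computed in log space for large kappa
  logsinh <- function(x) x + log1p(-exp(-2 * x)) - log(2)
  ls <- logsinh(kappa)
  y <- log(pmax(t, 1e-300)) + ls      # log(t * sinh(kappa))
  # asinh(e^y) = log(e^y + sqrt(e^{2y} + 1))
  as <- ifelse(y > 20, y + log(2), asinh(exp(pmin(y, 20))))
  pmin(as / kappa, 1)
}

# Growth displacement (world mm) of the analytic model at world points.
# Returns n x 3. Zero outside the bounded support radius.
.truthDisplacement <- function(spec, pts) {
  pts <- matrix(pts, ncol = 3)
  ctr <- spec@tumorCenter
  rel <- pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)
  rho <- .rowNorms(rel)
  R <- spec@tumorRadiusT1
  gmax <- max(spec@gainParallel, spec@gainPerpendicular)
  taper <- 5
  rOut <- R * gmax + taper
  u <- matrix(0, nrow(pts), 3)
  act <- rho > 1e-9 & rho < rOut
  if (!any(act)) return(u)
  rhat <- rel[act, , drop = FALSE] / rho[act]
  v <- .fiberDirection(spec, pts[act, , drop = FALSE])
  tdot <- rowSums(rhat * v)
  s <- ifelse(tdot >= 0, 1, -1)
  tf <- abs(tdot)
  tf2 <- .vmfFoldTransport(tf, spec@alignmentKappa)
  # growth direction: same fiber-orthogonal azimuth as r_hat, folded cosine tf2
  w <- rhat - tdot * v
  wn <- .rowNorms(w)
  what <- w
  ok <- wn > 1e-9
  what[ok, ] <- w[ok, , drop = FALSE] / wn[ok]
  what[!ok, ] <- 0
  d <- (s * tf2) * v + sqrt(pmax(0, 1 - tf2^2)) * what
  # direction-dependent gain and surface magnitude
  g <- spec@gainPerpendicular +
    (spec@gainParallel - spec@gainPerpendicular) * tf2^2
  mSurf <- R * (g - 1)
  rhoAct <- rho[act]
  wProf <- ifelse(rhoAct <= R, rhoAct / R,
                  pmax(0, (rOut - rhoAct) / (rOut - R)))
  u[act, ] <- (wProf * mSurf) * d
  u
}

# Inverse of the growth map phi(y) = y + u(y) by damped Picard iteration.
# The vMF direction transport is steep where the radial direction crosses
# the fiber equator, so after a few undamped steps the iteration switches to
# a small damping factor that keeps it contractive there. Only points inside
# the bounded support radius need iterating.
.invertGrowth <- function(spec, pts, tolMM = 0.01, maxIter = 300L) {
  gmax <- max(spec@gainParallel, spec@gainPerpendicular)
  rOut <- spec@tumorRadiusT1 * gmax + 5
  rel <- pts - matrix(spec@tumorCenter, nrow(pts), 3, byrow = TRUE)
  act <- .rowNorms(rel) < rOut
  y <- pts
  if (!any(act)) return(y)
  p <- pts[act, , drop = FALSE]
  ya <- p
  for (i in 1:6) ya <- p - .truthDisplacement(spec, ya)
  alpha <- 0.12
  for (i in seq_len(maxIter)) {
    resid <- p - ya - .truthDisplacement(spec, ya)
    ya <- ya + alpha * resid
    if (max(abs(resid)) < tolMM) break
  }
  y[act, ] <- ya
  y
}

# Fixed internal anatomy (ventricle-like CSF spaces and one deep-gray
# nucleus), shared by every patient and the template. Without it the
# spherical brain would be rotation-invariant and affine normalization to
# the template would be ill-posed; it also deforms with the growth map
# (evaluated at material coordinates), like peritumoral anatomy does.
.anatomyLevels <- c(ventricle = 40, nucleus = 140)

.paintAnatomy <- function(img, material) {
  inEll <- function(ctr, semi) {
    rel <- sweep(material, 2, ctr)
    rowSums(sweep(rel, 2, semi, "/")^2) <= 1
  }
  img[inEll(c(-9, 14, 4), c(5, 13, 7))] <- .anatomyLevels[["ventricle"]]
  img[inEll(c(11, 14, 2), c(7, 10, 9))] <- .anatomyLevels[["ventricle"]]
  img[inEll(c(6, -16, -8), c(7, 7, 7))] <- .anatomyLevels[["nucleus"]]
  img
}

# Smooth deterministic parenchymal texture (two harmonic octaves, ~40 and
# ~25 mm wavelengths), a stand-in for gyral/vascular intensity structure.
# It is a function of material coordinates, so it deforms with tumor growth
# exactly as peritumoral tissue does; without it the displacement field
# would only be observable along tissue-boundary normals (aperture problem)
# and tangential growth components could never be recovered by any
# intensity-driven registration.
.parenchymaTexture <- function(material) {
  x <- material[, 1]; y <- material[, 2]; z <- material[, 3]
  22 * sin(x / 6.9 + 1.1) * sin(y / 8.3 + 2.7) * sin(z / 5.9 + 0.5) +
    12 * sin(x / 4.1 + 4.2) * sin(y / 4.9 + 1.9) * sin(z / 4.3 + 3.3)
}

# Classify tissue at material (t1-time) points.
.tissueImage <- function(spec, material, current = material,
                         withTumor = TRUE) {
  lv <- spec@tissueContrast
  brain <- .rowNorms(current) <= spec@brainRadius
  img <- ifelse(brain, lv[["background"]] + .parenchymaTexture(material), 0)
  img <- ifelse(brain, .paintAnatomy(img, material), img)
  if (withTumor) {
    rel <- material - matrix(spec@tumorCenter, nrow(material), 3,
                             byrow = TRUE)
    rho <- .rowNorms(rel)
    R <- spec@tumorRadiusT1
    img[rho <= R] <- lv[["tumor"]]
    if (spec@necroticFraction > 0)
      img[rho <= spec@necroticFraction * R] <- lv[["necrosis"]]
  }
  img
}

.tumorMask <- function(spec, material) {
  rel <- material - matrix(spec@tumorCenter, nrow(material), 3, byrow = TRUE)
  as.numeric(.rowNorms(rel) <= spec@tumorRadiusT1)
}

# Uniform points on the t1 tumor surface plus their growth data.
.surfaceSample <- function(spec, n) {
  z <- matrix(stats::rnorm(3 * n), n, 3)
  rhat <- .normalizeRows(z)
  pts <- matrix(spec@tumorCenter, n, 3, byrow = TRUE) +
    spec@tumorRadiusT1 * rhat
  u <- .truthDisplacement(spec, pts)
  v <- .fiberDirection(spec, pts)
  list(points = pts, displacement = u, fiber = v)
}

#' Generate a synthetic white-matter tensor atlas
#'
#' Builds a diffusion-tensor volume on the atlas grid whose principal
#' eigenvector equals the analytic fiber direction of the configured geometry at
#' every in-brain voxel (anisotropic, FA about 0.46) and which is isotropic
#' (FA 0) outside the brain. Tensors are symmetric positive-definite.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [TensorVolume-class] with attribute `wmMask` (logical array of
#'   the designated white-matter region).
#' @export
makeFiberAtlas <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  .checkFiberParams(spec)
  dm <- pmax(16L, as.integer(ceiling(.fovMM(spec) / spec@atlasVoxelSize)))
  aff <- .centeredAffine(dm, spec@atlasVoxelSize)
  pts <- .gridWorld(aff, dm)
  brain <- .rowNorms(pts) <= spec@brainRadius
  v <- .fiberDirection(spec, pts)
  lambda1 <- 1.0; lambdaPerp <- 0.45; lambdaIso <- 0.7
  n <- nrow(pts)
  # D = lambdaPerp I + (lambda1 - lambdaPerp) v v^T inside, lambdaIso I outside
  dl <- lambda1 - lambdaPerp
  tensor <- matrix(0, n, 6)
  tensor[, 1] <- ifelse(brain, lambdaPerp + dl * v[, 1]^2, lambdaIso)  # Dxx
  tensor[, 2] <- ifelse(brain, dl * v[, 1] * v[, 2], 0)                # Dxy
  tensor[, 3] <- ifelse(brain, lambdaPerp + dl * v[, 2]^2, lambdaIso)  # Dyy
  tensor[, 4] <- ifelse(brain, dl * v[, 1] * v[, 3], 0)                # Dxz
  tensor[, 5] <- ifelse(brain, dl * v[, 2] * v[, 3], 0)                # Dyz
  tensor[, 6] <- ifelse(brain, lambdaPerp + dl * v[, 3]^2, lambdaIso)  # Dzz
  out <- new("TensorVolume", data = array(tensor, c(dm, 6L)), affine = aff)
  attr(out, "wmMask") <- array(brain, dm)
  out
}

#' Generate one synthetic two-timepoint patient
#'
#' The diagnostic (t1) image holds a spherical contrast-enhancing tumor
#' (optionally with a central non-enhancing core) inside a spherical brain;
#' the pre-operative (t2) image holds the tumor expanded by the analytic
#' growth map. Images are piecewise-constant tissue levels plus additive
#' Gaussian noise, on (possibly different) t1/t2 grids. The exact growth
#' displacement is returned on the t2 grid together with the expected folded
#' angle of growth against the fibers.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed RNG seed for this patient (noise and the truth-angle
#'   Monte-Carlo estimate).
#' @param id patient identifier.
#' @return A [PhantomPatient-class].
#' @export
makePatient <- function(spec, seed = spec@seed, id = "phantom") {
  stopifnot(is(spec, "PhantomSpec"))
  .checkFiberParams(spec)
  gmax <- max(spec@gainParallel, spec@gainPerpendicular)
  reach <- sqrt(sum(spec@tumorCenter^2)) + spec@tumorRadiusT1 * gmax
  if (any(reach > .fovMM(spec) / 2 - 2))
    stop("tumor exceeds grid bounds after growth; shrink it or move it inward")
  .withSeed(seed, {
    affT1 <- .t1Affine(spec); dmT1 <- .t1Dim(spec)
    affT2 <- .t2Affine(spec); dmT2 <- spec@gridShape
    ptsT1 <- .gridWorld(affT1, dmT1)
    ptsT2 <- .gridWorld(affT2, dmT2)
    yT2 <- .invertGrowth(spec, ptsT2) # material points of the t2 voxels
    img1 <- .tissueImage(spec, ptsT1)
    img2 <- .tissueImage(spec, yT2, current = ptsT2)
    if (spec@noiseSigma > 0) {
      img1 <- img1 + stats::rnorm(length(img1), 0, spec@noiseSigma)
      img2 <- img2 + stats::rnorm(length(img2), 0, spec@noiseSigma)
    }
    m1 <- .tumorMask(spec, ptsT1)
    m2 <- .tumorMask(spec, yT2)
    # truth field on the t2 grid: growth displacement arriving at each voxel
    u <- ptsT2 - yT2
    supp <- .rowNorms(u) > 1e-9
    vec <- array(u * supp, c(dmT2, 3L))
    field <- new("DisplacementField", vectors = vec, affine = affT2,
                 support = array(supp, dmT2))
    ss <- .surfaceSample(spec, 20000L)
    mag <- .rowNorms(ss$displacement)
    ok <- mag > 1e-9
    ang <- foldAngle(ss$displacement[ok, , drop = FALSE],
                     ss$fiber[ok, , drop = FALSE])
    meanAngle <- if (any(ok)) mean(ang) else NA_real_
    new("PhantomPatient", id = id,
        imageT1 = scalarVolume(array(img1, dmT1), affT1),
        imageT2 = scalarVolume(array(img2, dmT2), affT2),
        maskT1 = scalarVolume(array(m1, dmT1), affT1),
        maskT2 = scalarVolume(array(m2, dmT2), affT2),
        truthField = field, truthMeanAngle = meanAngle)
  })
}

#' Generate a phantom cohort with a shared template and tensor atlas
#'
#' Per-patient seeds derive deterministically from the master seed; tumor
#' centers are jittered uniformly within +/- `jitterMM` per axis (kept inside
#' the brain). A noise-free tumor-free brain volume on the t2 grid is
#' emitted as the normalization template.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPatients number of patients (>= 1).
#' @param seed master seed.
#' @param jitterMM tumor-center jitter half-width, mm.
#' @return list with elements `patients` (list of
#'   [PhantomPatient-class]), `atlas` ([TensorVolume-class]),
#'   `template` ([ScalarVolume-class]) and `specs` (per-patient specs).
#' @export
makeCohort <- function(spec, nPatients, seed = spec@seed, jitterMM = 8) {
  stopifnot(is(spec, "PhantomSpec"), nPatients >= 1)
  patients <- vector("list", nPatients)
  specs <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    si <- .childSeed(seed, i)
    ctr <- .withSeed(.childSeed(si, 7919L),
                     stats::runif(3, -jitterMM, jitterMM))
    # keep the grown tumor inside the brain
    gmax <- max(spec@gainParallel, spec@gainPerpendicular)
    maxOff <- spec@brainRadius - spec@tumorRadiusT1 * gmax - 6
    if (sqrt(sum(ctr^2)) > maxOff) ctr <- ctr * maxOff / sqrt(sum(ctr^2))
    sp <- spec
    sp@tumorCenter <- ctr
    specs[[i]] <- sp
    patients[[i]] <- makePatient(sp, seed = si, id = sprintf("P%02d", i))
  }
  ptsT2 <- .gridWorld(.t2Affine(spec), spec@gridShape)
  tmpl <- .tissueImage(spec, ptsT2, withTumor = FALSE)
  list(patients = patients,
       atlas = makeFiberAtlas(spec),
       template = scalarVolume(array(tmpl, spec@gridShape), .t2Affine(spec)),
       specs = specs)
}
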