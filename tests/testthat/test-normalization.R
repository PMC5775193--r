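# Template normalization, finite-strain reorientation, field down-sampling
# and tensor eigen-analysis.

test_that("template registration recovers identity and translation", {
  spec <- smallSpec(noiseSigma = 3)
  co <- makeCohort(spec, 1, seed = 61)
  p <- co$patients[[1]]
  tr <- suppressWarnings(registerToTemplate(co$template, co$template, type = "rigid"))
  expect_lt(max(abs(tr@matrix - diag(4))), 0.05)
  a2 <- co$template@affine
  a2[1:3, 4] <- a2[1:3, 4] + c(3, 1, -2)
  moved <- scalarVolume(volData(co$template), a2)
  tr2 <- suppressWarnings(registerToTemplate(moved, co$template, type = "rigid"))
  expect_lt(max(abs(tr2@matrix[1:3, 4] - c(-3, -1, 2))), 0.5)
})

test_that("finite-strain reorientation matches the polar-decomposition oracle", {
  spec <- smallSpec()
  p <- makePatient(spec, seed = 71)
  fld <- p@truthField
  supp <- as.vector(fieldSupport(fld))
  u0 <- matrix(volData(fld), prod(volDim(fld)), 3)

  # rigid: vectors rotated by R itself, norms preserved
  set.seed(3)
  R <- randomRotation()
  M <- diag(4); M[1:3, 1:3] <- R
  outR <- reorientVectors(fld, affineTransform(M))
  uR <- matrix(volData(outR), nrow(u0), 3)
  expect_lt(max(abs(uR[supp, ] - (u0 %*% t(R))[supp, ])), 1e-9)
  relNorm <- abs(sqrt(rowSums(uR[supp, ]^2)) / sqrt(rowSums(u0[supp, ]^2)) - 1)
  expect_lt(max(relNorm), 1e-6)

  # pure anisotropic scaling: rotation factor is the identity
  S <- diag(4); diag(S)[1:3] <- c(2, 1, 1)
  outS <- reorientVectors(fld, affineTransform(S))
  expect_lt(max(abs(matrix(volData(outS), nrow(u0), 3)[supp, ] -
                      u0[supp, ])), 1e-9)

  # rotation . scaling composite: direction change equals the rotation
  MC <- diag(4); MC[1:3, 1:3] <- R %*% diag(c(2, 1, 0.5))
  outC <- reorientVectors(fld, affineTransform(MC))
  uC <- matrix(volData(outC), nrow(u0), 3)
  expect_lt(max(abs(uC[supp, ] - (u0 %*% t(R))[supp, ])), 1e-9)
})

test_that("reorientation agrees with an independent oracle on random affines", {
  set.seed(17)
  vec <- array(0, c(3, 3, 3, 3))
  vec[2, 2, 2, ] <- c(1, 2, -0.5)
  fld <- displacementField(vec, diag(4))
  for (i in 1:200) {
    A <- matrix(rnorm(9), 3, 3)
    if (abs(det(A)) < 0.05) next
    M <- diag(4); M[1:3, 1:3] <- A
    got <- reorientVectors(fld, affineTransform(M))@vectors[2, 2, 2, ]
    want <- as.vector(polarOracle(A) %*% c(1, 2, -0.5))
    expect_lt(max(abs(got - want)) / sqrt(sum(want^2)), 1e-6)
  }
})

test_that("field down-sampling is exact for constant and linear fields", {
  dm <- c(24L, 24L, 24L)
  aff <- centeredAffineOf(dm, c(2, 2, 2))
  w <- gridWorldOf(scalarVolume(array(0, dm), aff))
  atlasDim <- c(14L, 14L, 12L)
  atlasAff <- centeredAffineOf(atlasDim, c(3, 3, 3.5))
  # constant field
  vec <- array(0, c(dm, 3L)); vec[, , , 1] <- 2; vec[, , , 2] <- -1
  fld <- displacementField(vec, aff, support = array(TRUE, dm))
  out <- downsampleField(fld, list(dim = atlasDim, affine = atlasAff))
  supp <- as.vector(fieldSupport(out))
  expect_true(any(supp))
  um <- matrix(volData(out), prod(atlasDim), 3)
  expect_lt(max(abs(sweep(um[supp, ], 2, c(2, -1, 0)))), 1e-9)
  # linear-in-position field, exact at atlas points inside the source grid
  lin <- array(0, c(dm, 3L))
  lin[, , , 1] <- array(0.1 * w[, 1] + 0.05 * w[, 3], dm)
  lin[, , , 2] <- array(-0.2 * w[, 2], dm)
  lin[, , , 3] <- array(0.03 * w[, 1], dm)
  fldL <- displacementField(lin, aff, support = array(TRUE, dm))
  outL <- downsampleField(fldL, list(dim = atlasDim, affine = atlasAff))
  wa <- t(atlasAff[1:3, 1:3] %*%
            t(gbmGrowth:::.gridVoxels(atlasDim))) +
    matrix(atlasAff[1:3, 4], prod(atlasDim), 3, byrow = TRUE)
  expect_true(any(fieldSupport(outL)))
  sel <- as.vector(fieldSupport(outL)) &
    abs(wa[, 1]) < 20 & abs(wa[, 2]) < 20 & abs(wa[, 3]) < 20
  uml <- matrix(volData(outL), prod(atlasDim), 3)
  want <- cbind(0.1 * wa[, 1] + 0.05 * wa[, 3], -0.2 * wa[, 2],
                0.03 * wa[, 1])
  expect_lt(max(abs(uml[sel, ] - want[sel, ])), 1e-9)
  # disjoint grids are rejected
  farAff <- atlasAff; farAff[1:3, 4] <- farAff[1:3, 4] + 500
  expect_error(downsampleField(fld, list(dim = atlasDim, affine = farAff)),
               "overlap")
})

test_that("principal directions and FA follow the closed forms", {
  dm <- c(2L, 2L, 2L)
  mk <- function(rows) {
    a <- array(0, c(dm, 6L))
    for (i in seq_len(nrow(rows)))
      a[i, 1, 1, ] <- rows[i, ]
    new("TensorVolume", data = a, affine = diag(4))
  }
  # rows: Dxx Dxy Dyy Dxz Dyz Dzz
  tv <- mk(rbind(c(1, 0, 1, 0, 0, 1),      # isotropic -> FA 0, invalid
                 c(3, 0, 1, 0, 0, 1)))     # principal (1,0,0), FA sqrt(4/11)
  dirs <- principalDirections(tv, faMin = 0.2)
  expect_false(validMask(dirs)[1, 1, 1])
  expect_equal(faValues(dirs)[1, 1, 1], 0)
  expect_true(validMask(dirs)[2, 1, 1])
  expect_equal(faValues(dirs)[2, 1, 1], sqrt(4 / 11), tolerance = 1e-12)
  expect_lt(foldAngle(dirs@vectors[2, 1, 1, ], c(1, 0, 0)), 1e-6)
  # degenerate leading pair -> invalid; non-finite -> invalid, not fatal
  tv2 <- mk(rbind(c(2, 0, 2, 0, 0, 1),
                  c(NA, 0, 1, 0, 0, 1)))
  dirs2 <- principalDirections(tv2, faMin = 0.1)
  expect_false(validMask(dirs2)[1, 1, 1])
  expect_false(validMask(dirs2)[2, 1, 1])
  # scale invariance: T and cT give identical directions and FA
  spec <- smallSpec(fiberGeometry = "fanning",
                    fiberParams = list(direction = c(1, 0, 1),
                                       axis = c(0, 1, 0), rate = 0.015))
  atlas <- makeFiberAtlas(spec)
  scaled <- new("TensorVolume", data = volData(atlas) * 3.7,
                affine = volAffine(atlas))
  d1 <- principalDirections(atlas)
  d2 <- principalDirections(scaled)
  expect_identical(validMask(d1), validMask(d2))
  expect_lt(max(abs(faValues(d1) - faValues(d2)), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(volData(d1) - volData(d2))), 1e-9)
})
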