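# Synthetic cohort generator: fiber atlas construction, growth model
# ground truth, and determinism.

test_that("fiber atlas principal eigenvectors match the analytic geometry", {
  # uniform geometry: eigenvector (+-1, 0, 0) at every white-matter voxel
  spec <- smallSpec(fiberGeometry = "uniform",
                    fiberParams = list(direction = c(1, 0, 0)))
  atlas <- makeFiberAtlas(spec)
  dirs <- principalDirections(atlas, faMin = 0.3)
  wm <- attr(atlas, "wmMask")
  expect_true(all(validMask(dirs)[wm]))
  expect_false(any(validMask(dirs)[!wm]))
  v <- matrix(volData(dirs), prod(volDim(dirs)), 3)[as.vector(wm), ]
  expect_lt(max(foldAngle(v, c(1, 0, 0))), 1e-4)

  # FA contrast: anisotropic inside the designated WM, near-isotropic outside
  fa <- faValues(dirs)
  expect_gt(min(fa[wm]), 0.3)
  expect_lt(max(fa[!wm]), 0.1)

  # circular geometry: at offset (r, 0, 0) from center the tangent is
  # (0, +-1, 0)
  specC <- smallSpec(fiberGeometry = "circular",
                     fiberParams = list(center = c(0, 0, 0),
                                        axis = c(0, 0, 1)))
  atlasC <- makeFiberAtlas(specC)
  dirsC <- principalDirections(atlasC, faMin = 0.3)
  w <- gridWorldOf(atlasC)
  onX <- which(abs(w[, 2]) < 0.6 & abs(w[, 3]) < 0.8 & w[, 1] > 10 &
                 as.vector(validMask(dirsC)))
  vC <- matrix(volData(dirsC), nrow(w), 3)[onX, , drop = FALSE]
  expect_lt(max(foldAngle(vC, c(0, 1, 0))), 5)
})

test_that("emitted tensors are SPD and their eigenvectors recover the stored direction", {
  for (geom in c("uniform", "circular", "fanning")) {
    spec <- smallSpec(fiberGeometry = geom,
                      fiberParams = switch(geom,
                        uniform = list(direction = c(1, 2, -1)),
                        circular = list(axis = c(0, 1, 1)),
                        fanning = list(direction = c(0, 1, 0),
                                       axis = c(0, 0, 1), rate = 0.02)))
    atlas <- makeFiberAtlas(spec)
    wm <- which(attr(atlas, "wmMask"))
    tm <- matrix(volData(atlas), prod(volDim(atlas)), 6)
    truth <- gbmGrowth:::.fiberDirection(spec, gridWorldOf(atlas))
    set.seed(1)
    for (i in sample(wm, 50)) {
      D <- matrix(c(tm[i, 1], tm[i, 2], tm[i, 4],
                    tm[i, 2], tm[i, 3], tm[i, 5],
                    tm[i, 4], tm[i, 5], tm[i, 6]), 3, 3)
      e <- eigen(D, symmetric = TRUE)
      expect_gt(min(e$values), 0)                      # positive definite
      expect_lt(foldAngle(e$vectors[, 1], truth[i, ]), 0.1)
    }
  }
  expect_error(makeFiberAtlas(smallSpec(fiberParams = list(direction = c(0, 0, 0)))),
               "direction")
})

test_that("no-growth phantom has zero truth field and matching images", {
  spec <- smallSpec(gainParallel = 1, gainPerpendicular = 1,
                    alignmentKappa = 0, noiseSigma = 0)
  p <- makePatient(spec, seed = 1)
  expect_equal(max(abs(volData(p@truthField))), 0)
  expect_false(any(fieldSupport(p@truthField)))
  # same voxel grids here, so t2 equals t1 exactly
  expect_equal(volData(p@imageT2), volData(p@imageT1))
})

test_that("strong fiber coupling gives near-parallel growth truth", {
  spec <- smallSpec(alignmentKappa = 400, gainParallel = 1.5,
                    gainPerpendicular = 1.0)
  p <- makePatient(spec, seed = 2)
  expect_lt(p@truthMeanAngle, 5)
})

test_that("kappa = 0 isotropic growth follows the uniform-sphere angle law", {
  spec <- smallSpec(alignmentKappa = 0, gainParallel = 1.4,
                    gainPerpendicular = 1.4)
  n <- 1e5
  ss <- gbmGrowth:::.withSeed(3, gbmGrowth:::.surfaceSample(spec, n))
  ang <- foldAngle(ss$displacement, ss$fiber)
  p20 <- 1 - cos(20 * pi / 180)
  p70 <- cos(70 * pi / 180)
  expect_lt(abs(mean(ang < 20) - p20), 3 * sqrt(p20 * (1 - p20) / n))
  expect_lt(abs(mean(ang > 70) - p70), 3 * sqrt(p70 * (1 - p70) / n))
})

test_that("truth field is consistent with the t2 mask (Dice >= 0.95)", {
  spec <- smallSpec(voxelSizeT1 = c(1.5, 1.5, 1.5),
                    voxelSizeT2 = c(1.5, 1.5, 1.5),
                    gridShape = c(64L, 64L, 64L))
  p <- makePatient(spec, seed = 9)
  w <- gridWorldOf(p@maskT2)
  u <- matrix(volData(p@truthField), nrow(w), 3)
  inv <- solve(volAffine(p@maskT1))
  vox <- t(inv[1:3, 1:3] %*% t(w - u)) +
    matrix(inv[1:3, 4], nrow(w), 3, byrow = TRUE)
  # trilinear mask warp with 0.5 threshold for subvoxel boundary accuracy
  warped <- gbmGrowth:::.interpTrilinear(volData(p@maskT1), vox) >= 0.5
  m2 <- volData(p@maskT2) != 0
  dice <- 2 * sum(warped & m2) / (sum(warped) + sum(m2))
  expect_gte(dice, 0.95)
  # growth never shrinks the tumor
  expect_gte(sum(m2) * prod(voxelSize(p@maskT2)),
             sum(volData(p@maskT1)) * prod(voxelSize(p@maskT1)))
})

test_that("truth field vanishes outside a bounded tumor neighborhood", {
  spec <- smallSpec()
  p <- makePatient(spec, seed = 4)
  w <- gridWorldOf(p@truthField)
  rOut <- spec@tumorRadiusT1 * spec@gainParallel + 5
  far <- sqrt(rowSums(w^2)) > rOut + 1e-6
  u <- matrix(volData(p@truthField), nrow(w), 3)
  expect_equal(max(abs(u[far, ])), 0)
})

test_that("cohorts are deterministic in the seed and vary across seeds", {
  spec <- smallSpec()
  c1 <- makeCohort(spec, 3, seed = 11)
  c2 <- makeCohort(spec, 3, seed = 11)
  expect_identical(c1, c2)
  expect_length(makeCohort(spec, 1, seed = 1)$patients, 1L)
  c3 <- makeCohort(spec, 3, seed = 12)
  cent <- function(co) t(vapply(co$specs, function(s) s@tumorCenter,
                                numeric(3)))
  expect_gt(max(abs(cent(c1) - cent(c3))), 0.5)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantomSpec(gridShape = c(8, 8, 8)), ">= 16")
  expect_error(phantomSpec(gainParallel = 0.8), "allowShrink")
  expect_error(phantomSpec(alignmentKappa = -1), "alignmentKappa")
  expect_error(makePatient(smallSpec(tumorCenter = c(44, 0, 0))),
               "exceeds grid bounds")
  expect_s4_class(phantomSpec(gainParallel = 0.8, gainPerpendicular = 0.8,
                              allowShrink = TRUE), "PhantomSpec")
})
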