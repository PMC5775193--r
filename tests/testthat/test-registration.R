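# Isotropic resampling, affine recovery and the non-linear growth engine.

test_that("isotropic resampling preserves world geometry and values", {
  # constant image stays constant
  aff <- centeredAffineOf(c(20L, 20L, 10L), c(2, 2, 4))
  const <- scalarVolume(array(7, c(20, 20, 10)), aff)
  out <- resampleIsotropic(const, 2)
  expect_equal(voxelSize(out), c(2, 2, 2))
  expect_true(all(abs(volData(out) - 7) < 1e-12 | volData(out) == 0))
  # a linear intensity ramp is reproduced exactly at interior grid points
  dm <- c(24L, 24L, 12L)
  affR <- centeredAffineOf(dm, c(2, 2, 4))
  w <- gridWorldOf(scalarVolume(array(0, dm), affR))
  ramp <- scalarVolume(array(2 * w[, 1] - w[, 2] + 0.5 * w[, 3] + 100, dm),
                       affR)
  iso <- resampleIsotropic(ramp, 2)
  wi <- gridWorldOf(iso)
  expected <- 2 * wi[, 1] - wi[, 2] + 0.5 * wi[, 3] + 100
  interior <- abs(wi[, 1]) < 18 & abs(wi[, 2]) < 18 & abs(wi[, 3]) < 16
  expect_lt(max(abs(as.vector(volData(iso))[interior] -
                      expected[interior])), 1e-9)
})

test_that("affine registration recovers identity, translation and scale", {
  spec <- smallSpec(noiseSigma = 5)
  p <- makePatient(spec, seed = 31)
  fixed <- p@imageT2
  # self-registration: identity within tolerance
  tr <- suppressWarnings(registerAffine(fixed, fixed, type = "rigid"))
  expect_lt(max(abs(tr@matrix[1:3, 4])), 0.1)
  expect_lt(max(abs(tr@matrix[1:3, 1:3] - diag(3))), 1e-3)
  # known translation (4, -3, 2) mm recovered within 0.5 mm
  a2 <- fixed@affine
  a2[1:3, 4] <- a2[1:3, 4] + c(4, -3, 2)
  moved <- scalarVolume(volData(fixed), a2)
  tr2 <- suppressWarnings(registerAffine(moved, fixed, type = "rigid"))
  expect_lt(max(abs(tr2@matrix[1:3, 4] - c(-4, 3, -2))), 0.5)
  # known scale 1.1 about the center recovered within 0.02
  a3 <- fixed@affine
  a3[1:3, 1:3] <- a3[1:3, 1:3] * 1.1
  a3[1:3, 4] <- a3[1:3, 4] * 1.1
  scaled <- scalarVolume(volData(fixed), a3)
  tr3 <- suppressWarnings(registerAffine(scaled, fixed, type = "similarity"))
  sc <- (abs(det(tr3@matrix[1:3, 1:3])))^(1 / 3)
  expect_lt(abs(sc - 1 / 1.1), 0.02)
  expect_error(registerAffine(scalarVolume(array(1, c(16, 16, 16)), diag(4)),
                              fixed), "non-constant")
})

test_that("random rigid perturbations are recovered within 0.5 mm / 0.5 deg", {
  # noise-free asymmetric multi-blob image: all six rigid degrees of freedom
  # are identifiable (a centered spherical phantom is rotation-invariant)
  dm <- c(32L, 32L, 32L)
  aff <- centeredAffineOf(dm, c(3, 3, 3))
  w <- gridWorldOf(scalarVolume(array(0, dm), aff))
  blob <- function(c0, s, amp) amp * exp(-rowSums(sweep(w, 2, c0)^2) /
                                           (2 * s^2))
  img <- blob(c(12, 5, -6), 8, 100) + blob(c(-15, -8, 8), 10, 80) +
    blob(c(2, 18, 10), 6, 120)
  fixed <- scalarVolume(array(img, dm), aff)
  set.seed(5)
  for (i in 1:3) {
    tmm <- runif(3, -5, 5)
    angdeg <- runif(1, -5, 5)
    ax <- c(0, 0, 1)
    th <- angdeg * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- tmm
    moved <- applyTransform(fixed, affineTransform(M), fixed)
    tr <- suppressWarnings(registerAffine(moved, fixed, type = "rigid"))
    err <- tr@matrix %*% M          # should compose to identity
    expect_lt(max(abs(err[1:3, 4])), 0.5)
    rotErr <- acos(pmin(1, (sum(diag(err[1:3, 1:3])) - 1) / 2)) * 180 / pi
    expect_lt(rotErr, 0.5)
  }
})

test_that("applyTransform handles volumes, masks and vector reorientation", {
  spec <- smallSpec(noiseSigma = 0)
  p <- makePatient(spec, seed = 41)
  ident <- affineTransform(diag(4))
  same <- applyTransform(p@imageT2, ident, p@imageT2)
  expect_equal(volData(same), volData(p@imageT2), tolerance = 1e-12)
  # whole-voxel translation of a binary mask preserves the voxel count
  M <- diag(4); M[1:3, 4] <- voxelSize(p@maskT2) * c(2, -1, 1)
  shifted <- applyTransform(p@maskT2, affineTransform(M), p@maskT2,
                            interp = "nearest")
  expect_equal(sum(volData(shifted)), sum(volData(p@maskT2)))
  expect_setequal(unique(as.vector(volData(shifted))), c(0, 1))
  # vectors under a pure rotation become R * original
  set.seed(2)
  R <- randomRotation()
  MR <- diag(4); MR[1:3, 1:3] <- R
  fld <- p@truthField
  out <- applyTransform(fld, affineTransform(MR),
                        list(dim = volDim(fld), affine = MR %*% fld@affine))
  u0 <- matrix(volData(fld), prod(volDim(fld)), 3)
  u1 <- matrix(volData(out), prod(volDim(out)), 3)
  supp <- as.vector(fieldSupport(out))
  expect_lt(max(abs(u1[supp, ] - (u0 %*% t(R))[supp, ])), 1e-6)
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(affineTransform(sing), "invertible")
})

test_that("growth registration is near-zero for identical inputs and outward for growth", {
  spec <- smallSpec(noiseSigma = 3)
  p <- makePatient(spec, seed = 51)
  vs <- voxelSize(p@imageT2)[1]
  # identity case: same image twice
  m2 <- p@maskT2
  fld0 <- registerGrowth(p@imageT2, p@imageT2, m2, m2)
  u0 <- matrix(volData(fld0), prod(volDim(fld0)), 3)
  supp <- as.vector(fieldSupport(fld0))
  rms <- sqrt(mean(rowSums(u0[supp, , drop = FALSE]^2)))
  expect_lt(rms / vs, 0.2)
  # grown sphere: field points outward on the t1 surface
  m1 <- resampleIsotropic(p@maskT1, vs, "nearest")
  i1 <- resampleIsotropic(p@imageT1, vs)
  fld <- registerGrowth(i1, p@imageT2, m1, m2)
  w <- gridWorldOf(fld)
  ctr <- spec@tumorCenter
  rel <- w - matrix(ctr, nrow(w), 3, byrow = TRUE)
  rho <- sqrt(rowSums(rel^2))
  surf <- abs(rho - spec@tumorRadiusT1) < vs & as.vector(fieldSupport(fld))
  u <- matrix(volData(fld), nrow(w), 3)
  dots <- rowSums(u[surf, , drop = FALSE] * rel[surf, , drop = FALSE] /
                    rho[surf])
  expect_gt(mean(dots), 0)
  # empty masks are rejected
  empty <- scalarVolume(array(0, volDim(m2)), volAffine(m2))
  expect_error(registerGrowth(p@imageT2, p@imageT2, empty, m2),
               "empty tumor mask")
})
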