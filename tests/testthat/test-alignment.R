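# Folded angles, angle maps and category summaries.

test_that("fold angle reproduces hand-computed cases", {
  expect_equal(foldAngle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(foldAngle(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_equal(foldAngle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(foldAngle(c(1, 1, 0), c(1, 0, 0)), 45)
  expect_error(foldAngle(c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("fold angle is symmetric, sign- and rotation-invariant, in range", {
  set.seed(23)
  n <- 2000
  u <- randomDirections(n) * runif(n, 0.1, 10)
  v <- randomDirections(n) * runif(n, 0.1, 10)
  a <- foldAngle(u, v)
  expect_true(all(a >= 0 & a <= 90))
  expect_equal(a, foldAngle(v, u))
  expect_equal(a, foldAngle(-u, v))
  expect_equal(a, foldAngle(u, -v))
  R <- randomRotation()
  expect_equal(a, foldAngle(u %*% t(R), v %*% t(R)), tolerance = 1e-9)
  # near-collinear inputs with accumulated rounding never produce NaN
  w <- randomDirections(500)
  wEps <- w * (1 + 3e-16) + 1e-16
  aa <- foldAngle(w, wEps)
  expect_false(any(is.nan(aa)))
  expect_true(all(aa >= 0))
  expect_false(any(is.nan(foldAngle(w, -w))))
})

test_that("angle maps respect validity, support and magnitude gating", {
  spec <- smallSpec()
  atlas <- makeFiberAtlas(spec)
  fibers <- principalDirections(atlas)
  dm <- volDim(fibers)
  aff <- volAffine(fibers)
  # field parallel to the fibers everywhere -> all valid angles 0
  fdir <- gbmGrowth:::.fiberDirection(spec, gridWorldOf(fibers))
  vec <- array(2 * fdir, c(dm, 3L))
  fld <- displacementField(vec, aff, support = array(TRUE, dm))
  am <- angleMap(fld, fibers, magMinMM = 0.5)
  expect_true(any(validMask(am)))
  expect_lt(max(am@theta[validMask(am)]), 1e-6)
  # invalid voxels are NA, never 0
  expect_true(all(is.na(am@theta[!validMask(am)])))
  # magnitudes below the threshold yield zero valid voxels
  tiny <- displacementField(vec * 0.1, aff, support = array(TRUE, dm))
  expect_equal(sum(validMask(angleMap(tiny, fibers, magMinMM = 0.5))), 0)
  # grid mismatch is rejected
  aff2 <- aff; aff2[1, 4] <- aff2[1, 4] + 1
  fld2 <- displacementField(vec, aff2, support = array(TRUE, dm))
  expect_error(angleMap(fld2, fibers), "grids differ")
})

test_that("classification counts the documented example correctly", {
  th <- c(5, 15, 45, 75, 85)
  theta <- array(NA_real_, c(5, 1, 1))
  theta[, 1, 1] <- th
  am <- new("AngleMap", theta = theta, affine = diag(4),
            valid = array(TRUE, c(5, 1, 1)))
  s <- classifyAndSummarize(am)
  expect_equal(unname(alignmentFractions(s)),
               c(0.2, 0.4, 0.4, 0.2, 0.2))
  expect_equal(nValid(s), 5)
  expect_equal(sum(angleHistogram(s)), 5)
  expect_equal(angleHistogram(s), c(1, 1, 0, 0, 1, 0, 0, 1, 1))
  # all-parallel map
  am0 <- new("AngleMap", theta = array(0, c(4, 1, 1)), affine = diag(4),
             valid = array(TRUE, c(4, 1, 1)))
  s0 <- classifyAndSummarize(am0)
  expect_equal(s0@fractions[["lt20"]], 1)
  expect_equal(s0@fractions[["gt70"]], 0)
  # empty map: flagged, not NaN-silent
  amE <- new("AngleMap", theta = array(NA_real_, c(3, 1, 1)),
             affine = diag(4), valid = array(FALSE, c(3, 1, 1)))
  sE <- classifyAndSummarize(amE)
  expect_true(sE@empty)
  expect_equal(nValid(sE), 0)
  expect_true(all(is.na(alignmentFractions(sE))))
  expect_error(classifyAndSummarize(am, tPar = 70, tPerp = 20), "below")
})

test_that("uniform random directions reproduce the spherical angle law", {
  set.seed(29)
  n <- 4e4
  u <- randomDirections(n)
  v <- randomDirections(n)
  theta <- array(foldAngle(u, v), c(n, 1, 1))
  am <- new("AngleMap", theta = theta, affine = diag(4),
            valid = array(TRUE, c(n, 1, 1)))
  s <- classifyAndSummarize(am)
  p20 <- 1 - cos(20 * pi / 180)
  p70 <- cos(70 * pi / 180)
  expect_lt(abs(s@fractions[["lt20"]] - p20), 3 * sqrt(p20 * (1 - p20) / n))
  expect_lt(abs(s@fractions[["gt70"]] - p70), 3 * sqrt(p70 * (1 - p70) / n))
  # nested-category and closure invariants
  f <- alignmentFractions(s)
  expect_lte(f[["lt10"]], f[["lt20"]])
  expect_lte(f[["gt80"]], f[["gt70"]])
  expect_equal(f[["lt20"]] + f[["gt70"]] + f[["other"]], 1, tolerance = 1e-9)
  expect_equal(sum(angleHistogram(s)), nValid(s))
})

test_that("summary tables and pooling are consistent", {
  mkSum <- function(id, th) {
    theta <- array(th, c(length(th), 1, 1))
    classifyAndSummarize(new("AngleMap", theta = theta, affine = diag(4),
                             valid = array(TRUE, dim(theta))),
                         patientId = id)
  }
  s1 <- mkSum("a", c(5, 15, 45))
  s2 <- mkSum("b", c(75, 85, 50, 40))
  df <- summariesAsDataFrame(list(s1, s2))
  expect_equal(nrow(df), 2)
  expect_equal(df$n_valid, c(3, 4))
  expect_equal(df$frac_lt20, c(2 / 3, 0))
  pool <- poolAlignment(list(s1, s2))
  expect_equal(unname(pool$pooled[["lt20"]]), 2 / 7)
  expect_equal(unname(pool$meanOfPatients[["lt20"]]), mean(c(2 / 3, 0)))
  expect_equal(pool$nValid, 7)
})
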