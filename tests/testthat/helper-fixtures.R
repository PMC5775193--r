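# Shared fixtures: small phantom specs and independent oracles.

# compact phantom for fast unit tests (t2 grid 32^3 at 3 mm, 96 mm FOV);
# any phantomSpec argument may be overridden
smallSpec <- function(...) {
  args <- list(gridShape = c(32L, 32L, 32L),
               voxelSizeT1 = c(3, 3, 3), voxelSizeT2 = c(3, 3, 3),
               tumorRadiusT1 = 9, brainRadius = 38, noiseSigma = 5)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantomSpec, args)
}

# uniform random unit vectors, n x 3
randomDirections <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent polar-decomposition oracle: R = A (A^T A)^(-1/2) via the
# eigen-decomposition of A^T A (a different route than the package's SVD)
polarOracle <- function(A) {
  e <- eigen(crossprod(A), symmetric = TRUE)
  sInv <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  A %*% sInv
}

# brute-force Wilcoxon signed-rank oracle: exact two-sided p by enumerating
# all 2^n sign assignments over the mid-ranked |differences|
wilcoxonEnumOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% ranks)
  pLow <- mean(ws <= w + 1e-9)
  pHigh <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pLow, pHigh))
}

# world-coordinate matrix of every voxel of a grid-carrying object
gridWorldOf <- function(obj) {
  dm <- volDim(obj)
  ijk <- cbind(rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
               rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3]),
               rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2]))
  aff <- volAffine(obj)
  t(aff[1:3, 1:3] %*% t(ijk)) + matrix(aff[1:3, 4], nrow(ijk), 3,
                                       byrow = TRUE)
}

# simple centered axis-aligned affine
centeredAffineOf <- function(dm, voxel) {
  a <- diag(4)
  diag(a)[1:3] <- voxel
  a[1:3, 4] <- -voxel * (dm - 1) / 2
  a
}
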