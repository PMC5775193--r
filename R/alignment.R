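# Voxel-wise folded angles between growth vectors and fiber directions.

#' Folded angle between two vectors, degrees in [0, 90]
#'
#' The angle between u and v is the inverse cosine of their dot product
#' divided by the product of their magnitudes; because fiber directions are
#' axes (defined only up to sign) the cosine is folded by taking its
#' absolute value, remapping the angle to [0, 90] degrees. The cosine is
#' clamped to [-1, 1] before the arccosine, so near-collinear inputs with
#' accumulated floating-point error never produce NaN.
#'
#' @param u,v numeric 3-vectors, or n x 3 matrices for vectorized use. Both
#'   must be non-zero (rows pre-filtered by the caller).
#' @return folded angle(s) in degrees.
#' @examples
#' foldAngle(c(1, 0, 0), c(-1, 0, 0)) # 0: anti-parallel folds to parallel
#' foldAngle(c(1, 1, 0), c(1, 0, 0))  # 45
#' @export
foldAngle <- function(u, v) {
  u <- matrix(u, ncol = 3)
  v <- matrix(v, ncol = 3)
  if (nrow(u) == 1L && nrow(v) > 1L) u <- u[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(u) > 1L) v <- v[rep(1L, nrow(u)), , drop = FALSE]
  nu <- .rowNorms(u); nv <- .rowNorms(v)
  if (any(nu == 0) || any(nv == 0))
    stop("foldAngle: zero-length vector; filter degenerate inputs first")
  cosv <- abs(rowSums(u * v)) / (nu * nv)
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Voxel-wise folded angle map between a growth field and fiber directions
#'
#' Both inputs must live on the same grid (the displacement field is
#' expected to have been down-sampled to the atlas grid first). A voxel is
#' valid when the fiber direction is valid, the voxel is in the field's
#' support, and the growth vector magnitude reaches `magMinMM` (the
#' "detectable vector" threshold).
#'
#' @param field a [DisplacementField-class] on the atlas grid.
#' @param fibers a [DirectionField-class].
#' @param magMinMM minimum growth-vector magnitude in mm (default 0.5).
#' @return An [AngleMap-class].
#' @export
angleMap <- function(field, fibers, magMinMM = 0.5) {
  stopifnot(is(field, "DisplacementField"), is(fibers, "DirectionField"))
  if (!.sameGrid(field@affine, volDim(field), fibers@affine, volDim(fibers)))
    stop("angleMap: field and fiber grids differ; down-sample the field first")
  dm <- volDim(field)
  u <- .fieldAsMatrix(field@vectors)
  v <- .fieldAsMatrix(fibers@vectors)
  mag <- .rowNorms(u)
  valid <- as.vector(fibers@valid) & as.vector(field@support) &
    mag >= magMinMM
  theta <- rep(NA_real_, prod(dm))
  if (any(valid))
    theta[valid] <- foldAngle(u[valid, , drop = FALSE],
                              v[valid, , drop = FALSE])
  new("AngleMap", theta = array(theta, dm), affine = field@affine,
      valid = array(valid, dm))
}

#' Classify a folded-angle map into parallel/perpendicular categories
#'
#' Thresholds follow the published convention: growth is parallel when
#' |theta| < 20 degrees and perpendicular when |theta| > 70 degrees (strict
#' inequalities as printed); nested fractions at 10 and 80 degrees are also
#' reported, together with a 9-bin histogram over [0, 90] (10-degree bins,
#' left-closed, final bin right-closed).
#'
#' @param map an [AngleMap-class].
#' @param tPar parallel threshold, degrees (default 20).
#' @param tPerp perpendicular threshold, degrees (default 70).
#' @param patientId identifier carried into the summary.
#' @return An [AlignmentSummary-class]; when the map has no valid
#'   voxels the summary is flagged `empty` and fractions are NA.
#' @export
classifyAndSummarize <- function(map, tPar = 20, tPerp = 70,
                                 patientId = "") {
  stopifnot(is(map, "AngleMap"))
  if (!(tPar < tPerp)) stop("tPar must be below tPerp")
  if (tPar <= 0 || tPerp >= 90) stop("thresholds must lie inside (0, 90)")
  th <- map@theta[map@valid]
  n <- length(th)
  if (n == 0L) {
    return(new("AlignmentSummary", patientId = patientId, nValid = 0,
               fractions = c(lt10 = NA_real_, lt20 = NA_real_,
                             gt70 = NA_real_, gt80 = NA_real_,
                             other = NA_real_),
               histogram = rep(0, 9), thresholds = c(tPar, tPerp),
               empty = TRUE))
  }
  fr <- c(lt10 = mean(th < 10), lt20 = mean(th < tPar),
          gt70 = mean(th > tPerp), gt80 = mean(th > 80))
  fr["other"] <- 1 - fr[["lt20"]] - fr[["gt70"]]
  hist <- vapply(seq_len(9), function(b) {
    lo <- (b - 1) * 10; hi <- b * 10
    if (b == 9L) sum(th >= lo & th <= hi) else sum(th >= lo & th < hi)
  }, numeric(1))
  new("AlignmentSummary", patientId = patientId, nValid = n,
      fractions = fr, histogram = hist, thresholds = c(tPar, tPerp),
      empty = FALSE)
}

#' Tabulate alignment summaries
#'
#' @param summaries list of [AlignmentSummary-class].
#' @return data.frame with one row per patient: n_valid, the five category
#'   fractions and the nine 10-degree bin counts.
#' @export
summariesAsDataFrame <- function(summaries) {
  if (is(summaries, "AlignmentSummary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    h <- as.list(s@histogram)
    names(h) <- sprintf("bin_%d_%d", seq(0, 80, 10), seq(10, 90, 10))
    c(list(patient_id = s@patientId, n_valid = s@nValid,
           frac_lt10 = s@fractions[["lt10"]],
           frac_lt20 = s@fractions[["lt20"]],
           frac_gt70 = s@fractions[["gt70"]],
           frac_gt80 = s@fractions[["gt80"]],
           frac_other = s@fractions[["other"]]), h)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Pool angle-map voxels across patients
#'
#' The published fractions can be read either as pooled voxels across the
#' cohort or as a mean of per-patient fractions; both are returned.
#'
#' @param summaries list of [AlignmentSummary-class].
#' @return list with `pooled` and `meanOfPatients` named fraction vectors and
#'   the pooled `nValid`.
#' @export
poolAlignment <- function(summaries) {
  keep <- Filter(function(s) !s@empty, summaries)
  if (!length(keep)) stop("no non-empty summaries to pool")
  counts <- vapply(keep, function(s) s@nValid, numeric(1))
  fr <- t(vapply(keep, function(s) s@fractions, numeric(5)))
  pooled <- colSums(fr * counts) / sum(counts)
  list(pooled = pooled, meanOfPatients = colMeans(fr),
       nValid = sum(counts))
}
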