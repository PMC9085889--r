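CLIP <- 1 - 1e-7

fisherZ <- function(r) atanh(pmin(pmax(r, -CLIP), CLIP))

#' Functional-connectivity pattern of a source voxel over a target region
#'
#' Pearson correlation of the source time course with every target-voxel
#' time course, Fisher z-transformed (|r| clipped at 1 - 1e-7 before
#' atanh). Zero-variance target voxels contribute z = 0 (with a warning)
#' so the pattern length stays fixed across subjects.
#'
#' @param sourceTs numeric vector, the source voxel's (cleaned) time course.
#' @param targetTs frames x voxels matrix of target time courses.
#' @return numeric vector of Fisher-z correlations, one per target voxel.
#' @export
fcPattern <- function(sourceTs, targetTs) {
  targetTs <- as.matrix(targetTs)
  stopifnot(length(sourceTs) == nrow(targetTs), nrow(targetTs) >= 10L)
  if (stats::sd(sourceTs) == 0) stop("zero-variance source time course")
  sdT <- apply(targetTs, 2, stats::sd)
  r <- numeric(ncol(targetTs))
  ok <- sdT > 0
  if (any(!ok)) warning("zero-variance target voxels set to z = 0")
  if (any(ok))
    r[ok] <- drop(stats::cor(sourceTs, targetTs[, ok, drop = FALSE]))
  z <- fisherZ(r)
  z[!ok] <- 0
  z
}

#' MCM value: spatial correlation of FC and CMRGlu patterns
#'
#' Fisher z of the Pearson correlation, across target voxels, between a
#' source voxel's FC pattern and the target region's CMRGlu pattern. A
#' constant FC pattern (no spatial structure) yields 0; a constant CMRGlu
#' pattern is an error.
#'
#' @param fc FC pattern from \code{\link{fcPattern}}.
#' @param cmrgluPattern CMRGlu values over the same target voxels.
#' @return scalar Fisher-z MCM value.
#' @export
mcmValue <- function(fc, cmrgluPattern) {
  stopifnot(length(fc) == length(cmrgluPattern), length(fc) >= 4L)
  if (stats::sd(cmrgluPattern) == 0)
    stop("constant CMRGlu pattern: MCM undefined")
  if (stats::sd(fc) == 0) return(0)
  fisherZ(stats::cor(fc, cmrgluPattern))
}

#' Whole-brain MCM map
#'
#' For every source voxel in the brain mask, correlates its time course
#' with all target-region time courses (Fisher z), spatially correlates
#' the resulting FC pattern with the target's CMRGlu pattern, and assigns
#' the Fisher-z MCM value to the source voxel. Target voxels are excluded
#' from the source set by default (self-correlation inflates MCM).
#'
#' @param bold cleaned BOLD data: \linkS4class{FrameSeries} or frames x
#'   voxels matrix covering the whole grid (voxels in linear order).
#' @param target logical array marking the target region.
#' @param cmrgluMap 3D CMRGlu array (only target voxels are used).
#' @param brainMask logical array of candidate source voxels; NULL = all.
#' @param excludeTarget drop target voxels from the source set.
#' @param labels optional named character vector (subject, time, condition).
#' @return an \linkS4class{McmMap}.
#' @export
mcmMap <- function(bold, target, cmrgluMap, brainMask = NULL,
                   excludeTarget = TRUE, labels = character()) {
  dims <- dim(target)
  Y <- if (is(bold, "FrameSeries")) timeCourses(bold) else as.matrix(bold)
  stopifnot(ncol(Y) == prod(dims), all(dim(cmrgluMap) == dims))
  if (is.null(brainMask)) brainMask <- array(TRUE, dims)
  stopifnot(all(dim(brainMask) == dims))
  tIdx <- which(target)
  if (length(tIdx) < 4L) stop("target region has fewer than 4 voxels")
  src <- as.logical(brainMask)
  if (excludeTarget) src <- src & !as.logical(target)
  sIdx <- which(src)
  if (!length(sIdx)) stop("empty source set")
  n <- nrow(Y)
  Tm <- Y[, tIdx, drop = FALSE]
  Sm <- Y[, sIdx, drop = FALSE]
  sdT <- apply(Tm, 2, stats::sd)
  sdS <- apply(Sm, 2, stats::sd)
  Ts <- scale(Tm); Ts[, sdT == 0] <- 0
  Ss <- scale(Sm)
  R <- crossprod(Ss, Ts) / (n - 1)        # source x target correlations
  Z <- fisherZ(R)
  Z[, sdT == 0] <- 0
  g <- cmrgluMap[tIdx]
  if (stats::sd(g) == 0) stop("constant CMRGlu pattern over the target")
  gs <- (g - mean(g)) / stats::sd(g)
  m <- length(tIdx)
  Zc <- Z - rowMeans(Z)
  zsd <- sqrt(rowSums(Zc^2) / (m - 1))
  rSpatial <- drop(Zc %*% gs) / ((m - 1) * zsd)
  mcm <- ifelse(zsd == 0, 0, fisherZ(rSpatial))
  mcm[sdS == 0] <- NA_real_
  vals <- array(NA_real_, dims)
  vals[sIdx] <- mcm
  new("McmMap", values = vals, target = array(as.logical(target), dims),
      labels = labels)
}
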