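#' Remove the lowest-valued fraction of a target region
#'
#' Deterministic value-ordered reduction: the floor(fraction * n) target
#' voxels with the lowest driver values are removed; ties are broken by
#' ascending linear voxel index, so reductions are stable and nested
#' across fractions.
#'
#' @param target logical array (or integer index vector) of target voxels.
#' @param valueMap numeric array on the same grid (or vector matched to
#'   the index form) supplying the ordering.
#' @param fraction fraction to remove, in [0, 1).
#' @return same form as \code{target}: reduced logical array or index
#'   vector. At least 4 voxels must survive.
#' @export
reduceTarget <- function(target, valueMap, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  if (is.logical(target) || is.array(target)) {
    idx <- which(target)
    vals <- valueMap[idx]
    drop <- idx[order(vals, idx)][seq_len(floor(fraction * length(idx)))]
    out <- target
    out[drop] <- FALSE
    if (sum(out) < 4L) stop("reduction leaves fewer than 4 target voxels")
    out
  } else {
    vals <- valueMap
    stopifnot(length(vals) == length(target))
    ord <- order(vals, target)
    keep <- sort(target[ord][-seq_len(floor(fraction * length(target)))])
    if (floor(fraction * length(target)) == 0L) keep <- sort(target)
    if (length(keep) < 4L) stop("reduction leaves fewer than 4 target voxels")
    keep
  }
}

#' Voxel-removal perturbation of the MCM training effect
#'
#' Recomputes the group x time interaction F of the cluster-level MCM
#' value while target voxels are progressively removed (steps of 10% up
#' to 90%) either by ascending CMRGlu value, by ascending FC value (mean
#' Fisher-z connectivity of each target voxel with the cluster), or at
#' random. The value map of the two specific drivers is the group mean
#' over all subjects at the first scan, computed once at fraction 0 and
#' reused, so reductions are nested. For the random driver, each record's
#' MCM z-score is averaged over \code{nRandom} seeded random reductions
#' before the F statistic is computed.
#'
#' @param study from \code{\link{simulateMcmStudy}}.
#' @param driver "cmrglu", "fc" or "random".
#' @param fractions removal fractions, default seq(0, 0.9, 0.1).
#' @param nRandom random selections per fraction (random driver).
#' @param seed RNG seed for the random driver.
#' @param condition which condition's group x time interaction to track.
#' @return data.frame of class "PerturbationCurve" with columns fraction,
#'   F, p, driver, nKept.
#' @export
perturbationCurve <- function(study, driver = c("cmrglu", "fc", "random"),
                              fractions = seq(0, 0.9, 0.1), nRandom = 500,
                              seed = 1, condition = "rest") {
  driver <- match.arg(driver)
  stopifnot(!is.unsorted(fractions, strictly = TRUE))
  design <- study$design
  sel <- which(design$condition == condition)
  recs <- lapply(study$records[sel], function(rec) {
    list(Z = fcPatternMatrix(rec$clusterTs, rec$targetTs),
         g = rec$cmrglu)
  })
  dsel <- design[sel, c("subject", "group", "time")]
  m <- ncol(recs[[1]]$Z)
  isM1 <- dsel$time == levels(factor(dsel$time))[1]
  valueMap <- switch(driver,
    cmrglu = rowMeans(vapply(recs[isM1], `[[`, numeric(m), "g")),
    fc = rowMeans(vapply(recs[isM1], function(r) colMeans(r$Z),
                         numeric(m))),
    random = NULL)
  fAt <- function(mcm) {
    d <- dsel
    d$condition <- condition
    d$value <- mcm
    posthocGroupTime(d, condition)$interaction
  }
  rows <- lapply(fractions, function(f) {
    nDrop <- floor(f * m)
    if (m - nDrop < 4L) stop("fraction leaves fewer than 4 target voxels")
    if (driver == "random") {
      set.seed(seed + round(1000 * f))
      draws <- replicate(nRandom, sort(sample.int(m, m - nDrop)),
                         simplify = FALSE)
      mcm <- vapply(recs, function(r) {
        mean(vapply(draws, function(idx)
          mean(fisherZ(rowCorSubset(r$Z, r$g, idx))), numeric(1)))
      }, numeric(1))
    } else {
      idx <- reduceTarget(seq_len(m), valueMap, f)
      mcm <- vapply(recs, function(r)
        mean(fisherZ(rowCorSubset(r$Z, r$g, idx))), numeric(1))
    }
    stat <- fAt(mcm)
    data.frame(fraction = f, F = stat$F, p = stat$p, driver = driver,
               nKept = m - nDrop)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PerturbationCurve", "data.frame")
  out
}
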