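#' Threshold a statistical map to a binary mask
#'
#' @param statMap numeric array (e.g. t-values).
#' @param threshold scalar threshold on the map's own scale.
#' @param direction ">" keeps values strictly above the threshold, "<"
#'   strictly below (for p-value maps).
#' @return logical array.
#' @export
binarize <- function(statMap, threshold, direction = c(">", "<")) {
  direction <- match.arg(direction)
  if (direction == ">") statMap > threshold else statMap < threshold
}

#' Intersection of binary masks
#'
#' Conjunction across modalities: logical AND over two or more grid-aligned
#' masks.
#'
#' @param masks list of logical arrays on one grid.
#' @return logical array.
#' @export
intersectMasks <- function(masks) {
  stopifnot(length(masks) >= 2L)
  ref <- dim(masks[[1]])
  for (m in masks[-1])
    if (!all(dim(m) == ref)) stop("mask grids differ")
  Reduce(`&`, masks)
}

#' Dice coefficient of two binary masks
#'
#' 2|A n B| / (|A| + |B|).
#'
#' @param a,b logical arrays on one grid; at least one must be non-empty.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask grids differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("Dice undefined: both masks empty")
  2 * sum(a & b) / (na + nb)
}

neighborOffsets26 <- function(dims) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  g$dx + g$dy * dims[1] + g$dz * dims[1] * dims[2]
}

#' Label connected components of a binary mask
#'
#' 26-connected component labeling by breadth-first flood fill over the
#' voxel lattice.
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 background, components
#'   labeled 1..k in order of their smallest linear index.
#' @export
labelClusters <- function(mask) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  lab <- array(0L, dims)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  inMask <- array(FALSE, dims); inMask[idx] <- TRUE
  coord <- arrayInd(seq_len(prod(dims)), dims)  # for border checks
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  nextLab <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      vc <- coord[v, ]
      nx <- vc[1] + g$dx; ny <- vc[2] + g$dy; nz <- vc[3] + g$dz
      ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
        nz >= 1 & nz <= dims[3]
      nb <- nx[ok] + (ny[ok] - 1) * dims[1] + (nz[ok] - 1) * dims[1] * dims[2]
      nb <- nb[inMask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nextLab
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Remove small clusters from a mask
#'
#' Labels 26-connected components, optionally merges components that are
#' mirror-symmetric across the grid's x midplane (left/right homologues),
#' and removes components whose volume falls below the cutoff.
#'
#' @param mask logical 3D array.
#' @param minVolumeCm3 minimum component volume in cm3, default 1.0.
#' @param voxelVolumeCm3 volume of one voxel in cm3.
#' @param mergeSymmetric if TRUE, components overlapping their own mirror
#'   image across the x midplane are counted together.
#' @return list with \code{mask} (filtered), \code{labels} (integer array),
#'   and \code{volumes} (cm3 per retained label).
#' @export
clusterFilter <- function(mask, minVolumeCm3 = 1.0, voxelVolumeCm3,
                          mergeSymmetric = FALSE) {
  lab <- labelClusters(mask)
  if (max(lab) == 0L)
    return(list(mask = mask & FALSE, labels = lab, volumes = numeric()))
  groups <- seq_len(max(lab))
  if (mergeSymmetric) {
    mirror <- lab[rev(seq_len(dim(lab)[1])), , , drop = FALSE]
    for (k in groups) {
      partners <- setdiff(unique(mirror[lab == k]), 0L)
      for (p in partners) {
        joint <- min(groups[c(k, p)])
        groups[groups == groups[k] | groups == groups[p]] <- joint
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  groupVol <- tapply(sizes * voxelVolumeCm3, groups, sum)
  keepGroup <- as.integer(names(groupVol))[groupVol >= minVolumeCm3]
  keepLab <- which(groups %in% groups[keepGroup])
  out <- array(lab %in% keepLab, dim(mask))
  vols <- sizes[keepLab] * voxelVolumeCm3
  names(vols) <- keepLab
  list(mask = out, labels = lab * as.integer(out), volumes = vols)
}
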