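#' Read a NIfTI image as a FrameSeries or array
#'
#' 4D images are returned as \linkS4class{FrameSeries} (frame times from the
#' header's temporal spacing); 3D images as a plain numeric array with the
#' affine attached as attribute \code{"affine"}.
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param tr optional override for the frame spacing in seconds (used when
#'   the header pixdim[4] is absent or zero).
#' @return A \linkS4class{FrameSeries} (4D) or numeric array (3D).
#' @export
readImage <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L) {
    pd <- attr(img, "pixdim")
    spacing <- if (!is.null(tr)) tr else if (length(pd) >= 4 && pd[4] > 0)
      pd[4] else 1
    FrameSeries(arr, tr = spacing, affine = aff)
  } else {
    attr(arr, "affine") <- aff
    arr
  }
}

#' Write a FrameSeries, array or mask to NIfTI-1
#'
#' @param img a \linkS4class{FrameSeries}, numeric or logical array.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeImage <- function(img, path) {
  if (is(img, "FrameSeries")) {
    tr <- if (nFrames(img) > 1) diff(frameTimes(img))[1] else 1
    nim <- RNifti::asNifti(frameData(img))
    attr(nim, "pixdim") <- c(1, 1, 1, tr)
  } else {
    if (is.logical(img)) img <- array(as.numeric(img), dim(img))
    nim <- RNifti::asNifti(img)
  }
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read an arterial blood sample table
#'
#' Expects a TSV with columns \code{time_min} (or \code{time_s}),
#' \code{wholeblood_kBq_ml}, \code{plasma_kBq_ml}.
#'
#' @param path TSV path.
#' @return data.frame with columns time_min, wholeblood, plasma.
#' @export
readBloodSamples <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  tm <- if ("time_min" %in% names(d)) d$time_min else d$time_s / 60
  out <- data.frame(time_min = tm,
                    wholeblood = d$wholeblood_kBq_ml,
                    plasma = d$plasma_kBq_ml)
  out[order(out$time_min), , drop = FALSE]
}

#' Read a 6-column motion parameter table
#'
#' @param path TSV path with columns trans_x, trans_y, trans_z (mm) and
#'   rot_x, rot_y, rot_z (rad).
#' @return numeric matrix, frames x 6.
#' @export
readMotion <- function(path) {
  d <- utils::read.delim(path)
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  stopifnot(all(cols %in% names(d)))
  as.matrix(d[, cols])
}

#' @rdname readMotion
#' @param motion frames x 6 matrix.
#' @export
writeMotion <- function(motion, path) {
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  utils::write.table(as.data.frame(motion), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

stopGrid <- function(...) {
  dims <- lapply(list(...), function(x)
    if (is(x, "FrameSeries")) gridDim(x) else dim(x)[1:3])
  ref <- dims[[1]]
  for (d in dims[-1])
    if (!all(d == ref)) stop("inputs are not on a shared voxel grid")
  invisible(ref)
}
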