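#' @import methods
NULL

#' FrameSeries: a 4D frame-indexed voxel grid
#'
#' Common carrier for dynamic imaging series (BOLD, dynamic PET frames,
#' ASL control/label pairs). Wraps a 4D numeric array (x, y, z, frame)
#' together with frame mid-times and a unit label. Frame times are stored
#' in seconds; PET routines convert to minutes internally.
#'
#' @slot data 4D numeric array, dimensions (nx, ny, nz, nframes).
#' @slot frameTimes numeric vector of frame mid-times in seconds.
#' @slot unit character, physical unit of the voxel values (e.g. "kBq/ml").
#' @slot affine 4x4 voxel-to-world matrix carried through I/O (never used
#'   for resampling; all stages assume a shared grid).
#'
#' @export
setClass("FrameSeries",
  representation(
    data = "array",
    frameTimes = "numeric",
    unit = "character",
    affine = "matrix"
  ),
  prototype(unit = "a.u.", affine = diag(4))
)

setValidity("FrameSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (x, y, z, frame)")
  if (length(object@frameTimes) != d[4L])
    return("frameTimes length must equal the number of frames")
  if (any(!is.finite(object@frameTimes)))
    return("frameTimes must be finite")
  if (is.unsorted(object@frameTimes, strictly = TRUE))
    return("frameTimes must be strictly increasing")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  TRUE
})

#' Construct a FrameSeries
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param frameTimes frame mid-times in seconds; defaults to
#'   \code{tr/2 + tr*(0:(n-1))}.
#' @param tr repetition time / frame length in seconds, used only to derive
#'   default frame times.
#' @param unit unit label for voxel values.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A \linkS4class{FrameSeries}.
#' @examples
#' fs <- FrameSeries(array(rnorm(2 * 2 * 2 * 5), c(2, 2, 2, 5)), tr = 2)
#' nFrames(fs)
#' @export
FrameSeries <- function(data, frameTimes = NULL, tr = 1, unit = "a.u.",
                        affine = diag(4)) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (is.null(frameTimes)) {
    n <- dim(data)[4L]
    frameTimes <- tr / 2 + tr * (seq_len(n) - 1L)
  }
  new("FrameSeries", data = data, frameTimes = as.numeric(frameTimes),
      unit = unit, affine = affine)
}

#' @describeIn FrameSeries Number of frames.
#' @param x a FrameSeries.
#' @export
nFrames <- function(x) dim(x@data)[4L]

#' @describeIn FrameSeries Spatial grid dimensions (length-3 integer).
#' @export
gridDim <- function(x) dim(x@data)[1:3]

#' @describeIn FrameSeries The underlying 4D array.
#' @export
frameData <- function(x) x@data

#' @describeIn FrameSeries Frame mid-times in seconds.
#' @export
frameTimes <- function(x) x@frameTimes

#' Voxel-by-time matrix view
#'
#' Flattens a FrameSeries to a frames x voxels matrix (time courses in
#' columns), optionally restricted to a logical mask.
#'
#' @param x a \linkS4class{FrameSeries}.
#' @param mask optional logical array on the same grid; columns are the
#'   masked voxels in linear (x-fastest) order.
#' @return numeric matrix, nframes x nvoxels.
#' @export
timeCourses <- function(x, mask = NULL) {
  d <- dim(x@data)
  m <- matrix(x@data, prod(d[1:3]), d[4L])
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == d[1:3]))
    m <- m[as.logical(mask), , drop = FALSE]
  }
  t(m)
}

setMethod("show", "FrameSeries", function(object) {
  d <- dim(object@data)
  cat("FrameSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "frames\n")
  cat("  frame times:", round(min(object@frameTimes), 2), "-",
      round(max(object@frameTimes), 2), "s; unit:", object@unit, "\n")
})

#' InputFunction: arterial plasma activity at PET frame times
#'
#' Arterial input function resampled to the PET frame grid, carrying the
#' plasma activity concentration and its running time-integral (the Patlak
#' abscissa numerator).
#'
#' @slot frameTimesMin frame mid-times in minutes.
#' @slot cp plasma activity (kBq/ml) at each frame.
#' @slot cumInt cumulative integral of cp from time zero (kBq*min/ml).
#'
#' @export
setClass("InputFunction",
  representation(
    frameTimesMin = "numeric",
    cp = "numeric",
    cumInt = "numeric"
  )
)

setValidity("InputFunction", function(object) {
  n <- length(object@frameTimesMin)
  if (length(object@cp) != n || length(object@cumInt) != n)
    return("frameTimesMin, cp and cumInt must have equal length")
  if (is.unsorted(object@frameTimesMin, strictly = TRUE))
    return("frameTimesMin must be strictly increasing")
  if (all(object@cp >= 0) && any(diff(object@cumInt) < -1e-9))
    return("cumInt must be non-decreasing when cp >= 0")
  TRUE
})

#' @describeIn InputFunction Plasma activity per frame (kBq/ml).
#' @param x an InputFunction.
#' @export
plasmaActivity <- function(x) x@cp

#' @describeIn InputFunction Cumulative integral of plasma activity
#'   (kBq*min/ml).
#' @export
plasmaIntegral <- function(x) x@cumInt

setMethod("show", "InputFunction", function(object) {
  cat("InputFunction:", length(object@cp), "frames,",
      round(min(object@frameTimesMin), 2), "-",
      round(max(object@frameTimesMin), 2), "min\n")
  cat("  cp range:", round(min(object@cp), 2), "-",
      round(max(object@cp), 2), "kBq/ml\n")
})

#' McmMap: whole-brain directional connectivity toward a target region
#'
#' Per-source-voxel Fisher-z value of the spatial correlation between the
#' voxel's functional-connectivity pattern over the target region and the
#' target's CMRGlu pattern.
#'
#' @slot values 3D numeric array of MCM z values (NA outside the source set).
#' @slot target logical array marking the target region.
#' @slot labels named character vector (subject, time, condition), free-form.
#'
#' @export
setClass("McmMap",
  representation(
    values = "array",
    target = "array",
    labels = "character"
  ),
  prototype(labels = character())
)

setValidity("McmMap", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (!all(dim(object@target) == dim(object@values)))
    return("target mask must share the grid of values")
  v <- object@values[!is.na(object@values)]
  if (any(!is.finite(v)))
    return("non-NA MCM values must be finite")
  TRUE
})

#' @describeIn McmMap MCM z values as a 3D array.
#' @param x an McmMap.
#' @export
mcmValues <- function(x) x@values

#' @describeIn McmMap The target-region mask.
#' @export
targetMask <- function(x) x@target

setMethod("show", "McmMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat("McmMap:", paste(dim(object@values), collapse = " x "), "grid,",
      sum(object@target), "target voxels,", length(v), "source voxels\n")
  if (length(v))
    cat("  z range:", round(min(v), 3), "-", round(max(v), 3), "\n")
  if (length(object@labels))
    cat(" ", paste(names(object@labels), object@labels, sep = "=",
                   collapse = ", "), "\n")
})
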