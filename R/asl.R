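#' ASL quantification constants
#'
#' Constants of the single-compartment CBF model: blood-tissue water
#' partition coefficient lambda (ml/g), longitudinal relaxation rate of
#' arterial blood R1a (1/s), tagging efficiency alpha, post-labeling delay
#' at the first slice omega (ms), labeling pulse duration tau (ms), and the
#' per-slice timing increment (ms) for 2D readouts.
#'
#' @param lambda ml/g, default 0.9.
#' @param r1a 1/s, default 0.67.
#' @param alpha tagging efficiency in (0, 1], default 0.8.
#' @param omegaMs post-labeling delay at slice 1, ms, default 1800.
#' @param tauMs labeling duration, ms, default 1508.
#' @param sliceTimeMs additional delay per slice index, ms, default 0.
#' @return named list of constants.
#' @export
aslConstants <- function(lambda = 0.9, r1a = 0.67, alpha = 0.8,
                         omegaMs = 1800, tauMs = 1508, sliceTimeMs = 0) {
  stopifnot(lambda > 0, r1a > 0, alpha > 0, alpha <= 1,
            omegaMs > 0, tauMs > 0, sliceTimeMs >= 0)
  list(lambda = lambda, r1a = r1a, alpha = alpha,
       omegaMs = omegaMs, tauMs = tauMs, sliceTimeMs = sliceTimeMs)
}

#' Zero out low-intensity voxels
#'
#' Voxels whose temporal mean falls below \code{factor} times the global
#' mean intensity are set to zero in every frame, removing spurious
#' out-of-brain signal before quantification.
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param factor threshold as a fraction of the global mean, default 0.8.
#' @return a \linkS4class{FrameSeries} with low-intensity voxels zeroed.
#' @export
maskLowIntensity <- function(series, factor = 0.8) {
  arr <- frameData(series)
  meanImg <- apply(arr, 1:3, mean)
  keep <- meanImg >= factor * mean(meanImg)
  arr <- arr * as.numeric(keep)[slice.index(arr, 1:3)]
  new("FrameSeries", data = arr, frameTimes = frameTimes(series),
      unit = series@unit, affine = series@affine)
}

#' Control-frame indices of an alternating ASL series
#'
#' @param nFrames number of frames.
#' @param parity "control-first" (odd frames are non-labeled) or
#'   "label-first".
#' @return integer vector of control (non-labeled) frame indices.
#' @export
controlFrames <- function(nFrames, parity = c("control-first", "label-first")) {
  parity <- match.arg(parity)
  if (parity == "control-first") seq(1L, nFrames, 2L) else seq(2L, nFrames, 2L)
}

#' Equilibrium magnetization M0
#'
#' Voxel-wise average over the non-labeled (control) frames only.
#'
#' @param series a \linkS4class{FrameSeries} of alternating control/label
#'   frames.
#' @param parity which frames are non-labeled; see \code{\link{controlFrames}}.
#' @return 3D numeric array.
#' @export
computeM0 <- function(series, parity = "control-first") {
  ctrl <- controlFrames(nFrames(series), parity)
  if (!length(ctrl)) stop("no control frames")
  arr <- frameData(series)[, , , ctrl, drop = FALSE]
  apply(arr, 1:3, mean)
}

aslDenominator <- function(constants, sliceIndex) {
  omega <- (constants$omegaMs + (sliceIndex - 1) * constants$sliceTimeMs) / 1000
  tau <- constants$tauMs / 1000
  exp(-omega * constants$r1a) - exp(-(tau + omega) * constants$r1a)
}

#' CBF from the control-label difference
#'
#' Single-compartment quantification:
#' CBF = lambda * dM * R1a / (2 alpha M0 [exp(-omega R1a) -
#' exp(-(tau + omega) R1a)]), with all times in seconds and the
#' post-labeling delay omega increased per slice for 2D readouts.
#' The result is rescaled from ml/g/s to ml/100g/min (x 6000). Voxels with
#' M0 = 0 are returned as 0 (masked).
#'
#' @param dm control - label difference (same shape as \code{m0}).
#' @param m0 equilibrium magnetization.
#' @param constants from \code{\link{aslConstants}}.
#' @param sliceIndex slice number (scalar, or per-slice vector matched to
#'   the 3rd array axis when \code{dm} is 3D).
#' @return CBF in ml/100g/min, same shape as \code{dm}.
#' @examples
#' cbfFromDeltaM(0.01, 1)  # ~118.75 ml/100g/min at default constants
#' @export
cbfFromDeltaM <- function(dm, m0, constants = aslConstants(), sliceIndex = 1) {
  if (length(sliceIndex) > 1L) {
    stopifnot(length(dim(dm)) == 3L, length(sliceIndex) == dim(dm)[3])
    den <- aslDenominator(constants, sliceIndex)[slice.index(dm, 3)]
  } else {
    den <- aslDenominator(constants, sliceIndex)
  }
  cbf <- ifelse(m0 > 0,
                constants$lambda * dm * constants$r1a /
                  (2 * constants$alpha * m0 * den),
                0)
  cbf * 6000
}

#' Invert the CBF equation for the expected control-label difference
#'
#' Solves the single-compartment equation for dM at a given CBF and M0;
#' used by the synthetic generator and for round-trip validation.
#'
#' @param cbf ml/100g/min.
#' @param m0 equilibrium magnetization.
#' @inheritParams cbfFromDeltaM
#' @return dM in the units of m0.
#' @export
deltaMFromCbf <- function(cbf, m0, constants = aslConstants(), sliceIndex = 1) {
  if (any(cbf < 0)) stop("CBF must be non-negative")
  den <- aslDenominator(constants, sliceIndex)
  (cbf / 6000) * 2 * constants$alpha * m0 * den /
    (constants$lambda * constants$r1a)
}

#' Condition-wise CBF maps with rest subtraction
#'
#' For each condition the alternating series is split into control/label
#' pairs, the pairwise difference (control - label) is quantified with
#' \code{\link{cbfFromDeltaM}} using the pair-mean M0 of the condition, and
#' the per-pair CBF maps are averaged. Task maps additionally have the
#' rest map subtracted (task maps acquired during performance contain
#' resting perfusion plus the task effect).
#'
#' @param seriesList named list of \linkS4class{FrameSeries}, one per
#'   condition; must contain an entry named \code{restName}.
#' @param constants from \code{\link{aslConstants}}.
#' @param parity frame parity, see \code{\link{controlFrames}}.
#' @param restName name of the rest condition, default "rest".
#' @param maskFactor low-intensity masking factor applied per series
#'   (NULL to skip).
#' @return list with per-condition \code{cbf} maps and \code{taskDelta}
#'   maps (task - rest) for the non-rest conditions.
#' @export
conditionCbf <- function(seriesList, constants = aslConstants(),
                         parity = "control-first", restName = "rest",
                         maskFactor = NULL) {
  stopifnot(restName %in% names(seriesList))
  nz <- dim(frameData(seriesList[[1]]))[3]
  sliceIdx <- seq_len(nz)
  cbf <- lapply(seriesList, function(series) {
    if (!is.null(maskFactor)) series <- maskLowIntensity(series, maskFactor)
    n <- nFrames(series)
    if (n %% 2L != 0L) stop("odd frame count: incomplete control/label pair")
    ctrl <- controlFrames(n, parity)
    lab <- setdiff(seq_len(n), ctrl)
    arr <- frameData(series)
    m0 <- computeM0(series, parity)
    dmMean <- apply(arr[, , , ctrl, drop = FALSE], 1:3, mean) -
      apply(arr[, , , lab, drop = FALSE], 1:3, mean)
    cbfFromDeltaM(dmMean, m0, constants, sliceIdx)
  })
  taskDelta <- lapply(cbf[setdiff(names(cbf), restName)],
                      function(m) m - cbf[[restName]])
  list(cbf = cbf, taskDelta = taskDelta)
}
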