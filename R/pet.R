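#' Assemble the arterial input function
#'
#' Whole-blood activities are linearly interpolated to the PET frame
#' mid-times (held at the nearest sample beyond the sampled range) and
#' multiplied by the subject's mean plasma-to-whole-blood ratio. The
#' cumulative integral is computed by the trapezoid rule from time zero,
#' holding the first interpolated value backwards to t = 0.
#'
#' @param samples data.frame with columns time_min, wholeblood, plasma
#'   (kBq/ml), as returned by \code{\link{readBloodSamples}}.
#' @param frameTimesMin PET frame mid-times in minutes.
#' @return An \linkS4class{InputFunction}.
#' @examples
#' s <- data.frame(time_min = c(0, 10), wholeblood = c(0, 20),
#'                 plasma = c(0, 20))
#' aif <- assembleInputFunction(s, frameTimesMin = seq(0.25, 9.75, 0.5))
#' plasmaActivity(aif)[10]  # 10 kBq/ml at ~5 min
#' @export
assembleInputFunction <- function(samples, frameTimesMin) {
  if (nrow(samples) < 2L) stop("need at least 2 blood samples")
  if (is.unsorted(samples$time_min, strictly = TRUE))
    stop("blood sample times must be strictly increasing")
  ok <- samples$wholeblood > 0
  if (!any(ok)) stop("all whole-blood activities are zero")
  ratio <- mean(samples$plasma[ok] / samples$wholeblood[ok])
  wb <- stats::approx(samples$time_min, samples$wholeblood,
                      xout = frameTimesMin, rule = 2)$y
  cp <- wb * ratio
  # integral from 0: prepend t = 0 holding the first value
  tt <- c(0, frameTimesMin)
  yy <- c(cp[1], cp)
  ci <- pracma::cumtrapz(tt, yy)[-1]
  new("InputFunction", frameTimesMin = as.numeric(frameTimesMin),
      cp = as.numeric(cp), cumInt = as.numeric(ci))
}

#' Baseline regressor from the gray matter mean time course
#'
#' Frame-wise mean over gray matter voxels, excluding voxels in an
#' exclusion mask (typically those activated during the hard task in the
#' subject's BOLD block design).
#'
#' @param pet a \linkS4class{FrameSeries} of PET frames.
#' @param gmMask logical array marking gray matter.
#' @param exclusionMask optional logical array of voxels to exclude.
#' @return numeric vector, one value per frame (kBq/ml).
#' @export
buildBaselineRegressor <- function(pet, gmMask, exclusionMask = NULL) {
  stopGrid(pet, gmMask)
  incl <- as.logical(gmMask)
  if (!is.null(exclusionMask)) {
    stopGrid(pet, exclusionMask)
    incl <- incl & !as.logical(exclusionMask)
  }
  if (!any(incl)) stop("no voxels left after exclusion")
  rowMeans(timeCourses(pet, incl))
}

#' Build the fPET GLM design
#'
#' Four regressors: the baseline time course, one linear ramp per task
#' condition (slope 1 kBq per frame within task blocks, flat elsewhere,
#' cumulative across repeated blocks), and the first principal component
#' of the six motion parameters.
#'
#' @param frameTimesMin PET frame mid-times (minutes).
#' @param baseline per-frame baseline regressor
#'   (\code{\link{buildBaselineRegressor}}).
#' @param taskBlocks named list, one entry per condition, each a 2-column
#'   matrix of block (start, end) times in minutes.
#' @param motion optional frames x 6 motion matrix; its first principal
#'   component is added as a nuisance column.
#' @return list with \code{X} (design matrix) and \code{taskCols}
#'   (names of the task columns).
#' @export
fpetDesign <- function(frameTimesMin, baseline, taskBlocks, motion = NULL) {
  n <- length(frameTimesMin)
  stopifnot(length(baseline) == n)
  X <- cbind(baseline = baseline)
  for (cond in names(taskBlocks)) {
    blocks <- taskBlocks[[cond]]
    inTask <- rep(FALSE, n)
    for (b in seq_len(nrow(blocks)))
      inTask <- inTask | (frameTimesMin >= blocks[b, 1] &
                          frameTimesMin < blocks[b, 2])
    ramp <- cumsum(as.numeric(inTask))  # +1 per task frame
    X <- cbind(X, ramp)
    colnames(X)[ncol(X)] <- cond
  }
  if (!is.null(motion)) {
    stopifnot(nrow(motion) == n, ncol(motion) == 6L)
    pc1 <- stats::prcomp(motion, center = TRUE, scale. = FALSE)$x[, 1]
    X <- cbind(X, motion = pc1)
  }
  list(X = X, taskCols = names(taskBlocks))
}

#' Moving-average low-pass filter for PET time-activity curves
#'
#' Centered moving average whose window spans the cutoff period
#' (default 3 min = 6 frames of 30 s); edges use shrinking windows so a
#' constant series is left exactly unchanged.
#'
#' @param y numeric vector or frames x voxels matrix.
#' @param width window width in frames.
#' @return filtered object of the same shape.
#' @export
lowpassTac <- function(y, width = 6L) {
  smooth1 <- function(v) {
    n <- length(v)
    half <- width %/% 2
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      out[i] <- mean(v[lo:hi])
    }
    out
  }
  if (is.matrix(y)) apply(y, 2, smooth1) else smooth1(y)
}

#' Fit the fPET general linear model
#'
#' Separates baseline from task-specific uptake: time-activity curves are
#' low-pass filtered, then regressed per voxel by ordinary least squares on
#' the design from \code{\link{fpetDesign}}.
#'
#' @param pet \linkS4class{FrameSeries} of PET frames (kBq/ml), or a
#'   frames x voxels matrix.
#' @param design list from \code{\link{fpetDesign}}.
#' @param lowpassCutoffMin low-pass cutoff in minutes (window of the
#'   moving-average filter).
#' @param frameLenMin frame length in minutes (default 0.5 = 30 s).
#' @param mask optional logical array restricting the fit.
#' @return list with \code{beta} (coefficients x voxels matrix),
#'   \code{taskBeta} (task coefficients, kBq/ml per ramp unit),
#'   \code{baselineTac} (baseline-only reconstruction, frames x voxels),
#'   and \code{filtered} (the filtered TACs).
#' @export
fitFpetGlm <- function(pet, design, lowpassCutoffMin = 3,
                       frameLenMin = 0.5, mask = NULL) {
  Y <- if (is(pet, "FrameSeries")) timeCourses(pet, mask) else as.matrix(pet)
  X <- design$X
  stopifnot(nrow(Y) == nrow(X))
  width <- max(1L, round(lowpassCutoffMin / frameLenMin))
  # same linear filter on data and regressors, so noise-free combinations
  # of the design columns are recovered exactly
  Yf <- lowpassTac(Y, width)
  Xf <- apply(X, 2, lowpassTac, width = width)
  colnames(Xf) <- colnames(X)
  if (qr(Xf)$rank < ncol(Xf)) stop("rank-deficient fPET design")
  beta <- qr.coef(qr(Xf), Yf)
  beta[is.na(beta)] <- 0
  baselineTac <- outer(X[, "baseline"], beta["baseline", ])
  list(beta = beta,
       taskBeta = beta[design$taskCols, , drop = FALSE],
       baselineTac = baselineTac,
       filtered = Yf)
}

#' Patlak graphical analysis
#'
#' Least-squares line through the Patlak coordinates
#' X = integral(cp)/cp, Y = tac/cp restricted to frames at or after
#' \code{tStarMin}; the slope is the influx constant Ki (1/min) and the
#' intercept the distribution volume V0.
#'
#' @param tac tissue time-activity curve (kBq/ml), one value per frame, or
#'   a frames x voxels matrix for many voxels at once.
#' @param inputFunction an \linkS4class{InputFunction}.
#' @param tStarMin start of the Patlak linear phase in minutes (default 10).
#' @return For a vector tac, list(ki, v0); for a matrix, list of vectors.
#' @examples
#' tt <- seq(0.25, 51.75, 0.5)
#' cp <- rep(30, length(tt))
#' ci <- pracma::cumtrapz(c(0, tt), c(30, cp))[-1]
#' aif <- new("InputFunction", frameTimesMin = tt, cp = cp, cumInt = ci)
#' fit <- patlakKi(0.02 * ci + 0.05 * cp, aif)
#' fit$ki  # 0.02
#' @export
patlakKi <- function(tac, inputFunction, tStarMin = 10) {
  tt <- inputFunction@frameTimesMin
  sel <- tt >= tStarMin
  if (sum(sel) < 3L) stop("fewer than 3 frames after t*")
  cp <- inputFunction@cp[sel]
  if (any(cp <= 0)) stop("cp must be positive in the Patlak window")
  x <- inputFunction@cumInt[sel] / cp
  Y <- if (is.matrix(tac)) tac[sel, , drop = FALSE] else
    matrix(tac[sel], ncol = 1)
  Y <- sweep(Y, 1, cp, "/")
  X <- cbind(1, x)
  coef <- qr.coef(qr(X), Y)
  ki <- coef[2, ]
  v0 <- coef[1, ]
  if (ncol(Y) == 1L) list(ki = unname(ki[1]), v0 = unname(v0[1]))
  else list(ki = unname(ki), v0 = unname(v0))
}

#' Convert the Patlak influx constant to CMRGlu
#'
#' CMRGlu = Ki * Glu_plasma / LC * 100, yielding micromol/100g/min for Ki
#' in 1/min and plasma glucose in mmol/l; the lumped constant defaults
#' to 0.89.
#'
#' @param ki influx constant (1/min), scalar, vector or array.
#' @param gluPlasma plasma glucose (mmol/l).
#' @param lc lumped constant (> 0).
#' @return CMRGlu in micromol/100g/min, same shape as \code{ki}.
#' @examples
#' cmrgluFromKi(0.0178, 5.45)  # ~10.9
#' @export
cmrgluFromKi <- function(ki, gluPlasma, lc = 0.89) {
  if (lc <= 0) stop("lumped constant must be positive")
  ki * gluPlasma / lc * 100
}

#' Condition-specific influx from task GLM coefficients
#'
#' Composes the baseline Patlak slope with the task ramp coefficient: the
#' ramp rises 1 unit per frame, so a coefficient beta (kBq/ml per ramp
#' unit) is an uptake rate beta/frameLenMin kBq/ml/min, and the task
#' increment to Ki is that rate divided by the mean plasma activity over
#' the task window.
#'
#' @param kiBase baseline influx constant (1/min).
#' @param taskBeta task ramp coefficient (kBq/ml per frame).
#' @param inputFunction an \linkS4class{InputFunction}.
#' @param taskFrames integer or logical index of frames within the task
#'   blocks.
#' @param frameLenMin frame length in minutes.
#' @return condition-specific Ki (1/min), same shape as inputs.
#' @export
conditionKi <- function(kiBase, taskBeta, inputFunction, taskFrames,
                        frameLenMin = 0.5) {
  cpTask <- mean(inputFunction@cp[taskFrames])
  if (cpTask <= 0) stop("mean plasma activity over the task window must be positive")
  kiBase + taskBeta / (frameLenMin * cpTask)
}
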