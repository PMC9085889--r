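#' Framewise displacement
#'
#' Power-style summary of head motion per frame: L1 sum of backward
#' differences of the three translations (mm) plus the three rotations
#' converted to displacement on a 50 mm sphere. The first frame has no
#' predecessor and is assigned 0.
#'
#' @param motion frames x 6 matrix: translations x/y/z in mm, rotations
#'   x/y/z in radians.
#' @param radiusMm sphere radius for the rotation-to-mm conversion.
#' @return numeric vector of FD values (mm), one per frame.
#' @export
framewiseDisplacement <- function(motion, radiusMm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6L, nrow(motion) >= 2L, all(is.finite(motion)))
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radiusMm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion scrubbing
#'
#' Frames whose FD exceeds the threshold are censored together with one
#' frame back and two forward (clipped at the series bounds).
#'
#' @param fd framewise displacement per frame (mm).
#' @param threshold censoring threshold (mm), default 0.5.
#' @return list with \code{fd}, logical \code{kept}, and
#'   \code{pctRemoved} (percent of frames censored).
#' @examples
#' scrub(c(0, .1, .6, .1, .1, .1))$kept  # only frames 1 and 6 survive
#' @export
scrub <- function(fd, threshold = 0.5) {
  n <- length(fd)
  kept <- rep(TRUE, n)
  for (t in which(fd > threshold)) {
    lo <- max(1L, t - 1L)
    hi <- min(n, t + 2L)
    kept[lo:hi] <- FALSE
  }
  list(fd = fd, kept = kept, pctRemoved = 100 * (1 - mean(kept)))
}

#' Nuisance regression and bandpass filtering of BOLD series
#'
#' Censored frames are dropped, nuisance signals (motion parameters, white
#' matter and CSF means, plus an intercept) are removed by least squares,
#' and a zero-phase Butterworth bandpass (two second-order passes via
#' filtfilt, default 0.01-0.15 Hz) is applied to the retained, re-indexed
#' series.
#'
#' @param bold \linkS4class{FrameSeries} or frames x voxels matrix.
#' @param kept logical vector of retained frames (from \code{\link{scrub}});
#'   NULL keeps all.
#' @param nuisance frames x k matrix of confound series (full length; rows
#'   are subset by \code{kept}), or NULL.
#' @param band bandpass edges in Hz; NULL skips filtering.
#' @param tr repetition time in seconds.
#' @param mask optional logical array restricting voxels (FrameSeries input).
#' @return list with \code{data} (cleaned frames x voxels matrix over the
#'   retained frames) and \code{kept}.
#' @export
cleanTimeseries <- function(bold, kept = NULL, nuisance = NULL,
                            band = c(0.01, 0.15), tr = 2, mask = NULL) {
  Y <- if (is(bold, "FrameSeries")) timeCourses(bold, mask) else as.matrix(bold)
  n <- nrow(Y)
  if (is.null(kept)) kept <- rep(TRUE, n)
  stopifnot(length(kept) == n)
  Y <- Y[kept, , drop = FALSE]
  if (nrow(Y) < 20L) stop("fewer than 20 frames retained")
  X <- matrix(1, nrow(Y), 1)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n)
    X <- cbind(X, nuisance[kept, , drop = FALSE])
  }
  Y <- Y - X %*% qr.coef(qr(X), Y)
  if (!is.null(band)) {
    fs <- 1 / tr
    wc <- band / (fs / 2)
    stopifnot(wc[1] > 0, wc[2] < 1)
    bf <- signal::butter(2, wc, type = "pass")
    Y <- apply(Y, 2, function(v) signal::filtfilt(bf, v))
  }
  list(data = Y, kept = kept)
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style difference of two gamma densities (peak 6 s, undershoot 16 s,
#' undershoot ratio 1/6), sampled at the given times.
#'
#' @param t time in seconds (vector).
#' @return HRF values, peak-normalized to 1.
#' @export
canonicalHrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Block-design GLM activation t-maps
#'
#' Boxcar regressors per condition are convolved with the canonical HRF
#' and fitted voxel-wise by ordinary least squares; per-voxel t-statistics
#' are returned for each requested contrast (rows of weights over the
#' condition columns).
#'
#' @param bold \linkS4class{FrameSeries} or frames x voxels matrix.
#' @param blocks named list, one entry per condition, each a 2-column
#'   matrix of (onset, end) times in seconds.
#' @param tr repetition time (s).
#' @param contrasts named list of numeric contrast vectors over the
#'   conditions (in \code{names(blocks)} order); default easy - control
#'   style pairwise contrasts must be supplied by the caller.
#' @param mask optional logical array (FrameSeries input).
#' @return list with \code{t} (contrast x voxels matrix of t-values),
#'   \code{beta}, and \code{df}.
#' @export
blockGlm <- function(bold, blocks, tr = 2, contrasts, mask = NULL) {
  Y <- if (is(bold, "FrameSeries")) timeCourses(bold, mask) else as.matrix(bold)
  n <- nrow(Y)
  tt <- tr * (seq_len(n) - 1)
  hrfT <- seq(0, 32, by = tr)
  h <- canonicalHrf(hrfT)
  Xc <- sapply(names(blocks), function(cond) {
    box <- rep(0, n)
    b <- blocks[[cond]]
    for (i in seq_len(nrow(b)))
      box[tt >= b[i, 1] & tt < b[i, 2]] <- 1
    stats::convolve(box, rev(h), type = "open")[seq_len(n)]
  })
  X <- cbind(1, Xc)
  colnames(X) <- c("intercept", names(blocks))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient block design")
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  tmat <- t(sapply(names(contrasts), function(cn) {
    cvec <- c(0, contrasts[[cn]])  # no weight on the intercept
    se <- sqrt(pmax(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec), 1e-300))
    drop(cvec %*% beta) / se
  }))
  list(t = tmat, beta = beta, df = df)
}
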