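#' Configuration of a synthetic PET/MR learning study
#'
#' Bundles every constant of the simulated study: grid geometry, frame
#' schedules, group sizes, the planted FC-CMRGlu coupling per
#' (group, time, condition) cell, kinetic and perfusion ground truth,
#' behavioral fold changes, and noise levels. Defaults mirror the study
#' shape the analysis assumes: 21 training / 20 control subjects, two
#' scans (M1, M2), three conditions (rest, easy, hard), 30-s PET frames
#' over 52 min, 2-s BOLD frames over 6 min.
#'
#' The default coupling plants the training effect of interest: at the
#' second scan the training group's rest coupling rises (0.30 to 0.55)
#' and its hard-task coupling falls (0.30 to 0.12); the control group and
#' the easy condition stay at baseline.
#'
#' @param gridShape voxel counts per axis.
#' @param nFramesBold,trBold continuous BOLD frames and TR (s).
#' @param nFramesPet,frameLenPet PET frame count and frame length (s).
#' @param nFramesAsl ASL frames (alternating control/label; must be even).
#' @param trAsl ASL repetition time (s).
#' @param nSubjects named vector c(training=, control=).
#' @param coupling 2 x 2 x 3 array (group x time x condition) of planted
#'   coupling strengths in [0, 1]; NULL builds the default described above.
#' @param kiMean,kiSd mean/sd of the background per-voxel influx constant
#'   (1/min).
#' @param kiTargetBase,kiTargetGain the target region's Ki pattern is
#'   base + gain * w_v over the seed-influence weights w_v.
#' @param gluPlasma plasma glucose (mmol/l).
#' @param lc lumped constant.
#' @param cbfRest,cbfEasy,cbfHard true CBF per condition (ml/100g/min);
#'   task values apply within the activation region, rest elsewhere.
#' @param foldChangeEasy,foldChangeHard behavioral fold changes of the
#'   training group between scans.
#' @param cmrgluNoiseSd relative noise of subject CMRGlu patterns.
#' @param seedRegionNoiseSd noise mixed into seed-region BOLD series.
#' @param aslNoiseSd additive noise of ASL frames (M0 units).
#' @param petNoiseSd additive TAC noise (kBq/ml); 0 = noise-free.
#' @param behaviorCv coefficient of variation of behavioral scores.
#' @param plasmaToWholeBloodRatio constant plasma/whole-blood ratio.
#' @param couplingMode "uniform" applies each cell's coupling to every
#'   target voxel; "focal" plants the cell-specific coupling only in the
#'   effect subset — the half of the target with the lowest true CMRGlu —
#'   while the remaining voxels stay at \code{backgroundRho} in every
#'   cell. The focal mode is the configuration of the voxel-removal
#'   perturbation experiment, where the training effect must reside in
#'   the low-CMRGlu (equivalently low-FC) part of the target.
#' @param backgroundRho coupling of non-effect voxels in focal mode.
#' @param nSpikes motion spikes injected per run.
#' @param tStarMin Patlak linear-phase start carried to the analysis.
#' @param seed RNG seed; a fixed seed makes the whole study bit-identical.
#' @return list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(gridShape = c(24, 24, 12),
                            nFramesBold = 180, trBold = 2,
                            nFramesPet = 104, frameLenPet = 30,
                            nFramesAsl = 88, trAsl = 4.06,
                            nSubjects = c(training = 21, control = 20),
                            coupling = NULL,
                            kiMean = 0.018, kiSd = 0.002,
                            kiTargetBase = 0.016, kiTargetGain = 0.006,
                            gluPlasma = 5.45, lc = 0.89,
                            cbfRest = 60, cbfEasy = 66, cbfHard = 72,
                            foldChangeEasy = 2.7, foldChangeHard = 3.1,
                            cmrgluNoiseSd = 0.04,
                            seedRegionNoiseSd = 0.3,
                            aslNoiseSd = 2,
                            petNoiseSd = 0,
                            behaviorCv = 0.2,
                            plasmaToWholeBloodRatio = 1.0,
                            couplingMode = c("uniform", "focal"),
                            backgroundRho = 0.3,
                            nSpikes = 2,
                            tStarMin = 10,
                            seed = 1) {
  couplingMode <- match.arg(couplingMode)
  if (is.null(coupling)) {
    base <- if (couplingMode == "uniform") 0.3 else 0.25
    coupling <- array(base, c(2, 2, 3),
                      dimnames = list(group = c("training", "control"),
                                      time = c("M1", "M2"),
                                      condition = c("rest", "easy", "hard")))
    coupling["training", "M2", "rest"] <- if (couplingMode == "uniform")
      0.55 else 0.6
    coupling["training", "M2", "hard"] <- if (couplingMode == "uniform")
      0.12 else 0
  }
  cfg <- list(gridShape = gridShape, nFramesBold = nFramesBold,
              trBold = trBold, nFramesPet = nFramesPet,
              frameLenPet = frameLenPet, nFramesAsl = nFramesAsl,
              trAsl = trAsl, nSubjects = nSubjects, coupling = coupling,
              kiMean = kiMean, kiSd = kiSd, kiTargetBase = kiTargetBase,
              kiTargetGain = kiTargetGain, gluPlasma = gluPlasma, lc = lc,
              cbfRest = cbfRest, cbfEasy = cbfEasy, cbfHard = cbfHard,
              foldChangeEasy = foldChangeEasy,
              foldChangeHard = foldChangeHard,
              cmrgluNoiseSd = cmrgluNoiseSd,
              seedRegionNoiseSd = seedRegionNoiseSd,
              aslNoiseSd = aslNoiseSd, petNoiseSd = petNoiseSd,
              behaviorCv = behaviorCv,
              plasmaToWholeBloodRatio = plasmaToWholeBloodRatio,
              couplingMode = couplingMode, backgroundRho = backgroundRho,
              nSpikes = nSpikes, tStarMin = tStarMin, seed = seed)
  class(cfg) <- "SyntheticConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  counts <- c(cfg$gridShape, cfg$nFramesBold, cfg$nFramesPet,
              cfg$nFramesAsl, cfg$nSubjects)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$nFramesAsl %% 2 != 0) stop("nFramesAsl must be even")
  if (any(cfg$coupling < 0 | cfg$coupling > 1))
    stop("coupling strengths must lie in [0, 1]")
  if (any(c(cfg$cbfRest, cfg$cbfEasy, cfg$cbfHard) < 0))
    stop("CBF must be non-negative")
  geom <- studyGeometry(cfg$gridShape)
  if (sum(geom$target) < 2) stop("degenerate grid: fewer than 2 target voxels")
  invisible(cfg)
}

#' Region geometry of the synthetic study
#'
#' Axis-aligned cuboid target ("Occ"-like) and a disjoint seed region
#' ("SN"-like), scaled to the grid; the activation mask (task-responsive
#' voxels across modalities) equals the target region.
#'
#' @param gridShape voxel counts per axis.
#' @return list of logical arrays: target, seed, brain, activation.
#' @export
studyGeometry <- function(gridShape) {
  d <- gridShape
  mk <- function(xr, yr, zr) {
    a <- array(FALSE, d)
    a[xr, yr, zr] <- TRUE
    a
  }
  clampSeq <- function(lo, hi, n) seq(max(1, min(lo, n)), max(1, min(hi, n)))
  target <- mk(clampSeq(round(d[1] * 0.2), round(d[1] * 0.45), d[1]),
               clampSeq(round(d[2] * 0.2), round(d[2] * 0.35), d[2]),
               clampSeq(round(d[3] * 0.3), round(d[3] * 0.6), d[3]))
  seed <- mk(clampSeq(round(d[1] * 0.6), round(d[1] * 0.75), d[1]),
             clampSeq(round(d[2] * 0.6), round(d[2] * 0.75), d[2]),
             clampSeq(round(d[3] * 0.45), round(d[3] * 0.75), d[3]))
  if (any(target & seed)) stop("target and seed regions overlap")
  brain <- array(TRUE, d)
  list(target = target, seed = seed, brain = brain, activation = target)
}

#' PET task schedule of the synthetic study
#'
#' Baseline, then alternating 6-min easy/hard blocks separated by 5-min
#' rests, within the 52-min scan.
#'
#' @return named list of 2-column (start, end) matrices in minutes.
#' @export
petTaskBlocks <- function() {
  list(easy = rbind(c(10, 16), c(32, 38)),
       hard = rbind(c(21, 27), c(43, 49)))
}

bloodSampleTimesMin <- c(3, 4, 5, 14, 25, 36, 47)

makeGroundTruth <- function(cfg) {
  geom <- studyGeometry(cfg$gridShape)
  m <- sum(geom$target)
  w <- stats::runif(m, 0.3, 1)
  kiMap <- array(stats::rnorm(prod(cfg$gridShape), cfg$kiMean, cfg$kiSd),
                 cfg$gridShape)
  kiMap[kiMap < 1e-4] <- 1e-4
  kiMap[geom$target] <- cfg$kiTargetBase + cfg$kiTargetGain * w
  cmrgluMap <- cmrgluFromKi(kiMap, cfg$gluPlasma, cfg$lc)
  effectVox <- if (cfg$couplingMode == "focal") {
    g <- cmrgluMap[geom$target]
    order(g, seq_along(g))[seq_len(floor(length(g) / 2))]
  } else seq_along(w)
  list(geometry = geom, w = w, kiTrue = kiMap, cmrgluTrue = cmrgluMap,
       cbfTrue = c(rest = cfg$cbfRest, easy = cfg$cbfEasy,
                   hard = cfg$cbfHard),
       couplingTrue = cfg$coupling, effectVox = effectVox)
}

# per-target-voxel coupling for one design cell
cellRho <- function(cfg, truth, group, time, condition) {
  rho <- cfg$coupling[group, time, condition]
  if (cfg$couplingMode == "uniform") return(rho)
  out <- rep(cfg$backgroundRho, length(truth$w))
  out[truth$effectVox] <- rho
  out
}

#' Generate one subject-session BOLD record at cluster level
#'
#' Target-region voxels follow
#' s_v(t) = rho * w_v * u(t) + sqrt(1 - rho^2 w_v^2) * e_v(t)
#' with u a shared latent seed series, so the FC pattern across target
#' voxels is proportional to rho * w_v; seed-region voxels carry u plus
#' noise. Used by both the fast study simulator and the image generator.
#' @noRd
genBoldRecord <- function(cfg, w, rho, nSeedVox) {
  n <- cfg$nFramesBold
  m <- length(w)
  u <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * m), n, m)
  lam <- rho * w  # rho scalar or per-voxel vector
  targetTs <- sweep(eps, 2, sqrt(1 - lam^2), "*") +
    outer(u, lam)
  sn <- cfg$seedRegionNoiseSd
  clusterTs <- (matrix(u, n, nSeedVox) +
                  sn * matrix(stats::rnorm(n * nSeedVox), n, nSeedVox)) /
    sqrt(1 + sn^2)
  list(u = u, targetTs = targetTs, clusterTs = clusterTs)
}

genCmrgluPattern <- function(cfg, truth) {
  g0 <- truth$cmrgluTrue[truth$geometry$target]
  g0 * (1 + cfg$cmrgluNoiseSd * stats::rnorm(length(g0)))
}

#' Fast cluster-level synthetic study
#'
#' Generates, for every subject x scan x condition cell, the BOLD time
#' courses of the seed cluster and the target region plus a subject-level
#' CMRGlu pattern over the target, with the configured coupling planted.
#' This compact representation carries exactly what the MCM group analysis
#' and the perturbation simulation consume, at a fraction of the cost of
#' full 4D volumes; behavioral tables are included.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list of class "McmStudy": \code{design} (data.frame with one
#'   row per record), \code{records} (list of targetTs, clusterTs, cmrglu),
#'   \code{behavior}, \code{truth}, \code{config}.
#' @export
simulateMcmStudy <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  truth <- makeGroundTruth(config)
  nSeedVox <- sum(truth$geometry$seed)
  groups <- rep(names(config$nSubjects), config$nSubjects)
  subjects <- sprintf("sub%02d", seq_along(groups))
  design <- expand.grid(condition = dimnames(config$coupling)$condition,
                        time = dimnames(config$coupling)$time,
                        subject = subjects, stringsAsFactors = FALSE)
  design$group <- groups[match(design$subject, subjects)]
  design <- design[, c("subject", "group", "time", "condition")]
  records <- vector("list", nrow(design))
  couplingTrue <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    couplingTrue[i] <- config$coupling[design$group[i], design$time[i],
                                       design$condition[i]]
    rho <- cellRho(config, truth, design$group[i], design$time[i],
                   design$condition[i])
    b <- genBoldRecord(config, truth$w, rho, nSeedVox)
    records[[i]] <- list(targetTs = b$targetTs, clusterTs = b$clusterTs,
                         cmrglu = genCmrgluPattern(config, truth))
  }
  design$couplingTrue <- couplingTrue
  behavior <- generateBehavior(config)
  out <- list(design = design, records = records, behavior = behavior,
              truth = truth, config = config)
  class(out) <- "McmStudy"
  out
}

#' Cluster-level MCM values for every record of a study
#'
#' For each subject x scan x condition record: the Fisher-z FC pattern of
#' every seed-cluster voxel over the target region, spatially correlated
#' with the record's CMRGlu pattern; the record's MCM value is the mean
#' Fisher-z over cluster voxels.
#'
#' @param study from \code{\link{simulateMcmStudy}}.
#' @param targetKeep optional integer index of retained target voxels
#'   (perturbation support); default all.
#' @return the study design data.frame with an added \code{mcm} column.
#' @export
clusterMcm <- function(study, targetKeep = NULL) {
  design <- study$design
  design$mcm <- vapply(seq_len(nrow(design)), function(i) {
    rec <- study$records[[i]]
    Z <- fcPatternMatrix(rec$clusterTs, rec$targetTs)
    idx <- if (is.null(targetKeep)) seq_len(ncol(Z)) else targetKeep
    if (length(idx) < 4L) stop("fewer than 4 target voxels retained")
    mean(fisherZ(rowCorSubset(Z, rec$cmrglu, idx)))
  }, numeric(1))
  design
}

# Fisher-z correlation of each column of S (sources, frames x k) with each
# column of T (targets, frames x m); returns k x m.
fcPatternMatrix <- function(S, T) {
  n <- nrow(S)
  Ss <- scale(S); Ts <- scale(T)
  bad <- attr(Ts, "scaled:scale") == 0
  R <- crossprod(Ss, Ts) / (n - 1)
  Z <- fisherZ(R)
  if (any(bad)) Z[, bad] <- 0
  Z
}

# Row-wise Pearson correlation of Z[, idx] with g[idx].
rowCorSubset <- function(Z, g, idx) {
  Zs <- Z[, idx, drop = FALSE]
  Zc <- Zs - rowMeans(Zs)
  gc <- g[idx] - mean(g[idx])
  den <- sqrt(rowSums(Zc^2) * sum(gc^2))
  r <- drop(Zc %*% gc) / pmax(den, 1e-300)
  r[den == 0] <- 0
  r
}

#' Synthetic fPET frames and arterial samples for one subject-session
#'
#' The plasma input follows a bolus (gamma-variate rise with exponential
#' washout) onto a constant infusion plateau. Tissue curves obey the
#' Patlak relation Ct = Ki * integral(Cp) + V0 * Cp, with an additional
#' linear task ramp (slope beta kBq/ml per frame) in activation-region
#' voxels during task blocks. Arterial samples are drawn at 3, 4, 5, 14,
#' 25, 36 and 47 min.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param truth ground truth from the generating study (list with kiTrue
#'   and geometry); NULL builds one from the config.
#' @param v0 distribution-volume intercept.
#' @param taskBeta named vector of task ramp amplitudes (kBq/ml per frame)
#'   applied to activation voxels, scaled by the target weights.
#' @return list with \code{pet} (\linkS4class{FrameSeries}, kBq/ml),
#'   \code{aif} (the dense per-frame \linkS4class{InputFunction}),
#'   \code{blood} (7-row sample table), \code{frameTimesMin}.
#' @export
generateFpetTacs <- function(config, truth = NULL, v0 = 0.05,
                             taskBeta = c(easy = 0.15, hard = 0.25)) {
  if (is.null(truth)) {
    set.seed(config$seed)
    truth <- makeGroundTruth(config)
  }
  n <- config$nFramesPet
  dtMin <- config$frameLenPet / 60
  tt <- dtMin * (seq_len(n) - 0.5)
  plateau <- 30
  cp <- plateau * (1 - exp(-tt / 0.8)) + 180 * tt * exp(-tt / 0.6)
  ci <- pracma::cumtrapz(c(0, tt), c(cp[1], cp))[-1]
  aif <- new("InputFunction", frameTimesMin = tt, cp = cp, cumInt = ci)
  geom <- truth$geometry
  nv <- prod(config$gridShape)
  ki <- as.numeric(truth$kiTrue)
  Y <- outer(ci, ki) + v0 * matrix(cp, n, nv)
  blocks <- petTaskBlocks()
  actIdx <- which(geom$activation)
  wAct <- truth$kiTrue[geom$activation]
  wAct <- (wAct - min(wAct)) / max(diff(range(wAct)), 1e-12) * 0.5 + 0.5
  for (cond in names(taskBeta)) {
    inTask <- rep(FALSE, n)
    for (b in seq_len(nrow(blocks[[cond]])))
      inTask <- inTask | (tt >= blocks[[cond]][b, 1] &
                          tt < blocks[[cond]][b, 2])
    ramp <- cumsum(as.numeric(inTask))
    Y[, actIdx] <- Y[, actIdx] + outer(ramp, taskBeta[[cond]] * wAct)
  }
  if (config$petNoiseSd > 0)
    Y <- Y + stats::rnorm(length(Y), sd = config$petNoiseSd)
  arr <- array(t(Y), c(config$gridShape, n))
  ratio <- config$plasmaToWholeBloodRatio
  cpSamp <- stats::approx(tt, cp, xout = bloodSampleTimesMin, rule = 2)$y
  blood <- data.frame(time_min = bloodSampleTimesMin,
                      wholeblood = cpSamp / ratio,
                      plasma = cpSamp)
  list(pet = FrameSeries(arr, frameTimes = tt * 60, unit = "kBq/ml"),
       aif = aif, blood = blood, frameTimesMin = tt)
}

#' Synthetic ASL control/label series
#'
#' Alternating non-labeled/labeled frames around an equilibrium
#' magnetization of 1000, with the control-label difference obtained by
#' inverting the CBF quantification equation at the configured true CBF
#' (task conditions: elevated within the activation region).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param truth ground truth (NULL to build from config).
#' @param condition "rest", "easy" or "hard".
#' @param constants \code{\link{aslConstants}}.
#' @param m0 equilibrium magnetization level.
#' @return a \linkS4class{FrameSeries} (control-first parity).
#' @export
generateAslSeries <- function(config, truth = NULL, condition = "rest",
                              constants = aslConstants(), m0 = 1000) {
  if (is.null(truth)) {
    set.seed(config$seed)
    truth <- makeGroundTruth(config)
  }
  cbfMap <- array(config$cbfRest, config$gridShape)
  if (condition != "rest")
    cbfMap[truth$geometry$activation] <- truth$cbfTrue[[condition]]
  dm <- deltaMFromCbf(cbfMap, m0, constants)
  n <- config$nFramesAsl
  arr <- array(0, c(config$gridShape, n))
  for (f in seq_len(n)) {
    base <- if (f %% 2 == 1) m0 else m0 - dm
    arr[, , , f] <- base + if (config$aslNoiseSd > 0)
      stats::rnorm(prod(config$gridShape), sd = config$aslNoiseSd) else 0
  }
  FrameSeries(arr, tr = config$trAsl, unit = "a.u.")
}

#' Synthetic motion trace with injected spikes
#'
#' Slow random-walk drift (well below the scrubbing threshold) plus
#' isolated translation jumps of 1 mm at randomly placed frames, each
#' exceeding the 0.5 mm FD threshold exactly once.
#'
#' @param nFrames number of frames.
#' @param nSpikes number of injected spikes.
#' @param driftSdMm per-frame translation random-walk step (mm).
#' @param driftSdRad per-frame rotation random-walk step (rad); the
#'   default keeps drift FD well below the 0.5 mm scrubbing threshold.
#' @return list with \code{motion} (frames x 6 matrix) and
#'   \code{spikes} (frame indices of the injected jumps).
#' @export
generateMotion <- function(nFrames, nSpikes = 2, driftSdMm = 0.01,
                           driftSdRad = 1e-4) {
  steps <- cbind(matrix(stats::rnorm(nFrames * 3, sd = driftSdMm),
                        nFrames, 3),
                 matrix(stats::rnorm(nFrames * 3, sd = driftSdRad),
                        nFrames, 3))
  motion <- apply(steps, 2, cumsum)
  spikes <- integer()
  if (nSpikes > 0) {
    candidates <- seq(4L, nFrames - 3L)
    for (k in seq_len(nSpikes)) {
      if (!length(candidates)) break
      s <- sample(candidates, 1)
      spikes <- c(spikes, s)
      candidates <- setdiff(candidates, (s - 7L):(s + 7L))
    }
    for (s in spikes) motion[s:nFrames, 1] <- motion[s:nFrames, 1] + 1.0
  }
  list(motion = motion, spikes = sort(spikes))
}

#' Synthetic behavioral tables
#'
#' Per-scan score-per-minute tables for both groups and conditions (the
#' training group's M2/M1 group-mean ratio equals the configured fold
#' change in expectation; the control group is flat) and a saturating
#' exponential learning curve over 21 training days for the training
#' group.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{scans} (subject, group, scan, condition,
#'   scorePerMin) and \code{daily} (subject, day, scorePerMin), plus
#'   \code{truth} (per-subject baselines and curve parameters).
#' @export
generateBehavior <- function(config) {
  groups <- rep(names(config$nSubjects), config$nSubjects)
  subjects <- sprintf("sub%02d", seq_along(groups))
  mu <- c(easy = 30, hard = 10)
  folds <- c(easy = config$foldChangeEasy, hard = config$foldChangeHard)
  cv <- config$behaviorCv
  scans <- NULL
  curvePars <- list()
  daily <- NULL
  tau <- 6
  for (i in seq_along(subjects)) {
    for (cond in names(mu)) {
      s1 <- max(mu[[cond]] * (1 + cv * stats::rnorm(1)), 0.1 * mu[[cond]])
      fold <- if (groups[i] == "training") folds[[cond]] else 1
      s2 <- s1 * fold * (1 + 0.1 * stats::rnorm(1))
      scans <- rbind(scans, data.frame(
        subject = rep(subjects[i], 2), group = rep(groups[i], 2),
        scan = c("M1", "M2"), condition = rep(cond, 2),
        scorePerMin = c(s1, s2)))
      if (cond == "hard")
        curvePars[[subjects[i]]] <- list(s1 = s1, fold = fold, tau = tau)
    }
    if (groups[i] == "training") {
      p <- curvePars[[subjects[i]]]
      d <- 1:21
      curve <- p$s1 * (1 + (p$fold - 1) *
                         (1 - exp(-d / p$tau)) / (1 - exp(-21 / p$tau)))
      curve <- curve * (1 + 0.05 * stats::rnorm(length(d)))
      daily <- rbind(daily, data.frame(subject = subjects[i], day = d,
                                       scorePerMin = curve))
    }
  }
  list(scans = scans, daily = daily, truth = curvePars)
}

#' Generate a complete synthetic study with images on disk
#'
#' Full-fidelity variant of \code{\link{simulateMcmStudy}}: for every
#' subject and scan it writes dynamic PET frames and an arterial blood
#' table, and for every condition an ASL series, a continuous BOLD series
#' (with the configured coupling planted in the target region), and a
#' motion trace; masks, true parameter maps, behavioral tables, the design
#' table and a ground-truth JSON sidecar complete the study. Intended for
#' small grids and group sizes; the cluster-level simulator carries the
#' same statistical structure at scale.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param dir output directory (created if missing); NULL keeps everything
#'   in memory.
#' @return list of class "SyntheticStudy" with \code{design} (one row per
#'   subject x time x condition with file references when written),
#'   \code{truth}, \code{behavior}, \code{config}, and (in-memory mode)
#'   \code{data}.
#' @export
generateStudy <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  truth <- makeGroundTruth(config)
  geom <- truth$geometry
  nSeedVox <- sum(geom$seed)
  groups <- rep(names(config$nSubjects), config$nSubjects)
  subjects <- sprintf("sub%02d", seq_along(groups))
  times <- dimnames(config$coupling)$time
  conditions <- dimnames(config$coupling)$condition
  write <- !is.null(dir)
  if (write) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- NULL
  data <- list()
  scrubTrue <- list()
  targetIdx <- which(geom$target)
  seedIdx <- which(geom$seed)
  nv <- prod(config$gridShape)
  for (si in seq_along(subjects)) {
    for (tm in times) {
      petOut <- generateFpetTacs(config, truth)
      petKey <- paste(subjects[si], tm, "pet", sep = "_")
      if (write) {
        writeImage(petOut$pet, file.path(dir, paste0(petKey, ".nii")))
        utils::write.table(
          data.frame(time_min = petOut$blood$time_min,
                     wholeblood_kBq_ml = petOut$blood$wholeblood,
                     plasma_kBq_ml = petOut$blood$plasma),
          file.path(dir, paste0(subjects[si], "_", tm, "_blood.tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE)
      } else data[[petKey]] <- petOut
      for (cond in conditions) {
        rho <- cellRho(config, truth, groups[si], tm, cond)
        b <- genBoldRecord(config, truth$w, rho, nSeedVox)
        bold <- matrix(stats::rnorm(config$nFramesBold * nv),
                       config$nFramesBold, nv)
        bold[, targetIdx] <- b$targetTs
        bold[, seedIdx] <- b$clusterTs
        boldFs <- FrameSeries(array(t(bold),
                                    c(config$gridShape, config$nFramesBold)),
                              tr = config$trBold)
        mot <- generateMotion(config$nFramesBold, config$nSpikes)
        asl <- generateAslSeries(config, truth, cond)
        key <- paste(subjects[si], tm, cond, sep = "_")
        scrubTrue[[key]] <- mot$spikes
        row <- data.frame(subject = subjects[si], group = groups[si],
                          time = tm, condition = cond,
                          couplingTrue = config$coupling[groups[si], tm,
                                                         cond])
        if (write) {
          # design paths are relative to dir, keeping the study relocatable
          row$bold <- paste0(key, "_bold.nii")
          row$asl <- paste0(key, "_asl.nii")
          row$motion <- paste0(key, "_motion.tsv")
          row$pet <- paste0(petKey, ".nii")
          row$blood <- paste0(subjects[si], "_", tm, "_blood.tsv")
          writeImage(boldFs, file.path(dir, row$bold))
          writeImage(asl, file.path(dir, row$asl))
          writeMotion(mot$motion, file.path(dir, row$motion))
        } else {
          data[[key]] <- list(bold = boldFs, asl = asl,
                              motion = mot$motion, spikes = mot$spikes)
        }
        design <- rbind(design, row)
      }
    }
  }
  behavior <- generateBehavior(config)
  truth$scrubFramesTrue <- scrubTrue
  truth$behaviorTrue <- behavior$truth
  out <- list(design = design, truth = truth, behavior = behavior,
              config = config)
  if (!write) out$data <- data
  if (write) {
    utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(behavior$scans, file.path(dir, "behavior_scans.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(behavior$daily))
      utils::write.table(behavior$daily,
                         file.path(dir, "behavior_daily.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    writeImage(geom$target, file.path(dir, "target_mask.nii"))
    writeImage(geom$seed, file.path(dir, "seed_mask.nii"))
    writeImage(truth$cmrgluTrue, file.path(dir, "cmrglu_true.nii"))
    sidecar <- list(seed = config$seed,
                    coupling = as.vector(config$coupling),
                    couplingDim = dimnames(config$coupling),
                    w = truth$w,
                    cbfTrue = as.list(truth$cbfTrue),
                    scrubFramesTrue = scrubTrue)
    jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(out) <- "SyntheticStudy"
  out
}
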