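test_that("configuration validation rejects degenerate settings", {
  expect_error(syntheticConfig(gridShape = c(0, 4, 4)), "positive")
  expect_error(syntheticConfig(coupling = nullCoupling(1.5)), "\\[0, 1\\]")
  expect_error(syntheticConfig(nFramesAsl = 7), "even")
  expect_error(syntheticConfig(gridShape = c(2, 2, 1)), "degenerate|overlap")
})

test_that("a fixed seed makes the generated study bit-identical", {
  cfg <- tinyConfig(seed = 7)
  d1 <- file.path(tempdir(), "studyA"); d2 <- file.path(tempdir(), "studyB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  generateStudy(cfg, d1)
  generateStudy(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, f2))
  expect_true(all(unname(sums1) == unname(sums2)))
  # cluster-level simulator is equally deterministic
  s1 <- simulateMcmStudy(cfg); s2 <- simulateMcmStudy(cfg)
  expect_identical(s1$records, s2$records)
})

test_that("zero coupling gives a null MCM and strong coupling saturates it", {
  cfg0 <- tinyConfig(coupling = nullCoupling(0))
  tab0 <- clusterMcm(simulateMcmStudy(cfg0))
  expect_lt(abs(mean(tab0$mcm)), 3 * sd(tab0$mcm) / sqrt(nrow(tab0)))

  # strong coupling with vanishing noise: spatial correlation of FC and
  # CMRGlu patterns approaches 1 before clipping (the Fisher transform of
  # the per-voxel correlations bounds it slightly below 1)
  cfg1 <- tinyConfig(coupling = nullCoupling(0.9),
                     seedRegionNoiseSd = 1e-4, cmrgluNoiseSd = 1e-5,
                     nFramesBold = 4000)
  st <- simulateMcmStudy(cfg1)
  rec <- st$records[[1]]
  z <- fcPattern(rec$clusterTs[, 1], rec$targetTs)
  expect_gt(cor(z, rec$cmrglu), 0.95)
})

test_that("synthetic fPET data obey the Patlak relation and sampling times", {
  cfg <- tinyConfig()
  set.seed(cfg$seed)
  truth <- mcmflow:::makeGroundTruth(cfg)
  out <- generateFpetTacs(cfg, truth)

  expect_equal(nrow(out$blood), 7)
  expect_equal(out$blood$time_min, c(3, 4, 5, 14, 25, 36, 47))

  # noise-free Patlak recovery of every planted Ki within 1%
  Y <- timeCourses(out$pet)
  fit <- patlakKi(Y, out$aif, cfg$tStarMin)
  quiet <- !as.vector(truth$geometry$activation)  # no task ramp there
  relErr <- abs(fit$ki[quiet] - as.vector(truth$kiTrue)[quiet]) /
    as.vector(truth$kiTrue)[quiet]
  expect_lt(max(relErr), 0.01)

  # Ki = 0, V0 = 0 gives an identically zero TAC
  cfg0 <- tinyConfig(kiMean = 1e-4, kiSd = 0)
  set.seed(cfg0$seed)
  tr0 <- mcmflow:::makeGroundTruth(cfg0)
  tr0$kiTrue[] <- 0
  out0 <- generateFpetTacs(cfg0, tr0, v0 = 0, taskBeta = c(easy = 0, hard = 0))
  expect_true(all(abs(frameData(out0$pet)) < 1e-12))

  # task ramps raise activation-voxel TACs during blocks (hard > easy planted)
  fitAct <- patlakKi(Y, out$aif, cfg$tStarMin)
  act <- as.vector(truth$geometry$activation)
  expect_gt(mean(fitAct$ki[act] - as.vector(truth$kiTrue)[act]), 0)
})

test_that("the fPET GLM pipeline recovers baseline Ki and task ordering", {
  cfg <- tinyConfig()
  set.seed(cfg$seed)
  truth <- mcmflow:::makeGroundTruth(cfg)
  out <- generateFpetTacs(cfg, truth, taskBeta = c(easy = 0.15, hard = 0.25))
  gm <- truth$geometry$brain
  baseline <- buildBaselineRegressor(out$pet, gm, truth$geometry$activation)
  des <- fpetDesign(out$frameTimesMin, baseline, petTaskBlocks())
  fit <- fitFpetGlm(out$pet, des, frameLenMin = cfg$frameLenPet / 60)
  act <- which(as.vector(truth$geometry$activation))
  # planted ordering hard > easy reproduced by the task betas
  expect_gt(mean(fit$taskBeta["hard", act]), mean(fit$taskBeta["easy", act]))
  expect_gt(mean(fit$taskBeta["hard", act]), 0.9 * 0.25 * 0.5)
  # baseline-only reconstruction yields Ki close to truth in quiet voxels
  quiet <- which(!as.vector(truth$geometry$activation))
  pat <- patlakKi(fit$baselineTac[, quiet], out$aif, cfg$tStarMin)
  relErr <- abs(pat$ki - as.vector(truth$kiTrue)[quiet]) /
    as.vector(truth$kiTrue)[quiet]
  expect_lt(stats::median(relErr), 0.05)
})

test_that("ground truth ties CMRGlu to Ki exactly and geometry is disjoint", {
  cfg <- tinyConfig()
  set.seed(cfg$seed)
  truth <- mcmflow:::makeGroundTruth(cfg)
  expect_equal(truth$cmrgluTrue,
               truth$kiTrue * cfg$gluPlasma / cfg$lc * 100)
  expect_false(any(truth$geometry$target & truth$geometry$seed))
  expect_gte(sum(truth$geometry$target), 2)
})

test_that("motion generation plants scrubbable spikes deterministically", {
  set.seed(5)
  g <- generateMotion(100, nSpikes = 3)
  expect_equal(dim(g$motion), c(100L, 6L))
  fd <- framewiseDisplacement(g$motion)
  expect_true(all(fd[g$spikes] > 0.5))
  # zero trace: all-zero FD
  expect_equal(framewiseDisplacement(matrix(0, 50, 6)), rep(0, 50))
  set.seed(5)
  g2 <- generateMotion(100, nSpikes = 3)
  expect_identical(g$motion, g2$motion)
})

test_that("stronger planted coupling differences raise the interaction F", {
  fAt <- function(rhoRestM2) {
    cp <- nullCoupling(0.3)
    cp["training", "M2", "rest"] <- rhoRestM2
    study <- simulateMcmStudy(statsConfig(seed = 55, coupling = cp,
      nSubjects = c(training = 8, control = 8)))
    tab <- clusterMcm(study)
    tab$value <- tab$mcm
    posthocGroupTime(tab, "rest")$interaction$F
  }
  fs <- vapply(c(0.3, 0.5, 0.7), fAt, numeric(1))
  expect_true(all(diff(fs) > 0))
})
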