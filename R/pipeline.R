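#' End-to-end pipeline on a synthetic study
#'
#' Runs the full analysis chain on a generated study: PET quantification
#' (input function, fPET GLM, Patlak, CMRGlu) and ASL quantification for
#' one exemplar subject-session; BOLD activation GLM; conjunction of the
#' three modality activation maps into a target region; cluster-level MCM
#' for every record; the group x time x condition ANOVA with post-hocs;
#' behavioral summaries; and the perturbation curves. Stages log to
#' stderr; a manifest records the seed and per-stage summary hashes.
#'
#' @param config a \code{\link{syntheticConfig}}; keep grids and group
#'   sizes small for the image-level stages.
#' @param withAsl include the ASL stage (and the CBF leg of the
#'   conjunction); when FALSE the target region is defined from CMRGlu
#'   and BOLD alone.
#' @param nRandom random selections for the random-driver perturbation.
#' @return list with per-stage results and \code{manifest}.
#' @export
runPipeline <- function(config = syntheticConfig(), withAsl = TRUE,
                        nRandom = 100) {
  log <- function(...) message("[mcmflow] ", ...)
  log("simulate: cluster-level study, seed ", config$seed)
  study <- simulateMcmStudy(config)
  geom <- study$truth$geometry

  log("simulate: exemplar image-level records")
  petOut <- generateFpetTacs(config, study$truth)
  aslRest <- if (withAsl) generateAslSeries(config, study$truth, "rest")
  aslHard <- if (withAsl) generateAslSeries(config, study$truth, "hard")

  log("quantify-pet: input function, fPET GLM, Patlak, CMRGlu")
  aif <- assembleInputFunction(petOut$blood, petOut$frameTimesMin)
  gm <- geom$brain
  baseline <- buildBaselineRegressor(petOut$pet, gm, geom$activation)
  des <- fpetDesign(petOut$frameTimesMin, baseline, petTaskBlocks())
  fit <- fitFpetGlm(petOut$pet, des,
                    frameLenMin = config$frameLenPet / 60)
  pat <- patlakKi(fit$baselineTac, aif, config$tStarMin)
  cmrglu <- array(cmrgluFromKi(pat$ki, config$gluPlasma, config$lc),
                  config$gridShape)
  hardBeta <- array(fit$taskBeta["hard", ], config$gridShape)

  cbfDelta <- NULL
  if (withAsl) {
    log("quantify-asl: condition CBF with rest subtraction")
    cbf <- conditionCbf(list(rest = aslRest, hard = aslHard))
    cbfDelta <- cbf$taskDelta$hard
  }

  log("conjunction: thresholded modality maps -> target region")
  # robust half-maximum thresholds (99th percentile guards noise spikes)
  halfMax <- function(x) 0.5 * stats::quantile(x, 0.99, names = FALSE)
  maps <- list(cmrglu = binarize(hardBeta, halfMax(hardBeta)),
               bold = geom$activation)
  if (withAsl) maps$cbf <- binarize(cbfDelta, halfMax(cbfDelta))
  target <- intersectMasks(maps)
  diceCmrgluBold <- dice(maps$cmrglu, maps$bold)

  log("mcm + stats: cluster MCM, group x time x condition ANOVA")
  mcmTab <- clusterMcm(study)
  mcmTab$value <- mcmTab$mcm
  anova <- rmAnovaGtc(mcmTab)
  ph <- lapply(stats::setNames(nm = unique(mcmTab$condition)),
               function(cc) posthocGroupTime(mcmTab, cc))
  phP <- holm(vapply(ph, function(x) x$interaction$p, numeric(1)))

  log("behavior: fold changes and learning-curve AUC")
  behav <- behaviorSummary(study$behavior$scans, study$behavior$daily)

  log("perturb: cmrglu and random drivers")
  m <- ncol(study$records[[1]]$targetTs)
  admissible <- seq(0, 0.9, 0.1)
  admissible <- admissible[m - floor(admissible * m) >= 4]
  fMax <- max(admissible)
  curves <- rbind(
    perturbationCurve(study, "cmrglu",
                      fractions = admissible[admissible <= 0.6],
                      condition = "rest"),
    perturbationCurve(study, "random", fractions = unique(c(0, fMax)),
                      nRandom = nRandom, seed = config$seed,
                      condition = "rest"))

  hash <- function(x) {
    f <- tempfile()
    saveRDS(x, f)
    h <- unname(tools::md5sum(f))
    unlink(f)
    h
  }
  manifest <- list(seed = config$seed,
                   nSubjects = as.list(config$nSubjects),
                   withAsl = withAsl,
                   hashes = list(mcm = hash(round(mcmTab$mcm, 12)),
                                 anova = hash(round(anova$F, 12)),
                                 behavior = hash(round(
                                   behav$folds$foldOfMeans, 12))))
  list(study = study, inputFunction = aif, patlak = pat, cmrglu = cmrglu,
       cbfDelta = cbfDelta, target = target, dice = diceCmrgluBold,
       mcm = mcmTab, anova = anova, posthoc = ph, posthocHolmP = phP,
       behavior = behav, perturbation = curves, manifest = manifest)
}
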