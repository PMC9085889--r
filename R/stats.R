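#' Three-factor repeated-measures ANOVA via difference values
#'
#' Training effects in a group (between) x time (2 scans, within) x
#' condition (within) design. The default route forms per-subject
#' time-2 minus time-1 differences and fits a group x condition
#' repeated-measures ANOVA on them: the group main effect on differences
#' is the group x time interaction and the group x condition effect is the
#' group x time x condition interaction. \code{method = "direct"} fits the
#' full three-factor mixed ANOVA on raw values instead; both routes agree
#' for a two-level time factor.
#'
#' @param data data.frame with columns subject, group, time, condition,
#'   value; time must have exactly 2 levels, the design complete and
#'   balanced within subject.
#' @param method "difference" (default) or "direct".
#' @return data.frame with columns effect, F, df1, df2, p. Effects are
#'   named for the raw-design interpretation (group:time,
#'   group:time:condition, plus the rest-vs-task contrast
#'   \code{group:time (rest vs task)} when a condition named "rest" is
#'   present).
#' @export
rmAnovaGtc <- function(data, method = c("difference", "direct")) {
  method <- match.arg(method)
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$time <- factor(data$time)
  data$condition <- factor(data$condition)
  if (nlevels(data$time) != 2L) stop("time must have exactly 2 levels")
  tab <- table(data$subject, data$time, data$condition)
  if (any(tab != 1L)) stop("incomplete or unbalanced design")
  tl <- levels(data$time)
  wide <- merge(
    data[data$time == tl[1], c("subject", "group", "condition", "value")],
    data[data$time == tl[2], c("subject", "condition", "value")],
    by = c("subject", "condition"), suffixes = c(".1", ".2"))
  wide$d <- wide$value.2 - wide$value.1
  if (method == "difference") {
    fit <- stats::aov(d ~ group * condition + Error(subject),
                      data = wide)
    s <- summary(fit)
    between <- s[["Error: subject"]][[1]]
    within <- s[["Error: Within"]][[1]]
    rn <- function(x) trimws(rownames(x))
    gRow <- which(rn(between) == "group")
    gcRow <- which(rn(within) == "group:condition")
    res <- data.frame(
      effect = c("group:time", "group:time:condition"),
      F = c(between$`F value`[gRow], within$`F value`[gcRow]),
      df1 = c(between$Df[gRow], within$Df[gcRow]),
      df2 = c(between$Df[nrow(between)], within$Df[nrow(within)]),
      p = c(between$`Pr(>F)`[gRow], within$`Pr(>F)`[gcRow]))
  } else {
    fit <- stats::aov(value ~ group * time * condition +
                        Error(subject / (time * condition)), data = data)
    s <- summary(fit)
    pick <- function(stratum, eff) {
      tabl <- s[[stratum]][[1]]
      i <- which(trimws(rownames(tabl)) == eff)
      c(tabl$`F value`[i], tabl$Df[i], tabl$Df[nrow(tabl)],
        tabl$`Pr(>F)`[i])
    }
    gt <- pick("Error: subject:time", "group:time")
    gtc <- pick("Error: subject:time:condition", "group:time:condition")
    res <- data.frame(
      effect = c("group:time", "group:time:condition"),
      F = c(gt[1], gtc[1]), df1 = c(gt[2], gtc[2]),
      df2 = c(gt[3], gtc[3]), p = c(gt[4], gtc[4]))
  }
  if ("rest" %in% levels(data$condition) && nlevels(data$condition) >= 2L) {
    task <- setdiff(levels(data$condition), "rest")
    byS <- split(wide, wide$subject)
    cval <- vapply(byS, function(w)
      w$d[w$condition == "rest"] -
        mean(w$d[w$condition %in% task]), numeric(1))
    grp <- vapply(byS, function(w) as.character(w$group[1]), character(1))
    tt <- twoSampleF(cval, factor(grp))
    res <- rbind(res, data.frame(
      effect = "group:time (rest vs task)",
      F = tt$F, df1 = 1, df2 = tt$df2, p = tt$p))
  }
  res$F[is.na(res$F)] <- 0
  res$p[is.na(res$p) | res$F == 0] <- 1
  rownames(res) <- NULL
  res
}

# Pooled-variance two-sample comparison as an F (= t^2); degenerate
# zero-variance inputs resolve to F = 0 (equal means) or Inf.
twoSampleF <- function(x, grp) {
  df2 <- length(x) - 2L
  if (stats::sd(x) == 0 ||
      all(vapply(split(x, grp), stats::sd, numeric(1)) == 0)) {
    dm <- diff(vapply(split(x, grp), mean, numeric(1)))
    if (dm == 0) return(list(F = 0, df2 = df2, p = 1))
    if (stats::sd(x) > 0) {
      # distinct constant groups: exact separation
      return(list(F = Inf, df2 = df2, p = 0))
    }
    return(list(F = 0, df2 = df2, p = 1))
  }
  tt <- stats::t.test(x ~ grp, var.equal = TRUE)
  list(F = unname(tt$statistic)^2, df2 = unname(tt$parameter),
       p = tt$p.value)
}

#' Post-hoc tests per condition
#'
#' For one condition: the group x time interaction as a two-sample
#' comparison of the per-subject time differences (F = t^2, pooled
#' variance), followed by a paired t-test of the time effect within each
#' group. Zero-variance differences with a non-zero mean are reported as
#' an exact difference (t = Inf, p = 0).
#'
#' @param data as in \code{\link{rmAnovaGtc}}.
#' @param condition which condition to test.
#' @return list with \code{interaction} (data.frame: F, df1, df2, p) and
#'   \code{within} (data.frame per group: mean difference, t, df, p).
#' @export
posthocGroupTime <- function(data, condition) {
  data <- data[data$condition == condition, ]
  if (!nrow(data)) stop("unknown condition")
  data$time <- factor(data$time)
  tl <- levels(data$time)
  wide <- merge(
    data[data$time == tl[1], c("subject", "group", "value")],
    data[data$time == tl[2], c("subject", "value")],
    by = "subject", suffixes = c(".1", ".2"))
  wide$d <- wide$value.2 - wide$value.1
  grp <- factor(wide$group)
  if (any(table(grp) < 2L)) stop("need at least 2 subjects per group")
  tt <- twoSampleF(wide$d, grp)
  interaction <- data.frame(F = tt$F, df1 = 1, df2 = tt$df2, p = tt$p)
  within <- do.call(rbind, lapply(levels(grp), function(g) {
    d <- wide$d[grp == g]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0)
        data.frame(group = g, meanDiff = 0, t = 0, df = length(d) - 1, p = 1)
      else
        data.frame(group = g, meanDiff = mean(d), t = Inf * sign(mean(d)),
                   df = length(d) - 1, p = 0)
    } else {
      w <- stats::t.test(d)
      data.frame(group = g, meanDiff = mean(d), t = unname(w$statistic),
                 df = unname(w$parameter), p = w$p.value)
    }
  }))
  list(interaction = interaction, within = within)
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm procedure (monotone, capped at 1).
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Cluster-extent permutation inference on difference maps
#'
#' Two-sample t-test per voxel on subject-level difference maps, threshold
#' at the two-sided cluster-forming p, 26-connected cluster extents, and a
#' max-extent null distribution over random group-label exchanges.
#' Clusters whose extent exceeds the 95th percentile of the null are
#' significant.
#'
#' @param diffMaps 4D array (x, y, z, subject) of difference maps, or a
#'   subjects x voxels matrix plus \code{dims}.
#' @param groups factor/character of group labels per subject (2 levels).
#' @param nPerm number of permutations, default 1000.
#' @param clusterFormingP two-sided voxel threshold, default 0.001.
#' @param dims grid dimensions when \code{diffMaps} is a matrix.
#' @param seed RNG seed for the permutations.
#' @return list with \code{tMap}, \code{clusters} (data.frame: label,
#'   extent, p), \code{mask} (significant voxels), \code{nullMax}.
#' @export
clusterPermutation <- function(diffMaps, groups, nPerm = 1000,
                               clusterFormingP = 0.001, dims = NULL,
                               seed = NULL) {
  if (length(dim(diffMaps)) == 4L) {
    dims <- dim(diffMaps)[1:3]
    M <- t(matrix(diffMaps, prod(dims), dim(diffMaps)[4]))
  } else {
    stopifnot(!is.null(dims))
    M <- as.matrix(diffMaps)
  }
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, nrow(M) == length(groups))
  if (nPerm < 100L) stop("need at least 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - clusterFormingP / 2, df)
  tstat <- function(lab1) {
    g1 <- M[lab1, , drop = FALSE]
    g2 <- M[!lab1, , drop = FALSE]
    m1 <- colMeans(g1); m2 <- colMeans(g2)
    v1 <- colSums(sweep(g1, 2, m1)^2)
    v2 <- colSums(sweep(g2, 2, m2)^2)
    sp <- sqrt((v1 + v2) / df * (1 / n1 + 1 / n2))
    (m1 - m2) / pmax(sp, 1e-300)
  }
  maxExtent <- function(tv) {
    supra <- array(abs(tv) > tcrit, dims)
    lab <- labelClusters(supra)
    if (max(lab) == 0L) 0L else max(tabulate(lab[lab > 0L]))
  }
  obs1 <- groups == levels(groups)[1]
  tObs <- tstat(obs1)
  labObs <- labelClusters(array(abs(tObs) > tcrit, dims))
  extents <- if (max(labObs) > 0L) tabulate(labObs[labObs > 0L]) else integer()
  nullMax <- vapply(seq_len(nPerm), function(i)
    maxExtent(tstat(sample(obs1))), numeric(1))
  pClust <- vapply(extents, function(e)
    (1 + sum(nullMax >= e)) / (1 + nPerm), numeric(1))
  sig <- which(pClust <= 0.05)
  mask <- array(labObs %in% sig, dims)
  list(tMap = array(tObs, dims),
       clusters = data.frame(label = seq_along(extents), extent = extents,
                             p = pClust),
       mask = mask, nullMax = nullMax)
}

#' Divergence of rest and task MCM values
#'
#' (rest - task) / mean(rest, task): the normalized difference summarizing
#' complementary increases at rest and decreases during the task while
#' avoiding mathematical coupling with the absolute level.
#'
#' @param mcmRest,mcmTask per-subject MCM values.
#' @return per-subject divergence scores.
#' @export
divergence <- function(mcmRest, mcmTask) {
  m <- (mcmRest + mcmTask) / 2
  if (any(m == 0)) stop("divergence undefined where mean(rest, task) = 0")
  (mcmRest - mcmTask) / m
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties allowed); robust to single
#' outlying values.
#'
#' @param x,y numeric vectors, length >= 4.
#' @return Spearman's rho.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y, method = "spearman")
}

#' Behavioral summaries: fold changes and learning-curve AUC
#'
#' Fold change per group and condition between the two scans, both as the
#' ratio of group means and as the mean of per-subject ratios; and the
#' normalized area under the per-subject training curve (trapezoid over
#' training days divided by the day span, i.e. the mean daily score, so a
#' flat curve at c has AUC c).
#'
#' @param scans data.frame with columns subject, group, scan ("M1"/"M2"),
#'   condition, scorePerMin.
#' @param daily optional data.frame with columns subject, day, scorePerMin.
#' @return list with \code{folds} (data.frame: group, condition,
#'   foldOfMeans, meanOfFolds) and \code{aucNorm} (named per-subject
#'   vector, NULL without daily data).
#' @export
behaviorSummary <- function(scans, daily = NULL) {
  stopifnot(all(c("M1", "M2") %in% scans$scan))
  folds <- do.call(rbind, lapply(split(scans,
                                       list(scans$group, scans$condition),
                                       drop = TRUE), function(d) {
    m1 <- d[d$scan == "M1", c("subject", "scorePerMin")]
    m2 <- d[d$scan == "M2", c("subject", "scorePerMin")]
    mm <- merge(m1, m2, by = "subject", suffixes = c(".1", ".2"))
    if (!nrow(mm)) stop("missing scans for a group/condition cell")
    data.frame(group = d$group[1], condition = d$condition[1],
               foldOfMeans = mean(mm$scorePerMin.2) / mean(mm$scorePerMin.1),
               meanOfFolds = mean(mm$scorePerMin.2 / mm$scorePerMin.1))
  }))
  rownames(folds) <- NULL
  aucNorm <- NULL
  if (!is.null(daily)) {
    aucNorm <- vapply(split(daily, daily$subject), function(d) {
      d <- d[order(d$day), ]
      if (nrow(d) < 2L) return(d$scorePerMin[1])
      pracma::trapz(d$day, d$scorePerMin) / (max(d$day) - min(d$day))
    }, numeric(1))
  }
  list(folds = folds, aucNorm = aucNorm)
}

#' Tetris line-clear score
#'
#' score = k * (n + 1) with n the speed level and k = 40, 100, 300, 1200
#' for one, two, three or four lines removed simultaneously.
#'
#' @param lines number of lines cleared at once (1-4).
#' @param speedLevel non-negative integer speed level n.
#' @return the score.
#' @examples
#' tetrisScore(1, 0)  # 40
#' tetrisScore(4, 3)  # 4800
#' @export
tetrisScore <- function(lines, speedLevel) {
  k <- c(40, 100, 300, 1200)
  if (!all(lines %in% 1:4)) stop("lines must be between 1 and 4")
  if (any(speedLevel < 0) || any(speedLevel != floor(speedLevel)))
    stop("speed level must be a non-negative integer")
  k[lines] * (speedLevel + 1)
}
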