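test_that("the group x time x condition ANOVA matches a sums-of-squares oracle", {
  d <- makeGtcData(seed = 2, delta = 1.5)
  res <- rmAnovaGtc(d)
  wide <- merge(d[d$time == "M1", c("subject", "group", "condition", "value")],
                d[d$time == "M2", c("subject", "condition", "value")],
                by = c("subject", "condition"), suffixes = c(".1", ".2"))
  wide$d <- wide$value.2 - wide$value.1
  oracle <- oracleMixedF(wide)
  expect_equal(res$F[res$effect == "group:time"], oracle$Fgroup,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:time:condition"], oracle$Fgc,
               tolerance = 1e-8)
  # difference and direct three-factor routes agree
  res2 <- rmAnovaGtc(d, method = "direct")
  expect_equal(res$F[1:2], res2$F[1:2], tolerance = 1e-8)
  expect_equal(res$p[1:2], res2$p[1:2], tolerance = 1e-8)
})

test_that("degenerate and invalid ANOVA inputs are handled", {
  d <- makeGtcData(seed = 3)
  d$value <- 5
  res <- rmAnovaGtc(d)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_error(rmAnovaGtc(makeGtcData()[-1, ]), "incomplete")
})

test_that("ANOVA p-values are uniform under a permuted null", {
  set.seed(6)
  ps <- replicate(400, {
    d <- makeGtcData(seed = sample.int(1e6, 1))
    rmAnovaGtc(d)$p[2]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("post-hoc interaction equals t^2 and the paired t identity holds", {
  d <- makeGtcData(seed = 4, delta = 1)
  ph <- posthocGroupTime(d, "rest")
  # two-sample t on differences, squared
  wide <- merge(d[d$time == "M1" & d$condition == "rest", ],
                d[d$time == "M2" & d$condition == "rest", ],
                by = "subject")
  dd <- wide$value.y - wide$value.x
  tt <- t.test(dd ~ wide$group.x, var.equal = TRUE)
  expect_equal(ph$interaction$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # paired t within a group equals a one-sample t on its differences
  g <- "training"
  one <- t.test(dd[wide$group.x == g])
  expect_equal(ph$within$t[ph$within$group == g], unname(one$statistic),
               tolerance = 1e-10)
  # zero-variance exact difference guarded
  d2 <- d
  sel <- d2$condition == "rest"
  d2$value[sel] <- ifelse(d2$time[sel] == "M2", 2, 1)
  ph2 <- posthocGroupTime(d2, "rest")
  expect_true(all(is.infinite(ph2$within$t)))
  expect_true(all(ph2$within$p == 0))
  expect_equal(ph2$interaction$F, 0)  # same shift in both groups
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm(0.03), 0.03)
  expect_equal(holm(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm(rep(1, 5)), rep(1, 5))
  p <- c(0.2, 0.001, 0.047, 0.9)
  # independent step-down oracle
  o <- order(p)
  adj <- pmin(cummax((length(p) - seq_along(p) + 1) * p[o]), 1)
  expect_equal(holm(p)[o], adj)
  expect_true(all(holm(p) >= p))
  expect_error(holm(c(0.5, 1.2)))
})

test_that("cluster permutation inference detects planted clusters and calibrates", {
  dims <- c(8, 8, 4)
  nv <- prod(dims)
  n1 <- 10; n2 <- 10
  set.seed(31)
  # planted: a large cube shifted in group 1
  M <- matrix(rnorm((n1 + n2) * nv), n1 + n2, nv)
  mask <- array(FALSE, dims); mask[2:6, 2:6, 2:3] <- TRUE
  M[1:n1, as.vector(mask)] <- M[1:n1, as.vector(mask)] + 3
  groups <- rep(c("a", "b"), c(n1, n2))
  res <- clusterPermutation(array(t(M), c(dims, n1 + n2)), groups,
                            nPerm = 199, seed = 5)
  expect_gte(sum(res$mask & mask), 0.5 * sum(mask))
  expect_true(any(res$clusters$p <= 0.05))

  # identity labels reproduce the observed statistic
  o1 <- clusterPermutation(array(t(M), c(dims, n1 + n2)), groups,
                           nPerm = 199, seed = 9)
  expect_equal(res$tMap, o1$tMap)

  expect_error(clusterPermutation(array(t(M), c(dims, n1 + n2)), groups,
                                  nPerm = 50), "100")

  # null family-wise error rate near the nominal 5%
  hits <- replicate(150, {
    Mn <- matrix(rnorm((n1 + n2) * 6 * 6 * 3), n1 + n2, 108)
    r <- clusterPermutation(Mn, groups, nPerm = 100, dims = c(6, 6, 3))
    any(r$clusters$p <= 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.055)  # 3 SE binomial allowance
})

test_that("divergence scores normalize the rest-task difference", {
  expect_equal(divergence(3, 1), 1)
  expect_equal(divergence(2, 2), 0)
  expect_equal(divergence(c(3, 2), c(1, 2)), c(1, 0))
  # invariant to common positive scaling
  expect_equal(divergence(3 * 7, 1 * 7), divergence(3, 1))
  expect_error(divergence(1, -1), "undefined")
})

test_that("Spearman correlation is rank-then-Pearson", {
  x <- c(1, 2, 5, 9, 20)
  expect_equal(spearman(x, x^3), 1)
  expect_equal(spearman(x, -x), -1)
  set.seed(13)
  a <- rnorm(40); b <- a + rnorm(40)
  expect_equal(spearman(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  # ties: average ranks
  a2 <- c(1, 1, 2, 3, 3, 4); b2 <- c(2, 1, 4, 4, 5, 6)
  expect_equal(spearman(a2, b2), cor(rank(a2), rank(b2)), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 3:1), "length")
})

test_that("behavior summaries compute fold changes and normalized AUC", {
  scans <- expand.grid(subject = c("s1", "s2"), scan = c("M1", "M2"),
                       condition = c("easy", "hard"),
                       stringsAsFactors = FALSE)
  scans$group <- "training"
  scans$scorePerMin <- ifelse(scans$scan == "M1", c(10, 20), 2 * c(10, 20))
  out <- behaviorSummary(scans)
  expect_true(all(abs(out$folds$foldOfMeans - 2) < 1e-12))
  expect_true(all(abs(out$folds$meanOfFolds - 2) < 1e-12))

  daily <- data.frame(subject = "s1", day = 1:10, scorePerMin = 7)
  expect_equal(unname(behaviorSummary(scans, daily)$aucNorm["s1"]), 7)
})

test_that("generator behavior reproduces the configured fold changes", {
  cfg <- syntheticConfig(nSubjects = c(training = 200, control = 200),
                         seed = 5)
  set.seed(cfg$seed)
  beh <- generateBehavior(cfg)
  out <- behaviorSummary(beh$scans, beh$daily)
  f <- out$folds
  tr <- f[f$group == "training", ]
  expect_equal(tr$foldOfMeans[tr$condition == "easy"], 2.7,
               tolerance = 0.05)
  expect_equal(tr$foldOfMeans[tr$condition == "hard"], 3.1,
               tolerance = 0.05)
  ct <- f[f$group == "control", ]
  expect_equal(ct$foldOfMeans, c(1, 1), tolerance = 0.05)
  # unit fold: no group x time interaction beyond the nominal rate
  cfgNull <- syntheticConfig(foldChangeEasy = 1, foldChangeHard = 1,
                             seed = 8)
  set.seed(cfgNull$seed)
  ps <- replicate(60, {
    b <- generateBehavior(cfgNull)
    b$scans$time <- b$scans$scan
    b$scans$value <- b$scans$scorePerMin
    posthocGroupTime(b$scans, "hard")$interaction$p
  })
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("the Tetris scoring rule reproduces the per-line constants", {
  expect_equal(tetrisScore(1, 0), 40)
  expect_equal(tetrisScore(2, 0), 100)
  expect_equal(tetrisScore(3, 0), 300)
  expect_equal(tetrisScore(4, 0), 1200)
  expect_equal(tetrisScore(4, 3), 4800)
  expect_equal(tetrisScore(1:4, 1), c(80, 200, 600, 2400))
  expect_error(tetrisScore(5, 0), "lines")
  expect_error(tetrisScore(2, -1), "speed")
  expect_error(tetrisScore(2, 1.5), "speed")
})
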