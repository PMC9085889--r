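# Independent statistical oracles shared across test files.

# brute-force sums-of-squares oracle for the mixed two-way ANOVA on
# per-subject time differences (groups between, conditions within)
oracleMixedF <- function(wide) {
  # wide: subject, group, condition, d
  G <- unique(wide$group); C <- unique(wide$condition)
  grand <- mean(wide$d)
  nPerG <- sapply(G, function(g)
    length(unique(wide$subject[wide$group == g])))
  mg <- sapply(G, function(g) mean(wide$d[wide$group == g]))
  mc <- sapply(C, function(cc) mean(wide$d[wide$condition == cc]))
  mgc <- outer(G, C, Vectorize(function(g, cc)
    mean(wide$d[wide$group == g & wide$condition == cc])))
  ms <- tapply(wide$d, wide$subject, mean)
  sGroup <- sapply(names(ms), function(s)
    wide$group[wide$subject == s][1])
  ssGroup <- length(C) * sum(nPerG * (mg - grand)^2)
  ssSubj <- length(C) * sum((ms - mg[match(sGroup, G)])^2)
  dev <- mgc - matrix(mg, length(G), length(C)) -
    matrix(mc, length(G), length(C), byrow = TRUE) + grand
  ssGC <- sum(matrix(nPerG, length(G), length(C)) * dev^2)
  ssTot <- sum((wide$d - grand)^2)
  ssCond <- sum(nPerG) * sum((mc - grand)^2)
  ssErr <- ssTot - ssGroup - ssSubj - ssCond - ssGC
  N <- sum(nPerG)
  dfGC <- (length(G) - 1) * (length(C) - 1)
  dfErr <- (N - length(G)) * (length(C) - 1)
  list(Fgroup = (ssGroup / (length(G) - 1)) / (ssSubj / (N - length(G))),
       Fgc = (ssGC / dfGC) / (ssErr / dfErr))
}

# balanced group x time x condition toy dataset with an optional planted
# training-rest shift at the second scan
makeGtcData <- function(seed = 1, delta = 0, n1 = 8, n2 = 7) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("s%02d", seq_len(n1 + n2)),
                   time = c("M1", "M2"),
                   condition = c("rest", "easy", "hard"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= n1,
                    "training", "control")
  d$value <- rnorm(nrow(d))
  sel <- d$group == "training" & d$time == "M2" & d$condition == "rest"
  d$value[sel] <- d$value[sel] + delta
  d
}
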