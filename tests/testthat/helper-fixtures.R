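# Shared fixtures: tiny configurations and hand-built inputs.

tinyConfig <- function(seed = 42, nFramesBold = 60,
                       nSubjects = c(training = 2, control = 2), ...) {
  syntheticConfig(gridShape = c(10, 10, 6), nSubjects = nSubjects,
                  nFramesBold = nFramesBold, nFramesAsl = 8,
                  seed = seed, ...)
}

# Cluster-level study sized for group statistics at speed.
statsConfig <- function(seed = 1, nFramesBold = 120, ...) {
  syntheticConfig(gridShape = c(16, 16, 8), nFramesBold = nFramesBold,
                  seed = seed, ...)
}

# A flat input function: cp constant, integral linear in time.
constantAif <- function(cp0 = 30, n = 104, dtMin = 0.5) {
  tt <- dtMin * (seq_len(n) - 0.5)
  cp <- rep(cp0, n)
  ci <- pracma::cumtrapz(c(0, tt), c(cp0, cp))[-1]
  new("InputFunction", frameTimesMin = tt, cp = cp, cumInt = ci)
}

# Null coupling: every cell at the same baseline level.
nullCoupling <- function(level = 0.3) {
  array(level, c(2, 2, 3),
        dimnames = list(group = c("training", "control"),
                        time = c("M1", "M2"),
                        condition = c("rest", "easy", "hard")))
}
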