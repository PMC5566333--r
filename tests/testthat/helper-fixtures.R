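# shared fixtures, built in code and cached for the session

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# a 3-site study small enough for detection/quant tests
smallStudy <- function() {
  cached("smallStudy", {
    d <- buildDesign(nSites = 3)
    simulateStudy(d, seed = 101, nProteins = 150, meanPeptides = 5)
  })
}

smallScored <- function() {
  cached("smallScored", {
    learnDiscriminant(smallStudy()@peakGroups, subsampleRatio = 0.2, seed = 1)
  })
}

smallDetection <- function() {
  cached("smallDetection", {
    sc <- smallScored()
    consecutiveFilter(
      estimateQvalues(sc, 0.4, "global", "peptide"),
      estimateQvalues(sc, 0.4, "global", "protein"),
      estimateQvalues(sc, 0.4, "experiment-wide", "peptide"),
      alpha = 0.01)
  })
}

# noise-free SIS curves on a design grid, for hand-checkable dilution tests
toyCurve <- function(slope = 7, nominal = 1000 / 3^(4:0), reps = 3,
                     sn = 100, cvAt = NULL, cvValue = 0) {
  do.call(rbind, lapply(seq_along(nominal), function(i) {
    a <- rep(slope * nominal[i], reps)
    if (!is.null(cvAt) && i == cvAt) {
      # deviations m(1-x), m, m(1+x) have sample CV exactly x
      a <- (a * (1 + cvValue * c(-1, 0, 1)))[seq_len(reps)]
    }
    data.frame(nominal_fmol = nominal[i], area = a, sn = sn)
  }))
}
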