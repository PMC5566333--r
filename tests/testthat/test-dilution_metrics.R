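test_that("response-curve fits recover exact lines", {
  x <- c(1, 3, 9, 27, 81)
  f <- fitResponseCurve(x, 7 * x)
  expect_equal(f$slope, 7)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  # two points interpolate exactly regardless of slope
  f2 <- fitResponseCurve(c(1, 10), c(3, 5))
  expect_equal(f2$r_squared, 1)
  expect_error(fitResponseCurve(c(1, 1), c(2, 3)), "distinct")
  expect_error(fitResponseCurve(c(1, 2, 3), c(4, 4, 4)), "zero-variance")
})

test_that("removing a saturated top point improves the weighted fit", {
  x <- 10000 / 3^(4:0)
  y <- softSat(x, 10000) * 1e4          # noiseless curve with saturation
  full <- fitResponseCurve(x, y)
  trimmed <- fitResponseCurve(x[-5], y[-5])
  expect_gt(trimmed$r_squared, full$r_squared)
})

test_that("LLOQ iteration applies the three criteria from the bottom up", {
  # clean noiseless curve, high S/N everywhere: LLOQ = lowest point
  r <- determineLLOQ(toyCurve())
  expect_equal(r$lloq, min(toyCurve()$nominal_fmol))
  expect_equal(r$dynamic_range, log10(81), tolerance = 1e-12)
  # replicate CV 35% at the lowest point: LLOQ moves one step up
  curved <- toyCurve(cvAt = 1, cvValue = 0.35)
  r2 <- determineLLOQ(curved)
  expect_equal(r2$lloq, sort(unique(curved$nominal_fmol))[2])
  # S/N below threshold at the two lowest points
  lowSN <- toyCurve()
  lowSN$sn[lowSN$nominal_fmol <= sort(unique(lowSN$nominal_fmol))[2]] <- 5
  expect_equal(determineLLOQ(lowSN)$lloq, sort(unique(lowSN$nominal_fmol))[3])
  # nothing passes -> undetermined, not an error
  none <- toyCurve(); none$sn <- 1
  expect_true(is.na(determineLLOQ(none)$lloq))
})

test_that("LLOQ determination is deterministic and order-independent", {
  curved <- toyCurve(cvAt = 1, cvValue = 0.35)
  r1 <- determineLLOQ(curved)
  r2 <- determineLLOQ(curved[sample(nrow(curved)), ])
  expect_equal(r1$lloq, r2$lloq)
  expect_equal(r1$fit$slope, r2$fit$slope)
})

test_that("added replicate noise never lowers the LLOQ", {
  base <- toyCurve(cvAt = 1, cvValue = 0.1)   # bottom CV 10%: still passes
  rBase <- determineLLOQ(base)
  expect_equal(rBase$lloq, min(base$nominal_fmol))
  noisy <- toyCurve(cvAt = 1, cvValue = 0.4)  # same curve, more noise
  rNoisy <- determineLLOQ(noisy)
  expect_gte(rNoisy$lloq, rBase$lloq)
  expect_gt(rNoisy$lloq, rBase$lloq)
})

test_that("dynamic range identity holds exactly", {
  expect_equal(dynamicRange(1, 10000), 4)
  expect_equal(dynamicRange(123, 123), 0)
  for (lloq in c(0.012, 0.111, 37)) {
    expect_equal(dynamicRange(lloq, 10000) + log10(lloq), log10(10000))
  }
  expect_error(dynamicRange(NA, 100), "undetermined")
})

test_that("averaged response curves reduce correctly", {
  nominal <- 1000 / 3^(4:0)
  mk <- function(pep, site = "s1", mult = 1) {
    data.frame(site_id = site, group_id = "A", ms_level = "MS2",
               peptide_id = pep, nominal_fmol = nominal,
               area = mult * 7 * nominal, sn = 100)
  }
  six <- do.call(rbind, lapply(paste0("p", 1:6), mk))
  avg <- averagedResponseCurve(six)
  # identical peptides: averaged curve equals each curve
  expect_equal(sort(avg$mean_area), sort(7 * nominal))
  expect_true(all(avg$n_peptides == 6))
  # permutation invariance in peptide order
  avg2 <- averagedResponseCurve(six[sample(nrow(six)), ])
  expect_equal(avg, avg2)
  # two sites differing by a global offset: parallel in log space
  two <- rbind(six, do.call(rbind, lapply(paste0("p", 1:6), mk,
                                          site = "s2", mult = 2.5)))
  avgT <- averagedResponseCurve(two)
  r <- avgT$mean_area[avgT$site_id == "s2"] /
    avgT$mean_area[avgT$site_id == "s1"]
  expect_equal(r, rep(2.5, 5))
})

test_that("step fold changes recover the design ratios without saturation", {
  nominal <- 1000 / 3^(4:0)
  sis <- data.frame(site_id = "s1", group_id = "A", ms_level = "MS2",
                    peptide_id = "p1", nominal_fmol = nominal,
                    area = 11 * nominal, sn = 100)
  fc <- stepFoldChanges(sis)
  expect_equal(unname(fc), c(3, 9, 27), tolerance = 1e-12)
  # single peptide, two points 30 and 10 -> ratio 3
  fc2 <- stepFoldChanges(data.frame(site_id = "s1", group_id = "A",
                                    ms_level = "MS2", peptide_id = "p1",
                                    nominal_fmol = c(10, 30),
                                    area = c(10, 30), sn = 100), maxStep = 1)
  expect_equal(unname(fc2), 3)
  # saturation compresses the mean adjacent ratio below 3
  satArea <- softSat(nominal, max(nominal)) * 11
  sat <- sis; sat$area <- satArea
  expect_lt(unname(stepFoldChanges(sat)["step1"]), 3)
})

test_that("percent-detected steps follow the LLOQ staircase", {
  # 30 peptides whose LLOQ equals their group start amount: detection
  # steps down by 20 percentage points per decade
  starts <- c(1, 10, 100, 1000, 10000)
  lloq <- data.frame(
    peptide_id = sprintf("p%02d", 1:30),
    site_id = "s1", ms_level = "MS2",
    group_id = rep(LETTERS[1:5], each = 6),
    lloq_fmol = rep(starts, each = 6),
    dynamic_range_orders = 0, r_squared = 1,
    max_fmol = rep(starts, each = 6))
  pct <- percentDetected(lloq, concentrations = starts)
  s1 <- pct[pct$site_id == "s1", ]
  expect_equal(s1$pct_detected[order(s1$fmol)], c(20, 40, 60, 80, 100))
  # all LLOQs at the design minimum -> 100% everywhere
  lloq2 <- lloq; lloq2$lloq_fmol <- 0.01
  pct2 <- percentDetected(lloq2, concentrations = starts)
  expect_true(all(pct2$pct_detected == 100))
  # undetermined LLOQ never counts
  lloq3 <- lloq; lloq3$lloq_fmol[1:6] <- NA
  pct3 <- percentDetected(lloq3, concentrations = 10000)
  expect_equal(pct3$pct_detected[pct3$site_id == "s1"], 80)
})
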