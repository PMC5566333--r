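# brute-force oracle: enumerate peak-group subsets of size <= k, maximizing
# total area, then sum top-m fragments in each selected group
bruteTop <- function(groups, k = 3, m = 5) {
  totals <- vapply(groups, sum, numeric(1))
  pick <- order(totals, decreasing = TRUE)[seq_len(min(k, length(groups)))]
  sum(vapply(groups[pick], function(g)
    sum(sort(g, decreasing = TRUE)[seq_len(min(m, length(g)))]), numeric(1)))
}

pgTable <- function(groups, protein = "P1", run = "r1") {
  do.call(rbind, lapply(seq_along(groups), function(i) {
    fr <- rep(NA_real_, 6); fr[seq_along(groups[[i]])] <- groups[[i]]
    df <- data.frame(run_id = run, peptide_query_id = paste0("pep", i),
                     protein_id = protein, decoy = 0L,
                     score_1 = 0, score_2 = 0, score_3 = 0, score_4 = 0,
                     score_5 = 0, stringsAsFactors = FALSE)
    for (j in 1:6) df[[paste0("frag_", j)]] <- fr[j]
    df$ms1_area <- 0; df$rt <- 0
    df
  }))
}

test_that("topN summation matches hand-enumerated oracles", {
  # single peak group, 5 fragments -> plain sum
  q1 <- inferProteinAbundance(pgTable(list(c(1, 2, 3, 4, 5))))
  expect_equal(unname(abundances(q1)["P1", "r1"]), 15)
  # 6 fragments -> drop the minimum
  q2 <- inferProteinAbundance(pgTable(list(c(10, 9, 8, 7, 6, 5))))
  expect_equal(unname(abundances(q2)["P1", "r1"]), 40)
  # four peak groups with totals {100, 50, 20, 5} -> top three
  gs <- list(rep(20, 5), rep(10, 5), rep(4, 5), rep(1, 5))
  q3 <- inferProteinAbundance(pgTable(gs))
  expect_equal(unname(abundances(q3)["P1", "r1"]), 170)
  expect_equal(unname(abundances(q3)["P1", "r1"]), bruteTop(gs))
  # randomized cases against the brute-force oracle
  set.seed(31)
  for (i in 1:20) {
    gs <- replicate(sample(1:6, 1),
                    runif(sample(1:6, 1), 0, 100), simplify = FALSE)
    q <- inferProteinAbundance(pgTable(gs))
    expect_equal(unname(abundances(q)["P1", "r1"]), bruteTop(gs))
  }
})

test_that("abundance inference is row-order invariant and handles empties", {
  ds <- smallStudy()
  pg <- ds@peakGroups[ds@peakGroups$run_id %in%
                        unique(ds@peakGroups$run_id)[1:4], ]
  q1 <- inferProteinAbundance(pg)
  q2 <- inferProteinAbundance(pg[sample(nrow(pg)), ])
  expect_equal(abundances(q1), abundances(q2))
  q0 <- inferProteinAbundance(pg[0, ])
  expect_equal(dim(abundances(q0)), c(0L, 0L))
})

test_that("median equalization behaves like a median", {
  base <- pgTable(list(c(5, 4, 3), c(50, 40, 30), c(2, 1, 1)), run = "rA")
  doubled <- base; doubled$run_id <- "rB"
  for (j in grep("^frag_", names(doubled))) doubled[[j]] <- doubled[[j]] * 2
  nc <- computeNormalization(rbind(base, doubled))
  k <- normCoefficients(nc)
  expect_equal(unname(k["rB"] / k["rA"]), 0.5)
  # single run -> coefficient 1
  nc1 <- computeNormalization(base)
  expect_equal(unname(normCoefficients(nc1)), 1)
  # after application, per-run medians all equal the reference
  ds <- smallStudy()
  nc2 <- computeNormalization(ds@peakGroups)
  pg <- ds@peakGroups[ds@peakGroups$decoy == 0L, ]
  tot <- rowSums(as.matrix(pg[grep("^frag_", names(pg))]), na.rm = TRUE) *
    normCoefficients(nc2)[pg$run_id]
  med <- tapply(tot, pg$run_id, median)
  expect_equal(as.numeric(med), rep(nc2@reference, length(med)),
               tolerance = 1e-9)
})

test_that("normalization application is exact and reversible", {
  ds <- smallStudy()
  det <- smallDetection()
  quant <- inferProteinAbundance(ds@peakGroups, det$peptide,
                                 schedule = ds@schedule)
  nc <- computeNormalization(ds@peakGroups, det$peptide)
  qn <- applyNormalization(quant, nc)
  expect_true(isNormalized(qn))
  # identity under unit coefficients
  unit <- new("NormalizationCoefficients",
              coefficients = setNames(rep(1, ncol(abundances(quant))),
                                      colnames(abundances(quant))),
              reference = 1)
  expect_equal(abundances(applyNormalization(quant, unit)), abundances(quant))
  # multiplicative round trip
  inv <- new("NormalizationCoefficients",
             coefficients = 1 / normCoefficients(nc), reference = 1)
  back <- applyNormalization(qn, inv)
  expect_equal(abundances(back), abundances(quant), tolerance = 1e-12)
  # missing cells stay missing
  expect_identical(is.na(abundances(qn)), is.na(abundances(quant)))
  # a run without coefficient is an error
  nc2 <- new("NormalizationCoefficients",
             coefficients = normCoefficients(nc)[-1], reference = nc@reference)
  expect_error(applyNormalization(quant, nc2), "missing coefficient")
})

test_that("background coefficients reduce inter-site SIS variability", {
  ds <- smallStudy()
  nc <- computeNormalization(ds@peakGroups)
  sisN <- applyNormalization(ds@sisAreas, nc)
  cvBefore <- cvBreakdown(ds@sisAreas, "inter-site")
  cvAfter <- cvBreakdown(sisN, "inter-site")
  expect_lt(cvAfter$median, cvBefore$median)
})

test_that("a pure per-run multiplicative offset is removed exactly", {
  base <- pgTable(list(c(5, 4, 3), c(50, 40, 30), c(9, 1, 1)), run = "rA")
  rb <- base; rb$run_id <- "rB"
  for (j in grep("^frag_", names(rb))) rb[[j]] <- rb[[j]] * 3.7
  both <- rbind(base, rb)
  nc <- computeNormalization(both)
  qn <- abundances(applyNormalization(inferProteinAbundance(both), nc))
  expect_equal(unname(qn[, "rA"]), unname(qn[, "rB"]), tolerance = 1e-12)
})

test_that("log2 transform is finite on present cells and flag-aware", {
  ds <- smallStudy()
  quant <- inferProteinAbundance(ds@peakGroups, smallDetection()$peptide)
  lg <- logTransform(quant)
  expect_equal(quantScale(lg), "log2")
  a <- abundances(lg)
  expect_true(all(is.finite(a[!is.na(a)])))
  expect_identical(logTransform(lg), lg)  # idempotent
})
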