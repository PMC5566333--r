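# small fully separable toy table: score_1 separates targets from decoys
separableRecords <- function(n = 200) {
  data.frame(
    run_id = rep(c("r1", "r2"), n),
    peptide_query_id = c(sprintf("pep%03d", seq_len(n)),
                         sprintf("DECOY_pep%03d", seq_len(n))),
    protein_id = c(sprintf("prot%03d", seq_len(n)),
                   sprintf("DECOY_prot%03d", seq_len(n))),
    decoy = rep(c(0L, 1L), each = n),
    score_1 = c(rnorm(n, 5), rnorm(n, 0)),
    score_2 = rnorm(2 * n),
    score_3 = rnorm(2 * n),
    score_4 = rnorm(2 * n),
    score_5 = rnorm(2 * n),
    stringsAsFactors = FALSE)
}

auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

test_that("a perfectly separating sub-score yields AUROC 1 after learning", {
  set.seed(42)
  rec <- separableRecords()
  rec$score_1 <- c(rnorm(200, 10, 0.1), rnorm(200, 0, 0.1))  # fully separated
  sc <- learnDiscriminant(rec, seed = 1)
  expect_equal(auroc(sc$d_score, sc$decoy == 0L), 1.0)
})

test_that("learning is invariant to record order and seeded", {
  set.seed(7)
  rec <- separableRecords()
  sc1 <- learnDiscriminant(rec, seed = 3)
  perm <- sample(nrow(rec))
  sc2 <- learnDiscriminant(rec[perm, ], seed = 3)
  expect_equal(attr(sc1, "weights"), attr(sc2, "weights"))
  expect_equal(sc1$d_score, sc2$d_score[order(perm)])
})

test_that("degenerate inputs are handled explicitly", {
  rec <- separableRecords()
  expect_error(learnDiscriminant(rec[rec$decoy == 0L, ]), "decoy")
  rec2 <- rec
  rec2$score_3 <- 1  # constant sub-score
  expect_warning(sc <- learnDiscriminant(rec2, seed = 1), "degenerate")
  expect_equal(unname(attr(sc, "weights")["score_3"]), 0)
})

test_that("q-values are zero when all decoys score below all targets", {
  set.seed(1)
  rec <- separableRecords(50)
  rec$d_score <- ifelse(rec$decoy == 0L, rnorm(50, 10, 0.1), rnorm(50, 0, 0.1))
  q <- estimateQvalues(rec, context = "global", level = "peptide")
  expect_true(all(q$q[q$decoy == 0L] == 0))
})

test_that("q-values are monotone in score and invariant to duplication", {
  sc <- smallScored()
  for (ctx in c("global", "experiment-wide")) {
    q <- estimateQvalues(sc, context = ctx, level = "peptide")
    tq <- q[q$decoy == 0L, ]
    o <- order(tq$score, decreasing = TRUE)
    expect_true(all(diff(tq$q[o]) >= -1e-12))
    expect_true(all(tq$q >= 0 & tq$q <= 1))
  }
  # duplicating every record leaves the per-unit q unchanged (rank-based)
  sub <- sc[sc$run_id == sc$run_id[1], ]
  q1 <- estimateQvalues(sub, context = "run-specific", level = "peptide")
  q2 <- estimateQvalues(rbind(sub, sub), context = "run-specific",
                        level = "peptide")
  m <- merge(q1[q1$decoy == 0L, c("unit_id", "q")],
             unique(q2[q2$decoy == 0L, c("unit_id", "q")]), by = "unit_id")
  expect_equal(m$q.x, m$q.y)
})

test_that("lambda outside (0,1) is rejected", {
  expect_error(estimateQvalues(smallScored(), lambda = 1.2), "lambda")
  expect_error(estimateQvalues(smallScored(), lambda = 0), "lambda")
})

test_that("consecutive filter has conjunction semantics", {
  # one query passes run-wise everywhere but its protein fails globally
  gpep <- data.frame(unit_id = c("p1", "p2"), protein_id = c("A", "B"),
                     run_id = NA, decoy = 0L, score = c(5, 5), q = c(0, 0))
  gprot <- data.frame(unit_id = c("A", "B"), protein_id = c("A", "B"),
                      run_id = NA, decoy = 0L, score = c(5, 5), q = c(0, 0.5))
  rw <- data.frame(unit_id = rep(c("p1", "p2"), 2),
                   protein_id = rep(c("A", "B"), 2),
                   run_id = rep(c("r1", "r2"), each = 2), decoy = 0L,
                   score = 5, q = 0)
  det <- consecutiveFilter(gpep, gprot, rw, alpha = 0.01)
  calls <- detectionCalls(det$peptide)
  expect_true(all(calls["p1", ]))
  expect_false(any(calls["p2", ]))   # protein filter vetoes everywhere
  pcalls <- detectionCalls(det$protein)
  expect_true(all(pcalls["A", ]))
  expect_false(any(pcalls["B", ]))
  expect_error(consecutiveFilter(gpep, NULL, rw), "required")
})

test_that("alpha = 1 makes detection equal presence, and filters nest", {
  sc <- smallScored()
  gp <- estimateQvalues(sc, context = "global", level = "peptide")
  gpr <- estimateQvalues(sc, context = "global", level = "protein")
  ew <- estimateQvalues(sc, context = "experiment-wide", level = "peptide")
  detAll <- consecutiveFilter(gp, gpr, ew, alpha = 1 - 1e-12)
  calls <- detectionCalls(detAll$peptide)
  expect_equal(sum(calls, na.rm = TRUE), sum(sc$decoy == 0L))
  # global-context detected set contains every run's detected set
  det <- smallDetection()
  globalSet <- gp$unit_id[gp$decoy == 0L & gp$q <= 0.01]
  m <- detectionCalls(det$peptide)
  for (r in sample(colnames(m), 5)) {
    runSet <- rownames(m)[!is.na(m[, r]) & m[, r]]
    expect_true(all(runSet %in% globalSet))
  }
})

test_that("filter output is idempotent w.r.t. input row order", {
  sc <- smallScored()
  gp <- estimateQvalues(sc, context = "global", level = "peptide")
  gpr <- estimateQvalues(sc, context = "global", level = "protein")
  ew <- estimateQvalues(sc, context = "experiment-wide", level = "peptide")
  d1 <- consecutiveFilter(gp, gpr, ew)
  perm <- sample(nrow(ew))
  d2 <- consecutiveFilter(gp, gpr, ew[perm, ])
  expect_identical(detectionCalls(d1$peptide), detectionCalls(d2$peptide))
  expect_identical(detectionCalls(d1$protein), detectionCalls(d2$protein))
})

test_that("cumulative detection curves behave like set unions", {
  m <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, TRUE, FALSE,
                FALSE, TRUE, TRUE), nrow = 3, byrow = TRUE,
              dimnames = list(c("u1", "u2", "u3"), c("r1", "r2", "r3")))
  dm <- new("DetectionMatrix", calls = m, level = "peptide", alpha = 0.01,
            proteinMap = character())
  cc <- cumulativeDetectionCurve(dm)
  expect_equal(unname(cc), c(2, 3, 3))
  expect_true(all(diff(cc) >= 0))
  # single run
  expect_equal(unname(cumulativeDetectionCurve(dm, "r2")), 3)
  # reversal preserves the final union
  ccRev <- cumulativeDetectionCurve(dm, rev(colnames(m)))
  expect_equal(unname(ccRev[length(ccRev)]), unname(cc[length(cc)]))
  # identical detection in all runs: flat after the first
  m2 <- matrix(TRUE, 3, 3, dimnames = dimnames(m))
  dm2 <- new("DetectionMatrix", calls = m2, level = "peptide", alpha = 0.01,
             proteinMap = character())
  expect_equal(unname(cumulativeDetectionCurve(dm2)), c(3, 3, 3))
  expect_error(cumulativeDetectionCurve(dm, c("r1", "rX")), "unknown run")
})

test_that("subsampled learning reproduces the full-data detection set", {
  ds <- smallStudy()
  full <- learnDiscriminant(ds@peakGroups, subsampleRatio = 1, seed = 2)
  sub <- learnDiscriminant(ds@peakGroups, subsampleRatio = 1 / 63, seed = 2)
  # fraction of target peak groups classified the same way relative to the
  # full-data fit's top-decile cut
  inTop <- function(x) {
    t <- x[x$decoy == 0L, ]
    setNames(t$d_score >= quantile(t$d_score, 0.9),
             paste(t$run_id, t$peptide_query_id))
  }
  a <- inTop(full); b <- inTop(sub)
  expect_gt(mean(a == b[names(a)]), 0.95)
})
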