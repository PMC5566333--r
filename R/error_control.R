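# --- target-decoy error control ---------------------------------------------

scoreColumns <- function(pg) grep("^score_[0-9]+$", names(pg), value = TRUE)

#' Learn a discriminant score from sub-scores (semi-supervised)
#'
#' Combines the peak-group sub-scores into a single discriminant score by
#' iterated linear discriminant analysis: the classifier is seeded on one
#' designated sub-score; at each iteration the targets passing a q-value
#' cut (default 0.15) against all decoys define the positive class, a
#' linear discriminant is fitted, and all records are rescored. Weights are
#' learned on a record subsample (ratio ~ 1/number of runs in the original
#' analysis) and applied to every record. The returned d-scores are
#' standardized against the decoy distribution (decoys ~ mean 0, sd 1).
#'
#' Record order does not affect the result: records are sorted by
#' (query id, run id) before subsampling.
#'
#' @param pg peak-group data.frame with \code{decoy} and \code{score_*}
#'   columns.
#' @param subsampleRatio fraction of records used for learning (default 1).
#' @param nIterations LDA refinement iterations (default 5).
#' @param seed RNG seed for the subsample.
#' @param initScore index of the seeding sub-score (default 1).
#' @param selectionAlpha q-value cut defining positives during learning
#'   (default 0.15).
#' @return \code{pg} with a \code{d_score} column; the learned weights are
#'   attached as \code{attr(, "weights")}.
#' @export
learnDiscriminant <- function(pg, subsampleRatio = 1, nIterations = 5,
                              seed = 1, initScore = 1,
                              selectionAlpha = 0.15) {
  stopifnot(subsampleRatio > 0, subsampleRatio <= 1)
  if (!any(pg$decoy == 1L)) stop("no decoy records: q-values are undefined")
  if (!any(pg$decoy == 0L)) stop("no target records")
  sc <- scoreColumns(pg)
  ord <- order(pg$peptide_query_id, pg$run_id)
  X <- as.matrix(pg[ord, sc, drop = FALSE])
  decoy <- pg$decoy[ord] == 1L

  keepCol <- apply(X, 2, function(z) sd(z) > 0)
  if (!all(keepCol)) {
    warning("degenerate constant sub-score(s) given weight 0: ",
            paste(sc[!keepCol], collapse = ", "))
  }
  idx <- withSeed(seed, sort(sample.int(nrow(X), max(2, round(subsampleRatio * nrow(X))))))
  if (!any(decoy[idx]) || !any(!decoy[idx])) idx <- seq_len(nrow(X))  # tiny-subsample fallback
  Xs <- X[idx, , drop = FALSE]
  ds <- decoy[idx]

  w <- rep(0, length(sc))
  w[initScore] <- 1
  scores <- drop(Xs %*% w)
  for (it in seq_len(nIterations)) {
    q <- decoyQvalues(scores, ds, lambda = 0.4)
    pos <- !ds & q <= selectionAlpha
    if (sum(pos) < 2L) break
    Xfit <- rbind(Xs[pos, keepCol, drop = FALSE], Xs[ds, keepCol, drop = FALSE])
    yfit <- factor(c(rep("target", sum(pos)), rep("decoy", sum(ds))))
    fit <- MASS::lda(Xfit, grouping = yfit)
    wNew <- rep(0, length(sc))
    wNew[keepCol] <- fit$scaling[, 1]
    # orient toward targets scoring high
    if (mean(Xs[pos, , drop = FALSE] %*% wNew) < mean(Xs[ds, , drop = FALSE] %*% wNew)) {
      wNew <- -wNew
    }
    w <- wNew
    scores <- drop(Xs %*% w)
  }
  d <- drop(X %*% w)
  d <- (d - mean(d[decoy])) / sd(d[decoy])
  out <- pg
  out$d_score <- d[order(ord)]  # back to the input row order
  attr(out, "weights") <- setNames(w, sc)
  out
}

# Storey q-values from a decoy null: p(s) = #decoys >= s / #decoys,
# pi0 from the target p-value mass above lambda, q = running minimum of
# pi0 * #targets * p / #{targets >= s} over thresholds at or below s.
decoyQvalues <- function(score, decoy, lambda = 0.4) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  t_scores <- score[!decoy]
  d_scores <- sort(score[decoy])
  nT <- length(t_scores); nD <- length(d_scores)
  if (nD == 0L) stop("no decoys")
  ordT <- order(t_scores, decreasing = TRUE)
  s <- t_scores[ordT]
  pD <- (nD - findInterval(s, d_scores)) / nD   # P(decoy > s); ties at
  # exactly s count as below, which is the conservative direction, and
  # continuous scores make ties measure-zero anyway.
  pi0 <- min(1, max(0, mean(pD > lambda) / (1 - lambda)))
  fdr <- pi0 * nT * pD / seq_len(nT)
  q <- rev(cummin(rev(fdr)))
  q <- pmin(pmax(q, 0), 1)
  out <- numeric(nT)
  out[ordT] <- q
  res <- numeric(length(score))
  res[!decoy] <- out
  res[decoy] <- NA_real_
  res
}

#' Estimate q-values in a chosen context and at a chosen level
#'
#' Computes target-decoy Storey q-values (fixed \eqn{\lambda}, default 0.4)
#' from discriminant scores.
#'
#' Contexts: \describe{
#'   \item{global}{one q-value per unit, computed on the best-scoring
#'     record of each unit across all runs;}
#'   \item{experiment-wide}{one q-value per unit per run, estimated from
#'     the score distribution pooled over the whole experiment;}
#'   \item{run-specific}{one q-value per unit per run, estimated within
#'     each run separately.}}
#'
#' At the protein level each protein is scored by the best d-score among
#' its peptide queries (decoy proteins inherit their decoy queries).
#'
#' @param scored peak-group data.frame with \code{d_score}, \code{decoy},
#'   \code{peptide_query_id}, \code{protein_id}, \code{run_id}.
#' @param lambda Storey tuning parameter in (0, 1), default 0.4.
#' @param context one of \code{"global"}, \code{"experiment-wide"},
#'   \code{"run-specific"}.
#' @param level \code{"peptide"} or \code{"protein"}.
#' @return data.frame with \code{unit_id}, \code{protein_id},
#'   \code{run_id} (\code{NA} in the global context), \code{level},
#'   \code{context}, \code{decoy}, \code{score}, \code{q} (\code{NA} for
#'   decoy rows).
#' @export
estimateQvalues <- function(scored, lambda = 0.4,
                            context = c("global", "experiment-wide", "run-specific"),
                            level = c("peptide", "protein")) {
  context <- match.arg(context)
  level <- match.arg(level)
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  dt <- data.table::as.data.table(
    scored[, c("peptide_query_id", "protein_id", "run_id", "decoy", "d_score")])
  if (level == "protein") {
    dt <- dt[, .(d_score = max(d_score), decoy = decoy[1]),
             by = .(protein_id, run_id)]
    dt[, unit_id := protein_id]
  } else {
    dt[, unit_id := peptide_query_id]
  }
  # stable tie-break: order by score desc then unit id
  data.table::setorder(dt, -d_score, unit_id)
  if (context == "global") {
    dt <- dt[, .SD[1], by = unit_id]   # best-scoring record per unit
    dt[, run_id := NA_character_]
    dt[, q := decoyQvalues(d_score, decoy == 1L, lambda)]
  } else if (context == "experiment-wide") {
    dt[, q := decoyQvalues(d_score, decoy == 1L, lambda)]
  } else {
    dt[, q := decoyQvalues(d_score, decoy == 1L, lambda), by = run_id]
  }
  out <- as.data.frame(dt[, .(unit_id, protein_id, run_id, decoy,
                              score = d_score, q)])
  out$level <- level
  out$context <- context
  out
}

#' Consecutive FDR filtering into detection calls
#'
#' A peptide query is called detected in a run iff (i) its global-context
#' q-value is at or below \code{alpha}, (ii) its protein's global-context
#' q-value is at or below \code{alpha}, and (iii) its run-wise
#' (experiment-wide context) q-value in that run is at or below
#' \code{alpha}. A protein is detected in a run iff any of its queries is.
#'
#' @param globalPeptide,globalProtein,runwisePeptide q-value tables from
#'   [estimateQvalues()] over the same dataset.
#' @param alpha FDR threshold in (0, 1), default 0.01.
#' @return list with \code{peptide} and \code{protein}
#'   \linkS4class{DetectionMatrix} objects (target units only).
#' @export
consecutiveFilter <- function(globalPeptide, globalProtein, runwisePeptide,
                              alpha = 0.01) {
  if (is.null(globalPeptide) || is.null(globalProtein) || is.null(runwisePeptide)) {
    stop("all three q-value tables are required")
  }
  stopifnot(alpha > 0, alpha < 1)
  rw <- runwisePeptide[runwisePeptide$decoy == 0L, , drop = FALSE]
  gpep <- globalPeptide[globalPeptide$decoy == 0L, , drop = FALSE]
  gprot <- globalProtein[globalProtein$decoy == 0L, , drop = FALSE]
  passPep <- setNames(gpep$q <= alpha, gpep$unit_id)
  passProt <- setNames(gprot$q <= alpha, gprot$unit_id)
  det <- (rw$q <= alpha) &
    !is.na(passPep[rw$unit_id]) & passPep[rw$unit_id] &
    !is.na(passProt[rw$protein_id]) & passProt[rw$protein_id]
  det[is.na(det)] <- FALSE

  units <- sort(unique(rw$unit_id))
  runs <- sort(unique(rw$run_id))
  m <- matrix(NA, nrow = length(units), ncol = length(runs),
              dimnames = list(units, runs))
  m[cbind(match(rw$unit_id, units), match(rw$run_id, runs))] <- det
  pmap <- setNames(rw$protein_id, rw$unit_id)[units]
  pepDM <- new("DetectionMatrix", calls = m, level = "peptide",
               alpha = alpha, proteinMap = pmap)

  prots <- sort(unique(rw$protein_id))
  pm <- matrix(NA, nrow = length(prots), ncol = length(runs),
               dimnames = list(prots, runs))
  dtt <- data.table::data.table(protein_id = rw$protein_id, run_id = rw$run_id,
                                det = det)
  agg <- dtt[, .(det = any(det)), by = .(protein_id, run_id)]
  pm[cbind(match(agg$protein_id, prots), match(agg$run_id, runs))] <- agg$det
  protDM <- new("DetectionMatrix", calls = pm, level = "protein",
                alpha = alpha, proteinMap = character())
  list(peptide = pepDM, protein = protDM)
}

#' Detection calls from a single per-run q-value table
#'
#' Threshold-only detection (no global filtering): used to contrast the
#' consecutive filter with naive run-context-only filtering.
#'
#' @param qtab a per-run q-value table (experiment-wide or run-specific
#'   context).
#' @param alpha FDR threshold.
#' @param level matrix level label.
#' @return a \linkS4class{DetectionMatrix}.
#' @export
detectionFromQ <- function(qtab, alpha = 0.01, level = "peptide") {
  rw <- qtab[qtab$decoy == 0L, , drop = FALSE]
  units <- sort(unique(rw$unit_id))
  runs <- sort(unique(rw$run_id))
  m <- matrix(NA, length(units), length(runs), dimnames = list(units, runs))
  m[cbind(match(rw$unit_id, units), match(rw$run_id, runs))] <- rw$q <= alpha
  new("DetectionMatrix", calls = m, level = level, alpha = alpha,
      proteinMap = character())
}

#' Cumulative distinct-unit detection curve
#'
#' Number of distinct units detected in the first k runs of a given
#' acquisition order, for k = 1..nRuns; non-decreasing and ending at the
#' study-wide distinct count.
#'
#' @param dm a \linkS4class{DetectionMatrix}.
#' @param runOrder run ids covering the matrix columns (default: column
#'   order).
#' @return named integer vector of cumulative counts.
#' @export
cumulativeDetectionCurve <- function(dm, runOrder = NULL) {
  m <- dm@calls
  if (is.null(runOrder)) runOrder <- colnames(m)
  if (!all(runOrder %in% colnames(m))) {
    stop("unknown run in order: ",
         paste(setdiff(runOrder, colnames(m)), collapse = ", "))
  }
  seen <- rep(FALSE, nrow(m))
  out <- integer(length(runOrder))
  for (k in seq_along(runOrder)) {
    seen <- seen | (!is.na(m[, runOrder[k]]) & m[, runOrder[k]])
    out[k] <- sum(seen)
  }
  names(out) <- runOrder
  out
}
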