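# --- multi-level CV, repeatability, completeness ----------------------------

#' Coefficient of variation in percent
#'
#' \code{100 * sample standard deviation / mean}.
#'
#' @param x at least two finite positive values.
#' @return CV in percent.
#' @export
cvPercent <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values")
  m <- mean(x)
  if (m == 0) stop("CV undefined for zero mean")
  100 * sd(x) / m
}

cvSafe <- function(x) if (length(x) >= 2 && mean(x) != 0) 100 * sd(x) / mean(x) else NA_real_

#' Multi-level CV breakdown
#'
#' Computes per-unit coefficients of variation at one of three nesting
#' levels and summarises the pooled distribution as median and standard
#' deviation (the field's conventional "median +/- sd" report).
#'
#' For a SIS area table (\code{scope = "sis"}; uses the replicate sample,
#' S4 by default, at MS2): \describe{
#'   \item{intra-day}{CV over the same-day replicate injections, one value
#'     per peptide x site x day;}
#'   \item{inter-day}{CV over all replicate-sample injections of the week,
#'     one value per peptide x site;}
#'   \item{inter-site}{CV over all replicate-sample injections study-wide,
#'     one value per peptide.}}
#'
#' For a \linkS4class{ProteinQuantMatrix} (\code{scope = "protein"};
#' requires run metadata in \code{colData}): the same nesting applied to
#' all runs, restricted to proteins present in more than
#' \code{completenessThreshold} of runs.
#'
#' @param x SIS area data.frame or \linkS4class{ProteinQuantMatrix}.
#' @param level \code{"intra-day"}, \code{"inter-day"} or
#'   \code{"inter-site"}.
#' @param replicateSample SIS scope: which sample carries the replicates
#'   (default \code{"S4"}).
#' @param msLevel SIS scope: MS level to use (default \code{"MS2"}).
#' @param completenessThreshold protein scope: strict lower bound on the
#'   present fraction (default 0.8).
#' @return list with \code{values} (per-unit data.frame), \code{median},
#'   \code{sd}, \code{n}, and \code{bySite} medians where applicable.
#' @export
cvBreakdown <- function(x, level = c("intra-day", "inter-day", "inter-site"),
                        replicateSample = "S4", msLevel = "MS2",
                        completenessThreshold = 0.8) {
  level <- match.arg(level)
  if (is(x, "ProteinQuantMatrix")) {
    a <- abundances(x)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    stopifnot(all(c("site_id", "day") %in% names(cd)))
    keep <- rowMeans(!is.na(a)) > completenessThreshold
    a <- a[keep, , drop = FALSE]
    long <- data.table::data.table(
      unit_id = rep(rownames(a), ncol(a)),
      run_id = rep(colnames(a), each = nrow(a)),
      site_id = rep(cd$site_id, each = nrow(a)),
      day = rep(cd$day, each = nrow(a)),
      value = as.vector(a))[!is.na(value)]
  } else {
    dt <- data.table::as.data.table(x)
    dt <- dt[sample_id == replicateSample & ms_level == msLevel]
    long <- dt[, .(unit_id = peptide_id, site_id, day, value = area)]
  }
  vals <- switch(level,
    "intra-day" = long[, .(cv_percent = cvSafe(value)),
                       by = .(unit_id, site_id, day)],
    "inter-day" = long[, .(cv_percent = cvSafe(value)),
                       by = .(unit_id, site_id)],
    "inter-site" = long[, .(cv_percent = cvSafe(value)), by = .(unit_id)])
  vals <- vals[!is.na(cv_percent)]
  bySite <- if ("site_id" %in% names(vals)) {
    bs <- vals[, .(median_cv = median(cv_percent)), by = site_id]
    setNames(bs$median_cv, bs$site_id)
  } else NULL
  list(values = as.data.frame(vals), level = level,
       median = median(vals$cv_percent), sd = sd(vals$cv_percent),
       n = nrow(vals), bySite = bySite)
}

#' Pairwise detection repeatability
#'
#' 100 x |A intersect B| / |A union B| between the detected sets of two
#' runs. Undefined (NA) when both sets are empty.
#'
#' @param a,b character vectors of detected unit ids.
#' @return percent overlap.
#' @export
repeatability <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  100 * length(intersect(a, b)) / u
}

#' Repeatability summary over a detection matrix
#'
#' All pairwise repeatability values between runs, grouped within sites or
#' study-wide, with the median per group. Undefined pairs (two empty runs)
#' are excluded from medians and counted separately.
#'
#' @param dm a \linkS4class{DetectionMatrix}.
#' @param schedule run schedule (needed for \code{"within-site"}).
#' @param grouping \code{"study-wide"} or \code{"within-site"}.
#' @return list with \code{pairs} (data.frame run_a, run_b, group,
#'   percent), \code{medians} (named numeric per group) and
#'   \code{nUndefined}.
#' @export
repeatabilitySummary <- function(dm, schedule = NULL,
                                 grouping = c("study-wide", "within-site")) {
  grouping <- match.arg(grouping)
  m <- dm@calls
  m[is.na(m)] <- FALSE
  runs <- colnames(m)
  groupOf <- if (grouping == "within-site") {
    stopifnot(!is.null(schedule))
    setNames(schedule$site_id, schedule$run_id)[runs]
  } else setNames(rep("study-wide", length(runs)), runs)

  pairs <- list()
  for (g in unique(groupOf)) {
    rg <- runs[groupOf == g]
    if (length(rg) < 2L) next
    cb <- utils::combn(rg, 2)
    # |A n B| and |A u B| via crossproducts on the 0/1 matrix
    sub <- m[, rg, drop = FALSE] * 1
    inter <- crossprod(sub)
    tot <- colSums(sub)
    uni <- outer(tot, tot, `+`) - inter
    pct <- ifelse(uni == 0, NA_real_, 100 * inter / uni)
    pairs[[g]] <- data.frame(
      run_a = cb[1, ], run_b = cb[2, ], group = g,
      percent = pct[cbind(cb[1, ], cb[2, ])],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  meds <- tapply(pairs$percent, pairs$group, median, na.rm = TRUE)
  list(pairs = pairs, medians = meds,
       nUndefined = sum(is.na(pairs$percent)))
}

#' Completeness filtering and reporting order
#'
#' Returns the units whose fraction of present (non-missing) cells
#' strictly exceeds \code{threshold}, plus a display ordering of all rows
#' by (completeness, mean abundance) descending.
#'
#' @param x a \linkS4class{ProteinQuantMatrix}.
#' @param threshold strict lower bound on the present fraction
#'   (default 0.8).
#' @return list with \code{units} (character), \code{fraction} (named
#'   numeric), and \code{ordering} (row names in display order).
#' @export
completeness <- function(x, threshold = 0.8) {
  a <- abundances(x)
  frac <- rowMeans(!is.na(a))
  meanAb <- rowMeans(a, na.rm = TRUE)
  ordering <- rownames(a)[order(-frac, -meanAb)]
  list(units = rownames(a)[frac > threshold], fraction = frac,
       ordering = ordering)
}
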