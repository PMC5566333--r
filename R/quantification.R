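# --- protein quantification and median normalization ------------------------

fragColumns <- function(pg) grep("^frag_[0-9]+$", names(pg), value = TRUE)

#' Infer protein abundances (topN fragment summation)
#'
#' Per protein and run: rank the detected peak groups by total fragment
#' area, keep the \code{topPeakGroups} most intense (all of them if fewer),
#' within each sum the \code{topFragments} most intense fragment areas (all
#' if fewer), and sum across the selected peak groups. With the defaults
#' this is the top-5-fragments-of-top-3-peak-groups estimator.
#'
#' @param pg peak-group data.frame with \code{frag_*} columns.
#' @param detection optional peptide-level \linkS4class{DetectionMatrix};
#'   when given, only (query, run) cells called detected contribute.
#' @param schedule optional run schedule; when given, run metadata (site,
#'   day, sample) is attached as column data.
#' @param topPeakGroups,topFragments selection depths (defaults 3 and 5).
#' @return a \linkS4class{ProteinQuantMatrix} (linear scale, unnormalized);
#'   cells are \code{NA} where a protein was not detected in a run. An
#'   empty input yields an empty matrix.
#' @export
inferProteinAbundance <- function(pg, detection = NULL, schedule = NULL,
                                  topPeakGroups = 3, topFragments = 5) {
  fc <- fragColumns(pg)
  dt <- data.table::as.data.table(pg)[decoy == 0L]
  if (!is.null(detection)) {
    calls <- detection@calls
    ok <- calls[cbind(match(dt$peptide_query_id, rownames(calls)),
                      match(dt$run_id, colnames(calls)))]
    dt <- dt[!is.na(ok) & ok]
  }
  if (nrow(dt) == 0L) {
    a <- matrix(numeric(0), 0, 0)
    se <- SummarizedExperiment::SummarizedExperiment(assays = list(abundance = a))
    return(new("ProteinQuantMatrix", se, scale = "linear", normalized = FALSE))
  }
  fm <- as.matrix(dt[, fc, with = FALSE])
  fm[is.na(fm)] <- 0
  topSum <- function(x, k) sum(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])
  dt[, total_area := rowSums(fm)]
  dt[, pg_quant := apply(fm, 1, topSum, k = topFragments)]
  agg <- dt[order(-total_area),
            .(abundance = sum(pg_quant[seq_len(min(topPeakGroups, .N))])),
            by = .(protein_id, run_id)]
  prots <- sort(unique(agg$protein_id))
  runs <- sort(unique(dt$run_id))
  a <- matrix(NA_real_, length(prots), length(runs),
              dimnames = list(prots, runs))
  a[cbind(match(agg$protein_id, prots), match(agg$run_id, runs))] <- agg$abundance
  cd <- NULL
  if (!is.null(schedule)) {
    cd <- schedule[match(runs, schedule$run_id),
                   c("run_id", "site_id", "day", "sample_id", "replicate_index")]
    rownames(cd) <- runs
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = a),
    colData = if (is.null(cd)) S4Vectors::DataFrame(row.names = runs)
              else S4Vectors::DataFrame(cd))
  new("ProteinQuantMatrix", se, scale = "linear", normalized = FALSE)
}

#' Median-equalization normalization coefficients
#'
#' Computes one multiplicative coefficient per run so that every run's
#' median peak-group area equals a common reference (the median of the
#' per-run medians). Computed on target (non-decoy) peak groups only, so
#' the invariant-background assumption holds; pass detection calls to
#' restrict to confidently detected peak groups.
#'
#' @param pg peak-group data.frame.
#' @param detection optional peptide-level \linkS4class{DetectionMatrix}.
#' @return a \linkS4class{NormalizationCoefficients}.
#' @export
computeNormalization <- function(pg, detection = NULL) {
  dt <- data.table::as.data.table(pg)[decoy == 0L]
  if (!is.null(detection)) {
    calls <- detection@calls
    ok <- calls[cbind(match(dt$peptide_query_id, rownames(calls)),
                      match(dt$run_id, colnames(calls)))]
    dt <- dt[!is.na(ok) & ok]
  }
  if (nrow(dt) == 0L) stop("no peak groups to normalize on")
  fm <- as.matrix(dt[, fragColumns(pg), with = FALSE])
  fm[is.na(fm)] <- 0
  dt[, total_area := rowSums(fm)]
  med <- dt[, .(m = median(total_area)), by = run_id]
  if (any(med$m <= 0)) {
    stop("run(s) with non-positive median area: ",
         paste(med$run_id[med$m <= 0], collapse = ", "))
  }
  ref <- median(med$m)
  new("NormalizationCoefficients",
      coefficients = setNames(ref / med$m, med$run_id), reference = ref)
}

#' @rdname applyNormalization
#' @export
setMethod("applyNormalization",
          signature(x = "ProteinQuantMatrix", coefficients = "NormalizationCoefficients"),
  function(x, coefficients) {
    if (x@scale != "linear") stop("normalize on the linear scale, before log transform")
    k <- coefficients@coefficients
    a <- abundances(x)
    missing <- setdiff(colnames(a), names(k))
    if (length(missing)) stop("missing coefficient for run(s): ",
                              paste(missing, collapse = ", "))
    SummarizedExperiment::assay(x, "abundance") <-
      sweep(a, 2, k[colnames(a)], `*`)
    x@normalized <- TRUE
    x
  })

#' @rdname applyNormalization
#' @export
setMethod("applyNormalization",
          signature(x = "matrix", coefficients = "NormalizationCoefficients"),
  function(x, coefficients) {
    k <- coefficients@coefficients
    missing <- setdiff(colnames(x), names(k))
    if (length(missing)) stop("missing coefficient for run(s): ",
                              paste(missing, collapse = ", "))
    sweep(x, 2, k[colnames(x)], `*`)
  })

#' @rdname applyNormalization
#' @export
setMethod("applyNormalization",
          signature(x = "data.frame", coefficients = "NormalizationCoefficients"),
  function(x, coefficients) {
    stopifnot(all(c("run_id", "area") %in% names(x)))
    k <- coefficients@coefficients
    missing <- setdiff(unique(x$run_id), names(k))
    if (length(missing)) stop("missing coefficient for run(s): ",
                              paste(missing, collapse = ", "))
    x$area <- x$area * k[x$run_id]
    x
  })

#' log2-transform a protein abundance matrix
#'
#' @param x a linear-scale \linkS4class{ProteinQuantMatrix}.
#' @return the matrix on the log2 scale; missing cells stay missing, and
#'   every present cell is finite (linear abundances are positive by
#'   class validity).
#' @export
logTransform <- function(x) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  if (x@scale == "log2") return(x)
  SummarizedExperiment::assay(x, "abundance") <- log2(abundances(x))
  x@scale <- "log2"
  x
}
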