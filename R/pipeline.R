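# --- orchestration, configuration, file I/O ---------------------------------

.PG_COLUMNS <- c("run_id", "peptide_query_id", "protein_id", "decoy",
                 paste0("score_", 1:5), paste0("frag_", 1:6), "ms1_area", "rt")
.SIS_COLUMNS <- c("run_id", "site_id", "day", "sample_id", "replicate_index",
                  "peptide_id", "group_id", "nominal_fmol", "ms_level",
                  "area", "sn")

#' Default pipeline configuration
#'
#' All analysis thresholds and synthetic-generator parameters in one list:
#' FDR threshold \code{alpha} 0.01, Storey \code{lambda} 0.4, LLOQ criteria
#' (CV < 20\%, S/N > 20, accuracy 80-120\%), completeness threshold 0.8,
#' and the generator sizes/noise levels.
#'
#' @param ... overrides merged over the defaults by name.
#' @return named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    alpha = 0.01, lambda = 0.4,
    cvMax = 20, snMin = 20, accuracyBand = c(80, 120),
    completenessThreshold = 0.8,
    seed = 1,
    nSites = 11, nProteins = 500, spanOrders = 4.5, meanPeptides = 8,
    dropout = 0, decoyRatio = 1, noiseTargetRate = 0.5, libraryFraction = 1,
    subsampleRatio = 1, nIterations = 5)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

configHash <- function(cfg) {
  stableHash(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}

#' Run the full benchmarking pipeline
#'
#' Executes simulate (synthetic mode) or load (real mode), then
#' discriminant scoring, q-value estimation, consecutive FDR filtering,
#' protein inference and normalization, dilution-series metrics,
#' CV/repeatability metrics and similarity analysis, and assembles a study
#' report. Identical config and seed give identical reports.
#'
#' @param config list from [defaultConfig()].
#' @param mode \code{"synthetic"} (generate the study) or \code{"real"}
#'   (supply \code{dataset}).
#' @param dataset a \linkS4class{StudyDataset} in real mode (read with
#'   [readPeakGroups()] / [readSISTable()] and assembled by the caller).
#' @param perSite also run the detection analysis independently per site
#'   (default FALSE; the aggregated analysis is always produced).
#' @return list (study report) with elements \code{design},
#'   \code{dataset}, \code{detection}, \code{quant}, \code{dilution},
#'   \code{reproducibility}, \code{similarity}, \code{provenance}.
#' @export
runPipeline <- function(config = defaultConfig(), mode = c("synthetic", "real"),
                        dataset = NULL, perSite = FALSE) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    design <- buildDesign(nSites = config$nSites)
    dataset <- simulateStudy(design, seed = config$seed,
                             dropout = config$dropout,
                             decoyRatio = config$decoyRatio,
                             noiseTargetRate = config$noiseTargetRate,
                             nProteins = config$nProteins,
                             spanOrders = config$spanOrders,
                             meanPeptides = config$meanPeptides,
                             libraryFraction = config$libraryFraction)
  } else if (is.null(dataset)) {
    stop("real mode requires a StudyDataset")
  } else {
    design <- dataset@design
  }
  sched <- dataset@schedule

  ## error control
  scored <- learnDiscriminant(dataset@peakGroups,
                              subsampleRatio = config$subsampleRatio,
                              nIterations = config$nIterations,
                              seed = config$seed)
  gPep <- estimateQvalues(scored, config$lambda, "global", "peptide")
  gProt <- estimateQvalues(scored, config$lambda, "global", "protein")
  ewPep <- estimateQvalues(scored, config$lambda, "experiment-wide", "peptide")
  det <- consecutiveFilter(gPep, gProt, ewPep, alpha = config$alpha)
  ordRuns <- sched$run_id[order(sched$site_id, sched$acquisition_order)]
  ordRuns <- intersect(ordRuns, colnames(det$protein@calls))
  cumCurve <- cumulativeDetectionCurve(det$protein, ordRuns)

  perSiteCounts <- NULL
  if (perSite) {
    perSiteCounts <- lapply(split(sched$run_id, sched$site_id), function(rr) {
      sub <- dataset@peakGroups[dataset@peakGroups$run_id %in% rr, , drop = FALSE]
      s <- learnDiscriminant(sub, subsampleRatio = config$subsampleRatio,
                             nIterations = config$nIterations,
                             seed = config$seed)
      d <- consecutiveFilter(
        estimateQvalues(s, config$lambda, "global", "peptide"),
        estimateQvalues(s, config$lambda, "global", "protein"),
        estimateQvalues(s, config$lambda, "experiment-wide", "peptide"),
        alpha = config$alpha)
      colSums(d$protein@calls, na.rm = TRUE)
    })
  }

  ## quantification + normalization
  quant <- inferProteinAbundance(dataset@peakGroups, detection = det$peptide,
                                 schedule = sched)
  coefs <- computeNormalization(dataset@peakGroups, detection = det$peptide)
  quantNorm <- applyNormalization(quant, coefs)
  sisNorm <- applyNormalization(dataset@sisAreas, coefs)

  ## dilution metrics (MS2 and MS1)
  lloq <- lloqReport(dataset@sisAreas, cvMax = config$cvMax,
                     snMin = config$snMin,
                     accuracyBand = config$accuracyBand)
  pct <- percentDetected(lloq)
  folds <- stepFoldChanges(
    dataset@sisAreas[dataset@sisAreas$ms_level == "MS2", ],
    lloq = lloq[lloq$ms_level == "MS2", ])

  ## reproducibility
  cvs <- list(
    intraDay = cvBreakdown(dataset@sisAreas, "intra-day"),
    interDay = cvBreakdown(dataset@sisAreas, "inter-day"),
    interSite = cvBreakdown(dataset@sisAreas, "inter-site"),
    interSiteNormalized = cvBreakdown(sisNorm, "inter-site"),
    proteinInterSite = cvBreakdown(
      quantNorm, "inter-site",
      completenessThreshold = config$completenessThreshold))
  rep_ws <- repeatabilitySummary(det$protein, sched, "study-wide")
  rep_site <- repeatabilitySummary(det$protein, sched, "within-site")
  comp <- completeness(quant, config$completenessThreshold)

  ## similarity
  cm <- pearsonMatrix(quantNorm)
  tree <- tryCatch(hierarchicalCluster(quantNorm), error = function(e) NULL)
  siteOf <- setNames(sched$site_id, sched$run_id)
  sim <- similaritySummary(cm, siteOf)

  list(
    design = design, dataset = dataset,
    detection = list(
      matrices = det, qGlobalPeptide = gPep, qGlobalProtein = gProt,
      qRunwisePeptide = ewPep,
      nProteinsGlobal = sum(gProt$q[gProt$decoy == 0L] <= config$alpha,
                            na.rm = TRUE),
      cumulativeCurve = cumCurve, perSiteCounts = perSiteCounts,
      weights = attr(scored, "weights")),
    quant = list(matrix = quant, normalized = quantNorm,
                 coefficients = coefs, completeness = comp),
    dilution = list(lloq = lloq, percentDetected = pct, foldChanges = folds),
    reproducibility = list(cv = cvs, repeatabilityStudyWide = rep_ws,
                           repeatabilityWithinSite = rep_site),
    similarity = list(correlation = cm, tree = tree, summary = sim),
    provenance = list(config = config, configHash = configHash(config),
                      seed = config$seed,
                      packageVersion = as.character(utils::packageVersion("swathQC"))))
}

# ---- TSV dialect: tab-separated, UTF-8, '.' decimals, no quoting -----------

writeTSV <- function(x, path, meta = NULL) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(meta)) {
    writeLines(paste(names(meta), unlist(meta), sep = "="),
               paste0(path, ".meta"))
  }
  invisible(path)
}

readTSVChecked <- function(path, required, numericCols) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in intersect(numericCols, names(x))) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]) & x[[col]] != "NA")
    if (length(bad)) {
      stop("malformed value in column '", col, "' at line ", bad[1] + 1L)
    }
    x[[col]] <- v
  }
  x
}

#' Read / write peak-group tables
#'
#' The peak-group dialect: one header line, tab-separated, UTF-8, '.'
#' decimal separator, no quoting; one row per peak group per run with
#' columns \code{run_id}, \code{peptide_query_id}, \code{protein_id},
#' \code{decoy} (0/1), \code{score_1..5}, \code{frag_1..6},
#' \code{ms1_area}, \code{rt}. Write/read round trips are the identity up
#' to float formatting. A sidecar \code{.meta} file carries provenance
#' (seed, config hash) when supplied.
#'
#' @param x peak-group data.frame.
#' @param path file path.
#' @param meta optional named list written to the sidecar.
#' @return \code{readPeakGroups} returns the checked data.frame.
#' @export
writePeakGroups <- function(x, path, meta = NULL) writeTSV(x, path, meta)

#' @rdname writePeakGroups
#' @export
readPeakGroups <- function(path) {
  x <- readTSVChecked(path, .PG_COLUMNS,
                      c(paste0("score_", 1:5), paste0("frag_", 1:6),
                        "ms1_area", "rt"))
  if (!all(x$decoy %in% c(0L, 1L))) stop("decoy flag must be 0 or 1")
  x$decoy <- as.integer(x$decoy)
  x
}

#' Read / write SIS area tables
#'
#' Same dialect as [writePeakGroups()]; columns \code{run_id},
#' \code{site_id}, \code{day}, \code{sample_id}, \code{replicate_index},
#' \code{peptide_id}, \code{group_id}, \code{nominal_fmol},
#' \code{ms_level}, \code{area}, \code{sn}.
#'
#' @inheritParams writePeakGroups
#' @export
writeSISTable <- function(x, path, meta = NULL) writeTSV(x, path, meta)

#' @rdname writeSISTable
#' @export
readSISTable <- function(path) {
  readTSVChecked(path, .SIS_COLUMNS, c("nominal_fmol", "area", "sn"))
}

#' Write ground truth (validation only)
#'
#' Ground-truth tables are never read by the analysis stages; they exist
#' so validation code can score the analysis output.
#'
#' @inheritParams writePeakGroups
#' @export
writeGroundTruth <- function(x, path, meta = NULL) writeTSV(x, path, meta)
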