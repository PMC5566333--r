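#' @rdname StudyDesign-class
#' @param object,x a \code{StudyDesign}
#' @export
setGeneric("designGroups", function(x) standardGeneric("designGroups"))
#' @rdname StudyDesign-class
#' @export
setMethod("designGroups", "StudyDesign", function(x) x@groups)

#' @rdname StudyDesign-class
#' @export
setGeneric("dilutionFactor", function(x) standardGeneric("dilutionFactor"))
#' @rdname StudyDesign-class
#' @export
setMethod("dilutionFactor", "StudyDesign", function(x) x@dilutionFactor)

#' @rdname StudyDesign-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname StudyDesign-class
#' @export
setMethod("sampleIds", "StudyDesign", function(x) x@sampleIds)

#' @rdname StudyDesign-class
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname StudyDesign-class
#' @export
setMethod("siteIds", "StudyDesign", function(x) x@sites)

setMethod("show", "StudyDesign", function(object) {
  g <- object@groups
  cat("StudyDesign:", length(unique(g$group_id)), "dilution groups,",
      nrow(g), "SIS peptides\n")
  cat("  samples:", paste(object@sampleIds, collapse = ", "),
      sprintf("(serial %g-fold dilution)\n", object@dilutionFactor))
  cat("  sites:", length(object@sites),
      " days:", paste(object@days, collapse = ","),
      " runs/site:", nRunsPerSite(object), "\n")
  rng <- range(concentrationTable(object)$fmol)
  cat(sprintf("  on-column range: %.3f - %g fmol\n", rng[1], rng[2]))
})

setMethod("show", "SiteProfile", function(object) {
  cat(sprintf(
    "SiteProfile %s: offset %.2f, pep x site sd %.2f, CV intra/inter-day %.0f%%/%.0f%%,\n  floor %.3g fmol, saturation %.3g fmol, MS1 interference x%.1f\n",
    object@siteId, object@responseOffset, object@peptideSiteEffectSd,
    100 * object@cvIntraday, 100 * object@cvInterday, object@detectionFloor,
    object@saturationLevel, object@ms1InterferenceScale))
})

setMethod("show", "BackgroundProteome", function(object) {
  cat("BackgroundProteome:", nrow(object@proteins), "proteins,",
      nrow(object@peptides), "proteotypic peptides\n")
  cat(sprintf("  log10 abundance span: %.2f orders\n",
              diff(range(object@proteins$log_abundance))))
})

setMethod("show", "StudyDataset", function(object) {
  cat("StudyDataset:", nrow(object@schedule), "runs over",
      length(unique(object@schedule$site_id)), "sites\n")
  cat("  peak groups:", nrow(object@peakGroups),
      sprintf("(%d decoys)", sum(object@peakGroups$decoy == 1L)), "\n")
  cat("  SIS area rows:", nrow(object@sisAreas), "\n")
})

#' @rdname DetectionMatrix-class
#' @param x a \code{DetectionMatrix}
#' @export
setGeneric("detectionCalls", function(x) standardGeneric("detectionCalls"))
#' @rdname DetectionMatrix-class
#' @export
setMethod("detectionCalls", "DetectionMatrix", function(x) x@calls)

setMethod("show", "DetectionMatrix", function(object) {
  cat(sprintf("DetectionMatrix (%s level, alpha = %g): %d units x %d runs, %d detections\n",
              object@level, object@alpha, nrow(object@calls), ncol(object@calls),
              sum(object@calls, na.rm = TRUE)))
})

#' @rdname ProteinQuantMatrix-class
#' @param x a \code{ProteinQuantMatrix}
#' @export
setGeneric("quantScale", function(x) standardGeneric("quantScale"))
#' @rdname ProteinQuantMatrix-class
#' @export
setMethod("quantScale", "ProteinQuantMatrix", function(x) x@scale)

#' @rdname ProteinQuantMatrix-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname ProteinQuantMatrix-class
#' @export
setMethod("isNormalized", "ProteinQuantMatrix", function(x) x@normalized)

#' @rdname ProteinQuantMatrix-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname ProteinQuantMatrix-class
#' @export
setMethod("abundances", "ProteinQuantMatrix", function(x)
  SummarizedExperiment::assay(x, "abundance"))

setMethod("show", "ProteinQuantMatrix", function(object) {
  a <- abundances(object)
  cat(sprintf("ProteinQuantMatrix: %d proteins x %d runs (%s scale, %snormalized)\n",
              nrow(a), ncol(a), object@scale, if (object@normalized) "" else "not "))
  cat(sprintf("  completeness: %.1f%% of cells present\n", 100 * mean(!is.na(a))))
})

#' @rdname NormalizationCoefficients-class
#' @param x a \code{NormalizationCoefficients}
#' @export
setGeneric("normCoefficients", function(x) standardGeneric("normCoefficients"))
#' @rdname NormalizationCoefficients-class
#' @export
setMethod("normCoefficients", "NormalizationCoefficients", function(x) x@coefficients)

setMethod("show", "NormalizationCoefficients", function(object) {
  cat(sprintf("NormalizationCoefficients: %d runs, reference median %.4g\n",
              length(object@coefficients), object@reference))
  cat(sprintf("  coefficient range: %.3f - %.3f\n",
              min(object@coefficients), max(object@coefficients)))
})

#' @rdname CorrelationMatrix-class
#' @param x a \code{CorrelationMatrix}
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))
#' @rdname CorrelationMatrix-class
#' @export
setMethod("correlations", "CorrelationMatrix", function(x) x@r)

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d runs; median r = %.3f, min r = %.3f\n",
              nrow(object@r), object@summary$median, object@summary$minimum))
})

#' Apply normalization coefficients
#'
#' Multiplies every run's values by its median-equalization coefficient.
#' Missing cells stay missing. Errors if a run lacks a coefficient.
#'
#' @param x a \linkS4class{ProteinQuantMatrix} (linear scale), a numeric
#'   matrix with run columns, or a SIS area data.frame with \code{run_id}
#'   and \code{area} columns.
#' @param coefficients a \linkS4class{NormalizationCoefficients}.
#' @return same class as \code{x}, rescaled.
#' @export
setGeneric("applyNormalization", function(x, coefficients)
  standardGeneric("applyNormalization"))
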