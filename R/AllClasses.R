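#' Class \code{StudyDesign}: SIS dilution groups and acquisition plan
#'
#' Describes a multi-site spike-in benchmarking design: five groups of six
#' stable isotope-labeled standard (SIS) peptides, each group serially
#' diluted by a fixed factor across samples S1..Sn (Sn is the most
#' concentrated), acquired at every site on a fixed day/replicate schedule.
#'
#' @slot groups data.frame with columns \code{group_id}, \code{peptide_id},
#'   \code{start_fmol} (the amount in the most concentrated sample).
#' @slot dilutionFactor positive numeric, serial dilution factor (default 3).
#' @slot sampleIds character, sample labels ordered from most dilute to most
#'   concentrated (default S1..S5).
#' @slot sites character, site identifiers.
#' @slot days integer, acquisition days (default 1, 3, 5).
#' @slot replicatePlan named integer, injections per sample per day
#'   (default one each, S4 in triplicate).
#' @export
setClass("StudyDesign", representation(
  groups = "data.frame",
  dilutionFactor = "numeric",
  sampleIds = "character",
  sites = "character",
  days = "integer",
  replicatePlan = "integer"
))

setValidity("StudyDesign", function(object) {
  g <- object@groups
  msg <- character()
  need <- c("group_id", "peptide_id", "start_fmol")
  if (!all(need %in% names(g))) {
    return(paste("groups must have columns", paste(need, collapse = ", ")))
  }
  if (any(g$start_fmol <= 0)) msg <- c(msg, "all start amounts must be positive")
  if (object@dilutionFactor <= 0) msg <- c(msg, "dilution factor must be positive")
  if (anyDuplicated(g$peptide_id)) msg <- c(msg, "peptide ids must be unique across groups")
  perGroup <- table(g$group_id)
  if (length(unique(perGroup)) > 1L) {
    msg <- c(msg, "all groups must contain the same number of peptides")
  }
  if (length(object@sites) < 1L) msg <- c(msg, "at least one site required")
  if (!all(object@sampleIds %in% names(object@replicatePlan))) {
    msg <- c(msg, "replicatePlan must cover every sample id")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Class \code{SiteProfile}: instrument/site characteristics for simulation
#'
#' Ground-truth parameters of one simulated acquisition site: a global
#' multiplicative response offset, peptide-by-site interaction spread,
#' intra-/inter-day noise levels, detection floor, saturation level and
#' MS1 interference scaling.
#'
#' @slot siteId site identifier.
#' @slot responseOffset global multiplicative sensitivity of the site.
#' @slot peptideSiteEffectSd log-scale sd of the peptide-by-site interaction.
#' @slot cvIntraday intra-day coefficient of variation (fraction).
#' @slot cvInterday inter-day coefficient of variation (fraction).
#' @slot detectionFloor amount-equivalent (fmol) at which S/N reaches the
#'   reference threshold of 20.
#' @slot saturationLevel amount-equivalent (fmol) of the hyperbolic
#'   saturation soft-clip.
#' @slot ms1InterferenceScale multiplier on the interference level at MS1
#'   relative to MS2 (default 10).
#' @slot driftPerDay log-scale signal drift per day.
#' @export
setClass("SiteProfile", representation(
  siteId = "character",
  responseOffset = "numeric",
  peptideSiteEffectSd = "numeric",
  cvIntraday = "numeric",
  cvInterday = "numeric",
  detectionFloor = "numeric",
  saturationLevel = "numeric",
  ms1InterferenceScale = "numeric",
  driftPerDay = "numeric"
))

setValidity("SiteProfile", function(object) {
  pos <- c(
    responseOffset = object@responseOffset,
    detectionFloor = object@detectionFloor,
    saturationLevel = object@saturationLevel,
    ms1InterferenceScale = object@ms1InterferenceScale
  )
  nonneg <- c(peptideSiteEffectSd = object@peptideSiteEffectSd,
              cvIntraday = object@cvIntraday,
              cvInterday = object@cvInterday)
  if (any(pos <= 0)) {
    paste("slots must be positive:", paste(names(pos)[pos <= 0], collapse = ", "))
  } else if (any(nonneg < 0)) {
    "sd/cv slots must be non-negative"
  } else TRUE
})

#' Class \code{BackgroundProteome}: simulated complex-matrix proteome
#'
#' A synthetic cell-lysate background: proteins with log10 abundances
#' spanning a configurable number of orders of magnitude, proteotypic
#' peptides (each mapping to exactly one protein) with lognormal response
#' factors, and six relative fragment intensities per peptide.
#'
#' @slot proteins data.frame: \code{protein_id}, \code{log_abundance}
#'   (log10 amount-equivalents, fmol).
#' @slot peptides data.frame: \code{peptide_id}, \code{protein_id},
#'   \code{response_factor}, \code{charge}.
#' @slot fragments numeric matrix (peptides x 6) of relative fragment
#'   intensities, rows summing to 1, rownames = peptide ids.
#' @export
setClass("BackgroundProteome", representation(
  proteins = "data.frame",
  peptides = "data.frame",
  fragments = "matrix"
))

setValidity("BackgroundProteome", function(object) {
  msg <- character()
  if (!all(object@peptides$protein_id %in% object@proteins$protein_id)) {
    msg <- c(msg, "every peptide must map to a known protein")
  }
  if (anyDuplicated(object@peptides$peptide_id)) {
    msg <- c(msg, "peptide ids must be unique (proteotypic)")
  }
  if (nrow(object@fragments) != nrow(object@peptides)) {
    msg <- c(msg, "one fragment-intensity row per peptide required")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Class \code{StudyDataset}: one simulated (or loaded) multi-site study
#'
#' Bundles the run schedule with the per-run peak-group table, the SIS
#' peptide area table (MS1 and MS2), and — in synthetic mode — the ground
#' truth used only by validation code, never by the analysis stages.
#'
#' @slot design the \linkS4class{StudyDesign}.
#' @slot schedule data.frame of planned runs actually acquired.
#' @slot peakGroups data.frame in the peak-group table dialect
#'   (see [writePeakGroups()]).
#' @slot sisAreas data.frame of SIS peptide areas per run and MS level.
#' @slot groundTruth data.frame of per (run, peptide query) truth records
#'   (empty in real mode).
#' @slot profiles list of \linkS4class{SiteProfile} (empty in real mode).
#' @export
setClass("StudyDataset", representation(
  design = "StudyDesign",
  schedule = "data.frame",
  peakGroups = "data.frame",
  sisAreas = "data.frame",
  groundTruth = "data.frame",
  profiles = "list"
))

#' Class \code{DetectionMatrix}: unit-by-run detection calls
#'
#' Boolean matrix of detection calls (peptide queries or proteins in rows,
#' runs in columns) produced by the consecutive FDR filter, with the
#' thresholds recorded as provenance.
#'
#' @slot calls logical matrix, \code{NA} where the unit was not queried in
#'   that run.
#' @slot level \code{"peptide"} or \code{"protein"}.
#' @slot alpha the FDR threshold used.
#' @slot proteinMap named character mapping peptide-query units to protein
#'   ids (empty at protein level).
#' @export
setClass("DetectionMatrix", representation(
  calls = "matrix",
  level = "character",
  alpha = "numeric",
  proteinMap = "character"
))

setValidity("DetectionMatrix", function(object) {
  if (!is.logical(object@calls)) return("calls must be a logical matrix")
  if (!object@level %in% c("peptide", "protein")) return("level must be peptide or protein")
  TRUE
})

#' Class \code{ProteinQuantMatrix}: protein abundances across runs
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{"abundance"} assay
#' (proteins x runs, \code{NA} = not detected in that run) plus flags for the
#' scale (linear or log2) and whether median normalization has been applied.
#'
#' @slot scale \code{"linear"} or \code{"log2"}.
#' @slot normalized logical flag.
#' @export
setClass("ProteinQuantMatrix",
  contains = "SummarizedExperiment",
  representation(scale = "character", normalized = "logical")
)

setValidity("ProteinQuantMatrix", function(object) {
  if (!object@scale %in% c("linear", "log2")) return("scale must be linear or log2")
  a <- SummarizedExperiment::assay(object)
  if (object@scale == "linear" && any(a <= 0, na.rm = TRUE)) {
    return("linear-scale abundances must be positive where present")
  }
  TRUE
})

#' Class \code{NormalizationCoefficients}: per-run median-equalization factors
#'
#' @slot coefficients named numeric, multiplicative coefficient per run.
#' @slot reference the reference statistic (median of per-run peak-group
#'   area medians) that every run's median equals after application.
#' @export
setClass("NormalizationCoefficients", representation(
  coefficients = "numeric",
  reference = "numeric"
))

setValidity("NormalizationCoefficients", function(object) {
  if (any(object@coefficients <= 0)) return("coefficients must be positive")
  if (is.null(names(object@coefficients))) return("coefficients must be named by run id")
  TRUE
})

#' Class \code{CorrelationMatrix}: pairwise run-level Pearson correlations
#'
#' @slot r run x run Pearson coefficients on log2 abundances
#'   (pairwise-complete proteins); \code{NA} where fewer than the minimum
#'   number of common proteins were available.
#' @slot nCommon integer matrix of common (pairwise-complete) proteins.
#' @slot summary list with \code{median} and \code{minimum} over the
#'   off-diagonal cells.
#' @export
setClass("CorrelationMatrix", representation(
  r = "matrix",
  nCommon = "matrix",
  summary = "list"
))

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("correlation matrix must be square")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) return("correlations must lie in [-1, 1]")
  TRUE
})
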