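#' Build a multi-site SIS dilution benchmarking design
#'
#' Constructs the default benchmarking layout: five groups (A-E) of six SIS
#' peptides, each group starting at a different amount in the most
#' concentrated sample (S5) and serially diluted by \code{dilutionFactor}
#' into the background four times (S4..S1). Every site acquires each sample
#' once per day on each acquisition day, except S4 which is injected in
#' triplicate, giving 7 injections/day and 21 runs/site with the defaults.
#'
#' With default start amounts of 1 fmol to 10 pmol the design spans
#' 0.012-10,000 fmol on column (six orders of magnitude overall).
#'
#' @param nSites number of acquisition sites (default 11).
#' @param starts amounts (fmol) of each group in the most concentrated
#'   sample; default \code{c(1, 10, 100, 1000, 10000)}.
#' @param dilutionFactor serial dilution factor between adjacent samples
#'   (default 3).
#' @param nSamples number of samples in the series (default 5, S1..S5).
#' @param days acquisition days (default \code{c(1, 3, 5)}).
#' @param replicatePlan named integer vector of injections per sample per
#'   day; default S4 in triplicate, others single.
#' @param peptidesPerGroup peptides per dilution group (default 6).
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' d <- buildDesign(nSites = 11)
#' range(concentrationTable(d)$fmol)   # 0.0123... to 10000
#' @export
buildDesign <- function(nSites = 11, starts = c(1, 10, 100, 1000, 10000),
                        dilutionFactor = 3, nSamples = 5,
                        days = c(1L, 3L, 5L), replicatePlan = NULL,
                        peptidesPerGroup = 6) {
  if (any(!is.finite(starts)) || any(starts <= 0)) {
    stop("invalid design: all start amounts must be positive")
  }
  if (dilutionFactor <= 0) stop("invalid design: dilution factor must be positive")
  if (nSites < 1) stop("invalid design: need at least one site")
  groupIds <- LETTERS[seq_along(starts)]
  groups <- data.frame(
    group_id = rep(groupIds, each = peptidesPerGroup),
    peptide_id = paste0("SIS_", rep(groupIds, each = peptidesPerGroup),
                        rep(seq_len(peptidesPerGroup), length(starts))),
    start_fmol = rep(starts, each = peptidesPerGroup),
    stringsAsFactors = FALSE
  )
  sampleIds <- paste0("S", seq_len(nSamples))
  if (is.null(replicatePlan)) {
    replicatePlan <- setNames(rep(1L, nSamples), sampleIds)
    if ("S4" %in% sampleIds) replicatePlan["S4"] <- 3L
  }
  new("StudyDesign",
      groups = groups, dilutionFactor = dilutionFactor,
      sampleIds = sampleIds,
      sites = sprintf("site%02d", seq_len(nSites)),
      days = as.integer(days),
      replicatePlan = replicatePlan)
}

#' Nominal on-column amount of a dilution group in a sample
#'
#' The most concentrated sample (the last one, S5 by default) carries the
#' group's start amount; each earlier sample is one serial dilution step
#' lower: \code{start / dilutionFactor^(nSamples - k)} for sample Sk.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param groupId group label (e.g. \code{"A"}).
#' @param sampleId sample label (e.g. \code{"S5"}).
#' @return amount in fmol.
#' @export
concentrationOf <- function(design, groupId, sampleId) {
  g <- design@groups
  i <- match(groupId, g$group_id)
  if (is.na(i)) stop("unknown dilution group: ", groupId)
  k <- match(sampleId, design@sampleIds)
  if (is.na(k)) stop("unknown sample: ", sampleId)
  g$start_fmol[i] / design@dilutionFactor^(length(design@sampleIds) - k)
}

#' All nominal concentrations of a design
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return data.frame with \code{group_id}, \code{sample_id}, \code{fmol}.
#' @export
concentrationTable <- function(design) {
  gids <- unique(design@groups$group_id)
  out <- expand.grid(group_id = gids, sample_id = design@sampleIds,
                     stringsAsFactors = FALSE)
  out$fmol <- mapply(function(g, s) concentrationOf(design, g, s),
                     out$group_id, out$sample_id)
  out[order(out$group_id, match(out$sample_id, design@sampleIds)), ,
      drop = FALSE]
}

nRunsPerSite <- function(design) {
  length(design@days) * sum(design@replicatePlan[design@sampleIds])
}

#' Acquisition schedule for one site
#'
#' Expands the replicate plan into an ordered run list: within each day the
#' samples are injected in ascending order (S1..Sn) with replicate
#' injections consecutive; the acquisition order increases chronologically
#' across days.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param siteId site identifier present in the design.
#' @return data.frame with \code{run_id}, \code{site_id}, \code{day},
#'   \code{sample_id}, \code{replicate_index}, \code{acquisition_order}.
#' @export
acquisitionSchedule <- function(design, siteId) {
  if (!siteId %in% design@sites) stop("unknown site: ", siteId)
  rows <- do.call(rbind, lapply(seq_along(design@days), function(di) {
    day <- design@days[di]
    samp <- rep(design@sampleIds, times = design@replicatePlan[design@sampleIds])
    rep_idx <- unlist(lapply(design@replicatePlan[design@sampleIds], seq_len),
                      use.names = FALSE)
    data.frame(site_id = siteId, day = day, sample_id = samp,
               replicate_index = rep_idx, stringsAsFactors = FALSE)
  }))
  rows$acquisition_order <- seq_len(nrow(rows))
  rows$run_id <- sprintf("%s_D%d_%s_R%d", rows$site_id, rows$day,
                         rows$sample_id, rows$replicate_index)
  rows[, c("run_id", "site_id", "day", "sample_id", "replicate_index",
           "acquisition_order")]
}

#' Full study schedule across all sites
#'
#' @param design a \linkS4class{StudyDesign}.
#' @return data.frame, the row-bound per-site schedules.
#' @export
studySchedule <- function(design) {
  do.call(rbind, lapply(design@sites, function(s) acquisitionSchedule(design, s)))
}

#' Write / read a design as CSV
#'
#' One row per peptide (columns \code{group_id}, \code{peptide_id},
#' \code{start_fmol}, \code{dilution_factor}, \code{n_samples},
#' \code{n_sites}); the round trip is the identity for designs built with
#' the default day/replicate plan.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param path file path.
#' @return \code{readDesignCSV} returns a \linkS4class{StudyDesign}.
#' @export
writeDesignCSV <- function(design, path) {
  g <- design@groups
  g$dilution_factor <- design@dilutionFactor
  g$n_samples <- length(design@sampleIds)
  g$n_sites <- length(design@sites)
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDesignCSV
#' @export
readDesignCSV <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  starts <- unique(g[, c("group_id", "start_fmol")])$start_fmol
  d <- buildDesign(nSites = g$n_sites[1], starts = starts,
                   dilutionFactor = g$dilution_factor[1],
                   nSamples = g$n_samples[1],
                   peptidesPerGroup = sum(g$group_id == g$group_id[1]))
  d@groups$peptide_id <- g$peptide_id
  validObject(d)
  d
}
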