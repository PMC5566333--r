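# --- SIS dilution-series analysis: fits, LLOQ, dynamic range ----------------

#' Weighted linear fit of a response curve
#'
#' Least squares of mean area versus nominal amount with 1/x weighting
#' (weights are the reciprocal of the nominal amount, the standard
#' bioanalytical choice emphasising the low end), or unweighted.
#'
#' @param nominal nominal amounts (fmol), one per concentration point.
#' @param meanArea mean replicate area per point.
#' @param weighting \code{"1/x"} (default) or \code{"none"}.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}
#'   (weighted coefficient of determination) and \code{weighting}.
#' @export
fitResponseCurve <- function(nominal, meanArea, weighting = c("1/x", "none")) {
  weighting <- match.arg(weighting)
  if (length(unique(nominal)) < 2L) stop("need at least 2 distinct concentrations")
  if (sd(meanArea) == 0) stop("zero-variance response: r_squared undefined")
  w <- if (weighting == "1/x") 1 / nominal else rep(1, length(nominal))
  fit <- lm(meanArea ~ nominal, weights = w)
  mw <- sum(w * meanArea) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (meanArea - mw)^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, weighting = weighting)
}

evalPoint <- function(fit, nominal, areas, snMean, cvMax, snMin, accuracyBand) {
  cv <- if (length(areas) >= 2) 100 * sd(areas) / mean(areas) else NA_real_
  backCalc <- (mean(areas) - fit$intercept) / fit$slope
  accuracy <- 100 * backCalc / nominal
  list(cv = cv, sn = snMean, accuracy = accuracy,
       cv_ok = !is.na(cv) && cv < cvMax,
       sn_ok = !is.na(snMean) && snMean > snMin,
       accuracy_ok = is.finite(accuracy) &&
         accuracy >= accuracyBand[1] && accuracy <= accuracyBand[2])
}

#' Determine the lower limit of quantitation of one response curve
#'
#' Iterates from the lowest concentration upward: the curve is refitted on
#' the currently retained points, and the lowest retained point is checked
#' against three bioanalytical criteria — replicate CV below \code{cvMax},
#' mean signal-to-noise above \code{snMin}, and back-calculated accuracy
#' (100 x fitted-inverse of the mean area / nominal) inside
#' \code{accuracyBand}. A failing point is dropped and the next higher
#' concentration evaluated; the LLOQ is the lowest retained point passing
#' all three.
#'
#' Before the LLOQ pass, points are trimmed from the top of the curve while
#' the highest retained point fails back-calculated accuracy against a
#' calibration anchored on the lowest three S/N-qualified points
#' (\code{trimUpper}, default on): detector saturation at high load makes
#' the top of the series leave the linear range, and a least-squares line
#' over the whole curve bends toward the saturated points, corrupting the
#' back-calibration of the low end — so the upper linear range is judged
#' from the quantifiable low end, whose S/N qualification does not depend
#' on any fit. Mid-curve failures (interference) are flagged in the
#' verdicts but retained.
#'
#' @param points data.frame with one row per replicate measurement:
#'   columns \code{nominal_fmol}, \code{area}, \code{sn}.
#' @param cvMax maximum replicate CV in percent (default 20).
#' @param snMin minimum mean S/N (default 20).
#' @param accuracyBand accuracy window in percent (default \code{c(80, 120)}).
#' @param weighting fit weighting, default \code{"1/x"}.
#' @param trimUpper drop saturated top points failing accuracy before the
#'   LLOQ pass (default TRUE), keeping at least 3 points.
#' @return list with \code{lloq} (fmol; \code{NA} if undetermined),
#'   \code{dynamic_range} (log10 orders; \code{NA} if undetermined),
#'   \code{fit} (the final [fitResponseCurve()] on retained points, or
#'   \code{NULL}), and \code{verdicts} (per-point criteria flags).
#' @export
determineLLOQ <- function(points, cvMax = 20, snMin = 20,
                          accuracyBand = c(80, 120), weighting = "1/x",
                          trimUpper = TRUE) {
  dt <- data.table::as.data.table(points)
  pts <- dt[, .(meanArea = mean(area), snMean = mean(sn),
                areas = list(area)), by = nominal_fmol]
  data.table::setorder(pts, nominal_fmol)
  retained <- rep(TRUE, nrow(pts))
  if (trimUpper) {
    snOK <- !is.na(pts$snMean) & pts$snMean > snMin
    while (sum(retained) > 3L) {
      anchor <- head(which(retained & snOK), 3L)
      top <- max(which(retained))
      if (length(anchor) < 3L || top %in% anchor) break
      fitU <- tryCatch(
        fitResponseCurve(pts$nominal_fmol[anchor], pts$meanArea[anchor],
                         weighting),
        error = function(e) NULL)
      if (is.null(fitU)) break
      v <- evalPoint(fitU, pts$nominal_fmol[top], pts$areas[[top]],
                     pts$snMean[top], cvMax, snMin, accuracyBand)
      if (v$accuracy_ok) break
      retained[top] <- FALSE
    }
  }
  lloq <- NA_real_
  fit <- NULL
  for (i in seq_len(nrow(pts))) {
    use <- which(retained)
    if (length(use) < 2L) break
    fit <- tryCatch(
      fitResponseCurve(pts$nominal_fmol[use], pts$meanArea[use], weighting),
      error = function(e) NULL)
    if (is.null(fit)) break
    v <- evalPoint(fit, pts$nominal_fmol[use[1]], pts$areas[[use[1]]],
                   pts$snMean[use[1]], cvMax, snMin, accuracyBand)
    if (v$cv_ok && v$sn_ok && v$accuracy_ok) {
      lloq <- pts$nominal_fmol[use[1]]
      break
    }
    retained[use[1]] <- FALSE
  }
  verdicts <- NULL
  if (!is.null(fit)) {
    verdicts <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
      v <- evalPoint(fit, pts$nominal_fmol[i], pts$areas[[i]],
                     pts$snMean[i], cvMax, snMin, accuracyBand)
      data.frame(nominal_fmol = pts$nominal_fmol[i], cv = v$cv, sn = v$sn,
                 accuracy = v$accuracy, cv_ok = v$cv_ok, sn_ok = v$sn_ok,
                 accuracy_ok = v$accuracy_ok, retained = retained[i])
    }))
  }
  list(lloq = lloq,
       dynamic_range = if (is.na(lloq)) NA_real_ else
         dynamicRange(lloq, max(pts$nominal_fmol)),
       fit = fit, verdicts = verdicts)
}

#' Dynamic range in orders of magnitude
#'
#' \code{log10(maxNominal / lloq)}: the span from the LLOQ to the highest
#' point of the series.
#'
#' @param lloq determined LLOQ (fmol), positive.
#' @param maxNominal highest nominal amount of the series (fmol).
#' @return orders of magnitude (numeric).
#' @export
dynamicRange <- function(lloq, maxNominal) {
  if (is.na(lloq)) stop("LLOQ undetermined: dynamic range undefined")
  stopifnot(lloq > 0)
  log10(maxNominal / lloq)
}

#' Per-peptide, per-site LLOQ report
#'
#' Runs [determineLLOQ()] on every (peptide, site, MS level) response curve
#' of a SIS area table.
#'
#' @param sis SIS area data.frame (\code{run_id}, \code{site_id},
#'   \code{peptide_id}, \code{group_id}, \code{nominal_fmol},
#'   \code{ms_level}, \code{area}, \code{sn}).
#' @param cvMax,snMin,accuracyBand,weighting,trimUpper passed to
#'   [determineLLOQ()].
#' @return data.frame with one row per curve: \code{peptide_id},
#'   \code{site_id}, \code{ms_level}, \code{group_id}, \code{lloq_fmol},
#'   \code{dynamic_range_orders}, \code{r_squared}, \code{max_fmol}.
#' @export
lloqReport <- function(sis, cvMax = 20, snMin = 20,
                       accuracyBand = c(80, 120), weighting = "1/x",
                       trimUpper = TRUE) {
  dt <- data.table::as.data.table(sis)
  out <- dt[, {
    r <- determineLLOQ(.SD, cvMax = cvMax, snMin = snMin,
                       accuracyBand = accuracyBand, weighting = weighting,
                       trimUpper = trimUpper)
    list(lloq_fmol = r$lloq,
         dynamic_range_orders = r$dynamic_range,
         r_squared = if (is.null(r$fit)) NA_real_ else r$fit$r_squared,
         max_fmol = max(nominal_fmol))
  }, by = .(peptide_id, site_id, ms_level, group_id)]
  as.data.frame(out)
}

#' Per-group averaged response curve
#'
#' Averages, per site, group and MS level, the mean peak areas of the
#' group's peptides at each shared concentration point (the group members
#' are measured on a common concentration grid). Missing peptides at a
#' point are averaged over, flagged in \code{n_peptides}.
#'
#' @param sis SIS area data.frame.
#' @return data.frame: \code{site_id}, \code{group_id}, \code{ms_level},
#'   \code{nominal_fmol}, \code{mean_area}, \code{n_peptides}.
#' @export
averagedResponseCurve <- function(sis) {
  dt <- data.table::as.data.table(sis)
  per <- dt[, .(pep_mean = mean(area)),
            by = .(site_id, group_id, ms_level, nominal_fmol, peptide_id)]
  out <- per[, .(mean_area = mean(pep_mean), n_peptides = .N),
             by = .(site_id, group_id, ms_level, nominal_fmol)]
  data.table::setorder(out, site_id, group_id, ms_level, -nominal_fmol)
  as.data.frame(out)
}

#' Fold changes between dilution steps
#'
#' Computes the ratios of mean peak areas between concentration points
#' one, two and three serial-dilution steps apart (expected 3x, 9x, 27x
#' with a threefold series), aggregated over peptides and sites by
#' geometric mean. Only points at or above the peptide's LLOQ contribute
#' when an LLOQ report is supplied.
#'
#' @param sis SIS area data.frame (typically MS2 rows).
#' @param lloq optional [lloqReport()] output used to censor sub-LLOQ
#'   points.
#' @param maxStep largest step spacing (default 3).
#' @return named numeric: geometric-mean observed ratio per step spacing
#'   (\code{step1}, \code{step2}, \code{step3}).
#' @export
stepFoldChanges <- function(sis, lloq = NULL, maxStep = 3) {
  dt <- data.table::as.data.table(sis)
  pts <- dt[, .(meanArea = mean(area)),
            by = .(peptide_id, site_id, ms_level, nominal_fmol)]
  if (!is.null(lloq)) {
    lq <- data.table::as.data.table(lloq)[, .(peptide_id, site_id, ms_level, lloq_fmol)]
    pts <- lq[pts, on = c("peptide_id", "site_id", "ms_level")]
    pts <- pts[!is.na(lloq_fmol) & nominal_fmol >= lloq_fmol]
  }
  data.table::setorder(pts, peptide_id, site_id, ms_level, nominal_fmol)
  ratios <- lapply(seq_len(maxStep), function(k) {
    r <- pts[, {
      n <- .N
      if (n > k) meanArea[(1 + k):n] / meanArea[1:(n - k)] else numeric(0)
    }, by = .(peptide_id, site_id, ms_level)]$V1
    r[is.finite(r) & r > 0]
  })
  setNames(vapply(ratios, function(r) if (length(r)) geomMean(r) else NA_real_,
                  numeric(1)),
           paste0("step", seq_len(maxStep)))
}

#' Percent of SIS peptides quantifiable at each concentration
#'
#' A peptide counts as detected at concentration c iff its determined LLOQ
#' is at or below c (undetermined LLOQ never counts). Reported per site
#' and MS level over the pooled design concentration grid, plus the
#' cross-site mean curve (site id \code{"mean"}).
#'
#' @param lloq output of [lloqReport()].
#' @param concentrations concentration grid; default all nominal values in
#'   the report's curves.
#' @return data.frame: \code{site_id}, \code{ms_level}, \code{fmol},
#'   \code{pct_detected}.
#' @export
percentDetected <- function(lloq, concentrations = NULL) {
  dt <- data.table::as.data.table(lloq)
  if (is.null(concentrations)) {
    # pooled grid: every nominal value of every group's series
    concentrations <- sort(unique(unlist(lapply(
      seq_len(nrow(dt)),
      function(i) dt$max_fmol[i] / 3^(0:4)))))
  }
  nPep <- length(unique(dt$peptide_id))
  out <- dt[, {
    p <- vapply(concentrations, function(cc)
      100 * sum(!is.na(lloq_fmol) & lloq_fmol <= cc) / nPep, numeric(1))
    list(fmol = concentrations, pct_detected = p)
  }, by = .(site_id, ms_level)]
  mean_curve <- out[, .(site_id = "mean", pct_detected = mean(pct_detected)),
                    by = .(ms_level, fmol)]
  as.data.frame(rbind(out, mean_curve[, .(site_id, ms_level, fmol, pct_detected)]))
}
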