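# --- synthetic multi-site study generator -----------------------------------
#
# Signal model (all multiplicative, lognormal noise):
#   area = base * site_offset * day_effect * drift * response_factor
#          * pep_site_effect * soft_sat(amount) * exp(eps)
# with soft_sat(a) = a / (1 + a / saturation_level) (hyperbolic soft clip)
# and eps ~ Normal(0, sdlog(cv_intraday)). Day effects carry the extra
# inter-day variance component; the peptide-by-site interaction (a surrogate
# for chromatography/resin differences) is what makes runs cluster by site.
# S/N is defined against a per-peptide noise level calibrated so that S/N
# reaches 20 at the site's detection-floor amount; MS1 signals carry an
# interference level ~10x the MS2 one, pushing the MS1 LLOQ up ~1 order.

.BASE_AREA_PER_FMOL <- 1e4
.SN_REF <- 20
.MS1_GAIN <- 3
.SCORE_LOADINGS <- c(1, 0.8, 0.6, 0.4, 0.3)

#' Hyperbolic saturation soft-clip
#'
#' \code{a / (1 + a / level)}: linear for \code{a << level}, flattening
#' toward \code{level} at high load (detector saturation).
#'
#' @param a amount (fmol), vectorized.
#' @param level saturation level (fmol); \code{Inf} disables saturation.
#' @return clipped amount.
#' @export
softSat <- function(a, level) if (is.infinite(level)) a else a / (1 + a / level)

#' Generate a synthetic background proteome
#'
#' Proteins receive log10 abundances spanning exactly \code{spanOrders}
#' orders of magnitude; each protein carries a Poisson (truncated at 1)
#' number of proteotypic peptides with lognormal response factors and six
#' relative fragment intensities (sorted, summing to 1).
#'
#' @param nProteins number of background proteins.
#' @param spanOrders realized log10 abundance span (default 4.5).
#' @param meanPeptides mean proteotypic peptides per protein (default 8).
#' @param seed RNG seed; identical seeds give identical proteomes.
#' @param logMin log10 abundance (fmol-equivalents) of the least abundant
#'   protein (default -2).
#' @return a \linkS4class{BackgroundProteome}.
#' @export
generateBackground <- function(nProteins = 500, spanOrders = 4.5,
                               meanPeptides = 8, seed = 1, logMin = -2) {
  stopifnot(nProteins >= 1, spanOrders > 0, meanPeptides >= 1)
  withSeed(seed, {
    la <- runif(nProteins)
    if (nProteins >= 2) {          # rescale so the realized span is exact
      la <- (la - min(la)) / diff(range(la))
    }
    la <- logMin + la * spanOrders
    proteins <- data.frame(
      protein_id = sprintf("BGP%05d", seq_len(nProteins)),
      log_abundance = la, stringsAsFactors = FALSE)
    nPep <- pmax(1L, rpois(nProteins, meanPeptides))
    peptides <- data.frame(
      peptide_id = sprintf("bgpep%06d", seq_len(sum(nPep))),
      protein_id = rep(proteins$protein_id, nPep),
      response_factor = rlnorm(sum(nPep), 0, 1),
      charge = sample(2:3, sum(nPep), replace = TRUE),
      stringsAsFactors = FALSE)
    fr <- matrix(rexp(6 * nrow(peptides)), ncol = 6)
    fr <- t(apply(fr, 1, function(z) sort(z / sum(z), decreasing = TRUE)))
    rownames(fr) <- peptides$peptide_id
    new("BackgroundProteome", proteins = proteins, peptides = peptides,
        fragments = fr)
  })
}

#' Pad a proteome with queried-but-absent library entries
#'
#' Peptide-centric DIA analysis queries a spectral library that is larger
#' than the set of proteins actually detectable in the sample (a 10,000+
#' protein library against ~5,000 detectable proteins in the original
#' study). These absent queries are what an FDR filter must reject: their
#' peak groups are pure noise. This helper appends \code{fraction} x
#' nProteins absent proteins (abundance far below any detection floor)
#' with their own peptides and fragment patterns.
#'
#' @param proteome a \linkS4class{BackgroundProteome}.
#' @param fraction absent proteins to add, as a fraction of the present
#'   ones (default 1: a library twice the size of the sample proteome).
#' @param seed RNG seed.
#' @param meanPeptides mean peptides per absent protein (default 8).
#' @return the padded \linkS4class{BackgroundProteome}.
#' @export
padLibrary <- function(proteome, fraction = 1, seed = 1, meanPeptides = 8) {
  nAbs <- round(nrow(proteome@proteins) * fraction)
  if (nAbs == 0L) return(proteome)
  withSeed(deriveSeed(seed, "library-pad"), {
    prot <- data.frame(
      protein_id = sprintf("LIBP%05d", seq_len(nAbs)),
      log_abundance = -10,   # effectively absent from the sample
      stringsAsFactors = FALSE)
    nPep <- pmax(1L, rpois(nAbs, meanPeptides))
    pep <- data.frame(
      peptide_id = sprintf("libpep%06d", seq_len(sum(nPep))),
      protein_id = rep(prot$protein_id, nPep),
      response_factor = rlnorm(sum(nPep), 0, 1),
      charge = sample(2:3, sum(nPep), replace = TRUE),
      stringsAsFactors = FALSE)
    fr <- matrix(rexp(6 * nrow(pep)), ncol = 6)
    fr <- t(apply(fr, 1, function(z) sort(z / sum(z), decreasing = TRUE)))
    rownames(fr) <- pep$peptide_id
    new("BackgroundProteome",
        proteins = rbind(proteome@proteins, prot),
        peptides = rbind(proteome@peptides, pep),
        fragments = rbind(proteome@fragments, fr))
  })
}

#' SIS peptide response factors, rank-assigned to dilution groups
#'
#' Draws one lognormal response factor per SIS peptide, ranks them, and
#' deals them round-robin into the dilution groups so every group spans a
#' comparable range of responses.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param seed RNG seed.
#' @param sdlog lognormal spread of the response factors (default 0.8).
#' @return data.frame \code{peptide_id}, \code{group_id}, \code{start_fmol},
#'   \code{response_factor}.
#' @export
sisResponseFactors <- function(design, seed = 1, sdlog = 0.8) {
  g <- design@groups
  gids <- unique(g$group_id)
  withSeed(deriveSeed(seed, "sis-response"), {
    rf <- sort(rlnorm(nrow(g), 0, sdlog), decreasing = TRUE)
  })
  # rank i -> group ((i-1) mod nGroups)+1, filling each group's next slot
  out <- g
  out$response_factor <- NA_real_
  for (gi in seq_along(gids)) {
    idx <- which(g$group_id == gids[gi])
    out$response_factor[idx] <- rf[seq(gi, nrow(g), by = length(gids))]
  }
  out
}

#' Build site profiles for a simulated study
#'
#' Global response offsets are drawn log-uniformly in
#' \code{responseOffsetRange}; the remaining characteristics are shared
#' defaults unless overridden.
#'
#' @param siteIds character vector of site ids.
#' @param seed RNG seed.
#' @param responseOffsetRange range of multiplicative site sensitivities
#'   (default 0.5x-2x).
#' @param peptideSiteEffectSd log-scale sd of peptide-by-site interactions
#'   (default 0.2).
#' @param cvIntraday,cvInterday within-day / within-week coefficients of
#'   variation (defaults 0.05, 0.09).
#' @param detectionFloor amount (fmol) at which S/N = 20 (default 0.05).
#' @param saturationLevel saturation amount (fmol, default 10000: signal visibly saturates at the top of the dilution series).
#' @param ms1InterferenceScale MS1/MS2 interference ratio (default 10).
#' @param driftPerDay log-scale drift per day (default 0).
#' @return named list of \linkS4class{SiteProfile}.
#' @export
makeSiteProfiles <- function(siteIds, seed = 1,
                             responseOffsetRange = c(0.5, 2),
                             peptideSiteEffectSd = 0.2,
                             cvIntraday = 0.05, cvInterday = 0.09,
                             detectionFloor = 0.05, saturationLevel = 10000,
                             ms1InterferenceScale = 10, driftPerDay = 0) {
  offsets <- withSeed(deriveSeed(seed, "site-offsets"),
    10^runif(length(siteIds), log10(responseOffsetRange[1]),
             log10(responseOffsetRange[2])))
  profs <- lapply(seq_along(siteIds), function(i) {
    new("SiteProfile", siteId = siteIds[i], responseOffset = offsets[i],
        peptideSiteEffectSd = peptideSiteEffectSd,
        cvIntraday = cvIntraday, cvInterday = cvInterday,
        detectionFloor = detectionFloor, saturationLevel = saturationLevel,
        ms1InterferenceScale = ms1InterferenceScale, driftPerDay = driftPerDay)
  })
  names(profs) <- siteIds
  profs
}

# per-(site, peptide) interaction effects, stable across the site's runs
sitePeptideEffects <- function(profile, peptideIds, masterSeed) {
  withSeed(deriveSeed(masterSeed, profile@siteId, "pep-effects"), {
    setNames(exp(rnorm(length(peptideIds), 0, profile@peptideSiteEffectSd)),
             peptideIds)
  })
}

# scalar day effect: carries the inter-day variance beyond the intra-day one
siteDayEffect <- function(profile, day, masterSeed) {
  sdDay <- sqrt(max(0, log(1 + profile@cvInterday^2) -
                       log(1 + profile@cvIntraday^2)))
  withSeed(deriveSeed(masterSeed, profile@siteId, paste0("day", day)),
           exp(rnorm(1, 0, sdDay)))
}

#' Simulate one SWATH-MS run
#'
#' Emits the run's target and decoy peak-group records, the SIS peptide
#' area table at MS2 and MS1 level, and the ground-truth records. A
#' background peptide is truly present when its effective amount exceeds
#' the site's stochastic detection floor; absent peptides still yield, with
#' probability \code{noiseTargetRate}, a decoy-like noise peak group
#' (peptide-centric scoring reports a best candidate even for absent
#' peptides). Decoy records are emitted 1:1 with targets with standard
#' normal sub-scores.
#'
#' @param proteome a \linkS4class{BackgroundProteome}.
#' @param design a \linkS4class{StudyDesign}.
#' @param sis output of [sisResponseFactors()].
#' @param profile the run's \linkS4class{SiteProfile}.
#' @param run single-row data.frame from [acquisitionSchedule()].
#' @param decoyRatio decoy:target ratio (default 1).
#' @param seed master seed; the run's substream is derived by stable
#'   hashing of its run id.
#' @param noiseTargetRate probability an absent peptide yields a noise
#'   target record (default 0.5).
#' @return list with \code{peakGroups}, \code{sisAreas}, \code{groundTruth}
#'   data.frames.
#' @export
simulateRun <- function(proteome, design, sis, profile, run,
                        decoyRatio = 1, seed = 1, noiseTargetRate = 0.5) {
  stopifnot(decoyRatio > 0, nrow(run) == 1L)
  pep <- proteome@peptides
  prot <- proteome@proteins
  allPepIds <- c(pep$peptide_id, sis$peptide_id)
  pepEff <- sitePeptideEffects(profile, allPepIds, seed)
  dayEff <- siteDayEffect(profile, run$day, seed)
  drift <- exp(profile@driftPerDay * (run$day - 1))
  sdIntra <- sdlogFromCV(profile@cvIntraday)
  base <- .BASE_AREA_PER_FMOL * profile@responseOffset * dayEff * drift

  withSeed(deriveSeed(seed, run$run_id, "records"), {
    ## ---- background targets
    amt <- 10^prot$log_abundance[match(pep$protein_id, prot$protein_id)]
    effAmt <- amt * pep$response_factor * pepEff[pep$peptide_id]
    floorJitter <- exp(rnorm(nrow(pep), 0, 0.35))
    present <- effAmt > profile@detectionFloor * floorJitter
    noiseLevel <- .BASE_AREA_PER_FMOL * profile@responseOffset *
      pep$response_factor * pepEff[pep$peptide_id] *
      profile@detectionFloor / .SN_REF

    expArea <- base * pep$response_factor * pepEff[pep$peptide_id] *
      softSat(amt, profile@saturationLevel)
    area <- expArea * exp(rnorm(nrow(pep), 0, sdIntra))
    noiseArea <- noiseLevel * exp(rnorm(nrow(pep), 0, 0.6))

    isNoise <- !present & (runif(nrow(pep)) < noiseTargetRate)
    keep <- present | isNoise
    n <- sum(keep)
    outArea <- ifelse(present, area, noiseArea)[keep]
    shift <- pmin(6, 1 + 1.5 * log10(effAmt / profile@detectionFloor))
    shift <- ifelse(present, shift, 0)[keep]
    scores <- matrix(rnorm(n * length(.SCORE_LOADINGS)), nrow = n) +
      outer(shift, .SCORE_LOADINGS)
    frag <- proteome@fragments[keep, , drop = FALSE] * outArea
    ms1 <- .MS1_GAIN * outArea * exp(rnorm(n, 0, 0.2)) +
      noiseLevel[keep] * profile@ms1InterferenceScale * exp(rnorm(n, 0, 0.6))

    targets <- data.table::data.table(
      run_id = run$run_id,
      peptide_query_id = pep$peptide_id[keep],
      protein_id = pep$protein_id[keep],
      decoy = 0L)
    for (j in seq_along(.SCORE_LOADINGS)) {
      data.table::set(targets, j = paste0("score_", j), value = scores[, j])
    }
    for (j in 1:6) data.table::set(targets, j = paste0("frag_", j), value = frag[, j])
    targets[, `:=`(ms1_area = ms1, rt = runif(n, 0, 6000))]

    ## ---- decoys, 1:1 with emitted targets, null sub-scores
    nd <- round(decoyRatio * n)
    di <- if (nd <= n) seq_len(nd) else sample.int(n, nd, replace = TRUE)
    dScores <- matrix(rnorm(nd * length(.SCORE_LOADINGS)), nrow = nd)
    dArea <- noiseLevel[keep][di] * exp(rnorm(nd, 0, 0.6))
    dFrag <- proteome@fragments[keep, , drop = FALSE][di, , drop = FALSE] * dArea
    decoys <- data.table::data.table(
      run_id = run$run_id,
      peptide_query_id = paste0("DECOY_", pep$peptide_id[keep][di]),
      protein_id = paste0("DECOY_", pep$protein_id[keep][di]),
      decoy = 1L)
    for (j in seq_along(.SCORE_LOADINGS)) {
      data.table::set(decoys, j = paste0("score_", j), value = dScores[, j])
    }
    for (j in 1:6) data.table::set(decoys, j = paste0("frag_", j), value = dFrag[, j])
    decoys[, `:=`(ms1_area = dArea * .MS1_GAIN,
                  rt = runif(nd, 0, 6000))]

    truth <- data.table::data.table(
      run_id = run$run_id,
      peptide_query_id = pep$peptide_id,
      protein_id = pep$protein_id,
      present = present,
      true_amount = effAmt,
      expected_area = expArea,
      emitted = keep)

    ## ---- SIS areas at MS2 and MS1
    nominal <- vapply(sis$group_id, function(g)
      concentrationOf(design, g, run$sample_id), numeric(1))
    sEff <- pepEff[sis$peptide_id]
    sNoiseBase <- .BASE_AREA_PER_FMOL * profile@responseOffset *
      sis$response_factor * sEff * profile@detectionFloor / .SN_REF
    sisOne <- function(msLevel) {
      gain <- if (msLevel == "MS1") .MS1_GAIN else 1
      msScale <- if (msLevel == "MS1") profile@ms1InterferenceScale else 1
      signal <- base * sis$response_factor * sEff *
        softSat(nominal, profile@saturationLevel) * gain *
        exp(rnorm(nrow(sis), 0, sdIntra))
      nl <- sNoiseBase * msScale * gain
      interference <- nl * exp(rnorm(nrow(sis), 0, 0.5))
      a <- signal + interference
      data.table::data.table(
        run_id = run$run_id, site_id = run$site_id, day = run$day,
        sample_id = run$sample_id, replicate_index = run$replicate_index,
        peptide_id = sis$peptide_id, group_id = sis$group_id,
        nominal_fmol = nominal, ms_level = msLevel, area = a, sn = a / nl)
    }
    sisAreas <- rbind(sisOne("MS2"), sisOne("MS1"))

    list(peakGroups = rbind(targets, decoys), sisAreas = sisAreas,
         groundTruth = truth)
  })
}

#' Simulate a complete multi-site study
#'
#' Runs [simulateRun()] for every planned acquisition (minus \code{dropout}
#' randomly removed runs), with per-run substreams derived from the master
#' seed, and assembles a \linkS4class{StudyDataset}.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param proteome a \linkS4class{BackgroundProteome}; generated from the
#'   master seed when \code{NULL}.
#' @param profiles named list of \linkS4class{SiteProfile} (one per site);
#'   generated from the master seed when \code{NULL}.
#' @param seed master seed.
#' @param dropout number of planned runs to remove at random (the deposited
#'   study kept 229 of 231 planned files).
#' @param decoyRatio,noiseTargetRate passed to [simulateRun()].
#' @param nProteins,spanOrders,meanPeptides background size when
#'   \code{proteome} is \code{NULL}.
#' @param libraryFraction queried-but-absent library proteins added via
#'   [padLibrary()], as a fraction of \code{nProteins} (default 1).
#' @param ... passed to [makeSiteProfiles()] when \code{profiles} is
#'   \code{NULL}.
#' @return a \linkS4class{StudyDataset}.
#' @export
simulateStudy <- function(design, proteome = NULL, profiles = NULL, seed = 1,
                          dropout = 0, decoyRatio = 1, noiseTargetRate = 0.5,
                          nProteins = 500, spanOrders = 4.5, meanPeptides = 8,
                          libraryFraction = 1, ...) {
  if (is.null(proteome)) {
    proteome <- generateBackground(nProteins, spanOrders, meanPeptides,
                                   seed = deriveSeed(seed, "background"))
  }
  if (libraryFraction > 0) {
    proteome <- padLibrary(proteome, libraryFraction, seed = seed,
                           meanPeptides = meanPeptides)
  }
  if (is.null(profiles)) {
    profiles <- makeSiteProfiles(design@sites,
                                 seed = deriveSeed(seed, "profiles"), ...)
  }
  if (!all(design@sites %in% names(profiles))) {
    stop("profiles must cover every site in the design")
  }
  sis <- sisResponseFactors(design, seed)
  sched <- studySchedule(design)
  if (dropout > 0) {
    if (dropout >= nrow(sched)) stop("dropout must be smaller than the number of planned runs")
    drop <- withSeed(deriveSeed(seed, "dropout"),
                     sample.int(nrow(sched), dropout))
    sched <- sched[-drop, , drop = FALSE]
  }
  parts <- lapply(seq_len(nrow(sched)), function(i) {
    r <- sched[i, , drop = FALSE]
    simulateRun(proteome, design, sis, profiles[[r$site_id]], r,
                decoyRatio = decoyRatio, seed = seed,
                noiseTargetRate = noiseTargetRate)
  })
  new("StudyDataset",
      design = design, schedule = sched,
      peakGroups = as.data.frame(data.table::rbindlist(lapply(parts, `[[`, "peakGroups"))),
      sisAreas = as.data.frame(data.table::rbindlist(lapply(parts, `[[`, "sisAreas"))),
      groundTruth = as.data.frame(data.table::rbindlist(lapply(parts, `[[`, "groundTruth"))),
      profiles = profiles)
}
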