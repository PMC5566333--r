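# --- global quantitative similarity: correlations and clustering ------------

#' Pairwise Pearson correlation of log2 protein abundances
#'
#' Correlates every pair of runs over their common (pairwise-complete)
#' proteins on the log2 scale; pairs with fewer than \code{minCommon}
#' common proteins are flagged undefined (NA). Runs without any present
#' protein are excluded.
#'
#' @param x a \linkS4class{ProteinQuantMatrix} (log2-transformed
#'   internally if still linear).
#' @param minCommon minimum common proteins per pair (default 3).
#' @return a \linkS4class{CorrelationMatrix} with the median and minimum
#'   over the off-diagonal cells in its summary.
#' @export
pearsonMatrix <- function(x, minCommon = 3) {
  a <- abundances(logTransform(x))
  empty <- colSums(!is.na(a)) == 0
  if (any(empty)) a <- a[, !empty, drop = FALSE]
  r <- suppressWarnings(cor(a, use = "pairwise.complete.obs"))
  n <- crossprod((!is.na(a)) * 1)
  r[n < minCommon] <- NA_real_
  diag(r) <- 1
  off <- r[upper.tri(r)]
  new("CorrelationMatrix", r = r, nCommon = n,
      summary = list(median = median(off, na.rm = TRUE),
                     minimum = min(off, na.rm = TRUE)))
}

#' Hierarchical clustering of runs
#'
#' Agglomerative clustering of runs on their log2 protein abundance
#' profiles (Euclidean distance, Ward linkage by default). Ward's method
#' recovers compact balanced clusters reliably; complete and average
#' linkage are available but are sensitive to single outlying runs, which
#' can absorb several sites into one cluster when the tree is cut.
#' Clustering uses the complete-case protein subset across all runs;
#' optionally, proteins at least half complete are kept and their missing
#' cells imputed by the protein median. Runs are ordered by id before
#' clustering so ties merge deterministically.
#'
#' @param x a \linkS4class{ProteinQuantMatrix}.
#' @param method linkage (default \code{"ward.D2"}).
#' @param impute impute missing cells with the protein median (proteins
#'   below \code{minComplete} present fraction are dropped first) instead
#'   of keeping only complete-case proteins (default FALSE).
#' @param minComplete completeness floor for the impute path (default 0.5).
#' @return list with \code{hclust}, \code{phylo} (ape tree) and
#'   \code{newick} (serialized string).
#' @export
hierarchicalCluster <- function(x, method = "ward.D2", impute = FALSE,
                                minComplete = 0.5) {
  a <- abundances(logTransform(x))
  if (ncol(a) < 2L) stop("need at least 2 runs to cluster")
  a <- a[, sort(colnames(a)), drop = FALSE]
  if (impute) {
    a <- a[rowMeans(!is.na(a)) >= minComplete, , drop = FALSE]
    med <- apply(a, 1, median, na.rm = TRUE)
    idx <- which(is.na(a), arr.ind = TRUE)
    a[idx] <- med[idx[, 1]]
    a <- a[is.finite(rowSums(a)), , drop = FALSE]
  } else {
    a <- a[stats::complete.cases(a), , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("no complete-case proteins to cluster on; consider impute = TRUE")
  hc <- hclust(dist(t(a)), method = method)
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph))
}

#' Cluster purity against known labels
#'
#' Cuts the run dendrogram into k groups and scores how well the clusters
#' align with known labels: the fraction of runs that belong to their
#' cluster's majority label.
#'
#' @param hc an \code{hclust} over runs (from [hierarchicalCluster()]).
#' @param labels named character vector (run id -> label).
#' @param k number of clusters (default: number of distinct labels).
#' @return purity in [0, 1].
#' @export
clusterPurity <- function(hc, labels, k = length(unique(labels))) {
  ct <- cutree(hc, k = k)
  lab <- labels[names(ct)]
  sum(tapply(lab, ct, function(z) max(table(z)))) / length(ct)
}

#' Within-site versus between-site correlation summary
#'
#' @param cm a \linkS4class{CorrelationMatrix}.
#' @param siteOf named character vector (run id -> site id).
#' @return list with \code{withinMedian} (median over all within-site
#'   pairs), \code{betweenMedian}, \code{siteMedians} (per site) and
#'   \code{siteRange}.
#' @export
similaritySummary <- function(cm, siteOf) {
  r <- cm@r
  runs <- rownames(r)
  site <- siteOf[runs]
  same <- outer(site, site, `==`)
  ut <- upper.tri(r)
  within <- r[ut & same]
  between <- r[ut & !same]
  siteMedians <- vapply(unique(site), function(s) {
    sel <- ut & outer(site == s, site == s, `&`)
    median(r[sel], na.rm = TRUE)
  }, numeric(1))
  list(withinMedian = median(within, na.rm = TRUE),
       betweenMedian = median(between, na.rm = TRUE),
       siteMedians = siteMedians,
       siteRange = range(siteMedians, na.rm = TRUE))
}
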