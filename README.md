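# swathQC

Reproducibility analysis for multi-laboratory SWATH-MS (data-independent
acquisition) proteomics benchmarks.

The package is aimed at labs and consortia who distribute a common
benchmarking sample — stable isotope-labeled standard (SIS) peptides spiked
at serially diluted, known amounts into a complex cell-lysate background —
acquire it at many sites over several days, and need to answer, from the
resulting peak-group tables: *is detection consistent across sites? how
reproducible is quantification within a day, across a week, across labs? how
sensitive and linear is the measurement? do quantitative profiles cluster by
site?*

## What it implements

* **Study design** — five dilution groups of six SIS peptides, group start
  amounts 1 fmol–10 pmol, threefold serial dilution over samples S1–S5
  (nominal amount `start / 3^(5−k)` for sample Sk; 0.012–10,000 fmol on
  column overall), 21 runs per site (days 1/3/5, S4 in triplicate).
* **Target–decoy error control** — semi-supervised linear-discriminant
  combination of sub-scores; Storey q-values (fixed λ = 0.4) from the decoy
  null in global, experiment-wide and run-specific contexts; the
  *consecutive filter* (global 1% FDR at peptide-query **and** protein
  level, then run-wise 1% at the query level) producing unit × run
  detection matrices and cumulative detection curves.
* **Quantification** — protein abundance as the summed top-5 fragment areas
  of the top-3 peak groups per protein and run; median-equalization
  normalization on detected background peak groups, with coefficient
  transfer to the SIS area tables. Results live in a
  `SummarizedExperiment`-based `ProteinQuantMatrix`.
* **Dilution metrics** — 1/x-weighted response-curve fits, lower limits of
  quantitation under bioanalytical criteria (CV < 20%, S/N > 20, 80–120%
  back-calculated accuracy), dynamic range, per-group averaged response
  curves, step fold changes, MS1-vs-MS2 percent-detected curves.
* **Reproducibility** — intra-day / inter-day / inter-site CV breakdowns at
  SIS-peptide and protein level (median ± sd), pairwise detection
  repeatability (intersection over union), completeness filtering.
* **Similarity** — pairwise Pearson correlation of log2 protein abundances
  on common proteins; hierarchical clustering of runs with Newick export.
* **Synthetic study generator** — a seeded multi-site simulator with known
  ground truth (site response offsets, peptide-by-site interactions, nested
  intra-/inter-day lognormal noise, detection floor, high-load saturation,
  MS1 interference ~10x MS2, 1:1 decoys, queried-but-absent library
  padding) used to validate every stage. Real peak-group/SIS tables in the
  documented TSV dialect drop into the same functions.

## Worked example

Simulate a 3-site study, run detection, quantification, normalization and
the downstream metrics:

```r
library(swathQC)

d <- buildDesign(nSites = 3)
d
#> StudyDesign: 5 dilution groups, 30 SIS peptides
#>   samples: S1, S2, S3, S4, S5 (serial 3-fold dilution)
#>   sites: 3  days: 1,3,5  runs/site: 21
#>   on-column range: 0.012 - 10000 fmol

ds <- simulateStudy(d, seed = 42, nProteins = 200, meanPeptides = 5)

sc  <- learnDiscriminant(ds@peakGroups, subsampleRatio = 1/63, seed = 1)
det <- consecutiveFilter(
  estimateQvalues(sc, context = "global", level = "peptide"),
  estimateQvalues(sc, context = "global", level = "protein"),
  estimateQvalues(sc, context = "experiment-wide", level = "peptide"),
  alpha = 0.01)
det$protein
#> DetectionMatrix (protein level, alpha = 0.01): 400 units x 63 runs, 10870 detections

quant <- inferProteinAbundance(ds@peakGroups, det$peptide, schedule = ds@schedule)
nc    <- computeNormalization(ds@peakGroups, det$peptide)
qn    <- applyNormalization(quant, nc)
qn
#> ProteinQuantMatrix: 186 proteins x 63 runs (linear scale, normalized)
#>   completeness: 92.8% of cells present
```

400 candidate protein units (half decoys) reduce to 186 confidently
quantified true proteins; the detection matrix is 93% complete, with the
missing cells concentrated in low-abundance proteins near the detection
floor.

```r
cvBreakdown(ds@sisAreas, "intra-day")$median                      # 4.3 (%)
cvBreakdown(ds@sisAreas, "inter-site")$median                     # 49.0
cvBreakdown(applyNormalization(ds@sisAreas, nc), "inter-site")$median  # 15.0
```

Replicate injections within a day vary by ~4% for the spiked standards;
across sites the raw areas differ by ~49% (instrument response offsets),
collapsing to ~15% once the background-derived median normalization is
transferred to the SIS areas.

```r
lq <- lloqReport(ds@sisAreas)
median(lq$lloq_fmol[lq$ms_level == "MS2"], na.rm = TRUE)   # 1.235 fmol
median(lq$lloq_fmol[lq$ms_level == "MS1"], na.rm = TRUE)   # 6.790 fmol
stepFoldChanges(ds@sisAreas[ds@sisAreas$ms_level == "MS2", ],
                lloq = lq[lq$ms_level == "MS2", ])
#> step1 step2 step3
#>  2.86  8.24 23.48
```

Fragment-level (MS2) quantification reaches several-fold lower limits of
quantitation than MS1 (interference dominates MS1 near the floor), and the
observed fold changes between dilution steps sit just below the nominal
3/9/27 because the top of the series saturates.

```r
rs <- repeatabilitySummary(det$protein, ds@schedule, "study-wide")
rs$medians        # 93.1 (% intersection-over-union, protein level)

sim <- similaritySummary(pearsonMatrix(qn),
                         setNames(ds@schedule$site_id, ds@schedule$run_id))
sim$withinMedian  # 0.9972
sim$betweenMedian # 0.9941

hc <- hierarchicalCluster(qn, impute = TRUE)   # Newick in hc$newick
clusterPurity(hc$hclust, setNames(ds@schedule$site_id, ds@schedule$run_id),
              k = 3)  # 1.0
```

Detection repeatability and quantitative correlations are high everywhere;
within-site correlations are only slightly higher than between-site ones,
yet the residual peptide-by-site structure is strong enough that the runs
cluster perfectly by acquisition site.

`runPipeline(defaultConfig(...))` executes all of the above (plus the
dilution and per-site analyses) in one call and returns a structured report
with provenance (config hash, seed, package version).

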