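---
title: "Benchmarking multi-site SWATH-MS: models and methods in swathQC"
author: "swathQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multi-site SWATH-MS: models and methods in swathQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathQC)
```

# Scope

swathQC implements the analysis side of a multi-laboratory benchmark of
data-independent acquisition (SWATH-MS) proteomics: a panel of stable
isotope-labeled standard (SIS) peptides is spiked into a complex cell-lysate
background at known serially diluted amounts, the same samples are acquired
at many sites over several days, and the resulting peak-group tables are
pushed through target–decoy error control, protein quantification,
dilution-series sensitivity analysis, multi-level variability metrics and
run-level similarity analysis. Because the deposited multi-terabyte raw data
is impractical for routine validation, the package carries a first-class
synthetic study generator with known ground truth; all statistical machinery
is agnostic to whether its input tables are simulated or real.

# Study design

The default design partitions 30 SIS peptides into five groups (A–E) of six.
Each group starts at a different amount in the most concentrated sample S5 —
1 fmol to 10 pmol in decade steps — and is diluted threefold into the
background four times (S4..S1), so the nominal on-column amount of group $g$
in sample $S_k$ is

$$c(g, S_k) = \mathrm{start}_g / 3^{\,5-k},$$

spanning 0.012–10,000 fmol over the whole design. Each site acquires every
sample once per day on days 1, 3 and 5, with S4 in triplicate: 7 injections
per day, 21 runs per site, 231 planned runs for 11 sites. Only the decade
start amounts are fixed by convention here; the spacing of the intermediate
group starts is configurable (`buildDesign(starts = ...)`), as is the
acquisition order within a day (ascending samples, replicates consecutive,
by default).

# The synthetic study generator

The generator defines the study conditions; its defaults are chosen once to
emulate the benchmark's printed, order-of-magnitude characteristics and are
not fitted quantities.

## Signal model

For a peptide with response factor $\rho$ measured at site $s$ on day $d$ at
amount $a$:

$$\mathrm{area} = B \cdot \omega_s \cdot \delta_{sd} \cdot \rho \cdot
  \eta_{ps} \cdot \frac{a}{1 + a/\kappa} \cdot e^{\varepsilon},
  \qquad \varepsilon \sim N(0, \sigma^2_\mathrm{intra})$$

* $B$ — a fixed area-per-fmol scale (10^4^, arbitrary units).
* $\omega_s$ — the site's global response offset, drawn log-uniformly in
  [0.5, 2]. Instrument sensitivity genuinely differs between sites; this is
  what median normalization must remove.
* $\delta_{sd}$ — a scalar day effect per site and day, carrying the
  inter-day variance in excess of the intra-day one:
  $\sigma^2_\mathrm{day} = \ln(1+\mathrm{CV}^2_\mathrm{inter}) -
  \ln(1+\mathrm{CV}^2_\mathrm{intra})$.
* $\eta_{ps}$ — a peptide-by-site lognormal interaction (sd 0.2 on the log
  scale), constant across a site's runs. It is the surrogate for
  chromatography/resin differences and is what makes runs cluster by site;
  a purely global offset would vanish under both median normalization and
  Pearson correlation.
* $a/(1+a/\kappa)$ — a hyperbolic soft-clip with saturation level
  $\kappa = 10{,}000$ fmol, so the top dilution point is visibly saturated
  and step ratios compress at the high end, while points a step or two below
  remain near-linear.
* $\mathrm{CV}_\mathrm{intra} = 0.05$, $\mathrm{CV}_\mathrm{inter} = 0.09$ —
  within-day and within-week variability in the few-percent range typical of
  well-behaved LC–MS platforms.

## Detection, noise and decoys

Each site has a detection-floor amount $f$ (default 0.05 fmol) at which the
signal-to-noise ratio is defined to reach 20. A background peptide is truly
present in a run when its effective amount exceeds a lognormally jittered
floor; sub-scores of present targets shift upward with
$\log_{10}(\mathrm{amount}/f)$, capped. Absent peptides still yield, with
probability 0.5, a noise peak group whose sub-scores follow the same
standard-normal null as the decoys — peptide-centric scoring always reports
a best-scoring candidate, and without such a false-target pool an empirical
false-discovery check would be vacuous. Decoys are emitted 1:1 with targets
and share no protein with any target.

The queried library is larger than the detectable proteome: `padLibrary()`
appends absent library proteins (default: as many as the sampled proteome,
emulating a 10,000+ protein assay library of which roughly half is
detectable in the sample). This pool is what run-context-only FDR filtering
keeps "discovering" and what the consecutive global filter suppresses.

MS1 areas carry an interference level ten times the MS2 one (and a 3x
precursor signal gain), so the MS1 lower limit of quantitation lands about
one order of magnitude above MS2 — interference, not absolute signal, is
what limits MS1 sensitivity near the floor.

## Reproducibility of the generator

A single master seed drives everything; per-run substreams are derived by a
stable string hash of the run id, and site-level effects (peptide-by-site,
day effects) by hashes of the site and day labels, so any run can be
regenerated in isolation and permuting the schedule does not change a run's
data.

## What the generator does not emulate

Raw spectra, chromatograms, retention-time drift, fragment-level
interference structure, inter-peptide correlation beyond the site
interaction, batch effects beyond multiplicative offsets, and instrument
failure modes (the deposited study lost 2 of 231 runs; `dropout` removes
runs at random rather than mechanistically). Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the statistical
machinery under this model, not performance claims about any instrument.

# Error control

Sub-scores are combined into a discriminant by iterated linear discriminant
analysis: seed on one designated sub-score, take targets at q ≤ 0.15
against all decoys, fit, rescore, repeat (5 iterations by default; the
procedure converges in 1–2 on separable data). Weights may be learned on a
record subsample (ratio ≈ 1/number of runs) and are applied to all records;
d-scores are standardized against the decoy distribution. Records are
sorted by (query, run) before subsampling so the result is order-invariant.

q-values use the decoy null with a Storey correction at fixed λ = 0.4:
$p(s)$ is the fraction of decoys above $s$, $\pi_0$ the fraction of target
p-values above λ scaled by $1/(1-\lambda)$, and
$q(s) = \min_{t \le s} \pi_0\, N_T\, p(t) / \#\{\mathrm{targets} \ge t\}$,
floored at 0 (when no decoy exceeds a threshold the estimate is reported as
0 rather than smoothed). Three contexts are supported: **global** (best
record per unit across the study, one q per unit), **experiment-wide** (one
q per unit per run from the pooled score distribution) and **run-specific**
(estimated within each run). Proteins are scored by their best peptide
query; this best-peptide proxy is the simplest defensible protein-level
estimator and is deliberately conservative about protein inference.

Detection uses the consecutive filter: a query counts as detected in run
$r$ iff its global q and its protein's global q and its run-wise q all pass
the threshold (1% by default). The cumulative distinct-protein curve under
this filter saturates, while run-context-only filtering accumulates false
units steadily — the contrast the filter exists to produce.

# Quantification and normalization

Protein abundance per run is the sum over the protein's top three detected
peak groups (ranked by total fragment area; all if fewer) of each group's
top five fragment areas (all if fewer). The ranking statistic is
configurable in principle; total area is the default because "most intense"
is otherwise underspecified. Normalization equalizes per-run medians of
peak-group total areas over detected, non-decoy background peak groups —
decoys and spike-ins are excluded so the invariant-background assumption
holds — with the reference set to the median of per-run medians (symmetric
and robust; any fixed reference would do). The same per-run coefficients
are transferred to the SIS area tables, mirroring how a background-derived
normalization is applied to standards quantified by a separate tool.
Missing cells are explicit and never imputed at this stage. Linear-scale
medians are used; the medians are equalized before any log transform.

# Dilution-series metrics

Response curves are weighted least squares of mean area on nominal amount
with 1/x weights. The LLOQ pass iterates from the lowest concentration
upward, refitting on retained points and dropping the lowest point while it
fails any of: replicate CV < 20%, mean S/N > 20, back-calculated accuracy
within 80–120%. Back-calculation includes the evaluated point (standard
bioanalytical practice).

Before that pass, the upper end is trimmed: while the highest retained
point fails back-calculated accuracy *against a fit anchored on the lowest
three S/N-qualified points*, it is dropped (at least three points are kept).
Two details matter here. First, with detector saturation at high load a
least-squares line over the whole curve bends toward the saturated top —
the top points then pass accuracy while the honest low points fail, so the
upper linear range must be judged from the quantifiable low end. Second,
the anchor uses S/N qualification because S/N does not depend on any fit,
which keeps the procedure well-defined when the bottom of the curve is
interference-dominated. Mid-curve failures are only flagged, never removed
automatically.

Dynamic range is $\log_{10}(\mathrm{top}/\mathrm{LLOQ})$ per curve; note a
single peptide spans at most $3^4 = 81$-fold by design, so study-wide
multi-order dynamic range statements belong to per-site averaged curves
(`averagedResponseCurve()`), which pool groups across the full 6-order
span. Step fold changes are geometric means of mean-area ratios at one,
two and three dilution-step spacings over points at or above the LLOQ;
saturation pulls the observed one-step ratio below the nominal 3.
Percent-detected curves count a peptide as detected at concentration $c$
iff its LLOQ is at or below $c$ (undetermined LLOQs never count).

# Variability, repeatability, completeness

CVs are 100·sd/mean. For SIS peptides the replicate sample (S4) yields one
intra-day CV per peptide x site x day (3 injections), one inter-day CV per
peptide x site (9 injections) and one inter-site CV per peptide (all S4
injections study-wide); distributions are reported as median ± sd, never
the median alone, with per-site medians also available. Protein-level CVs
use all runs, restricted to proteins present in strictly more than 80% of
runs (a strict reading of the ">80%" convention). Repeatability between
two runs is 100·|A∩B|/|A∪B| over detected units; a pair of empty runs is
undefined and excluded from medians but counted. Completeness ordering for
display sorts by (present fraction, mean abundance) descending.

# Similarity

Pairwise run correlations are Pearson on log2 abundances over
pairwise-complete proteins (pairs with fewer than 3 common proteins are
undefined). Clustering is agglomerative on Euclidean distances between
log2 run profiles using Ward linkage (`ward.D2`) by default. The
conventional default for this kind of figure is complete linkage, but on
data with occasional outlying runs complete (and average) linkage let a
single outlier absorb several sites into one cluster when the tree is cut
into k groups; Ward recovers the compact balanced site clusters this
analysis asks about, and the linkage remains a parameter. Clustering uses
complete-case proteins, or optionally proteins ≥ 50% complete with
median imputation. Trees serialize to Newick via `ape` and round-trip.

# Numerical and degenerate-input choices

* Ties in d-scores are broken by unit id so q assignment is deterministic.
* A constant sub-score gets weight 0 with a warning; learning without
  decoys is an error, not a fallback.
* `determineLLOQ` returns "undetermined" (NA) rather than erroring when no
  point passes; dynamic range on an undetermined LLOQ is an error.
* An empty peak-group table quantifies to an empty matrix, not an error;
  a run whose areas are all zero fails normalization loudly.
* Median normalization of a single run returns coefficient 1 exactly.
* Zero-CV inputs (noise-free simulation) are supported end to end: the
  generator accepts zero CVs and the metrics return exact zeros.

# Problem sizes used for validation

The test suite exercises the pipeline at desk scale, chosen so the full
suite runs in a few minutes: 3-site studies with 120–500 background
proteins for detection/quantification properties; ten replicate 3-site
simulations (500 proteins, ~4,000 peptides plus an equal absent-library
pool) for false-discovery calibration; ten 3-site simulations for
detection-floor recovery; and one 11-site study (250 proteins, ~2,000
peptides per arm) for site clustering. The deposited study's headline
numbers (protein counts near 5,000, specific CV medians, correlation
medians) are properties of the full 229-run dataset and are not asserted at
these scales; what is asserted is the calibration and direction of each
metric under known ground truth.

# Known limitations

* Protein-level FDR uses the best-peptide score proxy; no picked or
  grouped protein competition is implemented.
* The decoy model is a calibratable stand-in (standard-normal sub-scores);
  real decoy score distributions inherit library structure.
* Median equalization is the only batch correction offered; it removes
  exactly the multiplicative per-run component.
* The S/N definition in synthetic mode (area over a derived noise level)
  stands in for proprietary vendor noise estimation; in real mode S/N is an
  input column taken at face value.
* Peptide-to-protein inference assumes proteotypic peptides throughout.
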