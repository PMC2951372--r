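---
title: "tilemark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilemark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilemark)
```

## Scope

`tilemark` implements the analysis chain for ChIP-chip tiling-array profiling
of the repressive histone mark H3K27me3 in the Arabidopsis endosperm: from
probe intensities to enriched regions, gene-level target calls, their
classification against published seedling target lists, metagene and
chromosomal profiles, transposon-superfamily and functional-category
enrichment, DNA-methylation stratification by target class, and rank-product
differential expression. Because raw tiling-array data are rarely at hand, a
seeded synthetic-data generator produces every input with embedded ground
truth, so the whole chain can be exercised and validated end to end.

This vignette records the statistical model behind each stage, the parameters
that matter, and the design decisions taken where the method left genuine
choices open.

## Probe scoring

**Standardization.** Tiling probes differ in hybridisation affinity; ignoring
this inflates the variance of any enrichment contrast. Each probe carries a
scalar affinity covariate in [0, 1] (in the generator it is drawn uniformly;
with real data any per-probe baseline predictor can be supplied). Probes are
partitioned into `n_affinity_bins` (default 20) quantile bins of that
covariate — the binning is shared by all channels and replicates — and within
each bin and channel/replicate the intensities are standardized:

    t = (x - location) / max(scale, scale_floor)

with median and 1.4826·MAD as the default location/scale. The robust pair is
preferred over mean/SD (available via `robust = FALSE`) because enriched
probes sit in the same bins as null probes and would otherwise inflate the
scale; a `scale_floor` guards bins where all intensities coincide. This
replaces the full sequence-composition probe model of MAT-style scoring with
a single affinity covariate: the statistical role (a probe-specific baseline
removed before windowing) is preserved without any sequence machinery.

**Enrichment.** Two control channels are available, input chromatin and an
unspecific IgG immunoprecipitation. Per probe, the replicate-mean
standardized difference is formed against each control and the two contrasts
are averaged with equal weight:

    e = 1/2 * [ mean_r(t_IP - t_input) + mean_r(t_IP - t_IgG) ]

Replicate contrasts are averaged before windowing (the alternative — joint
scoring of replicates inside the window — is a one-line change but was not
needed).

**Windowed score.** For each probe, the enrichment values of all probes on
the same chromosome whose *start* lies within `window_size/2` (default
500/2 bp) of the focal probe's start are pooled, `floor(0.10 * n)` values are
trimmed from each end of the sorted pool, and

    score = mean(retained) * sqrt(m),      m = number retained.

The sqrt(m) factor puts the trimmed mean on a roughly standard-normal scale
under the null, so a fixed threshold has a stable meaning across probe
densities. Only the window size is a first-class parameter of the original
analysis; the 10 percent trim and the sqrt(m) scaling follow the cited
scoring method's defaults and are exposed in `scoring_params()`. Window
membership by probe start (rather than midpoint or fractional overlap) is a
deterministic convention whose effect is bounded by one probe length.

## Region calling

Probes with score at or above `score_threshold` (default 3.5) are chained
while the gap between consecutive qualifying probes — measured end-to-start —
does not exceed `max_gap` (default 200 bp). A chain spans from its first
probe's start to its last probe's end and is kept only if that genomic span
reaches `min_run` (default 300 bp). The published description does not state
whether the minimum run is in base pairs or probes; base pairs are assumed
(and configurable), which matches the 750-bp median region length reported
for dense tiling. The gap convention (end-to-start, not start-to-start) is
likewise fixed here and pinned by tests against a brute-force enumeration of
qualifying chains.

A region's score is the maximum probe score inside it (mean and 75th
percentile are available); the maximum matches the visual peak height of
browser tracks. Summaries report count, total bp, genome fraction, median
length, and the heterochromatic fraction, where a region is heterochromatic
when its midpoint falls inside a declared pericentromeric interval — midpoint
membership is unambiguous for regions straddling a boundary.

## Gene-level targets and classification

A feature's score is the 75th percentile of the scores of probes lying
entirely within its transcribed extent, absent when no probe qualifies. All
percentiles in the package — this one, region medians, box-plot quartiles,
methylation medians — use one convention: linear interpolation on ascending
order statistics with `h = (n - 1) q` (`stats::quantile` type 7).

A feature is a *target* when at least one enriched region overlaps its
transcribed extent by at least 1 bp under half-open interval semantics
(abutting regions do not count). The published counts tie genes to regions
without stating the linkage rule; overlap reproduces the "genes associated
with" semantics, and the gene score is carried alongside for score-by-class
summaries. Targets found in the union of the supplied reference lists
(published seedling H3K27me3 targets) are *shared*; the rest are
tissue-*specific*. Matching is by feature id — a cross-study coordinate
overlap criterion would need the external coordinates, which are not part of
the inputs.

## Profiles

Metagene profiles rescale each gene body to 20 equal-length bins (5 percent
intervals, 5' to 3' respecting strand) and each 2-kb flank to fixed 100-bp
bins; a probe contributes to the bin containing its start. The default
averages all contributing probes pooled across genes; per-gene averaging
(each gene weighted equally) is available, as the published figure legend
does not state the averaging unit. Unstranded features are treated as plus
strand with a warning. Chromosomal densities count regions, genes and TEs by
the 200-kb window containing their midpoint, so window totals equal element
counts exactly. Score-by-class box-plot summaries optionally split classes at
log2 expression 4.2, the split used in the study's figure; the value is a
parameter.

## Set statistics

All enrichment and overlap questions reduce to the hypergeometric
distribution: population N (the features probed by the array — never the
whole annotation), K population successes, a sample of n, k observed
successes. Upper tails (P(X >= k)) test enrichment, lower tails depletion;
`stats::phyper` supplies the exact, log-space-stable mass. Multiple testing
uses Benjamini-Hochberg, applied within each analysis family: all
superfamily tests (both tails pooled, so reporting enrichment and depletion
together does not double the false-positive budget), or all category tests.
Category results are filtered at an adjusted p of 1e-3, the study's critical
value. Calibration of the overlap test is checked at a design where the
discreteness of the hypergeometric matters little: with a universe of 1000
and two sets of 150, the achieved size of the nominal-0.05 test is 0.044
(computed analytically from the tail function), inside the tested
[0.03, 0.07] band.

## Methylation stratification

Element-level methylation is coverage-weighted: the summed methylated weight
over the summed total weight across an element's sites, per sequence context
(CG, CHG, CHH) and tissue. Zero total weight yields a missing value, not a
zero — unobserved is not unmethylated. Weighted aggregation is the standard
choice for bisulfite-derived levels; unweighted site means would let
low-coverage sites dominate. Medians are reported per feature type, target
class (all / shared / specific), context and tissue. CHH, which is uniformly
low, is computed but excluded from default report tables.

Expression-pattern clustering (two clusters for the expressed/repressed
split, five for the tissue-panel analysis) is centroid-based k-means with 25
restarts on row-standardized expression, where squared Euclidean distance is
monotone in correlation distance — a generic, seeded replacement for the
original GUI clustering tool. When a matrix has no more distinct
row-patterns than clusters, each distinct pattern becomes its own cluster
(identical rows share one) rather than failing.

## Rank-product differential expression

For k fold-change comparisons between mutant and wild-type replicates, each
gene's rank product is the geometric mean of its ranks (rank 1 = strongest
change, in each direction separately). The null distribution permutes the
ranks within each comparison independently, `n_permutations` (default 1000)
times; a gene's p-value is the fraction of pooled null rank products at or
below its observed one, and the false discovery rate at its cut-off is the
expected number of false positives (null count divided by permutations) over
the number of genes called. A gene is significant when either direction
passes FDR <= 0.1 and its absolute mean log2 fold change exceeds 0.6 — the
published fold-change cut-off is interpreted on the log2 scale
(about 1.52-fold), recorded as a configurable default.

Comparisons are formed one-to-one between mutant and wild-type replicates by
default (k = min of the replicate counts). The all-pairs scheme
(`pairing = "all"`) is available but shares replicates across comparisons,
which correlates a gene's ranks and makes the independent-permutation null
anti-conservative, inflating the fraction of small p-values well above
nominal. The one-to-one default keeps the permutation null exact, which the
calibration tests verify.

qPCR relative expression is the ratio of efficiency-corrected target to
reference expression, `R = x_t / x_r` with `x = E^(-Ct)`, and first-order
error propagation `se_R = R * sqrt((se_t/x_t)^2 + (se_r/x_r)^2)`.

## Mendelian seed classes

`expected_seed_fraction()` enumerates parental gamete combinations per locus
(independent segregation) and evaluates a per-locus predicate: either
zygotic-homozygous, or *maternal* — satisfied by the maternally transmitted
allele alone. The maternal flag encodes maternal-effect loci such as the
imprinted FIS2, where inheriting a mutant maternal allele abolishes FIS
activity regardless of the paternal allele; it is a predicate property, not
hard-coded biology. For a selfed fis2/FIS2; met1/MET1 double heterozygote
and the predicate (maternal fis2, met1/met1) the expectation is
1/2 x 1/4 = 12.5 percent of seeds.

## The synthetic-data generator

The generator emulates, at 1/24 scale, the genome the study analysed:

* **Genome**: two 2.5-Mb chromosomes, each with a central heterochromatin
  block covering 16 percent of its length — the genome-wide fraction of TEs
  located in pericentromeric heterochromatin.
* **Annotation**: 1100 genes, 40 pseudogenes, 400 TEs, 100 TEGs, placed
  without within-type overlap by free-gap sampling; genes and pseudogenes in
  euchromatin, TEs/TEGs heterochromatic with probability 0.16 (TE) and 0.46
  (TEG), the study's genome-wide values. Gene density (about one gene per
  4.5 kb) matches the Arabidopsis genome. TE superfamilies are drawn from a
  fixed weight table of the common Arabidopsis families.
* **Probes**: 25-mers spaced about 25 bp apart with uniform jitter,
  emulating a dense whole-genome tiling design, each with a uniform [0, 1]
  affinity covariate.
* **Truth domains**: 74 requested targets (55 genes, 4 pseudogenes, 6 TEs,
  9 TEGs — about the study's ratio of targets to genes), one domain per
  selected feature covering its body, padded to at least 600 bp so the
  300-bp minimum-run rule is exercised on both flanks, and separated by at
  least 1 kb so each domain is individually resolvable by a 500-bp window.
  Domain coverage is about 3 percent of the genome, the same order as the
  1.6 percent the study reports, which keeps the enriched fraction per
  affinity bin small enough not to distort the robust scale.
* **ChIP intensities**: log2 intensity = baseline + affinity slope x
  covariate + domain effect (IP channel only, probes whose midpoint lies in
  a domain) + Gaussian noise. Defaults: noise SD 1 (so a domain effect of
  2.0 is also about 2.0 in standardized-score units), three replicates per
  channel, matching the replication level the study states for its arrays.
* **Methylation**: per-element Beta-distributed levels around class means
  with binomial counts at Poisson coverage. Shared targets are essentially
  unmethylated in both tissues; specific targets and background TEs are
  methylated in vegetative tissue with reduced endosperm levels
  (the endosperm is globally hypomethylated); CHH is low everywhere.
* **Expression**: log2-scale Gaussian matrices; a deregulated set shifted by
  a chosen log2 effect in the mutant, and a tissue panel with two planted
  archetypes (endosperm-expressed / endosperm-repressed) for clustering.
* **Reference lists**: 86.5 percent of true targets are included (these
  become shared targets), padded with non-target ids, mimicking the larger
  seedling target complement.

What the generator deliberately does **not** model: probe sequence and
cross-hybridisation, array spatial artifacts, CEL-level preprocessing,
bisulfite reads (methylation is emitted directly as weighted fractions),
biological correlation between neighbouring genes, and allele-specific
(imprinted) signal. Passing tests therefore demonstrate that the algorithms
recover planted structure under an idealised noise model — they do not
certify performance on real arrays, where probe effects are sequence-driven
and heavier-tailed.

## Numerical choices and degenerate inputs

* One shared percentile convention (type 7) across every module.
* `scale_floor = 1e-6` keeps standardization defined for constant bins
  (t = 0 there).
* Affinity bins collapse, with a warning, when fewer distinct covariate
  values (or probes) than bins exist.
* Windows never cross chromosomes; the focal probe is always in its own
  window, so scores exist for every probe.
* Rank ties use average ranks; k-means ties on identical rows resolve to a
  shared cluster; all stochastic steps take explicit seeds, and the pipeline
  fans a single global seed out to per-stage seeds by hashing the stage
  name, so any stage can be reproduced in isolation.
* Empty cases return empty, typed objects (no regions, empty groups,
  zero-coverage methylation) rather than zeros that could be mistaken for
  measurements.

## Problem sizes used by the test suite

The bundled tests run the full pipeline on the default 5-Mb genome (about
200,000 probes; one run takes well under a minute), check the region caller
against brute-force enumeration on 1000 random small tracks, the windowed
score against a naive recomputation on 1000 probes, hypergeometric tails
against exhaustive draw enumeration up to N = 12, rank-product calibration
on 2000 genes with 3+3 replicates and 1000 permutations, and overlap-test
calibration over 2000 null draws. These sizes were chosen so the whole suite
documents the package's statistical behaviour while remaining quick to run
routinely.

## Known limitations

* The affinity covariate is an abstraction; with real arrays a sequence-based
  baseline model (or an externally computed covariate) must be supplied.
* Cross-study target matching is id-based; coordinate-based matching across
  annotation versions is out of scope.
* The rank-product FDR is the permutation-based expected proportion of false
  positives, which can exceed 1 for weak genes; it is not capped.
* Region calling uses a fixed score threshold, as in the original analysis —
  no FDR-calibrated peak calling or replicate-consistency analysis.
* GO-style category maps are flat labels; no ontology propagation.
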