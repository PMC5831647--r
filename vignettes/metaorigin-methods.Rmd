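---
title: "Meta-origin analysis of cohesin regulation data: models and methods"
author: "cohesinmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-origin analysis of cohesin regulation data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesinmeta)
```

# Scope

`cohesinmeta` implements the genome-wide analysis machinery used to study
how cohesin and its regulators (Pds5, Wapl, Brca2, Nipped-B, and the SA
subunit) are distributed around early DNA replication origins, and how
RNAi depletions of those regulators reshape that distribution. The package
covers six analysis layers — input-normalized ChIP-seq enrichment,
percentile-based binding-region calling, meta-origin statistics,
enrichment at 500 bp regulatory elements, depletion-versus-mock expression
contrasts, and dual-label DNA fiber statistics — plus a seeded
synthetic-data generator that supplies ground-truth inputs for all of
them. Everything upstream of coverage tracks (sequencing, alignment) and
everything imaging-based (metaphase spreads, wing morphometrics) is out of
scope; coverage tracks, origin tables, element tables, expression tables
and fiber tables are the package's inputs.

# Enrichment model

ChIP signal is quantified as log2 enrichment relative to input chromatin
on a fixed anchor grid: 250 bp sliding windows advanced every 50 bp. For
anchor $i$ on a chromosome,

$$E_i = \log_2\!\frac{s\,C_i + c}{I_i + c},
\qquad s = \frac{\text{total input depth}}{\text{total ChIP depth}},$$

where $C_i$ and $I_i$ are the ChIP and input coverage sums in window $i$
and $c$ is a pseudocount (default 1 count per window, guaranteeing finite
values). Scaling the ChIP sums by $s$ puts both samples on the input's
sequencing depth; windows are anchored at multiples of 50 bp from
coordinate 0 and trailing bases that do not fill a complete window carry
no anchor. Working at window rather than base resolution suppresses
counting noise and puts every sample on one grid, so replicates can be
averaged anchor-wise and conditions compared anchor-wise
(`average_replicates()`, `fold_change_track()`). Replicate agreement is
summarized by the genome-wide Pearson correlation of two tracks
(`replicate_correlation()`), with a restricted-region variant for
single-locus views.

All downstream statistics assign anchors to bins or elements by the
*window midpoint*; anchors are never overlap-weighted. The alternative
(weighting anchors by overlap fraction) changes bin means by far less than
replicate noise at 50 bp spacing and complicates the oracle definition,
so the midpoint rule is used uniformly.

# Binding-region calling

Regions of significant enrichment are called with a percentile threshold:
the threshold is the 95th percentile (linear interpolation between order
statistics) of all anchor values on the included chromosomes jointly, ties
at the threshold included. Maximal runs of consecutive above-threshold
anchors are expanded to their full 250 bp window extents; extents that
touch or overlap are merged, and merged intervals shorter than 300 bp are
discarded. The percentile is computed genome-wide over an explicit
chromosome include-list — in fly data that list is the major euchromatic
chromosome arms — because site counts are reported genome-wide, not per
chromosome. Overlap between two factors' region sets counts an A region as
overlapping when it shares at least one base with any B region (half-open
semantics, the `bedtools intersect` convention), and reports the fraction
to the nearest percent. With the reference site counts (6,452 and 6,430
regions, 3,600 overlapping) the report reads 56%.

Degenerate case worth knowing: on a constant track every anchor ties with
the threshold, so each chromosome becomes a single region — percentile
thresholds are only meaningful on tracks with real variation.

# Meta-origin statistics

The meta-origin coordinate system averages enrichment in twenty
non-overlapping 10 kb bins spanning −100 kb to +100 kb around each origin
center; the per-origin × per-bin matrix (`bin_matrix()`) is the unit of
all meta-origin statistics. Bins extending past a chromosome end are
missing, never zero. Three summaries are computed:

* **Mean profile** (`mean_profile()`): missing-aware column means with
  per-bin origin counts.
* **Ratio profile** (`ratio_profile()`): for a subunit pair such as
  SA/Rad21, the per-origin per-bin ratio of mean enrichments taken in the
  *linear* domain ($2^{E}$), then averaged across origins. This is the
  stoichiometry proxy: it reports the direction of variation of, say, the
  SA-to-ring ratio, not absolute stoichiometry. The linear domain is a
  deliberate choice — "ratio of mean enrichments" reads as a ratio of
  magnitudes — and matrices already in linear units are accepted via
  `log2_input = FALSE`. Bins with a non-positive denominator are missing.
* **Per-bin paired Wilcoxon** (`bin_wilcoxon()`): for mock versus
  depleted, the two-sided Wilcoxon signed-rank test of the paired per-bin
  differences across origins. Zero differences are dropped before ranking
  (Wilcoxon's original rule), ties share average ranks, the exact null
  distribution is used up to n = 25 and the normal approximation with
  continuity correction beyond. Profiles are displayed as raw
  −log10 p; Benjamini–Hochberg adjustment is available (`adjust = "BH"`)
  for decision rules such as the planted-effect recovery experiment below.

Elements are handled analogously at 500 bp scale: per-element mean
enrichment by anchor midpoint, per-element linear-domain ratios with class
medians (the violin-plot median convention), uniform random 500 bp
control elements with optional exclusion intervals, and per-class paired
signed-rank depletion tests.

# Expression contrasts

Expression tables hold mean normalized nucleotide coverage per gene. A
depletion contrast compares (by default) three depletion replicates to six
mock replicates: log2 fold-change of pseudocounted means, a Welch t-test
per gene on log2(coverage + 1), and BH q values across all tested genes.
The test choice is a package decision — the original analyses do not name
their per-gene statistic — and the Welch test on logs is the conventional
robust default for small replicate groups; its type-I error is verified
empirically at 5% in the acceptance suite. Contrast similarity is the
genome-wide Pearson correlation of log2 fold-changes. Thresholded overlap
analysis partitions the shared gene universe by significance (p ≤ 0.05 by
default; p rather than q yields larger gene groups) and direction, and
tests the increase/increase and decrease/decrease overlaps with Fisher's
exact test against the shared universe. The wing-disc active-gene rule is
the union of genes at or above the control median in controls and genes
at or above the *control* median in mutants.

# Fiber statistics

Dual-label fiber tables carry the lengths of the first (IdU) and second
(CldU) analog tracts; only connected pairs are measured, so both lengths
are positive by construction. The per-fiber CldU/IdU ratio reports fork
progression after the label switch — fork stalling (e.g. hydroxyurea)
shortens the second tract, pulling the ratio below 1. Group comparisons
use the unpaired two-sided Wilcoxon rank-sum test (different groups are
different cells), exact up to 20 fibers per group and tie-corrected normal
approximation beyond; pooling of treated and untreated first-label tracts
is left to the caller by filtering the table, since the measured tracts
are combined in some designs.

# The synthetic-data generator

No generative model is published for these data; the generator's only
contract is to reproduce the qualitative genome-wide structure and the
reported reproducibility statistics, so that every pipeline stage can be
tested against planted truth.

**Genome** (`simulate_genome()`): chromosomes carry genes (log-normal
lengths, mean ≈ 6 kb; exponential intergenic gaps, mean 2 kb; 50% active),
500 bp elements (promoters at active gene starts, extragenic enhancers at
4.4/Mb, PREs at 1.6/Mb — the genome-wide densities implied by the
full-scale counts of 7,389 / 523 / 195 elements), and origins placed
evenly with jitter, at least 200 kb from chromosome ends so a full
meta-origin window fits.

**Occupancy** (`occupancy_model()`): expected relative ChIP occupancy at
distance $d$ from the nearest origin is
$\lambda(d) = b + a\,\mu(d)\,e^{-d/(\ell\,\delta)}$ inside active genes
and $b$ outside (inactive genes and intergenic DNA carry baseline only —
the "skipping" of spreading cohesin over inactive chromatin). Defaults:
baseline $b = 0.5$, amplitude $a = 8$, decay $\ell = 25$ kb. Depletion
conditions act through $\delta$ (decay-scale multiplier; domain extension
as with Pds5/Wapl loss) and $\mu(d)$, which interpolates between an
origin-center multiplier and a flanking multiplier with scale $\ell/2$:
SA loss at origin centers under Pds5 depletion is an origin multiplier
below 1, SA gain under Brca2 depletion one above 1, flanking gains a
flank multiplier above 1. Anchoring the modifiers to the origin component
(rather than the genome-wide baseline) matters: enrichment is
depth-normalized, so a genome-wide occupancy lift is compositionally
invisible, whereas origin-anchored changes survive normalization the way
the real regional effects do.

**Coverage** (`simulate_chip_pair()`): per-base Poisson read starts
proportional to occupancy (times a mean-one gamma noise field in 1 kb
blocks, independent per replicate, variance = `dispersion`), each start
extended by a fixed 300 bp fragment (typical sonication size), summed to
integer depth. The input sample is occupancy-independent Poisson around
uniform depth, 45× by default; ChIP depth defaults to 20×, within the
"at least 10× per replicate" regime of the emulated experiments. Total
simulated depth lands within 5% of the request.

**Noise calibration** (`calibrate_dispersion()`): the experiments report
a replicate-correlation band (0.65–0.9 genome-wide), not a noise model, so
the generator searches the dispersion that lands two simulated replicates
at mid-band; correlation is monotone decreasing in dispersion, and the
helper brackets and interpolates on a fixed grid. On the default genome
the calibrated dispersion is ≈ 0.055 with r ≈ 0.77; the package default
(0.05) is that calibration rounded.

**Expression** (`simulate_expression()`): per-depletion true log2
fold-change vectors share a latent component so that any two depletions
correlate at a target value (default 0.6, matching the strongest observed
depletion-pair correlations); 40% of genes are affected with effect SD
0.9, baselines are log-normal, and replicates add 0.25 log2-units of
noise — enough to keep replicate correlations above 0.95 while letting a
3-versus-6 contrast recover true fold-changes at r ≥ 0.9 (the analytical
attenuation of the contrast correlation is ≈ 0.91, keeping the recovered
0.6 inside ±0.1).

**Fibers** (`simulate_fibers()`): log-normal first-label tracts (median
9 µm, log-SD 0.45), connected second tracts equal to the first times
log-normal noise (log-SD 0.25) times a stall factor in (0, 1] under
treatment. The median CldU/IdU ratio equals the stall factor by
construction.

All generators take one explicit integer seed and restore the caller's
RNG state; fixed seed means byte-identical output.

## What the generator does *not* emulate

Real ChIP-seq has mappability artifacts, copy-number variation, GC bias,
fragment-size variation and non-uniform input chromatin; real expression
data have length/GC biases and dispersion–mean trends; real fibers have
measurement truncation at the resolution limit. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the *analysis machinery* under the planted statistical structure — not
robustness of biological conclusions to those artifacts.

# Planted-effect recovery: design and problem sizes

The flagship validation plants a Pds5-style depletion (flank amplitude
×1.5, decay ×2) in the Rad21 occupancy model and asks the meta-origin
Wilcoxon analysis to flag the flanking bins. Study-scale conditions: 78
origins spaced 210 kb on six ~2.9 Mb chromosomes, plus four 16.5 Mb
origin-free chromosomes so that origin territory covers a realistic
minority (~20%) of the genome — without that dilution, depth
normalization cancels the planted regional gains, which is a property of
the real measurement, not an artifact. Tested tracks emulate the
replicate-averaged design (three ≥10× replicates ≈ one 30× track) with
amplitude 2, matching the ~1 log2 scale of observed center-bin means; all
ChIP samples in a run are normalized to one shared 45× input. Across 50
seeded runs, every bin beyond ±20 kb must be BH-significant (α = 0.05)
with an occupancy increase in at least 90% of runs, and the SA variant
(origin multiplier 0.5) must show the center decrease with flanking
increase. Companion recoveries: a planted SA:Rad21 origin-center ratio
elevation within 10%, the planted 0.6 expression-effect correlation
within ±0.1, and a 0.5 fiber stall factor at p < 1e-6 in ≥95% of runs at
200 fibers per group.

Problem sizes elsewhere are chosen to exercise the statistics at
desk scale: oracle-equivalence suites use ≥100 randomized small instances
per operation; type-I calibration uses 2,000 null tests per statistic;
the default end-to-end pipeline genome is five 1.2 Mb chromosomes with 20
origins.

# Numerical choices and degenerate inputs

* Percentiles: `quantile(type = 7)` (linear interpolation), ties
  included at the threshold.
* Pseudocounts: 1 count per window (enrichment), 1 coverage unit
  (expression); both guarantee finiteness and are negligible at the
  depths used.
* Wilcoxon zero differences dropped; all-zero bins give a missing p.
* Fisher tables with an empty margin give p = 1 (no evidence, not an
  error).
* Non-positive fiber lengths are rejected row-wise with a warning count;
  all-tied group comparisons return p = 1 with a warning.
* Coverage vectors are per-base; window sums accumulate in double
  precision so deep tracks cannot overflow integer range.
* Random-element placement retries in bounded batches and errors if the
  exclusion set leaves no room.

# Known limitations

The Welch-on-logs contrast and the paired signed-rank element test are
package decisions where the original statistic is unstated; both are
calibrated empirically but may differ from the original p values in
detail. The region-calling rule reproduces the stated thresholding
semantics, not the idiosyncrasies of the genome-browser tool originally
used to export regions. Ratio profiles assume the linear enrichment
domain. The synthetic occupancy model is a stand-in: its parameters are
tuned to qualitative structure, so effect sizes recovered from it should
not be read as biological estimates.

# A complete run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "pipeline_out")
res$regions$overlap           # binding-region overlap between Rad21 and SA
head(res$metaorigin$wilcoxon) # per-bin mock vs iPds5 test
res$expression$fc_correlation # correlation of the two depletion contrasts
```
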