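# cohesinmeta

Genome-wide analysis machinery for studies of cohesin regulation around
DNA replication origins, written for analysts working with ChIP-seq,
RNA-seq and DNA-fiber readouts of cohesin accessory-factor depletions
(Pds5, Wapl, Brca2, Nipped-B) in cultured cells.

The package implements, as tested and reusable R functions:

* **Input-normalized sliding-window enrichment.** For ChIP coverage $C$
  and input coverage $I$ summed over 250 bp windows anchored every 50 bp,
  $E_i = \log_2\left((s\,C_i + c)/(I_i + c)\right)$ with
  $s = \text{total input}/\text{total ChIP}$ and pseudocount $c$;
  replicate averaging, genome-wide Pearson replicate agreement, and
  per-anchor fold-change tracks between conditions.
* **Binding-region calling**: anchors at or above the genome-wide 95th
  percentile, merged over their window extents, kept when ≥ 300 bp; plus
  shared-base overlap statistics between two factors' region sets.
* **Meta-origin analysis**: per-origin mean enrichment in 10 kb bins from
  −100 kb to +100 kb around early replication-origin centers; mean
  profiles, linear-domain subunit-ratio profiles (e.g. SA/Rad21, the
  stoichiometry proxy), and per-bin paired Wilcoxon signed-rank tests
  between mock and depleted conditions.
* **Regulatory-element enrichment**: mean enrichment per 500 bp promoter /
  enhancer / PRE element, class-wise ratio distributions and medians,
  random control elements, per-class paired depletion tests.
* **Expression contrasts**: depletion-versus-mock log2 fold-changes with
  Welch tests and BH q values, contrast correlations, thresholded
  gene-set overlaps with Fisher's exact test, and the wing-disc
  active-gene rule (union over the control median).
* **DNA-fiber statistics**: CldU/IdU connected-tract ratios, group
  medians, and Wilcoxon rank-sum comparisons (fork-stall detection).
* **A seeded synthetic-data generator** for all of the above: genomes
  with genes/elements/origins, origin-centered factor occupancy gated to
  active genes, depletion modifiers (domain extension, origin-center SA
  loss/gain), calibrated replicate noise, correlated expression effects,
  and log-normal fiber tracts — so the entire pipeline runs end to end
  with ground truth and no downloads.

A bundled table of 78 early-origin positions
(`inst/extdata/bg3_early_origins_synthetic.tsv`; synthetic stand-in
coordinates on the five major fly chromosome arms) drives full-scale
meta-origin analyses.

## Worked example

One command simulates a complete depletion experiment (5 × 1.2 Mb
chromosomes, 20 origins, Rad21 and SA ChIP in mock and Pds5-depleted
conditions, expression and fibers) and runs every analysis stage:

```r
library(cohesinmeta)
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "pipeline_out")

res$regions$overlap
#> overlap_report: |A| = 221, |B| = 221, 157 A regions overlap B (71%)

subset(res$metaorigin$wilcoxon, abs(bin_start + 5000) > 20000 & p < 0.01)[, 1:5]
#>    bin_start bin_end n_pairs           p minus_log10_p
#> 5     -60000  -50000      20 0.003654480      2.437174
#> 8     -30000  -20000      20 0.001432419      2.843930
#> 13     20000   30000      20 0.002712250      2.566670

res$expression$fc_correlation
#> [1] 0.5551908
```

Reading the output: the two cohesin subunits' binding regions overlap
heavily (71% of Rad21 regions share bases with an SA region, as expected
for subunits of one complex); the per-bin Wilcoxon table shows the
planted Pds5-depletion domain extension reaching significance tens of
kilobases from the origin centers; and the two synthetic depletions'
fold-change profiles correlate near the planted 0.6 (attenuated by
estimation noise). All tables are also written as TSV/BED under
`pipeline_out/` with a parameter log.

The methods vignette (`vignettes/metaorigin-methods.Rmd`) documents the
models, every tunable parameter with its default and rationale, the
synthetic generator's contracts, and known limitations.

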