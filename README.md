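# chromdyn

Integrative analysis of histone-modification peak sets, chromatin states,
bivalent domains and stress-induced mark/expression dynamics — built for
plant epigenomes profiled with a small panel of marks (H3K4me3, H3K9ac,
H3K27me3, H3K9me2) under a control and a treatment condition, and tested
end to end on a synthetic genome with planted ground truth.

It is aimed at analysts who already have called peaks (BED/narrowPeak),
gene models (GFF3), FPKM tables and—optionally—reChIP peak sets and
untargeted metabolomics tables, and who want the downstream integration
reproducible and auditable from one configuration.

## What it computes

* **Six-way genome partition and peak annotation.** Every base is labelled
  promoter / 5' UTR / coding exon / 3' UTR / intron / intergenic, with
  overlaps resolved by fixed priority (promoter wins). Peaks are annotated
  at their summit-or-midpoint anchor; genes are *marked* when a peak
  overlaps the promoter (default 2 kb) or gene body by at least one bp.
  Multi-mark Venn counts, genome coverage, peak-length histograms and
  scaled TSS–TTS metagene profiles round out the descriptive layer.
* **Chromatin states.** Mark presence is binarized in 200-bp bins
  (peak overlap, or a Poisson upper-tail test on counts) and segmented
  with a multivariate Bernoulli-emission hidden Markov model fitted by
  Baum–Welch — per-bin emission likelihood
  `P(x | k) = prod_m E[k,m]^x_m (1-E[k,m])^(1-x_m)` — with seeded restarts,
  scaled forward–backward recursions, posterior or Viterbi decoding, a
  K = 8..20 scan with BIC, per-state feature/TE fold enrichments and
  mean expression, and a bin-level dynamics comparison across conditions.
* **Bivalent domains.** Merged intersections of an activating and a
  repressive mark's peaks (H3K9ac + H3K27me3), involved-peak fractions,
  covered genes, validation against reciprocal reChIP sets (a domain is
  supported when both directions overlap it) and a within-chromosome
  shuffle permutation null.
* **Expression integration.** FPKM strata (0 / ≤1 / ≤10 / >10), category
  composition of marked gene sets, an exact tie-corrected Wilcoxon
  rank-sum test (subset-sum dynamic program over midranks; normal
  approximation with tie correction for large groups), seeded random gene
  sets and expression breadth / tau.
* **CK→NaCl dynamics.** Per-gene mark gain/loss (marked-state transitions
  plus a bp-Jaccard stability floor with an occupancy log-ratio
  tie-break), DE thresholding at |log2FC| ≥ 1 and FDR < 0.05, the six
  mark/expression concordance classes, promoter enrichment rates of
  condition-specific peaks, mark–expression and mark–mark fold-change
  correlations, 1 − Jaccard variability scores, and the
  VIP > 1 / FC > 1.5 or < 0.667 / p < 0.05 metabolite filter.
* **Synthetic data.** `simulate_epigenome()` builds a 10-Mb, 2,000-gene,
  two-condition world with planted chromatin states, bivalent promoters,
  mark-coupled expression and concordant dynamics — every planted
  assignment is exactly re-derivable from the emitted files.

## Worked example

```r
library(chromdyn)

world <- simulate_epigenome(sim_config(seed = 1))
index <- build_feature_index(world$genes, world$layout, promoter_window = 2000)

assign_peaks(world$peaks$H3K9ac$CK, index) |> feature_distribution()
#> # A tibble: 6 × 3
#>   feature         n fraction
#>   <fct>       <dbl>    <dbl>
#> 1 promoter      552  0.312
#> 2 utr5          544  0.307
#> 3 coding_exon     5  0.00282
#> 4 utr3            0  0
#> 5 intron          0  0
#> 6 intergenic    670  0.378

biv <- call_bivalent(world$peaks$H3K9ac$CK, world$peaks$H3K27me3$CK,
                     world$layout, genes = world$genes)
biv
#> Bivalent domains (H3K9ac + H3K27me3): 647 domains, 402600 bp
#> involved peaks: 640/1771 (36.1%) H3K9ac, 639/1546 (41.3%) H3K27me3
#> genes covered: 464

validate_rechip(biv, world$rechip$ab, world$rechip$ba, world$layout)$frac_both
#> [1] 0.7573416
```

H3K9ac peaks anchor overwhelmingly around transcription starts (62% in
promoter + 5' UTR), about a third of them co-occur with H3K27me3, and
with the default 10%/15% simulated reChIP dropout ~76% of called domains
are supported by both reChIP directions (≈ 0.9 × 0.85, as planted). The
numbers above are exactly what the code prints under seed 1.

The whole analysis can also be driven from one YAML-serialisable config:

```r
run_pipeline("all", pipeline_config(seed = 1, outdir = "run1"))
```

which writes per-stage TSV tables and JSON summaries (each carrying the
config hash and seed) under `run1/`.

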