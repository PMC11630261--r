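---
title: "Chromatin states, bivalent domains and mark-expression dynamics with chromdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin states, bivalent domains and mark-expression dynamics with chromdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

## What the package models

chromdyn analyses how a small set of histone modifications — here the plant
quartet H3K4me3, H3K9ac (activating), H3K27me3 (repressive) and H3K9me2
(heterochromatic) — is laid out over a genome, how that layout couples to
gene expression, and how both change between a control and a stress
condition (labelled CK and NaCl throughout). The pipeline starts from called
peak intervals, gene models and FPKM tables, not from reads: alignment and
peak calling are upstream tools' business.

Four analytical layers build on each other:

1. **Feature partition and peak annotation.** Every base of the genome gets
   exactly one of six labels — promoter, 5' UTR, coding exon, 3' UTR,
   intron, intergenic — with conflicts resolved by a fixed priority
   (promoter highest, intergenic the implicit remainder). Peaks are then
   annotated by the label at a single anchor point (their summit when the
   peak caller recorded one, else the midpoint), genes are called *marked*
   when a peak shares at least one base with the promoter-plus-gene-body
   region, and metagene profiles average signal over a common
   TSS-to-TTS axis.
2. **Chromatin-state segmentation.** Mark presence is binarized in 200-bp
   bins and a hidden Markov model with independent Bernoulli emissions per
   mark (the ChromHMM model family) is fitted by Baum-Welch; decoded state
   labels summarise local mark combinations and are compared across
   conditions bin by bin.
3. **Bivalency.** Domains simultaneously carrying an activating and a
   repressive mark (the interesting pairing here is H3K9ac with H3K27me3)
   are called as merged intersections of the two peak sets, quantified as
   fractions of each mark's peaks, validated against reciprocal
   sequential-ChIP (reChIP) peak sets, and given a permutation-based
   significance.
4. **Dynamics and integration.** Per-gene mark gain/loss between conditions
   is crossed with differential expression into six concordance classes
   (activating mark up with expression up, repressive mark opposed),
   promoter enrichment of the changed peaks is reported, fold changes of
   marks and expression are correlated, and a VIP/fold-change/p filter
   classifies differential metabolites.

## Coordinate and boundary conventions

All intervals are 0-based half-open, BED style; GFF3 input is converted at
the file boundary. Half-openness decides every boundary case: a peak ending
exactly where a promoter starts shares zero bases and does not mark the
gene; the first base of an intron is intron.

Expression strata use the conventional FPKM cuts — non-expressed (= 0), low,
medium, high with breakpoints at 1 and 10. The published stratum
definitions are open intervals that leave FPKM = 1 and FPKM = 10
unassigned; we close each boundary onto the lower stratum (1 is low, 10 is
medium) so the map is total. The differential-expression rule includes its
fold-change boundary (`|log2FC| >= 1`) and is strict on FDR (`< 0.05`).
The metabolite filter defaults to VIP > 1.0, FC > 1.5 or FC < 0.667,
p < 0.05; a stricter FC >= 2 / FC <= 0.5 variant used in some protocols is
reachable through the function arguments.

## Tunable parameters that matter

* `promoter_window` (bp upstream of the TSS, default 2000). Plant ChIP
  studies rarely state their promoter definition; 2 kb is the common
  default in legumes and is exposed everywhere it is used. Feature
  fractions, marked-gene counts and promoter rates all depend on it, so
  reports should quote the window alongside.
* `bin_size` (default 200 bp): the chromatin-state resolution; also the
  unit of the state-dynamics "fraction of dynamic bins".
* `K` (state count): the scan utility fits K = 8..20 by default and
  reports log-likelihood and BIC (`-2 LL + p log n`, with
  `p = K-1 + K(K-1) + KM` free parameters). The BIC argmin is a default
  guide only — published chromatin-state maps typically choose K by
  interpretability, and the choice is deliberately left to the caller.
* `min_jaccard_stable` (default 0.25): a gene marked in both conditions is
  *stable* only if the basepair Jaccard of its condition-specific peak
  bases reaches this floor; below it the peaks were effectively replaced
  and the sign of the occupancy log-ratio (pseudocount 100 bp) decides
  gain versus loss. Pure presence/absence rules miss such replacements;
  this is the package's operational definition of gain/loss, since the
  source analyses never state one.
* `min_overlap_bp` (default 1): minimal shared bases for bivalent-domain
  intersections and reChIP support, the most permissive choice and the one
  matching plain `bedtools intersect` usage.

## Numerical choices

The HMM uses scaled forward-backward recursions (per-position scaling
constants), so likelihoods do not underflow even for millions of bins, and
a compiled core for speed. Emission probabilities are clamped to
`[1e-10, 1 - 1e-10]` only inside likelihood evaluation, so stored
parameters remain exact — with K = 1 the fitted emissions are exactly the
data column means. Baum-Welch restarts (default 3) draw initial parameters
from a seeded generator and keep the best likelihood; a fixed seed gives
bit-identical fits, and the log-likelihood is asserted non-decreasing at
every iteration. Posterior decoding takes the per-bin argmax of
forward-backward marginals (first state wins exact ties); Viterbi is
available when a single coherent path matters.

The exact Wilcoxon rank-sum mode computes the permutation null of the
rank-sum over midranks by a subset-sum dynamic program (doubled midranks
are integers even under ties) and reports the symmetric two-sided tail
`P(|W - EW| >= |w - EW|)`. Under ties this is well defined where the
classical exact test is not; for tie-free data it coincides with the
classical two-tail value. Exact mode engages automatically when both
groups have at most 20 observations; beyond that the tie-corrected normal
approximation is used.

Degenerate inputs are flagged rather than silently absorbed: empty peak
sets make feature distributions an error, an empty domain set makes reChIP
fractions `NA` with a warning, two empty peak sets get variability score 0
by convention with a warning, and all-tied rank comparisons return p = 1
with a warning.

## The synthetic world and what it does (not) show

`simulate_epigenome()` generates the study world the tests run on: by
default five 2-Mb chromosomes (10 Mb), 2,000 genes, the four marks under
two conditions, and five replicates per condition — sizes chosen so the
whole pipeline runs in minutes on one CPU while keeping per-criterion
statistics meaningful (the HMM-recovery checks use 5 x 10^4 bins).

Its key structural decision: gene *regions* (promoter plus body) are placed
disjoint along each chromosome, background chromatin (a state path sampled
from a configurable HMM truth, with heterochromatin biased onto simulated
transposable elements) is cleared under those regions, and planted
promoter/body peaks never extend beyond their own region. Consequently
every planted per-gene mark status is exactly re-derivable from the
emitted BED files — this is what makes "noise-free recovery equals truth"
checks well posed rather than approximately true. Planted bivalent
promoters force both H3K9ac and H3K27me3 over the same promoter bins, so
called bivalent domains coincide bin-for-bin with the planted truth.

Expression couples to marks twice: cross-sectionally (FPKM means are
multiplied by 3 per activating promoter mark and divided by 2 for
H3K27me3, on top of class-specific lognormal baselines), and dynamically —
a latent per-gene stress response drives background gain/loss
probabilities (positively for activating marks, negatively for H3K27me3)
and the expression shift, while 300 planted concordant genes — drawn from
the high-expression tier so their shifts stay measurable on the
pseudocounted fold-change scale — receive clean mark transitions with
coupled shifts of 2 to 3 log2 units. Planted
H3K9ac/H3K27me3 transitions also flip the partner mark in the opposite
direction 60% of the time, mimicking bivalent-domain resolution under
stress; this is what gives the mark-mark fold-change correlation its
negative sign. Metabolite tables are generated independently of the genes
— only the filter logic is under test, since any gene-metabolite link in
real data is correlative.

What the simulation does *not* emulate: read-level noise and peak-caller
artefacts, realistic repeat landscapes, isoform diversity, batch effects,
or any mechanistic gene-to-metabolite pathway. Passing recovery tests
therefore demonstrates the correctness of the implemented logic under the
model's assumptions, not performance on real pea data.

## Design choices where the ground was open

* **Anchor-point peak annotation** (summit else midpoint) rather than
  bp-share: gives each peak one category, matching how single-category
  peak percentages are usually reported; a max-overlap rule is available.
* **Marked = promoter or body overlap**: consistent with
  promoter-dominated mark placement; the same rule is reused for bivalent
  gene attribution and state mean-expression so gene sets are comparable
  across modules.
* **Bivalent domain extent = intersection** of the two marks' peaks (a
  bivalent base should carry both marks); union mode exists as an option.
* **reChIP support is reported at domain, basepair and gene level**, since
  a published overlap rate of this kind does not state its unit.
* **Promoter rates are reported per changed peak and per gene**, for the
  same reason.
* **Fold-change correlations** default to Pearson with Spearman as an
  option; both are computed by the pipeline stage since the choice is
  rarely stated in publications.
* **H3K9me2** enters state learning as a fourth mark column but is
  excluded from gene-level analyses, reflecting its heterochromatic role.

## Known limitations

Only the first mRNA of a gene is used; alternative isoforms are ignored.
The simple FPKM-based t-test DE is a stand-in appropriate for synthetic
lognormal data, not a replacement for count-based DE models on real data.
Poisson binarization assumes a single genome-wide background rate. The
permutation null shuffles one peak set uniformly within chromosomes, which
ignores accessibility structure real peaks have. Runtime of the default
world is dominated by the HMM fit and by per-gene interval operations; at
10 Mb / 2,000 genes a full run takes a few minutes on one CPU.

## A short tour

```{r tour, eval = FALSE}
world <- simulate_epigenome(sim_config(seed = 1))
index <- build_feature_index(world$genes, world$layout, promoter_window = 2000)

# where do H3K9ac peaks sit?
assign_peaks(world$peaks$H3K9ac$CK, index) |> feature_distribution()

# chromatin states
bins <- bin_genome(world$layout, 200)
bx <- binarize_marks(purrr::map(world$peaks, "CK"), bins)
fit <- fit_hmm(bx, K = 13, seed = 1)
glance(fit)
autoplot(fit)

# bivalency with reChIP support
biv <- call_bivalent(world$peaks$H3K9ac$CK, world$peaks$H3K27me3$CK,
                     world$layout, genes = world$genes)
validate_rechip(biv, world$rechip$ab, world$rechip$ba, world$layout)

# condition dynamics
de <- call_de(simple_de(world$expression))
dyn <- purrr::map(c(H3K4me3 = "H3K4me3", H3K9ac = "H3K9ac", H3K27me3 = "H3K27me3"),
                  ~ mark_gain_loss(world$peaks[[.x]]$CK, world$peaks[[.x]]$NaCl,
                                   world$genes, world$layout))
concordance(de, dyn)
fc_correlation(dyn, de)
```

Or run everything behind the single-config orchestrator:

```{r pipeline, eval = FALSE}
run_pipeline("all", pipeline_config(seed = 1, outdir = "run1"))
```
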