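# enhancerFlux

Does a metabolic perturbation leave lasting marks on the liver's
regulatory landscape, or does the landscape revert once the perturbation
is withdrawn? `enhancerFlux` is an R toolkit for answering that question
from sequencing count data in a four-group dietary-intervention design
(control, perturbed, and both arms after a reversal phase): it tests
differential transcription and enhancer activity, distinguishes ongoing
transcription from mRNA-turnover effects, links enhancers to genes, and
classifies every regulated region as reversible, persistent, or
weight-loss-specific — with the diagnostics needed to tell a genuinely
persistent mark from a lenient-threshold false positive.

It is aimed at analysts working with bulk RNA-seq (exon and intron
counts), H3K27Ac ChIP-seq quantified at accessible regions, and DNase
accessibility tags. Everything downstream of alignment is covered;
everything upstream (wet lab, read mapping) is out of scope.

## What it computes

**Negative-binomial differential testing.** For a two-group contrast on a
count matrix $K$, with median-of-ratios size factors $s_j$ and a
trend-shrunken method-of-moments dispersion $\alpha_i$
(var $= \mu + \alpha\mu^2$), the package tests
$H_0: \log_2(\mu_B/\mu_A) = 0$ with a Wald statistic whose standard error
comes from the NB delta method and whose reference distribution is a
moderated $t$ (df reflecting the dispersion shrinkage). FDR is
Benjamini–Hochberg.

**Nascent transcription.** Intron-mapping reads report ongoing synthesis.
A gene regulated at the exon level (FDR < 0.01, ≥ 1.5-fold) is classified
as regulated *by ongoing transcription* at threshold $t$ when its
intron-level FDR < $t$ with a sign-concordant fold change.

**Peak calling.** Sliding-window Poisson scan against a genome-wide
uniform background; windows pass at BH-FDR < 0.001 and ≥ 35 tags, then
merge.

**Enhancer–gene proximity enrichment.** Regions-per-gene within ±100 kb
of the TSSs of a test gene set, against a null of repeated draws
(4 rounds × 200 genes) from the remaining genes; two-tailed one-sample
t-test.

**Persistence classification.** Regions significant (p < 0.01) in the
perturbation contrast are `putative_persistent` if also significant, with
concordant sign, in the reversal contrast — otherwise `reversible`;
reversal-only regions are `weightloss_specific`. Per-class FDR
distributions expose false-positive persistents.

**Motifs.** PWM best-hit log2-odds scanning on both strands,
hypergeometric occurrence enrichment, and rank-sum motif-strength
comparisons.

**Synthetic studies.** `simulate_study()` generates a complete,
seed-reproducible four-group study with planted ground truth (effect
classes, enhancer–gene coupling, planted motifs) used to validate every
claim above.

## Worked example

```r
library(enhancerFlux)

b <- simulate_study(sim_config(seed = 42))
b
#> sim_study (seed 42): 3000 genes, 8000 regions; 300 regulated genes, 640 regulated regions

# Differential acetylation, perturbation contrast
res <- diff_test(b$counts_k27ac, contrast("Chow", "HFD"))
res
#> diff_result: HFD vs Chow (reference)
#> 8000 features tested; 485 at FDR < 0.05, 552 at FDR < 0.1

sets <- threshold_results(res, fdr_max = 0.1)
length(sets$up); length(sets$down)
#> [1] 363
#> [1] 189

# Are induced regions enriched near up-regulated genes?
ind <- b$regions[b$regions$id %in% sets$up, ]
up  <- threshold_results(diff_test(b$counts_exon, contrast("Chow", "HFD")),
                         fdr_max = 0.05)$up
proximity_enrichment(ind, b$genes, up, seed = 1)
#> proximity enrichment [regions ~ test_set, +/-100 kb]: observed 3.174
#> pairs/gene, null mean 1.370, ratio 2.32, p = 4.44e-05

# Does the acetylation change persist after the reversal phase?
rev <- diff_test(b$counts_k27ac, contrast("ChowChow", "HFDChow"))
pc  <- classify_persistence(res, rev)
table(pc$calls$class)
#> putative_persistent          reversible         unregulated weightloss_specific
#>                   2                 581                7382                  35
pc$venn_fdr
#> dio_only rev_only   shared
#>      552        0        0
```

Reading: 552 regions change acetylation in the perturbation contrast
(FDR < 0.1) and none of them remains significant after the reversal phase
— the planted study is fully reversible, and the two regions surviving
the lenient p < 0.01 overlap screen are the expected false positives
(their reversal-contrast FDR is high; see `persistence_diagnostics()`).
The induced regions sit 2.3× closer to up-regulated genes than random
gene sets predict, because the generator coupled 80% of them to within
100 kb of a regulated TSS.

`run_full_analysis(run_config(...))` chains all of the above (including
the DNase invariance check, motif analyses, and PCA/correlation
concordance summaries) and writes TSV/BED tables plus a `summary.json`.

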