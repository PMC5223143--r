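---
title: "Methods: differential enhancer activity, nascent transcription and reversal analysis"
author: "enhancerFlux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enhancer activity, nascent transcription and reversal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerFlux)
```

# The scientific question

A dietary perturbation such as a high-fat diet (HFD) reprograms hepatic
transcription, and much of that reprogramming runs through the activity of
pre-established enhancers — distal regulatory regions that are already
accessible and gain or lose histone H3K27 acetylation (H3K27Ac) rather
than being created de novo. The question this package is built around is
whether such changes *persist* after the perturbation is withdrawn and
body weight normalizes, or whether the regulatory landscape reverts.

The design it analyzes is a four-group study: `Chow` and `HFD` animals
profiled at the end of the diet phase, and `ChowChow` / `HFDChow` animals
profiled after a subsequent reversal phase on control diet. Assays are
exon/intron RNA-seq counts (three replicates per group), H3K27Ac ChIP-seq
counts at accessible regions (three replicates), and DNase accessibility
counts (two replicates). The package implements every analytical step from
count matrices and tag positions onward; alignment and wet-lab processing
are out of scope.

# Negative-binomial differential testing

Counts for feature $i$ in sample $j$ are modeled as negative binomial with
mean $\mu_{ij} = s_j q_{ij}$ and variance $\mu + \alpha\mu^2$, where $s_j$
is a per-sample size factor and $\alpha$ the dispersion.

**Size factors** are median-of-ratios: $s_j = \mathrm{median}_i\,
k_{ij}/(\prod_{j'} k_{ij'})^{1/n}$ over features with all-positive counts.
Note that size factors are defined only up to an overall scale; rescaling
one sample rescales the whole vector's reference, so only relative factors
are meaningful.

**Dispersion** is estimated per feature by method of moments on normalized
counts pooled within groups, after subtracting the depth-rescaled Poisson
component:
$\hat\alpha_i = \max\{0, (v_i - \bar\mu_i \overline{1/s})/\bar\mu_i^2\}$.
Because $\hat\alpha_i$ is extremely noisy with 2–3 replicates, it is shrunk
halfway toward a mean–dispersion trend $a_0 + a_1/\mu$ fitted by least
squares over features with $\mu > 5$. Constant features (zero pooled
variance) and absent features are floored at $10^{-8}$.

**The Wald test** compares group means of normalized counts with
pseudocount 0.5 (avoiding infinite fold changes at zero). The standard
error of $\log_2$FC comes from the NB delta method:
$\mathrm{var}(\log_2 \bar y_g) = \big(\bar\mu_g \sum_{j \in g} 1/s_j +
n_g \alpha \bar\mu_g^2\big) / (n_g^2 \bar\mu_g^2 \ln^2 2)$.
The statistic $\log_2\mathrm{FC}/\mathrm{se}$ is referred to a
**moderated t** distribution rather than a standard normal. The reasoning:
shrinking the dispersion halfway toward the trend — which is estimated
from thousands of features and is effectively exact — multiplies the
sampling variance of the plugged-in dispersion by the square of the shrink
weight, so the effective degrees of freedom are
$d_\mathrm{eff} = d/w^2$ with $d$ the residual df of the contrast
($n_a + n_b - 2$) and $w = 0.5$. With a normal reference the test was
roughly two-fold anti-conservative at $p < 0.01$ and the realized FDR at a
nominal 0.1 cutoff was ~0.20 in null-calibration simulations; with the
moderated t both are restored to nominal (~0.01 and ~0.10). The same
simulations are frozen into the test suite.

**Multiple testing** is Benjamini–Hochberg, implemented explicitly (the
running-minimum form over the sorted p-values) and property-tested against
both a literal double-loop oracle and `p.adjust(method = "BH")`. Features
with zero counts in every sample are reported untested (`NA`) and excluded
from the correction.

Only two-group contrasts are supported — the study's comparisons are all
pairwise (HFD vs Chow; HFD-chow vs Chow-chow) — so a full GLM/IRLS fit
would add machinery without adding power. Two replicates per group are
accepted, accommodating the accessibility assay. There is no independent
filtering and no outlier handling; these are deliberate simplifications
documented here rather than silent defaults.

# Nascent transcription from intron reads

Introns are spliced out co-transcriptionally, so intron-mapping reads
report ongoing transcription while exon reads report steady-state mRNA.
`partition_tags()` assigns a tag position to a gene's exon tally if it
falls in any exon and to the intron tally if it falls in any intron, with
genes treated independently (a tag may count for two overlapping genes).
Gene models are single-isoform: multi-isoform ambiguity resolution is a
non-goal, and the simulator never generates overlapping isoforms.

`classify_ongoing()` takes exon-level and intron-level differential
results over the same genes. A gene is *exon-regulated* at FDR < 0.01 and
fold change ≥ 1.5. For each threshold $t$ in the intron-FDR grid (default
{0.01, 0.05, 0.1}), the gene is *regulated by ongoing transcription* when
its intronic FDR < $t$ **and** the intronic fold change has the same sign
as the exonic one. The sign-concordance requirement prevents a gene whose
nascent synthesis moves opposite to its mRNA (a turnover-dominated gene)
from being called transcriptionally regulated. Fractions are reported
separately for up- and down-regulated genes.

# Peak calling on accessibility tags

`call_peaks()` is a sliding-window Poisson scan: windows of 200 bp advance
by half a window; each window's tag count is tested against a single
genome-wide uniform background rate (total tags divided by the summed
maximal tag coordinate per chromosome). Windows passing both BH-FDR
< 0.001 and a tag-density floor of 35 are merged into maximal regions
scored by their best window. The global-background simplification (no
local lambda, no control track) is adequate for the synthetic fixtures the
caller is validated on and is stated as such; replicate-concordant regions
are then obtained with `concordant_regions()`, which keeps regions of one
replicate overlapping the other and widens them to the union span.

# Enhancer–gene proximity enrichment

To link acetylation changes to transcription, `proximity_enrichment()`
counts qualifying region–gene pairs — a region qualifies for a gene when
any part of it lies within ±100 kb of the gene's TSS — and normalizes by
the number of genes in the test set. The null distribution is the same
statistic over rounds (default 4) of 200 genes drawn uniformly without
replacement from the gene universe *excluding the test set* (drawing from
the full universe would contaminate the null with true targets). The
p-value is a two-tailed one-sample t-test of the round values against the
observed value. With four rounds this test is deliberately low-powered;
that is a property of the emulated protocol, documented rather than
"fixed". The enrichment metric (pairs per gene) is symmetric and easy to
test; the fraction of test genes with at least one qualifying region is
emitted alongside as `frac_genes_with_hit`.

# Persistence classification and its diagnostics

`classify_persistence()` crosses the perturbation contrast (DIO: HFD vs
Chow) with the reversal contrast (HFD-chow vs Chow-chow) over the same
region universe, using the lenient screen $p < 0.01$:

* **putative_persistent** — significant in both contrasts with concordant
  fold-change sign;
* **reversible** — significant in the DIO contrast only (or with a
  discordant reversal direction);
* **weightloss_specific** — significant in the reversal contrast only;
* **unregulated** — neither.

The partition is exhaustive and mutually exclusive. Venn counts are
reported both at the p-screen and at FDR < 0.1. Under the null hypothesis
that no region is truly persistent, the expected number of
putative-persistent calls is Binomial$(|{\rm DIO\ set}|,\,
p_{\rm cut} \cdot \Pr[\text{sign agreement}])$ with sign agreement 0.5 —
the false-overlap expectation the test suite checks across 20 simulated
studies. `persistence_diagnostics()` summarizes, per class, the per-group
z-scored count distributions and the empirical FDR distributions of both
contrasts: false-positive persistents carry weak reversal-contrast
evidence (high `fdr_rev`), planted true persistents carry strong evidence.
This is the package's version of the false-positive audit that
distinguishes a genuinely persistent regulatory mark from a lenient
threshold artifact.

# Motif analyses

PWMs are 4×L base-probability matrices (JASPAR-style PFM text is read,
counts normalized per column); probabilities are floored at $10^{-3}$
before log-odds to avoid $-\infty$, and `N` bases contribute 0 (background
score). "Motif strength" of a sequence is defined as its best-hit
additive log2-odds over all offsets and both strands; ties prefer the
forward strand and the smallest position. Occurrence enrichment between
two sequence sets is a hypergeometric upper-tail test on the counts of
sequences whose best score clears a threshold — a deliberate
simplification of ZOOPS-style models with GC-matched backgrounds, which
synthetic sequences with controlled composition do not need. Strength
comparisons across sets use two-sided Wilcoxon rank-sum tests, since
best-hit scores are distinctly non-normal.

# The synthetic-data generator

`simulate_study()` is first-class, tested code: it defines the study
conditions under which every downstream claim is validated.

* **Layout.** One synthetic chromosome (default 50 Mb). Gene TSS anchors
  and region starts sit on jittered regular grids (jitter ±¼ pitch), which
  guarantees spacing of at least half the pitch — about 8.3 kb for 3,000
  genes — while remaining feasible for any gene count, and spreads
  features uniformly at large scale. Genes have 2–4 exons (150–500 bp)
  separated by 400–2,000 bp introns; regions are 500 bp.
* **Counts.** NB with mean $\mathrm{depth}\cdot s_j q_i 2^{\rm effect}$,
  dispersion 0.05, size factors log-uniform on [0.7, 1.4], relative
  abundances log-normal(0, 1) normalized to sum to one. Defaults: RNA and
  ChIP depth $5\times10^5$, DNase depth $3\times10^5$ (mean ~37 tags per
  region, matching the density regime of the peak-calling threshold).
  Intronic abundance is 0.5× exonic — introns are longer but their RNA is
  short-lived, and this puts median intronic means near 50–100 where the
  classifier's operating range is interesting rather than trivial.
* **Effect classes.** Genes: `up/down_transcriptional` (exon and intron
  shift), `up/down_turnover` (exon only), `persistent_up` (shift in HFD
  *and* HFD-chow). Regions: `induced`, `reduced` (HFD only),
  `persistent` (both), `weightloss_only` (HFD-chow only). Default
  proportions are 0.03/0.03/0.02/0.02 for gene classes and 0.05/0.03 for
  induced/reduced, with *no* persistent or weight-loss-only features: the
  default study is fully reversible, encoding the central finding the
  pipeline is designed to test. Accessibility counts carry no class effect
  by default for the same reason (a `dnase_effects` switch exists for
  power studies). The planted effect size is $|\log_2\mathrm{FC}| = 1.5$.
* **Coupling.** 80% of induced/reduced regions are relocated to within
  100 kb of a same-direction regulated gene's TSS and recorded as linked
  in the ground truth; the induced-vs-up-gene enrichment ratio this
  produces (~2.5 at defaults) depends on the incidental pair rate set by
  gene density, which is why the class proportions above were chosen
  jointly with the genome length.
* **Motifs.** A built-in 13-bp DR1-style repeat (consensus
  `AGGTCAAAGGTCA`, consensus-base probability 0.97) is planted centered in
  70% of induced-region sequences; all other sequence is i.i.d. uniform
  ACGT.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: multi-isoform genes, non-uniform genomic
sequence composition (GC bias, repeats), batch effects, local background
structure in tag density, replicate-correlated library artifacts, and any
real motif catalog. Claims validated here are about the statistical
machinery under the stated model, not about biological rediscovery.

# Numerical and design choices

* Coordinates are 0-based half-open throughout (BED convention); tags are
  single-bp 5′ positions; strand is carried but ignored by counting.
* `log2(normalized + 1)` is the transform before PCA and Pearson
  correlation; PCA component signs are fixed by making the
  largest-magnitude loading positive, so scores are deterministic.
* Row z-scores of constant rows are defined as zero and flagged rather
  than `NaN`.
* The proximity test's random draws are governed by an explicit seed and
  restore the caller's RNG state; the full pipeline is byte-reproducible
  given its seeds.
* All thresholds default to the analysis's canonical values: mRNA FDR
  0.05; ongoing-transcription exon FDR 0.01 with 1.5-fold change; region
  screen p 0.01 and FDR 0.1; peak FDR 0.001 with density 35; proximity
  window 100 kb with 4 rounds of 200 genes.

# Problem sizes used in validation

The test suite and acceptance script run the generator at its default
size (3,000 genes, 8,000 regions, 20 libraries) — a scale chosen so that
every distributional check (null calibration on 5,000 features,
20-study false-overlap audits, 100-instance oracle sweeps) completes in a
couple of minutes on a single core while keeping Monte-Carlo error well
inside the asserted bands.

# Known limitations

Two-group contrasts only; no shrunken fold-change estimator; no
independent filtering, so very-low-count features cost a little power; the
peak caller's global background will over-call in genomes with strong
regional tag-density trends; the proximity t-test with four rounds has
wide confidence intervals by construction; and single-isoform gene models
mean intron signal from retained or alternative introns is outside the
model.
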