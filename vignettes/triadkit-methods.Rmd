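---
title: "triadkit methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{triadkit methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadkit)
```

This vignette documents the statistical models, algorithmic choices and
default parameters behind each module of triadkit, and states explicitly
what the synthetic generators emulate and what they do not. The running
context is a CRISPR editing study of a homoeologous grain-shape gene triad
(*TaGW7*) in allohexaploid wheat: three near-identical gene copies on the
A, B and D subgenomes, edited plants segregating mutations in the B and D
copies, an expression compendium for network analysis, and resequencing
panels of wild and domesticated relatives for evolutionary analysis.

## 1. Amplicon genotyping

### Homoeolog assignment

Reads from a pooled amplicon library are assigned to a subgenome by
*diagnostic bases*: positions where the three homoeologous amplicons differ
from one another. `assign_homoeolog()` inspects the diagnostic positions of
each reference and assigns a read to the unique genome whose diagnostic
bases all match (at least `min_diagnostics` of them readable). Reads
matching no genome, or more than one, are reported with reasons
(`no_match`, `conflict`, `ambiguous`, `too_short`) rather than silently
dropped, because the discard rate itself is a quality signal for the
amplicon design.

This positional approach assumes reads are co-registered with the
reference (amplicon sequencing, not shotgun). Diagnostic positions in the
simulator are placed upstream of the cut-site window so that target-site
indels cannot shift them.

### Indel calling

`call_indel_allele()` aligns each read globally (Needleman–Wunsch, via
`Biostrings::pairwiseAlignment`) with match +2, mismatch −2, gap open −6,
gap extend −1. Global alignment is appropriate because amplicon reads span
the full reference; the mild gap-open penalty relative to mismatch keeps a
10-bp deletion cheaper than 10 mismatches while discouraging spurious
1-bp gaps. Identical reads are deduplicated before alignment, which makes
the caller's cost proportional to the number of *distinct* reads — in deep
amplicon data most reads are exact duplicates of a few alleles.

Each indel is **left-normalized** (shifted to its leftmost equivalent
position, the VCF convention) so that the same biological allele aligned
differently still collapses to one row in the allele table. Only events
whose normalized start lies within ±20 bp of the Cas9 cut site are counted
as editing outcomes (`window = 20`); Cas9 blunt cuts 3 bp upstream of the
PAM, and real repair outcomes concentrate tightly around that point, so the
window excludes distal sequencing artifacts without touching genuine
alleles. Reads under 80% alignment identity are excluded as chimeric or
foreign (`min_identity = 80`).

An allele is a (net indel length, inserted sequence, normalized start)
triple; `frameshift` is `net %% 3 != 0`. Editing efficiency is the percent
of kept reads carrying any indel.

### Zygosity

With one gene copy per subgenome in a diploid-behaving hexaploid, the
mutant read fraction *f* of a subgenome is expected near 0, 0.5 or 1.
`zygosity_from_fraction()` calls WT for *f* < 0.10, heterozygous for
0.30 ≤ *f* ≤ 0.70, homozygous for *f* > 0.90, and *ambiguous* in the gaps.
The deliberately unclassified bands (0.10–0.30 and 0.70–0.90) flag samples
with allele dropout, chimerism or cross-contamination instead of forcing a
call. At 200 reads per homoeolog the binomial noise around 0.5 has
standard deviation ≈ 0.035, so the ambiguous bands are > 5 SD from the
expected fractions. Genotype codes use uppercase for wild type and
lowercase for mutant (`AAbbdd`; heterozygotes written `Bb`), and
`functional_copies` counts the remaining uppercase (non-mutated) alleles,
0–6.

## 2. Phenotype statistics

Spike-level measurements (3 spikes per plant) are averaged per plant first
(`plant_trait_means()`); the plant, not the spike, is the experimental
unit. Group effects are reported as percent change against the *segregated
wild type* (`AABBDD` plants from the same family), which controls for
transformation and background effects:

$$\Delta\% = 100 \cdot \frac{\bar{x}_g - \bar{x}_{ref}}{\bar{x}_{ref}},$$

rounded to 2 decimals. Group comparisons use the pooled-variance two-tailed
Student's *t* (the classical choice for small balanced family data), with
significance stars at 0.05/0.01/0.001/0.0001. Multi-group comparisons use
one-way ANOVA with Tukey HSD (`stats::aov` + `stats::TukeyHSD`). Dosage
trends summarize traits by functional copy number (0–6) and report the
trend direction as the sign of the Spearman correlation between group means
and copy count — monotonicity, not linearity, is the claim being made.
qPCR expression uses the standard 2^−ΔΔCt model.

The bundled `grain_trait_reference()` table carries the published group
means, SEs and group sizes of the two edited families, so the trait-table
percent-change cells can be recomputed from group summaries alone;
per-plant raw data are not available and are not fabricated.

## 3. Co-expression networks

Expression matrices (TPM, genes × samples) are quantile-normalized
(`limma::normalizeQuantiles`, ties averaged) and transformed with
log2(x + 1). Quantile normalization forces every sample onto a common
distribution — appropriate for a compendium pooling many tissues and runs —
and the pseudo-count keeps zeros finite.

The **global network** is built over the top `k` most variable genes
(default 10,000, the study's working set) and keeps only extreme Pearson
correlations: PCC < −0.90 or PCC > 0.98. The asymmetric thresholds reflect
that strong positive co-expression is abundant (so the positive cutoff must
be severe) while strong negative correlation is rare and informative at
−0.90.

The **local network** around the focal triad ranks, for each focal
homoeolog separately, all other genes by *signed* PCC and keeps genes in
the top 1% of that ranking that also exceed |PCC| > 0.60; the member set is
the union over the three homoeologs. Ranking is per-homoeolog because the
three copies have correlated but not identical profiles; the conjunction
with the absolute threshold prevents the top-1% rule from admitting noise
genes when no strong partners exist; boundary ties at the quantile cut are
all kept. Signed ranking (the default) targets co-activated partners;
`rank_abs = TRUE` switches to magnitude ranking when repressors are of
interest.

## 4. GO enrichment

Each term is tested with a two-tailed Fisher exact test on the 2×2 table
(in set & annotated, in set & not, outside set & annotated, outside set &
not). Two-sided *p* sums, via the probability-mass rule, all
hypergeometric tables whose probability does not exceed the observed
table's probability times (1 + 10⁻⁷); the relative tolerance absorbs
floating-point noise in probability ties, matching the convention of
`stats::fisher.test`. Multiplicity is handled with Benjamini–Hochberg
(`stats::p.adjust`), and fold change is the ratio of the term's frequency
in the set to its frequency in the background. No GO-graph propagation is
performed: annotations are taken as given, so ancestors must be
pre-propagated by the annotation provider if desired.

## 5. Population genetics

Per-site diversity uses the unbiased estimator
$$\pi = 2 p (1-p) \cdot \frac{n}{n-1}$$
with *n* the number of called allele copies at the site; accessions are
effectively inbred, so genotypes are coded 0/2 with heterozygous calls
treated as unresolved for haplotyping. Differentiation uses Hudson's
$$F_{ST} = 1 - H_w / H_b,$$
computed in windows as a **ratio of averages** (sum of within-population
heterozygosities over sum of between-population heterozygosities), which is
the recommended aggregation — averaging per-site ratios overweights
low-information sites. Windows are 2 Mb stepping 400 kb, matching the scale
of wheat domestication sweeps against the sparse SNP density of exome
capture; a site enters a window only if both populations have ≥ 2 called
copies there.

Genic haplotypes are the exact multi-SNP genotype vectors across the gene
region; accessions with any missing or heterozygous genic call are
excluded, and haplotypes are labeled H1, H2, … by descending pooled
frequency. Between-population carrier counts of a haplotype are compared
with the same two-tailed Fisher test as §4.

## 6. Sequence comparison

Nucleotide distances use Kimura's 2-parameter model,
$$d = -\tfrac{1}{2}\ln\!\big((1-2P-Q)\sqrt{1-2Q}\,\big),$$
with *P*, *Q* the transition and transversion proportions over pairwise
gap-free columns (pairwise deletion). The implementation is cross-checked
in the test suite against `ape::dist.dna(model = "K80")`. Saturated pairs
(non-positive log arguments) yield `NA` rather than an arbitrary cap.

Trees are built with neighbor joining (`ape::nj`); NJ is consistent on
additive matrices, and the suite verifies exact topology recovery on
random additive trees. Negative branch lengths, an artifact of NJ on noisy
data, are clamped to zero with the length transferred to the sister edge,
preserving path lengths. Bootstrap support (`ape::boot.phylo`) resamples
alignment columns after alignment-wide removal of gap columns
(complete deletion), with a seeded RNG for reproducibility; supports are
integer percentages of `n_reps`. Amino-acid divergence is the count and
percentage of differing gap-free columns.

## 7. Synthetic generators

`sim_config()` collects every generator tunable; the defaults *are* the
study conditions and are not adjusted per analysis:

* **Amplicons** (`sim_amplicon_reads`): 200 reads per homoeolog, programmed
  allele mixes (default: −10 bp segregating at 0.5 in B, −2 bp at 0.5 in D,
  A wild type), per-base substitution error 0.001. Emulates allele
  sampling and substitution noise; does **not** emulate PCR chimeras,
  indel-type sequencing errors or coverage imbalance between homoeologs.
* **Phenotypes** (`sim_phenotypes`): additive dosage model — trait =
  baseline × (1 + Σ_g effect_g · mutant-alleles_g / 2) plus plant-level and
  spike-level Gaussian noise; negative draws are resampled. Baselines
  (width 3.67 mm, length 6.27 mm, area 16.67 mm², TGW 42.72 g), per-genome
  effects (B: +1.91/+0.32/+1.78%; D: +2.18/−2.07/+2.90% for
  width/length/TGW) and noise SDs are set to the published group summaries;
  the area effect is the sum of the width and length effects. No
  dominance, epistasis or genotype-by-environment terms.
* **Expression** (`sim_expression`): 10,000 genes × 209 samples; a planted
  module of 50 genes (the triad included) shares one latent factor with
  loading 1.5 and residual SD 0.4 on log2 scale; background genes are
  independent; TPM = 2^x. `n_genes = 10000` matches the study's
  top-variable-gene working set and keeps the local network's top-1% rule
  (100 genes) comfortably larger than the planted module — with far fewer
  genes the top-1% rule is structurally unable to return a 50-gene module.
  One module only; no hub structure or batch effects.
* **Popgen** (`sim_popgen`): 4,000 SNPs on a 50-Mb chromosome; 34 wild and
  40 domesticated inbred accessions; wild allele frequencies
  Uniform(0.05, 0.95); inside the planted sweep (20–24 Mb) domesticated
  frequencies are pushed fraction 0.9 of the way to fixation of the wild
  major allele; the genic region (21.5–21.6 Mb) is overwritten with
  discrete haplotypes at programmed population frequencies; 2% missing
  calls. Independent sites — no linkage disequilibrium, recombination maps
  or demography; the sweep is a frequency shift, not a coalescent sweep.

Every generator returns a truth table alongside the data, and all
randomness flows from `cfg$seed` (with fixed offsets per data type), so
identical configurations are byte-identical.

## 8. Problem sizes and verification

The test suite verifies each module along two independent routes: exact
oracles (enumeration Fisher over all small tables, closed-form K2P and
3-taxon NJ branch lengths, hand-computed quantile-normalization targets,
per-site window statistics recomputed naively) and recovery of planted
truth at study scale (1,000 genotyped plants at error rate 0; 200 phenotype
replicates at n = 50 per group; module recall/precision on the
10,000 × 209 matrix; sweep localization over 50 seeds; topology recovery
over 1,000 random additive trees). `scripts/acceptance.R` re-runs a
representative subset against the installed package and writes the
quantities to JSON.

## Limitations

Beyond the generator simplifications above: the amplicon caller assumes one
cut site per amplicon and does not model large structural outcomes or
homology-directed repair; zygosity calling assumes balanced amplification
of the two alleles; the enrichment module tests terms independently
(no term–term correlation handling); F_ST windows use physical, not
genetic, distance; and bootstrap support is interpretable only as
column-resampling stability, not as a posterior probability.
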