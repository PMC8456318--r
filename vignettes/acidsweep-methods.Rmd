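---
title: "acidsweep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{acidsweep: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidsweep)
```

## The scientific question

Two pear varieties differ sharply in fruit acidity: `AMT` (*Pyrus
sinkiangensis* cv. Amute) accumulates far more malic and citric acid than
`DSHS` (*P. bretschneideri* cv. Dangshansuli). `acidsweep` implements the
inference chain that connects this phenotype to candidate "domestication
genes": organic-acid statistics, FPKM quantification and
negative-binomial differential expression across a 2-variety x 4-stage x
3-replicate design, weighted co-expression modules linked to acid traits,
mutual-rank transcription-factor networks, windowed selection scans
(Weir-Cockerham F_ST and a cross-population composite-likelihood score) on
population genotypes, and finally the intersection of all layers. A
synthetic-data module generates every input with the statistical structure
the analysis assumes, so the whole chain is testable offline.

## Differential expression

FPKM is computed as fragments / (mapped fragments in millions x merged
exonic length in kb); the merged-exon length (not the gene span) is used
because fragments are counted against exons. DEGs require all three of
`max group-mean FPKM > 0.1`, `BH-adjusted p < 0.05` and `|log2FC| > 2`;
the fold-change orientation is AMT over DSHS so "+" always means "up in
the high-acid variety".

The Wald test is implemented rather than delegated: median-of-ratios size
factors (normalised to geometric mean 1), a per-gene method-of-moments
dispersion from within-group residuals of the normalised counts, a
pseudocount of 0.5 (on the normalised scale) in the fold change, a
delta-method standard error under NB variance mu + alpha mu^2, and normal
two-sided p-values. Two numerical choices matter at n = 3 + 3:

* the per-gene dispersion is moderated toward an across-gene central value
  with weight df / (df + 8); raw moment estimates at 4 residual df are
  unusable on their own (half of them hit the lower bound by chance);
* the central value is a clamped **mean** of the per-gene estimates, not a
  median. Per-gene moment estimates are right-skewed, so their median
  under-estimates the dispersion by roughly the chi-square-median ratio
  (~0.83 at 4 df), which inflates the type-I error from ~5.5% to ~7.3%.

With these choices the measured type-I error at nominal 0.05 is 5.3-5.7%
(2000-gene null, five seeds) and power for |log2FC| = 3 at alpha = 0.1 is
essentially 1. Exact agreement with DESeq2 is *not* a contract; the
calibration and power contracts replace it.

## Co-expression modules

The network is unsigned at both stages: adjacency `|cor|^beta` with beta =
14 on log2(FPKM + 1), and the standard unsigned topological overlap. Genes
enter the network when their mean FPKM over retained samples exceeds 5;
samples flagged by replicate QC (mean within-condition correlation of
log2(FPKM + 1) below 0.8) are excluded first.

Module detection cuts an average-linkage tree on 1 - TOM at the merge
height (scanned up to its 0.99 quantile) yielding the most clusters of at
least `min_module_size` = 40 genes. Two refinements address known failure
modes of a single global cut:

* clusters at least twice the minimum size are recursively re-clustered on
  their own subtree. Without this, two or three genuine modules glued into
  one cluster at the best global height stay glued (observed in roughly 1
  in 20 simulated data sets); modules that the recursion splits too far are
  re-joined by eigengene merging (cut height 0.3), so over-splitting is
  self-healing while under-splitting is not;
* after rescuing unassigned genes (eigengene correlation > 0.3), a
  module-membership pass moves any gene whose correlation with another
  module's eigengene exceeds its own module's by more than 0.2. The margin
  is essential: an unmargined argmax pass lets eigengene drift churn whole
  modules, while the margined pass only relocates genes that are clearly
  misplaced (typically genes with strong condition-specific effects that
  the height cut attached to a covariate-driven cluster).

The dynamic-hybrid algorithm of the reference WGCNA implementation is not
reproduced label-for-label; the contract is planted-structure recovery
(adjusted Rand index >= 0.9 on three-block fixtures, and ~0.99 on the full
simulated world).

Eigengenes are first singular vectors of the per-gene z-scored module
expression, signed so the mean member correlation is non-negative. Key
modules per trait maximise |module-trait correlation| (ties: smaller p,
then larger module).

## Mutual-rank networks

For each variety separately (11-12 samples after QC), Pearson correlations
on log2(FPKM + 1) are ranked per gene (self excluded, average ranks on
ties) and MR = sqrt(rank_AB x rank_BA). Edges between TFs and candidate
genes survive only with PCC >= 0.3 **and** both directed ranks <= 5; the
filter sentence in the source methods is grammatically ambiguous, and
failing either condition marks a weak edge, so exclusion on either is
implemented (both thresholds configurable). Ranks depend on the gene
universe; the universe is the expressed-gene set of that variety. TF-TF
edges are excluded by default (flag `include_tf_tf`).

## Selection scans

SNPs pass GATK-style hard filters (QD >= 2, FS <= 60, MQ >= 40, QUAL >=
30, MQRankSum >= -12.5, ReadPosRankSum >= -8; strict inequalities drop,
missing annotations pass). Per-SNP Weir-Cockerham (1984) variance
components a, b, c are combined per 10-kb window (1-kb step, windows
starting at 1) as ratio-of-sums ("weighted" convention); windows with
fewer than 3 usable SNPs are undefined and excluded from quantiles.
Negative per-SNP components are retained in the sums.

The XP-CLR-style score is a documented surrogate (the original's internals
are not reproduced): object-population frequencies are modelled as
truncated-normal around mu(c) = (1 - c) p_ref + c 1[p_ref >= 0.5] with
variance omega p_ref (1 - p_ref), omega estimated genome-wide by the
median of (p_obj - p_ref)^2 / (p_ref (1 - p_ref)), and the window score is
2 (max over c in {0, 0.05, ..., 0.95} - loglik at c = 0), floored at 0.
Higher score = stronger frequency differentiation toward fixation, which
is the method's contract. An externally computed XP-CLR window table can
be dropped in instead (any `genome_scan`-shaped table works).

Sweep regions take the top 5% (F_ST) and top 1% (XP-CLR) of defined
windows by nearest-rank quantile, merging adjacent or overlapping
windows. Candidate "domestication genes" must overlap **both** region
sets by at least 1 bp; the universe is the candidate genes plus TF nodes
of both networks (the original study's second hit was a network TF).

LD decay is the distance-binned mean r^2 of genotype dosages; the
half-decay distance is measured against the long-range baseline (mean of
the last 10% of bins) because the finite-sample r^2 floor of ~1/(n-1)
would otherwise make shallow curves look like infinite-range LD.

## The synthetic world

`simulation_spec()` states the world once; all defaults are either from
the study design (24 samples, 2 x 4 x 3; FPKM filter 5; WGCNA constants;
window geometry; top fractions) or chosen once as realistic and recorded
here:

* **Counts.** 2000 genes, five modules (120/100/80/60/40), latent
  intra-module correlation 0.8 on the log2 scale, NB dispersion 0.1,
  library sizes log-uniform on 8-12 M. 100 variety-DE genes at |log2FC| =
  3 (half up), 100 stage-trend genes. The acid-linked module's factor
  carries a +1 (log2) offset in AMT: its genes run higher in the high-acid
  variety without individually passing the DEG fold-change bar, which is
  how the acid module behaved in the study.
* **Planted positives.** One "TCA" and one "transporter" gene sit inside
  the sweep interval, belong to the acid module, and are up-regulated in
  AMT *at stage S3 only* — matching the behaviour of the study's two
  domestication genes. A constant all-stage shift was rejected: it makes
  the positives co-cluster with the variety-DE background genes instead of
  their module.
* **Traits.** MA = 4 + f + N(0, 0.3), CA = 1.5 + 0.4 f + N(0, 0.15) (f =
  acid-module factor, mg/g FW), OA independent noise — MA/CA linked, OA
  not, as the fruit data show.
* **Genotypes.** Hierarchical Balding-Nichols: a domesticated-ancestor
  branch (F = 0.08) from which both domesticated populations drift (F =
  0.03 each), and a wild population drifting straight from the species
  ancestor (F = 0.03). Realized baseline F_ST between the two domesticated
  groups is ~0.04, a realistic within-species subgroup value. Founder
  alleles are frequency-matched (exactly floor(K p) carriers plus a
  stochastic remainder): i.i.d. Bernoulli founders would add ~1/(2K) of
  spurious drift per population (K = 12), doubling baseline F_ST and
  fattening the background window tails without adding any wanted
  structure. Individuals are founder mosaics (switch rate 1e-5/bp
  domesticated, 4e-5 wild): fewer founders give larger r^2 amplitude, and
  the slower domesticated switch rate gives the longer-range LD that
  domestication bottlenecks produce. The planted sweep multiplies
  POP_SINK frequencies toward the *reference population's realized major
  allele* with strength c(x) = 0.9 exp(-|x - 1 Mb| / 50 kb) — exactly the
  alternative hypothesis the composite-likelihood scan models. Planting
  the sweep toward POP_SINK's own major allele instead drops scan power to
  ~70% at the center (mismatched-majority SNPs testify against the
  shared-c model); both worlds are arguable, and the one in which the
  planted signal lies inside the tested model family is the one a
  calibration fixture should state.
* **INFO fields.** 5% of SNPs are planted to fail exactly one hard-filter
  criterion, with pass labels stored in the ground truth, so filter counts
  are checkable exactly.

What a green test does *not* establish: the generator draws library sizes
independently of biology, plants rectangular module structure with a
single shared factor, uses a mosaic-founder model rather than coalescent
genealogies, and its sweep is a frequency shift rather than a haplotype
fixation event. Real data have correlated GC/length biases, nested module
structure, unequal founder contributions and soft sweeps; conclusions
about real pear biology are out of scope.

## Known limitations

* The NB Wald test is calibrated for the simulated world's dispersion
  range; strongly outlying dispersions (single-gene alpha >> 10) are
  ceilinged and will be anti-conservative.
* The XP-CLR surrogate shares only the original's contract, not its
  likelihood; absolute score values are not comparable to the original
  implementation's.
* Module counts on real-scale data (tens of thousands of genes) are
  data-dependent and no contract; the recursive cut has O(n^2 log n)
  clustering cost per level and is sized for desk-scale inputs (<= ~5000
  network genes).
* `pos` fields and emitted window tables are 1-based inclusive; internal
  interval arithmetic is 0-based half-open only at the GFF3 boundary via
  the underlying range libraries.
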