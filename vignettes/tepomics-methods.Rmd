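---
title: "Integrative multi-omics profiling of tumor-educated platelets: models and methods"
author: "tepomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative multi-omics profiling of tumor-educated platelets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepomics)
```

## The analytical problem

Blood platelets of cancer patients carry an altered RNA and protein cargo
("tumor-educated platelets", TEPs). Comparing platelets of pancreatic
cancer (PDAC) patients with those of patients with benign pancreatic
disease produces five molecular layers measured on the same cohort:
canonical miRNAs and their sequence isoforms (isomiRs) from small-RNA
sequencing, spliced intron-spanning reads and mature mRNAs from total
RNA sequencing, and protein spectral counts from label-free mass
spectrometry. The two groups have 11 samples each; the proteomics subset
of the PDAC-like group has 8.

`tepomics` implements the full analytical cascade on these layers:
isomiR classification, presence filtering and TMM normalization,
per-layer differential expression, sign-constrained
miRNA–gene–protein correlation networks with hub analysis, gene-set
enrichment integration, and isomiR class-frequency profiling — together
with a synthetic-data generator that plants every effect the cascade is
supposed to find, so each stage is testable without access to patient
data.

## isomiR classification

Reads are anchored to an extended template (5' flank + mature + 3'
flank) of each reference miRNA. End shifts of up to `max_offset` (default
3 nt) must match the genomic template; up to `max_subs` (default 1)
internal substitutions are tolerated inside the mature region; a
3' suffix that does not match the template is a candidate non-templated
tail of up to `max_tail` (default 3 nt). Among all valid anchorings the
one with the fewest modifications wins; ties prefer the longer templated
core, so a read extending into a flank is a templated length variant,
never a spurious tail. Classes follow a fixed priority:

1. exact match → `canonical`;
2. internal substitutions only → `nve`;
3. uniform-base non-templated tail, canonical ends → `nta#A/C/G/T`
   (tails are reported in DNA letters, so a poly-U tail is `nta#T`);
4. one templated end shift → `lv5p` / `lv3p`;
5. both ends shifted → `mlv5p` if `|offset5| >= |offset3|` (ties to
   `mlv5p`), else `mlv3p`;
6. anything else (tail + shift, substitution + shift, mixed tail) → `mv`.

Reads shorter than 15 nt, or with no anchoring within limits, are
no-calls — counted in a QC table, never forced into `mv`. A read
classifiable against several reference entries is assigned to the parent
needing the fewest modifications, ties broken alphabetically, and flagged
ambiguous. The taxonomy is decidable for every read by construction;
5' non-templated additions are not modelled as their own class and fall
into `mv`.

The canonical count matrix aggregates *all* calls of a parent miRNA
(canonical reads plus every variant), matching the convention that a
miRNA's expression is the size of its whole isoform family; the isomiR
matrix keys features by `parent|class|offset5|offset3|tail`.

Class-frequency profiles (the side-barplot view) are read-count
weighted within each group, restricted to isoforms of differentially
expressed canonical miRNAs; the heatmap values are `log2(mean CPM + 1)`
per (miRNA, class, group) — the pseudo-count keeps classes absent from
one group finite.

## Filtering and normalization

Counts are converted to counts per million (CPM) on raw library sizes. A
feature is kept when it reaches 1 CPM in strictly more than 40% of all
samples. Features failing that rule are rescued as "black and white"
cases when their pattern is a strict on/off contrast: one group entirely
zero, at most 18% zeros in the other ("positive") group. We read the
rule strictly — the non-positive group must be all zero — because that is
what makes the pattern black-and-white; a configuration switch
(`bw_strict = FALSE`) implements the permissive reading in which the
positive group is simply the one containing every sample that passes the
CPM threshold. Note that with realistic library sizes a black-and-white
feature typically has several nonzero samples *below* 1 CPM; that is
exactly why the global rule misses it.

TMM factors are computed with the trimmed mean of M-values: reference
sample by 75th-percentile CPM closest to the mean of those percentiles,
log-ratios and average log-proportions over features nonzero in both
sample and reference, two-sided rank trimming (30% on M, 5% on A),
inverse delta-method-variance weights, and a final rescaling to
geometric mean one. Fewer than ten surviving features triggers a factor
of one with a warning — deliberately loud, never silent. The protein
layer bypasses CPM/TMM entirely: its test conditions on per-sample
totals, and a median-ratio scaling is provided for reporting only.

## Differential expression

**Count layers** use an exact negative-binomial test. Counts are
linearly rescaled to the geometric-mean effective library and rounded
(an acknowledged simplification of quantile-adjusted pseudo-counts);
group sums are NB with a common dispersion, and conditioning on the
total gives a negative-hypergeometric split law that is enumerated
exactly, with a two-sided p-value by minimum-likelihood ordering. For
large totals the law's log-concavity lets the implementation locate the
likelihood-ordering boundaries by binary search and accumulate the tails
outward-in; at dispersion zero the law is binomial and the test reduces
to the exact conditional Poisson comparison. The common dispersion comes
from a method-of-moments estimate pooled over features and groups —
simpler than conditional maximum likelihood with empirical-Bayes
shrinkage, and adequate for a shared nuisance parameter; per-feature
moderation is deliberately out of scope.

**The protein layer** uses an unpaired beta-binomial likelihood-ratio
test: each sample's spectral count is beta-binomial in the sample's
total; H0 fits one success probability for all samples, H1 one per
group, overdispersion shared; 2ΔlogL is referred to χ²(1). The paired
inverted-beta-binomial variant does not fit the unbalanced 8-vs-11
design, which is why the unpaired test is used. Optimization is bounded
quasi-Newton on the (logit π, log θ) scale with a Nelder–Mead polish —
the likelihood has flat ridges in θ near the binomial boundary where a
line search alone can abort. Non-convergence yields `NaN` with a
diagnostic, never a silent number. Under a realistic null (8 vs 11
samples, ~3·10⁴ spectra per sample, 40% biological CV) the empirical
type-I error at nominal 0.05 sits near 0.06: the χ²(1) reference is
mildly anticonservative at this sample size, a known property of
likelihood-ratio asymptotics that users should keep in mind near the
threshold.

Significance follows the study's thresholds: raw `p < 0.05` and
`|log2FC| > 1` for count layers, raw `p < 0.05` alone for proteins. The
fold change is `log2((mean_A + 0.5) / (mean_B + 0.5))` on normalized
abundances, group A being the PDAC-like group; the pseudo-count of 0.5
avoids infinities for one-sided zeros. A Benjamini–Hochberg column is
emitted for reference but never feeds the flags, since the original
thresholds act on raw p-values.

## Expected-correlation networks

Within each patient group, candidate features (by default the
differentially expressed features of each layer; a switch allows
all-filtered-features mode) are correlated pairwise on normalized
`log2(CPM + 1)` values: miRNA-layer features against gene-layer
features, and gene-layer features against proteins — the latter on the
samples present in both layers (8 for group A). Pearson correlation with
the analytic t-test is the default; Spearman is available. An edge is
kept only when it is "expected": miRNA→gene requires `r < 0` and
`p < 0.05`, gene→protein requires `r > 0` and `p < 0.05`. This sign
constraint halves the null edge rate to α/2 per candidate pair, a
calibration the acceptance suite verifies. Two groups × two miRNA layers
(canonical, isomiR) × two gene layers (mRNA, intron-spanning) give eight
networks. isomiR features collapse to their parent miRNA node for
display while edges stay per-isoform, so parallel edges between a miRNA
and a gene represent distinct isomiR classes. Node degree ranks hubs;
the cross-network core is the intersection of transcript nodes over the
four same-group networks. Normalization is computed on the *full* layer
before candidate subsetting — library sizes belong to the whole
repertoire, not to the candidate list.

Edges are correlation-only: no target-prediction (seed-match) filter is
applied, and no multiple-testing control is performed on edges, matching
the per-pair α of the original design.

## Enrichment integration

Ranked layers (mRNA, intron, protein) use the preranked weighted
Kolmogorov–Smirnov statistic with ranking value `-log10(p) × sign(FC)`
(p floored at 1e-300), weight exponent `w = 1`, and a gene-label
permutation null preserving set size (default 1000 permutations,
seeded). The p-value is `(1 + #{same-sign |ES*| ≥ |ES|}) / (1 + #same-
sign permutations)` and NES divides ES by the mean same-sign |ES*|. The
miRNA layer instead uses hypergeometric over-representation of the DE
miRNAs in annotation sets, because miRNAs have no natural ranked
universe in this workflow; since ORA yields no enrichment score, every
significant miRNA set carries a fixed NES of 1.5 times its direction
sign (the majority fold-change sign of its hit miRNAs). Cross-layer
integration keeps the terms significant in *every* provided layer and
reports each term's per-layer NES and direction. Raw p < 0.05 is the
default criterion with a BH switch, matching the thresholds used
elsewhere in the pipeline. Annotation collections are flat GMT sets; no
ontology-graph propagation and no live database queries are performed
(miRNA annotation sets must be supplied, or are generated synthetically
in simulate mode).

## The synthetic-data generator

The generator is the package's test bed: it draws all five layers from
one hierarchical gamma-Poisson world and records every planted effect.

* **Library sizes** are log-normal (default ln-mean `log(3e5)`, ln-sd
  0.3); baseline relative abundances are log-normal with ln-sd 1.25
  (a realistically skewed repertoire); counts are NB with dispersion
  φ = 0.1 via the gamma-Poisson mixture; per-sample biological noise has
  ln-sd 0.5.
* **Design**: 11 vs 11 samples; the protein layer keeps only 8 group-A
  samples. Defaults: 60 miRNAs (with 3 isomiR features each), 120 genes,
  80 intron-spanning features (a subset of the same gene identifiers —
  intron-spanning reads are a second measurement of the same genes,
  which is what makes the cross-network core intersection meaningful),
  60 proteins mapped 1:1 onto genes.
* **Planted differential expression**: a fraction `frac_de` (default
  0.1) of features per layer receives a signed log2 fold change of
  magnitude 2, implemented as a group-B mean multiplier.
* **Repression couplings**: regulator miRNAs repress their target gene's
  latent mean by `exp(-β z)`, where `z` is the regulator's standardized
  log abundance (β default 1.5). Standardization is *within group*: the
  networks are per-group constructs, and per-group standardization keeps
  the coupling from leaking random group-mean shifts into targets, which
  would contaminate the fold-change plantings. Regulating miRNAs swing
  with twice the baseline biological amplitude — the planted correlation
  must clear the Pearson detection threshold at n = 11 (|r| ≈ 0.6), and
  a coupling hidden below observation noise would be a planted effect
  that is not in fact planted.
* **The hub**: one transcript is repressed by six miRNAs acting through
  a shared latent factor (loading 0.95) — a tightly co-regulated
  cluster. A product of six independent repression terms would have
  inflated the hub's marginal variance beyond anything detectable, so
  the shared factor is the biologically and statistically coherent way
  to plant a multi-regulator hub. Its planted fold change is 1.5× the
  standard magnitude (six up-regulated regulators compound), and hub and
  regulators sit at mid-range baseline abundance: a planted feature that
  dominated the layer would drive the compositional CPM denominator and
  cancel its own signal out of every relative abundance.
* **Protein coupling**: protein log-means are `protein_coupling`
  (default 0.7) times the standardized log abundance of the matched gene
  plus N(0, 0.3) noise, drawn Poisson — planting the positive gene-
  protein correlation the network layer expects.
* **isomiR class mixtures**: reads are drawn per group from an
  11-class mixture. Defaults encode the qualitative contrast the
  package profiles: the benign-like group rich in `nta#G` (25%), the
  PDAC-like group nearly devoid of it (1%) and rich in `lv3p` (20%) and
  `nta#T` (15%). The isomiR *count* layer also applies the mixture
  ratio as a group multiplier, so expression-level profiles mirror the
  read-level mixture. With unequal mixtures this is a real planted
  group effect and is recorded as such in the truth object — a fully
  null world therefore requires equal mixtures as well as
  `frac_de = 0`.
* **Read construction**: length variants trim or extend templated from
  the flanks; `nta#X` appends a uniform tail whose base the 3' flank
  must not template (otherwise the parent is re-drawn, and re-draws are
  counted); `nve` substitutes a mid-sequence base; `mv` combines a 5'
  trim with a non-templated tail. Sequencing errors, adapters and
  quality strings are not emulated.

Truth (per-layer fold changes, target map, protein map, mixtures, hub
identity and regulators) is serialized as JSON next to the data, so
validation never re-derives plantings.

### What passing tests do and do not show

The generator draws from the same model families the engines assume
(NB counts, beta-binomial spectra, log-linear couplings). Passing the
acceptance suite therefore demonstrates correctness of the
implementations and internal consistency of the cascade — planted
effects of the stated sizes are recovered at the stated rates — not
robustness to everything real platelet data can do: batch effects,
outlier libraries, zero-inflation beyond NB, adapter artefacts and
mapping ambiguity are all outside the emulation.

## Numerical choices and degenerate inputs

* NB exact p-values: minimum-likelihood ordering with a 1e-12 relative
  tie tolerance; totals ≤ 5·10⁴ enumerate fully, larger totals use the
  log-concave tail algorithm; empty totals give p = 1.
* Beta-binomial: bounds logit π ∈ [-20, 15], log θ ∈ [-12, 5]; all-zero
  (or all-saturated) features give p = 1.
* Zero-variance features are skipped in correlations with a log entry,
  never silently imputed.
* Pseudo-counts: +1 inside `log2` for expression values, +0.5 in fold
  changes, 1e-300 floor under `-log10(p)`.
* Tie-breaks are deterministic everywhere: anchoring order in the
  classifier, lexicographic parent names, feature ids in DE tables and
  degree rankings.
* Every stochastic step takes an explicit seed; identical seeds give
  bit-identical outputs, including pipeline manifests.

## Problem sizes used in validation

The acceptance suite exercises the full pipeline at desk scale — 60
miRNAs (180 isomiR features), 120 genes, 80 intron features, 60
proteins, 22 samples, 20,000 reads per group for classifier validation,
2000-feature nulls for the NB engine and 1000-feature nulls for the
beta-binomial engine, 20 seeded replicates for network recovery — sizes
chosen so the whole suite runs in minutes while keeping every estimate's
Monte-Carlo error well inside the tested tolerances. The real study's
repertoire (hundreds of miRNAs, tens of thousands of transcripts) only
scales these computations linearly in features.

## Known limitations

* The common-dispersion NB test has no per-feature moderation; features
  whose true dispersion far exceeds the common value (e.g. strongly
  regulated targets) get anticonservative p-values.
* The χ²(1) reference of the beta-binomial LRT is mildly
  anticonservative at 19 samples (~0.06 at nominal 0.05).
* The linear pseudo-count rescaling distorts NB variances when library
  sizes are very unequal; with ln-sd 0.3 libraries the effect on type-I
  error is within the tested band.
* The arithmetic-mean fold change is heavy-tail sensitive; strongly
  repressed targets show inflated |log2FC| estimates.
* Network edges are marginal correlations: strong co-regulation
  produces edges between a gene and every member of a correlated miRNA
  cluster, not only its direct regulator. The hub analysis exploits
  exactly this; causal claims need orthogonal evidence.
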