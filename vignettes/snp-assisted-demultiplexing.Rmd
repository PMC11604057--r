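---
title: "SNP-assisted demultiplexing of hashed single-cell data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-assisted demultiplexing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdemux)
```

## The problem

Cell hashing multiplexes several biological samples in one droplet-based
scRNA-seq run: each sample's cells are stained with a distinct hashtag
oligo (HTO) before pooling, and demultiplexing recovers sample identity
from the per-cell hashtag counts. When hashing works well, each cell shows
a clearly bimodal count pattern — background in most hashtags, a strong
signal in its own — and probabilistic callers assign most cells with high
confidence. When hashing quality degrades (nonspecific binding, weak
staining), a substantial fraction of cells ends up *negative* (no
confident signal anywhere) or *uncertain*, and those cells are usually
discarded even though many are perfectly good cells.

Genetically distinct samples offer a second, independent modality: sparse
per-cell SNP calls at common polymorphic loci (e.g. from VarTrix consensus
mode). This package combines the two. Confident hashing singlets provide
*labelled training data*; from them we infer each sample's consensus SNP
profile and every sample-pair's expected doublet profile; then every
negative, uncertain and doublet-flagged cell is reassigned to its nearest
profile under a Jaccard distance adapted for missing data.

## The hashing caller

Counts for one hashtag across cells are modelled as a two-component
negative-binomial mixture,

$$x \sim (1-\pi)\,\mathrm{NB}(\mu_b,\theta_b) + \pi\,\mathrm{NB}(\mu_s,\theta_s),
\qquad \mu_s \ge \mu_b,$$

fitted by EM (`fit_nbmix()`). Initialisation takes the background moments
from counts at or below the median and the signal moments from the top
decile; mean updates are exact weighted means, dispersion updates are
univariate likelihood maximisations with a keep-the-better safeguard, so
the observed log-likelihood never decreases. A cell's per-hashtag signal
posterior then drives the call (`call_hashing()`): with
$S = \{h : P(\text{signal}_h \mid x_h) \ge \alpha\}$ and acceptance
threshold $\alpha$ (default 0.75),

* $|S| = 1$ — confident singlet of that hashtag;
* $|S| \ge 2$ — doublet;
* $|S| = 0$ and all posteriors $\le 1-\alpha$ — negative;
* otherwise — uncertain.

Confident singlets keep their hashing label; the other three classes are
all forwarded to the SNP classifier. An externally produced call table
(for instance from another probabilistic hashing caller) can be supplied
to `demux()` in place of the built-in one.

One numerical subtlety: when the fitted signal dispersion is smaller than
the background dispersion, the NB likelihood ratio is not perfectly
monotone in the count — it can dip by around $10^{-9}$ deep in the
background tail, where the posterior is itself $\sim 10^{-8}$. This is
invisible at any decision threshold; the posterior is strictly monotone
from the background mean upward.

## The masked Jaccard distance

Write $m$ for the binary alt-allele indicator over loci and $p$ for the
coverage indicator ($p_{ij} = 1$ when cell $i$ has any reads at locus
$j$). For a set of training profiles (subscript $t$) against cells to
predict (subscript $q$), the agreement and disagreement counts are

$$a = (m_t * p_t)\,(m_q * p_q)^T,\qquad
  b = ((1-m_t) * p_t)\,(m_q * p_q)^T,\qquad
  c = (m_t * p_t)\,((1-m_q) * p_q)^T,$$

with $*$ the elementwise product, and the distance is $1 - a/(a+b+c)$.
The elementwise multiplication by $p$ on each side removes every locus
not covered in *both* vectors from all three counts — that is the whole
adaptation for missing data. Loci covered in both but reference in both
contribute to none of $a,b,c$, exactly as in the textbook binary Jaccard
index; with full coverage the measure reduces to it (tested against
`vegan::vegdist`). Pairs with $a+b+c=0$ carry no information; they get a
sentinel distance of 1 and are flagged rather than silently assigned.

Homozygous and heterozygous alt calls are deliberately not distinguished:
consensus SNP callers on shallow single-cell data cannot separate them
reliably, so both binarise to alt.

## Centroids, doublet profiles and prediction

Per-cell profiles are far too sparse to compare directly (80% dropout is
typical), so each sample's confident cells are pooled: per locus, the
*multivariate mode* over covered calls (an alt-vs-ref vote; no coverage or
an exact tie leaves the locus missing). Doublet classes are built for
every unordered sample pair by the union rule — alt if either parent is
alt, else ref if either is ref, else missing — which is exactly what
pooled reads from two cells would show. With $K$ samples this yields
$K + K(K-1)/2$ centroids.

Prediction is nearest-centroid (1-NN over class centroids — each class
contributes a single training point, so larger $k$ has no meaning). A
cell sharing fewer than `min_shared` covered loci (default 5) with every
centroid is declared `UNASSIGNABLE` instead of being forced onto an
uninformative match. Exact distance ties prefer a singlet class over a
doublet class, then the lowest class index; tie counts are reported.
Hashing-confident doublet calls are always re-predicted against the SNP
centroids rather than trusted, since hashing doublet calls are the least
reliable part of a degraded experiment.

Tunable parameters:

| parameter    | default | meaning |
|--------------|---------|---------|
| `acceptance` | 0.75    | posterior threshold for a confident hashing call |
| `min_shared` | 5 loci  | minimum informative overlap for SNP assignment |
| `min_train`  | 10 cells| minimum confident singlets per sample to train |

`acceptance` trades training purity against training size; 0.75 keeps
singlet precision near 1 while leaving enough cells per class. Below
`min_train` confident cells a sample's modal profile is too noisy to
trust, and centroid inference aborts listing the deficient samples.

## SNP pre-filtering

Candidate panels from population references (common variants) contain
mostly loci with no reads in scRNA-seq. `rank_genes_by_expression()` and
`filter_snps_to_genes()` restrict the panel to SNPs inside the most
commonly expressed genes — "commonly expressed" quantified as the
fraction of cells with a nonzero count, the simplest choice robust to a
few high-count cells. Coordinates are handled 0-based half-open
internally, converting at the VCF (1-based positions) and BED/GFF
boundaries; strand is ignored because point containment is
strand-agnostic; SNPs under overlapping genes are kept once. Accuracy is
insensitive to the panel size as long as a couple of hundred informative
loci survive (tested across top-50/100/200 gene panels).

## The simulator

`simulate_dataset()` generates the benchmark conditions entirely at the
count/call level:

* **genotypes** — each sample is an i.i.d. Bernoulli(0.3 by default)
  alt-allele vector over 500 loci, standing in for inter-individual
  variation at common variants;
* **composition** — exactly `round(n_cells * doublet_rate)` droplets get
  two cells, both parents drawn independently from the sample
  proportions. A pair from the same sample is *labelled as that sample*:
  single-sample doublets are indistinguishable from singlets to any
  demultiplexer, so only multisample pairs are `DOUBLET`. The expected
  multisample fraction of pairs is $1 - \sum_k p_k^2$ (5/6 for six equal
  samples);
* **SNP calls** — a singlet observes its genotype through i.i.d. dropout
  (default 0.8) and call error (alt↔ref flip, default 0.005); a doublet is
  the union of two independently generated parent vectors;
* **hashing counts** — background NB(10, 10) everywhere, own hashtag
  NB(signal_mean × signal_scale + background_mean, 5) with signal mean
  1,000; doublets sum their parents' vectors. `signal_scale` in (0, 1]
  degrades hashing quality by shrinking the signal mode toward
  background.

The defaults (6 samples, 3,000 cells, 20% doublets) are the package's
fixed study conditions for the end-to-end tests; `run_benchmark()` sweeps
doublet rates 5–50% and a signal-scale grid of {1, 0.5, 0.25, 0.1}.
`calibrate_signal_scale()` searches the scale at which hashing-only
accuracy falls into a chosen band (0.70–0.85 by default) so that the
hybrid-vs-hashing comparison is made at a controlled level of hashing
degradation rather than at an arbitrary scale.

What the simulator does *not* emulate — and hence what passing tests do
not demonstrate about real data: dropout is i.i.d. per cell × locus,
whereas real coverage is strongly gene-correlated (loci in unexpressed
genes are missing in *blocks*); genotypes are independent Bernoulli
rather than linkage-structured population haplotypes; hashtag signal
strength is shared across hashtags (real experiments show per-hashtag
quality differences — per-hashtag overrides are possible by scaling
columns of the returned counts); there is no ambient RNA, no
RNA-quality/negative-cell correlation, and no triplets or higher
multiplets.

## Evaluation conventions

`score()` reports the confusion matrix, overall accuracy, per-class
precision/recall (`NA`, not 0, where undefined) and the adjusted Rand
index. Labels are semantically fixed by sample identity, so no optimal
label matching is applied. `UNASSIGNABLE` cells are excluded from
accuracy and reported separately by default; passing
`exclude = character(0)` scores every cell, which is the right variant
for hashing-only baselines where negatives and uncertains are real
losses — both variants are available because reasonable benchmarks differ
here. `doublet_accounting()` restricts doublet precision/recall to
multisample doublets, per the convention above.

`within_group_distances()` is the post-hoc QC used to spot contaminated
groups: within each assigned group, all pairwise masked Jaccard distances
(subsampled beyond `max_pairs`) should be unimodal; a second mode
indicates misassigned cells from another genotype. Modality is judged
visually in practice; as a testable proxy the summary includes Sarle's
bimodality coefficient with the conventional 0.555 threshold, and the raw
distances are returned regardless.

## Numerical and design choices

* Ternary calls are coded missing = 0 < ref = 1 < alt = 2, so the doublet
  union rule is the elementwise maximum — one branch-free primitive
  shared by the simulator, the centroid builder and the tests.
* Sparse storage throughout (`Matrix`); missing is the implicit zero.
* Centroid ties and modal ties resolve to missing / singlet-first /
  lowest-index deterministically; no randomness anywhere in the fitting
  path, so a fixed input gives byte-identical outputs.
* EM: `max_iter = 100`, relative log-likelihood tolerance `1e-6`,
  dispersions bounded in $[10^{-3}, 10^{6}]$, weights clamped away from
  0/1. Degenerate (constant) hashtag counts abort with instructions to
  mark the hashtag unusable rather than returning a sham fit.
* Problem sizes in the shipped tests (3,000 cells × 500 SNPs for the
  recovery experiments, 10,000 cells for composition analytics, ten
  doublet rates for the minority sweep) were chosen as the smallest sizes
  at which the binomial error bands are tight enough for the claims being
  tested.

## Known limitations

Beyond the simulator caveats above: triplets and higher-order multiplets
are not modelled (all multiplet classes are unordered pairs); there is no
genotype-reference mode (samples must be distinguishable from the data
itself); heterozygosity is collapsed by design, which discards a little
information when deep coverage is available; and the minority-sample
guarantee requires at least `min_train` confident hashing singlets for
every sample — with a 2% sample and very few cells, training itself
becomes the bottleneck before classification does.
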