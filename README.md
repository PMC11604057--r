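# snpdemux

Hybrid demultiplexing of cell-hashing single-cell RNA-seq experiments in R.

## The problem

Cell hashing pools several biological samples into one scRNA-seq run by
staining each sample's cells with a distinct hashtag oligo (HTO). With
high-quality hashing, per-cell hashtag counts separate cleanly and most
cells are confidently assigned. With degraded hashing, many cells come out
**negative** (no confident signal in any hashtag) or **uncertain**, and
**doublet** calls become unreliable — cells that are usually thrown away.

When the pooled samples are genetically distinct, sparse per-cell SNP
calls (e.g. a VarTrix consensus matrix) provide an independent route to
sample identity. `snpdemux` uses the cells hashing *can* call confidently
as labelled training data for a supervised SNP classifier, then rescues
everything hashing could not call:

1. a per-hashtag negative-binomial mixture model classifies hashing counts
   into confident singlets, doublets, negatives and uncertains
   (`call_hashing()`, acceptance threshold 0.75 by default);
2. each sample's consensus SNP profile is inferred as the per-locus
   multivariate mode over its confident cells, and a doublet profile is
   built for every sample pair by the union rule (`infer_singlet_centroids()`,
   `build_doublet_centroids()`);
3. negative/uncertain/doublet cells are assigned to their nearest profile
   under a Jaccard distance adapted for missing data (`predict_cells()`).

The distance is the core primitive. With alt-allele mask `m` and coverage
mask `p` (1 where a cell has reads at a locus), the counts between
training profiles (t) and cells to predict (q) are

    a = (m_t * p_t) (m_q * p_q)^T
    b = ((1 - m_t) * p_t) (m_q * p_q)^T
    c = (m_t * p_t) ((1 - m_q) * p_q)^T

(`*` elementwise) and the distance is `1 - a/(a + b + c)`: loci without
reads in either vector contribute to none of the counts, and with full
coverage this is exactly the textbook binary Jaccard distance.

The package also ships a count-level benchmark simulator
(`simulate_dataset()`: genotypes, dropout, call errors, negative-binomial
hashing counts, doublets by merging, tunable doublet rate / class
imbalance / hashing quality) and evaluation utilities (`score()`,
`doublet_accounting()`, `within_group_distances()`).

## Worked example

Simulate a 6-sample, 3,000-cell experiment with 20% doublets and badly
degraded hashing (signal scaled to 3%), then demultiplex:

```r
library(snpdemux)

sim <- simulate_dataset(sim_config(signal_scale = 0.03, seed = 101))
fit <- demux(sim$snp, sim$hto)
fit
#> snp_demux: 3000 cells, 6 samples
#>   hashing-confident singlets: 1848; SNP-predicted: 1152
#>   doublets: 425; unassignable: 0; distance ties: 0
```

Hashing alone could confidently call only 1,848 of 3,000 cells; the other
1,152 (negatives, uncertains and doublet calls) were re-assigned from
their SNP profiles. Scoring against the simulator's ground truth:

```r
pred <- fit$assignments$label[match(sim$truth$cell_barcode,
                                    fit$assignments$cell_barcode)]
score(sim$truth$true_label, pred)
#> eval_report: n = 3000 (excluded 0)
#>   accuracy 0.9747   ARI 0.9404
#>   per-class precision / recall:
#>           DOUBLET Sample1 Sample2 Sample3 Sample4 Sample5 Sample6
#> precision   1.000   0.961   0.967   0.974   0.973   0.983   0.965
#> recall      0.859   1.000   1.000   0.996   1.000   0.996   0.995
```

Hashing-only assignment on the same data reaches accuracy 0.739 (all
negatives/uncertains are losses), so the SNP step recovers about 24
percentage points. Doublet precision of 1.0 with recall 0.859 reflects
the usual asymmetry of SNP-based doublet detection: cells called doublets
really are doublets, but some multisample doublets still pass as singlets.

Per-cell output is in `fit$assignments` (barcode, final label, provenance
`HASHING`/`SNP_PREDICTED`, nearest-centroid distance, shared covered
loci); `write_assignments()` saves it as TSV. `run_demux()`,
`run_simulate()`, `run_benchmark()` and `run_select_snps()` are
file-in/file-out wrappers, with a thin command-line front end in
`inst/cli/snpdemux.R`.

Real inputs enter through `read_vartrix()` (Matrix Market consensus
matrix + barcode/variant sidecars), `read_hto_counts()` (CSV or MTX) and,
optionally, `read_hashing_calls()` for an externally produced hashing
call table. SNP panels can be pre-filtered to the most commonly expressed
genes with `rank_genes_by_expression()` + `filter_snps_to_genes()`
(VCF/BED/GFF readers included).

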