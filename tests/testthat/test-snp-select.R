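test_that("genes are ranked by detection fraction with stable ties", {
  rna <- cbind(geneA = c(1, 2, 0, 5), geneB = c(0, 0, 0, 3),
               geneC = c(1, 1, 1, 1), geneD = c(0, 0, 0, 0))
  r <- rank_genes_by_expression(rna)
  expect_identical(r$gene_id[1], "geneC")   # detected everywhere
  expect_identical(r$gene_id[nrow(r)], "geneD")  # detected nowhere
  expect_equal(r$fraction[r$gene_id == "geneA"], 0.75)
  expect_equal(r$fraction[r$gene_id == "geneB"], 0.25)
  expect_equal(r$fraction[r$gene_id == "geneC"], 1.0)
  expect_equal(r$fraction[r$gene_id == "geneD"], 0.0)
  # stable tie order by gene id
  tie <- rank_genes_by_expression(cbind(z = c(1, 0), a = c(0, 1)))
  expect_identical(tie$gene_id, c("a", "z"))
  expect_error(rank_genes_by_expression(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("SNP filtering respects the half-open coordinate convention", {
  ranked <- data.frame(gene_id = "g1", fraction = 1, chrom = "chr1",
                       start = 100L, end = 200L)  # 0-based half-open
  snps <- data.frame(chrom = "chr1", pos = c(100L, 101L, 150L, 200L, 201L))
  idx <- filter_snps_to_genes(snps, ranked, top_n = 1)
  # 1-based pos 100 -> coordinate 99, outside [100, 200); pos 200 -> 199, inside
  expect_identical(idx, c(2L, 3L, 4L))
  expect_error(
    suppressWarnings(filter_snps_to_genes(data.frame(chrom = "chr2",
                                                     pos = 150L),
                                          ranked, top_n = 1)),
    "larger top_n|top_n")
})

test_that("increasing top_n never drops a retained SNP, and dedups overlaps", {
  set.seed(301)
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       fraction = seq(1, 0.05, length.out = 20),
                       chrom = "chr1",
                       start = seq(0, 1900, by = 100),
                       end = seq(150, 2050, by = 100))  # overlapping genes
  snps <- data.frame(chrom = "chr1", pos = sample(1:2100, 300, replace = FALSE))
  prev <- integer(0)
  for (n in c(2, 5, 10, 20)) {
    idx <- filter_snps_to_genes(snps, ranked, top_n = n)
    expect_true(all(prev %in% idx))
    expect_identical(anyDuplicated(idx), 0L)
    prev <- idx
  }
})

test_that("VCF and BED inputs drive end-to-end SNP selection", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "snps.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t150\t.\tA\tG\t.\tPASS\t.",
               "chr1\t250\t.\tC\tT\t.\tPASS\t.",
               "chr2\t50\t.\tG\tA\t.\tPASS\t."), vcf)
  bed <- file.path(dir, "genes.bed")
  writeLines(c("chr1\t100\t200\tgeneA",
               "chr2\t10\t80\tgeneB",
               "chr1\t900\t950\tgeneC"), bed)
  rna <- file.path(dir, "rna.csv")
  write.csv(data.frame(cell_barcode = c("b1", "b2"),
                       geneA = c(1, 2), geneB = c(0, 1), geneC = c(0, 0)),
            rna, row.names = FALSE, quote = FALSE)
  out <- file.path(dir, "kept.tsv")
  kept <- run_select_snps(vcf, bed, rna, top_n = 2, out = out)
  # geneA (frac 1) and geneB (frac 0.5) are the top 2 genes
  expect_identical(kept$pos, c(150L, 50L))
  expect_true(file.exists(out))
  tab <- read.table(out, header = TRUE, sep = "\t")
  expect_identical(nrow(tab), 2L)
})

test_that("classification accuracy is stable across SNP panel subsets", {
  # genes tile the SNP panel 4 loci apiece; expression ranks are arbitrary,
  # so keeping the top 50/100/200 genes keeps random panels of 200/400/800
  # SNPs - accuracy should not depend on the panel as long as it stays
  # informative
  set.seed(302)
  n_genes <- 200
  cfg <- sim_config(n_cells = 1200, n_snps = 4 * n_genes, seed = 302)
  sim <- simulate_dataset(cfg)
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:n_genes),
                       fraction = seq(1, 0.5, length.out = n_genes),
                       chrom = "chr1",
                       start = seq(0, by = 4, length.out = n_genes),
                       end = seq(4, by = 4, length.out = n_genes))
  snp_pos <- data.frame(chrom = "chr1", pos = seq_len(cfg$n_snps))
  calls <- call_hashing(sim$hto)
  acc <- sapply(c(50, 100, 200), function(top_n) {
    idx <- filter_snps_to_genes(snp_pos, ranked, top_n = top_n)
    fit <- demux(sim$snp[, idx], calls = calls)
    pred <- fit$assignments$label[match(sim$truth$cell_barcode,
                                        fit$assignments$cell_barcode)]
    score(sim$truth$true_label, pred)$accuracy
  })
  expect_lte(max(abs(acc - mean(acc))), 0.02)
})
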