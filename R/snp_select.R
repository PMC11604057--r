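#' Rank genes by detection fraction
#'
#' Orders genes by the fraction of cells in which they are detected
#' (nonzero RNA count), descending, with ties broken by gene id for a
#' stable order. "Commonly expressed" is quantified as detection fraction
#' rather than mean expression because it is robust to a few
#' high-count cells.
#'
#' @param rna_counts Cells x genes non-negative count matrix.
#' @param gene_ids Gene identifiers, one per column (default
#'   `colnames(rna_counts)`).
#' @param intervals Optional data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open) to carry genomic coordinates along,
#'   e.g. from [read_gene_intervals()].
#' @return Data frame `gene_id`, `fraction` (plus interval columns when
#'   supplied), sorted descending by fraction.
#' @export
rank_genes_by_expression <- function(rna_counts, gene_ids = colnames(rna_counts),
                                     intervals = NULL) {
  rna_counts <- as.matrix(rna_counts)
  if (!nrow(rna_counts) || !ncol(rna_counts)) {
    .stopf("RNA count matrix is empty")
  }
  if (length(gene_ids) != ncol(rna_counts)) {
    .stopf("gene_ids length does not match number of genes")
  }
  frac <- colMeans(rna_counts > 0)
  out <- data.frame(gene_id = as.character(gene_ids), fraction = frac,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(intervals)) {
    i <- match(out$gene_id, intervals$gene_id)
    out$chrom <- intervals$chrom[i]
    out$start <- intervals$start[i]
    out$end <- intervals$end[i]
  }
  out[order(-out$fraction, out$gene_id), , drop = FALSE]
}

#' Filter SNPs to those inside the top expressed genes
#'
#' Retains the SNPs whose position falls inside any of the `top_n`
#' highest-ranked genes' intervals. Positions are VCF-style 1-based; gene
#' intervals are 0-based half-open, so a 1-based position `pos` is inside
#' `[start, end)` when `start <= pos - 1 < end`. SNPs covered by several
#' genes are retained once.
#'
#' @param snp_positions Data frame with columns `chrom` and `pos`
#'   (1-based), e.g. from [read_vcf_positions()].
#' @param ranked Ranked gene table from [rank_genes_by_expression()] with
#'   interval columns.
#' @param top_n Number of top genes to keep (default 100).
#' @return Integer indices (rows of `snp_positions`) of retained SNPs, in
#'   input order.
#' @export
filter_snps_to_genes <- function(snp_positions, ranked, top_n = 100L) {
  if (!.is_count(top_n)) .stopf("top_n must be a positive integer")
  if (!all(c("chrom", "pos") %in% names(snp_positions))) {
    .stopf("snp_positions needs chrom and pos columns")
  }
  if (!all(c("chrom", "start", "end") %in% names(ranked))) {
    .stopf("ranked gene table has no interval columns; supply intervals")
  }
  top <- utils::head(ranked, top_n)
  top <- top[stats::complete.cases(top[, c("chrom", "start", "end")]), ,
             drop = FALSE]
  if (!nrow(top)) .stopf("no gene intervals among the top %d genes", top_n)
  if (any(top$start >= top$end)) .stopf("malformed gene interval (start >= end)")
  genes <- GenomicRanges::GRanges(top$chrom,
                                  IRanges::IRanges(top$start + 1L, top$end))
  snps <- GenomicRanges::GRanges(snp_positions$chrom,
                                 IRanges::IRanges(snp_positions$pos,
                                                  snp_positions$pos))
  hits <- GenomicRanges::findOverlaps(snps, genes)
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  if (!length(idx)) {
    .stopf("no SNP falls inside the top %d genes; try a larger top_n", top_n)
  }
  idx
}

#' Read variant positions from a VCF
#'
#' Only coordinates and alleles are used; genotype columns are ignored.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return Data frame `chrom`, `pos` (1-based), `id`
#'   (`chrom:pos:ref>alt`).
#' @export
read_vcf_positions <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  data.frame(chrom = fix$CHROM,
             pos = as.integer(fix$POS),
             id = sprintf("%s:%s:%s>%s", fix$CHROM, fix$POS, fix$REF,
                          fix$ALT),
             stringsAsFactors = FALSE)
}

#' Read gene intervals from BED or GFF
#'
#' Coordinates are converted to the package's internal 0-based half-open
#' convention (BED is natively 0-based half-open; GFF is 1-based closed).
#' Strand is ignored: SNP containment is strand-agnostic.
#'
#' @param path Path to a BED or GFF/GTF file (format inferred from the
#'   extension).
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  id <- NULL
  mc <- S4Vectors::mcols(gr)
  for (col in c("name", "gene_id", "ID", "Name")) {
    if (col %in% names(mc) && !all(is.na(mc[[col]]))) {
      id <- as.character(mc[[col]])
      break
    }
  }
  if (is.null(id)) {
    id <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), GenomicRanges::end(gr))
  }
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a filtered variant position table
#'
#' @param snp_positions Data frame as from [read_vcf_positions()].
#' @param idx Retained row indices from [filter_snps_to_genes()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_filtered_variants <- function(snp_positions, idx, path) {
  utils::write.table(snp_positions[idx, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
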