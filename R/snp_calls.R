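#' Sparse ternary SNP call matrix
#'
#' Container for per-cell SNP calls from a consensus variant caller. Calls
#' are ternary (`MISSING`/`REF`/`ALT`, see [snp_codes()]) and stored sparsely
#' with `MISSING` as the implicit default: the vast majority of cell-locus
#' pairs in droplet scRNA-seq carry no reads.
#'
#' @param calls A cells x SNPs matrix (base matrix or [Matrix::Matrix]) with
#'   integer codes 0 (missing), 1 (ref) and 2 (alt).
#' @param cell_barcodes Character vector of unique cell barcodes, one per row.
#'   Defaults to `rownames(calls)`.
#' @param snp_ids Character vector of unique variant identifiers
#'   (`chrom:pos:ref>alt`, 1-based positions), one per column. Defaults to
#'   `colnames(calls)`.
#'
#' @return An object of class `snp_calls`: a list with elements `calls`
#'   (a `dgCMatrix`), `cell_barcodes` and `snp_ids`.
#' @seealso [read_vartrix()], [decompose_calls()], [merge_calls()]
#' @export
#' @examples
#' m <- rbind(c(2, 1, 0), c(0, 2, 2))
#' x <- snp_call_matrix(m, c("AAAC", "AAAG"), c("1:10:A>G", "1:20:C>T", "2:5:G>A"))
#' x
snp_call_matrix <- function(calls, cell_barcodes = rownames(calls),
                            snp_ids = colnames(calls)) {
  if (is.null(cell_barcodes) || is.null(snp_ids)) {
    .stopf("cell_barcodes and snp_ids are required (or set as dimnames)")
  }
  cell_barcodes <- as.character(cell_barcodes)
  snp_ids <- as.character(snp_ids)
  if (nrow(calls) != length(cell_barcodes)) {
    .stopf("number of barcodes (%d) does not match number of rows (%d)",
           length(cell_barcodes), nrow(calls))
  }
  if (ncol(calls) != length(snp_ids)) {
    .stopf("number of snp_ids (%d) does not match number of columns (%d)",
           length(snp_ids), ncol(calls))
  }
  if (anyDuplicated(cell_barcodes)) .stopf("cell barcodes must be unique")
  if (anyDuplicated(snp_ids)) .stopf("snp_ids must be unique")
  calls <- methods::as(methods::as(Matrix::Matrix(calls, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
  calls <- Matrix::drop0(calls)
  vals <- calls@x
  if (length(vals) && !all(vals %in% c(.REF, .ALT))) {
    .stopf("call codes must be in {0, 1, 2}; found %s",
           paste(utils::head(setdiff(unique(vals), c(.REF, .ALT)), 5),
                 collapse = ", "))
  }
  dimnames(calls) <- list(cell_barcodes, snp_ids)
  structure(list(calls = calls, cell_barcodes = cell_barcodes,
                 snp_ids = snp_ids),
            class = "snp_calls")
}

#' @export
print.snp_calls <- function(x, ...) {
  nz <- length(x$calls@x)
  n_alt <- sum(x$calls@x == .ALT)
  cat(sprintf("snp_calls: %d cells x %d SNPs\n", nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  covered entries: %d (%.1f%%); ALT calls: %d\n",
              nz, 100 * nz / prod(dim(x$calls)), n_alt))
  invisible(x)
}

#' @export
dim.snp_calls <- function(x) dim(x$calls)

#' Subset a SNP call matrix by cells and/or SNPs
#'
#' @param x A `snp_calls` object.
#' @param i,j Row (cell) and column (SNP) indices: integer, logical, or
#'   character (matched against barcodes / SNP ids).
#' @param ... Ignored.
#' @return A `snp_calls` object.
#' @export
`[.snp_calls` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  sub <- x$calls[i, j, drop = FALSE]
  snp_call_matrix(sub, rownames(sub), colnames(sub))
}

#' Decompose ternary calls into alt and coverage masks
#'
#' Splits an `snp_calls` object into the two binary matrices the masked
#' Jaccard distance operates on: `m` marks loci where the alternative allele
#' was observed, `p` marks loci with any reads (coverage). By construction
#' `m <= p` elementwise and `p == 0` exactly where the call is `MISSING`.
#'
#' @param x An `snp_calls` object.
#' @return A list with sparse 0/1 matrices `m` (alt mask) and `p`
#'   (coverage mask), both cells x SNPs.
#' @seealso [recompose_calls()] for the inverse.
#' @export
#' @examples
#' x <- snp_call_matrix(rbind(c(2, 1, 0)), "bc1", c("s1", "s2", "s3"))
#' decompose_calls(x)$m[1, ]  # 1 0 0
#' decompose_calls(x)$p[1, ]  # 1 1 0
decompose_calls <- function(x) {
  stopifnot(inherits(x, "snp_calls"))
  m <- x$calls
  m@x <- as.numeric(m@x == .ALT)
  m <- Matrix::drop0(m)
  p <- x$calls
  p@x <- rep(1, length(p@x))
  list(m = m, p = p)
}

#' Recompose ternary calls from alt and coverage masks
#'
#' Inverse of [decompose_calls()]: `calls = p + m` under the integer coding
#' (covered-ref becomes 1, alt becomes 2, uncovered stays 0).
#'
#' @param m,p Binary cells x SNPs matrices with `m <= p` elementwise.
#' @param cell_barcodes,snp_ids Optional dimension labels; default to the
#'   dimnames of `p`.
#' @return An `snp_calls` object.
#' @export
recompose_calls <- function(m, p, cell_barcodes = rownames(p),
                            snp_ids = colnames(p)) {
  if (!identical(dim(m), dim(p))) .stopf("m and p must have equal dimensions")
  calls <- p + m
  if (length(calls@x) && any(calls@x > .ALT)) {
    .stopf("m must be <= p elementwise (alt observed implies covered)")
  }
  snp_call_matrix(calls, cell_barcodes, snp_ids)
}

#' Merge two ternary call vectors as a doublet would
#'
#' Pools the calls of two cells the way reads pool in a droplet containing
#' both: per locus the merged call is `ALT` if either cell shows `ALT`,
#' otherwise `REF` if either is covered, otherwise `MISSING`. Under the
#' integer coding (missing < ref < alt) this union rule is exactly the
#' elementwise maximum, so the operation is commutative, associative and
#' idempotent.
#'
#' @param a,b Integer vectors (or matrices of equal shape) of ternary codes.
#' @return The merged calls, same shape as the inputs.
#' @export
#' @examples
#' merge_calls(c(2, 1, 0), c(1, 1, 2))  # 2 1 2
merge_calls <- function(a, b) {
  if (length(a) != length(b)) {
    .stopf("call vectors have different lengths (%d vs %d)",
           length(a), length(b))
  }
  pmax(a, b)
}
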