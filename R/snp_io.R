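#' Read a VarTrix consensus matrix
#'
#' Reads the sparse integer matrix VarTrix emits in consensus mode together
#' with its barcode and variant sidecar files, and recodes it to the ternary
#' convention used here. VarTrix consensus codes are 0 = no reads, 1 = ref
#' only, 2 = alt only, 3 = both alleles; codes 2 and 3 are both binarised to
#' `ALT` because the classifier does not distinguish homozygous from
#' heterozygous loci. Ref-only loci are kept as covered-ref (`p = 1, m = 0`)
#' since the distance's disagreement terms require observed reference calls.
#'
#' The on-disk matrix may be oriented either cells x SNPs or SNPs x cells
#' (VarTrix writes variants as rows); orientation is resolved against the
#' sidecar lengths.
#'
#' @param mtx_path Path to the Matrix Market coordinate integer file.
#' @param barcodes_path Path to a text file with one cell barcode per line.
#' @param variants_path Path to a text file with one variant id per line.
#' @return An `snp_calls` object (cells x SNPs).
#' @export
read_vartrix <- function(mtx_path, barcodes_path, variants_path) {
  for (f in c(mtx_path, barcodes_path, variants_path)) {
    if (!file.exists(f)) .stopf("file not found: %s", f)
  }
  mm <- Matrix::readMM(mtx_path)
  bc <- readLines(barcodes_path)
  vs <- readLines(variants_path)
  bc <- bc[nzchar(bc)]
  vs <- vs[nzchar(vs)]
  if (nrow(mm) == length(bc) && ncol(mm) == length(vs)) {
    # cells x SNPs as-is
  } else if (nrow(mm) == length(vs) && ncol(mm) == length(bc)) {
    mm <- Matrix::t(mm)
  } else {
    .stopf(paste0("matrix dimensions (%d x %d) match neither sidecar: ",
                  "%s has %d entries, %s has %d entries"),
           nrow(mm), ncol(mm), barcodes_path, length(bc),
           variants_path, length(vs))
  }
  mm <- methods::as(mm, "TsparseMatrix")
  bad <- which(!(mm@x %in% 0:3))
  if (length(bad)) {
    .stopf("invalid VarTrix code %s at cell %d, SNP %d (codes must be 0-3)",
           format(mm@x[bad[1]]), mm@i[bad[1]] + 1L, mm@j[bad[1]] + 1L)
  }
  x <- mm@x
  x[x == 3] <- .ALT
  mm@x <- x
  snp_call_matrix(mm, bc, vs)
}

#' Write an `snp_calls` object in VarTrix-like on-disk layout
#'
#' Writes `calls.mtx` (Matrix Market coordinate integer, cells x SNPs,
#' codes 1 = ref, 2 = alt, missing implicit), `barcodes.tsv` and
#' `variants.tsv` into `dir`.
#'
#' @param x An `snp_calls` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_snp_calls <- function(x, dir) {
  stopifnot(inherits(x, "snp_calls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("calls.mtx", "barcodes.tsv", "variants.tsv"))
  m <- x$calls
  dimnames(m) <- NULL
  Matrix::writeMM(m, paths[1])
  writeLines(x$cell_barcodes, paths[2])
  writeLines(x$snp_ids, paths[3])
  invisible(paths)
}

#' Read a hashtag-oligo count matrix
#'
#' Accepts either a CSV with a header row and the cell barcode in the first
#' column (cells x hashtags), or a Matrix Market file with barcode and
#' hashtag-name sidecars.
#'
#' @param path Path to the CSV or `.mtx` file.
#' @param barcodes_path,features_path Sidecar files (one entry per line),
#'   required when `path` is an `.mtx` file.
#' @return An integer matrix, cells x hashtags, with barcode rownames.
#' @export
read_hto_counts <- function(path, barcodes_path = NULL, features_path = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(barcodes_path) || is.null(features_path)) {
      .stopf("barcodes_path and features_path are required for MTX input")
    }
    mm <- as.matrix(Matrix::readMM(path))
    bc <- readLines(barcodes_path)
    ft <- readLines(features_path)
    if (nrow(mm) == length(ft) && ncol(mm) == length(bc)) mm <- t(mm)
    if (nrow(mm) != length(bc) || ncol(mm) != length(ft)) {
      .stopf("MTX dimensions do not match sidecars")
    }
    dimnames(mm) <- list(bc, ft)
    counts <- mm
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  }
  validate_hto_counts(counts)
}

#' Validate a hashing count matrix
#'
#' @param counts Numeric cells x hashtags matrix with barcode rownames and
#'   hashtag colnames.
#' @return The validated matrix (storage mode integer-valued numeric).
#' @export
validate_hto_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    .stopf("hashing counts need barcode rownames and hashtag colnames")
  }
  if (anyDuplicated(colnames(counts))) .stopf("hashtag names must be unique")
  if (any(colnames(counts) %in% .RESERVED_LABELS)) {
    .stopf("hashtag names may not use reserved labels (%s)",
           paste(.RESERVED_LABELS, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    .stopf("hashing counts must be non-negative integers")
  }
  counts
}

#' Write hashing counts as CSV
#'
#' @param counts Cells x hashtags matrix (see [validate_hto_counts()]).
#' @param path Output CSV path; first column `cell_barcode`.
#' @return Invisibly, `path`.
#' @export
write_hto_counts <- function(counts, path) {
  counts <- validate_hto_counts(counts)
  df <- data.frame(cell_barcode = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write hashing call tables
#'
#' Call tables are TSV files with columns `cell_barcode`, `label`, then one
#' posterior column per hashtag. Externally produced tables (e.g. from other
#' probabilistic hashing callers) can be read and passed to [demux()] in
#' place of the built-in caller.
#'
#' @param path TSV path.
#' @return For `read_hashing_calls`, a `hashing_calls` data frame.
#' @export
read_hashing_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell_barcode", "label") %in% names(df))) {
    .stopf("call table must have cell_barcode and label columns")
  }
  class(df) <- c("hashing_calls", "data.frame")
  df
}

#' @rdname read_hashing_calls
#' @param calls A `hashing_calls` data frame (from [call_hashing()]).
#' @export
write_hashing_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a demultiplexing assignment table
#'
#' Writes the per-cell assignments as TSV with columns `cell_barcode`,
#' `label`, `provenance`, `distance`, `shared_snps`, `nearest_class`.
#'
#' @param x A `snp_demux` fit (from [demux()]) or its `assignments` data
#'   frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(x, path) {
  df <- if (inherits(x, "snp_demux")) x$assignments else x
  cols <- c("cell_barcode", "label", "provenance", "distance",
            "shared_snps", "nearest_class")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
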