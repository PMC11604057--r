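# Internal ternary call codes. MISSING is the implicit (sparse) default.
.MISSING <- 0L
.REF <- 1L
.ALT <- 2L

# Labels with fixed meaning in call tables and results; hashtag/sample names
# must not collide with these.
.RESERVED_LABELS <- c("DOUBLET", "NEGATIVE", "UNCERTAIN", "UNASSIGNABLE")

#' Ternary SNP call codes
#'
#' Integer codes used throughout the package for per-cell SNP calls:
#' `MISSING = 0` (no reads at the locus), `REF = 1` (only the reference
#' allele observed), `ALT = 2` (alternative allele observed, homozygous or
#' heterozygous -- the two are not distinguished).
#'
#' @return Named integer vector `c(MISSING = 0L, REF = 1L, ALT = 2L)`.
#' @export
#' @examples
#' snp_codes()
snp_codes <- function() {
  c(MISSING = .MISSING, REF = .REF, ALT = .ALT)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

.logsumexp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Stable content hash of a configuration list (for run summaries).
.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}
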