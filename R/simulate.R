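#' Configuration for the benchmark simulator
#'
#' Bundles and validates the parameters of the synthetic multiplexed
#' dataset: number of genetically distinct samples and their proportions,
#' doublet rate, SNP panel size and genotype divergence, per-cell call
#' sparsity and error, and the negative-binomial hashing count model with a
#' signal-scaling knob emulating hashing-quality degradation.
#'
#' Defaults describe a mid-sized hashed experiment: 6 samples in equal
#' proportion, 3,000 droplets, a 20% doublet rate, 500 candidate SNPs with
#' a 0.3 alt-allele frequency per sample, 80% per-locus dropout, a 0.5%
#' call error rate, and hashing counts with background mean 10 (dispersion
#' 10) against signal mean 1,000 (dispersion 5).
#'
#' @param n_samples Number of multiplexed samples `K >= 2`.
#' @param sample_proportions Positive weights summing to 1 (default equal).
#' @param n_cells Number of droplets.
#' @param doublet_rate Fraction of droplets containing two cells, in
#'   `[0, 0.5]`.
#' @param n_snps Number of SNP loci.
#' @param alt_allele_prob Per-sample, per-SNP Bernoulli probability of
#'   carrying the alternative allele.
#' @param dropout_prob Probability a locus is unobserved (`MISSING`) in a
#'   cell.
#' @param call_error_prob Probability an observed call flips `ALT <-> REF`.
#' @param background_mean,background_size Negative-binomial background
#'   hashing count parameters (all hashtags, all cells).
#' @param signal_mean,signal_size Negative-binomial signal parameters for a
#'   cell's own hashtag.
#' @param signal_scale Hashing-quality degradation multiplier in `(0, 1]`
#'   applied to the signal mean before the background mean is added.
#' @param seed Integer RNG seed (`< 2^31 - 16`); each generator stage uses a
#'   fixed offset from it, so stages are individually reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 6L,
                       sample_proportions = NULL,
                       n_cells = 3000L,
                       doublet_rate = 0.2,
                       n_snps = 500L,
                       alt_allele_prob = 0.3,
                       dropout_prob = 0.8,
                       call_error_prob = 0.005,
                       background_mean = 10,
                       background_size = 10,
                       signal_mean = 1000,
                       signal_size = 5,
                       signal_scale = 1,
                       seed = 1L) {
  if (!.is_count(n_samples) || n_samples < 2) {
    .stopf("n_samples must be an integer >= 2")
  }
  if (is.null(sample_proportions)) {
    sample_proportions <- rep(1 / n_samples, n_samples)
  }
  if (length(sample_proportions) != n_samples ||
      any(sample_proportions <= 0) ||
      abs(sum(sample_proportions) - 1) > 1e-9) {
    .stopf("sample_proportions must be %d positive values summing to 1",
           n_samples)
  }
  if (!.is_count(n_cells) || !.is_count(n_snps)) {
    .stopf("n_cells and n_snps must be positive integers")
  }
  if (!is.numeric(doublet_rate) || doublet_rate < 0 || doublet_rate > 0.5) {
    .stopf("doublet_rate must be in [0, 0.5]")
  }
  for (nm in c("alt_allele_prob", "dropout_prob", "call_error_prob")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) .stopf("%s must be in [0, 1]", nm)
  }
  for (nm in c("background_mean", "background_size", "signal_mean",
               "signal_size")) {
    if (get(nm) <= 0) .stopf("%s must be positive", nm)
  }
  if (signal_scale <= 0 || signal_scale > 1) {
    .stopf("signal_scale must be in (0, 1]")
  }
  if (!is.numeric(seed) || seed != round(seed) || abs(seed) >= 2^31 - 16) {
    .stopf("seed must be an integer below 2^31 - 16 in magnitude")
  }
  structure(list(n_samples = as.integer(n_samples),
                 sample_proportions = sample_proportions,
                 n_cells = as.integer(n_cells),
                 doublet_rate = doublet_rate,
                 n_snps = as.integer(n_snps),
                 alt_allele_prob = alt_allele_prob,
                 dropout_prob = dropout_prob,
                 call_error_prob = call_error_prob,
                 background_mean = background_mean,
                 background_size = background_size,
                 signal_mean = signal_mean,
                 signal_size = signal_size,
                 signal_scale = signal_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sample_names <- function(cfg) paste0("Sample", seq_len(cfg$n_samples))

#' Simulate sample genotypes
#'
#' Draws each sample's binary alt-allele genotype independently per SNP as
#' Bernoulli(`alt_allele_prob`). This is a stand-in for real
#' inter-individual variation at common polymorphic sites.
#'
#' @param cfg A [sim_config()].
#' @return Samples x SNPs 0/1 matrix with sample rownames.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 0L)
  g <- matrix(stats::rbinom(cfg$n_samples * cfg$n_snps, 1L,
                            cfg$alt_allele_prob),
              nrow = cfg$n_samples,
              dimnames = list(.sample_names(cfg),
                              sprintf("chr1:%d:A>G", seq_len(cfg$n_snps))))
  g
}

#' Simulate droplet composition (singlets and doublets)
#'
#' Exactly `round(n_cells * doublet_rate)` droplets receive two cells, each
#' parent drawn independently from `sample_proportions`; the rest receive
#' one. Following standard demultiplexing accounting, a droplet whose two
#' cells come from the same sample is labelled as that sample (single-sample
#' doublets are indistinguishable from singlets), and only multisample
#' pairs are labelled `DOUBLET`.
#'
#' @param cfg A [sim_config()].
#' @return Data frame of class `sim_truth`: `cell_barcode`, `sample_1`,
#'   `sample_2` (`NA` for singlets), `true_label`.
#' @export
simulate_cell_composition <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_cells
  sn <- .sample_names(cfg)
  n_dbl <- round(n * cfg$doublet_rate)
  dbl_idx <- sort(sample.int(n, n_dbl))
  s1 <- sample(sn, n, replace = TRUE, prob = cfg$sample_proportions)
  s2 <- rep(NA_character_, n)
  s2[dbl_idx] <- sample(sn, n_dbl, replace = TRUE,
                        prob = cfg$sample_proportions)
  label <- s1
  multi <- !is.na(s2) & s2 != s1
  label[multi] <- "DOUBLET"
  out <- data.frame(cell_barcode = sprintf("cell_%05d", seq_len(n)),
                    sample_1 = s1, sample_2 = s2, true_label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_truth", "data.frame")
  out
}

#' Simulate sparse per-cell SNP calls
#'
#' Each singlet cell observes its sample's genotype through two noise
#' layers: a locus is `MISSING` with probability `dropout_prob`, and an
#' observed call flips `ALT <-> REF` with probability `call_error_prob`.
#' A doublet's calls are the union ([merge_calls()]) of two parent call
#' vectors generated independently, mimicking pooled reads.
#'
#' @param genotypes Samples x SNPs 0/1 matrix ([simulate_genotypes()]).
#' @param truth A `sim_truth` composition table.
#' @param cfg A [sim_config()].
#' @return An `snp_calls` object.
#' @export
simulate_snp_calls <- function(genotypes, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- nrow(truth)
  s <- cfg$n_snps
  cell_vec <- function(sample_name) {
    code <- genotypes[sample_name, ] + .REF  # 0/1 genotype -> REF/ALT
    flip <- stats::runif(s) < cfg$call_error_prob
    code[flip] <- .REF + .ALT - code[flip]
    code[stats::runif(s) < cfg$dropout_prob] <- .MISSING
    code
  }
  calls <- matrix(.MISSING, nrow = n, ncol = s)
  for (i in seq_len(n)) {
    v <- cell_vec(truth$sample_1[i])
    if (!is.na(truth$sample_2[i])) {
      v <- merge_calls(v, cell_vec(truth$sample_2[i]))
    }
    calls[i, ] <- v
  }
  snp_call_matrix(calls, truth$cell_barcode, colnames(genotypes))
}

#' Simulate hashtag-oligo counts
#'
#' Every cell draws background counts `NB(background_mean,
#' background_size)` in every hashtag; a cell of sample `k` draws its own
#' hashtag from `NB(signal_mean * signal_scale + background_mean,
#' signal_size)`. A doublet's counts are the elementwise sum of its two
#' parents' simulated count vectors, so multisample doublets show elevated
#' counts in both parental hashtags. Lowering `signal_scale` collapses the
#' signal mode toward background, emulating degraded hashing quality.
#'
#' @param truth A `sim_truth` composition table.
#' @param cfg A [sim_config()].
#' @return Cells x hashtags integer matrix (hashtag `k` named after sample
#'   `k`).
#' @export
simulate_hashing <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  n <- nrow(truth)
  sn <- .sample_names(cfg)
  k <- length(sn)
  own_mu <- cfg$signal_mean * cfg$signal_scale + cfg$background_mean
  parent_counts <- function(sample_name) {
    v <- stats::rnbinom(k, mu = cfg$background_mean,
                        size = cfg$background_size)
    i <- match(sample_name, sn)
    v[i] <- stats::rnbinom(1L, mu = own_mu, size = cfg$signal_size)
    v
  }
  counts <- matrix(0L, nrow = n, ncol = k, dimnames = list(truth$cell_barcode,
                                                           sn))
  for (i in seq_len(n)) {
    v <- parent_counts(truth$sample_1[i])
    if (!is.na(truth$sample_2[i])) {
      v <- v + parent_counts(truth$sample_2[i])
    }
    counts[i, ] <- v
  }
  counts
}

#' Simulate a complete benchmark dataset
#'
#' Composes [simulate_genotypes()], [simulate_cell_composition()],
#' [simulate_snp_calls()] and [simulate_hashing()] into a row-aligned
#' synthetic dataset. Bit-for-bit reproducible for a fixed config.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_dataset`: `snp` (`snp_calls`), `hto`
#'   (count matrix), `truth` (`sim_truth`), `genotypes`, `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_cells = 300, n_snps = 100, seed = 42))
#' table(sim$truth$true_label)
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  genotypes <- simulate_genotypes(cfg)
  truth <- simulate_cell_composition(cfg)
  snp <- simulate_snp_calls(genotypes, truth, cfg)
  hto <- simulate_hashing(truth, cfg)
  structure(list(snp = snp, hto = hto, truth = truth,
                 genotypes = genotypes, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d cells, %d samples, %d SNPs, doublet rate %.2f\n",
              x$config$n_cells, x$config$n_samples, x$config$n_snps,
              x$config$doublet_rate))
  print(table(x$truth$true_label))
  invisible(x)
}
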