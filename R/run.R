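#' Build a simulator configuration from a plain list
#'
#' Convenience for YAML-driven runs: unknown fields abort.
#'
#' @param lst Named list of [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
sim_config_from_list <- function(lst) {
  if (is.null(lst)) return(sim_config())
  bad <- setdiff(names(lst), names(formals(sim_config)))
  if (length(bad)) {
    .stopf("unknown simulator field(s): %s", paste(bad, collapse = ", "))
  }
  do.call(sim_config, lst)
}

#' Read a YAML run configuration
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

.write_summary <- function(out_dir, name, fields) {
  fields$config_hash <- .config_hash(fields)
  fields$package_version <- as.character(utils::packageVersion("snpdemux"))
  path <- file.path(out_dir, name)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' Writes the SNP calls (`calls.mtx`, `barcodes.tsv`, `variants.tsv`),
#' hashing counts (`hto_counts.csv`), ground truth (`truth.tsv`) and a JSON
#' run summary into `out_dir`.
#'
#' @param cfg A [sim_config()], or a named list / YAML path of its fields.
#' @param out_dir Output directory.
#' @return Invisibly, the `sim_dataset`.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  if (!inherits(cfg, "sim_config")) cfg <- sim_config_from_list(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(cfg)
  write_snp_calls(sim$snp, out_dir)
  write_hto_counts(sim$hto, file.path(out_dir, "hto_counts.csv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_summary(out_dir, "simulate_summary.json",
                 c(unclass(cfg),
                   list(true_label_counts = as.list(table(sim$truth$true_label)))))
  invisible(sim)
}

#' Demultiplex from on-disk inputs
#'
#' Reads the VarTrix-style SNP matrix and hashing counts (or an external
#' call table), runs [demux()], and writes `assignments.tsv` plus a JSON
#' summary (class counts, tie count, unassignable count, seed, parameters).
#'
#' @param snp_mtx,barcodes,variants SNP matrix and sidecar paths
#'   ([read_vartrix()]).
#' @param hto_counts Hashing count CSV path (ignored when `hto_calls` is
#'   given).
#' @param hto_calls Optional external hashing call TSV
#'   ([read_hashing_calls()]).
#' @param out_dir Output directory.
#' @param acceptance,min_shared,min_train Passed to [demux()].
#' @param seed Recorded in the summary (the workflow itself is
#'   deterministic).
#' @return Invisibly, the `snp_demux` fit.
#' @export
run_demux <- function(snp_mtx, barcodes, variants, hto_counts = NULL,
                      hto_calls = NULL, out_dir, acceptance = 0.75,
                      min_shared = 5L, min_train = 10L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  snp <- read_vartrix(snp_mtx, barcodes, variants)
  calls <- NULL
  hto <- NULL
  if (!is.null(hto_calls)) {
    calls <- read_hashing_calls(hto_calls)
  } else if (!is.null(hto_counts)) {
    hto <- read_hto_counts(hto_counts)
  } else {
    .stopf("supply hto_counts or hto_calls")
  }
  fit <- demux(snp, hto = hto, calls = calls, acceptance = acceptance,
               min_shared = min_shared, min_train = min_train)
  write_assignments(fit, file.path(out_dir, "assignments.tsv"))
  .write_summary(out_dir, "demux_summary.json",
                 list(seed = seed,
                      acceptance = acceptance,
                      min_shared = min_shared,
                      min_train = min_train,
                      n_cells = nrow(fit$assignments),
                      label_counts = as.list(table(fit$assignments$label)),
                      provenance_counts =
                        as.list(table(fit$assignments$provenance)),
                      n_ties = fit$n_ties,
                      n_unassignable = fit$n_unassignable))
  invisible(fit)
}

#' Filter a VCF to SNPs inside the top expressed genes
#'
#' @param vcf Path to the candidate-variant VCF.
#' @param genes Path to gene intervals (BED or GFF).
#' @param rna_csv RNA count CSV, cells x genes, header row, first column
#'   the cell barcode; gene columns matched to interval `gene_id`s.
#' @param top_n Number of top expressed genes (default 100).
#' @param out Output TSV of retained variant positions.
#' @return Invisibly, the retained `snp_positions` rows.
#' @export
run_select_snps <- function(vcf, genes, rna_csv, top_n = 100L, out) {
  pos <- read_vcf_positions(vcf)
  iv <- read_gene_intervals(genes)
  df <- utils::read.csv(rna_csv, check.names = FALSE)
  rna <- as.matrix(df[, -1, drop = FALSE])
  ranked <- rank_genes_by_expression(rna, intervals = iv)
  idx <- filter_snps_to_genes(pos, ranked, top_n = top_n)
  write_filtered_variants(pos, idx, out)
  invisible(pos[idx, , drop = FALSE])
}

.hashing_only_accuracy <- function(truth, calls) {
  score(truth$true_label, calls$label, exclude = character(0))$accuracy
}

#' Find a signal scale producing a target hashing-only accuracy
#'
#' Degrades hashing quality by scaling the signal mean until the
#' hashing-only caller's overall accuracy (negatives and uncertains scored
#' as errors) falls inside `band`. Scales are tried in descending order;
#' when the accuracy jumps past the band between two grid points, the gap
#' is bisected in log space.
#'
#' @param cfg Base [sim_config()].
#' @param band Target accuracy interval (default `c(0.70, 0.85)`).
#' @param scales Descending grid of candidate scales.
#' @param max_bisect Maximum bisection refinements (default 8).
#' @return List: `signal_scale`, `hashing_accuracy`, `evaluations`
#'   (data frame of all probed scales).
#' @export
calibrate_signal_scale <- function(cfg, band = c(0.70, 0.85),
                                   scales = exp(seq(log(1), log(0.002),
                                                    length.out = 15)),
                                   max_bisect = 8L) {
  probe <- function(s) {
    cfg$signal_scale <- s
    sim <- simulate_dataset(cfg)
    calls <- call_hashing(sim$hto, acceptance = 0.75)
    .hashing_only_accuracy(sim$truth, calls)
  }
  evals <- data.frame(signal_scale = numeric(0), accuracy = numeric(0))
  above <- NULL
  for (s in sort(scales, decreasing = TRUE)) {
    acc <- probe(s)
    evals <- rbind(evals, data.frame(signal_scale = s, accuracy = acc))
    if (acc >= band[1] && acc <= band[2]) {
      return(list(signal_scale = s, hashing_accuracy = acc,
                  evaluations = evals))
    }
    if (acc > band[2]) {
      above <- s
    } else if (!is.null(above)) {
      lo <- s
      hi <- above
      for (i in seq_len(max_bisect)) {
        mid <- exp((log(lo) + log(hi)) / 2)
        acc <- probe(mid)
        evals <- rbind(evals,
                       data.frame(signal_scale = mid, accuracy = acc))
        if (acc >= band[1] && acc <= band[2]) {
          return(list(signal_scale = mid, hashing_accuracy = acc,
                      evaluations = evals))
        }
        if (acc > band[2]) hi <- mid else lo <- mid
      }
      break
    }
  }
  i <- which.min(abs(evals$accuracy - mean(band)))
  list(signal_scale = evals$signal_scale[i],
       hashing_accuracy = evals$accuracy[i], evaluations = evals)
}

#' Run a simulation benchmark grid
#'
#' Simulates one dataset per grid point (doublet rate x signal scale),
#' demultiplexes it, and scores the result against ground truth. Each grid
#' point gets its own seed derived from the base config's seed so points
#' are independent but the whole grid is reproducible.
#'
#' @param cfg Base [sim_config()].
#' @param doublet_rates Vector of doublet rates (default `seq(0.05, 0.5,
#'   0.05)`).
#' @param signal_scales Vector of hashing signal scales (default
#'   `c(1, 0.5, 0.25, 0.1)`).
#' @param acceptance,min_shared,min_train Passed to [demux()].
#' @param out_dir Optional directory; when given, per-point JSON reports
#'   and the aggregate TSV are written.
#' @return List: `table` (one row per grid point: accuracy, ARI,
#'   hashing-only accuracy, doublet precision/recall, unassignable count)
#'   and `reports` (the `eval_report`s).
#' @export
run_benchmark <- function(cfg = sim_config(),
                          doublet_rates = seq(0.05, 0.5, by = 0.05),
                          signal_scales = c(1, 0.5, 0.25, 0.1),
                          acceptance = 0.75, min_shared = 5L,
                          min_train = 10L, out_dir = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  grid <- expand.grid(doublet_rate = doublet_rates,
                      signal_scale = signal_scales)
  rows <- vector("list", nrow(grid))
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg
    cfg_i$doublet_rate <- grid$doublet_rate[i]
    cfg_i$signal_scale <- grid$signal_scale[i]
    cfg_i$seed <- cfg$seed + i
    sim <- simulate_dataset(cfg_i)
    calls <- call_hashing(sim$hto, acceptance = acceptance)
    fit <- demux(sim$snp, calls = calls, acceptance = acceptance,
                 min_shared = min_shared, min_train = min_train)
    pred <- fit$assignments$label[match(sim$truth$cell_barcode,
                                        fit$assignments$cell_barcode)]
    rep <- score(sim$truth$true_label, pred)
    da <- doublet_accounting(sim$truth, pred)
    rows[[i]] <- data.frame(doublet_rate = grid$doublet_rate[i],
                            signal_scale = grid$signal_scale[i],
                            n_cells = cfg$n_cells,
                            accuracy = rep$accuracy,
                            ari = rep$ari,
                            hashing_only_accuracy =
                              .hashing_only_accuracy(sim$truth, calls),
                            doublet_precision = da$precision,
                            doublet_recall = da$recall,
                            n_unassignable = rep$n_excluded)
    reports[[i]] <- rep
    if (!is.null(out_dir)) {
      write_eval_report(rep, file.path(out_dir,
                                       sprintf("report_rate%.2f_scale%.3g.json",
                                               grid$doublet_rate[i],
                                               grid$signal_scale[i])))
    }
  }
  table <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.table(table, file.path(out_dir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_summary(out_dir, "benchmark_summary.json",
                   list(seed = cfg$seed,
                        doublet_rates = doublet_rates,
                        signal_scales = signal_scales,
                        n_points = nrow(grid)))
  }
  list(table = table, reports = reports)
}
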