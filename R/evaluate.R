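#' Score predicted labels against ground truth
#'
#' Computes the confusion matrix, overall accuracy, per-class precision and
#' recall, and the adjusted Rand index between true and predicted label
#' vectors. Labels are semantically fixed (sample identities), so no
#' optimal label matching is applied. Cells whose predicted label is in
#' `exclude` (by default `UNASSIGNABLE`) are removed before scoring and
#' reported separately; pass `exclude = character(0)` to score every cell
#' (negatives and uncertains then count as errors).
#'
#' @param truth,predicted Character vectors of equal length, aligned by
#'   cell.
#' @param exclude Predicted labels to drop before scoring (default
#'   `"UNASSIGNABLE"`).
#' @return An `eval_report`: list with `confusion`, `accuracy`, `precision`,
#'   `recall` (named per class, `NA` where undefined), `ari`, `n_scored`,
#'   `n_excluded`, `excluded_counts`.
#' @export
#' @examples
#' score(c("A", "A", "A", "B", "B", "B"),
#'       c("A", "A", "B", "B", "B", "B"))
score <- function(truth, predicted, exclude = "UNASSIGNABLE") {
  if (length(truth) != length(predicted)) {
    .stopf("truth and predicted have different lengths (%d vs %d)",
           length(truth), length(predicted))
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (anyNA(truth) || anyNA(predicted)) .stopf("labels must not be NA")
  drop <- predicted %in% exclude
  excluded_counts <- table(predicted[drop])
  truth_s <- truth[!drop]
  pred_s <- predicted[!drop]
  if (!length(truth_s)) .stopf("no cells left to score after exclusion")
  levs <- sort(union(truth_s, pred_s))
  conf <- table(factor(truth_s, levs), factor(pred_s, levs),
                dnn = c("truth", "predicted"))
  acc <- sum(diag(conf)) / sum(conf)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), NA_real_)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), NA_real_)
  names(prec) <- names(rec) <- levs
  ari <- mclust::adjustedRandIndex(truth_s, pred_s)
  structure(list(confusion = conf, accuracy = acc, precision = prec,
                 recall = rec, ari = ari, n_scored = length(truth_s),
                 n_excluded = sum(drop), excluded_counts = excluded_counts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d (excluded %d)\n", x$n_scored,
              x$n_excluded))
  cat(sprintf("  accuracy %.4f   ARI %.4f\n", x$accuracy, x$ari))
  cat("  per-class precision / recall:\n")
  print(round(rbind(precision = x$precision, recall = x$recall), 3))
  invisible(x)
}

#' Multisample-doublet accounting
#'
#' Precision and recall for doublet detection under the standard
#' demultiplexing convention: only multisample doublets (two cells from
#' different samples) are positives; single-sample doublets count as
#' singlets, since no demultiplexer can see them.
#'
#' @param truth Either a `sim_truth` table or a character vector in which
#'   multisample doublets are labelled `"DOUBLET"`.
#' @param predicted Character vector of predicted labels.
#' @return List: `precision` (`NA` when nothing was called a doublet),
#'   `recall`, `n_true`, `n_called`, `n_true_positive`.
#' @export
doublet_accounting <- function(truth, predicted) {
  tl <- if (is.data.frame(truth)) truth$true_label else as.character(truth)
  if (length(tl) != length(predicted)) {
    .stopf("truth and predicted have different lengths")
  }
  pos <- tl == "DOUBLET"
  called <- predicted == "DOUBLET"
  tp <- sum(pos & called)
  list(precision = if (sum(called)) tp / sum(called) else NA_real_,
       recall = if (sum(pos)) tp / sum(pos) else NA_real_,
       n_true = sum(pos), n_called = sum(called), n_true_positive = tp)
}

# Sarle's bimodality coefficient; > 0.555 (the uniform's value) suggests
# more than one mode. NA for degenerate samples (n < 4 or zero variance).
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(NA_real_)
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Within-group pairwise SNP distance QC
#'
#' Computes the masked Jaccard distance between all unordered pairs of cells
#' assigned to the same group. Homogeneous groups (cells from one genotype)
#' give a unimodal distance distribution; groups contaminated by
#' misassigned cells from another genotype show a second, higher mode.
#' Modality is summarised with Sarle's bimodality coefficient (values above
#' 0.555 flag likely multimodality); the raw distances are returned for
#' inspection regardless.
#'
#' @param m,p Alt and coverage masks (cells x SNPs).
#' @param assigned_labels Per-cell group labels (length `nrow(m)`).
#' @param max_pairs Per group, subsample to at most this many pairs
#'   (default 5000).
#' @param seed Seed for the pair subsampling.
#' @return A list of class `within_group_dist`: `distances` (named list of
#'   per-group distance vectors) and `summary` (data frame with group size,
#'   pair count, quartiles, bimodality coefficient and flag). Singleton
#'   groups are skipped with a warning.
#' @export
within_group_distances <- function(m, p, assigned_labels, max_pairs = 5000L,
                                   seed = 1L) {
  if (nrow(m) != length(assigned_labels)) {
    .stopf("assigned_labels length does not match number of cells")
  }
  labels <- as.character(assigned_labels)
  groups <- sort(unique(labels))
  dist_list <- list()
  rows <- list()
  for (g in groups) {
    idx <- which(labels == g)
    if (length(idx) < 2L) {
      warning(sprintf("group %s has a single cell; skipped", g),
              call. = FALSE)
      next
    }
    mg <- as.matrix(m[idx, , drop = FALSE])
    pg <- as.matrix(p[idx, , drop = FALSE])
    d <- jaccard_missing(mg, pg, mg, pg)
    vals <- d[upper.tri(d)]
    if (length(vals) > max_pairs) {
      set.seed(seed)
      vals <- vals[sample.int(length(vals), max_pairs)]
    }
    bc <- bimodality_coefficient(vals)
    dist_list[[g]] <- vals
    rows[[g]] <- data.frame(group = g, n_cells = length(idx),
                            n_pairs = length(vals),
                            q1 = unname(stats::quantile(vals, 0.25)),
                            median = unname(stats::median(vals)),
                            q3 = unname(stats::quantile(vals, 0.75)),
                            bimodality = bc,
                            bimodal = !is.na(bc) && bc > 0.555,
                            stringsAsFactors = FALSE)
  }
  structure(list(distances = dist_list,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "within_group_dist")
}

#' @export
print.within_group_dist <- function(x, ...) {
  cat("Within-group masked Jaccard distances\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report` from [score()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(accuracy = report$accuracy,
              ari = report$ari,
              precision = as.list(report$precision),
              recall = as.list(report$recall),
              n_scored = report$n_scored,
              n_excluded = report$n_excluded,
              confusion = as.data.frame(report$confusion))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
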