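#' Infer per-sample consensus SNP profiles from confident singlets
#'
#' Computes the multivariate mode of each sample's confident cells: per SNP,
#' the modal call among covered cells (an ALT-vs-REF vote over cells with
#' reads at the locus). Loci with no covered call, or with an exact tie,
#' stay `MISSING`. Pooling calls across a sample's cells fills in most of
#' the per-cell dropout, giving a far more complete profile than any single
#' cell.
#'
#' @param m,p Alt and coverage masks of the confident cells
#'   (cells x SNPs, from [decompose_calls()]).
#' @param labels Character vector of per-cell sample labels (length
#'   `nrow(m)`).
#' @param min_train Minimum confident cells per sample (default 10); any
#'   sample below this aborts with a message listing the deficient samples.
#' @return A `centroid_set`: list with `profiles` (classes x SNPs ternary
#'   integer matrix), `class_labels`, `is_doublet` (all `FALSE` here) and
#'   `pairs`.
#' @seealso [build_doublet_centroids()], [predict_cells()]
#' @export
infer_singlet_centroids <- function(m, p, labels, min_train = 10L) {
  if (nrow(m) != length(labels)) {
    .stopf("labels length (%d) does not match number of cells (%d)",
           length(labels), nrow(m))
  }
  labels <- as.character(labels)
  tab <- table(labels)
  deficient <- names(tab)[tab < min_train]
  if (length(deficient)) {
    .stopf("samples with fewer than %d confident cells: %s",
           min_train, paste(deficient, collapse = ", "))
  }
  classes <- sort(names(tab))
  profiles <- matrix(.MISSING, nrow = length(classes), ncol = ncol(m),
                     dimnames = list(classes, colnames(m)))
  for (cl in classes) {
    idx <- which(labels == cl)
    alt <- Matrix::colSums(m[idx, , drop = FALSE])
    cov <- Matrix::colSums(p[idx, , drop = FALSE])
    ref <- cov - alt
    profiles[cl, alt > ref] <- .ALT
    profiles[cl, ref > alt] <- .REF
    # cov == 0 or alt == ref stays MISSING
  }
  structure(list(profiles = profiles,
                 class_labels = classes,
                 is_doublet = rep(FALSE, length(classes)),
                 pairs = matrix(NA_character_, length(classes), 2)),
            class = "centroid_set")
}

#' Add doublet profiles for every unordered sample pair
#'
#' A droplet containing cells of two samples pools both cells' reads, so its
#' expected profile is the union of the parents': per SNP `ALT` if either
#' parent is `ALT`, else `REF` if either is `REF`, else `MISSING`
#' ([merge_calls()]). With `K` singlet classes this appends `K(K-1)/2`
#' doublet classes labelled `"A+B"`.
#'
#' @param centroids A singlet-only `centroid_set` with at least 2 classes.
#' @return A `centroid_set` with `K + K(K-1)/2` classes.
#' @export
build_doublet_centroids <- function(centroids) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (any(centroids$is_doublet)) {
    .stopf("centroid set already contains doublet classes")
  }
  singlets <- centroids$class_labels
  if (length(singlets) < 2L) .stopf("need at least 2 singlet classes")
  pairs <- utils::combn(singlets, 2)
  dbl <- t(apply(pairs, 2L, function(pr) {
    merge_calls(centroids$profiles[pr[1], ], centroids$profiles[pr[2], ])
  }))
  rownames(dbl) <- apply(pairs, 2L, paste, collapse = "+")
  structure(list(profiles = rbind(centroids$profiles, dbl),
                 class_labels = c(singlets, rownames(dbl)),
                 is_doublet = c(rep(FALSE, length(singlets)),
                                rep(TRUE, ncol(pairs))),
                 pairs = rbind(centroids$pairs, t(pairs))),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("centroid_set: %d singlet + %d doublet classes, %d SNPs\n",
              sum(!x$is_doublet), sum(x$is_doublet), ncol(x$profiles)))
  invisible(x)
}

#' Jaccard distance between binary profiles with missing data
#'
#' Jaccard distance on alt-allele indicator vectors, masked so that loci
#' without reads in either of the two vectors being compared contribute
#' nothing. With alt mask `m` and coverage mask `p`, the agreement and
#' disagreement counts between every training row and every prediction row
#' are the matrix products
#' \deqn{a = (m_t p_t) (m_q p_q)^T,\quad
#'       b = ((1-m_t) p_t) (m_q p_q)^T,\quad
#'       c = (m_t p_t) ((1-m_q) p_q)^T,}
#' (elementwise products inside the parentheses), and the distance is
#' `1 - a/(a+b+c)`. Pairs with `a+b+c = 0` (no informative overlap) get the
#' sentinel distance 1 and are flagged.
#'
#' @param m_train,p_train Binary masks of the training profiles
#'   (classes x SNPs).
#' @param m_predict,p_predict Binary masks of the cells to score
#'   (cells x SNPs).
#' @return A classes x predict-cells distance matrix in `[0, 1]`, with
#'   attributes `"shared"` (jointly covered locus counts) and `"flagged"`
#'   (logical, `a+b+c == 0`).
#' @export
#' @examples
#' tr <- snp_call_matrix(rbind(c(2, 1, 2, 0)), "train", paste0("s", 1:4))
#' qu <- snp_call_matrix(rbind(c(2, 2, 0, 1)), "query", paste0("s", 1:4))
#' dt <- decompose_calls(tr); dq <- decompose_calls(qu)
#' jaccard_missing(dt$m, dt$p, dq$m, dq$p)  # a=1, b=1, c=0 -> 0.5
jaccard_missing <- function(m_train, p_train, m_predict, p_predict) {
  mt <- as.matrix(m_train); pt <- as.matrix(p_train)
  mq <- as.matrix(m_predict); pq <- as.matrix(p_predict)
  if (!(ncol(mt) == ncol(pt) && ncol(pt) == ncol(mq) &&
        ncol(mq) == ncol(pq))) {
    .stopf("all masks must have the same number of SNP columns")
  }
  if (!identical(dim(mt), dim(pt)) || !identical(dim(mq), dim(pq))) {
    .stopf("m and p must have equal dimensions on each side")
  }
  # the elementwise products mask out anything m claims at uncovered loci,
  # so stray alt bits where p = 0 can never influence a distance
  a <- (mt * pt) %*% t(mq * pq)
  b <- ((1 - mt) * pt) %*% t(mq * pq)
  cc <- (mt * pt) %*% t((1 - mq) * pq)
  tot <- a + b + cc
  d <- matrix(1, nrow(a), ncol(a), dimnames = dimnames(a))
  ok <- tot > 0
  d[ok] <- 1 - a[ok] / tot[ok]
  attr(d, "shared") <- pt %*% t(pq)
  attr(d, "flagged") <- !ok
  d
}

#' Nearest-centroid classification of cells
#'
#' Assigns each cell the label of its minimum-distance centroid under
#' [jaccard_missing()] (1-NN over class centroids). Cells sharing fewer than
#' `min_shared` covered loci with every centroid are `UNASSIGNABLE`. Exact
#' distance ties prefer a singlet class over a doublet class, then the
#' lowest class index; the number of tied decisions is recorded.
#'
#' @param centroids A `centroid_set` including doublet classes
#'   ([build_doublet_centroids()]).
#' @param m_predict,p_predict Masks of the cells to classify
#'   (cells x SNPs, SNP columns aligned with the centroids).
#' @param min_shared Minimum jointly covered loci required for assignment
#'   (default 5).
#' @return A data frame with one row per cell: `label` (sample name,
#'   `"DOUBLET"`, or `"UNASSIGNABLE"`), `nearest_class` (the winning class,
#'   e.g. `"A+B"` for doublets), `distance`, `shared_snps`; attribute
#'   `"n_ties"`.
#' @export
predict_cells <- function(centroids, m_predict, p_predict, min_shared = 5L) {
  stopifnot(inherits(centroids, "centroid_set"))
  if (!any(centroids$is_doublet)) {
    .stopf("centroids must include doublet classes; see build_doublet_centroids()")
  }
  prof <- centroids$profiles
  m_tr <- (prof == .ALT) * 1
  p_tr <- (prof != .MISSING) * 1
  d <- jaccard_missing(m_tr, p_tr, m_predict, p_predict)
  shared <- attr(d, "shared")
  n <- ncol(d)
  label <- character(n)
  nearest <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  sh <- integer(n)
  n_ties <- 0L
  for (j in seq_len(n)) {
    cand <- which(shared[, j] >= min_shared)
    if (!length(cand)) {
      label[j] <- "UNASSIGNABLE"
      sh[j] <- as.integer(max(shared[, j]))
      next
    }
    dj <- d[cand, j]
    best <- cand[dj <= min(dj) + 1e-12]
    if (length(best) > 1L) {
      n_ties <- n_ties + 1L
      sing <- best[!centroids$is_doublet[best]]
      best <- if (length(sing)) sing[1] else best[1]
    }
    nearest[j] <- centroids$class_labels[best]
    label[j] <- if (centroids$is_doublet[best]) "DOUBLET" else nearest[j]
    dist[j] <- d[best, j]
    sh[j] <- as.integer(shared[best, j])
  }
  out <- data.frame(label = label, nearest_class = nearest, distance = dist,
                    shared_snps = sh, stringsAsFactors = FALSE)
  if (!is.null(rownames(m_predict))) out$cell_barcode <- rownames(m_predict)
  attr(out, "n_ties") <- n_ties
  out
}

#' Demultiplex cells by hashing calls plus SNP-profile classification
#'
#' The full workflow: (1) classify hashing counts with the per-hashtag
#' negative-binomial mixture caller (or take an externally supplied call
#' table); (2) keep confident singlets as-is and use them to infer
#' per-sample consensus SNP profiles and all sample-pair doublet profiles;
#' (3) reassign every negative, uncertain and doublet cell to its
#' nearest profile under the missing-data-adapted Jaccard distance.
#'
#' @param snp An `snp_calls` object (cells x SNPs).
#' @param hto Cells x hashtags count matrix; ignored when `calls` is given.
#' @param calls Optional `hashing_calls` table (e.g. from another
#'   probabilistic hashing caller) with columns `cell_barcode` and `label`,
#'   where a confident singlet's label is its hashtag/sample name and
#'   other cells are `DOUBLET`, `NEGATIVE` or `UNCERTAIN`.
#' @param acceptance Posterior acceptance threshold for the built-in caller
#'   (default 0.75).
#' @param min_shared Minimum jointly covered loci for SNP assignment
#'   (default 5).
#' @param min_train Minimum confident cells per sample for centroid
#'   inference (default 10).
#' @return An object of class `snp_demux` with elements `assignments`
#'   (per-cell `cell_barcode`, `label`, `nearest_class`, `provenance`,
#'   `distance`, `shared_snps`), `centroids`, `calls`, `n_ties`,
#'   `n_unassignable`, and `params`. `label` is a sample name, `"DOUBLET"`
#'   or `"UNASSIGNABLE"`; `provenance` is `"HASHING"` for kept confident
#'   singlets and `"SNP_PREDICTED"` otherwise.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_cells = 400, n_snps = 200, seed = 7))
#' fit <- demux(sim$snp, sim$hto)
#' fit
demux <- function(snp, hto = NULL, calls = NULL, acceptance = 0.75,
                  min_shared = 5L, min_train = 10L) {
  stopifnot(inherits(snp, "snp_calls"))
  if (is.null(calls)) {
    if (is.null(hto)) .stopf("supply hashing counts (hto) or a call table")
    calls <- call_hashing(hto, acceptance = acceptance)
  }
  if (!all(c("cell_barcode", "label") %in% names(calls))) {
    .stopf("call table must have cell_barcode and label columns")
  }
  common <- intersect(snp$cell_barcodes, calls$cell_barcode)
  if (!length(common)) .stopf("no shared barcodes between SNP and hashing data")
  snp <- snp[common, ]
  lab <- calls$label[match(common, calls$cell_barcode)]

  confident <- !(lab %in% .RESERVED_LABELS)
  samples <- sort(unique(lab[confident]))
  if (length(samples) < 2L) {
    .stopf("fewer than 2 samples with confident singlets; cannot train")
  }
  masks <- decompose_calls(snp)
  cs <- infer_singlet_centroids(masks$m[confident, , drop = FALSE],
                                masks$p[confident, , drop = FALSE],
                                lab[confident], min_train = min_train)
  cs <- build_doublet_centroids(cs)

  assignments <- data.frame(cell_barcode = common,
                            label = lab,
                            nearest_class = lab,
                            provenance = "HASHING",
                            distance = NA_real_,
                            shared_snps = NA_integer_,
                            stringsAsFactors = FALSE)
  n_ties <- 0L
  if (any(!confident)) {
    pr <- predict_cells(cs, masks$m[!confident, , drop = FALSE],
                        masks$p[!confident, , drop = FALSE],
                        min_shared = min_shared)
    assignments$label[!confident] <- pr$label
    assignments$nearest_class[!confident] <- pr$nearest_class
    assignments$provenance[!confident] <- "SNP_PREDICTED"
    assignments$distance[!confident] <- pr$distance
    assignments$shared_snps[!confident] <- pr$shared_snps
    n_ties <- attr(pr, "n_ties")
  }
  structure(list(assignments = assignments,
                 centroids = cs,
                 calls = calls,
                 n_ties = n_ties,
                 n_unassignable = sum(assignments$label == "UNASSIGNABLE"),
                 params = list(acceptance = acceptance,
                               min_shared = min_shared,
                               min_train = min_train)),
            class = "snp_demux")
}

#' @export
print.snp_demux <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("snp_demux: %d cells, %d samples\n",
              nrow(a), sum(!x$centroids$is_doublet)))
  cat(sprintf("  hashing-confident singlets: %d; SNP-predicted: %d\n",
              sum(a$provenance == "HASHING"),
              sum(a$provenance == "SNP_PREDICTED")))
  cat(sprintf("  doublets: %d; unassignable: %d; distance ties: %d\n",
              sum(a$label == "DOUBLET"), x$n_unassignable, x$n_ties))
  invisible(x)
}

#' @export
summary.snp_demux <- function(object, ...) {
  a <- object$assignments
  tab <- table(label = a$label, provenance = a$provenance)
  pred <- a[a$provenance == "SNP_PREDICTED" & !is.na(a$distance), ]
  out <- list(label_by_provenance = tab,
              n_cells = nrow(a),
              n_ties = object$n_ties,
              n_unassignable = object$n_unassignable,
              distance_quartiles = if (nrow(pred))
                stats::quantile(pred$distance, c(0.25, 0.5, 0.75)) else NULL,
              params = object$params)
  class(out) <- "summary.snp_demux"
  out
}

#' @export
print.summary.snp_demux <- function(x, ...) {
  cat(sprintf("Demultiplexing summary (%d cells)\n", x$n_cells))
  print(x$label_by_provenance)
  if (!is.null(x$distance_quartiles)) {
    cat("nearest-centroid distance quartiles (SNP-predicted cells):\n")
    print(round(x$distance_quartiles, 3))
  }
  cat(sprintf("ties: %d  unassignable: %d\n", x$n_ties, x$n_unassignable))
  invisible(x)
}

#' @export
plot.snp_demux <- function(x, ...) {
  a <- x$assignments
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  tab <- table(a$label, a$provenance)
  graphics::barplot(t(tab), las = 2, col = c(grey(0.3), grey(0.7)),
                    main = "Final labels", ylab = "cells",
                    legend.text = colnames(tab), ...)
  pred <- a$distance[a$provenance == "SNP_PREDICTED" & !is.na(a$distance)]
  if (length(pred)) {
    graphics::hist(pred, breaks = 30, main = "Nearest-centroid distance",
                   xlab = "masked Jaccard distance", col = grey(0.7))
  }
  invisible(x)
}

#' Classify new cells against a fitted demultiplexer's centroids
#'
#' @param object A `snp_demux` fit.
#' @param newdata An `snp_calls` object with the same SNP panel.
#' @param ... Ignored.
#' @return A data frame as returned by [predict_cells()].
#' @export
predict.snp_demux <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "snp_calls"))
  if (!identical(newdata$snp_ids, colnames(object$centroids$profiles))) {
    .stopf("newdata SNP panel does not match the fitted centroids")
  }
  masks <- decompose_calls(newdata)
  predict_cells(object$centroids, masks$m, masks$p,
                min_shared = object$params$min_shared)
}
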