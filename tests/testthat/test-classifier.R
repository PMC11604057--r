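test_that("singlet centroids are per-SNP modes over covered calls", {
  x <- make_snp(rbind(c(2, 1, 0),
                      c(2, 2, 0),
                      c(1, 2, 2)))
  mk <- decompose_calls(x)
  cs <- infer_singlet_centroids(mk$m, mk$p, rep("A", 3), min_train = 3)
  expect_equal(unname(cs$profiles["A", ]), c(2, 2, 2))

  # a group of identical cells reproduces that profile
  y <- make_snp(rbind(c(2, 0, 1), c(2, 0, 1), c(2, 0, 1)))
  mky <- decompose_calls(y)
  csy <- infer_singlet_centroids(mky$m, mky$p, rep("A", 3), min_train = 3)
  expect_equal(unname(csy$profiles["A", ]), c(2, 0, 1))

  # exact ALT/REF tie and zero coverage both give MISSING
  z <- make_snp(rbind(c(2, 0), c(1, 0)))
  mkz <- decompose_calls(z)
  csz <- infer_singlet_centroids(mkz$m, mkz$p, rep("A", 2), min_train = 2)
  expect_equal(unname(csz$profiles["A", ]), c(0, 0))

  expect_error(infer_singlet_centroids(mk$m, mk$p, c("A", "A", "B"),
                                       min_train = 2),
               "B")
})

test_that("doublet centroids are the pairwise union of singlet profiles", {
  prof <- rbind(A = c(2, 1, 0), B = c(1, 1, 2))
  cs <- structure(list(profiles = prof, class_labels = c("A", "B"),
                       is_doublet = c(FALSE, FALSE),
                       pairs = matrix(NA_character_, 2, 2)),
                  class = "centroid_set")
  full <- build_doublet_centroids(cs)
  expect_equal(unname(full$profiles["A+B", ]), c(2, 1, 2))
  expect_identical(full$class_labels, c("A", "B", "A+B"))
  expect_false(any(full$pairs[3, 1] == full$pairs[3, 2]))

  # K = 6 gives 15 doublet classes, 21 in total
  prof6 <- matrix(sample(0:2, 6 * 10, replace = TRUE), 6,
                  dimnames = list(paste0("S", 1:6), NULL))
  cs6 <- structure(list(profiles = prof6, class_labels = paste0("S", 1:6),
                        is_doublet = rep(FALSE, 6),
                        pairs = matrix(NA_character_, 6, 2)),
                   class = "centroid_set")
  full6 <- build_doublet_centroids(cs6)
  expect_identical(sum(full6$is_doublet), 15L)
  expect_identical(length(full6$class_labels), 21L)
})

test_that("masked Jaccard matches hand-computed contingency cases", {
  tr <- make_snp(rbind(c(2, 1, 2, 0)))
  qu <- make_snp(rbind(c(2, 2, 0, 1)))
  dt <- decompose_calls(tr); dq <- decompose_calls(qu)
  d <- jaccard_missing(dt$m, dt$p, dq$m, dq$p)
  expect_equal(as.numeric(d), 0.5)  # a=1, b=1, c=0 over loci 1-2

  allalt <- make_snp(rbind(c(2, 2, 2)))
  allref <- make_snp(rbind(c(1, 1, 1)))
  da <- decompose_calls(allalt); dr <- decompose_calls(allref)
  expect_equal(as.numeric(jaccard_missing(da$m, da$p, da$m, da$p)), 0)
  expect_equal(as.numeric(jaccard_missing(da$m, da$p, dr$m, dr$p)), 1)

  # no informative overlap -> sentinel 1 and flag
  drr <- decompose_calls(make_snp(rbind(c(1, 1, 1))))
  d0 <- jaccard_missing(drr$m, drr$p, drr$m, drr$p)
  expect_equal(as.numeric(d0), 1)
  expect_true(attr(d0, "flagged")[1, 1])
})

test_that("masked Jaccard equals the brute-force contingency oracle", {
  set.seed(201)
  for (rep in 1:200) {
    nt <- sample(1:20, 1); nq <- sample(1:20, 1); s <- sample(1:30, 1)
    tr <- random_masks(nt, s); qu <- random_masks(nq, s)
    d <- jaccard_missing(tr$m, tr$p, qu$m, qu$p)
    expect_equal(as_plain(d), jaccard_brute(tr$m, tr$p, qu$m, qu$p),
                 tolerance = 1e-14)
  }
})

test_that("with full coverage the distance reduces to binary Jaccard", {
  skip_if_not_installed("vegan")
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(3:10, 1); s <- sample(5:30, 1)
    m <- matrix(rbinom(n * s, 1, 0.5), n)
    p <- matrix(1, n, s)
    d <- jaccard_missing(m, p, m, p)
    ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    keep <- rowSums(m) > 0  # vegdist leaves empty vectors undefined
    expect_equal(unname(d[keep, keep]), unname(ref[keep, keep]),
                 tolerance = 1e-12)
  }
})

test_that("distance is mask-invariant, symmetric and permutation-invariant", {
  set.seed(203)
  a <- random_masks(8, 25); b <- random_masks(6, 25)
  d <- jaccard_missing(a$m, a$p, b$m, b$p)

  # flipping m where p = 0 changes nothing
  m2 <- a$m
  hidden <- a$p == 0
  m2[hidden] <- 1 - m2[hidden]
  d_dirty <- jaccard_missing(m2, a$p, b$m, b$p)
  expect_equal(as_plain(d_dirty), as_plain(d),
               tolerance = 1e-14)

  # swapping train/predict transposes the distance
  expect_equal(t(as_plain(jaccard_missing(b$m, b$p, a$m, a$p))),
               as_plain(d), tolerance = 1e-14)

  # permuting SNP columns identically on both sides changes nothing
  perm <- sample(25)
  dp <- jaccard_missing(a$m[, perm], a$p[, perm], b$m[, perm], b$p[, perm])
  expect_equal(as_plain(dp), as_plain(d), tolerance = 1e-14)
})

test_that("predict_cells assigns nearest centroid and flags no-coverage cells", {
  set.seed(204)
  prof <- matrix(sample(1:2, 3 * 40, replace = TRUE), 3,
                 dimnames = list(c("A", "B", "C"), NULL))
  cs <- structure(list(profiles = prof, class_labels = c("A", "B", "C"),
                       is_doublet = rep(FALSE, 3),
                       pairs = matrix(NA_character_, 3, 2)),
                  class = "centroid_set")
  cs <- build_doublet_centroids(cs)

  cells <- rbind(prof["C", ],                      # exact copy of C
                 merge_calls(prof["A", ], prof["B", ]),  # perfect A+B doublet
                 rep(0, 40))                       # no coverage at all
  m <- (cells == 2) * 1; p <- (cells != 0) * 1
  pr <- predict_cells(cs, m, p, min_shared = 5)
  expect_identical(pr$label[1], "C")
  expect_equal(pr$distance[1], 0)
  expect_identical(pr$label[2], "DOUBLET")
  expect_identical(pr$nearest_class[2], "A+B")
  expect_equal(pr$distance[2], 0)
  expect_identical(pr$label[3], "UNASSIGNABLE")
  expect_true(is.na(pr$distance[3]))
})

test_that("demux keeps confident singlets and re-predicts the rest", {
  set.seed(205)
  sim <- simulate_dataset(sim_config(n_cells = 600, n_snps = 300, seed = 205))
  # all-confident call table: output must equal the hashing calls
  calls <- data.frame(cell_barcode = sim$truth$cell_barcode,
                      label = sim$truth$sample_1,
                      stringsAsFactors = FALSE)
  fit <- demux(sim$snp, calls = calls)
  expect_identical(fit$assignments$label, calls$label)
  expect_true(all(fit$assignments$provenance == "HASHING"))

  # withheld singlets (forced NEGATIVE) are recovered from their SNPs
  real <- call_hashing(sim$hto)
  conf <- which(!(real$label %in% c("DOUBLET", "NEGATIVE", "UNCERTAIN")) &
                  sim$truth$true_label != "DOUBLET")
  withheld <- sample(conf, round(0.3 * length(conf)))
  real$label[withheld] <- "NEGATIVE"
  fit2 <- demux(sim$snp, calls = real)
  a <- fit2$assignments
  expect_true(all(a$provenance[withheld] == "SNP_PREDICTED"))
  rec <- mean(a$label[withheld] == sim$truth$true_label[withheld])
  expect_gte(rec, 0.9)
  expect_identical(sum(a$label == "NEGATIVE"), 0L)
})

test_that("demux propagates UNASSIGNABLE and validates its inputs", {
  set.seed(206)
  sim <- simulate_dataset(sim_config(n_cells = 400, n_snps = 200, seed = 206))
  calls <- call_hashing(sim$hto)
  # blank out one cell's SNP row and force it through prediction
  victim <- 5L
  calls$label[victim] <- "NEGATIVE"
  dense <- as.matrix(sim$snp$calls)
  dense[victim, ] <- 0
  snp <- snp_call_matrix(dense)
  fit <- demux(snp, calls = calls)
  expect_identical(fit$assignments$label[victim], "UNASSIGNABLE")
  expect_identical(fit$n_unassignable, 1L)

  # disjoint barcodes
  bad <- calls
  bad$cell_barcode <- paste0("other_", seq_len(nrow(bad)))
  expect_error(demux(snp, calls = bad), "no shared barcodes")

  # a single confident sample cannot train the classifier
  one <- calls
  one$label[!(one$label %in% c("DOUBLET", "NEGATIVE", "UNCERTAIN"))] <- "Sample1"
  expect_error(demux(snp, calls = one), "fewer than 2 samples")
})

test_that("predict method classifies new cells against fitted centroids", {
  set.seed(207)
  sim <- simulate_dataset(sim_config(n_cells = 500, n_snps = 250, seed = 207))
  fit <- demux(sim$snp, sim$hto)
  new_cfg <- sim_config(n_cells = 100, n_snps = 250, seed = 208)
  new <- simulate_dataset(new_cfg)
  # same genotypes are re-drawn per seed, so rebuild calls from fit genotypes
  snp_new <- simulate_snp_calls(sim$genotypes, new$truth, new_cfg)
  pr <- predict(fit, snp_new)
  singles <- new$truth$true_label != "DOUBLET"
  expect_gte(mean(pr$label[singles] == new$truth$true_label[singles]), 0.9)
})
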