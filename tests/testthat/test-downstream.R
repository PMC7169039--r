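test_that("differential accessibility is calibrated under the null", {
  m <- null_count_matrix(n_peaks = 1000, n_cells = 40, seed = 1)
  norm <- tfidf(m)
  g1 <- colnames(m)[1:20]; g2 <- colnames(m)[21:40]
  da <- diff_accessibility(norm, g1, g2)
  expect_lte(sum(da$qval < 0.05), 2)       # near-zero false positives
  expect_true(all(da$pval > 0 & da$pval <= 1))
})

test_that("fully separated groups reach the exact minimal rank-sum p", {
  set.seed(2)
  X <- matrix(c(rnorm(20, 10, 0.1), rnorm(20, 0, 0.1)), 1, 40,
              dimnames = list("pk", paste0("s", 1:40)))
  da <- diff_accessibility(X, paste0("s", 1:20), paste0("s", 21:40))
  # disjoint supports, no ties: two-sided exact p = 2 / C(40, 20)
  expect_equal(da$pval, 2 / choose(40, 20))
  expect_lt(da$qval, 0.05)
})

test_that("swapping the groups negates the fold change only", {
  m <- null_count_matrix(n_peaks = 50, n_cells = 20, seed = 3)
  norm <- tfidf(m)
  g1 <- colnames(m)[1:10]; g2 <- colnames(m)[11:20]
  a <- diff_accessibility(norm, g1, g2)
  b <- diff_accessibility(norm, g2, g1)
  data.table::setkey(a, feature); data.table::setkey(b, feature)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$pval, b$pval)
  expect_error(diff_accessibility(norm, g1, c(g2, g1[1])), "disjoint")
  expect_error(diff_accessibility(norm, g1[1:2], g2), ">= 3 cells")
})

test_that("variable-peak selection takes the top ceiling(fraction * k)", {
  m <- null_count_matrix(n_peaks = 1000, n_cells = 30, seed = 4)
  expect_length(select_variable_peaks(m), 300)
  expect_length(select_variable_peaks(m, 1), 1000)
  # at equal depth, a constant peak never outranks varying ones
  set.seed(5)
  eq <- matrix(rpois(20 * 10, 5), 20, 10)
  eq[1, ] <- 5L
  eq <- rbind(eq, max(colSums(eq)) - colSums(eq) + 1L)  # equalize depths
  eqm <- as(as(eq, "generalMatrix"), "CsparseMatrix")
  dimnames(eqm) <- list(paste0("p", seq_len(nrow(eq))),
                        paste0("c", seq_len(ncol(eq))))
  expect_false(1L %in% select_variable_peaks(eqm, 0.1))
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(50:500, 1))^sample(1:3, 1)
    # agreement to floating-point associativity
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("motif deviations are null-centered and detect planted signal", {
  m <- null_count_matrix(n_peaks = 500, n_cells = 120, seed = 1)
  set.seed(1)
  mm <- matrix(rbinom(500 * 20, 1, 0.1), 500, 20,
               dimnames = list(rownames(m), paste0("mo", 1:20)))
  gc <- rbeta(500, 5, 5)
  dev <- motif_deviation_scores(m, mm, gc, seed = 1)
  expect_length(dev$selected, ceiling(0.30 * 500))
  expect_lt(max(abs(rowMeans(dev$z, na.rm = TRUE)), na.rm = TRUE), 0.2)
  # planted: motif 1's peaks boosted 3x in half the cells
  m2 <- as.matrix(m)
  boost <- seq_len(60)
  m2[mm[, 1] == 1, boost] <- m2[mm[, 1] == 1, boost] * 3L
  m2 <- as(as(m2, "generalMatrix"), "CsparseMatrix")
  dev2 <- motif_deviation_scores(m2, mm, gc, seed = 1)
  gap <- mean(dev2$z[1, boost], na.rm = TRUE) -
    mean(dev2$z[1, -boost], na.rm = TRUE)
  expect_gt(gap, 1)
  # motif spanning every selected peak: background equals foreground
  mm_all <- matrix(1L, 500, 1, dimnames = list(rownames(m), "all"))
  dev3 <- motif_deviation_scores(m, mm_all, gc, seed = 1)
  expect_lt(mean(abs(dev3$z), na.rm = TRUE), 0.5)
  # a motif with no member among the selected peaks is a sentinel row
  mm_none <- matrix(0L, 500, 1, dimnames = list(rownames(m), "empty"))
  dev4 <- motif_deviation_scores(m, mm_none, gc, seed = 1)
  expect_true(all(is.na(dev4$z)))
})

test_that("per-cluster TF ranking finds the planted motif and stays null-calibrated", {
  m <- null_count_matrix(n_peaks = 500, n_cells = 120, seed = 1)
  set.seed(1)
  mm <- matrix(rbinom(500 * 20, 1, 0.1), 500, 20,
               dimnames = list(rownames(m), paste0("mo", 1:20)))
  gc <- rbeta(500, 5, 5)
  m2 <- as.matrix(m)
  boost <- seq_len(60)
  m2[mm[, 1] == 1, boost] <- m2[mm[, 1] == 1, boost] * 3L
  m2 <- as(as(m2, "generalMatrix"), "CsparseMatrix")
  dev <- motif_deviation_scores(m2, mm, gc, seed = 1)
  labels <- setNames(rep(c(0L, 1L), each = 60), colnames(m2))
  enr <- enriched_tfs_per_cluster(dev, labels)
  expect_identical(enr[cluster == 0]$motif[1], "mo1")
  # random labels: about nominal false-positive rate
  dev_null <- motif_deviation_scores(m, mm, gc, seed = 1)
  set.seed(7)
  rand <- setNames(sample(rep(c(0L, 1L), each = 60)), colnames(m))
  enr_null <- enriched_tfs_per_cluster(dev_null, rand)
  expect_lte(mean(enr_null$qval < 0.05), 0.10)
  # two identical clusters: nothing significant
  dup_z <- dev_null
  dup_z$z <- cbind(dev_null$z[, 1:60], dev_null$z[, 1:60])
  colnames(dup_z$z) <- paste0("cell", seq_len(120))
  lab2 <- setNames(rep(c(0L, 1L), each = 60), colnames(dup_z$z))
  enr2 <- enriched_tfs_per_cluster(dup_z, lab2)
  expect_equal(sum(enr2$qval < 0.05), 0)
})

test_that("cluster tracks apply the RPKM formula and its invariances", {
  set.seed(8)
  n <- 10000
  st <- as.integer(floor(runif(n) * 99000))
  dt <- data.table(chrom = "chr1", start = st, end = st + 100L,
                   barcode = "B1", dup_count = 1L)
  dt <- unique(dt, by = c("chrom", "start", "end", "barcode"))
  ft <- fragment_table(dt)
  labels <- c(B1 = 0L)
  tr <- cluster_tracks(ft, labels, c(chr1 = 100000L), bin = 1000L)[["0"]]
  total <- nrow(dt)
  one <- tr[start == 0]
  raw_count <- sum(dt$start >= 0 & dt$start < 1000)
  expect_equal(one$rpkm, raw_count / ((1000 / 1000) * (total / 1e6)))
  # conservation: sum(RPKM * bin_kb) = 1e6 when every fragment is binned
  expect_equal(sum(tr$rpkm * (tr$end - tr$start) / 1000), 1e6)
  # uniform duplication leaves the track unchanged
  dt2 <- rbind(dt, data.table(chrom = dt$chrom, start = dt$start, end = dt$end,
                              barcode = "B2", dup_count = dt$dup_count))
  tr2 <- cluster_tracks(fragment_table(dt2), c(B1 = 0L, B2 = 0L),
                        c(chr1 = 100000L), bin = 1000L)[["0"]]
  expect_equal(tr2$rpkm, tr$rpkm)
  # bedGraph files are written per cluster
  d <- withr::local_tempdir()
  cluster_tracks(ft, labels, c(chr1 = 100000L), bin = 1000L, dir = d)
  expect_true(file.exists(file.path(d, "cluster_0.bedGraph")))
})
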