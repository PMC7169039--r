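toy_counts <- function() {
  m <- sparseMatrix(i = 1:2, j = 1:2, x = c(1, 1), dims = c(2, 2),
                    dimnames = list(c("chr1:0-100", "chr1:100-200"),
                                    c("A", "B")))
  as(m, "CsparseMatrix")
}

test_that("TF-IDF matches its closed form and binarization invariance", {
  m <- toy_counts()
  out <- tfidf(m)
  # TF = I, IDF_i = log(1 + 2/(1+1)) = log 2
  expect_equal(as.matrix(out), log(2) * diag(2), ignore_attr = TRUE)
  # scaling counts changes nothing
  expect_equal(as.matrix(tfidf(m * 7)), as.matrix(out))
  # ubiquitous peaks get the smallest IDF weight
  set.seed(1)
  big <- as(as(matrix(rbinom(300, 1, 0.3), 30, 10), "generalMatrix"),
            "CsparseMatrix")
  big[1, ] <- 1  # accessible everywhere
  big <- big[, Matrix::colSums(big) > 0]
  dimnames(big) <- list(paste0("chr1:", 0:29 * 100, "-", 0:29 * 100 + 50),
                        paste0("c", seq_len(ncol(big))))
  B <- big; B@x <- rep(1, length(B@x))
  idf <- log(1 + ncol(B) / (1 + Matrix::rowSums(B)))
  expect_equal(unname(which.min(idf)), 1L)
  z <- toy_counts(); z[, 2] <- 0
  expect_error(tfidf(z), "all-zero column")
})

test_that("log-regression residuals are orthogonal to depth", {
  set.seed(2)
  depth <- round(rlnorm(50, log(1000), 0.8))
  base <- runif(20, 0.5, 2)
  m <- as(as(round(outer(base, depth) / 50), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(paste0("chr1:", 0:19 * 100, "-", 0:19 * 100 + 50),
                      paste0("c", 1:50))
  res <- lognorm_regress(m)
  ld <- log(Matrix::colSums(m))
  for (i in c(1, 10, 20))
    expect_lt(abs(cor(res[i, ], ld)), 1e-10)
  # constant depth: row-centered log counts with a warning
  cm <- as(as(matrix(3, 5, 4), "generalMatrix"), "CsparseMatrix")
  dimnames(cm) <- list(paste0("chr1:", 0:4 * 10, "-", 0:4 * 10 + 5),
                       paste0("c", 1:4))
  expect_warning(rc <- lognorm_regress(cm), "constant depth")
  expect_equal(max(abs(rc)), 0)
})

test_that("depth regression reduces depth leakage into the leading PC", {
  # single population whose counts scale with a strongly variable depth
  set.seed(3)
  n_cells <- 80; n_peaks <- 200
  depth <- round(rlnorm(n_cells, log(500), 1.0))
  base <- rgamma(n_peaks, 2, 2); base <- base / sum(base)
  m <- as(as(matrix(rpois(n_peaks * n_cells, outer(base, depth)),
                    n_peaks, n_cells), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(paste0("chr1:", seq_len(n_peaks) * 1000, "-",
                             seq_len(n_peaks) * 1000 + 400),
                      paste0("c", seq_len(n_cells)))
  ld <- log(Matrix::colSums(m))
  pre <- pca_fast(log1p(as.matrix(m)), n_components = 5, depth = NULL)
  post <- pca_fast(lognorm_regress(m), n_components = 5, depth = NULL)
  expect_lt(abs(cor(post$coordinates[, 1], ld)),
            abs(cor(pre$coordinates[, 1], ld)))
})

test_that("fast PCA is deterministic, orthogonal and depth-stable", {
  set.seed(4)
  # enough cells that a chance depth correlation (~1/sqrt(n)) is negligible
  X <- matrix(rnorm(100 * 500), 100, 500)   # features x cells, structure-free
  dimnames(X) <- list(paste0("f", 1:100), paste0("c", 1:500))
  depth <- round(rlnorm(500, log(1000), 0.4))  # independent of the data
  r1 <- pca_fast(X, n_components = 10, depth = depth)
  r2 <- pca_fast(X, n_components = 10, depth = depth)
  expect_identical(r1$coordinates, r2$coordinates)
  raw <- pca_fast(X, n_components = 10, depth = NULL)
  # components are mutually orthogonal before regression
  cp <- crossprod(raw$coordinates)
  expect_lt(max(abs(cp[upper.tri(cp)])) / nrow(X), 1e-8)
  # independent depth: residual PCs track the raw PCs
  for (k in 1:5)
    expect_gte(abs(cor(raw$coordinates[, k], r1$coordinates[, k])), 0.99)
  small <- X[1:30, 1:20]
  expect_warning(pca_fast(small, n_components = 25), "truncated")
})

test_that("SNN graph separates distant blobs and bounds its weights", {
  set.seed(5)
  blob1 <- matrix(rnorm(40 * 5), 40, 5)
  blob2 <- matrix(rnorm(40 * 5) + 100, 40, 5)
  coords <- rbind(blob1, blob2)
  rownames(coords) <- paste0("c", 1:80)
  g <- snn_graph(coords, k = 10)
  w <- igraph::E(g)$weight
  expect_true(all(w >= 0 & w <= 1))
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_false(any(el[, 1] <= 40 & el[, 2] > 40))
  expect_false(any(el[, 1] > 40 & el[, 2] <= 40))
  # identical points: complete graph at weight 1
  same <- matrix(1, 10, 3); rownames(same) <- paste0("s", 1:10)
  gs <- suppressWarnings(snn_graph(same, k = 5))
  expect_equal(igraph::ecount(gs), choose(10, 2))
  expect_true(all(igraph::E(gs)$weight == 1))
  expect_warning(snn_graph(matrix(rnorm(12), 4, 3), k = 20), "reducing k")
})

test_that("Louvain clustering is reproducible and resolution-monotone", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("v", 1:20)
  cl <- louvain_cluster(g, seed = 1)
  expect_equal(length(unique(cl$labels)), 2)
  expect_identical(cl$labels, louvain_cluster(g, seed = 1)$labels)
  # labels renumbered from 0 by decreasing size
  expect_equal(sort(unique(cl$labels)), c(0L, 1L))
  # more resolution never fewer clusters on a fixed random graph
  set.seed(6)
  gr <- igraph::sample_gnp(60, 0.12)
  igraph::V(gr)$name <- paste0("n", 1:60)
  igraph::E(gr)$weight <- runif(igraph::ecount(gr))
  n_cl <- vapply(c(0.4, 0.8, 1.2), function(res)
    length(unique(louvain_cluster(gr, resolution = res, seed = 2)$labels)), 0L)
  expect_true(all(diff(n_cl) >= 0))
  # edgeless graph: singletons with a warning
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- paste0("x", 1:3)
  expect_warning(cl0 <- louvain_cluster(g0), "no edges")
  expect_equal(sort(unname(cl0$labels)), 0:2)
})

test_that("the default clustering path separates simulated cell types", {
  spec <- noise_sim_spec(noise_profile(), q = 0, cells_per_type = 100L, seed = 3)
  sim <- simulate_noise_counts(spec)
  cl <- cluster_counts(sim$counts, seed = 1)
  expect_gte(adjusted_rand_index(sim$labels, cl$labels[names(sim$labels)]), 0.95)
  # deterministic 2-D embedding is just the leading components
  red <- pca_fast(tfidf(sim$counts), depth = Matrix::colSums(sim$counts))
  em <- embed_2d(red)
  expect_identical(em, red$coordinates[, 1:2])
})
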