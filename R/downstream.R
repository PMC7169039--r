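#' Differential accessibility between two groups of cells
#'
#' Two-sided Wilcoxon rank-sum test per peak on normalized accessibility,
#' Benjamini-Hochberg adjusted across peaks. The fold change is
#' `log2((mean1 + eps) / (mean2 + eps))` with `eps = 1e-9`.
#'
#' @param norm normalized features x cells matrix (dense or sparse).
#' @param group1,group2 disjoint character/integer vectors of cell columns,
#'   each of size >= 3.
#' @return data.table with `feature`, `mean1`, `mean2`, `log2fc`, `pval`,
#'   `qval`, sorted by `pval`.
#' @export
diff_accessibility <- function(norm, group1, group2) {
  idx <- function(g) if (is.character(g)) match(g, colnames(norm)) else as.integer(g)
  i1 <- idx(group1); i2 <- idx(group2)
  if (anyNA(i1) || anyNA(i2)) stop("unknown cells in group specification")
  if (length(intersect(i1, i2))) stop("groups must be disjoint")
  if (length(i1) < 3 || length(i2) < 3) stop("each group needs >= 3 cells")
  X <- as.matrix(norm)
  eps <- 1e-9
  m1 <- rowMeans(X[, i1, drop = FALSE])
  m2 <- rowMeans(X[, i2, drop = FALSE])
  pv <- vapply(seq_len(nrow(X)), function(i) {
    suppressWarnings(wilcox.test(X[i, i1], X[i, i2])$p.value)
  }, numeric(1))
  pv[is.na(pv)] <- 1  # constant peak across both groups
  ratio <- (m1 + eps) / (m2 + eps)
  out <- data.table(
    feature = if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(nrow(X))),
    mean1 = m1, mean2 = m2,
    # a negative mean (possible on residual-normalized input) has no
    # meaningful fold change
    log2fc = data.table::fifelse(ratio > 0, log2(pmax(ratio, 1e-300)), NA_real_),
    pval = pv, qval = p.adjust(pv, method = "BH"))
  setorder(out, pval)
  out[]
}

#' Select the most variable peaks
#'
#' Peaks ranked by the variance of their depth-normalized counts
#' (`x_ij / depth_j`); the top `ceiling(fraction * n_peaks)` are returned.
#'
#' @param m features x cells count matrix.
#' @param fraction fraction of peaks to keep (default 0.30).
#' @return integer vector of selected row indices (descending variance).
#' @export
select_variable_peaks <- function(m, fraction = 0.30) {
  stopifnot(fraction > 0, fraction <= 1)
  depth <- Matrix::colSums(m)
  depth[depth == 0] <- 1
  Xn <- as.matrix(m %*% Diagonal(x = 1 / depth))
  v <- apply(Xn, 1, var)
  n_keep <- ceiling(fraction * nrow(m))
  order(v, decreasing = TRUE)[seq_len(n_keep)]
}

#' Per-cell motif deviation z-scores
#'
#' chromVAR-style gain/loss-of-accessibility scores. The matrix is first
#' restricted to the top `fraction` most variable peaks. For each motif and
#' cell, the observed count over the motif's peaks is compared with the
#' expectation under the cell's depth and the peaks' mean accessibility
#' (`e_i = rowsum_i / total`): `d = (o - E) / E`. The raw deviation is
#' z-scored against `n_background` background peak sets in which every
#' motif peak is replaced by one of its nearest neighbours in standardized
#' (GC content, mean accessibility) space — iteration `b` uses each peak's
#' `b`-th nearest neighbour, so no background peak is reused for the same
#' peak across iterations.
#'
#' @param m features x cells count matrix.
#' @param motif_membership peaks x motifs binary matrix (rows aligned with
#'   `m`), logical or 0/1.
#' @param gc per-peak GC fraction in `[0, 1]`.
#' @param n_background number of background sets.
#' @param fraction variable-peak fraction (default 0.30).
#' @param seed RNG seed (distance tie-breaking).
#' @return list of class `motif_deviation`: `z` (motifs x cells; `NA` rows
#'   for motifs with no member peak after selection), `deviation` (raw
#'   d), `selected` (row indices of selected peaks), `background`
#'   (selected-peaks x n_background matrix of background indices), `seed`.
#' @export
motif_deviation_scores <- function(m, motif_membership, gc,
                                   n_background = 50L, fraction = 0.30,
                                   seed = 1L) {
  stopifnot(nrow(motif_membership) == nrow(m), length(gc) == nrow(m),
            all(gc >= 0 & gc <= 1))
  sel <- sort(select_variable_peaks(m, fraction))
  X <- as.matrix(m[sel, , drop = FALSE])
  M <- as.matrix(motif_membership[sel, , drop = FALSE]) != 0
  gcs <- gc[sel]
  depth <- colSums(X)
  total <- sum(X)
  e <- rowSums(X) / total
  dev_of <- function(idx) {
    o <- colSums(X[idx, , drop = FALSE])
    E <- depth * sum(e[idx])
    ifelse(E > 0, (o - E) / E, NA_real_)
  }
  # neighbor order in standardized (gc, mean accessibility) space
  zsc <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  set.seed(seed)
  feat <- cbind(zsc(gcs), zsc(e)) + matrix(stats::rnorm(2L * length(sel), sd = 1e-9),
                                           ncol = 2)  # deterministic tie-break
  D <- as.matrix(dist(feat))
  diag(D) <- Inf
  n_sel <- length(sel)
  n_bg <- min(n_background, n_sel - 1L)
  if (n_bg < n_background)
    warning("too few selected peaks; using ", n_bg, " background sets")
  nb_order <- apply(D, 1, function(d) order(d)[seq_len(n_bg)])  # n_bg x n_sel
  n_motifs <- ncol(M)
  z <- dmat <- matrix(NA_real_, n_motifs, ncol(X),
                      dimnames = list(colnames(motif_membership), colnames(m)))
  for (mm in seq_len(n_motifs)) {
    members <- which(M[, mm])
    if (!length(members)) next
    d_obs <- dev_of(members)
    bg <- matrix(0, n_bg, ncol(X))
    for (b in seq_len(n_bg)) bg[b, ] <- dev_of(nb_order[b, members])
    mu_bg <- colMeans(bg)
    sd_bg <- apply(bg, 2, sd)
    dmat[mm, ] <- d_obs
    z[mm, ] <- ifelse(sd_bg > 1e-12, (d_obs - mu_bg) / sd_bg, NA_real_)
  }
  structure(list(z = z, deviation = dmat, selected = sel,
                 background = t(nb_order), n_background = n_bg, seed = seed),
            class = "motif_deviation")
}

#' Per-cluster enriched transcription factors
#'
#' For every motif and cluster, a one-sided Wilcoxon rank-sum test of the
#' motif's deviation z-scores in the cluster against all other cells
#' (alternative: greater), Benjamini-Hochberg adjusted across motifs within
#' each cluster and ranked by q-value then effect size (difference of mean
#' z).
#'
#' @param dev a [motif_deviation_scores()] result.
#' @param clusters a `cluster_assignment` or named label vector covering
#'   the scored cells.
#' @return data.table with `cluster`, `motif`, `effect`, `pval`, `qval`,
#'   ordered within cluster by (`qval`, `-effect`).
#' @export
enriched_tfs_per_cluster <- function(dev, clusters) {
  labels <- if (is(clusters, "cluster_assignment")) clusters$labels else clusters
  cells <- colnames(dev$z)
  if (!all(cells %in% names(labels)))
    stop("clusters must cover all scored cells")
  lab <- labels[cells]
  res <- list()
  for (cl in sort(unique(lab))) {
    in_cl <- lab == cl
    if (sum(in_cl) < 2) {
      warning("singleton cluster ", cl, " skipped")
      next
    }
    pv <- eff <- rep(NA_real_, nrow(dev$z))
    for (mm in seq_len(nrow(dev$z))) {
      zi <- dev$z[mm, ]
      if (all(is.na(zi))) next
      pv[mm] <- suppressWarnings(
        wilcox.test(zi[in_cl], zi[!in_cl], alternative = "greater")$p.value)
      eff[mm] <- mean(zi[in_cl], na.rm = TRUE) - mean(zi[!in_cl], na.rm = TRUE)
    }
    keep <- !is.na(pv)
    dtc <- data.table(cluster = cl, motif = rownames(dev$z)[keep],
                      effect = eff[keep], pval = pv[keep],
                      qval = p.adjust(pv[keep], method = "BH"))
    setorder(dtc, qval, -effect)
    res[[as.character(cl)]] <- dtc
  }
  if (!length(res)) return(data.table(cluster = integer(), motif = character(),
                                      effect = numeric(), pval = numeric(),
                                      qval = numeric()))
  data.table::rbindlist(res)
}

#' Per-cluster RPKM coverage tracks
#'
#' Bins the genome at `bin` bp, counts each cluster's fragments by start
#' position (one count per fragment) and converts to reads per kilobase
#' per million mapped fragments:
#' `RPKM = count / ((bin / 1000) * (cluster_total / 1e6))`. Zero bins are
#' omitted. Tracks can be written as 4-column bedGraph files.
#'
#' @param frags a [fragment_table()].
#' @param clusters `cluster_assignment` or named label vector
#'   (barcode -> cluster); unlabeled barcodes are ignored.
#' @param chrom_sizes named integer vector.
#' @param bin bin width (bp).
#' @param dir optional output directory; when given, one
#'   `cluster_<label>.bedGraph` per cluster is written.
#' @return named list (per cluster) of data.tables
#'   (`chrom`, `start`, `end`, `rpkm`), 0-based half-open.
#' @export
cluster_tracks <- function(frags, clusters, chrom_sizes, bin = 50L,
                           dir = NULL) {
  labels <- if (is(clusters, "cluster_assignment")) clusters$labels else clusters
  dt <- as.data.table(frags)
  dt <- dt[barcode %in% names(labels)]
  dt[, cluster := labels[barcode]]
  dt <- dt[!is.na(cluster)]
  if (nrow(dt) == 0) stop("no fragments belong to a labeled cluster")
  out <- list()
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cl in sort(unique(dt$cluster))) {
    sub <- dt[cluster == cl]
    total <- nrow(sub)
    sub[, bin_start := (start %/% bin) * bin]
    tr <- sub[, .(count = .N), by = .(chrom, bin_start)]
    tr[, `:=`(start = bin_start,
              end = pmin(bin_start + bin, chrom_sizes[chrom]),
              rpkm = count / ((bin / 1000) * (total / 1e6)))]
    setorder(tr, chrom, start)
    tr <- tr[, .(chrom, start, end, rpkm)]
    out[[as.character(cl)]] <- tr
    if (!is.null(dir))
      fwrite(tr, file.path(dir, paste0("cluster_", cl, ".bedGraph")),
             sep = "\t", col.names = FALSE)
  }
  out
}
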