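#' Peak-caller parameters
#'
#' @param window sliding-window width (bp).
#' @param step window step (bp, `<= window`).
#' @param local_bg half-width of the local background used for the local
#'   Poisson rate (bp).
#' @param qvalue_cutoff Benjamini-Hochberg FDR cutoff.
#' @param min_frags_per_window minimum fragment count for a window to be
#'   reported.
#' @return list of class `peak_call_params`.
#' @export
peak_call_params <- function(window = 200L, step = 100L, local_bg = 10000L,
                             qvalue_cutoff = 0.05, min_frags_per_window = 5L) {
  stopifnot(step <= window, qvalue_cutoff > 0, qvalue_cutoff < 1,
            window > 0, local_bg >= window)
  structure(list(window = window, step = step, local_bg = local_bg,
                 qvalue_cutoff = qvalue_cutoff,
                 min_frags_per_window = min_frags_per_window),
            class = "peak_call_params")
}

#' Sliding-window Poisson peak caller
#'
#' Scores sliding windows by their fragment-overlap count against a Poisson
#' null whose rate is the larger of the genome-wide fragment rate and the
#' local rate in a `+/- local_bg` neighbourhood (both per bp, scaled to the
#' window width). Window p-values are Benjamini-Hochberg adjusted;
#' significant windows (`q < qvalue_cutoff` and count >=
#' `min_frags_per_window`) that overlap or touch are merged into peaks.
#' Each peak carries its summit (maximum-coverage base) and the smallest
#' constituent q-value.
#'
#' @param frags a [fragment_table()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param params a [peak_call_params()].
#' @return `GRanges` of peaks with mcols `name`, `score` (`-log10 q`),
#'   `summit`, `qvalue`, sorted.
#' @export
call_peaks_poisson <- function(frags, chrom_sizes, params = peak_call_params()) {
  dt <- as.data.table(frags)
  if (nrow(dt) == 0) {
    warning("no fragments; returning empty peak set")
    return(GRanges())
  }
  gr <- fragments_to_granges(frags)
  chrs <- GRanges(names(chrom_sizes), IRanges(1L, unname(chrom_sizes)))
  win <- unlist(GenomicRanges::slidingWindows(chrs, width = params$window,
                                              step = params$step))
  win <- win[GenomicRanges::width(win) == params$window]
  cnt <- countOverlaps(win, gr)
  # a fragment of width f overlaps a w-bp window iff its start falls in a
  # (w + f - 1)-bp interval, so the expected overlap count of a window is the
  # per-bp fragment-start rate times this effective width
  mean_fw <- mean(GenomicRanges::width(gr))
  eff_w <- params$window + mean_fw - 1
  genome_rate <- length(gr) / sum(as.numeric(chrom_sizes))
  loc <- suppressWarnings(resize(win, width = 2L * params$local_bg + params$window,
                                 fix = "center"))
  loc <- GenomicRanges::trim(loc)
  local_rate <- countOverlaps(loc, gr) /
    (GenomicRanges::width(loc) + mean_fw - 1)
  lambda <- eff_w * pmax(genome_rate, local_rate)
  p <- ppois(cnt - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- q < params$qvalue_cutoff & cnt >= params$min_frags_per_window
  if (!any(sig)) return(GRanges())
  peaks <- reduce(win[sig])
  # summit + q-value per merged peak
  cov <- coverage(gr)
  summit <- integer(length(peaks)); qv <- numeric(length(peaks))
  hitw <- findOverlaps(peaks, win[sig])
  qs <- q[sig]
  for (i in seq_along(peaks)) {
    qv[i] <- min(qs[subjectHits(hitw)[queryHits(hitw) == i]])
    chr <- as.character(seqnames(peaks))[i]
    v <- cov[[chr]][start(peaks)[i]:end(peaks)[i]]
    summit[i] <- start(peaks)[i] + which.max(as.numeric(v)) - 1L
  }
  mcols(peaks)$name <- paste0("peak_", seq_along(peaks))
  mcols(peaks)$score <- round(-log10(pmax(qv, 1e-300)), 3)
  mcols(peaks)$summit <- summit
  mcols(peaks)$qvalue <- qv
  sort(peaks)
}

#' Cluster barcodes on genome bins
#'
#' First stage of the combined peak-calling strategy: barcodes with fewer
#' than `prefilter_min` unique fragments are removed (kept iff `>=
#' prefilter_min`), the survivors are counted over fixed genome bins, and
#' the bin matrix is taken through TF-IDF, fast PCA and SNN-Louvain
#' clustering. Excluded barcodes are labeled `NA` (unassigned).
#'
#' @param frags a [fragment_table()].
#' @param chrom_sizes named integer vector.
#' @param prefilter_min minimum unique fragments per barcode.
#' @param bin_size genome bin width (bp).
#' @param n_components number of principal components.
#' @param resolution Louvain resolution.
#' @param k SNN neighbors.
#' @param seed RNG seed.
#' @return named integer vector: cluster label (0-based) per barcode,
#'   `NA` for barcodes below the prefilter.
#' @export
cluster_barcodes_on_bins <- function(frags, chrom_sizes, prefilter_min = 1000L,
                                     bin_size = 5000L, n_components = 30L,
                                     resolution = 0.8, k = 20L, seed = 1L) {
  dt <- as.data.table(frags)
  nfrag <- dt[, .N, by = barcode]
  keep <- nfrag$barcode[nfrag$N >= prefilter_min]
  if (length(keep) < 2)
    stop("fewer than 2 barcodes pass the prefilter (", prefilter_min, ")")
  bins <- make_bins(chrom_sizes, bin_size)
  m <- count_features(frags, bins, barcodes = sort(keep))
  m <- m[Matrix::rowSums(m) > 0, , drop = FALSE]
  norm <- tfidf(m)
  red <- pca_fast(norm, n_components = n_components,
                  depth = Matrix::colSums(m))
  g <- snn_graph(red, k = k)
  cl <- louvain_cluster(g, resolution = resolution, seed = seed)
  out <- rep(NA_integer_, nrow(nfrag))
  names(out) <- nfrag$barcode
  out[names(cl$labels)] <- cl$labels
  out
}

#' Combined two-step peak calling
#'
#' Calls peaks per cell cluster rather than once on the pooled data, so
#' that peaks private to rare populations are not drowned out by the
#' majority: barcodes are clustered on a bin-level matrix, the internal
#' Poisson caller runs on each cluster's fragments, the per-cluster peak
#' sets are pooled and merged (`merge_close`, 200 bp default) and peaks
#' overlapping the blacklist are removed. Summits are recomputed on the
#' pooled coverage; each peak records the clusters that contributed to it.
#'
#' @param frags a [fragment_table()].
#' @param chrom_sizes named integer vector.
#' @param blacklist optional `GRanges` of excluded regions.
#' @param params a [peak_call_params()].
#' @param prefilter_min,bin_size,n_components,resolution,k,seed passed to
#'   [cluster_barcodes_on_bins()].
#' @param merge_gap merge distance for pooled peaks (bp).
#' @return sorted disjoint `GRanges` with mcols `name`, `clusters`
#'   (comma-separated contributing cluster labels), `summit`.
#' @export
call_peaks_combined <- function(frags, chrom_sizes, blacklist = NULL,
                                params = peak_call_params(),
                                prefilter_min = 1000L, bin_size = 5000L,
                                n_components = 30L, resolution = 0.8,
                                k = 20L, seed = 1L, merge_gap = 200L) {
  labels <- cluster_barcodes_on_bins(frags, chrom_sizes,
                                     prefilter_min = prefilter_min,
                                     bin_size = bin_size,
                                     n_components = n_components,
                                     resolution = resolution, k = k,
                                     seed = seed)
  dt <- as.data.table(frags)
  percl <- list()
  for (cl in sort(unique(labels[!is.na(labels)]))) {
    bcs <- names(labels)[!is.na(labels) & labels == cl]
    sub <- fragment_table(dt[barcode %in% bcs])
    pk <- call_peaks_poisson(sub, chrom_sizes, params)
    if (length(pk)) {
      mcols(pk)$cluster <- cl
      percl[[as.character(cl)]] <- pk
    }
  }
  if (!length(percl)) return(GRanges())
  pooled <- suppressWarnings(do.call(c, unname(percl)))
  merged <- merge_close(pooled, max_gap = merge_gap)
  merged <- remove_blacklist(merged, blacklist)
  if (!length(merged)) return(merged)
  hits <- findOverlaps(merged, pooled)
  contrib <- vapply(seq_along(merged), function(i) {
    cls <- sort(unique(mcols(pooled)$cluster[subjectHits(hits)[queryHits(hits) == i]]))
    paste(cls, collapse = ",")
  }, "")
  cov <- coverage(fragments_to_granges(frags))
  summit <- vapply(seq_along(merged), function(i) {
    chr <- as.character(seqnames(merged))[i]
    v <- cov[[chr]][start(merged)[i]:end(merged)[i]]
    start(merged)[i] + which.max(as.numeric(v)) - 1L
  }, integer(1))
  mcols(merged)$name <- paste0("peak_", seq_along(merged))
  mcols(merged)$clusters <- contrib
  mcols(merged)$summit <- summit
  merged
}
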