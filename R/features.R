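#' Tile the genome into fixed-width bins
#'
#' Consecutive `[i*b, (i+1)*b)` bins per chromosome; the trailing partial
#' bin is kept so the bins cover the genome exactly.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_size bin width in bp (default 5000).
#' @return `GRanges` of bins, ordered by chromosome then position.
#' @export
make_bins <- function(chrom_sizes, bin_size = 5000L) {
  stopifnot(bin_size > 0, all(chrom_sizes > 0))
  bins <- tileGenome(chrom_sizes, tilewidth = bin_size,
                     cut.last.tile.in.chrom = TRUE)
  unname(bins)
}

#' Count fragments per feature per barcode
#'
#' Entry (i, j) is the number of unique fragments of barcode j overlapping
#' feature i by at least one base; a fragment spanning several features
#' increments each of them, but a feature at most once per fragment.
#'
#' @param frags a [fragment_table()].
#' @param features `GRanges` of features (bins or peaks).
#' @param barcodes barcodes to keep as columns; defaults to all barcodes in
#'   `frags` (sorted). Fragments from other barcodes are ignored.
#' @return sparse integer `dgCMatrix`, features x barcodes, with
#'   `chrom:start-end` rownames.
#' @export
count_features <- function(frags, features, barcodes = NULL) {
  dt <- as.data.table(frags)
  if (is.null(barcodes)) barcodes <- sort(unique(dt$barcode))
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  ids <- granges_to_id(features)
  if (anyDuplicated(ids)) stop("duplicate feature intervals")
  gr <- fragments_to_granges(frags)
  j <- match(dt$barcode, barcodes)
  keep <- !is.na(j)
  hits <- findOverlaps(gr[keep], features)
  m <- sparseMatrix(i = subjectHits(hits), j = j[keep][queryHits(hits)],
                    x = 1L, dims = c(length(features), length(barcodes)),
                    dimnames = list(ids, barcodes))
  as(m, "CsparseMatrix")
}

#' Remove features overlapping a blacklist
#'
#' @param features `GRanges`.
#' @param blacklist `GRanges` of excluded regions; any >= 1 bp overlap
#'   removes the feature.
#' @return filtered `GRanges`.
#' @export
remove_blacklist <- function(features, blacklist) {
  if (is.null(blacklist) || length(blacklist) == 0) return(features)
  features[!overlapsAny(features, blacklist)]
}

#' Merge intervals closer than a gap threshold
#'
#' Intervals that overlap, touch, or are separated by fewer than `max_gap`
#' bases are unioned transitively; the result is sorted and disjoint with
#' all pairwise gaps >= `max_gap`. With the default 200 bp, two peaks
#' "less than 200 bp apart" (gap <= 199) are merged; a gap of exactly
#' 200 bp keeps them separate.
#'
#' @param intervals `GRanges`.
#' @param max_gap minimum separating gap that prevents merging (bp).
#' @return merged `GRanges`.
#' @export
merge_close <- function(intervals, max_gap = 200L) {
  stopifnot(max_gap >= 0)
  reduce(sort(intervals), min.gapwidth = max_gap)
}
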