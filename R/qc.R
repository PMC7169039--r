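#' Per-barcode quality metrics
#'
#' Computes, for every barcode in a fragment table, the total (duplicate
#' weighted) read count, the number of unique fragments, the fraction of
#' unique fragments in peaks (FRiP), the mitochondrial fraction and the
#' fraction overlapping each supplied annotation class. A fragment counts
#' toward a class when it overlaps any interval of that class by at least
#' one base, and at most once per class.
#'
#' @param frags a [fragment_table()].
#' @param peaks `GRanges` of called peaks (may be empty).
#' @param annotations named list of `GRanges` (e.g. promoter, enhancer, tss);
#'   each adds a `frac_<name>` column.
#' @param mito_chroms chromosome names counted as mitochondrial.
#' @return data.table keyed by barcode with columns `total_reads`,
#'   `unique_frags`, `frip`, `frac_mito`, `frac_<annotation>` and `is_cell`
#'   (`NA` until a cell-calling step fills it).
#' @export
per_barcode_qc <- function(frags, peaks, annotations = list(),
                           mito_chroms = MITO_ALIASES) {
  dt <- as.data.table(frags)
  if (nrow(dt) == 0) {
    out <- data.table(barcode = character(), total_reads = integer(),
                      unique_frags = integer(), frip = numeric(),
                      frac_mito = numeric(), is_cell = logical())
    return(out)
  }
  gr <- fragments_to_granges(frags)
  ovl <- function(subj) {  # disjoint seqlevels (e.g. chrM-only) are fine
    if (!length(subj)) return(FALSE)
    suppressWarnings(overlapsAny(gr, subj))
  }
  dt <- data.table(barcode = dt$barcode, dup_count = dt$dup_count,
                   in_peak = ovl(peaks),
                   is_mito = dt$chrom %in% mito_chroms)
  for (nm in names(annotations))
    data.table::set(dt, j = paste0("in_", nm), value = ovl(annotations[[nm]]))
  frac_cols <- if (length(annotations)) paste0("in_", names(annotations))
               else character(0)
  qc <- dt[, c(list(total_reads = sum(dup_count), unique_frags = .N,
                    frip = mean(in_peak), frac_mito = mean(is_mito)),
               lapply(.SD, mean)),
           by = barcode, .SDcols = frac_cols]
  if (length(frac_cols))
    data.table::setnames(qc, frac_cols, sub("^in_", "frac_", frac_cols))
  qc[, is_cell := NA]
  data.table::setkey(qc, barcode)
  qc[]
}

#' Insert-size distribution
#'
#' Histogram of fragment spans (`end - start`), one count per unique
#' fragment. Sizes above `max_size` are pooled into a single overflow bin
#' reported at `max_size + 1`, so the histogram mass always equals the
#' number of fragments.
#'
#' @param frags a [fragment_table()].
#' @param max_size largest size kept as its own bin (bp).
#' @return data.table of (`size`, `count`), sizes ascending.
#' @export
insert_size_distribution <- function(frags, max_size = 1000L) {
  stopifnot(max_size > 0)
  dt <- as.data.table(frags)
  if (nrow(dt) == 0) return(data.table(size = integer(), count = integer()))
  size <- pmin(dt$end - dt$start, max_size + 1L)
  out <- data.table(size = size)[, .(count = .N), by = size]
  setorder(out, size)
  out[]
}

#' Transcription start site enrichment profile
#'
#' Both ends of every fragment are treated as Tn5 insertion events (the
#' first and last covered base). Insertions are accumulated by offset from
#' each TSS over `-window..+window`, with offsets mirrored for minus-strand
#' sites. The profile is normalized by the mean signal over the outermost
#' `flank` positions on both sides; the enrichment score is the maximum of
#' the normalized profile after smoothing with a `smooth`-bp moving average.
#'
#' @param frags a [fragment_table()].
#' @param tss `GRanges` of single-base TSS positions with strand.
#' @param window half-width of the profile window (bp).
#' @param flank number of outermost positions (each side) used as background.
#' @param smooth moving-average width (bp, odd).
#' @return list of class `tss_profile`: `position` (-window..window),
#'   `signal`, `norm_signal`, `score` (`NA` when the flank signal is zero).
#' @export
tss_enrichment <- function(frags, tss, window = 2000L, flank = 100L,
                           smooth = 51L) {
  stopifnot(window > 0, flank > 0, flank <= window, smooth %% 2 == 1)
  dt <- as.data.table(frags)
  positions <- seq(-window, window)
  signal <- numeric(2L * window + 1L)
  if (nrow(dt) > 0 && length(tss) > 0) {
    # insertion sites in 0-based coordinates: start and end - 1
    ins <- GRanges(rep(dt$chrom, 2L),
                   IRanges(c(dt$start, dt$end - 1L) + 1L, width = 1L))
    win <- suppressWarnings(resize(tss, width = 2L * window + 1L, fix = "center"))
    hits <- findOverlaps(ins, win, ignore.strand = TRUE)
    if (length(hits)) {
      off <- start(ins)[queryHits(hits)] - start(tss)[subjectHits(hits)]
      minus <- as.character(strand(tss))[subjectHits(hits)] == "-"
      off[minus] <- -off[minus]
      keep <- abs(off) <= window
      tab <- tabulate(off[keep] + window + 1L, nbins = 2L * window + 1L)
      signal <- as.numeric(tab)
    }
  }
  flank_idx <- c(seq_len(flank), length(signal) - seq_len(flank) + 1L)
  fm <- mean(signal[flank_idx])
  if (fm > 0) {
    norm_signal <- signal / fm
    sm <- stats::filter(norm_signal, rep(1 / smooth, smooth), sides = 2)
    score <- max(sm, na.rm = TRUE)
  } else {
    norm_signal <- rep(NA_real_, length(signal))
    score <- NA_real_
  }
  structure(list(position = positions, signal = signal,
                 norm_signal = norm_signal, score = score),
            class = "tss_profile")
}

#' Library complexity estimate
#'
#' Estimates the number of distinct molecules `C` in a library from the
#' total read count `N` and the observed number of unique fragments `U` by
#' inverting the Lander-Waterman relation `U = C * (1 - exp(-N / C))`
#' (bisection, relative tolerance 1e-6). Returns `NA` when `U == N`
#' (no duplication observed, `C` unbounded).
#'
#' @param total_reads `N`, duplicate-weighted read count.
#' @param unique_frags `U`, number of distinct fragments observed.
#' @return estimated distinct-molecule count, `>= U`.
#' @export
library_complexity <- function(total_reads, unique_frags) {
  N <- as.numeric(total_reads); U <- as.numeric(unique_frags)
  if (U > N) stop("unique_frags must not exceed total_reads")
  if (U <= 0) stop("unique_frags must be positive")
  if (U == N) return(NA_real_)
  f <- function(C) C * (1 - exp(-N / C)) - U
  lo <- U
  hi <- U
  while (f(hi) < 0 && hi < U * 1e12) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) / mid < 1e-6) break
  }
  (lo + hi) / 2
}

#' Aggregate library-level quality statistics
#'
#' Summaries over all barcodes and, where marked, over called cells only:
#' duplication rate, mitochondrial and in-peak fractions (fragment
#' weighted), library complexity, number of cells, median fragments per
#' cell and the fraction of duplicate-weighted reads belonging to cells.
#' Cell-restricted fields are `NA` when no cell calls are available.
#'
#' @param qc a [per_barcode_qc()] table (with `is_cell` filled for the
#'   cell-restricted fields).
#' @param frags optional [fragment_table()] (unused fields are derived from
#'   `qc`; kept for API symmetry).
#' @return named list of aggregate metrics.
#' @export
aggregate_qc <- function(qc, frags = NULL) {
  tot <- sum(qc$total_reads); uni <- sum(qc$unique_frags)
  w <- qc$unique_frags
  wmean <- function(x) if (sum(w) > 0) sum(x * w) / sum(w) else NA_real_
  cells <- !is.na(qc$is_cell) & qc$is_cell
  out <- list(
    total_reads = tot,
    total_unique_frags = uni,
    duplicate_rate = if (tot > 0) 1 - uni / tot else NA_real_,
    frac_mito = wmean(qc$frac_mito),
    frac_in_peaks = wmean(qc$frip),
    frac_in_promoters = if ("frac_promoter" %in% names(qc))
      wmean(qc$frac_promoter) else NA_real_,
    library_complexity_estimate =
      if (tot > 0 && uni > 0) library_complexity(tot, uni) else NA_real_,
    n_cells_called = if (all(is.na(qc$is_cell))) NA_integer_ else sum(cells),
    median_frags_per_cell = if (any(cells))
      as.numeric(median(qc$unique_frags[cells])) else NA_real_,
    frac_reads_in_cells = if (any(cells) && tot > 0)
      sum(qc$total_reads[cells]) / tot else NA_real_
  )
  out
}
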