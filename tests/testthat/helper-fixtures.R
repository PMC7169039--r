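suppressPackageStartupMessages({
  library(data.table)
  library(Matrix)
  library(GenomicRanges)
})

# three-fragment toy table used across the IO/QC tests
tiny_fragments <- function() {
  fragment_table(data.table(
    chrom = c("chr1", "chr1", "chrM"),
    start = c(100L, 200L, 5L),
    end = c(250L, 350L, 105L),
    barcode = c("BC1", "BC2", "BC1"),
    dup_count = c(1L, 2L, 1L),
    mapq = c(60L, 29L, 30L)))
}

# random valid fragment table for round-trip properties
random_fragments <- function(n, seed, with_mapq = TRUE) {
  set.seed(seed)
  st <- as.integer(floor(runif(n) * 1e5))
  dt <- data.table(chrom = sample(c("chr1", "chr2", "chrM"), n, TRUE),
                   start = st, end = st + sample(30:500, n, TRUE),
                   barcode = sprintf("BC%03d", sample(50, n, TRUE)),
                   dup_count = 1L + rpois(n, 0.5))
  if (with_mapq) dt[, mapq := sample(0:60, n, TRUE)]
  dt <- unique(dt, by = c("chrom", "start", "end", "barcode"))
  fragment_table(dt)
}

# uniform fragments over one chromosome (homogeneous Poisson background)
uniform_fragments <- function(n, chrom_len, seed, frag_width = 150L,
                              n_barcodes = 200L, chrom = "chr1") {
  set.seed(seed)
  st <- as.integer(floor(runif(n) * (chrom_len - frag_width - 1)))
  fragment_table(data.table(
    chrom = chrom, start = st, end = st + frag_width,
    barcode = sprintf("BC%04d", sample(n_barcodes, n, TRUE)),
    dup_count = 1L))
}

# two cell populations with disjoint peak sets on a 10-Mb chromosome; the
# rare population (5%) additionally carries a weak private peak tuned to be
# invisible against the pooled background but clear within the rare subset
rare_population_fragments <- function(seed = 11, n_major = 570L, n_rare = 30L,
                                      depth = 1200L) {
  set.seed(seed)
  chrom_len <- 10000000L
  maj_peaks <- seq(50000L, 9000000L, by = 450000L)[1:20]
  rare_peaks <- maj_peaks + 200000L
  private_start <- 9500000L
  make_pop <- function(bcs, peak_starts, private_frac) {
    n <- length(bcs) * depth
    u <- runif(n)
    in_peak <- u < 0.6 * (1 - private_frac)
    in_priv <- !in_peak & u < 0.6
    st <- integer(n)
    pk <- sample(peak_starts, n, TRUE)
    st[in_peak] <- pk[in_peak] + as.integer(floor(runif(sum(in_peak)) * 400)) - 75L
    st[in_priv] <- private_start + as.integer(floor(runif(sum(in_priv)) * 400)) - 75L
    bg <- !in_peak & !in_priv
    st[bg] <- as.integer(floor(runif(sum(bg)) * (chrom_len - 500)))
    data.table(chrom = "chr1", start = pmax(st, 0L), end = pmax(st, 0L) + 150L,
               barcode = rep(bcs, each = depth), dup_count = 1L)
  }
  maj <- make_pop(sprintf("MAJ%03d", seq_len(n_major)), maj_peaks, 0)
  rar <- make_pop(sprintf("RARE%03d", seq_len(n_rare)), rare_peaks, 0.0008)
  list(fragments = fragment_table(rbind(maj, rar)),
       chrom_sizes = c(chr1 = chrom_len),
       private = GRanges("chr1", IRanges(private_start + 1L,
                                         private_start + 400L)))
}

# depth-structured Poisson count matrix with no cell-type structure
null_count_matrix <- function(n_peaks = 500L, n_cells = 120L, seed = 1,
                              depth_sdlog = 0.4) {
  set.seed(seed)
  depth <- round(rlnorm(n_cells, log(2000), depth_sdlog))
  base <- rgamma(n_peaks, 2, 2); base <- base / sum(base)
  m <- matrix(rpois(n_peaks * n_cells, outer(base, depth)), n_peaks, n_cells,
              dimnames = list(paste0("chr1:", (seq_len(n_peaks) - 1) * 1000,
                                     "-", (seq_len(n_peaks) - 1) * 1000 + 400),
                              paste0("cell", seq_len(n_cells))))
  as(as(m, "generalMatrix"), "CsparseMatrix")
}

# memoised full default pipeline run shared by pipeline & acceptance tests
pipeline_cached <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !dir.exists(dir)) {
      d <- file.path(tempdir(), "pipeline_default_run")
      cfg <- pipeline_config(output_dir = d, seed = 1)
      suppressWarnings(run_step("all", config = cfg))
      dir <<- d
    }
    dir
  }
})
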