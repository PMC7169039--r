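test_that("per-barcode metrics count each fragment at most once per class", {
  # one barcode, 4 unique fragments, 2 overlapping peaks -> FRiP 0.5
  ft <- fragment_table(data.table(chrom = "chr1",
                                  start = c(100L, 300L, 700L, 900L),
                                  end = c(200L, 400L, 800L, 1000L),
                                  barcode = "BC1", dup_count = 1L))
  peaks <- GRanges("chr1", IRanges(c(150, 350), c(220, 420)))
  qc <- per_barcode_qc(ft, peaks)
  expect_equal(qc$frip, 0.5)
  expect_equal(qc$unique_frags, 4L)

  # a fragment spanning two adjacent peaks still counts once
  span <- fragment_table(data.table(chrom = "chr1", start = 100L, end = 400L,
                                    barcode = "BC1", dup_count = 1L))
  two_peaks <- GRanges("chr1", IRanges(c(101, 301), c(200, 400)))
  expect_equal(per_barcode_qc(span, two_peaks)$frip, 1)

  # fully mitochondrial barcode
  mito <- fragment_table(data.table(chrom = "chrM", start = c(1L, 50L),
                                    end = c(100L, 150L), barcode = "BCM",
                                    dup_count = 1L))
  expect_equal(per_barcode_qc(mito, peaks)$frac_mito, 1)

  # empty input is an empty table, not an error
  empty <- fragment_table(data.table(chrom = character(), start = integer(),
                                     end = integer(), barcode = character(),
                                     dup_count = integer()))
  expect_identical(nrow(per_barcode_qc(empty, peaks)), 0L)

  # annotation classes appear as frac_ columns in [0, 1]
  ann <- list(promoter = GRanges("chr1", IRanges(1, 250)))
  qca <- per_barcode_qc(ft, peaks, ann)
  expect_true(all(qca$frac_promoter >= 0 & qca$frac_promoter <= 1))
  expect_equal(qca$frac_promoter, 0.25)
})

test_that("insert-size histogram conserves fragment count", {
  ft <- fragment_table(data.table(chrom = "chr1", start = c(0L, 10L, 20L),
                                  end = c(100L, 110L, 270L), barcode = "B",
                                  dup_count = 1L))
  h <- insert_size_distribution(ft)
  expect_equal(h$count[h$size == 100], 2L)
  expect_equal(h$count[h$size == 250], 1L)

  empty <- fragment_table(data.table(chrom = character(), start = integer(),
                                     end = integer(), barcode = character(),
                                     dup_count = integer()))
  expect_identical(nrow(insert_size_distribution(empty)), 0L)

  rf <- random_fragments(1000, seed = 5)
  expect_equal(sum(insert_size_distribution(rf, max_size = 100)$count), nrow(rf))
})

test_that("TSS enrichment self-normalizes, localizes and respects strand", {
  tss <- GRanges("chr1", IRanges(50000, 50000), strand = "+")
  # uniform insertions across the window -> flat profile, score near 1
  set.seed(2)
  st <- as.integer(47000 + floor(runif(6000) * 6000))
  uf <- fragment_table(data.table(chrom = "chr1", start = st, end = st + 100L,
                                  barcode = "B", dup_count = 1L))
  prof <- tss_enrichment(uf, tss)
  expect_lt(abs(prof$score - 1), 0.35)

  # width-1 fragments put both insertion events exactly at the TSS (with
  # uniform background providing the flank normalizer)
  at <- fragment_table(data.table(chrom = "chr1", start = rep(49999L, 50),
                                  end = rep(50000L, 50), barcode = "B",
                                  dup_count = 1L))
  both <- fragment_table(rbind(as.data.table(uf), as.data.table(at)))
  p2 <- tss_enrichment(both, tss)
  expect_equal(p2$position[which.max(p2$signal)], 0)

  # minus-strand TSS mirrors offsets: insertion at +10 appears at -10
  mtss <- GRanges("chr1", IRanges(50000, 50000), strand = "-")
  one <- fragment_table(data.table(chrom = "chr1", start = 50009L, end = 50200L,
                                   barcode = "B", dup_count = 1L))
  p3 <- tss_enrichment(one, mtss)
  expect_equal(p3$signal[p3$position == -10], 1)
  # (the fragment's other end lands at offset -(200 - 1 + 10))
  expect_equal(sum(p3$signal), 2)

  # translation invariance
  shifted <- as.data.table(both)
  shifted[, `:=`(start = start + 777L, end = end + 777L)]
  tss_sh <- GRanges("chr1", IRanges(50777, 50777), strand = "+")
  p4 <- tss_enrichment(fragment_table(shifted), tss_sh)
  expect_equal(p4$signal, p2$signal)

  # zero flank signal -> sentinel score
  p5 <- tss_enrichment(at, tss)
  expect_true(is.na(p5$score))
})

test_that("library complexity inverts the Lander-Waterman curve", {
  # oracle: forward-evaluate U(C) = C (1 - exp(-N/C)) at C = 1000, N = 2000,
  # then invert; U = 1000 * (1 - exp(-2)) = 864.66
  U <- 1000 * (1 - exp(-2000 / 1000))
  expect_equal(library_complexity(2000, U), 1000, tolerance = 1e-4)
  expect_true(is.na(library_complexity(500, 500)))
  expect_error(library_complexity(100, 200), "exceed")
  # monotone in N at fixed U, and always >= U
  cs <- vapply(c(1200, 2000, 5000, 20000), library_complexity,
               numeric(1), unique_frags = 1000)
  expect_true(all(diff(cs) < 0))   # more reads, same uniques => smaller library
  expect_true(all(cs >= 1000))
  # asymptotic regime N = 100 C recovers C ~ U
  expect_equal(library_complexity(100000, 1000), 1000, tolerance = 1e-3)
})

test_that("aggregate statistics follow their definitions", {
  qc <- data.table(barcode = c("A", "B"), total_reads = c(10L, 10L),
                   unique_frags = c(5L, 10L), frip = c(0.2, 0.8),
                   frac_mito = c(0, 0.1), is_cell = c(NA, NA))
  agg <- aggregate_qc(qc)
  expect_equal(agg$duplicate_rate, 1 - 15 / 20)
  expect_true(is.na(agg$n_cells_called))
  expect_true(is.na(agg$median_frags_per_cell))

  qc2 <- data.table(barcode = c("A", "B", "C"),
                    total_reads = c(800L, 800L, 400L),
                    unique_frags = c(700L, 700L, 300L),
                    frip = c(0.7, 0.7, 0.1), frac_mito = 0,
                    is_cell = c(TRUE, TRUE, FALSE))
  agg2 <- aggregate_qc(qc2)
  expect_equal(agg2$frac_reads_in_cells, 1600 / 2000)
  expect_equal(agg2$n_cells_called, 2L)
  expect_equal(agg2$median_frags_per_cell, 700)
})
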