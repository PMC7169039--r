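test_that("fragment files parse, validate and round-trip exactly", {
  ft <- tiny_fragments()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(ft, tmp)
  expect_identical(nrow(fread(tmp, header = FALSE)), 3L)
  expect_identical(ncol(fread(tmp, header = FALSE)), 6L)  # mapq kept
  back <- read_fragments(tmp)
  expect_equal(as.data.frame(back), as.data.frame(ft), ignore_attr = TRUE)

  # gzip round-trip is byte-equivalent to the plain file
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_fragments(ft, gz)
  expect_equal(as.data.frame(read_fragments(gz)), as.data.frame(ft),
               ignore_attr = TRUE)

  # empty table round-trips to an empty file
  empty <- fragment_table(data.table(chrom = character(), start = integer(),
                                     end = integer(), barcode = character(),
                                     dup_count = integer()))
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(empty, tmp2)
  expect_identical(nrow(read_fragments(tmp2)), 0L)
})

test_that("malformed fragment records are rejected with a line number", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t200\tBC1\t1", "chr1\t100\t50\tBC1\t1"), tmp)
  expect_error(read_fragments(tmp), "line 2")
  writeLines("chr1\t10\t200", tmp)
  expect_error(read_fragments(tmp), ">= 5 columns")
  writeLines("chr1\tten\t200\tBC1\t1", tmp)
  expect_error(read_fragments(tmp), "non-integer")
  expect_error(fragment_table(data.table(chrom = "chr1", start = 5L, end = 5L,
                                         barcode = "a", dup_count = 1L)),
               "invalid fragment")
})

test_that("fragment round-trip holds on arbitrary valid tables", {
  for (seed in 1:4) {
    ft <- random_fragments(200, seed, with_mapq = seed %% 2 == 0)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_fragments(ft, tmp)
    expect_equal(as.data.frame(read_fragments(tmp)), as.data.frame(ft),
                 ignore_attr = TRUE)
  }
})

test_that("BED intervals read with 0-based half-open semantics", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", tmp)
  gr <- read_intervals(tmp)
  expect_identical(GenomicRanges::width(gr), 100L)
  expect_identical(GenomicRanges::start(gr), 1L)

  writeLines("chr1\t10\t20\tpk1\t0\t-", tmp)
  gr6 <- read_intervals(tmp)
  expect_identical(as.character(GenomicRanges::strand(gr6)), "-")
  expect_identical(S4Vectors::mcols(gr6)$name, "pk1")

  writeLines(character(0), tmp)
  expect_length(read_intervals(tmp), 0)

  writeLines("chr1\t100\t100", tmp)
  expect_error(read_intervals(tmp), "end <= start")

  # round-trip through write_intervals
  gr <- GRanges(c("chr1", "chr2"), IRanges(c(11, 51), c(40, 90)))
  write_intervals(gr, tmp)
  expect_equal(granges_to_id(read_intervals(tmp)), granges_to_id(gr))
})

test_that("fragment filtering applies MAPQ and chromosome rules strictly", {
  ft <- fragment_table(data.table(chrom = c("chr1", "chr1", "chr1", "chrM"),
                                  start = c(1L, 10L, 20L, 30L),
                                  end = c(100L, 110L, 120L, 130L),
                                  barcode = "BC1", dup_count = 1L,
                                  mapq = c(29L, 30L, 31L, 60L)))
  kept <- filter_fragments(ft, min_mapq = 30)
  expect_setequal(kept$mapq, c(30L, 31L, 60L))  # MAPQ < 30 removed
  expect_identical(unname(attr(kept, "removed")[["mapq"]]), 1L)

  no_mito <- filter_fragments(ft, exclude_chroms = "chrM")
  expect_false("chrM" %in% no_mito$chrom)
  expect_identical(nrow(no_mito), 3L)

  expect_equal(as.data.frame(filter_fragments(ft, min_mapq = 0)),
               as.data.frame(ft), ignore_attr = TRUE)

  # idempotent and order-independent across the two criteria
  a <- filter_fragments(filter_fragments(ft, min_mapq = 30), exclude_chroms = "chrM")
  b <- filter_fragments(filter_fragments(ft, exclude_chroms = "chrM"), min_mapq = 30)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  expect_equal(as.data.frame(filter_fragments(a, min_mapq = 30,
                                              exclude_chroms = "chrM")),
               as.data.frame(a), ignore_attr = TRUE)

  noq <- fragment_table(as.data.table(ft)[, !"mapq"])
  expect_error(filter_fragments(noq, min_mapq = 30), "no mapq column")
})

test_that("sparse matrix triple round-trips exactly", {
  m <- sparseMatrix(i = 1:2, j = 1:2, x = c(1, 1), dims = c(2, 2),
                    dimnames = list(c("chr1:0-100", "chr1:100-200"),
                                    c("BCA", "BCB")))
  d <- withr::local_tempdir()
  write_matrix(m, d)
  expect_equal(as.matrix(read_matrix(d)), as.matrix(m))

  # all-zero matrix: header declares 0 entries
  z <- sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(2, 2),
                    dimnames = dimnames(m))
  d2 <- withr::local_tempdir()
  write_matrix(z, d2)
  hdr <- readLines(file.path(d2, "matrix.mtx"), n = 3)
  expect_match(tail(hdr, 1), "2 2 0")
  expect_equal(as.matrix(read_matrix(d2)), as.matrix(z))

  # random 100 x 50 sparse matrix
  set.seed(3)
  r <- sparseMatrix(i = sample(100, 400, TRUE), j = sample(50, 400, TRUE),
                    x = rpois(400, 2) + 1, dims = c(100, 50))
  r <- as(r, "CsparseMatrix")
  dimnames(r) <- list(paste0("chr1:", 0:99 * 10, "-", 0:99 * 10 + 5),
                      sprintf("BC%02d", 1:50))
  d3 <- withr::local_tempdir()
  write_matrix(r, d3)
  expect_equal(as.matrix(read_matrix(d3)), as.matrix(r))

  # corrupt the barcode sidecar: dimension mismatch must be caught
  writeLines(c("BCA"), file.path(d, "barcodes.txt"))
  expect_error(read_matrix(d), "do not match")
})

test_that("chromosome size tables round-trip and validate", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_chrom_sizes(c(chr1 = 1000L, chrM = 16571L), tmp)
  expect_identical(read_chrom_sizes(tmp), c(chr1 = 1000L, chrM = 16571L))
  writeLines("chr1\t0", tmp)
  expect_error(read_chrom_sizes(tmp), "non-positive")
})
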