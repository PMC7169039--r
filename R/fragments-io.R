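#' @importFrom data.table data.table fread fwrite setDT setorder as.data.table :=
#' @importFrom GenomicRanges GRanges seqnames start end strand countOverlaps
#'   findOverlaps reduce tileGenome coverage resize
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom Matrix sparseMatrix colSums rowSums t readMM writeMM Diagonal
#' @importFrom methods as is
#' @importFrom stats p.adjust ppois rbinom rnbinom rgamma rmultinom dnbinom
#'   wilcox.test prcomp dist optimize rlnorm runif rnorm rpois rgeom median
#'   var sd cor setNames quantile complete.cases lm residuals
#' @importFrom utils head tail write.table read.table
NULL

# Chromosome names treated as mitochondrial throughout the package.
MITO_ALIASES <- c("chrM", "MT", "chrMT", "M")

is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# fread with gzip handled through a base connection (no R.utils dependency)
fread_maybe_gz <- function(path, ...) {
  if (file.size(path) == 0)
    return(data.table())
  if (is_gzip(path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines)) return(data.table())
    fread(text = lines, header = FALSE, sep = "\t", fill = FALSE, ...)
  } else {
    fread(path, header = FALSE, sep = "\t", fill = FALSE, ...)
  }
}

#' Construct a fragment table
#'
#' A fragment table holds deduplicated per-barcode genomic fragments, one row
#' per unique (chrom, start, end, barcode) with the number of read pairs
#' collapsed into it. Coordinates are 0-based half-open, as in on-disk
#' fragment files.
#'
#' @param df data.frame/data.table with columns chrom, start, end, barcode,
#'   dup_count and optionally mapq.
#' @param sorted logical; whether rows are known to be sorted by
#'   (chrom, start, end). Verified, not trusted, when `TRUE`.
#' @return A `fragment_table` (a data.table subclass).
#' @export
fragment_table <- function(df, sorted = FALSE) {
  dt <- as.data.table(df)
  req <- c("chrom", "start", "end", "barcode", "dup_count")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("fragment table missing column(s): ", paste(miss, collapse = ", "))
  validate_fragments(dt)
  if (sorted) sorted <- !is.unsorted_fragments(dt)
  setattr(dt, "sorted_flag", isTRUE(sorted))
  setattr(dt, "class", c("fragment_table", class(dt)))
  dt
}

setattr <- data.table::setattr

validate_fragments <- function(dt) {
  bad <- which(dt$start < 0 | dt$end <= dt$start | dt$dup_count < 1)
  if (length(bad))
    stop(sprintf("invalid fragment record at line %d: start=%s end=%s dup_count=%s",
                 bad[1], dt$start[bad[1]], dt$end[bad[1]], dt$dup_count[bad[1]]))
  invisible(TRUE)
}

is.unsorted_fragments <- function(dt) {
  o <- order(dt$chrom, dt$start, dt$end)
  !identical(o, seq_len(nrow(dt)))
}

#' Read a fragment file
#'
#' Reads a TSV fragment file (chrom, start, end, barcode, dup_count, with an
#' optional 6th MAPQ column), plain or gzip-compressed. File order is
#' preserved; records are validated (`end > start`, `dup_count >= 1`).
#'
#' @param path path to the fragment file.
#' @param has_mapq force interpretation of a 6th column as MAPQ; by default
#'   inferred from the column count.
#' @return A [fragment_table()].
#' @export
read_fragments <- function(path, has_mapq = NULL) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  dt <- tryCatch(
    fread_maybe_gz(path, colClasses = list(character = 1)),
    error = function(e) stop("malformed fragment file '", path, "': ",
                             conditionMessage(e)))
  if (nrow(dt) == 0) {
    return(fragment_table(data.table(chrom = character(), start = integer(),
                                     end = integer(), barcode = character(),
                                     dup_count = integer())))
  }
  if (ncol(dt) < 5)
    stop("fragment file must have >= 5 columns (chrom,start,end,barcode,dup_count); got ",
         ncol(dt))
  if (is.null(has_mapq)) has_mapq <- ncol(dt) >= 6
  cols <- c("chrom", "start", "end", "barcode", "dup_count")
  if (has_mapq) {
    if (ncol(dt) < 6) stop("has_mapq = TRUE but file has only ", ncol(dt), " columns")
    dt <- dt[, 1:6]
    data.table::setnames(dt, c(cols, "mapq"))
  } else {
    dt <- dt[, 1:5]
    data.table::setnames(dt, cols)
  }
  for (cc in c("start", "end", "dup_count")) {
    v <- dt[[cc]]
    if (!is.numeric(v)) {
      vi <- suppressWarnings(as.integer(v))
      if (anyNA(vi))
        stop(sprintf("non-integer value in column '%s' at line %d of %s",
                     cc, which(is.na(vi))[1], path))
      data.table::set(dt, j = cc, value = vi)
    } else data.table::set(dt, j = cc, value = as.integer(v))
  }
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop(sprintf("end <= start at line %d of %s", bad[1], path))
  fragment_table(dt, sorted = TRUE)
}

#' Write a fragment table to a TSV file
#'
#' Inverse of [read_fragments()]: `read_fragments(write_fragments(t))`
#' reproduces `t` exactly.
#'
#' @param table a [fragment_table()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @export
write_fragments <- function(table, path) {
  stopifnot(is(table, "fragment_table") || is.data.frame(table))
  fwrite(as.data.table(table), path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Filter fragments by mapping quality and chromosome
#'
#' @param table a [fragment_table()].
#' @param min_mapq retain records with `mapq >= min_mapq` (MAPQ below the
#'   threshold removed). `NULL` disables the filter.
#' @param exclude_chroms chromosome names to drop (e.g. `"chrM"`).
#' @return Filtered `fragment_table`; attribute `"removed"` holds the counts
#'   removed by each criterion.
#' @export
filter_fragments <- function(table, min_mapq = NULL, exclude_chroms = NULL) {
  dt <- as.data.table(table)
  removed <- c(mapq = 0L, chrom = 0L)
  if (!is.null(min_mapq) && min_mapq > 0) {
    if (!"mapq" %in% names(dt))
      stop("min_mapq given but fragment table has no mapq column")
    keep <- dt$mapq >= min_mapq
    removed["mapq"] <- sum(!keep)
    dt <- dt[keep]
  }
  if (!is.null(exclude_chroms) && length(exclude_chroms)) {
    keep <- !(dt$chrom %in% exclude_chroms)
    removed["chrom"] <- sum(!keep)
    dt <- dt[keep]
  }
  out <- fragment_table(dt, sorted = isTRUE(attr(table, "sorted_flag")))
  setattr(out, "removed", removed)
  out
}

#' Convert fragments to GRanges
#'
#' 0-based half-open fragment coordinates become 1-based closed GRanges.
#' @param table a [fragment_table()].
#' @return `GRanges` with mcols `barcode`, `dup_count` (and `mapq` if present).
#' @export
fragments_to_granges <- function(table) {
  dt <- as.data.table(table)
  gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end))
  mcols(gr)$barcode <- dt$barcode
  mcols(gr)$dup_count <- dt$dup_count
  if ("mapq" %in% names(dt)) mcols(gr)$mapq <- dt$mapq
  gr
}

#' Read a BED file of genomic intervals
#'
#' BED3/BED4/BED6 with 0-based half-open coordinates; returns standard
#' 1-based closed `GRanges`. Name and strand columns are captured when present.
#'
#' @param path BED file path (plain or gzip).
#' @return `GRanges`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  dt <- fread_maybe_gz(path, colClasses = list(character = 1))
  if (nrow(dt) == 0) return(GRanges())
  if (ncol(dt) < 3) stop("BED file needs >= 3 columns: ", path)
  s <- as.integer(dt[[2]]); e <- as.integer(dt[[3]])
  bad <- which(is.na(s) | is.na(e) | e <= s)
  if (length(bad))
    stop(sprintf("invalid interval (end <= start or non-integer) at line %d of %s",
                 bad[1], path))
  strand <- if (ncol(dt) >= 6) dt[[6]] else "*"
  gr <- GRanges(dt[[1]], IRanges(s + 1L, e), strand = strand)
  if (ncol(dt) >= 4) mcols(gr)$name <- as.character(dt[[4]])
  gr
}

#' Write GRanges as a BED file
#'
#' @param gr `GRanges`; written 0-based half-open. A `name` metadata column
#'   and non-`*` strand produce BED4/BED6 output.
#' @param path output path.
#' @export
write_intervals <- function(gr, path) {
  dt <- data.table(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  has_strand <- any(as.character(strand(gr)) != "*")
  if (!is.null(mcols(gr)$name) || has_strand) {
    dt$name <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
               else paste0("interval_", seq_along(gr))
  }
  if (has_strand) {
    dt$score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    dt$strand <- as.character(strand(gr))
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#' @param path TSV of (chrom, length).
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("chromosome sizes file needs 2 columns: ", path)
  sz <- as.integer(dt[[2]])
  if (any(is.na(sz) | sz <= 0)) stop("non-positive chromosome length in ", path)
  setNames(sz, as.character(dt[[1]]))
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  fwrite(data.table(names(sizes), as.integer(sizes)), path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

# Feature identifiers use the on-disk 0-based half-open convention
# ("chrom:start-end") so ids match the BED sidecar byte for byte.
granges_to_id <- function(gr) {
  paste0(as.character(seqnames(gr)), ":", start(gr) - 1L, "-", end(gr))
}

id_to_granges <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  if (any(lengths(m) != 4)) stop("malformed feature id: ", ids[which(lengths(m) != 4)[1]])
  chrom <- vapply(m, `[`, "", 2)
  s <- as.integer(vapply(m, `[`, "", 3)); e <- as.integer(vapply(m, `[`, "", 4))
  GRanges(chrom, IRanges(s + 1L, e))
}

#' Write a sparse count matrix as a MatrixMarket triple
#'
#' Writes `matrix.mtx` (1-based coordinate format), `features.bed` (the row
#' intervals) and `barcodes.txt` (one barcode per line) into `dir`.
#' Round-trips exactly through [read_matrix()].
#'
#' @param m sparse features-by-barcodes matrix (`dgCMatrix`), rownames are
#'   feature ids (`chrom:start-end`, 0-based half-open), colnames barcodes.
#' @param dir output directory (created if needed).
#' @export
write_matrix <- function(m, dir) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMM(as(as(m, "generalMatrix"), "TsparseMatrix"),
          file.path(dir, "matrix.mtx"))
  write_intervals(id_to_granges(rownames(m)), file.path(dir, "features.bed"))
  writeLines(colnames(m), file.path(dir, "barcodes.txt"))
  invisible(dir)
}

#' Read a MatrixMarket count-matrix triple
#' @param dir directory containing `matrix.mtx`, `features.bed`, `barcodes.txt`.
#' @return sparse `dgCMatrix` with feature-id rownames and barcode colnames.
#' @export
read_matrix <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.bed", "barcodes.txt"))
  if (!all(file.exists(paths)))
    stop("matrix directory must contain matrix.mtx, features.bed, barcodes.txt: ", dir)
  m <- readMM(paths[1])
  # pattern matrices (written when every entry is 1) come back logical
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  feats <- read_intervals(paths[2])
  bcs <- readLines(paths[3])
  if (nrow(m) != length(feats) || ncol(m) != length(bcs))
    stop(sprintf("matrix dimensions (%d x %d) do not match features (%d) / barcodes (%d)",
                 nrow(m), ncol(m), length(feats), length(bcs)))
  dimnames(m) <- list(granges_to_id(feats), bcs)
  m
}
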