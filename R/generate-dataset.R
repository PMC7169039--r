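#' Scenario parameters for the synthetic fragment generator
#'
#' Describes a small scATAC-seq experiment on a toy genome (two 1-Mb
#' autosomes plus chrM): a set of true peaks with per-type accessibility
#' profiles, real cells with high depth and FRiP, ambient noise barcodes
#' with low depth and mostly background fragments, PCR duplicates, a
#' mitochondrial fraction and a MAPQ distribution.
#'
#' @param n_types number of cell types.
#' @param cells_per_type real cells per type.
#' @param n_peaks total true peaks; the first `n_types * markers_per_type`
#'   are type-private markers, the rest shared.
#' @param markers_per_type marker peaks per type.
#' @param peak_width peak width (bp).
#' @param n_noise_barcodes ambient (non-cell) barcodes.
#' @param cell_depth_meanlog,cell_depth_sdlog log-normal unique-fragment
#'   depth of cells (median 8000 by default, comfortably above the
#'   5000-fragment calling threshold).
#' @param noise_depth_meanlog,noise_depth_sdlog depth of noise barcodes
#'   (median 300).
#' @param cell_frip,noise_frip probability that a fragment lands in a peak.
#' @param cell_mito,noise_mito probability of a chrM fragment.
#' @param dup_rate expected duplicate rate (`dup_count = 1 + Geom(1 - dup_rate)`).
#' @param mapq_good_prob probability of MAPQ 60 (else uniform on 0..29).
#' @param n_motifs number of synthetic motifs; the first `n_types` are
#'   enriched in the corresponding type's marker peaks.
#' @return list of class `dataset_config`.
#' @export
dataset_config <- function(n_types = 3L, cells_per_type = 200L,
                           n_peaks = 300L, markers_per_type = 50L,
                           peak_width = 400L, n_noise_barcodes = 500L,
                           cell_depth_meanlog = log(8000), cell_depth_sdlog = 0.3,
                           noise_depth_meanlog = log(300), noise_depth_sdlog = 0.7,
                           cell_frip = 0.75, noise_frip = 0.15,
                           cell_mito = 0.02, noise_mito = 0.15,
                           dup_rate = 0.3, mapq_good_prob = 0.92,
                           n_motifs = 10L) {
  stopifnot(n_types * markers_per_type <= n_peaks, dup_rate >= 0, dup_rate < 1,
            cell_frip + cell_mito <= 1, noise_frip + noise_mito <= 1)
  cfg <- as.list(environment())
  cfg$chrom_sizes <- c(chr1 = 1000000L, chr2 = 1000000L, chrM = 16571L)
  structure(cfg, class = "dataset_config")
}

#' Generate a complete synthetic scATAC-seq dataset with ground truth
#'
#' Draws a fragment table from the scenario in [dataset_config()] together
#' with everything needed to score every pipeline stage: true cell labels,
#' the true peak set, TSS/promoter/enhancer annotations, a peak-by-motif
#' membership matrix and per-peak GC content. Fully deterministic under
#' `seed`.
#'
#' @param config a [dataset_config()].
#' @param seed RNG seed.
#' @return list: `fragments` ([fragment_table()], sorted), `labels`
#'   (data.table: barcode, type, is_cell), `true_peaks` (`GRanges`),
#'   `annotations` (list of `GRanges`: tss, promoter, enhancer),
#'   `motif_membership` (peaks x motifs sparse 0/1), `gc` (per-peak
#'   fraction), `chrom_sizes`, `config`, `seed`.
#' @export
generate_dataset <- function(config = dataset_config(), seed = 1L) {
  stopifnot(is(config, "dataset_config"))
  set.seed(seed)
  cs <- config$chrom_sizes
  autosomes <- setdiff(names(cs), MITO_ALIASES)
  # --- true peaks: evenly spaced over the autosomes, non-overlapping
  n_peaks <- config$n_peaks
  per_chr <- ceiling(n_peaks / length(autosomes))
  peak_list <- list()
  left <- n_peaks
  for (chr in autosomes) {
    np <- min(per_chr, left); left <- left - np
    if (np == 0) next
    spacing <- (cs[[chr]] - 2000L) %/% np
    if (spacing <= config$peak_width)
      stop("infeasible scenario: peaks exceed genome capacity on ", chr)
    starts <- 1000L + (seq_len(np) - 1L) * spacing
    peak_list[[chr]] <- GRanges(chr, IRanges(starts + 1L,
                                             starts + config$peak_width))
  }
  true_peaks <- sort(suppressWarnings(do.call(c, unname(peak_list))))
  mcols(true_peaks)$name <- paste0("true_peak_", seq_along(true_peaks))
  n_marker <- config$n_types * config$markers_per_type
  # marker blocks interleaved across the genome so each type's peaks span it
  marker_of <- rep(NA_integer_, n_peaks)
  marker_of[seq_len(n_marker)] <- rep(seq_len(config$n_types),
                                      config$markers_per_type)
  marker_of <- marker_of[sample.int(n_peaks)]
  # --- per-type peak weight profiles (markers 8x shared weight)
  w <- matrix(1, n_peaks, config$n_types)
  for (t in seq_len(config$n_types)) {
    w[!is.na(marker_of) & marker_of != t, t] <- 0.05
    w[!is.na(marker_of) & marker_of == t, t] <- 8
  }
  w <- sweep(w, 2, colSums(w), "/")
  bg_profile <- rowMeans(w)
  # --- barcodes
  n_cells <- config$n_types * config$cells_per_type
  cell_bc <- sprintf("CELL%04d", seq_len(n_cells))
  noise_bc <- sprintf("NOISE%04d", seq_len(config$n_noise_barcodes))
  cell_type <- rep(seq_len(config$n_types), each = config$cells_per_type)
  depth <- c(pmax(50L, as.integer(round(rlnorm(n_cells, config$cell_depth_meanlog,
                                               config$cell_depth_sdlog)))),
             pmax(5L, as.integer(round(rlnorm(config$n_noise_barcodes,
                                              config$noise_depth_meanlog,
                                              config$noise_depth_sdlog)))))
  barcodes <- c(cell_bc, noise_bc)
  is_cell <- c(rep(TRUE, n_cells), rep(FALSE, config$n_noise_barcodes))
  frip <- ifelse(is_cell, config$cell_frip, config$noise_frip)
  mito <- ifelse(is_cell, config$cell_mito, config$noise_mito)
  # --- fragments
  total <- sum(depth)
  bc_col <- rep(barcodes, depth)
  dest <- runif(total)
  fr <- rep(frip, depth); mi <- rep(mito, depth)
  in_peak <- dest < fr
  in_mito <- !in_peak & dest < fr + mi
  # fragment sizes: nucleosome-free / mono-nucleosome mixture
  fsize <- data.table::fifelse(runif(total) < 0.7,
                               round(rnorm(total, 120, 30)),
                               round(rnorm(total, 220, 40)))
  fsize <- as.integer(pmin(pmax(fsize, 30), 500))
  chrom <- character(total); startv <- integer(total)
  # peak fragments: peak sampled from the barcode's profile (0 = ambient)
  prof_idx <- rep(c(cell_type, rep(0L, config$n_noise_barcodes)), depth)
  pk_rows <- which(in_peak)
  if (length(pk_rows)) {
    pk_choice <- integer(length(pk_rows))
    for (t in c(0L, seq_len(config$n_types))) {
      rows <- which(prof_idx[pk_rows] == t)
      if (!length(rows)) next
      prob <- if (t == 0L) bg_profile else w[, t]
      pk_choice[rows] <- sample.int(n_peaks, length(rows), replace = TRUE,
                                    prob = prob)
    }
    pchr <- as.character(seqnames(true_peaks))[pk_choice]
    ps <- start(true_peaks)[pk_choice] - 1L  # 0-based peak start
    offset <- as.integer(floor(runif(length(pk_rows)) *
                                 (config$peak_width + fsize[pk_rows]))) -
      fsize[pk_rows]
    chrom[pk_rows] <- pchr
    startv[pk_rows] <- pmax(0L, ps + offset)
  }
  mt_rows <- which(in_mito)
  if (length(mt_rows)) {
    chrom[mt_rows] <- "chrM"
    startv[mt_rows] <- as.integer(floor(runif(length(mt_rows)) *
                                          (cs[["chrM"]] - fsize[mt_rows])))
  }
  bg_rows <- which(!in_peak & !in_mito)
  if (length(bg_rows)) {
    bgc <- sample(autosomes, length(bg_rows), replace = TRUE)
    chrom[bg_rows] <- bgc
    startv[bg_rows] <- as.integer(floor(runif(length(bg_rows)) *
                                          (cs[bgc] - fsize[bg_rows])))
  }
  dt <- data.table(chrom = chrom, start = startv,
                   end = startv + fsize, barcode = bc_col)
  # collapse to unique fragments; PCR duplicates drawn per unique fragment
  data.table::setkey(dt, chrom, start, end, barcode)
  dt <- unique(dt)
  dup <- if (config$dup_rate > 0)
    1L + rgeom(nrow(dt), prob = 1 - config$dup_rate) else rep(1L, nrow(dt))
  dt[, dup_count := dup]
  dt[, mapq := data.table::fifelse(runif(.N) < config$mapq_good_prob, 60L,
                                   as.integer(floor(runif(.N) * 30)))]
  data.table::setkey(dt, NULL)
  frags <- fragment_table(dt, sorted = TRUE)
  # --- annotations derived from the true peaks
  mid <- as.integer((start(true_peaks) + end(true_peaks)) / 2)
  strands <- rep(c("+", "-"), length.out = n_peaks)
  tss <- GRanges(seqnames(true_peaks), IRanges(mid, mid), strand = strands)
  promoter <- suppressWarnings(resize(tss, width = 2000L, fix = "center"))
  enhancer <- true_peaks[seq(1, n_peaks, by = 3)]
  # --- motif membership and GC
  M <- matrix(0L, n_peaks, config$n_motifs,
              dimnames = list(mcols(true_peaks)$name,
                              paste0("motif_", seq_len(config$n_motifs))))
  for (mm in seq_len(config$n_motifs)) {
    if (mm <= config$n_types) {
      p_in <- ifelse(!is.na(marker_of) & marker_of == mm, 0.8, 0.05)
    } else p_in <- rep(0.10, n_peaks)
    M[, mm] <- as.integer(runif(n_peaks) < p_in)
  }
  gc <- stats::rbeta(n_peaks, 5, 5)
  labels <- data.table(
    barcode = barcodes,
    type = c(paste0("type", cell_type), rep("noise", config$n_noise_barcodes)),
    is_cell = is_cell)
  data.table::setkey(labels, barcode)
  list(fragments = frags, labels = labels, true_peaks = true_peaks,
       annotations = list(tss = tss, promoter = promoter, enhancer = enhancer),
       motif_membership = as(as(M, "generalMatrix"), "CsparseMatrix"),
       gc = gc, chrom_sizes = cs, config = config, seed = seed)
}

#' Write a generated dataset's truth bundle to a directory
#'
#' Plain-text export of [generate_dataset()] output: fragment TSV, label
#' TSV, BED annotation files, motif matrix and GC table, chromosome sizes
#' and a JSON scenario record.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fragments(ds$fragments, file.path(dir, "fragments.tsv"))
  fwrite(ds$labels, file.path(dir, "labels.tsv"), sep = "\t")
  write_intervals(ds$true_peaks, file.path(dir, "true_peaks.bed"))
  for (nm in names(ds$annotations))
    write_intervals(ds$annotations[[nm]], file.path(dir, paste0(nm, ".bed")))
  write_chrom_sizes(ds$chrom_sizes, file.path(dir, "chrom_sizes.tsv"))
  mm <- ds$motif_membership
  rownames(mm) <- granges_to_id(ds$true_peaks)
  write_matrix(mm, file.path(dir, "motif_membership"))
  fwrite(data.table(peak = granges_to_id(ds$true_peaks), gc = ds$gc),
         file.path(dir, "gc.tsv"), sep = "\t")
  cfg <- ds$config; class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(seed = ds$seed)),
                       file.path(dir, "scenario.json"), auto_unbox = TRUE)
  invisible(dir)
}
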