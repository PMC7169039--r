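#' Pipeline configuration
#'
#' One namespace holding every module's defaults. Values are validated
#' against the corresponding module's preconditions at construction and at
#' load time.
#'
#' @param cell_min_unique_frags,cell_min_frip cell-calling thresholds
#'   (strict `>`).
#' @param bin_prefilter_min minimum unique fragments for the bin-level
#'   clustering prefilter.
#' @param bin_size genome bin width (bp).
#' @param merge_gap peak merge distance (bp).
#' @param mapq_min minimum mapping quality retained.
#' @param n_components principal components.
#' @param variable_peak_fraction fraction of peaks kept for motif scoring.
#' @param knn_k SNN neighbors.
#' @param louvain_resolution Louvain resolution.
#' @param n_background motif background sets.
#' @param peak_window,peak_step,peak_local_bg,peak_qvalue,peak_min_frags
#'   internal peak-caller parameters.
#' @param track_bin coverage-track bin width (bp).
#' @param output_dir pipeline output directory.
#' @param seed RNG seed used by every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_min_unique_frags = 5000, cell_min_frip = 0.5,
                            bin_prefilter_min = 1000, bin_size = 5000,
                            merge_gap = 200, mapq_min = 30,
                            n_components = 30, variable_peak_fraction = 0.30,
                            knn_k = 20, louvain_resolution = 0.8,
                            n_background = 50, peak_window = 200,
                            peak_step = 100, peak_local_bg = 10000,
                            peak_qvalue = 0.05, peak_min_frags = 5,
                            track_bin = 50, output_dir = "./output",
                            seed = 1) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num <- setdiff(names(cfg), "output_dir")
  for (nm in num) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("config field '", nm, "' must be a single number")
  }
  stopifnot(cfg$cell_min_frip >= 0, cfg$cell_min_frip <= 1,
            cfg$variable_peak_fraction > 0, cfg$variable_peak_fraction <= 1,
            cfg$peak_qvalue > 0, cfg$peak_qvalue < 1,
            cfg$peak_step <= cfg$peak_window,
            cfg$n_components >= 2, cfg$knn_k >= 1,
            cfg$bin_size > 0, cfg$merge_gap >= 0, cfg$mapq_min >= 0)
  invisible(TRUE)
}

#' Save / load a pipeline configuration
#'
#' Flat `key = value` text format, one field per line; [load_config()]
#' round-trips [save_config()] exactly and validates every field.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @export
save_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    paste0(nm, " = ", if (is.character(v)) v else format(v, digits = 15))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  cfg <- pipeline_config()
  for (m in kv) {
    nm <- m[2]; val <- m[3]
    if (!nm %in% names(cfg)) stop("unknown config field '", nm, "'")
    cfg[[nm]] <- if (nm == "output_dir") val else as.numeric(val)
  }
  validate_config(cfg)
  cfg
}

PIPELINE_STEPS <- c("simulate", "peaks_combined", "qc", "call_cell", "matrix",
                    "reduce", "cluster", "diff", "motif", "tracks", "report")

step_dir <- function(output_dir, step) file.path(output_dir, step)

need_output <- function(output_dir, step, file) {
  p <- file.path(output_dir, step, file)
  if (!file.exists(p))
    stop("missing upstream output '", file, "'; run step '", step, "' first")
  p
}

write_provenance <- function(dir, step, config, inputs) {
  cfg <- config; class(cfg) <- NULL
  tmp <- tempfile(); on.exit(unlink(tmp))
  saveRDS(cfg, tmp)
  jsonlite::write_json(
    list(step = step, inputs = inputs, parameters = cfg,
         parameter_hash = unname(tools::md5sum(tmp)),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("scatacpipe"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline step
#'
#' Orchestrates the pipeline on disk: each step reads its upstream stage's
#' outputs under `output_dir`, writes its own outputs under
#' `output_dir/<step>/` together with a provenance JSON, and fails with a
#' dependency error naming the required prior step when an upstream output
#' is missing. Rerunning a step with identical inputs, config and seed
#' reproduces identical primary outputs.
#'
#' Steps: `simulate` (synthetic dataset + truth bundle), `peaks_combined`
#' (two-step peak calling), `qc` (per-barcode metrics), `call_cell`
#' (threshold filtering), `matrix` (peak-by-cell counts over called
#' cells), `reduce` (TF-IDF + fast PCA), `cluster` (SNN-Louvain), `diff`
#' (each cluster vs rest), `motif` (deviation z-scores + enriched TFs),
#' `tracks` (per-cluster RPKM bedGraph), `report`, or `all`.
#'
#' @param step step name (see above).
#' @param input path to a fragment file; defaults to the simulated one.
#' @param config a [pipeline_config()].
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, the step's output directory (or list of them for
#'   `"all"`).
#' @export
run_step <- function(step, input = NULL, config = pipeline_config(),
                     output_dir = config$output_dir) {
  if (!step %in% c(PIPELINE_STEPS, "all"))
    stop("unknown step '", step, "'; available steps: ",
         paste(c(PIPELINE_STEPS, "all"), collapse = ", "))
  if (step == "all") {
    out <- lapply(PIPELINE_STEPS, run_step, input = input, config = config,
                  output_dir = output_dir)
    return(invisible(out))
  }
  # dependency pre-check before touching the output tree
  frag_dep <- if (is.null(input)) "simulate/fragments.tsv" else character(0)
  deps <- list(
    peaks_combined = c(frag_dep, "simulate/chrom_sizes.tsv"),
    qc = c(frag_dep, "peaks_combined/peaks.bed"),
    call_cell = "qc/barcode_qc.tsv",
    matrix = c(frag_dep, "peaks_combined/peaks.bed", "call_cell/barcode_qc.tsv"),
    reduce = "matrix/matrix.mtx",
    cluster = "reduce/reduced.tsv",
    diff = c("matrix/matrix.mtx", "cluster/clusters.tsv"),
    motif = c("matrix/matrix.mtx", "cluster/clusters.tsv",
              "simulate/motif_membership/matrix.mtx", "simulate/gc.tsv"),
    tracks = c(frag_dep, "simulate/chrom_sizes.tsv", "cluster/clusters.tsv"))
  for (r in deps[[step]]) {
    if (!file.exists(file.path(output_dir, r)))
      stop("missing upstream output '", basename(r), "'; run step '",
           sub("/.*$", "", r), "' first")
  }
  dir <- step_dir(output_dir, step)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inputs <- list()

  frag_path <- function() {
    if (!is.null(input)) return(input)
    need_output(output_dir, "simulate", "fragments.tsv")
  }
  load_frags <- function() {
    p <- frag_path(); inputs$fragments <<- p
    filter_fragments(read_fragments(p), min_mapq = config$mapq_min)
  }
  load_sizes <- function() {
    p <- need_output(output_dir, "simulate", "chrom_sizes.tsv")
    inputs$chrom_sizes <<- p
    read_chrom_sizes(p)
  }

  if (step == "simulate") {
    ds <- generate_dataset(dataset_config(), seed = config$seed)
    write_dataset(ds, dir)
  } else if (step == "peaks_combined") {
    frags <- load_frags(); cs <- load_sizes()
    auto <- filter_fragments(frags, exclude_chroms = MITO_ALIASES)
    peaks <- call_peaks_combined(
      auto, cs,
      params = peak_call_params(config$peak_window, config$peak_step,
                                config$peak_local_bg, config$peak_qvalue,
                                config$peak_min_frags),
      prefilter_min = config$bin_prefilter_min, bin_size = config$bin_size,
      n_components = config$n_components,
      resolution = config$louvain_resolution, k = config$knn_k,
      seed = config$seed, merge_gap = config$merge_gap)
    write_intervals(peaks, file.path(dir, "peaks.bed"))
  } else if (step == "qc") {
    frags <- load_frags()
    peaks <- read_intervals(need_output(output_dir, "peaks_combined", "peaks.bed"))
    ann <- list()
    for (nm in c("promoter", "enhancer", "tss")) {
      p <- file.path(output_dir, "simulate", paste0(nm, ".bed"))
      if (file.exists(p)) ann[[nm]] <- read_intervals(p)
    }
    qc <- per_barcode_qc(frags, peaks, ann)
    fwrite(qc, file.path(dir, "barcode_qc.tsv"), sep = "\t")
    isd <- insert_size_distribution(frags)
    fwrite(isd, file.path(dir, "insert_sizes.tsv"), sep = "\t")
    if (!is.null(ann$tss)) {
      prof <- tss_enrichment(frags, ann$tss)
      fwrite(data.table(position = prof$position, signal = prof$signal,
                        norm_signal = prof$norm_signal),
             file.path(dir, "tss_profile.tsv"), sep = "\t")
      writeLines(format(prof$score, digits = 6), file.path(dir, "tss_score.txt"))
    }
  } else if (step == "call_cell") {
    qc <- fread(need_output(output_dir, "qc", "barcode_qc.tsv"))
    qc <- call_cells_filter(qc, cell_call_config(config$cell_min_unique_frags,
                                                 config$cell_min_frip))
    fwrite(qc, file.path(dir, "barcode_qc.tsv"), sep = "\t")
    jsonlite::write_json(aggregate_qc(qc), file.path(dir, "aggregate_qc.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else if (step == "matrix") {
    frags <- load_frags()
    peaks <- read_intervals(need_output(output_dir, "peaks_combined", "peaks.bed"))
    qc <- fread(need_output(output_dir, "call_cell", "barcode_qc.tsv"))
    cells <- sort(qc$barcode[qc$is_cell %in% TRUE])
    if (length(cells) < 2) stop("fewer than 2 called cells; cannot build matrix")
    m <- count_features(frags, peaks, barcodes = cells)
    keep <- Matrix::colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    write_matrix(m, dir)
  } else if (step == "reduce") {
    m <- read_matrix(need_output(output_dir, "matrix", "matrix.mtx") |> dirname())
    red <- pca_fast(tfidf(m), n_components = config$n_components,
                    depth = Matrix::colSums(m))
    out <- data.table(barcode = rownames(red$coordinates), red$coordinates)
    fwrite(out, file.path(dir, "reduced.tsv"), sep = "\t")
  } else if (step == "cluster") {
    red <- fread(need_output(output_dir, "reduce", "reduced.tsv"))
    coords <- as.matrix(red[, -1])
    rownames(coords) <- red$barcode
    g <- snn_graph(coords, k = config$knn_k)
    cl <- louvain_cluster(g, resolution = config$louvain_resolution,
                          seed = config$seed)
    fwrite(data.table(barcode = names(cl$labels), cluster = cl$labels),
           file.path(dir, "clusters.tsv"), sep = "\t")
  } else if (step == "diff") {
    m <- read_matrix(need_output(output_dir, "matrix", "matrix.mtx") |> dirname())
    cl <- fread(need_output(output_dir, "cluster", "clusters.tsv"))
    norm <- tfidf(m)
    res <- list()
    for (g1 in sort(unique(cl$cluster))) {
      c1 <- cl$barcode[cl$cluster == g1]; c2 <- cl$barcode[cl$cluster != g1]
      if (length(c1) < 3 || length(c2) < 3) next
      da <- diff_accessibility(norm, c1, c2)
      da[, cluster := g1]
      res[[as.character(g1)]] <- da
    }
    fwrite(data.table::rbindlist(res), file.path(dir, "differential.tsv"),
           sep = "\t")
  } else if (step == "motif") {
    mdir <- dirname(need_output(output_dir, "matrix", "matrix.mtx"))
    m <- read_matrix(mdir)
    cl <- fread(need_output(output_dir, "cluster", "clusters.tsv"))
    mmdir <- dirname(need_output(output_dir, "simulate",
                                 file.path("motif_membership", "matrix.mtx")))
    mm_all <- read_matrix(mmdir)
    gc_all <- fread(need_output(output_dir, "simulate", "gc.tsv"))
    # align annotation rows (true peaks) with called-peak rows by overlap
    called <- id_to_granges(rownames(m))
    truth <- id_to_granges(rownames(mm_all))
    hits <- findOverlaps(called, truth, select = "first")
    mm <- matrix(0L, nrow(m), ncol(mm_all),
                 dimnames = list(rownames(m), colnames(mm_all)))
    gc <- rep(0.5, nrow(m))
    ok <- !is.na(hits)
    mm[ok, ] <- as.matrix(mm_all[hits[ok], , drop = FALSE])
    gc[ok] <- gc_all$gc[hits[ok]]
    dev <- motif_deviation_scores(m, mm, gc,
                                  n_background = config$n_background,
                                  fraction = config$variable_peak_fraction,
                                  seed = config$seed)
    fwrite(data.table(motif = rownames(dev$z), as.data.table(dev$z)),
           file.path(dir, "motif_z.tsv"), sep = "\t")
    labels <- setNames(cl$cluster, cl$barcode)
    enr <- enriched_tfs_per_cluster(dev, labels)
    fwrite(enr, file.path(dir, "enriched_tfs.tsv"), sep = "\t")
  } else if (step == "tracks") {
    frags <- load_frags(); cs <- load_sizes()
    cl <- fread(need_output(output_dir, "cluster", "clusters.tsv"))
    cluster_tracks(frags, setNames(cl$cluster, cl$barcode), cs,
                   bin = config$track_bin, dir = dir)
  } else if (step == "report") {
    generate_report(output_dir)
  }
  write_provenance(dir, step, config, inputs)
  invisible(dir)
}

#' Generate the summary report
#'
#' Collects whatever stage outputs exist under `output_dir` into a
#' machine-readable JSON summary and a static HTML rendering. Stages that
#' were not run are marked `"not run"`, never fabricated.
#'
#' @param output_dir pipeline output directory with at least one stage.
#' @return invisibly, the report list.
#' @export
generate_report <- function(output_dir) {
  stages <- intersect(PIPELINE_STEPS, list.dirs(output_dir, recursive = FALSE,
                                                full.names = FALSE))
  stages <- setdiff(stages, "report")
  has_files <- vapply(stages, function(s)
    length(list.files(file.path(output_dir, s))) > 0, TRUE)
  stages <- stages[has_files]
  if (!length(stages)) stop("no stage outputs found under ", output_dir)
  rep_list <- list(stages_run = stages)
  absent <- function() "not run"
  qc_p <- file.path(output_dir, "call_cell", "aggregate_qc.json")
  rep_list$aggregate_qc <- if (file.exists(qc_p))
    jsonlite::read_json(qc_p) else absent()
  cl_p <- file.path(output_dir, "cluster", "clusters.tsv")
  if (file.exists(cl_p)) {
    cl <- fread(cl_p)
    sizes <- as.list(table(cl$cluster))
    rep_list$clusters <- list(n_clusters = length(sizes), sizes = sizes)
  } else rep_list$clusters <- absent()
  pk_p <- file.path(output_dir, "peaks_combined", "peaks.bed")
  rep_list$n_peaks <- if (file.exists(pk_p)) nrow(fread(pk_p)) else absent()
  da_p <- file.path(output_dir, "diff", "differential.tsv")
  rep_list$differential <- if (file.exists(da_p)) {
    da <- fread(da_p)
    list(n_tests = nrow(da), n_significant = sum(da$qval < 0.05))
  } else absent()
  mo_p <- file.path(output_dir, "motif", "enriched_tfs.tsv")
  rep_list$motifs <- if (file.exists(mo_p)) {
    enr <- fread(mo_p)
    if (nrow(enr)) {
      top <- enr[, .SD[1], by = cluster]
      list(top_motif_per_cluster = as.list(setNames(top$motif,
                                                    paste0("cluster_", top$cluster))))
    } else list(top_motif_per_cluster = list())
  } else absent()
  ts_p <- file.path(output_dir, "qc", "tss_score.txt")
  rep_list$tss_enrichment_score <- if (file.exists(ts_p))
    as.numeric(readLines(ts_p)[1]) else absent()
  dir <- step_dir(output_dir, "report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(rep_list, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  render_report_html(rep_list, file.path(dir, "report.html"))
  invisible(rep_list)
}

render_report_html <- function(rep_list, path) {
  fmt <- function(x) {
    if (identical(x, "not run")) return("<em>not run</em>")
    paste0("<pre>", jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                                     digits = NA, na = "null"), "</pre>")
  }
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>scatacpipe summary report</title></head><body>",
            "<h1>scatacpipe summary report</h1>",
            paste0("<p>Stages run: ", paste(rep_list$stages_run, collapse = ", "),
                   "</p>"),
            "<h2>Aggregate QC</h2>", fmt(rep_list$aggregate_qc),
            "<h2>Peaks</h2>", fmt(rep_list$n_peaks),
            "<h2>TSS enrichment</h2>", fmt(rep_list$tss_enrichment_score),
            "<h2>Clusters</h2>", fmt(rep_list$clusters),
            "<h2>Differential accessibility</h2>", fmt(rep_list$differential),
            "<h2>Motif enrichment</h2>", fmt(rep_list$motifs),
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Validate a summary report against the shipped schema
#'
#' Light structural validation: required keys must be present and, when the
#' stage has run, of the declared type. The schema ships at
#' `system.file("schema", "report_schema.json", package = "scatacpipe")`.
#'
#' @param report report list (from [generate_report()]) or a path to a
#'   `summary.json`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema", "report_schema.json",
                                            package = "scatacpipe"))
  for (field in names(schema$required)) {
    if (is.null(report[[field]]))
      stop("report missing required field '", field, "'")
    type <- schema$required[[field]]
    v <- report[[field]]
    if (identical(v, "not run")) next
    ok <- switch(type,
                 list = is.list(v),
                 number = is.numeric(v) || (is.list(v) && all(vapply(v, is.numeric, TRUE))),
                 array = is.list(v) || is.vector(v),
                 TRUE)
    if (!ok) stop("report field '", field, "' has wrong type (expected ", type, ")")
  }
  invisible(TRUE)
}
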