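#' Specification for the binomial noise-model simulator
#'
#' Defines a peak-by-cell-type bulk profile `r` (columns sum to 1: the
#' fraction of the type's reads in each peak), a noise level `q`, a
#' per-cell fragment scale `n` and the peak count `k`. Counts are later
#' drawn as `Binomial(2, p_i_t)` with
#' `p_i_t = (1 - q) * n * r_i_t / 2 + q * n / (2 * k)`, i.e. `q`
#' interpolates between the bulk profile (`q = 0`, no noise) and a uniform
#' profile over peaks (`q = 1`, pure noise) at a constant expected per-cell
#' total of `n` fragments.
#'
#' @param r peaks x types non-negative matrix; each column must sum to 1
#'   (percent-scale input summing to 100 is rescaled with a warning).
#' @param q noise level in `[0, 1]`.
#' @param n expected fragments per cell; default `k / 10`.
#' @param cells_per_type simulated cells per type.
#' @param seed RNG seed.
#' @return list of class `noise_sim_spec`.
#' @export
noise_sim_spec <- function(r, q, n = nrow(r) / 10, cells_per_type = 200L,
                           seed = 1L) {
  r <- as.matrix(r)
  cs <- colSums(r)
  if (any(abs(cs - 100) < 1e-6)) {
    warning("profile columns sum to 100; rescaling percent values to fractions")
    r <- sweep(r, 2, cs, "/")
    cs <- colSums(r)
  }
  if (any(abs(cs - 1) > 1e-9))
    stop("profile columns must sum to 1 (got ", paste(signif(cs, 4), collapse = ", "), ")")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  k <- nrow(r)
  p <- (1 - q) * n * r / 2 + q * n / (2 * k)
  if (any(p < 0 | p > 1))
    stop("derived success probabilities fall outside [0, 1]; reduce n or ",
         "flatten the profile (max p = ", signif(max(p), 4), ")")
  structure(list(r = r, q = q, n = n, k = k,
                 cells_per_type = as.integer(cells_per_type),
                 p = p, seed = as.integer(seed)),
            class = "noise_sim_spec")
}

#' Default separable bulk profile for the noise simulator
#'
#' Each cell type concentrates `marker_mass` of its reads uniformly on its
#' own block of `markers_per_type` marker peaks and spreads the remainder
#' over all other peaks, giving cleanly separable types at `q = 0`.
#'
#' @param n_types number of cell types.
#' @param k total number of peaks.
#' @param markers_per_type marker peaks per type.
#' @param marker_mass fraction of each type's reads in its markers.
#' @return peaks x types profile matrix with unit column sums.
#' @export
noise_profile <- function(n_types = 3L, k = 1000L, markers_per_type = 100L,
                          marker_mass = 0.8) {
  stopifnot(n_types * markers_per_type <= k, marker_mass > 0, marker_mass < 1)
  r <- matrix(0, k, n_types)
  for (t in seq_len(n_types)) {
    mk <- ((t - 1L) * markers_per_type + 1L):(t * markers_per_type)
    r[mk, t] <- marker_mass / markers_per_type
    r[-mk, t] <- (1 - marker_mass) / (k - markers_per_type)
  }
  colnames(r) <- paste0("type", seq_len(n_types))
  r
}

#' Simulate a noisy peak-by-cell count matrix
#'
#' Draws every entry independently as `Binomial(2, p_i_t)` for the cell's
#' type (see [noise_sim_spec()]); seeded and reproducible.
#'
#' @param spec a [noise_sim_spec()].
#' @return list: `counts` (sparse peaks x cells), `labels` (type per cell).
#' @export
simulate_noise_counts <- function(spec) {
  stopifnot(is(spec, "noise_sim_spec"))
  set.seed(spec$seed)
  n_types <- ncol(spec$r)
  n_cells <- n_types * spec$cells_per_type
  labels <- rep(colnames(spec$r), each = spec$cells_per_type)
  counts <- matrix(0L, spec$k, n_cells)
  for (t in seq_len(n_types)) {
    cols <- ((t - 1L) * spec$cells_per_type + 1L):(t * spec$cells_per_type)
    counts[, cols] <- matrix(
      rbinom(spec$k * spec$cells_per_type, size = 2L, prob = spec$p[, t]),
      spec$k, spec$cells_per_type)
  }
  dimnames(counts) <- list(paste0("peak_", seq_len(spec$k)),
                           paste0("cell_", seq_len(n_cells)))
  list(counts = as(as(counts, "generalMatrix"), "CsparseMatrix"),
       labels = setNames(labels, colnames(counts)))
}

#' Synthesize per-type bulk read pools
#'
#' Builds per-type pools of reads (one peak index per read) from skewed
#' per-type peak profiles, for use with [subsample_bulk()] when no real
#' bulk data is at hand. Profiles follow [noise_profile()].
#'
#' @param n_types number of cell types (default 13).
#' @param k number of peaks.
#' @param reads_per_type pool size per type.
#' @param markers_per_type,marker_mass profile shape (see [noise_profile()]).
#' @param seed RNG seed.
#' @return list: `pools` (list of integer vectors of peak indices), `k`.
#' @export
simulate_bulk_pools <- function(n_types = 13L, k = 2000L,
                                reads_per_type = 50000L,
                                markers_per_type = 100L, marker_mass = 0.8,
                                seed = 1L) {
  set.seed(seed)
  r <- noise_profile(n_types, k, markers_per_type, marker_mass)
  pools <- lapply(seq_len(n_types), function(t) {
    sample.int(k, reads_per_type, replace = TRUE, prob = r[, t])
  })
  names(pools) <- colnames(r)
  list(pools = pools, k = k)
}

#' Specification for the bulk-subsampling simulator
#'
#' @param bulk_pools list of per-type read pools (integer peak indices, one
#'   per mapped read), e.g. from [simulate_bulk_pools()].
#' @param k number of peaks indexed by the pools.
#' @param cells_per_type simulated cells per type (default 200).
#' @param reads_per_cell reads drawn per cell without replacement
#'   (default 10000).
#' @param seed RNG seed.
#' @return list of class `subsample_spec`.
#' @export
subsample_spec <- function(bulk_pools, k, cells_per_type = 200L,
                           reads_per_cell = 10000L, seed = 1L) {
  small <- vapply(bulk_pools, length, 0L) < reads_per_cell
  if (any(small))
    stop("bulk pool smaller than reads_per_cell for type(s): ",
         paste(names(bulk_pools)[small], collapse = ", "))
  structure(list(bulk_pools = bulk_pools, k = as.integer(k),
                 cells_per_type = as.integer(cells_per_type),
                 reads_per_cell = as.integer(reads_per_cell),
                 seed = as.integer(seed)),
            class = "subsample_spec")
}

#' Simulate single cells by subsampling bulk read pools
#'
#' For each simulated cell, exactly `reads_per_cell` reads are drawn
#' uniformly without replacement from its type's bulk pool and tagged with
#' a fresh barcode.
#'
#' @param spec a [subsample_spec()].
#' @return list: `counts` (sparse peaks x cells), `labels` (type per cell).
#' @export
subsample_bulk <- function(spec) {
  stopifnot(is(spec, "subsample_spec"))
  set.seed(spec$seed)
  types <- names(spec$bulk_pools)
  n_cells <- length(types) * spec$cells_per_type
  ii <- list(); jj <- list(); xx <- list()
  labels <- character(n_cells)
  cell <- 0L
  for (t in types) {
    pool <- spec$bulk_pools[[t]]
    for (cc in seq_len(spec$cells_per_type)) {
      cell <- cell + 1L
      labels[cell] <- t
      reads <- pool[sample.int(length(pool), spec$reads_per_cell)]
      tab <- tabulate(reads, nbins = spec$k)
      nz <- which(tab > 0)
      ii[[cell]] <- nz; jj[[cell]] <- rep(cell, length(nz)); xx[[cell]] <- tab[nz]
    }
  }
  counts <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(spec$k, n_cells),
                         dimnames = list(paste0("peak_", seq_len(spec$k)),
                                         paste0("cell_", seq_len(n_cells))))
  list(counts = as(counts, "CsparseMatrix"),
       labels = setNames(labels, colnames(counts)))
}

#' Draw a cell-type composition from a Dirichlet prior
#'
#' Type weights are drawn from a symmetric Dirichlet (shape `alpha` per
#' component) and cell counts from a multinomial over those weights, so
#' counts always sum to `total_cells`.
#'
#' @param n_types number of types (default 13).
#' @param alpha shared Dirichlet shape (default 3).
#' @param total_cells total cells to allocate (default 1000).
#' @param seed RNG seed.
#' @return integer vector of per-type cell counts (sums to `total_cells`),
#'   with the drawn weight vector in the `"weights"` attribute.
#' @export
dirichlet_composition <- function(n_types = 13L, alpha = 3, total_cells = 1000L,
                                  seed = 1L) {
  stopifnot(alpha > 0, n_types >= 1, total_cells >= 0)
  set.seed(seed)
  g <- rgamma(n_types, shape = alpha, rate = 1)
  w <- g / sum(g)
  counts <- as.integer(rmultinom(1, total_cells, w))
  structure(setNames(counts, paste0("type", seq_len(n_types))), weights = w)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)`.
#'
#' @param a,b label vectors of equal length (`>= 2`); any label type.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 items")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-12) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
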