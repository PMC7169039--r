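#' Cluster a count matrix with the default pipeline
#'
#' Convenience wrapper for the default clustering path: normalization
#' (TF-IDF, or log + per-peak depth regression), fast PCA with depth
#' regression, SNN graph and Louvain.
#'
#' @param m features x cells count matrix.
#' @param normalization `"tfidf"` (default) or `"lognorm"`.
#' @param n_components principal components kept.
#' @param k SNN neighbors.
#' @param resolution Louvain resolution.
#' @param seed RNG seed.
#' @param regress_pcs regress log depth out of each component
#'   (the fast path); `FALSE` leaves the components untouched.
#' @return `cluster_assignment` (see [louvain_cluster()]).
#' @export
cluster_counts <- function(m, normalization = c("tfidf", "lognorm"),
                           n_components = 30L, k = 20L, resolution = 0.8,
                           seed = 1L, regress_pcs = TRUE) {
  normalization <- match.arg(normalization)
  depth <- Matrix::colSums(m)
  norm <- if (normalization == "tfidf") tfidf(m) else lognorm_regress(m)
  red <- pca_fast(norm, n_components = n_components,
                  depth = if (regress_pcs) depth else NULL)
  g <- snn_graph(red, k = k)
  louvain_cluster(g, resolution = resolution, seed = seed)
}

#' Clustering accuracy as a function of simulated noise
#'
#' Runs the binomial noise simulator over a grid of noise levels, clusters
#' every replicate with the default pipeline and scores it against the true
#' type labels with the adjusted Rand index.
#'
#' @param q_values noise levels to test.
#' @param n_reps replicates per level.
#' @param profile bulk profile matrix (default [noise_profile()]).
#' @param n expected fragments per cell (default `k / 10`).
#' @param cells_per_type cells per type per replicate.
#' @param seed base RNG seed; replicate `j` at level `i` uses
#'   `seed + 1000 * i + j`.
#' @param ... passed to [cluster_counts()].
#' @return data.table with `q`, `rep`, `ari`.
#' @export
noise_benchmark <- function(q_values = c(0, 0.3, 0.6, 0.9), n_reps = 5L,
                            profile = noise_profile(), n = nrow(profile) / 10,
                            cells_per_type = 200L, seed = 1L, ...) {
  res <- list()
  for (i in seq_along(q_values)) {
    for (j in seq_len(n_reps)) {
      spec <- noise_sim_spec(profile, q = q_values[i], n = n,
                             cells_per_type = cells_per_type,
                             seed = seed + 1000L * i + j)
      sim <- simulate_noise_counts(spec)
      cl <- cluster_counts(sim$counts, seed = seed, ...)
      res[[length(res) + 1L]] <- data.table(
        q = q_values[i], rep = j,
        ari = adjusted_rand_index(sim$labels, cl$labels[names(sim$labels)]))
    }
  }
  data.table::rbindlist(res)
}
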