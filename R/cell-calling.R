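#' Cell-calling thresholds
#'
#' Default filtering rule: a barcode is a cell when its number of unique
#' fragments is greater than 5000 and its fraction of fragments in peaks is
#' greater than 0.5 (both strict inequalities). Optional thresholds on
#' mitochondrial, promoter, enhancer and TSS fractions tighten the rule.
#'
#' @param min_unique_frags unique-fragment threshold (strict `>`).
#' @param min_frip FRiP threshold (strict `>`).
#' @param max_frac_mito optional mitochondrial-fraction cap (strict `<`).
#' @param min_frac_promoter,min_frac_enhancer,min_frac_tss optional
#'   annotation-fraction thresholds (strict `>`).
#' @return list of class `cell_call_config`.
#' @export
cell_call_config <- function(min_unique_frags = 5000, min_frip = 0.5,
                             max_frac_mito = NULL, min_frac_promoter = NULL,
                             min_frac_enhancer = NULL, min_frac_tss = NULL) {
  cfg <- list(min_unique_frags = min_unique_frags, min_frip = min_frip,
              max_frac_mito = max_frac_mito,
              min_frac_promoter = min_frac_promoter,
              min_frac_enhancer = min_frac_enhancer,
              min_frac_tss = min_frac_tss)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v < 0))
      stop("threshold '", nm, "' must be a non-negative number")
    if (!is.null(v) && nm != "min_unique_frags" && v > 1)
      stop("fraction threshold '", nm, "' must be <= 1")
  }
  structure(cfg, class = "cell_call_config")
}

#' Call cells by threshold filtering
#'
#' @param qc a [per_barcode_qc()] table.
#' @param cfg a [cell_call_config()].
#' @return the QC table with `is_cell` set.
#' @export
call_cells_filter <- function(qc, cfg = cell_call_config()) {
  qc <- data.table::copy(as.data.table(qc))
  if (nrow(qc) == 0) { qc[, is_cell := logical(0)]; return(qc[]) }
  need <- c(frac_mito = "max_frac_mito", frac_promoter = "min_frac_promoter",
            frac_enhancer = "min_frac_enhancer", frac_tss = "min_frac_tss")
  ok <- qc$unique_frags > cfg$min_unique_frags & qc$frip > cfg$min_frip
  for (col in names(need)) {
    thr <- cfg[[need[[col]]]]
    if (is.null(thr)) next
    if (!col %in% names(qc))
      stop("threshold on absent QC column '", col, "'")
    ok <- ok & (if (col == "frac_mito") qc[[col]] < thr else qc[[col]] > thr)
  }
  qc[, is_cell := ok]
  qc[]
}

# zero-inflated negative binomial density (mean/size parameterization)
dzinb <- function(x, pi0, mu, size, log = FALSE) {
  p <- (1 - pi0) * dnbinom(x, mu = mu, size = size)
  p[x == 0] <- p[x == 0] + pi0
  if (log) log(p) else p
}

# weighted NB maximum likelihood in (mu, size); mu is the weighted mean,
# size maximized on a log grid refined by optimize()
fit_nb_weighted <- function(x, w, size_range = c(1e-3, 1e4)) {
  sw <- sum(w)
  if (sw <= 0) return(list(mu = NA_real_, size = NA_real_))
  mu <- max(sum(w * x) / sw, 1e-8)
  ll <- function(ls) sum(w * dnbinom(x, mu = mu, size = exp(ls), log = TRUE))
  opt <- optimize(ll, log(size_range), maximum = TRUE, tol = 1e-6)
  list(mu = mu, size = exp(opt$maximum))
}

#' Fit a two-component zero-inflated negative binomial mixture
#'
#' Models per-barcode fragment counts as a mixture of a low-count ambient
#' ("noise") component and a high-count cell component, each zero-inflated
#' negative binomial. Fit by EM: latent variables are the component label
#' and the structural-zero indicator. Initialization is 2-means on
#' `log1p(counts)`; components are relabeled so the cell mean is the larger
#' one. The log-likelihood is non-decreasing across iterations.
#'
#' @param counts non-negative integer counts, one per barcode (named vector
#'   accepted; names propagate to posteriors).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed RNG seed for the initialization.
#' @return list of class `zinb_mixture`: `pi0`, `mu`, `size` (length-2,
#'   `noise`/`cell`), `w` (cell-component weight), `posterior` (per-barcode
#'   cell probability), `loglik` trace, `converged`.
#' @export
fit_zinb_mixture <- function(counts, max_iter = 500L, tol = 1e-6, seed = 1L) {
  x <- counts
  if (any(x < 0) || any(x != floor(x))) stop("counts must be non-negative integers")
  if (length(x) < 50) stop("need at least 50 barcodes to fit the mixture")
  pos <- unique(x[x > 0])
  if (length(pos) < 2)
    stop("degenerate counts (all zero or a single distinct positive value); ",
         "use the threshold filtering strategy instead")
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(log1p(x), centers = 2, nstart = 5))
  hi <- which.max(km$centers)
  comp <- ifelse(km$cluster == hi, 2L, 1L)  # 1 = noise, 2 = cell
  pi0 <- c(0.05, 0.05)
  mu <- size <- numeric(2)
  for (cc in 1:2) {
    f <- fit_nb_weighted(x, as.numeric(comp == cc))
    mu[cc] <- f$mu; size[cc] <- f$size
  }
  w <- mean(comp == 2L)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E step
    lf1 <- dzinb(x, pi0[1], mu[1], size[1], log = TRUE)
    lf2 <- dzinb(x, pi0[2], mu[2], size[2], log = TRUE)
    l1 <- log(1 - w) + lf1; l2 <- log(w) + lf2
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    loglik <- c(loglik, ll)
    if (it > 1 && abs(ll - loglik[it - 1]) / (abs(loglik[it - 1]) + 1e-12) < tol) {
      converged <- TRUE; break
    }
    r2 <- exp(l2 - m) / (exp(l1 - m) + exp(l2 - m))
    r1 <- 1 - r2
    # structural-zero posteriors within each component
    z1 <- z2 <- numeric(length(x))
    is0 <- x == 0
    z1[is0] <- pi0[1] / (pi0[1] + (1 - pi0[1]) * dnbinom(0, mu = mu[1], size = size[1]))
    z2[is0] <- pi0[2] / (pi0[2] + (1 - pi0[2]) * dnbinom(0, mu = mu[2], size = size[2]))
    # M step
    w <- mean(r2)
    w <- min(max(w, 1e-6), 1 - 1e-6)
    pi0[1] <- min(max(sum(r1 * z1) / sum(r1), 1e-8), 1 - 1e-8)
    pi0[2] <- min(max(sum(r2 * z2) / sum(r2), 1e-8), 1 - 1e-8)
    f1 <- fit_nb_weighted(x, r1 * (1 - z1))
    f2 <- fit_nb_weighted(x, r2 * (1 - z2))
    mu[1] <- f1$mu; size[1] <- f1$size
    mu[2] <- f2$mu; size[2] <- f2$size
  }
  # relabel so the cell component has the larger mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); size <- rev(size); pi0 <- rev(pi0); w <- 1 - w
  }
  lf1 <- dzinb(x, pi0[1], mu[1], size[1], log = TRUE)
  lf2 <- dzinb(x, pi0[2], mu[2], size[2], log = TRUE)
  l1 <- log(1 - w) + lf1; l2 <- log(w) + lf2
  m <- pmax(l1, l2)
  post <- exp(l2 - m) / (exp(l1 - m) + exp(l2 - m))
  names(post) <- names(x)
  structure(list(pi0 = setNames(pi0, c("noise", "cell")),
                 mu = setNames(mu, c("noise", "cell")),
                 size = setNames(size, c("noise", "cell")),
                 w = w, posterior = post, loglik = loglik,
                 converged = converged, n_iter = length(loglik)),
            class = "zinb_mixture")
}

#' Posterior cell probability under a fitted ZINB mixture
#' @param fit a [fit_zinb_mixture()] result.
#' @param counts counts to score.
#' @return per-count posterior probability of the cell component.
#' @export
zinb_posterior <- function(fit, counts) {
  l1 <- log(1 - fit$w) + dzinb(counts, fit$pi0["noise"], fit$mu["noise"],
                               fit$size["noise"], log = TRUE)
  l2 <- log(fit$w) + dzinb(counts, fit$pi0["cell"], fit$mu["cell"],
                           fit$size["cell"], log = TRUE)
  m <- pmax(l1, l2)
  unname(exp(l2 - m) / (exp(l1 - m) + exp(l2 - m)))
}

#' Call cells from a ZINB mixture fit
#'
#' @param qc a [per_barcode_qc()] table; the scored quantity is the in-peak
#'   unique-fragment count `round(unique_frags * frip)` by default, matching
#'   the quantity the mixture is normally fit on.
#' @param fit a converged [fit_zinb_mixture()].
#' @param posterior_cutoff minimum posterior cell probability.
#' @param counts optional explicit counts (overrides the default quantity).
#' @return QC table with `is_cell` set.
#' @export
call_cells_zinb <- function(qc, fit, posterior_cutoff = 0.99, counts = NULL) {
  if (!isTRUE(fit$converged))
    stop("ZINB mixture did not converge; refusing to call cells ",
         "(increase max_iter or use call_cells_filter)")
  qc <- data.table::copy(as.data.table(qc))
  if (is.null(counts)) counts <- round(qc$unique_frags * qc$frip)
  qc[, is_cell := zinb_posterior(fit, counts) >= posterior_cutoff]
  qc[]
}

#' Knee-point detection on a barcode rank-count curve
#'
#' Sorts counts in decreasing order, forms the log10(rank) vs log10(count)
#' curve and returns the count at the point of maximum perpendicular
#' distance from the chord joining the curve's endpoints. Barcodes with
#' counts above the returned threshold are candidate cells.
#'
#' @param counts per-barcode counts (zeros are dropped from the curve).
#' @return the count value at the knee, or `NA` if the curve is degenerate
#'   (fewer than 3 distinct positive counts).
#' @export
knee_point <- function(counts) {
  x <- sort(counts[counts > 0], decreasing = TRUE)
  if (length(counts) < 10) stop("need at least 10 barcodes")
  if (length(unique(x)) < 3) return(NA_real_)
  lr <- log10(seq_along(x)); lc <- log10(x)
  p1 <- c(lr[1], lc[1]); p2 <- c(lr[length(lr)], lc[length(lc)])
  v <- p2 - p1; v <- v / sqrt(sum(v^2))
  d <- abs((lr - p1[1]) * v[2] - (lc - p1[2]) * v[1])
  x[which.max(d)]
}
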