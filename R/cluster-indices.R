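# Internal index implementations for clustering solutions. Each is checked
# in the test suite against an independent textbook recomputation.

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `(B/(k-1)) / (W/(n-k))`; larger is better.
#'
#' @param x Numeric matrix (rows = observations).
#' @param labels Integer cluster labels.
#' @return Index value.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  gmean <- colMeans(x)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    cm <- colMeans(xi)
    B <- B + nrow(xi) * sum((cm - gmean)^2)
    W <- W + sum(sweep(xi, 2, cm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio of summed within-cluster
#' scatters to centroid separation; smaller is better.
#'
#' @inheritParams calinski_harabasz
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  gs <- sort(unique(labels)); k <- length(gs)
  if (k < 2) return(NA_real_)
  cents <- t(vapply(gs, function(g) colMeans(x[labels == g, , drop = FALSE]),
                    numeric(ncol(x))))
  scat <- vapply(seq_along(gs), function(i) {
    xi <- x[labels == gs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cents[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_len(k), function(i) {
    r <- vapply(seq_len(k), function(j) {
      if (i == j) return(-Inf)
      (scat[i] + scat[j]) / sqrt(sum((cents[i, ] - cents[j, ])^2))
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(db)
}

#' Mean silhouette width
#'
#' Wrapper over [cluster::silhouette()]; in `[-1, 1]`, larger is better.
#'
#' @inheritParams calinski_harabasz
#' @export
mean_silhouette <- function(x, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(as.matrix(x)))
  mean(sil[, "sil_width"])
}

# pooled within-cluster dispersion (Tibshirani W_k) from squared pairwise
# distances
gap_wk <- function(x, labels) {
  x <- as.matrix(x)
  W <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    if (nrow(xi) < 2) next
    d2 <- as.matrix(stats::dist(xi))^2
    W <- W + sum(d2) / (2 * nrow(xi))  # D_r over ordered pairs / (2 n_r)
  }
  W
}

#' Gap statistic for one clustering
#'
#' `Gap(k) = mean_b log W*_kb - log W_k`, with `B` reference data sets
#' drawn uniformly over the embedding's bounding box and re-clustered by
#' the supplied function.
#'
#' @param x Numeric matrix.
#' @param labels Cluster labels of the real data at this `k`.
#' @param cluster_fun `function(x, k)` returning labels, used on the
#'   reference draws.
#' @param B Number of reference draws (default 20).
#' @param seed Integer seed for the reference draws.
#' @return List `gap`, `s_k` (reference spread, for the Tibshirani
#'   selection rule).
#' @export
gap_statistic <- function(x, labels, cluster_fun, B = 20, seed = 1) {
  x <- as.matrix(x)
  k <- length(unique(labels))
  logW <- log(gap_wk(x, labels))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  set.seed(stage_seed(seed, "gap"))
  logWstar <- vapply(seq_len(B), function(b) {
    ref <- vapply(seq_along(lo), function(j) stats::runif(nrow(x), lo[j], hi[j]),
                  numeric(nrow(x)))
    log(gap_wk(ref, cluster_fun(ref, k)))
  }, numeric(1))
  list(gap = mean(logWstar) - logW,
       s_k = stats::sd(logWstar) * sqrt(1 + 1 / B))
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbour distances of `m` uniformly drawn points
#' (over the data's bounding box) against those of `m` sampled data
#' points: `H = sum(u) / (sum(u) + sum(w))`. Near 0.5 for spatially
#' uniform data, near 1 for strongly clustered data.
#'
#' @param x Numeric matrix.
#' @param m Probe sample size (default 10% of rows, at least 2).
#' @param seed Integer seed.
#' @return Hopkins statistic in `[0, 1]`.
#' @export
hopkins_statistic <- function(x, m = max(2L, ceiling(0.1 * nrow(x))),
                              seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(m < n)
  set.seed(stage_seed(seed, "hopkins"))
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  uni <- vapply(seq_along(lo), function(j) stats::runif(m, lo[j], hi[j]),
                numeric(m))
  if (m == 1) uni <- matrix(uni, nrow = 1)
  probe <- sample.int(n, m)
  u <- vapply(seq_len(m), function(i) {
    min(sqrt(rowSums(sweep(x, 2, uni[i, ])^2)))
  }, numeric(1))
  w <- vapply(probe, function(i) {
    d <- sqrt(rowSums(sweep(x[-i, , drop = FALSE], 2, x[i, ])^2))
    min(d)
  }, numeric(1))
  sum(u) / (sum(u) + sum(w))
}

#' Dunn index
#'
#' Minimum between-cluster distance divided by the maximum within-cluster
#' diameter. Singleton clusters have diameter 0 by convention; if all
#' clusters are singletons the index is `NA`.
#'
#' @inheritParams calinski_harabasz
#' @export
dunn_index <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  gs <- sort(unique(labels))
  if (length(gs) < 2) return(NA_real_)
  diam <- vapply(gs, function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2) return(0)
    max(d[idx, idx])
  }, numeric(1))
  if (all(diam == 0)) return(NA_real_)
  sep <- Inf
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    sep <- min(sep, min(d[labels == gs[i], labels == gs[j]]))
  }
  sep / max(diam)
}

#' Jaccard bootstrap stability
#'
#' Mean, over `B` bootstrap resamples and original clusters, of the best
#' Jaccard match between each original cluster and the clusters obtained
#' by re-fitting the same configuration on the resample (memberships
#' compared on the resampled points).
#'
#' @param x Numeric matrix.
#' @param labels Original cluster labels.
#' @param cluster_fun `function(x, k)` returning labels.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Mean Jaccard stability in `[0, 1]`.
#' @export
jaccard_bootstrap <- function(x, labels, cluster_fun, B = 100, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  set.seed(stage_seed(seed, "jaccard"))
  gs <- sort(unique(labels))
  means <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    lab_b <- tryCatch(cluster_fun(x[idx, , drop = FALSE], k),
                      error = function(e) NULL)
    if (is.null(lab_b)) return(NA_real_)
    uniq <- unique(idx)
    jac <- vapply(gs, function(g) {
      orig <- intersect(which(labels == g), uniq)
      if (length(orig) == 0) return(NA_real_)
      best <- 0
      for (gb in unique(lab_b)) {
        memb <- unique(idx[lab_b == gb])
        j <- length(intersect(orig, memb)) / length(union(orig, memb))
        best <- max(best, j)
      }
      best
    }, numeric(1))
    mean(jac, na.rm = TRUE)
  }, numeric(1))
  mean(means, na.rm = TRUE)
}
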