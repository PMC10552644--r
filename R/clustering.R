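#' Per-arm feature centering
#'
#' Subtracts, within each trial arm, the arm-wise mean of each protein's
#' predicted activity. This removes the direct per-arm concentration
#' offset while preserving inter- and intra-protein variability (the
#' per-protein variance within an arm is unchanged by centering).
#'
#' @param mat An `activity_matrix`.
#' @param arms Per-row arm labels (default: the matrix `arm` attribute).
#' @return Centered matrix with per-arm per-protein means of zero; a
#'   single-row arm centers to a zero row (with a warning).
#' @export
normalize_by_arm <- function(mat, arms = attr(mat, "arm")) {
  if (is.null(arms)) stop("normalize_by_arm: no arm labels")
  stopifnot(length(arms) == nrow(mat))
  out <- unclass(mat)
  for (a in unique(arms)) {
    idx <- arms == a
    if (sum(idx) == 1) {
      warning("normalize_by_arm: arm '", a, "' has a single row")
    }
    out[idx, ] <- sweep(out[idx, , drop = FALSE], 2,
                        colMeans(out[idx, , drop = FALSE]))
  }
  structure(out, arm = arms, groups = attr(mat, "groups"),
            class = class(mat))
}

#' Clustering configuration
#'
#' One cell of the strategy grid: a reduction (PCA or MDS), a target
#' dimensionality (2, 3 or 5), a reduction distance (Euclidean, or
#' 1 - Spearman rank correlation, MDS only), a clustering algorithm and,
#' for hierarchical clustering, a linkage.
#'
#' @param reduction `"pca"` or `"mds"`.
#' @param dims 2, 3 or 5.
#' @param reduction_distance `"euclidean"` or `"spearman"` (MDS only).
#' @param algorithm One of `"kmeans"`, `"som"`, `"spectral"`, `"gmm"`,
#'   `"hierarchical"`.
#' @param linkage Hierarchical linkage: `"average"`, `"complete"` or
#'   `"ward"`.
#' @param k_range Candidate cluster numbers (min 2; silhouette is
#'   undefined at k = 1).
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(reduction = c("mds", "pca"), dims = 5,
                           reduction_distance = c("euclidean", "spearman"),
                           algorithm = c("hierarchical", "kmeans", "som",
                                         "spectral", "gmm"),
                           linkage = c("average", "complete", "ward"),
                           k_range = 2:6) {
  reduction <- match.arg(reduction)
  reduction_distance <- match.arg(reduction_distance)
  algorithm <- match.arg(algorithm)
  linkage <- match.arg(linkage)
  stopifnot(dims %in% c(2, 3, 5), min(k_range) >= 2)
  if (reduction_distance == "spearman" && reduction != "mds") {
    stop("cluster_config: spearman distance is only defined for mds")
  }
  structure(list(reduction = reduction, dims = as.integer(dims),
                 reduction_distance = reduction_distance,
                 algorithm = algorithm, linkage = linkage,
                 k_range = as.integer(k_range)),
            class = "cluster_config")
}

config_id <- function(cfg) {
  paste(cfg$reduction, cfg$dims, cfg$reduction_distance, cfg$algorithm,
        if (cfg$algorithm == "hierarchical") cfg$linkage else "",
        sep = "_")
}

#' The best-performing configuration of the reported strategy
#'
#' Five-dimensional MDS on 1 - Spearman distance followed by hierarchical
#' clustering with Euclidean distance and average linkage.
#'
#' @param k_range Candidate cluster numbers.
#' @export
best_reported_config <- function(k_range = 2:6) {
  cluster_config("mds", 5, "spearman", "hierarchical", "average", k_range)
}

#' Dimensionality reduction
#'
#' PCA returns the top-`dims` principal-component scores (with the
#' explained-variance fractions as an attribute); MDS returns a classical
#' multidimensional scaling of the chosen distance, where the Spearman
#' distance between rows is `1 - spearman rank correlation` of their
#' profiles.
#'
#' @param mat Numeric matrix (rows > dims).
#' @param config A [cluster_config()] (or just `reduction`, `dims`,
#'   `reduction_distance` in a list).
#' @return Rows x dims embedding matrix; attribute `explained_variance`
#'   for PCA.
#' @export
reduce_dims <- function(mat, config) {
  x <- unclass(as.matrix(mat))
  stopifnot(nrow(x) >= config$dims + 1)
  if (config$reduction == "pca") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    emb <- pc$x[, seq_len(config$dims), drop = FALSE]
    attr(emb, "explained_variance") <-
      (pc$sdev^2 / sum(pc$sdev^2))[seq_len(config$dims)]
    return(emb)
  }
  d <- if (config$reduction_distance == "spearman") {
    const <- which(apply(x, 1, stats::sd) == 0)
    if (length(const) > 0) {
      stop("reduce_dims: constant rows under spearman distance: ",
           paste(utils::head(rownames(x)[const] %||% const, 5),
                 collapse = ", "))
    }
    stats::as.dist(1 - stats::cor(t(x), method = "spearman"))
  } else {
    stats::dist(x)
  }
  emb <- stats::cmdscale(d, k = config$dims)
  if (ncol(emb) < config$dims) {
    stop("reduce_dims: mds produced fewer than ", config$dims,
         " positive-eigenvalue dimensions")
  }
  rownames(emb) <- rownames(x)
  emb
}

#' Fit one clustering algorithm at a fixed k
#'
#' @param x Embedding matrix.
#' @param algorithm,k,linkage,seed See [cluster_config()].
#' @return Integer labels in `1..k` (re-coded to consecutive integers).
#' @export
fit_clusters <- function(x, algorithm, k, linkage = "average", seed = 1) {
  x <- as.matrix(x)
  set.seed(stage_seed(seed, paste0("fit_", algorithm), k))
  labels <- switch(
    algorithm,
    kmeans = stats::kmeans(x, centers = k, nstart = 10,
                           iter.max = 100)$cluster,
    hierarchical = {
      meth <- if (linkage == "ward") "ward.D2" else linkage
      stats::cutree(stats::hclust(stats::dist(x), method = meth), k = k)
    },
    gmm = {
      fit <- mclust::Mclust(x, G = k, verbose = FALSE)
      if (is.null(fit)) stop("gmm did not converge")
      fit$classification
    },
    spectral = {
      # specc is restart-sensitive (embedded k-means) and its automatic
      # sigma estimation can fail on block-structured kernels; restart a
      # few times (median-distance sigma as fallback) and keep the
      # best-silhouette labeling
      one_fit <- function() {
        tryCatch(as.integer(kernlab::specc(x, centers = k)),
                 error = function(e) {
                   sig <- 1 / (2 * stats::median(stats::dist(x))^2)
                   as.integer(kernlab::specc(x, centers = k,
                                             kernel = "rbfdot",
                                             kpar = list(sigma = sig)))
                 })
      }
      best <- NULL; best_sil <- -Inf
      for (r in 1:5) {
        lab <- tryCatch(one_fit(), error = function(e) NULL)
        if (is.null(lab) || length(unique(lab)) < 2) next
        sil <- mean_silhouette(x, lab)
        if (sil > best_sil) { best <- lab; best_sil <- sil }
      }
      if (is.null(best)) stop("spectral clustering did not converge")
      best
    },
    som = {
      # 1-D chain of k nodes so that node = cluster; restarted from
      # random row samples, keeping the run with the lowest quantization
      # error among those with k live nodes
      grid <- class::somgrid(xdim = k, ydim = 1, topo = "rectangular")
      best <- NULL; best_err <- Inf; best_live <- 0
      for (r in 1:10) {
        init <- x[sample.int(nrow(x), k), , drop = FALSE]
        sm <- class::batchSOM(x, grid, radii = c(2, 1, 0.5, 0),
                              init = init)
        lab <- apply(x, 1, function(row) {
          which.min(colSums((t(sm$codes) - row)^2))
        })
        err <- sum((x - sm$codes[lab, , drop = FALSE])^2)
        live <- length(unique(lab))
        if (live > best_live || (live == best_live && err < best_err)) {
          best <- lab; best_err <- err; best_live <- live
        }
      }
      best
    },
    stop("unknown algorithm ", algorithm))
  as.integer(factor(labels))
}

#' Run the clustering grid
#'
#' For every configuration, embeds the data once and fits every candidate
#' `k`, computing the Calinski-Harabasz, Davies-Bouldin, Gap and
#' silhouette indices; each index nominates an optimal `k`, and the
#' silhouette's choice is recorded as the configuration's `k`
#' (prioritized over the other indices). Algorithm failures at a given
#' `k` flag the solution instead of aborting the grid.
#'
#' @param mat Normalized activity matrix (or any numeric matrix).
#' @param configs List of [cluster_config()].
#' @param seed Integer seed.
#' @param gap_B Reference draws for the gap statistic.
#' @return List of `cluster_solution` objects: `config`, `embedding`,
#'   `labels` (at the chosen k), `k`, `indices` (per-k table),
#'   `optimal_k` (per index), `failed_k`.
#' @export
cluster_grid <- function(mat, configs, seed = 1, gap_B = 20) {
  if (inherits(configs, "cluster_config")) configs <- list(configs)
  lapply(configs, function(cfg) {
    emb <- reduce_dims(mat, cfg)
    stopifnot(max(cfg$k_range) <= nrow(emb) - 1)
    cfun <- function(x, k) fit_clusters(x, cfg$algorithm, k, cfg$linkage,
                                        seed)
    rows <- list(); labels_k <- list(); failed <- integer(0)
    for (k in cfg$k_range) {
      lab <- tryCatch(cfun(emb, k), error = function(e) NULL)
      if (is.null(lab) || length(unique(lab)) < 2) {
        failed <- c(failed, k)
        next
      }
      labels_k[[as.character(k)]] <- lab
      gap <- gap_statistic(emb, lab, cfun, B = gap_B, seed = seed)
      rows[[as.character(k)]] <- data.frame(
        k = k,
        calinski_harabasz = calinski_harabasz(emb, lab),
        davies_bouldin = davies_bouldin(emb, lab),
        gap = gap$gap, gap_s = gap$s_k,
        silhouette = mean_silhouette(emb, lab))
    }
    if (length(rows) == 0) {
      return(structure(list(config = cfg, embedding = emb, labels = NULL,
                            k = NA_integer_, indices = NULL,
                            optimal_k = NULL, failed_k = failed,
                            converged = FALSE),
                       class = "cluster_solution"))
    }
    idx <- do.call(rbind, rows)
    # Tibshirani rule: smallest k with Gap(k) >= Gap(k+1) - s_{k+1}
    gap_k <- idx$k[nrow(idx)]
    for (i in seq_len(nrow(idx) - 1)) {
      if (idx$gap[i] >= idx$gap[i + 1] - idx$gap_s[i + 1]) {
        gap_k <- idx$k[i]; break
      }
    }
    optimal_k <- c(calinski_harabasz = idx$k[which.max(idx$calinski_harabasz)],
                   davies_bouldin = idx$k[which.min(idx$davies_bouldin)],
                   gap = gap_k,
                   silhouette = idx$k[which.max(idx$silhouette)])
    k_sel <- optimal_k[["silhouette"]]
    structure(list(config = cfg, embedding = emb,
                   labels = labels_k[[as.character(k_sel)]], k = k_sel,
                   indices = idx, optimal_k = optimal_k, failed_k = failed,
                   converged = TRUE),
              class = "cluster_solution")
  })
}

#' Quality report for a clustering solution
#'
#' The three stability/structure indicators: Hopkins statistic (10%
#' probe sample against a uniform bounding-box null), Dunn index, and
#' mean Jaccard bootstrap stability over `n_bootstrap` resamples.
#'
#' @param solution A `cluster_solution` from [cluster_grid()].
#' @param n_bootstrap Bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return List of class `quality_report`: `hopkins`, `dunn`,
#'   `jaccard_bootstrap`.
#' @export
quality <- function(solution, n_bootstrap = 100, seed = 1) {
  stopifnot(inherits(solution, "cluster_solution"), solution$converged)
  emb <- solution$embedding
  cfg <- solution$config
  cfun <- function(x, k) fit_clusters(x, cfg$algorithm, k, cfg$linkage, seed)
  structure(list(
    hopkins = hopkins_statistic(emb, seed = seed),
    dunn = dunn_index(emb, solution$labels),
    jaccard_bootstrap = jaccard_bootstrap(emb, solution$labels, cfun,
                                          B = n_bootstrap, seed = seed)),
    class = "quality_report")
}

#' Select the best clustering solution
#'
#' Ranks candidate solutions lexicographically on their quality triple
#' (Jaccard bootstrap, then Hopkins, then Dunn), each rounded to two
#' decimals; ties resolve to the earliest configuration, so selection is
#' deterministic and invariant to permutations up to that documented
#' tie-break.
#'
#' @param solutions List of `cluster_solution`.
#' @param reports List of matching `quality_report`.
#' @return List `solution`, `report`, `rank` (selection order).
#' @export
select_best <- function(solutions, reports) {
  stopifnot(length(solutions) == length(reports), length(solutions) > 0)
  key <- vapply(reports, function(r) {
    c(round(r$jaccard_bootstrap, 2), round(r$hopkins, 2), round(r$dunn, 2))
  }, numeric(3))
  ord <- order(-key[1, ], -key[2, ], -key[3, ], seq_along(solutions))
  list(solution = solutions[[ord[1]]], report = reports[[ord[1]]],
       rank = ord)
}

#' Euclidean distances between cluster centroids
#'
#' @param x Embedding matrix.
#' @param labels Cluster labels (>= 2 clusters).
#' @return Symmetric zero-diagonal distance matrix.
#' @export
intercluster_distances <- function(x, labels) {
  x <- as.matrix(x)
  gs <- sort(unique(labels))
  stopifnot(length(gs) >= 2)
  cents <- t(vapply(gs, function(g) colMeans(x[labels == g, , drop = FALSE]),
                    numeric(ncol(x))))
  d <- as.matrix(stats::dist(cents))
  dimnames(d) <- list(gs, gs)
  d
}

#' Demographic characterization of clusters
#'
#' For each cluster versus the rest: two-sided t-tests on age, height,
#' weight and BMI; chi-squared on sex (with the male:female ratio);
#' Fisher's exact test on each comorbidity tag; arm incidence; and
#' Benjamini-Hochberg correction across the whole table.
#'
#' @param labels Cluster labels aligned to patient-arm rows.
#' @param patients `virtual_population` rows aligned to `labels` (one row
#'   per patient-arm model).
#' @param arms Per-row arm labels (optional).
#' @return data.frame with one row per (cluster, variable): estimate
#'   columns, `p`, `q`. Empty clusters are excluded with a warning.
#' @export
characterize_clusters <- function(labels, patients, arms = NULL) {
  stopifnot(length(labels) == nrow(patients))
  gs <- sort(unique(labels))
  tags <- setdiff(unique(unlist(strsplit(patients$comorbidities, ";"))), "")
  rows <- list()
  for (g in gs) {
    sel <- labels == g
    if (sum(sel) == 0) { warning("empty cluster ", g); next }
    for (v in c("age", "height_cm", "weight_kg", "bmi")) {
      x <- patients[[v]][sel]; y <- patients[[v]][!sel]
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) NA_real_ else
        stats::t.test(x, y)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        cluster = g, variable = v, test = "t",
        mean = mean(x), sd = stats::sd(x), p = p)
    }
    tb <- table(factor(patients$sex[sel] == "male", c(FALSE, TRUE)),
                dnn = NULL)
    mf <- unname(tb["TRUE"] / max(tb["FALSE"], 1))
    cs <- suppressWarnings(stats::chisq.test(
      rbind(table(factor(patients$sex[sel], c("male", "female"))),
            table(factor(patients$sex[!sel], c("male", "female"))))))
    rows[[length(rows) + 1]] <- data.frame(
      cluster = g, variable = "sex_mf_ratio", test = "chisq",
      mean = mf, sd = NA_real_, p = cs$p.value)
    for (tg in tags) {
      has <- has_tag(patients, tg)
      ft <- stats::fisher.test(table(factor(sel, c(FALSE, TRUE)),
                                     factor(has, c(FALSE, TRUE))))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = g, variable = paste0("tag_", tg), test = "fisher",
        mean = mean(has[sel]), sd = NA_real_, p = ft$p.value)
    }
    if (!is.null(arms)) {
      for (a in unique(arms)) {
        rows[[length(rows) + 1]] <- data.frame(
          cluster = g, variable = paste0("arm_", a), test = "incidence",
          mean = mean(arms[sel] == a), sd = NA_real_, p = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  testable <- !is.na(out$p)
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out
}

#' Cluster-differential proteins
#'
#' A protein is differential for a cluster when its cluster mean deviates
#' from the overall mean by more than `delta_min` (default 0.1 activity
#' units) and the Wilcoxon rank-sum test of cluster versus rest survives
#' Benjamini-Hochberg FDR at `q_max` (default 1e-4). The sign of the
#' deviation routes the protein to the cluster's UP or DOWN list.
#'
#' @param mat Activity matrix (typically arm-normalized).
#' @param labels Cluster labels per row.
#' @param delta_min Minimum absolute mean difference.
#' @param q_max FDR threshold.
#' @return data.frame `cluster, protein, direction, mean_diff, q`.
#' @export
differential_proteins <- function(mat, labels, delta_min = 0.1,
                                  q_max = 1e-4) {
  x <- unclass(as.matrix(mat))
  gs <- sort(unique(labels))
  overall <- colMeans(x)
  rows <- list()
  for (g in gs) {
    sel <- labels == g
    for (j in seq_len(ncol(x))) {
      diff_j <- mean(x[sel, j]) - overall[j]
      p <- if (stats::sd(x[, j]) == 0) 1 else
        suppressWarnings(stats::wilcox.test(x[sel, j], x[!sel, j],
                                            exact = FALSE)$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = g, protein = colnames(x)[j], mean_diff = unname(diff_j),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  keep <- abs(out$mean_diff) > delta_min & out$q < q_max
  out <- out[keep, , drop = FALSE]
  out$direction <- ifelse(out$mean_diff > 0, "UP", "DOWN")
  rownames(out) <- NULL
  out[, c("cluster", "protein", "direction", "mean_diff", "q")]
}

# stratified k-fold assignment (fold ids per observation)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# train a one-feature threshold rule (midpoint scan maximizing balanced
# accuracy, vectorized via cumulative class counts) and return its BACC on
# the test split
bacc_threshold_cv <- function(x, y, k = 10, seed = 1) {
  set.seed(stage_seed(seed, "bacc"))
  y <- factor(y)
  lev <- levels(y)
  k <- max(2L, min(k, min(table(y))))
  fold <- stratified_folds(y, k)
  bacc_fold <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    xt <- x[tr]; yt <- y[tr]
    o <- order(xt)
    xs <- xt[o]; cls2 <- yt[o] == lev[2]
    n <- length(xs)
    tot2 <- sum(cls2); tot1 <- n - tot2
    # threshold after position i (i = 0..n): predict ">" for i+1..n
    cum2 <- c(0, cumsum(cls2)); cum1 <- c(0, cumsum(!cls2))
    sens_gt <- (tot2 - cum2) / tot2
    spec_gt <- cum1 / tot1
    bacc_gt <- (sens_gt + spec_gt) / 2
    bacc_lt <- 1 - bacc_gt
    thr_at <- c(xs[1] - 1, (xs[-1] + xs[-n]) / 2, xs[n] + 1)
    i_gt <- which.max(bacc_gt); i_lt <- which.max(bacc_lt)
    if (bacc_gt[i_gt] >= bacc_lt[i_lt]) {
      thr <- thr_at[i_gt]; dir <- 1
    } else {
      thr <- thr_at[i_lt]; dir <- -1
    }
    xv <- x[!tr]; yv <- y[!tr]
    pred <- if (dir == 1) xv > thr else xv < thr
    sens <- mean(pred[yv == lev[2]])
    spec <- mean(!pred[yv == lev[1]])
    (sens + spec) / 2
  }, numeric(1))
  mean(bacc_fold, na.rm = TRUE)
}

#' Cluster-classifier proteins
#'
#' For each protein and each pair of clusters, evaluates a single-feature
#' threshold classifier by stratified k-fold (default 10) cross-validated
#' balanced accuracy. Proteins exceeding `bacc_min` (default 0.8) for at
#' least one pair are reported, with a permutation p-value (labels
#' permuted, same CV procedure) attached for the passing pairs.
#'
#' @param mat Activity matrix.
#' @param labels Cluster labels (>= 2 clusters).
#' @param k_folds CV folds (reduced with a warning when a cluster is
#'   smaller).
#' @param bacc_min Reporting threshold on balanced accuracy.
#' @param n_perm Label permutations for the p-value (default 199; 0
#'   skips).
#' @param seed Integer seed.
#' @return data.frame `protein, cluster_a, cluster_b, bacc, perm_p`
#'   restricted to proteins with at least one pair above `bacc_min`
#'   (all pairs of such proteins are reported, mirroring a
#'   per-protein table).
#' @export
classifier_proteins <- function(mat, labels, k_folds = 10, bacc_min = 0.8,
                                n_perm = 199, seed = 1) {
  x <- unclass(as.matrix(mat))
  gs <- sort(unique(labels))
  stopifnot(length(gs) >= 2)
  if (min(table(labels)) < k_folds) {
    warning("classifier_proteins: smallest cluster has fewer than ",
            k_folds, " members; folds reduced")
  }
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  rows <- list()
  for (j in seq_len(ncol(x))) {
    for (pr in pairs) {
      sel <- labels %in% pr
      y <- factor(labels[sel], levels = pr)
      b <- bacc_threshold_cv(x[sel, j], y, k = k_folds,
                             seed = stage_seed(seed, "pair", j))
      rows[[length(rows) + 1]] <- data.frame(
        protein = colnames(x)[j], cluster_a = pr[1], cluster_b = pr[2],
        bacc = b, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  pass_prot <- unique(out$protein[out$bacc > bacc_min])
  out <- out[out$protein %in% pass_prot, , drop = FALSE]
  out$perm_p <- NA_real_
  if (n_perm > 0 && nrow(out) > 0) {
    set.seed(stage_seed(seed, "perm"))
    for (i in which(out$bacc > bacc_min)) {
      pr <- c(out$cluster_a[i], out$cluster_b[i])
      sel <- labels %in% pr
      y <- factor(labels[sel], levels = pr)
      xj <- x[sel, out$protein[i]]
      null_b <- vapply(seq_len(n_perm), function(b) {
        bacc_threshold_cv(xj, sample(y), k = k_folds,
                          seed = stage_seed(seed, "permfold", b))
      }, numeric(1))
      out$perm_p[i] <- (1 + sum(null_b >= out$bacc[i])) / (1 + n_perm)
    }
  }
  rownames(out) <- NULL
  out
}
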