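test_that("arm-wise centering zeroes per-arm means, preserves variance", {
  fx <- make_grouped_activity(1, n_per_group = 10, n_proteins = 12)
  mat <- rbind(unclass(fx$activity), unclass(fx$activity) + 0.2)
  mat <- structure(mat, arm = rep(c("a", "b"), each = nrow(fx$activity)),
                   class = c("activity_matrix", "matrix", "array"))
  cen <- normalize_by_arm(mat)
  for (a in c("a", "b")) {
    sub <- cen[attr(cen, "arm") == a, ]
    expect_true(all(abs(colMeans(sub)) < 1e-12))
    raw <- mat[attr(mat, "arm") == a, ]
    expect_equal(apply(sub, 2, var), apply(raw, 2, var), tolerance = 1e-12)
  }
  # single-arm input equals global centering
  one <- structure(unclass(fx$activity), arm = rep("a", nrow(fx$activity)),
                   class = class(mat))
  expect_equal(unclass(normalize_by_arm(one))[, ],
               scale(unclass(fx$activity), scale = FALSE)[, ],
               tolerance = 1e-12)
})

test_that("PCA reduction is exact on low-rank data", {
  set.seed(2)
  basis <- matrix(rnorm(10 * 2), 10, 2)
  scores <- matrix(rnorm(60 * 2), 60, 2)
  x <- scores %*% t(basis)          # exactly rank 2
  emb <- reduce_dims(x, cluster_config("pca", 2, "euclidean", "kmeans"))
  expect_equal(sum(attr(emb, "explained_variance")), 1, tolerance = 1e-9)
  expect_equal(dim(emb), c(60, 2))
})

test_that("classical MDS recovers a planar configuration (Procrustes)", {
  set.seed(3)
  x <- matrix(rnorm(80), 40, 2)
  emb <- reduce_dims(x, cluster_config("mds", 2, "euclidean", "kmeans"))
  # align by Procrustes rotation and compare
  xc <- scale(x, scale = FALSE); ec <- scale(emb, scale = FALSE)
  sv <- svd(t(ec) %*% xc)
  rot <- sv$u %*% t(sv$v)
  expect_lt(max(abs(ec %*% rot - xc)), 1e-6)
})

test_that("spearman-distance MDS accepts five dimensions", {
  fx <- make_grouped_activity(4, n_per_group = 10, n_proteins = 15)
  emb <- reduce_dims(unclass(fx$activity), best_reported_config())
  expect_equal(dim(emb), c(30, 5))
  # constant rows are rejected by name
  bad <- unclass(fx$activity); bad[3, ] <- 0.5
  rownames(bad) <- sprintf("row%02d", seq_len(nrow(bad)))
  expect_error(reduce_dims(bad, best_reported_config()), "row03")
})

test_that("every algorithm finds k = 3 on well-separated blobs", {
  blobs <- make_blobs(1)
  suppressWarnings({
    for (alg in c("kmeans", "hierarchical", "gmm", "spectral", "som")) {
      cfg <- cluster_config("pca", 2, "euclidean", alg, k_range = 2:5)
      sol <- cluster_grid(blobs$x, cfg, seed = 1, gap_B = 5)[[1]]
      expect_equal(sol$k, 3)
      expect_gt(rand_index(sol$labels, blobs$truth), 0.95)
      expect_false(1 %in% sol$indices$k)
    }
  })
})

test_that("silhouette's k overrides disagreeing indices", {
  blobs <- make_blobs(2)
  sol <- cluster_grid(blobs$x,
                      cluster_config("pca", 2, "euclidean", "kmeans",
                                     k_range = 2:6),
                      seed = 2, gap_B = 5)[[1]]
  expect_equal(sol$k, unname(sol$optimal_k[["silhouette"]]))
})

test_that("indices match independent textbook recomputation", {
  set.seed(9)
  x <- matrix(rnorm(100), 50, 2)
  lab <- sample(1:3, 50, replace = TRUE)
  # Calinski-Harabasz from scratch
  gm <- colMeans(x); B <- 0; W <- 0
  for (g in 1:3) {
    xg <- x[lab == g, , drop = FALSE]
    B <- B + nrow(xg) * sum((colMeans(xg) - gm)^2)
    W <- W + sum(sweep(xg, 2, colMeans(xg))^2)
  }
  expect_equal(calinski_harabasz(x, lab), (B / 2) / (W / 47),
               tolerance = 1e-9)
  # Davies-Bouldin from scratch
  cent <- t(sapply(1:3, function(g) colMeans(x[lab == g, , drop = FALSE])))
  s <- sapply(1:3, function(g) {
    mean(sqrt(rowSums(sweep(x[lab == g, , drop = FALSE], 2,
                            cent[g, ])^2)))
  })
  db <- mean(sapply(1:3, function(i) {
    max(sapply(setdiff(1:3, i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }))
  }))
  expect_equal(davies_bouldin(x, lab), db, tolerance = 1e-9)
  # silhouette from scratch (full pairwise loop)
  d <- as.matrix(dist(x))
  sil <- sapply(1:50, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(50) != i])
    b <- min(sapply(setdiff(1:3, lab[i]), function(g) {
      mean(d[i, lab == g])
    }))
    (b - a) / max(a, b)
  })
  expect_equal(mean_silhouette(x, lab), mean(sil), tolerance = 1e-9)
  # Dunn from scratch
  sep <- min(sapply(1:2, function(i) {
    min(sapply((i + 1):3, function(j) min(d[lab == i, lab == j])))
  }))
  diam <- max(sapply(1:3, function(g) max(d[lab == g, lab == g])))
  expect_equal(dunn_index(x, lab), sep / diam, tolerance = 1e-9)
})

test_that("index ranges hold on fuzzed inputs", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    x <- matrix(rnorm(2 * n, sd = sample(c(0.1, 1, 10), 1)), n, 2)
    lab <- sample(1:sample(2:4, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_true(abs(mean_silhouette(x, lab)) <= 1)
    h <- hopkins_statistic(x, seed = i)
    expect_true(h >= 0 && h <= 1)
    dn <- dunn_index(x, lab)
    expect_true(is.na(dn) || dn >= 0)
  }
})

test_that("Hopkins statistic is near 0.5 on uniform data", {
  hs <- vapply(1:20, function(s) {
    set.seed(s)
    hopkins_statistic(matrix(stats::runif(400), ncol = 2), seed = s)
  }, numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.1)
})

test_that("stability diagnostics separate tight blobs from noise", {
  set.seed(4)
  x <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
             matrix(rnorm(100, 30, 0.2), ncol = 2))
  lab <- rep(1:2, each = 50)
  cfun <- function(x, k) fit_clusters(x, "kmeans", k, seed = 4)
  expect_gt(jaccard_bootstrap(x, lab, cfun, B = 30, seed = 4), 0.95)
  expect_gt(dunn_index(x, lab), 1)
  q <- quality(structure(list(config = cluster_config("pca", 2,
                                                      "euclidean", "kmeans"),
                              embedding = x, labels = lab, k = 2,
                              converged = TRUE),
                         class = "cluster_solution"),
               n_bootstrap = 20, seed = 1)
  expect_named(unclass(q), c("hopkins", "dunn", "jaccard_bootstrap"))
})

test_that("select_best ranks on the quality triple deterministically", {
  mk <- function(j, h, d, id) {
    list(solution = structure(list(id = id), class = "cluster_solution"),
         report = structure(list(hopkins = h, dunn = d,
                                 jaccard_bootstrap = j),
                            class = "quality_report"))
  }
  cands <- list(mk(0.50, 0.80, 0.10, "a"), mk(0.90, 0.85, 0.30, "b"),
                mk(0.90, 0.70, 0.50, "c"))
  sols <- lapply(cands, `[[`, "solution")
  reps <- lapply(cands, `[[`, "report")
  best <- select_best(sols, reps)
  expect_equal(best$solution$id, "b")   # dominant jaccard, then hopkins
  # singleton
  single <- select_best(sols[1], reps[1])
  expect_equal(single$solution$id, "a")
  # permutation invariance of the winner
  perm <- c(3, 1, 2)
  best_p <- select_best(sols[perm], reps[perm])
  expect_equal(best_p$solution$id, "b")
})

test_that("intercluster centroid distances are metric and exact", {
  x <- rbind(matrix(0, 10, 2),
             matrix(rep(c(3, 4), each = 10), 10, 2))
  lab <- rep(1:2, each = 10)
  d <- intercluster_distances(x, lab)
  expect_equal(d["1", "2"], 5)
  expect_equal(d, t(d))
  expect_equal(diag(d), c("1" = 0, "2" = 0))
  # brute-force recomputation on random data
  set.seed(6)
  xr <- matrix(rnorm(90), 45, 2)
  lr <- sample(1:3, 45, replace = TRUE)
  dr <- intercluster_distances(xr, lr)
  for (i in 1:2) for (j in (i + 1):3) {
    ci <- colMeans(xr[lr == i, , drop = FALSE])
    cj <- colMeans(xr[lr == j, , drop = FALSE])
    expect_equal(dr[as.character(i), as.character(j)],
                 sqrt(sum((ci - cj)^2)), tolerance = 1e-12)
  }
})

test_that("cluster characterization controls type I error and finds
           planted shifts", {
  # null: identical distributions -> BH-significant rows are rare
  fp <- vapply(1:40, function(s) {
    pop <- assign_comorbidities(
      generate_population(ref_population_spec(60), height_model(), s),
      default_comorbidities(), s)
    set.seed(s)
    lab <- sample(1:3, 60, replace = TRUE)
    tab <- characterize_clusters(lab, pop)
    mean(tab$q[!is.na(tab$q)] < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.05)
  # power: +2 sigma weight shift in one cluster
  pop <- assign_comorbidities(
    generate_population(ref_population_spec(300), height_model(), 77),
    default_comorbidities(), 77)
  set.seed(77)
  lab <- sample(1:3, 300, replace = TRUE)
  pop$weight_kg[lab == 2] <- pop$weight_kg[lab == 2] + 2 * sd(pop$weight_kg)
  tab <- characterize_clusters(lab, pop)
  expect_lt(tab$q[tab$cluster == 2 & tab$variable == "weight_kg"], 0.001)
  expect_true("sex_mf_ratio" %in% tab$variable)
})

test_that("differential proteins obey both the effect and FDR gates", {
  set.seed(15)
  n <- 900; lab <- rep(1:3, each = 300)
  mat <- matrix(rnorm(n * 6, 0, 0.05), n, 6,
                dimnames = list(NULL, sprintf("pr%d", 1:6)))
  mat[lab == 1, "pr1"] <- mat[lab == 1, "pr1"] + 0.3   # planted UP
  mat[, "pr6"] <- 0.42                                  # constant
  # pr5: tiny but ultra-significant shift (0.09 < 0.1 gate)
  mat[lab == 2, "pr5"] <- mat[lab == 2, "pr5"] + 0.09
  res <- differential_proteins(mat, lab)
  expect_true(any(res$cluster == 1 & res$protein == "pr1" &
                    res$direction == "UP"))
  expect_false("pr6" %in% res$protein)
  expect_false(any(res$protein == "pr5" & res$cluster == 2))
})

test_that("balanced accuracy is calibrated at chance and perfection", {
  set.seed(16)
  # identical distributions: chance level
  x0 <- rnorm(1000); y0 <- rep(1:2, each = 500)
  b0 <- psorqsp:::bacc_threshold_cv(x0, factor(y0), k = 10, seed = 1)
  expect_lt(abs(b0 - 0.5), 0.05)
  # disjoint supports: perfect
  x1 <- c(runif(100, 0, 1), runif(100, 5, 6))
  b1 <- psorqsp:::bacc_threshold_cv(x1, factor(rep(1:2, each = 100)),
                                    k = 10, seed = 1)
  expect_equal(b1, 1.0)
})

test_that("label-permuted features concentrate at BACC 0.5", {
  set.seed(17)
  x <- rnorm(120); y <- factor(rep(1:2, each = 60))
  b <- vapply(1:200, function(i) {
    psorqsp:::bacc_threshold_cv(x, sample(y), k = 5, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(b) - 0.5), 0.02)
})

test_that("classifier screening reports separating proteins above 0.8", {
  set.seed(18)
  n <- 90; lab <- rep(1:3, each = 30)
  mat <- matrix(rnorm(n * 4, 0, 0.3), n, 4,
                dimnames = list(NULL, sprintf("pr%d", 1:4)))
  mat[lab == 1, "pr2"] <- mat[lab == 1, "pr2"] + 10   # disjoint support
  suppressWarnings(
    res <- classifier_proteins(mat, lab, n_perm = 49, seed = 3))
  r12 <- res[res$protein == "pr2" & res$cluster_a == 1 &
               res$cluster_b == 2, ]
  expect_equal(r12$bacc, 1.0)
  expect_lt(r12$perm_p, 0.05)
  expect_true(all(vapply(unique(res$protein), function(p) {
    any(res$bacc[res$protein == p] > 0.8)
  }, logical(1))))
})

test_that("full strategy recovers planted mechanistic groups", {
  hits <- vapply(1:20, function(s) {
    fx <- make_grouped_activity(s)     # shift 0.5, noise 0.1 -> ratio 5
    norm <- normalize_by_arm(fx$activity)
    sol <- cluster_grid(norm, best_reported_config(2:6), seed = s,
                        gap_B = 5)[[1]]
    sol$k == 3 && rand_index(sol$labels, fx$groups) > 0.95
  }, logical(1))
  expect_gte(sum(hits), 19)
})
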