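#' Cohort-to-population size arithmetic
#'
#' The population size needed for the rarest subgroup to reach a target
#' cohort: `ceiling(cohort_n / frequency)`. With a 15-patient cohort and
#' a 4.38% frequency this gives 343.
#'
#' @param cohort_n Required subgroup cohort size.
#' @param frequency Subgroup frequency in `(0, 1]`.
#' @return Integer population size.
#' @export
cohort_population_size <- function(cohort_n, frequency) {
  stopifnot(cohort_n > 0, frequency > 0, frequency <= 1)
  as.integer(ceiling(cohort_n / frequency))
}

# best two-feature linear classifier: exhaustive pair search (greedy seeded
# by single-feature t-statistics beyond `pair_cap` features), LDA decision
# rule, k-fold CV accuracy
best_pair_cv <- function(x, y, k_folds = 10, pair_cap = 200) {
  p <- ncol(x)
  pairs <- if (p <= pair_cap) {
    utils::combn(p, 2, simplify = FALSE)
  } else {
    # greedy: rank features by |t|, pair the top feature with the rest
    tstat <- vapply(seq_len(p), function(j) {
      abs(stats::t.test(x[y == levels(y)[1], j],
                        x[y == levels(y)[2], j])$statistic)
    }, numeric(1))
    top <- order(-tstat)[1:pair_cap]
    lapply(top[-1], function(j) c(top[1], j))
  }
  k <- max(2L, min(k_folds, min(table(y))))
  fold <- stratified_folds(y, k)
  cv_acc <- function(cols) {
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- tryCatch(MASS::lda(x[tr, cols, drop = FALSE], grouping = y[tr]),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- stats::predict(fit, x[!tr, cols, drop = FALSE])$class
      mean(pred == y[!tr])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }
  accs <- vapply(pairs, cv_acc, numeric(1))
  best <- which.max(accs)
  list(accuracy = accs[best], pair = pairs[[best]])
}

#' Progressive-sampling learning curve
#'
#' Estimates the minimum sample size at which a two-feature classifier
#' reaches stated fractions of its maximum accuracy. For each subset size
#' (starting at 10), the data is repeatedly subsampled with class
#' stratification; on each subsample the best two-feature pair is found
#' by exhaustive search (greedy beyond 200 features) with a linear
#' discriminant decision rule, scored by k-fold (default 10)
#' cross-validated accuracy. The maximum accuracy is the same procedure
#' on the full data set. `min_n` for a threshold is the smallest size
#' whose accuracy exceeds `threshold * max_accuracy` in at least `power`
#' of the repeats.
#'
#' @param features Numeric matrix or data.frame (samples x features).
#' @param labels Binary class labels.
#' @param sizes Subset sizes (all >= 10; default 10 to n by 10).
#' @param k_folds CV folds (default 10).
#' @param repeats Subsampling repeats per size (default 20).
#' @param thresholds Fractions of maximum accuracy (default 0.90, 0.95).
#' @param power Required fraction of repeats meeting the threshold
#'   (default 0.95).
#' @param seed Integer seed.
#' @return List of class `learning_curve`: `sizes`, `mean_accuracy`,
#'   `sd_accuracy`, `accuracy` (sizes x repeats), `max_accuracy`,
#'   `min_n` (named by threshold; `NA` when never reached).
#' @export
progressive_sampling <- function(features, labels, sizes = NULL,
                                 k_folds = 10, repeats = 20,
                                 thresholds = c(0.90, 0.95), power = 0.95,
                                 seed = 1) {
  x <- as.matrix(features)
  y <- factor(labels)
  stopifnot(nlevels(y) == 2)
  n <- nrow(x)
  if (is.null(sizes)) sizes <- seq(10, n, by = 10)
  stopifnot(all(sizes >= 10), all(sizes <= n))
  set.seed(stage_seed(seed, "progressive"))
  acc <- matrix(NA_real_, nrow = length(sizes), ncol = repeats)
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    for (r in seq_len(repeats)) {
      for (try in 1:50) {
        # stratified subsample preserving class proportions
        idx <- unlist(lapply(levels(y), function(l) {
          pool <- which(y == l)
          sample(pool, max(2, round(s * length(pool) / n)))
        }))
        idx <- if (length(idx) > s) sample(idx, s) else idx
        if (length(unique(y[idx])) == 2 && min(table(y[idx])) >= 2) break
        if (try == 50) stop("progressive_sampling: could not draw both ",
                            "classes at size ", s)
      }
      acc[si, r] <- best_pair_cv(x[idx, , drop = FALSE], droplevels(y[idx]),
                                 k_folds)$accuracy
    }
  }
  max_accuracy <- best_pair_cv(x, y, k_folds)$accuracy
  min_n <- vapply(thresholds, function(th) {
    hit <- rowMeans(acc >= th * max_accuracy) >= power
    if (any(hit)) sizes[which(hit)[1]] else NA_integer_
  }, numeric(1))
  names(min_n) <- paste0("max_acc_", thresholds)
  structure(list(sizes = sizes, mean_accuracy = rowMeans(acc),
                 sd_accuracy = apply(acc, 1, stats::sd), accuracy = acc,
                 max_accuracy = max_accuracy, thresholds = thresholds,
                 power = power, min_n = min_n),
            class = "learning_curve")
}
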