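# shared fixture builders; everything is generated in code at test time

# three well-separated Gaussian blobs in 2-D (separation ~ 10 sigma)
make_blobs <- function(seed, n_per = 50, sd = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 40))
  x <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(stats::rnorm(2 * n_per, 0, sd), ncol = 2), 2,
          centers[g, ], `+`)
  }))
  list(x = x, truth = rep(1:3, each = n_per))
}

# drug panel with noise-free effector proteins responding linearly to drug
# strength plus `n_dist` planted distorters that track an independent
# random signal; mirrors a definition whose tSignal is distorted by a
# known subset
make_distorter_panel <- function(seed, n_drugs = 100, n_total = 124,
                                 n_dist = 9, noise = 0) {
  set.seed(seed)
  n_good <- n_total - n_dist
  prots <- sprintf("PR%03d", seq_len(n_total))
  v <- sample(c(-1, 1), n_total, replace = TRUE)
  s <- stats::runif(n_drugs, 0, 1)
  panel <- matrix(0, n_drugs, n_total, dimnames = list(NULL, prots))
  for (i in seq_len(n_drugs)) {
    panel[i, seq_len(n_good)] <- v[seq_len(n_good)] * (1 - s[i])
    if (n_dist > 0) {
      panel[i, (n_good + 1):n_total] <-
        v[(n_good + 1):n_total] * stats::runif(n_dist, -1, 1)
    }
  }
  if (noise > 0) {
    panel <- panel + matrix(stats::rnorm(length(panel), 0, noise),
                            nrow = n_drugs)
  }
  list(panel = panel, efficacy = 0.05 + 0.8 * s,
       definition = protein_definition(prots, v, "synthetic"),
       distorters = if (n_dist > 0) prots[(n_good + 1):n_total]
                    else character(0))
}

# activity matrix with three planted mechanistic groups at a given
# shift-to-noise ratio
make_grouped_activity <- function(seed, n_per_group = 30, n_proteins = 40,
                                  shift = 0.5, noise = 0.1) {
  n <- 3 * n_per_group
  pop <- generate_population(ref_population_spec(n), height_model(), seed)
  set.seed(stage_seed(seed, "test_expo"))
  expo <- stats::setNames(stats::runif(n, 20, 60), pop$id)
  set.seed(stage_seed(seed, "test_def"))
  defn <- protein_definition(sprintf("P%02d", seq_len(n_proteins)),
                             sample(c(-1, 1), n_proteins, replace = TRUE))
  groups <- rep(1:3, each = n_per_group)
  sc <- mechanistic_scenario(n_groups = 3, effect_shift = shift,
                             noise_sd = noise)
  act <- generate_activity(pop, expo, defn, sc, seed = seed, arm = "a",
                           groups = groups)
  list(activity = act, groups = groups, definition = defn,
       patients = pop, exposures = expo)
}

# independent textbook hypergeometric tail by direct enumeration
enum_hyper_tail <- function(N, K, n, ov) {
  i <- ov:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
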