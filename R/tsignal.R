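#' tSignal statistic
#'
#' Mean sign-weighted predicted activity over a condition's effector set:
#' `tSignal = (1/n) * sum(v_i * y_i)`, where `n` counts the definition
#' proteins whose signal `y_i` is non-zero (the defining convention; a
#' fixed denominator over all definition proteins is available with
#' `denominator = "all"`). Ranges from -1 (fully reverted) to +1 (fully
#' pathological).
#'
#' @param y Named numeric activity vector; must contain every definition
#'   protein.
#' @param definition A [protein_definition()].
#' @param denominator `"nonzero"` (default) or `"all"`.
#' @return List of class `tsignal_result`: `value`, `n_used`, `label`.
#'   All-zero signals are an error (the statistic is undefined).
#' @examples
#' def <- protein_definition(c("a", "b", "c"), c(1, -1, 1))
#' tsignal(c(a = 0.5, b = 0, c = 0.5), def)$value  # 0.5 over n = 2
#' @export
tsignal <- function(y, definition, denominator = c("nonzero", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(definition, "protein_definition"))
  missing_p <- setdiff(definition$protein, names(y))
  if (length(missing_p) > 0) {
    stop("tsignal: activity vector lacks protein(s) ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  }
  yi <- unname(y[definition$protein])
  vi <- definition$sign
  nz <- yi != 0
  n <- if (denominator == "nonzero") sum(nz) else length(yi)
  if (sum(nz) == 0) {
    stop("tsignal: all signals are zero; the statistic is undefined")
  }
  structure(list(value = sum(vi * yi) / n, n_used = sum(nz),
                 label = attr(definition, "label")),
            class = "tsignal_result")
}

#' tSignal per model row of an activity matrix
#'
#' @param mat An `activity_matrix`.
#' @param definition A [protein_definition()].
#' @param ... Passed to [tsignal()].
#' @return Named numeric vector of tSignal values, one per row.
#' @export
tsignal_rows <- function(mat, definition, ...) {
  vapply(seq_len(nrow(mat)),
         function(i) tsignal(mat[i, ], definition, ...)$value,
         numeric(1)) |> stats::setNames(rownames(mat))
}

#' Calibrate tSignal against clinical efficacy
#'
#' Ordinary least-squares fit of
#' `efficacy = A * tSignal + B` with the Pearson correlation between the
#' two variables. PASI75 given as a percentage is divided by 100.
#'
#' @param tsignals Per-drug tSignal values (>= 3, non-constant).
#' @param efficacy Per-drug PASI75, fraction in `[0, 1]` (values > 1 are
#'   treated as percentages).
#' @return List of class `calibration_result`: `A`, `B`, `rho`,
#'   `retained`, `discarded`.
#' @export
calibrate <- function(tsignals, efficacy) {
  stopifnot(length(tsignals) == length(efficacy), length(tsignals) >= 3)
  if (any(efficacy > 1)) efficacy <- efficacy / 100
  if (stats::sd(tsignals) == 0) {
    stop("calibrate: tSignal values are constant; correlation undefined")
  }
  fit <- stats::lm(efficacy ~ tsignals)
  structure(list(A = unname(stats::coef(fit)[2]),
                 B = unname(stats::coef(fit)[1]),
                 rho = stats::cor(tsignals, efficacy),
                 retained = NULL, discarded = character(0)),
            class = "calibration_result")
}

#' Greedy protein-set optimization of the calibration
#'
#' Iteratively discards the definition proteins that distort the
#' tSignal-efficacy relationship: at each step the single protein whose
#' removal most increases `|rho|` is dropped (ties broken by
#' lexicographic protein id). Pruning stops when no removal shrinks the
#' unexplained part `1 - |rho|` by at least the fraction `min_improve`
#' (a scale-free criterion: near-perfect correlations demand
#' proportionally large gains, which guards against chasing noise), or
#' when fewer than two proteins would remain.
#'
#' @param panel Numeric matrix, rows = drugs, columns (named) = proteins;
#'   per-drug predicted activities.
#' @param efficacy Per-drug PASI75.
#' @param definition A [protein_definition()].
#' @param min_improve Minimum fractional reduction of `1 - |rho|` to
#'   accept a removal (default 0.05).
#' @param denominator tSignal denominator convention, as in [tsignal()].
#' @return A `calibration_result` with `retained` (a pruned
#'   `protein_definition`) and `discarded` (protein ids in removal
#'   order). Status `"degenerate"` is attached if pruning stopped at the
#'   two-protein floor.
#' @export
optimize_definition <- function(panel, efficacy, definition,
                                min_improve = 0.05,
                                denominator = c("nonzero", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(is.matrix(panel), nrow(panel) >= 3,
            inherits(definition, "protein_definition"),
            nrow(definition) >= 2)
  if (any(efficacy > 1)) efficacy <- efficacy / 100
  def_df <- as.data.frame(definition)
  W <- sweep(panel[, def_df$protein, drop = FALSE], 2, def_df$sign, `*`)
  NZ <- (panel[, def_df$protein, drop = FALSE] != 0) * 1
  safe_cor <- function(ts) {
    if (anyNA(ts) || stats::sd(ts) == 0) return(NA_real_)
    stats::cor(ts, efficacy)
  }
  rho_keep <- function(keep) {
    num <- rowSums(W[, keep, drop = FALSE])
    den <- if (denominator == "nonzero") {
      rowSums(NZ[, keep, drop = FALSE])
    } else {
      sum(keep)
    }
    safe_cor(ifelse(den == 0, NA_real_, num / den))
  }
  keep <- rep(TRUE, nrow(def_df))
  current <- abs(rho_keep(keep))
  if (is.na(current)) stop("optimize_definition: undefined initial correlation")
  discarded <- character(0)
  status <- "ok"
  repeat {
    if (sum(keep) <= 2) { status <- "degenerate"; warning(
      "optimize_definition: stopped at the two-protein floor"); break }
    idx <- which(keep)
    rs <- rowSums(W[, idx, drop = FALSE])
    nzs <- if (denominator == "nonzero") rowSums(NZ[, idx, drop = FALSE])
           else length(idx)
    num <- rs - W[, idx, drop = FALSE]              # drug x candidate
    den <- if (denominator == "nonzero") nzs - NZ[, idx, drop = FALSE]
           else matrix(length(idx) - 1, nrow(panel), length(idx))
    TS <- num / ifelse(den == 0, NA_real_, den)
    cand <- abs(apply(TS, 2, safe_cor))
    if (all(is.na(cand))) break
    best <- max(cand, na.rm = TRUE)
    # accept only if the unexplained part 1 - |rho| shrinks by the
    # required fraction (and strictly improves)
    if (best <= current ||
        (1 - best) > (1 - current) * (1 - min_improve)) break
    # lexicographic tie-break on protein id
    tied <- idx[!is.na(cand) & cand >= best - 1e-15]
    drop_j <- tied[order(def_df$protein[tied])][1]
    keep[drop_j] <- FALSE
    discarded <- c(discarded, def_df$protein[drop_j])
    current <- abs(rho_keep(keep))
  }
  retained_def <- protein_definition(def_df$protein[keep], def_df$sign[keep],
                                     attr(definition, "label"))
  ts <- vapply(seq_len(nrow(panel)),
               function(i) tsignal(panel[i, ], retained_def,
                                   denominator = denominator)$value,
               numeric(1))
  cal <- calibrate(ts, efficacy)
  cal$retained <- retained_def
  cal$discarded <- discarded
  cal$status <- status
  cal
}

#' Correlation-strength band
#'
#' Bands by absolute Pearson correlation: strong `|rho| > 0.8`; moderate
#' `(0.5, 0.8]`; low `(0.3, 0.5]`; negligible `<= 0.3`.
#'
#' @param rho Correlation value(s).
#' @return Character band label(s).
#' @export
correlation_band <- function(rho) {
  a <- abs(rho)
  ifelse(a > 0.8, "strong",
         ifelse(a > 0.5, "moderate",
                ifelse(a > 0.3, "low", "negligible")))
}

#' Severity-marker correlations with the tSignal
#'
#' Per trial arm, computes each marker protein's Pearson correlation with
#' the per-model tSignal across model rows, with Benjamini-Hochberg FDR
#' q-values and correlation-strength bands. The summary band is derived
#' from the weakest arm (`|rho|` minimum), so "moderate" means moderate
#' or better in every arm.
#'
#' @param mat An `activity_matrix` with an `arm` attribute (or single
#'   arm).
#' @param definition A [protein_definition()].
#' @param markers Character vector of marker protein ids (must be matrix
#'   columns).
#' @return data.frame: `protein`, then `rho_<arm>`, `q_<arm>` per arm,
#'   then `band`.
#' @export
severity_correlations <- function(mat, definition, markers) {
  stopifnot(all(markers %in% colnames(mat)))
  arms <- attr(mat, "arm") %||% rep("arm", nrow(mat))
  if (nrow(mat) < 3) stop("severity_correlations: need >= 3 model rows")
  out <- data.frame(protein = markers, stringsAsFactors = FALSE)
  min_abs_rho <- rep(Inf, length(markers))
  for (a in unique(arms)) {
    sub <- mat[arms == a, , drop = FALSE]
    if (nrow(sub) < 3) stop("severity_correlations: arm '", a,
                            "' has fewer than 3 rows")
    ts <- tsignal_rows(sub, definition)
    rho <- vapply(markers, function(m) stats::cor(sub[, m], ts), numeric(1))
    n <- nrow(sub)
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    q <- stats::p.adjust(p, method = "BH")
    out[[paste0("rho_", a)]] <- rho
    out[[paste0("q_", a)]] <- q
    min_abs_rho <- pmin(min_abs_rho, abs(rho))
  }
  out$band <- correlation_band(min_abs_rho)
  out
}
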