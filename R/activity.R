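#' Signed protein effector set
#'
#' The set of proteins defining a condition, each with its pathological
#' sign: `+1` if the protein is active in the condition, `-1` if
#' inactive. These signs are the `v_i` weights of the tSignal statistic.
#'
#' @param proteins Character vector of unique protein ids.
#' @param signs Integer vector of `+1` / `-1`.
#' @param label Condition label.
#' @return An object of class `protein_definition`.
#' @examples
#' protein_definition(c("TNF", "IL17A", "IL10"), c(1, 1, -1), "psoriasis")
#' @export
protein_definition <- function(proteins, signs, label = "condition") {
  stopifnot(length(proteins) == length(signs),
            !anyDuplicated(proteins),
            all(signs %in% c(-1, 1)))
  structure(data.frame(protein = as.character(proteins),
                       sign = as.integer(signs),
                       stringsAsFactors = FALSE),
            label = label,
            class = c("protein_definition", "data.frame"))
}

#' Read / write a protein definition CSV (`protein,sign`)
#' @param path File path.
#' @param label Condition label.
#' @export
read_protein_definition <- function(path, label = "condition") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  protein_definition(df$protein, df$sign, label)
}

#' @rdname read_protein_definition
#' @param definition A `protein_definition`.
#' @export
write_protein_definition <- function(definition, path) {
  utils::write.csv(as.data.frame(definition), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Mechanistic scenario for the synthetic activity generator
#'
#' Controls the structure the generator plants in predicted protein
#' activities: an exposure-dependent drug effect (Hill link), a number of
#' mechanistic patient groups with per-group mean offsets of magnitude
#' `effect_shift`, and additive Gaussian noise. Group membership is
#' derived from comorbidity tags via `group_tags` (first matching tag
#' wins; untagged patients fall in group 1), or supplied explicitly.
#'
#' @param n_groups Number of mechanistic groups.
#' @param group_tags Character vector of comorbidity tags, one per group
#'   beyond the first (e.g. `c("obesity", "diabetes")` with
#'   `n_groups = 3`: obesity -> group 2, diabetes -> group 3, rest ->
#'   group 1). Ignored when explicit groups are passed to
#'   [generate_activity()].
#' @param effect_shift Offset magnitude delta (>= 0) in activity units.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param emax Maximal fractional drug effect in `(0, 1]`.
#' @param ec50 Exposure at half-maximal effect, mg/L (> 0).
#' @param hill Hill exponent (> 0, default 1).
#' @return An object of class `mechanistic_scenario`.
#' @export
mechanistic_scenario <- function(n_groups = 3,
                                 group_tags = c("obesity", "diabetes"),
                                 effect_shift = 0.5, noise_sd = 0.1,
                                 emax = 0.9, ec50 = 10, hill = 1) {
  stopifnot(n_groups >= 1, effect_shift >= 0, noise_sd >= 0,
            emax > 0, emax <= 1, ec50 > 0, hill > 0)
  structure(list(n_groups = as.integer(n_groups), group_tags = group_tags,
                 effect_shift = effect_shift, noise_sd = noise_sd,
                 emax = emax, ec50 = ec50, hill = hill),
            class = "mechanistic_scenario")
}

#' Exposure-effect link (Hill function)
#'
#' Fractional drug effect at a given exposure:
#' `emax * conc^hill / (ec50^hill + conc^hill)`, bounded in `[0, emax]`
#' and non-decreasing in concentration.
#'
#' @param conc Concentration(s), mg/L (>= 0).
#' @param emax,ec50,hill Hill parameters.
#' @return Effect fraction(s) in `[0, emax]`.
#' @export
exposure_effect <- function(conc, emax = 0.9, ec50 = 10, hill = 1) {
  if (any(conc < 0)) stop("exposure_effect: negative concentration")
  stopifnot(emax > 0, emax <= 1, ec50 > 0, hill > 0)
  emax * conc^hill / (ec50^hill + conc^hill)
}

#' Map patients to mechanistic groups
#'
#' @param patients A `virtual_population` with assigned comorbidities.
#' @param scenario A [mechanistic_scenario()].
#' @return Integer group labels in `1..n_groups`.
#' @export
assign_groups <- function(patients, scenario) {
  g <- rep(1L, nrow(patients))
  for (j in seq_along(scenario$group_tags)) {
    hit <- has_tag(patients, scenario$group_tags[j]) & g == 1L
    g[hit] <- j + 1L
  }
  pmin(g, scenario$n_groups)
}

#' Generate a synthetic predicted-activity matrix
#'
#' Emulates per-patient, per-protein predicted activities for one trial
#' arm. Before the drug acts, every effector sits at its pathological
#' sign (`+v_i`); exposure moves it toward zero by the Hill effect
#' fraction; each mechanistic group adds a fixed +/- `effect_shift`
#' offset pattern (drawn once per protein and group from the seed);
#' Gaussian noise is added; and the result is squashed into `[-1, 1]`
#' with a hyperbolic tangent (smooth and sign-preserving; `clip` gives
#' hard clipping instead). Optional background proteins carry pure noise
#' around zero, giving downstream enrichment a non-effector universe.
#'
#' @param patients A `virtual_population`.
#' @param exposures Named numeric vector (names = patient ids) of the
#'   per-patient exposure summary, mg/L (e.g. average steady-state
#'   concentration). Every patient must have one.
#' @param definition A [protein_definition()].
#' @param scenario A [mechanistic_scenario()].
#' @param seed Integer seed; same seed gives a byte-identical matrix.
#' @param arm Arm label appended to row ids (`patientID_arm`).
#' @param groups Optional explicit integer group labels (overrides the
#'   tag rule).
#' @param n_background Number of pure-noise background proteins
#'   (`BG0001`, ...).
#' @param squash `"tanh"` or `"clip"`.
#' @return An `activity_matrix`: numeric matrix rows = patient-arm
#'   models, columns = proteins, values in `[-1, 1]`, with attributes
#'   `arm` (per-row labels) and `groups` (true group labels).
#' @export
generate_activity <- function(patients, exposures, definition, scenario,
                              seed, arm = "arm", groups = NULL,
                              n_background = 0, squash = c("tanh", "clip")) {
  squash <- match.arg(squash)
  stopifnot(inherits(definition, "protein_definition"),
            inherits(scenario, "mechanistic_scenario"))
  missing_ids <- setdiff(patients$id, names(exposures))
  if (length(missing_ids) > 0) {
    stop("generate_activity: no exposure record for patient(s) ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  if (any(exposures < 0)) stop("generate_activity: negative exposure")
  if (is.null(groups)) groups <- assign_groups(patients, scenario)
  stopifnot(length(groups) == nrow(patients))
  set.seed(stage_seed(seed, paste0("activity_", arm)))
  n <- nrow(patients)
  p <- nrow(definition)
  v <- definition$sign
  # fixed per-(group, protein) offset pattern, +/- effect_shift
  offsets <- matrix(sample(c(-1, 1), scenario$n_groups * p, replace = TRUE),
                    nrow = scenario$n_groups) * scenario$effect_shift
  eff <- exposure_effect(unname(exposures[patients$id]),
                         scenario$emax, scenario$ec50, scenario$hill)
  base <- outer(1 - eff, v)            # v_i pulled toward 0 by the drug
  shift <- offsets[groups, , drop = FALSE]
  noise <- matrix(stats::rnorm(n * p, 0, scenario$noise_sd), nrow = n)
  raw <- base + shift + noise
  mat <- if (squash == "tanh") tanh(raw) else pmin(pmax(raw, -1), 1)
  if (n_background > 0) {
    bg <- matrix(stats::rnorm(n * n_background, 0, scenario$noise_sd),
                 nrow = n)
    bg <- if (squash == "tanh") tanh(bg) else pmin(pmax(bg, -1), 1)
    mat <- cbind(mat, bg)
  }
  rownames(mat) <- paste0(patients$id, "_", arm)
  colnames(mat) <- c(definition$protein,
                     if (n_background > 0) sprintf("BG%04d", seq_len(n_background)))
  structure(mat, arm = rep(arm, n), groups = groups,
            class = c("activity_matrix", class(mat)))
}

#' Synthetic reference-drug efficacy panel
#'
#' Emulates the panel of psoriasis drugs with published PASI75 outcomes
#' used to anchor the tSignal-efficacy calibration. Per drug, an exposure
#' metric is drawn over `exposure_range`; the true tSignal is
#' `1 - 2 * hill(exposure)` (disease signal relaxing toward -1 with
#' exposure); and PASI75 is an exactly linear function of the true
#' tSignal (hence a monotone, logistic-shaped function of exposure) plus
#' Gaussian noise, clamped to `[0, 1]`. The generating intercept/slope
#' are recorded so a calibration can be checked against ground truth.
#'
#' @param n_drugs Number of drugs (>= 3).
#' @param exposure_range Numeric `c(min, max)` exposure, mg/L.
#' @param noise PASI75 noise sd.
#' @param seed Integer seed.
#' @param ec50 Exposure of half-maximal molecular response.
#' @param placebo PASI75 at zero exposure.
#' @param max_response PASI75 at full molecular response.
#' @return data.frame `drug, exposure, tsignal_true, pasi75` with
#'   attributes `A_true`, `B_true` (PASI75 = A * tSignal + B).
#' @export
generate_reference_panel <- function(n_drugs, exposure_range = c(0, 60),
                                     noise = 0.02, seed = 1, ec50 = 10,
                                     placebo = 0.05, max_response = 0.85) {
  stopifnot(n_drugs >= 3)
  set.seed(stage_seed(seed, "ref_panel"))
  exposure <- c(0, stats::runif(n_drugs - 1, exposure_range[1],
                                exposure_range[2]))
  tsig <- 1 - 2 * exposure_effect(exposure, emax = 1, ec50 = ec50)
  A <- -(max_response - placebo) / 2
  B <- placebo + (max_response - placebo) / 2
  pasi <- A * tsig + B + stats::rnorm(n_drugs, 0, noise)
  pasi <- pmin(pmax(pasi, 0), 1)
  structure(data.frame(drug = sprintf("drug%02d", seq_len(n_drugs)),
                       exposure = exposure, tsignal_true = tsig,
                       pasi75 = pasi, stringsAsFactors = FALSE),
            A_true = A, B_true = B)
}

#' Write / read an activity matrix TSV
#'
#' First column `model_id` (patientID_arm), remaining columns one per
#' protein; a sidecar CSV (`<path>.arms.csv`) stores the per-row arm
#' label.
#'
#' @param mat An `activity_matrix`.
#' @param path TSV path.
#' @export
write_activity <- function(mat, path) {
  df <- data.frame(model_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  arms <- attr(mat, "arm")
  if (!is.null(arms)) {
    utils::write.csv(data.frame(model_id = rownames(mat), arm = arms),
                     paste0(path, ".arms.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$model_id
  arms_path <- paste0(path, ".arms.csv")
  arms <- NULL
  if (file.exists(arms_path)) {
    arms <- utils::read.csv(arms_path, stringsAsFactors = FALSE)$arm
  }
  structure(mat, arm = arms, class = c("activity_matrix", class(mat)))
}
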