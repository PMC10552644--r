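#' Trial configuration
#'
#' Bundles everything one virtual-trial run needs: population spec and
#' height model, comorbidity set, the per-arm regimens (the same patients
#' are reused across arms), reference PK parameters, the mechanistic
#' scenario, the protein definition, the clustering configuration, and a
#' single global seed deterministically split per stage.
#'
#' @param spec A [population_spec()].
#' @param heights A [height_model()].
#' @param comorbidities List of [comorbidity_spec()].
#' @param regimens Named list of [regimen()] (arm label -> regimen); arm
#'   labels must be unique.
#' @param reference_pk A [pk_parameters()] for the reference patient.
#' @param scenario A [mechanistic_scenario()].
#' @param definition A [protein_definition()].
#' @param cluster_cfg A [cluster_config()] (or list of them).
#' @param seed Global integer seed.
#' @param exposure_window Numeric `c(from, to)` days over which the
#'   exposure summary (mean concentration) is taken; default days 84-112
#'   (weeks 12-16, the steady-state window).
#' @param n_background Background (non-effector) proteins in the
#'   activity matrix.
#' @param n_bootstrap Bootstrap resamples for the quality report.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(spec = ref_population_spec(),
                         heights = height_model(),
                         comorbidities = default_comorbidities(),
                         regimens = list(czp200 = czp_regimen(200),
                                         czp400 = czp_regimen(400)),
                         reference_pk = pk_parameters(
                           ka = absorption_constant(tmax = 5),
                           kel = log(2) / 14, v_blood = 5, v_skin = 3),
                         scenario = mechanistic_scenario(),
                         definition = default_definition(),
                         cluster_cfg = best_reported_config(),
                         seed = 1,
                         exposure_window = c(84, 112),
                         n_background = 0,
                         n_bootstrap = 50) {
  stopifnot(!anyDuplicated(names(regimens)), length(regimens) >= 1)
  structure(list(spec = spec, heights = heights,
                 comorbidities = comorbidities, regimens = regimens,
                 reference_pk = reference_pk, scenario = scenario,
                 definition = definition, cluster_cfg = cluster_cfg,
                 seed = as.integer(seed), exposure_window = exposure_window,
                 n_background = n_background, n_bootstrap = n_bootstrap),
            class = "trial_config")
}

#' A small default psoriasis-like effector definition
#'
#' Twelve placeholder effector proteins with pathological signs, used by
#' the smoke pipeline and fixtures. This is a synthetic stand-in, not a
#' curated disease definition.
#'
#' @export
default_definition <- function() {
  protein_definition(
    c("TNF", "IFNG", "IL17A", "IL23A", "IL1B", "CXCL8", "S100A9",
      "DEFB4A", "VEGFA", "MMP9", "IL10", "FOXP3"),
    c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1, -1),
    label = "psoriasis_synthetic")
}

#' Run the virtual trial
#'
#' Orchestrates the full pipeline: population generation, comorbidity
#' tagging, individualized PBPK simulation of every arm (closed-form
#' path; exact for this linear system), per-patient exposure summaries,
#' synthetic activity generation per arm, per-model tSignal, arm-wise
#' normalization, clustering with quality indices, cluster
#' characterization, differential and classifier proteins, and (when a
#' collection and network are supplied) enrichment networks per cluster
#' and direction. Exactly `n_patients x n_arms` patient-arm records are
#' produced, the same patients reused across arms. Reruns with the same
#' config are byte-identical; every stage seed is recorded in the
#' manifest.
#'
#' @param config A [trial_config()].
#' @param out_dir Optional output directory; when given, all tables are
#'   written (CSV/TSV/JSON) and a manifest with seeds and md5 checksums
#'   is included.
#' @param stages How far to run: `"activity"`, `"tsignal"`,
#'   `"clustering"` or `"enrichment"` (default; runs everything
#'   available).
#' @param collection,graph Optional `annotation_collection` and igraph
#'   protein network for the enrichment stage.
#' @param link_threshold Edge threshold for the enrichment network.
#' @param enrich_args Named list of extra arguments for [enrich()] (e.g.
#'   `min_size` for small toy collections).
#' @return List of class `trial_result`: `patients`, `profiles` (long
#'   data.frame), `exposures`, `activity`, `arms`, `tsignal`,
#'   `clustering` (solution, report, characterization, differential,
#'   classifiers), `enrichment`, `manifest`.
#' @export
run_trial <- function(config, out_dir = NULL,
                      stages = c("enrichment", "clustering", "tsignal",
                                 "activity"),
                      collection = NULL, graph = NULL,
                      link_threshold = 2, enrich_args = list()) {
  stages <- match.arg(stages)
  stage_rank <- c(activity = 1, tsignal = 2, clustering = 3,
                  enrichment = 4)
  run_to <- stage_rank[[stages]]
  seed <- config$seed
  manifest <- list(global_seed = seed,
                   stage_seeds = list(
                     vpop = stage_seed(seed, "vpop"),
                     comorbidity = stage_seed(seed, "comorbidity")),
                   n_patients = config$spec$n_patients,
                   arms = names(config$regimens))

  patients <- generate_population(config$spec, config$heights, seed)
  patients <- assign_comorbidities(patients, config$comorbidities, seed)

  grid <- seq(0, max(vapply(config$regimens,
                            function(r) max(r$time_day), numeric(1))) + 14,
              by = 0.1)
  win <- config$exposure_window
  profiles <- list(); exposures <- list()
  for (arm in names(config$regimens)) {
    reg <- config$regimens[[arm]]
    for (i in seq_len(nrow(patients))) {
      par_i <- individualize(patients[i, ], config$reference_pk)
      prof <- simulate_pk(par_i, reg, grid = grid, method = "closed",
                          patient_id = patients$id[i], label = arm)
      sel <- prof$time_day >= win[1] & prof$time_day <= win[2]
      exposures[[arm]][[patients$id[i]]] <- mean(prof$conc_mg_per_L[sel])
      profiles[[length(profiles) + 1]] <- data.frame(
        patient_id = patients$id[i], regimen = arm,
        time_day = prof$time_day, conc_mg_per_L = prof$conc_mg_per_L,
        stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, profiles)
  exposures <- lapply(exposures, unlist)

  acts <- lapply(names(config$regimens), function(arm) {
    generate_activity(patients, exposures[[arm]], config$definition,
                      config$scenario, seed = stage_seed(seed, "synth"),
                      arm = arm, n_background = config$n_background)
  })
  activity <- do.call(rbind, lapply(acts, unclass))
  arms <- unlist(lapply(acts, attr, "arm"))
  groups <- unlist(lapply(acts, attr, "groups"))
  activity <- structure(activity, arm = arms, groups = groups,
                        class = c("activity_matrix", class(activity)))
  stopifnot(nrow(activity) ==
              config$spec$n_patients * length(config$regimens))
  result <- list(patients = patients, profiles = profiles,
                 exposures = exposures, activity = activity, arms = arms,
                 manifest = manifest)

  if (run_to >= 2) {
    result$tsignal <- tsignal_rows(activity, config$definition)
  }
  if (run_to >= 3) {
    normalized <- normalize_by_arm(activity)
    sols <- cluster_grid(normalized, config$cluster_cfg,
                         seed = stage_seed(seed, "cluster"))
    reports <- lapply(sols, quality, n_bootstrap = config$n_bootstrap,
                      seed = stage_seed(seed, "quality"))
    best <- select_best(sols, reports)
    labels <- best$solution$labels
    pat_rows <- patients[match(sub("_[^_]+$", "", rownames(activity)),
                               patients$id), ]
    result$clustering <- list(
      solutions = sols, reports = reports, best = best,
      labels = labels,
      distances = intercluster_distances(best$solution$embedding, labels),
      characterization = characterize_clusters(labels, pat_rows, arms),
      differential = differential_proteins(normalized, labels),
      classifiers = classifier_proteins(normalized, labels, n_perm = 0,
                                        seed = stage_seed(seed, "bacc")))
  }
  if (run_to >= 4 && !is.null(collection) && !is.null(graph)) {
    universe <- colnames(activity)
    diff <- result$clustering$differential
    nets <- list()
    for (g in unique(diff$cluster)) for (dr in c("UP", "DOWN")) {
      qset <- diff$protein[diff$cluster == g & diff$direction == dr]
      qset <- intersect(qset, universe)
      if (length(qset) == 0) next
      res <- do.call(enrich, c(list(qset, collection, universe,
                                    direction = dr,
                                    cluster = as.character(g)),
                               enrich_args))
      nets[[paste0("cluster", g, "_", dr)]] <-
        list(results = res,
             network = build_network(res, collection, graph,
                                     link_threshold, universe))
    }
    result$enrichment <- nets
  }
  class(result) <- "trial_result"
  if (!is.null(out_dir)) write_trial(result, out_dir)
  result
}

# write the results bundle plus a manifest with md5 checksums
write_trial <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wp <- function(fn, writer) {
    p <- file.path(out_dir, fn)
    writer(p)
    paths[[length(paths) + 1]] <<- p
    p
  }
  wp("patients.csv", function(p) write_patients(result$patients, p))
  wp("profiles.csv", function(p)
    utils::write.csv(result$profiles, p, row.names = FALSE, quote = FALSE))
  wp("activity.tsv", function(p) write_activity(result$activity, p))
  paths[[length(paths) + 1]] <- file.path(out_dir, "activity.tsv.arms.csv")
  if (!is.null(result$tsignal)) {
    wp("tsignal.csv", function(p)
      utils::write.csv(data.frame(model_id = names(result$tsignal),
                                  tsignal = unname(result$tsignal)),
                       p, row.names = FALSE, quote = FALSE))
  }
  if (!is.null(result$clustering)) {
    cl <- result$clustering
    wp("labels.csv", function(p)
      utils::write.csv(data.frame(model_id = rownames(result$activity),
                                  cluster = cl$labels),
                       p, row.names = FALSE, quote = FALSE))
    wp("indices.json", function(p)
      jsonlite::write_json(list(
        k = cl$best$solution$k,
        optimal_k = as.list(cl$best$solution$optimal_k),
        quality = unclass(cl$best$report)), p, auto_unbox = TRUE,
        digits = NA))
    wp("characterization.csv", function(p)
      utils::write.csv(cl$characterization, p, row.names = FALSE))
    wp("differential_proteins.csv", function(p)
      utils::write.csv(cl$differential, p, row.names = FALSE))
    wp("classifier_proteins.csv", function(p)
      utils::write.csv(cl$classifiers, p, row.names = FALSE))
  }
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      wp(paste0("enrichment_", nm, ".csv"), function(p)
        utils::write.csv(as.data.frame(result$enrichment[[nm]]$results), p,
                         row.names = FALSE))
      np <- write_network(result$enrichment[[nm]]$network,
                          file.path(out_dir, paste0("network_", nm)))
      paths <- c(paths, np)
    }
  }
  manifest <- result$manifest
  manifest$files <- lapply(unname(unlist(paths)), function(p) {
    list(file = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Generate small deterministic fixture inputs
#'
#' Writes a 20-patient population spec (YAML) and table, a toy 12-protein
#' definition, a 3-set GMT collection and a 10-node protein-network edge
#' list — enough to exercise every pipeline stage. Regeneration under the
#' same seed is idempotent.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, the named file paths.
#' @export
make_fixtures <- function(seed = 1, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- ref_population_spec(20)
  spec_path <- file.path(out_dir, "population_spec.yaml")
  yaml::write_yaml(list(
    n_patients = spec$n_patients, female_fraction = spec$female_fraction,
    age = as.list(spec$age), weight = as.list(spec$weight),
    bmi = as.list(spec$bmi), reference_n = spec$reference_n,
    seed = seed), spec_path)
  pts <- assign_comorbidities(
    generate_population(spec, height_model(), seed),
    default_comorbidities(), seed)
  pts_path <- file.path(out_dir, "patients.csv")
  write_patients(pts, pts_path)
  def <- default_definition()
  def_path <- file.path(out_dir, "definition.csv")
  write_protein_definition(def, def_path)
  prots <- def$protein
  gmt_path <- file.path(out_dir, "toy.gmt")
  writeLines(c(
    paste(c("inflammatory", "toy", prots[1:6]), collapse = "\t"),
    paste(c("barrier", "toy", prots[5:10]), collapse = "\t"),
    paste(c("regulatory", "toy", prots[7:12]), collapse = "\t")),
    gmt_path)
  graph_path <- file.path(out_dir, "network.tsv")
  edges <- data.frame(from = prots[c(1:9, 1, 3, 5)],
                      to = prots[c(2:10, 6, 8, 11)])
  utils::write.table(rbind(edges, data.frame(from = prots[11],
                                             to = prots[12])),
                     graph_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(spec = spec_path, patients = pts_path, definition = def_path,
              gmt = gmt_path, graph = graph_path))
}

#' Read a population spec YAML
#'
#' @param path YAML file as written by [make_fixtures()].
#' @return A [population_spec()].
#' @export
read_population_spec <- function(path) {
  y <- yaml::read_yaml(path)
  population_spec(y$n_patients, y$female_fraction,
                  age = c(y$age$mean, y$age$sd),
                  weight = c(y$weight$mean, y$weight$sd),
                  bmi = c(y$bmi$mean, y$bmi$sd),
                  reference_n = y$reference_n %||% NA_integer_)
}
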