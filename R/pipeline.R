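#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Exactly one input mode is
#' used: a trajectory simulation (stage "simulate") or paths to bulk and
#' single-cell matrices. Unknown threshold keys are rejected and every
#' threshold is echoed into the run manifest.
#'
#' @param output_dir directory for artifacts (created if needed).
#' @param seed master integer seed; each randomized stage derives its own
#'   seed from a stable hash of the stage name and this value, so toggling
#'   stages does not shift other stages' randomness.
#' @param stages subset of "simulate", "saturate", "fit_time",
#'   "predict_time", "timer_genes", executed in dependency order.
#' @param bulk_path,sc_path,bulk_meta_path,sc_meta_path input files (TSV),
#'   required unless "simulate" is among the stages.
#' @param simulate named list of [trajectory_sim_spec()] overrides.
#' @param thresholds named list overriding any of: `min_level` (0.5),
#'   `min_samples` (8), `bulk_pcc_cutoff` (0.6), `bulk_p_cutoff` (0.003),
#'   `sc_pcc_cutoff` (0.4), `sc_p_cutoff` (0.001), `n_perm` (1000),
#'   `max_combos` (30), `epsilon` (0.01), `log_input` (TRUE for file input,
#'   ignored for simulated input which is already log-scale).
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1,
                       stages = c("simulate", "fit_time", "predict_time",
                                  "timer_genes"),
                       bulk_path = NULL, sc_path = NULL,
                       bulk_meta_path = NULL, sc_meta_path = NULL,
                       simulate = list(), thresholds = list()) {
  known_stages <- c("simulate", "saturate", "fit_time", "predict_time",
                    "timer_genes")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defaults <- list(min_level = 0.5, min_samples = 8,
                   bulk_pcc_cutoff = 0.6, bulk_p_cutoff = 0.003,
                   sc_pcc_cutoff = 0.4, sc_p_cutoff = 0.001,
                   n_perm = 1000, max_combos = 30, epsilon = 0.01,
                   log_input = TRUE)
  bad <- setdiff(names(thresholds), names(defaults))
  if (length(bad)) stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  for (k in names(thresholds)) {
    if (k == "log_input") {
      if (!is.logical(thresholds[[k]])) stop("`log_input` must be logical")
    } else if (!is.numeric(thresholds[[k]]) || length(thresholds[[k]]) != 1) {
      stop("threshold `", k, "` must be a single number")
    }
    defaults[[k]] <- thresholds[[k]]
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("`seed` must be a single integer")
  if (!"simulate" %in% stages &&
      (is.null(bulk_path) || is.null(sc_path)))
    stop("without the simulate stage, `bulk_path` and `sc_path` are required")
  if (length(simulate) && length(setdiff(names(simulate),
      names(formals(trajectory_sim_spec)))))
    stop("unknown simulate key(s): ",
         paste(setdiff(names(simulate), names(formals(trajectory_sim_spec))),
               collapse = ", "))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = stages, bulk_path = bulk_path, sc_path = sc_path,
                 bulk_meta_path = bulk_meta_path,
                 sc_meta_path = sc_meta_path, simulate = simulate,
                 thresholds = defaults), class = "run_config")
}

# stable per-stage seed from the master seed and stage name (< 2^31)
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1e9
  as.integer((as.numeric(master_seed) * 7919 + h) %% (2^31 - 1))
}

#' Run the differentiation-time pipeline
#'
#' Executes the requested stages in dependency order (simulate/load ->
#' preprocess -> saturate -> fit_time -> predict_time -> timer_genes),
#' writing TSV artifacts plus a `manifest.json` recording inputs, every
#' parameter value, per-stage seeds, the package version and output
#' checksums. [run_pipeline_from_manifest()] reproduces a run from the
#' manifest alone.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  th <- config$thresholds
  artifacts <- character(0)
  seeds <- list()
  ran <- character(0)

  if ("simulate" %in% config$stages) {
    seeds$simulate <- stage_seed(config$seed, "simulate")
    spec <- do.call(trajectory_sim_spec,
                    utils::modifyList(list(seed = seeds$simulate),
                                      config$simulate))
    sim <- simulate_trajectory(spec)
    bulk <- sim$bulk; sc <- sim$sc
    write_matrix(bulk, out("bulk.tsv"))
    write_matrix(sc, out("sc.tsv"))
    utils::write.table(bulk$sample_meta, out("bulk_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sc$sample_meta, out("sc_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "bulk.tsv", "sc.tsv", "bulk_meta.tsv",
                   "sc_meta.tsv")
    log_input <- FALSE  # generator output is already log-scale
    ran <- c(ran, "simulate")
  } else {
    bulk <- read_matrix(config$bulk_path, sample_meta = config$bulk_meta_path)
    sc <- read_matrix(config$sc_path, sample_meta = config$sc_meta_path)
    log_input <- isTRUE(th$log_input)
  }

  sc_proc <- preprocess_matrix(sc, min_level = th$min_level,
                               min_samples = th$min_samples, log = log_input)
  bulk_proc <- if (log_input) log_transform(bulk) else bulk

  if ("saturate" %in% config$stages) {
    seeds$saturate <- stage_seed(config$seed, "saturate")
    tps <- sample_times(bulk)
    last <- max(tps)
    ref <- rowMeans(bulk$values[, tps == last, drop = FALSE])
    cells <- sc$sample_meta$sample_id[sample_times(sc, require = FALSE) == last]
    sat <- sampling_saturation(sc[, cells], ref, max_combos = th$max_combos,
                               min_level = th$min_level,
                               min_samples = th$min_samples,
                               seed = seeds$saturate,
                               reference_id = paste0("t", last))
    write_saturation(sat, out("saturation.tsv"))
    artifacts <- c(artifacts, "saturation.tsv")
    ran <- c(ran, "saturate")
  }

  model <- NULL; predictions <- NULL
  if ("fit_time" %in% config$stages) {
    seeds$fit_time <- stage_seed(config$seed, "fit_time")
    deg <- timer_genes(bulk_proc, pcc_cutoff = th$bulk_pcc_cutoff,
                       p_cutoff = th$bulk_p_cutoff, n_perm = th$n_perm,
                       seed = seeds$fit_time, class_label = "T-gene")
    model <- fit_pls_time(bulk_proc,
                          sc_expressed_genes = rownames(sc_proc$values),
                          cp_deg_genes = deg$gene_id[deg$selected])
    write_time_model(model, out("model.json"))
    utils::write.table(deg, out("bulk_timer_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "model.json", "bulk_timer_genes.tsv")
    ran <- c(ran, "fit_time")
  }

  if ("predict_time" %in% config$stages) {
    if (is.null(model)) stop("stage `predict_time` needs stage `fit_time` ",
                             "(no model available)")
    predictions <- predict_sc_time(model, sc_proc)
    branches <- detect_branches(model, predictions, sc_proc,
                                seed = stage_seed(config$seed, "predict_time"))
    predictions$branch <- branches$branch
    utils::write.table(predictions, out("predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "predictions.tsv")
    ran <- c(ran, "predict_time")
  }

  if ("timer_genes" %in% config$stages) {
    if (is.null(predictions)) stop("stage `timer_genes` needs stage ",
                                   "`predict_time` (no predicted times)")
    seeds$timer_genes <- stage_seed(config$seed, "timer_genes")
    tg <- timer_genes(sc_proc, time_vector = predictions$t,
                      pcc_cutoff = th$sc_pcc_cutoff,
                      p_cutoff = th$sc_p_cutoff, n_perm = th$n_perm,
                      seed = seeds$timer_genes, class_label = "t-gene")
    utils::write.table(tg, out("sc_timer_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "sc_timer_genes.tsv")
    ran <- c(ran, "timer_genes")
  }

  manifest <- list(
    package = "popclock",
    version = as.character(utils::packageVersion("popclock")),
    created = "run",  # no wall-clock stamp: manifests must be reproducible
    config = unclass(config),
    stage_seeds = seeds,
    stages_run = ran,
    artifacts = artifacts,
    checksums = as.list(tools::md5sum(file.path(config$output_dir,
                                                artifacts))))
  names(manifest$checksums) <- artifacts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param output_dir where to write the reproduced artifacts (defaults to
#'   the manifest's own directory, overwriting).
#' @return the new manifest, invisibly.
#' @export
run_pipeline_from_manifest <- function(manifest_path, output_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  config <- run_config(
    output_dir = if (is.null(output_dir)) cfg$output_dir else output_dir,
    seed = cfg$seed, stages = cfg$stages,
    bulk_path = cfg$bulk_path, sc_path = cfg$sc_path,
    bulk_meta_path = cfg$bulk_meta_path, sc_meta_path = cfg$sc_meta_path,
    simulate = as.list(cfg$simulate),
    thresholds = as.list(cfg$thresholds))
  run_pipeline(config)
}
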