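#' Pipeline run configuration
#'
#' Collects every tunable of the simulate -> QC -> EWAS -> smooth -> call
#' pipeline in one validated list. `sim` may be `NULL` to run on existing
#' input files (`beta_path`/`meta_path`/`manifest_path`/`islands_path`)
#' instead of a fresh simulation.
#'
#' @param sim A [sim_config()] or `NULL`.
#' @param beta_path,meta_path,manifest_path,islands_path Input files used
#'   when `sim` is `NULL`.
#' @param t_test `"welch"` or `"student"`.
#' @param radius Smoothing window radius (probes).
#' @param alpha Island-call significance level on Bonferroni P.
#' @param low,high Three-state classification thresholds.
#' @param flank_bp Island flank width in bp.
#' @param min_fraction_concordant,min_probes,require_significant Island
#'   call thresholds, see [call_island()].
#' @param highlight_threshold Nominal-P highlight line of the Manhattan
#'   export.
#' @param pca_k Number of principal components to report.
#' @param seed Integer seed for the simulation stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       beta_path = NULL, meta_path = NULL,
                       manifest_path = NULL, islands_path = NULL,
                       t_test = "welch", radius = 3, alpha = 0.05,
                       low = 0.2, high = 0.6, flank_bp = 250,
                       min_fraction_concordant = 1.0, min_probes = 3,
                       require_significant = 1,
                       highlight_threshold = 1e-100, pca_k = 10,
                       seed = 1L) {
  cfg <- list(sim = sim, beta_path = beta_path, meta_path = meta_path,
              manifest_path = manifest_path, islands_path = islands_path,
              t_test = t_test, radius = radius, alpha = alpha,
              low = low, high = high, flank_bp = flank_bp,
              min_fraction_concordant = min_fraction_concordant,
              min_probes = min_probes,
              require_significant = require_significant,
              highlight_threshold = highlight_threshold, pca_k = pca_k,
              seed = seed)
  if (!(cfg$low > 0 && cfg$high < 1 && cfg$low < cfg$high))
    stop("classification thresholds must satisfy 0 < low < high < 1",
         call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0,1)", call. = FALSE)
  if (cfg$radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (is.null(cfg$sim) &&
      (is.null(cfg$beta_path) || is.null(cfg$meta_path) ||
       is.null(cfg$manifest_path) || is.null(cfg$islands_path)))
    stop("without a simulation config, all four input paths are required",
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys override the [run_config()] defaults; the `sim:` block (if
#' present) overrides the [sim_config()] defaults. `sim: none` disables
#' the simulation stage.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_raw <- raw$sim
  raw$sim <- NULL
  sim <- if (identical(sim_raw, "none")) {
    NULL
  } else if (is.null(sim_raw)) {
    sim_config()
  } else {
    if (!is.null(sim_raw$islands))
      sim_raw$islands <- as.data.frame(lapply(sim_raw$islands, unlist))
    do.call(sim_config, sim_raw)
  }
  do.call(run_config, c(list(sim = sim), raw))
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full epimutation-discovery pipeline
#'
#' Stages: simulate (or load), PCA QC, per-probe EWAS with smoothing,
#' island-level epimutation calling, and reporting. All outputs are
#' written to `outdir` as plain text: the beta matrix and metadata (when
#' simulated), the EWAS table, the epi-Manhattan export, per-island
#' epigram summaries (per-probe mean case and control beta), PCA scores,
#' island calls (TSV + BED of epimutated intervals) and a JSON run
#' manifest recording package version, seed and a parameter hash. The
#' manifest contains no timestamp, so identical config and seed reproduce
#' byte-identical output directories.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the in-memory stage results: `beta`,
#'   `manifest`, `islands`, `pca`, `ewas`, `calls`, `truth_islands` (when
#'   simulated) and `outdir`.
#' @export
run_full_pipeline <- function(config = run_config(), outdir, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop("need a run_config", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_ <- if (quiet) function(...) invisible() else .log_stage

  truth_islands <- NULL
  if (!is.null(config$sim)) {
    config$sim$seed <- config$seed
    sim <- simulate_methylome(config$sim)
    bm <- sim$beta; manifest <- sim$manifest; islands <- sim$islands
    truth_islands <- sim$truth_islands
    write_beta_matrix(bm, file.path(outdir, "beta.tsv"),
                      file.path(outdir, "samples.tsv"))
    write_manifest(manifest, file.path(outdir, "manifest.tsv"))
    write_islands(islands, file.path(outdir, "islands.bed"))
    write_manifest(probe_manifest(sim$truth_probes),
                   file.path(outdir, "truth_probes.tsv"))
    utils::write.table(as.data.frame(truth_islands),
                       file.path(outdir, "truth_islands.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_("simulate", "%d probes x %d samples, %d islands (seed %d)",
         n_probes(bm), n_samples(bm), nrow(islands), config$seed)
  } else {
    bm <- read_beta_matrix(config$beta_path, config$meta_path)
    manifest <- read_manifest(config$manifest_path)
    islands <- read_islands(config$islands_path)
    log_("load", "%d probes x %d samples read", n_probes(bm), n_samples(bm))
  }

  if (!"island_relation" %in% names(manifest))
    manifest <- map_probes_to_islands(manifest, islands, config$flank_bp)

  pca <- pca_qc(bm, k = config$pca_k)
  scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                       group = pca$sample_meta$group,
                       sex = pca$sample_meta$sex, check.names = FALSE)
  utils::write.table(scores, file.path(outdir, "pca_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  log_("qc-pca", "top eigenvalue explains %.1f%% of variance",
       100 * pca$prop_variance[1])

  ewas <- run_ewas(bm, manifest, islands, variant = config$t_test,
                   radius = config$radius, flank_bp = config$flank_bp)
  write_ewas(ewas, file.path(outdir, "ewas.tsv"),
             genome_build = bm$genome_build)
  utils::write.table(
    as.data.frame(manhattan_table(ewas, config$highlight_threshold)),
    file.path(outdir, "manhattan.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  log_("ewas", "%d of %d probes tested (m_tests for Bonferroni)",
       attr(ewas, "m_tests"), nrow(ewas))

  epigram <- ewas[!is.na(ewas$island_id),
                  c("island_id", "probe_id", "chromosome", "position",
                    "island_relation", "mean_beta_cases",
                    "mean_beta_controls", "delta_beta")]
  utils::write.table(as.data.frame(epigram),
                     file.path(outdir, "island_epigrams.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  calls <- scan_genome(ewas, islands, alpha = config$alpha,
                       min_fraction_concordant = config$min_fraction_concordant,
                       min_probes = config$min_probes,
                       require_significant = config$require_significant,
                       low = config$low, high = config$high)
  write_calls(calls, islands, file.path(outdir, "calls.tsv"),
              file.path(outdir, "epimutated.bed"),
              genome_build = bm$genome_build)
  log_("call", "%d/%d islands called epimutated",
       sum(calls$verdict == "epimutated"), nrow(calls))

  params <- unclass(config)
  if (!is.null(params$sim)) {
    params$sim <- unclass(params$sim)
    params$sim$islands <- as.data.frame(params$sim$islands)
  }
  params_json <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE,
                                  digits = NA, null = "null")
  tmp <- file.path(outdir, ".params.json")
  writeLines(params_json, tmp)
  run_manifest <- list(
    package = "epimutr",
    version = as.character(utils::packageVersion("epimutr")),
    seed = config$seed,
    parameter_hash = unname(tools::md5sum(tmp)),
    parameters = jsonlite::fromJSON(params_json, simplifyVector = TRUE),
    stage_counts = list(
      probes = n_probes(bm), samples = n_samples(bm),
      probes_tested = attr(ewas, "m_tests"),
      islands = nrow(islands),
      islands_called = sum(calls$verdict == "epimutated")))
  file.remove(tmp)
  jsonlite::write_json(run_manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_("report", "run manifest written to %s",
       file.path(outdir, "run_manifest.json"))

  invisible(list(beta = bm, manifest = manifest, islands = islands,
                 pca = pca, ewas = ewas, calls = calls,
                 truth_islands = truth_islands, outdir = outdir))
}
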