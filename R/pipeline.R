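#' Read and validate a pipeline run configuration
#'
#' The run configuration is a YAML file with a `seed`, an output directory,
#' and *exactly one* of an `input` block (paths to an existing wide-format
#' panel, covariate and outcome CSVs) or a `simulate` block (parameters for
#' the synthetic-cohort generator). Optional keys: `span` (`start_age`,
#' `end_age`), `k_range` (`min`, `max`), `reference` trajectory, `covariates`
#' (adjustment set), `site` (outcome site filter).
#'
#' @param path YAML file path, or a list already parsed.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim)
    stop("run config must have exactly one of 'input' or 'simulate'")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$span)) cfg$span <- list(start_age = 16L, end_age = 65L)
  if (is.null(cfg$k_range)) cfg$k_range <- list(min = 2L, max = 10L)
  if (has_sim && is.null(cfg$simulate$gender))
    cfg$simulate$gender <- "female"
  class(cfg) <- c("run_config", "list")
  cfg
}

sim_config <- function(cfg) {
  sim <- cfg$simulate
  templates <- builtin_templates(sim$gender)
  args <- list(templates = templates,
               n_per_cluster = if (is.null(sim$n_per_cluster)) 100L else sim$n_per_cluster,
               noise_rate = if (is.null(sim$noise_rate)) 0.05 else sim$noise_rate,
               gender = sim$gender,
               seed = cfg$seed)
  if (!is.null(sim$covariate_model)) args$covariate_model <- sim$covariate_model
  om <- sim$outcome_model
  if (!is.null(om)) {
    if (!is.null(om$log_or_cluster)) om$log_or_cluster <- unlist(om$log_or_cluster)
    if (!is.null(om$log_or_covariates)) om$log_or_covariates <- unlist(om$log_or_covariates)
    args$outcome_model <- om
  }
  do.call(synthetic_config, args)
}

stage_log <- function(stage, ...) {
  message(sprintf("[lifetraj] %s: %s", stage,
                  paste(sprintf("%s=%s", names(c(...)), c(...)), collapse = " ")))
}

#' Simulate stage: write a synthetic cohort to disk
#'
#' Writes `panel_wide.csv`, `covariates.csv`, `outcomes.csv`,
#' `true_labels.csv` and a `manifest.json` recording the seed, the generator
#' settings and an md5 checksum per file.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param outdir output directory (defaults to `config$outdir`).
#' @return Invisibly, the manifest list.
#' @export
pipeline_simulate <- function(config, outdir = config$outdir) {
  t0 <- Sys.time()
  if (is.null(config$simulate)) stop("config has no simulate block")
  if (is.null(outdir)) stop("no output directory configured")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sc <- sim_config(config)
  cohort <- generate_cohort(sc)
  files <- c(panel = "panel_wide.csv", covariates = "covariates.csv",
             outcomes = "outcomes.csv", true_labels = "true_labels.csv")
  write_wide(cohort$panel, file.path(outdir, files["panel"]))
  utils::write.csv(cohort$covariates, file.path(outdir, files["covariates"]),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = cohort$panel$meta$subject_id,
                              cancer = cohort$outcome, site = NA),
                   file.path(outdir, files["outcomes"]), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = cohort$panel$meta$subject_id,
                              label = cohort$labels),
                   file.path(outdir, files["true_labels"]), row.names = FALSE)
  manifest <- list(
    stage = "simulate", seed = sc$seed, gender = sc$gender,
    n = n_sequences(cohort$panel), noise_rate = sc$noise_rate,
    files = as.list(files),
    md5 = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log("simulate", n = manifest$n, gender = sc$gender,
            runtime_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  invisible(manifest)
}

load_panel <- function(config, outdir) {
  path <- if (!is.null(config$input)) config$input$panel
          else file.path(outdir, "panel_wide.csv")
  read_wide(path)
}

#' Cluster stage: distances, ASW-driven PAM, typology outputs
#'
#' Aligns and completeness-filters the panel, computes the Hamming matrix,
#' selects the number of trajectory types by ASW over the configured range,
#' and writes `asw_profile.csv`, `assignments.csv`, `typology_summary.csv`,
#' per-cluster chronogram CSVs, and `solution.json` (medoids, cost, ASW).
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, a list with the selected `cluster_solution`, the ASW
#'   profile, and the filtered panel.
#' @export
pipeline_cluster <- function(config, outdir = config$outdir) {
  t0 <- Sys.time()
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  panel <- load_panel(config, outdir)
  if (n_sequences(panel) == 0L) stop("empty panel")
  panel <- align(panel, config$span$start_age, config$span$end_age)
  fc <- filter_complete(panel)
  panel <- fc$panel
  if (n_sequences(panel) == 0L) stop("no complete sequences after filtering")
  d <- hamming_matrix(panel)
  sel <- select_k(d, config$k_range$min, config$k_range$max)
  sol <- sel$best
  utils::write.csv(sel$profile, file.path(outdir, "asw_profile.csv"),
                   row.names = FALSE)
  write_assignments(sol, panel, file.path(outdir, "assignments.csv"))
  summ <- typology_summary(panel, sol$cluster, d = d)
  utils::write.csv(summ, file.path(outdir, "typology_summary.csv"),
                   row.names = FALSE)
  write_chronogram(chronogram(panel, sol$cluster),
                   file.path(outdir, "chronograms"))
  jsonlite::write_json(
    list(stage = "cluster", n = n_sequences(panel), k = sol$k,
         asw = sol$asw, total_cost = sol$total_cost,
         medoid_ids = sol$medoid_ids, excluded = fc$report,
         asw_profile = sel$profile),
    file.path(outdir, "solution.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  stage_log("cluster", n = n_sequences(panel), k = sol$k,
            asw = round(sol$asw, 4),
            runtime_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  invisible(list(solution = sol, profile = sel$profile, panel = panel))
}

#' Associate stage: covariate-adjusted trajectory odds ratios
#'
#' Joins cluster assignments, covariates and outcomes by `subject_id`,
#' optionally restricts the outcome to one cancer site, fits the logistic
#' model, and writes `association_table.csv` (with the `Ref.` row) and
#' `model.json` (all coefficients, SEs, diagnostics).
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the `association_result`.
#' @export
pipeline_associate <- function(config, outdir = config$outdir) {
  t0 <- Sys.time()
  asg_path <- file.path(outdir, "assignments.csv")
  if (!file.exists(asg_path)) stop("no assignments.csv in ", outdir,
                                   "; run pipeline_cluster first")
  asg <- utils::read.csv(asg_path, stringsAsFactors = FALSE)
  cov_path <- if (!is.null(config$input)) config$input$covariates
              else file.path(outdir, "covariates.csv")
  out_path <- if (!is.null(config$input)) config$input$outcomes
              else file.path(outdir, "outcomes.csv")
  cov <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  outc <- utils::read.csv(out_path, stringsAsFactors = FALSE)
  cov <- cov[match(asg$subject_id, cov$subject_id), , drop = FALSE]
  outc <- outc[match(asg$subject_id, outc$subject_id), , drop = FALSE]
  y <- filter_outcome_site(outc, config$site)
  cov$birth_cohort <- factor(cov$birth_cohort,
                             levels = c("no_crisis", "war", "great_depression"))
  cov$attrition <- factor(cov$attrition,
                          levels = c("no_dropout", "dropout", "deceased"))
  if (!is.null(config$covariates))
    cov <- cov[intersect(names(cov), c("subject_id", config$covariates))]
  reference <- config$reference
  res <- fit_trajectory_outcome_model(y, asg$cluster, cov, reference)
  utils::write.csv(make_association_table(res),
                   file.path(outdir, "association_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(stage = "associate", n = res$n, n_excluded = res$n_excluded,
         reference = res$reference, converged = res$converged,
         message = res$message, covariates = res$covariates_used,
         table = res$table,
         coefficients = as.list(res$coefficients), se = as.list(res$se)),
    file.path(outdir, "model.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  stage_log("associate", n = res$n, reference = res$reference,
            converged = res$converged,
            runtime_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  invisible(res)
}

#' Report stage: one-page text summary of a completed run
#'
#' Collates the clustering and association outputs already present in the
#' output directory into `report.txt`.
#'
#' @inheritParams pipeline_simulate
#' @return Invisibly, the report lines.
#' @export
pipeline_report <- function(config, outdir = config$outdir) {
  lines <- c("lifetraj run report", strrep("=", 19), "")
  sol_path <- file.path(outdir, "solution.json")
  if (file.exists(sol_path)) {
    sol <- jsonlite::read_json(sol_path, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("Typology: k = %d clusters over n = %d sequences, ASW = %.3f",
                       sol$k, sol$n, sol$asw), "")
    summ <- utils::read.csv(file.path(outdir, "typology_summary.csv"))
    lines <- c(lines, utils::capture.output(print(summ, row.names = FALSE)), "")
  }
  tab_path <- file.path(outdir, "association_table.csv")
  if (file.exists(tab_path)) {
    tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
    lines <- c(lines, "Trajectory odds ratios (95% CI):",
               sprintf("  %-45s %s", tab$trajectory, tab$or_ci))
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(lines)
}
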