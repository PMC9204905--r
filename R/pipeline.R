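# End-to-end pipeline entry points: simulate a full synthetic dataset bundle,
# screen it through the five-criterion funnel, and evaluate monitoring and
# survival, each writing plain-text outputs plus a run manifest. The
# analysis/ driver scripts are thin wrappers over these.

#' Simulate and write a complete synthetic dataset bundle
#'
#' Generates the discovery and replication paired cohorts, a therapy-response
#' cohort (PD vs CR tumors with a planted response effect at the planted
#' genes), a multi-tissue normal panel, coupled expression, a paired-sample
#' QMSP Cq table, plasma monitoring trajectories and survival records, and
#' writes them under `out_dir` together with a manifest JSON recording the
#' configurations, seed and file digests.
#'
#' @param config a [cohort_config()] for the discovery cohort. The
#'   replication cohort reuses it with an offset seed; the response cohort
#'   uses `response_n_pd` + `response_n_cr` pairs with shared effect
#'   `response_base_effect` plus `response_delta_beta` in PD tumors; the
#'   normal panel uses `panel_background_beta`.
#' @param plasma_config a [plasma_sim_config()].
#' @param out_dir output directory (created if needed).
#' @param response_n_pd,response_n_cr response-cohort group sizes.
#' @param response_base_effect hypermethylation effect shared by all response
#'   tumors at planted genes.
#' @param response_delta_beta extra PD-tumor effect (the planted PD-CR
#'   contrast).
#' @param panel_background_beta background beta of the normal panel.
#' @param survival_hazard_ratio planted hazard ratio for the survival table.
#' @param survival_n survival cohort size.
#' @return invisibly, a list with the generated objects and `files`.
#' @export
simulate_bundle <- function(config = cohort_config(),
                            plasma_config = plasma_sim_config(),
                            out_dir,
                            response_n_pd = 8, response_n_cr = 21,
                            response_base_effect = 0.2,
                            response_delta_beta = 0.4,
                            panel_background_beta = 0.05,
                            survival_hazard_ratio = 6,
                            survival_n = 500) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(plasma_config, "plasma_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  discovery <- simulate_beta_cohort(config)

  repl_cfg <- config
  repl_cfg$seed <- config$seed + 101L
  replication <- simulate_beta_cohort(repl_cfg)

  resp_cfg <- config
  resp_cfg$seed <- config$seed + 202L
  resp_cfg$n_pairs <- as.integer(response_n_pd + response_n_cr)
  resp_cfg$responder_fraction <- response_n_cr / resp_cfg$n_pairs
  resp_cfg$delta_beta_effect <- response_base_effect
  resp_cfg$response_delta_beta <- response_delta_beta
  response <- simulate_beta_cohort(resp_cfg)

  panel_cfg <- config
  panel_cfg$seed <- config$seed + 303L
  panel_cfg$background_beta <- panel_background_beta
  panel <- simulate_normal_panel(panel_cfg)

  expression <- simulate_expression(config, discovery)

  # paired QMSP measurements: planted twofold-and-above tumor/normal folds in
  # roughly half the pairs, sub-twofold in the rest
  set.seed(config$seed + 404L)
  n_qmsp <- 20
  qmsp <- list()
  for (i in seq_len(n_qmsp)) {
    fold <- if (i %% 2 == 0) stats::runif(1, 2.5, 8) else stats::runif(1, 0.5, 1.5)
    normal_level <- 0.01 * exp(stats::rnorm(1, 0, 0.3))
    qmsp[[2 * i - 1]] <- simulate_qpcr(
      normal_level * fold, sample_id = sprintf("Q%03d_T", i), cq_sd = 0.1
    )
    qmsp[[2 * i]] <- simulate_qpcr(
      normal_level, sample_id = sprintf("Q%03d_N", i), cq_sd = 0.1
    )
  }

  plasma <- simulate_plasma_series(plasma_config)
  surv <- simulate_survival(survival_n, hazard_ratio = survival_hazard_ratio,
                            seed = config$seed + 505L)

  files <- c(
    write_beta_cohort(discovery, file.path(out_dir, "discovery")),
    write_beta_cohort(replication, file.path(out_dir, "replication")),
    write_beta_cohort(response, file.path(out_dir, "response")),
    write_beta_cohort(panel, file.path(out_dir, "normal_panel")),
    expression_tsv = {
      p <- file.path(out_dir, "expression.tsv")
      df <- data.frame(gene = rownames(expression$expression),
                       expression$expression, check.names = FALSE)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    },
    cq_csv = write_cq_table(qmsp, file.path(out_dir, "qmsp_cq.csv")),
    plasma_csv = write_plasma_series(plasma, file.path(out_dir, "plasma.csv")),
    survival_csv = write_survival_table(surv, file.path(out_dir,
                                                        "survival.csv"))
  )
  manifest <- write_manifest(
    out_dir, subcommand = "simulate",
    config = list(cohort = unclass(config), plasma = unclass(plasma_config),
                  response_n_pd = response_n_pd,
                  response_n_cr = response_n_cr,
                  response_base_effect = response_base_effect,
                  response_delta_beta = response_delta_beta,
                  panel_background_beta = panel_background_beta,
                  survival_hazard_ratio = survival_hazard_ratio,
                  survival_n = survival_n),
    seed = config$seed, files = files
  )
  invisible(list(
    discovery = discovery, replication = replication, response = response,
    panel = panel, expression = expression, qmsp = qmsp, plasma = plasma,
    survival = surv, files = files, manifest = manifest
  ))
}

#' Run the screening funnel on a simulated bundle directory
#'
#' @param bundle_dir directory written by [simulate_bundle()].
#' @param config a [funnel_config()].
#' @param out_dir where to write the report (defaults to `bundle_dir`).
#' @return the [run_funnel()] report, invisibly; writes
#'   `funnel_report.json`, per-criterion gene-list TSVs and a Venn-style
#'   count summary.
#' @export
screen_bundle <- function(bundle_dir, config = funnel_config(),
                          out_dir = bundle_dir) {
  discovery <- read_beta_cohort(file.path(bundle_dir, "discovery"))
  replication <- read_beta_cohort(file.path(bundle_dir, "replication"))
  response <- read_beta_cohort(file.path(bundle_dir, "response"))
  panel <- read_beta_cohort(file.path(bundle_dir, "normal_panel"))
  expr_path <- file.path(bundle_dir, "expression.tsv")
  if (!file.exists(expr_path)) stop("missing input file: ", expr_path)
  edf <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  expr <- as.matrix(edf[, -1, drop = FALSE])
  rownames(expr) <- edf$gene
  expression <- list(expression = expr, samples = discovery$samples)

  report <- run_funnel(config, discovery, replication, response, panel,
                       expression)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(counts = as.list(report$counts), final = report$final,
         evidence = report$evidence),
    file.path(out_dir, "funnel_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (nm in names(report$sets)) {
    utils::write.table(
      data.frame(gene = report$sets[[nm]]),
      file.path(out_dir, paste0("criterion_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  utils::write.table(
    data.frame(criterion = c(names(report$counts), "final"),
               n_genes = c(unname(report$counts), length(report$final))),
    file.path(out_dir, "venn_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(report)
}

#' Evaluate monitoring and survival outputs of a bundle
#'
#' Runs the plasma-monitoring benchmark and the survival comparison
#' (Kaplan-Meier, log-rank, Cox on the methylation group) on the bundle's
#' plasma and survival tables, writing JSON/TSV reports.
#'
#' @param bundle_dir directory written by [simulate_bundle()].
#' @param out_dir where to write reports (defaults to `bundle_dir`).
#' @param cutoff,clearance_window monitoring parameters; see
#'   [classify_patient()].
#' @param horizon follow-up truncation for survival (months).
#' @return invisibly, list with `monitoring`, `km`, `logrank`, `cox`.
#' @export
evaluate_bundle <- function(bundle_dir, out_dir = bundle_dir,
                            cutoff = 0.002, clearance_window = 1,
                            horizon = 120) {
  plasma <- read_plasma_series(file.path(bundle_dir, "plasma.csv"))
  surv <- read_survival_table(file.path(bundle_dir, "survival.csv"))

  bench <- benchmark_markers(plasma, cutoff = cutoff,
                             clearance_window = clearance_window)
  surv <- truncate_followup(surv, horizon)
  km <- lapply(split(surv, surv$group), km_estimate)
  lr <- logrank_test(surv)
  cox <- cox_ph(transform(surv, group = factor(
    group, levels = c("hypomethylated", "hypermethylated")
  )), "group")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pick <- function(r) r[c("sensitivity_pct", "specificity_pct",
                          "accuracy_pct", "auc", "n")]
  jsonlite::write_json(
    list(methylation = pick(bench$methylation), cea = pick(bench$cea),
         ca153 = pick(bench$ca153),
         logrank = lr,
         cox = cox),
    file.path(out_dir, "evaluation_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (nm in names(bench$roc)) {
    utils::write.table(bench$roc[[nm]],
                       file.path(out_dir, paste0("roc_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(km)) {
    utils::write.table(km[[nm]],
                       file.path(out_dir, paste0("km_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(monitoring = bench, km = km, logrank = lr, cox = cox))
}

#' Write a run manifest JSON
#'
#' Records the subcommand, configuration snapshot, seed, package version,
#' timestamp and md5 digests of the files produced, so identical inputs can be
#' verified to reproduce identical outputs.
#'
#' @param out_dir output directory.
#' @param subcommand pipeline stage name.
#' @param config configuration snapshot (list).
#' @param seed integer seed.
#' @param files character vector of produced files.
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(out_dir, subcommand, config, seed, files) {
  digests <- tools::md5sum(unname(files))
  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("methfunnel")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = data.frame(path = basename(names(digests)),
                       md5 = unname(digests))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
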