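#' Configuration of the five-criterion screening funnel
#'
#' @param delta_beta_cutoff strict tumor-normal delta-beta threshold for the
#'   two hypermethylation criteria (default 0.4).
#' @param top_k_response number of top response-contrast genes kept (default
#'   20).
#' @param normal_panel_max_beta "close to zero" bound: a gene passes the
#'   normal-panel criterion when its mean beta in every tissue type is
#'   strictly below this (default 0.1).
#' @param expression_ratio_cutoff tumor/normal expression ratio at or below
#'   which a gene counts as silenced (default 0.5).
#' @param expression_inclusive whether the expression cutoff is inclusive
#'   (`<=`, the default, reading "decreased by 50\%" as ratio <= 0.5).
#' @return list of class `funnel_config`.
#' @export
funnel_config <- function(delta_beta_cutoff = 0.4,
                          top_k_response = 20,
                          normal_panel_max_beta = 0.1,
                          expression_ratio_cutoff = 0.5,
                          expression_inclusive = TRUE) {
  stopifnot(delta_beta_cutoff > -1, delta_beta_cutoff < 1,
            top_k_response >= 1,
            normal_panel_max_beta > 0, normal_panel_max_beta <= 1,
            expression_ratio_cutoff > 0)
  structure(
    list(delta_beta_cutoff = delta_beta_cutoff,
         top_k_response = as.integer(top_k_response),
         normal_panel_max_beta = normal_panel_max_beta,
         expression_ratio_cutoff = expression_ratio_cutoff,
         expression_inclusive = expression_inclusive),
    class = "funnel_config"
  )
}

#' Criterion 1/2: genes hypermethylated in a paired cohort
#'
#' Genes with tumor-normal delta average beta strictly greater than the
#' cutoff. Used both for the discovery cohort and for an independent
#' replication cohort.
#'
#' @param cohort a paired [beta_cohort()].
#' @param cutoff strict delta-beta threshold.
#' @param region optional probe region filter.
#' @return character vector of gene identifiers, with the per-gene deltas as
#'   attribute `delta`.
#' @export
criterion_hypermethylation <- function(cohort, cutoff = 0.4, region = NULL) {
  if (ncol(cohort$beta) == 0) stop("empty cohort")
  d <- delta_avg_beta_all(cohort, region = region)
  hit <- !is.na(d$delta_avg_beta) & d$delta_avg_beta > cutoff
  structure(d$gene[hit], delta = stats::setNames(d$delta_avg_beta, d$gene))
}

#' Criterion 3: top-k genes by poor-response methylation contrast
#'
#' Ranks genes by the difference of mean gene-level beta between
#' progressive-disease (PD) and complete-response (CR) tumors, descending;
#' ties are broken lexicographically by gene identifier.
#'
#' @param pd_beta,cr_beta gene x sample matrices of gene-level betas (same
#'   gene order) for the PD and CR tumors.
#' @param k number of genes returned.
#' @return data.frame `gene`, `diff` (mean PD - mean CR), `rank`, k rows.
#' @export
criterion_response_topk <- function(pd_beta, cr_beta, k = 20) {
  stopifnot(nrow(pd_beta) == nrow(cr_beta),
            identical(rownames(pd_beta), rownames(cr_beta)),
            ncol(pd_beta) >= 1, ncol(cr_beta) >= 1)
  if (k > nrow(pd_beta)) stop("k exceeds the number of genes")
  diff <- rowMeans(pd_beta, na.rm = TRUE) - rowMeans(cr_beta, na.rm = TRUE)
  ord <- order(-diff, rownames(pd_beta))
  data.frame(
    gene = rownames(pd_beta)[ord][seq_len(k)],
    diff = diff[ord][seq_len(k)],
    rank = seq_len(k),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Criterion 4: genes near-unmethylated across a normal-tissue panel
#'
#' A gene passes when its mean beta within every tissue type of the panel is
#' strictly below `max_beta`.
#'
#' @param panel a [beta_cohort()] of normal-panel samples.
#' @param max_beta strict per-tissue mean-beta bound.
#' @param region optional probe region filter.
#' @return character vector of gene identifiers.
#' @export
criterion_normal_low <- function(panel, max_beta = 0.1, region = NULL) {
  stopifnot(ncol(panel$beta) >= 1)
  gb <- gene_beta_matrix(panel, region = region)
  tis <- factor(panel$samples$tissue, levels = unique(panel$samples$tissue))
  tissue_means <- t(rowsum(t(gb), tis) / as.vector(table(tis)))
  ok <- apply(tissue_means, 1, function(v) all(!is.na(v) & v < max_beta))
  rownames(gb)[ok]
}

#' Criterion 5: genes with halved tumor expression
#'
#' Genes whose mean tumor expression over mean normal expression is at or
#' below the cutoff (inclusive by default). Genes with zero mean normal
#' expression are flagged and excluded.
#'
#' @param expression list with `expression` (gene x sample matrix) and
#'   `samples` metadata, as produced by [simulate_expression()].
#' @param ratio_cutoff tumor/normal ratio cutoff.
#' @param inclusive compare with `<=` (default) or strict `<`.
#' @return character vector of gene identifiers; genes excluded for a zero
#'   normal mean are recorded in attribute `flagged`.
#' @export
criterion_expression_halved <- function(expression, ratio_cutoff = 0.5,
                                        inclusive = TRUE) {
  expr <- expression$expression
  roles <- expression$samples$role
  tum <- roles == "tumor"
  nor <- roles == "adjacent_normal"
  stopifnot(any(tum), any(nor))
  mt <- rowMeans(expr[, tum, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(expr[, nor, drop = FALSE], na.rm = TRUE)
  zero <- mn == 0
  ratio <- mt / mn
  hit <- if (inclusive) ratio <= ratio_cutoff else ratio < ratio_cutoff
  hit <- hit & !zero & !is.na(ratio)
  structure(rownames(expr)[hit],
            ratio = stats::setNames(ratio, rownames(expr)),
            flagged = rownames(expr)[zero])
}

#' Run the five-criterion screening funnel
#'
#' Intersects (1) discovery-cohort hypermethylation, (2) replication-cohort
#' hypermethylation, (3) top-k poor-response methylation contrast, (4)
#' near-zero methylation across a normal-tissue panel, and (5) halved tumor
#' expression, and orders the surviving genes by their response-contrast
#' rank.
#'
#' @param config a [funnel_config()].
#' @param discovery,replication paired [beta_cohort()]s for criteria 1 and 2.
#' @param response a [beta_cohort()] whose tumor samples carry `"PD"` / `"CR"`
#'   response labels (criterion 3).
#' @param panel a normal-tissue [beta_cohort()] (criterion 4).
#' @param expression paired expression data as in
#'   [criterion_expression_halved()] (criterion 5).
#' @param region optional probe region filter applied to all beta criteria.
#' @return list of class `funnel_report`: `sets` (the five gene sets),
#'   `counts`, `final` (ordered intersection), `evidence` (per-final-gene
#'   record of delta betas, response rank, panel beta, expression ratio).
#' @export
run_funnel <- function(config, discovery, replication, response, panel,
                       expression, region = NULL) {
  stopifnot(inherits(config, "funnel_config"))
  s1 <- criterion_hypermethylation(discovery, config$delta_beta_cutoff, region)
  s2 <- criterion_hypermethylation(replication, config$delta_beta_cutoff, region)

  tum <- response$samples$role == "tumor"
  pd <- tum & response$samples$response == "PD"
  cr <- tum & response$samples$response == "CR"
  if (!any(pd) || !any(cr)) stop("response cohort needs both PD and CR tumors")
  gb <- gene_beta_matrix(response, region = region)
  topk <- criterion_response_topk(gb[, pd, drop = FALSE],
                                  gb[, cr, drop = FALSE],
                                  k = config$top_k_response)
  s3 <- topk$gene

  s4 <- criterion_normal_low(panel, config$normal_panel_max_beta, region)
  s5 <- criterion_expression_halved(expression,
                                    config$expression_ratio_cutoff,
                                    config$expression_inclusive)

  final <- Reduce(intersect, list(s1, s2, s3, s4, s5))
  # order by response rank
  final <- topk$gene[topk$gene %in% final]

  d1 <- attr(s1, "delta"); d2 <- attr(s2, "delta")
  er <- attr(s5, "ratio")
  panel_mean <- rowMeans(gene_beta_matrix(panel, region = region))
  evidence <- data.frame(
    gene = final,
    delta_beta_discovery = unname(d1[final]),
    delta_beta_replication = unname(d2[final]),
    response_rank = match(final, topk$gene),
    response_diff = topk$diff[match(final, topk$gene)],
    normal_panel_mean_beta = unname(panel_mean[final]),
    expression_ratio = unname(er[final]),
    stringsAsFactors = FALSE
  )
  sets <- list(discovery_hypermethylated = as.character(s1),
               replication_hypermethylated = as.character(s2),
               response_topk = as.character(s3),
               normal_low = as.character(s4),
               expression_halved = as.character(s5))
  structure(
    list(sets = sets,
         counts = vapply(sets, length, integer(1)),
         final = final,
         evidence = evidence,
         config = config),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Five-criterion screening funnel\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %6d genes\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  %-28s %6d genes\n", "final intersection", length(x$final)))
  if (length(x$final)) {
    cat("  final:", paste(utils::head(x$final, 25), collapse = ", "),
        if (length(x$final) > 25) "..." else "", "\n")
  }
  invisible(x)
}
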