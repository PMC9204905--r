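#' Beta value from methylated/unmethylated signal intensities
#'
#' beta = M / (M + U), the methylated fraction of total signal, in \[0,1\].
#' Vectorized; a probe with both signals zero yields `NA` and is flagged with
#' a warning.
#'
#' @param methylated,unmethylated nonnegative signal intensities.
#' @return beta fractions.
#' @export
beta_from_intensities <- function(methylated, unmethylated) {
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE)) {
    stop("signal intensities must be nonnegative")
  }
  tot <- methylated + unmethylated
  zero <- !is.na(tot) & tot == 0
  if (any(zero)) {
    warning(sum(zero), " probe(s) with zero total signal set to NA")
    tot[zero] <- NA_real_
  }
  methylated / tot
}

#' Gene-level beta per sample
#'
#' Unweighted mean of the non-missing probe betas annotated to a gene,
#' optionally restricted to a region (e.g. promoter + exon1, the region a
#' junction-targeting methylation-specific assay interrogates) and a sample
#' subset. Missing probe values are excluded pairwise; the number of probes
#' used per sample is attached as attribute `n_probes`.
#'
#' @param cohort a [beta_cohort()].
#' @param gene gene identifier.
#' @param region optional character vector of region tags to keep.
#' @param samples optional character vector of sample ids.
#' @return named numeric vector of per-sample gene-level betas.
#' @export
aggregate_gene_beta <- function(cohort, gene, region = NULL, samples = NULL) {
  stopifnot(inherits(cohort, "beta_cohort"))
  keep <- cohort$probes$gene == gene
  if (!is.null(region)) keep <- keep & cohort$probes$region %in% region
  if (!any(keep)) {
    stop("gene not covered: no probes annotated to '", gene, "'",
         if (!is.null(region)) paste0(" in region(s) ",
                                      paste(region, collapse = "/")))
  }
  m <- cohort$beta[keep, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  attr(out, "n_probes") <- colSums(!is.na(m))
  out
}

#' Gene x sample matrix of gene-level betas
#'
#' Vectorized probe-to-gene aggregation (unweighted mean of non-missing
#' probes) for all genes at once.
#'
#' @inheritParams aggregate_gene_beta
#' @return numeric matrix, genes x samples.
#' @export
gene_beta_matrix <- function(cohort, region = NULL) {
  stopifnot(inherits(cohort, "beta_cohort"))
  keep <- rep(TRUE, nrow(cohort$probes))
  if (!is.null(region)) keep <- cohort$probes$region %in% region
  b <- cohort$beta[keep, , drop = FALSE]
  g <- factor(cohort$probes$gene[keep],
              levels = unique(cohort$probes$gene[keep]))
  num <- rowsum(ifelse(is.na(b), 0, b), g)
  den <- rowsum((!is.na(b)) * 1, g)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Tumor-normal difference of mean gene-level beta
#'
#' delta = mean over tumor samples minus mean over adjacent-normal samples of
#' the gene-level beta (unpaired group means; per-pair differences are
#' available via [aggregate_gene_beta()] on the paired samples).
#'
#' @inheritParams aggregate_gene_beta
#' @return data.frame with `gene`, `mean_tumor`, `mean_normal`,
#'   `delta_avg_beta`.
#' @export
delta_avg_beta <- function(cohort, gene, region = NULL) {
  stopifnot(inherits(cohort, "beta_cohort"))
  tum <- cohort$samples$sample_id[cohort$samples$role == "tumor"]
  nor <- cohort$samples$sample_id[cohort$samples$role == "adjacent_normal"]
  if (length(tum) == 0 || length(nor) == 0) {
    stop("both tumor and adjacent_normal samples are required")
  }
  gb <- aggregate_gene_beta(cohort, gene, region = region)
  mt <- mean(gb[tum], na.rm = TRUE)
  mn <- mean(gb[nor], na.rm = TRUE)
  data.frame(gene = gene, mean_tumor = mt, mean_normal = mn,
             delta_avg_beta = mt - mn, stringsAsFactors = FALSE)
}

#' Tumor-normal delta beta for every gene
#'
#' @inheritParams aggregate_gene_beta
#' @return data.frame with one row per gene: `gene`, `mean_tumor`,
#'   `mean_normal`, `delta_avg_beta`.
#' @export
delta_avg_beta_all <- function(cohort, region = NULL) {
  stopifnot(inherits(cohort, "beta_cohort"))
  gb <- gene_beta_matrix(cohort, region = region)
  tum <- cohort$samples$role == "tumor"
  nor <- cohort$samples$role == "adjacent_normal"
  if (!any(tum) || !any(nor)) {
    stop("both tumor and adjacent_normal samples are required")
  }
  mt <- rowMeans(gb[, tum, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(gb[, nor, drop = FALSE], na.rm = TRUE)
  data.frame(gene = rownames(gb), mean_tumor = mt, mean_normal = mn,
             delta_avg_beta = mt - mn, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Array-based hypermethylation call
#'
#' A tumor beta strictly greater than the cutoff (default 0.25) is called
#' hypermethylated; missing beta gives a missing call.
#'
#' @param beta tumor beta value(s) in \[0,1\].
#' @param cutoff strict threshold.
#' @return logical vector.
#' @export
call_hypermethylated_beta <- function(beta, cutoff = 0.25) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta must lie in [0,1]")
  beta > cutoff
}
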