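#' Probe-level beta-value cohort container
#'
#' Bundles a probes x samples matrix of methylation beta values (fractions in
#' \[0,1\]) with its probe annotation and sample metadata, mirroring the
#' tables exported from Illumina 450K/EPIC processing.
#'
#' @param beta numeric matrix, probes in rows, samples in columns; values in
#'   \[0,1\] or `NA`.
#' @param probes data.frame with columns `probe_id`, `gene`, `region`
#'   (e.g. `"promoter"`, `"exon1"`), one row per row of `beta`.
#' @param samples data.frame with columns `sample_id`, `role` (one of
#'   `"tumor"`, `"adjacent_normal"`, `"normal_panel"`), `pair_id`, `response`
#'   (`"CR"`, `"PD"` or `"none"`), `tissue`; one row per column of `beta`.
#'
#' @return an object of class `beta_cohort`.
#' @export
beta_cohort <- function(beta, probes, samples) {
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == nrow(probes), ncol(beta) == nrow(samples))
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values must lie in [0, 1]")
  }
  need_p <- c("probe_id", "gene", "region")
  need_s <- c("sample_id", "role", "pair_id", "response", "tissue")
  stopifnot(all(need_p %in% names(probes)), all(need_s %in% names(samples)))
  rownames(beta) <- probes$probe_id
  colnames(beta) <- samples$sample_id
  structure(
    list(beta = beta, probes = probes, samples = samples),
    class = "beta_cohort"
  )
}

#' @export
print.beta_cohort <- function(x, ...) {
  cat(sprintf(
    "beta_cohort: %d probes (%d genes) x %d samples (%d tumor / %d normal)\n",
    nrow(x$beta), length(unique(x$probes$gene)), ncol(x$beta),
    sum(x$samples$role == "tumor"),
    sum(x$samples$role != "tumor")
  ))
  invisible(x)
}

#' Subset a beta cohort by sample
#'
#' @param x a `beta_cohort`.
#' @param keep logical or integer index over samples.
#' @return a `beta_cohort` restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  stopifnot(inherits(x, "beta_cohort"))
  beta_cohort(x$beta[, keep, drop = FALSE], x$probes,
              x$samples[keep, , drop = FALSE])
}
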