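# Plain-text readers/writers for the pipeline's tabular dialects:
# beta matrix TSV (probes x samples), probe-annotation TSV, sample-metadata
# TSV, long-format Cq CSV, plasma-series CSV, survival CSV, manifest JSON.

#' Write a beta cohort to its three-file TSV dialect
#'
#' @param cohort a [beta_cohort()].
#' @param prefix file path prefix; writes `<prefix>_beta.tsv`,
#'   `<prefix>_probes.tsv`, `<prefix>_samples.tsv`.
#' @return invisibly, the three file paths.
#' @export
write_beta_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "beta_cohort"))
  paths <- paste0(prefix, c("_beta.tsv", "_probes.tsv", "_samples.tsv"))
  beta_df <- data.frame(probe_id = rownames(cohort$beta), cohort$beta,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(beta_df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$probes, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a beta cohort written by [write_beta_cohort()]
#'
#' @param prefix the file path prefix used when writing.
#' @return a [beta_cohort()].
#' @export
read_beta_cohort <- function(prefix) {
  paths <- paste0(prefix, c("_beta.tsv", "_probes.tsv", "_samples.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  beta_df <- utils::read.delim(paths[1], check.names = FALSE,
                               stringsAsFactors = FALSE)
  probes <- utils::read.delim(paths[2], stringsAsFactors = FALSE)
  samples <- utils::read.delim(paths[3], stringsAsFactors = FALSE)
  beta <- as.matrix(beta_df[, -1, drop = FALSE])
  rownames(beta) <- beta_df$probe_id
  beta_cohort(beta[, samples$sample_id, drop = FALSE], probes, samples)
}

#' Write qPCR measurements as a long-format Cq CSV
#'
#' Columns: `sample_id`, `assay`, `role` (target/reference), `replicate`,
#' `cq`, `max_cycles`.
#'
#' @param measurements list of [qpcr_measurement()] objects.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cq_table <- function(measurements, path) {
  rows <- lapply(measurements, function(m) {
    rbind(
      data.frame(sample_id = m$sample_id, assay = m$target, role = "target",
                 replicate = seq_along(m$target_cq), cq = m$target_cq,
                 max_cycles = m$max_cycles, stringsAsFactors = FALSE),
      data.frame(sample_id = m$sample_id, assay = m$reference,
                 role = "reference", replicate = seq_along(m$reference_cq),
                 cq = m$reference_cq, max_cycles = m$max_cycles,
                 stringsAsFactors = FALSE)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a long-format Cq CSV into qPCR measurements
#'
#' @param path CSV written by [write_cq_table()].
#' @return named list of [qpcr_measurement()] objects, one per sample.
#' @export
read_cq_table <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "role", "replicate", "cq", "max_cycles")
  stopifnot(all(need %in% names(df)))
  out <- lapply(split(df, df$sample_id), function(d) {
    tgt <- d[d$role == "target", , drop = FALSE]
    ref <- d[d$role == "reference", , drop = FALSE]
    if (nrow(tgt) == 0 || nrow(ref) == 0) {
      stop("sample '", d$sample_id[1], "' lacks a target or reference assay")
    }
    qpcr_measurement(d$sample_id[1], tgt$assay[1], ref$assay[1],
                     tgt$cq, ref$cq, max_cycles = d$max_cycles[1])
  })
  out[unique(df$sample_id)]
}

#' Write / read the plasma-series CSV
#'
#' Columns: `patient_id`, `timepoint`, `timepoint_month`, `level`,
#' `cea_ng_ml`, `ca153_u_ml`, `progression`, `therapy`, `onset`.
#'
#' @param cohort a plasma cohort data.frame.
#' @param path CSV path.
#' @return invisibly `path`, or the data.frame when reading.
#' @export
write_plasma_series <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plasma_series
#' @export
read_plasma_series <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("plasma_cohort", "data.frame")
  out
}

#' Write / read the survival CSV
#'
#' @param records survival data.frame (`time`, `event`, `group`,
#'   covariates...).
#' @param path CSV path.
#' @return invisibly `path`, or the data.frame when reading.
#' @export
write_survival_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_table
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a gene-level methylation summary TSV
#'
#' @param summary data.frame from [delta_avg_beta_all()].
#' @param path TSV path.
#' @return invisibly `path`.
#' @export
write_gene_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
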