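#' A qPCR measurement: replicate Cq values for a target and a reference assay
#'
#' @param sample_id sample label.
#' @param target,reference assay names (e.g. a methylation-specific target
#'   normalized to ACTB, or an expression target normalized to GAPDH).
#' @param target_cq,reference_cq numeric replicate Cq values, each in
#'   `(0, max_cycles]`.
#' @param max_cycles sentinel cycle count: a replicate at `max_cycles` means
#'   no amplification (default 50, a common methylation-specific PCR cycle
#'   count).
#' @return object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(sample_id, target, reference,
                             target_cq, reference_cq, max_cycles = 50) {
  stopifnot(length(target_cq) >= 1, length(reference_cq) >= 1,
            all(target_cq > 0), all(target_cq <= max_cycles),
            all(reference_cq > 0), all(reference_cq <= max_cycles))
  structure(
    list(sample_id = sample_id, target = target, reference = reference,
         target_cq = target_cq, reference_cq = reference_cq,
         max_cycles = max_cycles),
    class = "qpcr_measurement"
  )
}

#' Relative level of a target vs its reference assay
#'
#' level = efficiency^(mean reference Cq - mean target Cq). Replicates are
#' averaged on the Cq scale before exponentiation (the behaviour of
#' instrument relative-quantification software); `replicate_mode =
#' "mean_level"` instead averages per-replicate levels. A target at the
#' no-amplification sentinel yields level 0 and `detected = FALSE`; a
#' reference at the sentinel is a reference failure and raises an error.
#'
#' @param measurement a [qpcr_measurement()].
#' @param efficiency amplification efficiency, fold per cycle (> 1; default
#'   2).
#' @param replicate_mode `"mean_cq"` (default) or `"mean_level"`.
#' @return list of class `relative_level`: `sample_id`, `level`, `detected`.
#' @export
relative_level <- function(measurement, efficiency = 2,
                           replicate_mode = c("mean_cq", "mean_level")) {
  stopifnot(inherits(measurement, "qpcr_measurement"), efficiency > 1)
  replicate_mode <- match.arg(replicate_mode)
  if (mean(measurement$reference_cq) >= measurement$max_cycles) {
    stop("invalid sample '", measurement$sample_id,
         "': reference assay failed to amplify")
  }
  undetected <- all(measurement$target_cq >= measurement$max_cycles)
  if (undetected) {
    lev <- 0
  } else if (replicate_mode == "mean_cq") {
    lev <- efficiency^(mean(measurement$reference_cq) -
                         mean(measurement$target_cq))
  } else {
    n <- max(length(measurement$target_cq), length(measurement$reference_cq))
    tc <- rep_len(measurement$target_cq, n)
    rc <- rep_len(measurement$reference_cq, n)
    lev <- mean(efficiency^(rc - tc))
  }
  structure(
    list(sample_id = measurement$sample_id, level = lev,
         detected = !undetected),
    class = "relative_level"
  )
}

#' Fold change of a sample's relative level against a calibrator
#'
#' Typically the tumor level calibrated to the paired normal tissue. A
#' calibrator level of 0 with a detected sample signal is methylation over an
#' unmethylated background: the fold is `Inf` and flagged.
#'
#' @param sample_level,calibrator_level numeric levels or `relative_level`
#'   objects.
#' @return the fold ratio, with attribute `infinite_fold` when the calibrator
#'   was 0 and the sample detected; `NA` when both are 0.
#' @export
calibrated_fold <- function(sample_level, calibrator_level) {
  s <- if (inherits(sample_level, "relative_level")) sample_level$level
       else sample_level
  k <- if (inherits(calibrator_level, "relative_level")) calibrator_level$level
       else calibrator_level
  stopifnot(s >= 0, k >= 0)
  if (k == 0) {
    if (s == 0) return(NA_real_)
    return(structure(Inf, infinite_fold = TRUE))
  }
  s / k
}

#' Methylation-specific PCR hypermethylation call
#'
#' Hypermethylated when the tumor/normal fold is at least `cutoff`
#' (inclusive, "at least twofold"); an infinite fold (signal over an
#' unmethylated calibrator) is hypermethylated.
#'
#' @param fold nonnegative fold change(s).
#' @param cutoff inclusive threshold (default 2).
#' @return logical.
#' @export
call_hypermethylation_qmsp <- function(fold, cutoff = 2) {
  if (any(fold < 0, na.rm = TRUE)) stop("fold must be nonnegative")
  fold >= cutoff
}

#' Low-expression call for RT-qPCR fold changes
#'
#' Low expression when the tumor/normal expression fold is at or below
#' `cutoff` (default 0.5); an undetected target (fold 0) is low.
#'
#' @param fold nonnegative fold change(s).
#' @param cutoff inclusive threshold (default 0.5).
#' @return logical.
#' @export
call_low_expression <- function(fold, cutoff = 0.5) {
  if (any(fold < 0, na.rm = TRUE)) stop("fold must be nonnegative")
  fold <= cutoff
}

#' Treatment effect as percent-of-control and fold change
#'
#' Compares group means of relative levels between treated and control
#' samples (e.g. demethylating-agent vs vehicle), reporting
#' `100 * mean(treated)/mean(control)` and the equivalent fold change, with a
#' delta-method standard deviation for the ratio.
#'
#' @param treated,control numeric vectors of relative levels.
#' @return list: `percent_of_control`, `fold_change`, `sd_fold` (delta-method
#'   SE of the fold), group means and ns.
#' @export
treatment_effect <- function(treated, control) {
  stopifnot(length(treated) >= 1, length(control) >= 1)
  mt <- mean(treated); mc <- mean(control)
  if (mc == 0) stop("control mean is zero; percent of control undefined")
  fold <- mt / mc
  vt <- if (length(treated) > 1) stats::var(treated) / length(treated) else 0
  vc <- if (length(control) > 1) stats::var(control) / length(control) else 0
  sd_fold <- abs(fold) * sqrt(vt / mt^2 + vc / mc^2)
  list(
    percent_of_control = 100 * fold,
    fold_change = fold,
    sd_fold = sd_fold,
    mean_treated = mt, mean_control = mc,
    n_treated = length(treated), n_control = length(control)
  )
}
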