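#' Classify a single plasma draw
#'
#' A circulating methylated-marker level strictly above the cutoff (default
#' 0.002, methylated-target/ACTB ratio) is abnormal.
#'
#' @param level nonnegative level(s); `NA` propagates.
#' @param cutoff strict threshold.
#' @return character vector of `"abnormal"` / `"normal"` (or `NA`).
#' @export
classify_timepoint <- function(level, cutoff = 0.002) {
  if (any(level < 0, na.rm = TRUE)) stop("levels must be nonnegative")
  ifelse(is.na(level), NA_character_,
         ifelse(level > cutoff, "abnormal", "normal"))
}

#' Patient-level progression call from a monitoring trajectory
#'
#' The baseline draw and the first `clearance_window` post-baseline draws are
#' allowed for treatment clearance (levels are high at the start of monitoring
#' even in patients who never progress). The patient is called
#' `high_methylation` — progression predicted — if any later draw is abnormal;
#' otherwise `no_methylation`.
#'
#' @param series numeric vector of levels in draw order, or a data.frame with
#'   a `level` column ordered by timepoint.
#' @param cutoff strict per-draw abnormality threshold.
#' @param clearance_window number of post-baseline draws excluded as the
#'   clearance phase (default 1): draws with 0-based index
#'   `> clearance_window` are evaluated.
#' @return list of class `monitoring_call`: `timepoint_status`,
#'   `patient_status` (`"high_methylation"`/`"no_methylation"`/
#'   `"indeterminate"`), `predicted` (`"progression"`/`"non_progression"`/
#'   `NA`), `score` (maximum post-window level, the ROC score).
#' @export
classify_patient <- function(series, cutoff = 0.002, clearance_window = 1) {
  levels <- if (is.data.frame(series)) {
    if (!is.null(series$timepoint)) {
      series$level[order(series$timepoint)]
    } else {
      series$level
    }
  } else {
    series
  }
  stopifnot(clearance_window >= 0)
  status <- classify_timepoint(levels, cutoff)
  idx <- seq_along(levels) - 1L  # 0-based draw index
  eligible <- idx > clearance_window
  if (!any(eligible)) {
    return(structure(
      list(timepoint_status = status, patient_status = "indeterminate",
           predicted = NA_character_, score = NA_real_),
      class = "monitoring_call"
    ))
  }
  abnormal <- any(status[eligible] == "abnormal", na.rm = TRUE)
  structure(
    list(
      timepoint_status = status,
      patient_status = if (abnormal) "high_methylation" else "no_methylation",
      predicted = if (abnormal) "progression" else "non_progression",
      score = max(levels[eligible], na.rm = TRUE)
    ),
    class = "monitoring_call"
  )
}

#' Serum tumor-marker abnormality calls
#'
#' CEA abnormal strictly above 5 ng/mL; CA15-3 abnormal strictly above
#' 25 U/mL.
#'
#' @param cea CEA concentration (ng/mL), `NA` allowed.
#' @param ca153 CA15-3 concentration (U/mL), `NA` allowed.
#' @param cea_cutoff,ca153_cutoff strict thresholds.
#' @return list with `cea` and `ca153` status vectors
#'   (`"abnormal"`/`"normal"`/`NA`).
#' @export
serum_marker_call <- function(cea, ca153, cea_cutoff = 5, ca153_cutoff = 25) {
  if (any(cea < 0, na.rm = TRUE) || any(ca153 < 0, na.rm = TRUE)) {
    stop("marker concentrations must be nonnegative")
  }
  list(
    cea = ifelse(is.na(cea), NA_character_,
                 ifelse(cea > cea_cutoff, "abnormal", "normal")),
    ca153 = ifelse(is.na(ca153), NA_character_,
                   ifelse(ca153 > ca153_cutoff, "abnormal", "normal"))
  )
}

#' Benchmark the circulating methylation call against serum markers
#'
#' Applies [classify_patient()] to every patient, builds confusion metrics for
#' the methylation call and for the analogous any-abnormal-after-window serum
#' CEA and CA15-3 calls, and compares ROC/AUC using each patient's maximum
#' post-window value as the score.
#'
#' @param cohort long-format plasma data.frame as produced by
#'   [simulate_plasma_series()] (columns `patient_id`, `timepoint`, `level`,
#'   `cea_ng_ml`, `ca153_u_ml`, `progression`).
#' @param cutoff methylation abnormality threshold.
#' @param clearance_window see [classify_patient()].
#' @param cea_cutoff,ca153_cutoff serum thresholds.
#' @return list: `methylation`, `cea`, `ca153` (each a
#'   [confusion_metrics()] report plus `auc`), `roc` (per-marker ROC point
#'   tables), and `calls` (per-patient data.frame).
#' @export
benchmark_markers <- function(cohort, cutoff = 0.002, clearance_window = 1,
                              cea_cutoff = 5, ca153_cutoff = 25) {
  need <- c("patient_id", "timepoint", "level", "cea_ng_ml", "ca153_u_ml",
            "progression")
  stopifnot(all(need %in% names(cohort)))
  split_pat <- split(cohort, cohort$patient_id)
  calls <- do.call(rbind, lapply(split_pat, function(df) {
    df <- df[order(df$timepoint), , drop = FALSE]
    mc <- classify_patient(df$level, cutoff, clearance_window)
    eligible <- seq_len(nrow(df)) - 1L > clearance_window
    sm <- serum_marker_call(df$cea_ng_ml[eligible], df$ca153_u_ml[eligible],
                            cea_cutoff, ca153_cutoff)
    data.frame(
      patient_id = df$patient_id[1],
      progression = df$progression[1],
      predicted = identical(mc$predicted, "progression"),
      score = mc$score,
      cea_abnormal = any(sm$cea == "abnormal", na.rm = TRUE),
      cea_score = suppressWarnings(max(df$cea_ng_ml[eligible], na.rm = TRUE)),
      ca153_abnormal = any(sm$ca153 == "abnormal", na.rm = TRUE),
      ca153_score = suppressWarnings(max(df$ca153_u_ml[eligible],
                                         na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(calls) <- NULL
  if (length(unique(calls$progression)) < 2) {
    stop("cohort contains a single outcome class; benchmark undefined")
  }
  report_for <- function(pred, score) {
    rep <- confusion_metrics(confusion_from_calls(pred, calls$progression))
    roc <- roc_auc(score, calls$progression)
    rep$auc <- roc$auc
    list(report = rep, roc = roc$points)
  }
  meth <- report_for(calls$predicted, calls$score)
  cea <- report_for(calls$cea_abnormal, calls$cea_score)
  ca153 <- report_for(calls$ca153_abnormal, calls$ca153_score)
  list(
    methylation = meth$report,
    cea = cea$report,
    ca153 = ca153$report,
    roc = list(methylation = meth$roc, cea = cea$roc, ca153 = ca153$roc),
    calls = calls
  )
}
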