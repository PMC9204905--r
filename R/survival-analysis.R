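#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: at tied times, events precede censorings. S(0) = 1 and
#' the estimate is nonincreasing.
#'
#' @param records data.frame with `time` (months, >= 0) and `event` (1 =
#'   death, 0 = censored).
#' @return data.frame: `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   one row per distinct observed time.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1, all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events over the distinct event times with
#' hypergeometric variance, 1 df.
#'
#' @param records data.frame with `time`, `event` and a two-level `group`.
#' @return list: `chisq`, `df`, `p_value`. With no events in the pooled
#'   sample the statistic is undefined and returned as `NA` with a warning.
#' @export
logrank_test <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)),
            length(unique(records$group)) == 2)
  if (sum(records$event) == 0) {
    warning("no events in either group; log-rank statistic undefined")
    return(list(chisq = NA_real_, df = 1L, p_value = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  list(chisq = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood maximization with Efron handling of tied event times.
#' Hazard ratios with Wald 95% confidence intervals and p-values.
#'
#' @param records data.frame with `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names; categorical
#'   covariates are coded by reference-level indicators.
#' @return data.frame: `term`, `coef`, `hr`, `ci_lower`, `ci_upper`, `se`,
#'   `p_value`.
#' @export
cox_ph <- function(records, covariates) {
  stopifnot(all(c("time", "event") %in% names(records)),
            all(covariates %in% names(records)), sum(records$event) > 0)
  for (cv in covariates) {
    if (length(unique(records[[cv]])) < 2) {
      stop("covariate '", cv, "' is constant")
    }
  }
  f <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(f, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    se = s$coefficients[, "se(coef)"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Administrative censoring at a follow-up horizon
#'
#' Times beyond the horizon are capped and their events become censorings;
#' used e.g. to restrict analysis to 10-year overall survival.
#'
#' @param records data.frame with `time` and `event`.
#' @param horizon months (> 0), default 120.
#' @return the records with capped times.
#' @export
truncate_followup <- function(records, horizon = 120) {
  stopifnot(horizon > 0)
  over <- records$time > horizon
  records$event[over] <- 0L
  records$time[over] <- horizon
  records
}
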