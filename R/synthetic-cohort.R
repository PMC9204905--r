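#' Configuration for a synthetic paired tumor/normal methylation cohort
#'
#' The generator plants a hypermethylation effect at a chosen set of genes in
#' tumor samples, on top of a common background methylation level, and couples
#' gene expression negatively to the planted methylation. It emulates the
#' statistical structure of paired tumor/adjacent-normal array cohorts used in
#' promoter-hypermethylation biomarker screening.
#'
#' @param n_pairs number of tumor/normal patient pairs (>= 2).
#' @param n_genes number of genes.
#' @param probes_per_gene probes annotated to each gene's promoter/exon-1
#'   region.
#' @param planted_genes character vector of gene identifiers carrying the
#'   planted tumor hypermethylation effect; must be a subset of the gene
#'   universe.
#' @param delta_beta_effect methylation fraction added to tumor means at
#'   planted genes.
#' @param response_delta_beta additional methylation fraction added to tumors
#'   of progressive-disease (PD) patients at planted genes; used to plant a
#'   therapy-response association.
#' @param background_beta baseline methylation fraction everywhere else.
#' @param noise_sd standard deviation of beta noise (on the beta scale; noise
#'   is drawn on the logit scale and back-transformed so values stay inside
#'   \[0,1\] without mass at the bounds).
#' @param responder_fraction fraction of pairs labelled complete response
#'   (CR); the rest are progressive disease (PD).
#' @param expression_coupling fold-reduction of tumor expression at planted
#'   hypermethylated genes (1 = no coupling).
#' @param seed integer random seed.
#'
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 20,
                          n_genes = 1000,
                          probes_per_gene = 3,
                          planted_genes = sprintf("g%04d", 1:20),
                          delta_beta_effect = 0.5,
                          response_delta_beta = 0,
                          background_beta = 0.1,
                          noise_sd = 0.05,
                          responder_fraction = 0.7,
                          expression_coupling = 4,
                          seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    planted_genes = planted_genes,
    delta_beta_effect = delta_beta_effect,
    response_delta_beta = response_delta_beta,
    background_beta = background_beta, noise_sd = noise_sd,
    responder_fraction = responder_fraction,
    expression_coupling = expression_coupling, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_pairs >= 2, cfg$n_genes >= 1, cfg$probes_per_gene >= 1,
    cfg$background_beta >= 0, cfg$background_beta <= 1,
    cfg$delta_beta_effect >= 0, cfg$delta_beta_effect <= 1,
    cfg$noise_sd >= 0,
    cfg$responder_fraction >= 0, cfg$responder_fraction <= 1,
    cfg$expression_coupling > 0
  )
  genes <- gene_universe(cfg)
  if (!all(cfg$planted_genes %in% genes)) {
    stop("planted_genes must be a subset of the gene universe ",
         "(sprintf('g%04d', 1:n_genes))")
  }
  class(cfg) <- "cohort_config"
  cfg
}

gene_universe <- function(config) sprintf("g%04d", seq_len(config$n_genes))

probe_annotation <- function(config) {
  genes <- gene_universe(config)
  data.frame(
    probe_id = sprintf("cg%05d", seq_len(config$n_genes * config$probes_per_gene)),
    gene = rep(genes, each = config$probes_per_gene),
    region = rep(
      rep_len(c("promoter", "exon1"), config$probes_per_gene),
      config$n_genes
    ),
    stringsAsFactors = FALSE
  )
}

# Beta noise drawn on the logit scale and back-transformed, so values stay in
# (0,1) without mass at the bounds. The logit sd is the delta-method image of
# the requested beta-scale sd, and the logit location is calibrated
# numerically (per distinct mean) so that E[beta] equals the target mean —
# uncorrected logit-normal noise would bias small means upward. At sd = 0 the
# mean is returned exactly (clipped to [0,1] with a warning if the planted
# effect overshoots).
noisy_beta <- function(mu, sd) {
  if (any(mu > 1 + 1e-12) || any(mu < -1e-12)) {
    warning("planted effect pushes mean beta outside [0,1]; values clipped")
    mu <- pmin(pmax(mu, 0), 1)
  }
  if (sd == 0) return(mu)
  eps <- 1e-6
  mu_c <- pmin(pmax(mu, eps), 1 - eps)
  sd_logit <- sd / (mu_c * (1 - mu_c))
  key <- paste(mu_c, sd_logit)
  loc <- numeric(length(mu_c))
  for (k in unique(key)) {
    i <- which(key == k)[1]
    loc[key == k] <- calibrated_logit_location(mu_c[i], sd_logit[i])
  }
  stats::plogis(loc + stats::rnorm(length(mu_c), 0, sd_logit))
}

# location a such that E[plogis(a + sigma * Z)] = target, Z standard normal
calibrated_logit_location <- function(target, sigma) {
  mean_at <- function(a) {
    stats::integrate(
      function(z) stats::plogis(a + sigma * z) * stats::dnorm(z),
      -8, 8
    )$value - target
  }
  stats::uniroot(mean_at, lower = stats::qlogis(target) - 6 * sigma - 1,
                 upper = stats::qlogis(target) + 1, tol = 1e-10)$root
}

#' Simulate a paired tumor/normal beta-value cohort
#'
#' Tumor samples at planted genes have mean beta
#' `background_beta + delta_beta_effect` (plus `response_delta_beta` for PD
#' patients); all other probe/sample cells sit at `background_beta`.
#' Deterministic under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return a [beta_cohort()] with `2 * n_pairs` samples, paired `pair_id`s and
#'   per-pair response labels.
#' @export
simulate_beta_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  probes <- probe_annotation(config)
  n_cr <- round(config$n_pairs * config$responder_fraction)
  response <- rep(c("CR", "PD"), c(n_cr, config$n_pairs - n_cr))
  samples <- data.frame(
    sample_id = c(sprintf("P%03d_T", seq_len(config$n_pairs)),
                  sprintf("P%03d_N", seq_len(config$n_pairs))),
    role = rep(c("tumor", "adjacent_normal"), each = config$n_pairs),
    pair_id = rep(sprintf("P%03d", seq_len(config$n_pairs)), 2),
    response = rep(response, 2),
    tissue = "breast",
    stringsAsFactors = FALSE
  )
  mu <- matrix(config$background_beta, nrow(probes), nrow(samples))
  planted <- probes$gene %in% config$planted_genes
  tumor <- samples$role == "tumor"
  mu[planted, tumor] <- mu[planted, tumor] + config$delta_beta_effect
  pd_tumor <- tumor & samples$response == "PD"
  mu[planted, pd_tumor] <- mu[planted, pd_tumor] + config$response_delta_beta
  beta <- matrix(noisy_beta(mu, config$noise_sd), nrow(mu), ncol(mu))
  beta_cohort(beta, probes, samples)
}

#' Simulate a multi-tissue normal panel
#'
#' All genes (planted or not) sit at `background_beta` in normal tissues,
#' emulating the near-zero promoter methylation of tumor-suppressor candidates
#' across a panel of healthy tissue types.
#'
#' @param config a [cohort_config()]; `background_beta` and `noise_sd` are
#'   used.
#' @param n_tissues number of tissue types (>= 1). Up to ten named tissue
#'   types matching common normal panels are used, then generic labels.
#' @param samples_per_tissue samples per tissue type (default 32, giving a
#'   ten-tissue panel of ~320 normals, the scale of published multi-tissue
#'   normal methylation panels).
#' @return a [beta_cohort()] of `normal_panel` samples.
#' @export
simulate_normal_panel <- function(config, n_tissues = 10,
                                  samples_per_tissue = 32) {
  stopifnot(inherits(config, "cohort_config"), n_tissues >= 1,
            samples_per_tissue >= 1)
  set.seed(config$seed + 1L)
  named <- c("breast", "colon", "rectum", "lung", "uterus", "stomach",
             "esophagus", "pancreas", "liver", "prostate")
  tissues <- if (n_tissues <= length(named)) named[seq_len(n_tissues)] else
    c(named, sprintf("tissue%02d", seq_len(n_tissues - length(named))))
  probes <- probe_annotation(config)
  n_samp <- n_tissues * samples_per_tissue
  samples <- data.frame(
    sample_id = sprintf("NP%03d", seq_len(n_samp)),
    role = "normal_panel",
    pair_id = NA_character_,
    response = "none",
    tissue = rep(tissues, each = samples_per_tissue),
    stringsAsFactors = FALSE
  )
  mu <- matrix(config$background_beta, nrow(probes), n_samp)
  beta <- matrix(noisy_beta(mu, config$noise_sd), nrow(mu), ncol(mu))
  beta_cohort(beta, probes, samples)
}

#' Simulate expression coupled negatively to planted methylation
#'
#' Tumor expression of planted hypermethylated genes is reduced
#' `expression_coupling`-fold relative to normals; all other genes are
#' unchanged in expectation. Multiplicative lognormal noise is applied when
#' `noise_sd > 0`.
#'
#' @param config the [cohort_config()] used to generate `methylation`.
#' @param methylation the paired [beta_cohort()] from
#'   [simulate_beta_cohort()].
#' @param base_expression mean expression of an unsilenced gene (arbitrary
#'   normalized units).
#' @param sdlog lognormal noise sd (applied only when `config$noise_sd > 0`).
#' @return list with `expression` (gene x sample matrix) and `samples`
#'   (metadata shared with `methylation`).
#' @export
simulate_expression <- function(config, methylation, base_expression = 100,
                                sdlog = 0.2) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(methylation, "beta_cohort"))
  set.seed(config$seed + 2L)
  genes <- gene_universe(config)
  samples <- methylation$samples
  mu <- matrix(base_expression, length(genes), nrow(samples),
               dimnames = list(genes, samples$sample_id))
  planted <- genes %in% config$planted_genes
  tumor <- samples$role == "tumor"
  mu[planted, tumor] <- mu[planted, tumor] / config$expression_coupling
  expr <- if (config$noise_sd > 0) {
    mu * exp(stats::rnorm(length(mu), 0, sdlog))
  } else {
    mu
  }
  list(expression = expr, samples = samples)
}

#' Simulate qPCR Cq replicates from a true relative level
#'
#' Inverse of the relative-quantification model: with amplification efficiency
#' E, a target present at `true_ratio` times the reference amplifies
#' `log(true_ratio, E)` cycles earlier/later than the reference. A zero ratio
#' (no methylated template) yields the no-amplification sentinel
#' `max_cycles`.
#'
#' @param true_ratio true target/reference abundance ratio (>= 0).
#' @param cq_reference reference-assay Cq (cycles).
#' @param efficiency amplification efficiency, fold per cycle (> 1).
#' @param replicates number of technical replicates.
#' @param cq_sd per-replicate Cq noise sd (cycles).
#' @param seed optional integer seed; `NULL` leaves the RNG state alone.
#' @param sample_id sample label.
#' @param target,reference assay names (reference defaults to ACTB as in
#'   methylation-specific PCR).
#' @param max_cycles sentinel cycle count for no amplification.
#' @return an object of class `qpcr_measurement`.
#' @export
simulate_qpcr <- function(true_ratio, cq_reference = 28, efficiency = 2,
                          replicates = 3, cq_sd = 0, seed = NULL,
                          sample_id = "S1", target = "TARGET",
                          reference = "ACTB", max_cycles = 50) {
  stopifnot(true_ratio >= 0, efficiency > 1, replicates >= 1, cq_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  ref_cq <- cq_reference + stats::rnorm(replicates, 0, cq_sd)
  if (true_ratio == 0) {
    tgt_cq <- rep(max_cycles, replicates)
  } else {
    tgt <- cq_reference - log(true_ratio, base = efficiency)
    tgt_cq <- pmin(tgt + stats::rnorm(replicates, 0, cq_sd), max_cycles)
  }
  qpcr_measurement(sample_id, target, reference, tgt_cq, ref_cq, max_cycles)
}

#' Configuration for circulating methylated-DNA trajectory simulation
#'
#' Emulates longitudinal plasma monitoring after treatment: the circulating
#' methylated-marker level clears (geometric decay) in all patients; in
#' progressors it reappears and rises again from a designated onset timepoint.
#' Serum CEA and CA15-3 are generated as mostly normal, with a late,
#' incomplete abnormality in progressors.
#'
#' @param n_patients cohort size.
#' @param baseline_level pre-clearance methylated-target/ACTB ratio.
#' @param clearance_halflife clearance half-life in timepoints; draws are
#'   three months apart for the first two years, so sub-timepoint half-lives
#'   reflect the days-scale clearance of circulating tumor DNA.
#' @param progression_fraction fraction of patients who progress.
#' @param regrowth_rate multiplicative per-timepoint growth factor after
#'   progression onset (> 1).
#' @param detection_floor assay detection limit; values below it are reported
#'   as 0.
#' @param assay_cv multiplicative lognormal coefficient of variation.
#' @param n_timepoints draws per patient (including the baseline draw).
#' @param hormone_fraction fraction of patients under hormone therapy (label
#'   only).
#' @param cea_normal,ca153_normal median normal serum marker levels (ng/mL,
#'   U/mL).
#' @param serum_lag timepoints after progression onset before serum markers
#'   can turn abnormal.
#' @param serum_abnormal_fraction fraction of progressors whose serum markers
#'   eventually turn abnormal.
#' @param seed integer seed.
#' @return a list of class `plasma_sim_config`.
#' @export
plasma_sim_config <- function(n_patients = 200,
                              baseline_level = 0.016,
                              clearance_halflife = 0.5,
                              progression_fraction = 0.3,
                              regrowth_rate = 2,
                              detection_floor = 0.002,
                              assay_cv = 0.3,
                              n_timepoints = 8,
                              hormone_fraction = 0.5,
                              cea_normal = 2,
                              ca153_normal = 15,
                              serum_lag = 2,
                              serum_abnormal_fraction = 0.5,
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), baseline_level = baseline_level,
    clearance_halflife = clearance_halflife,
    progression_fraction = progression_fraction,
    regrowth_rate = regrowth_rate, detection_floor = detection_floor,
    assay_cv = assay_cv, n_timepoints = as.integer(n_timepoints),
    hormone_fraction = hormone_fraction,
    cea_normal = cea_normal, ca153_normal = ca153_normal,
    serum_lag = as.integer(serum_lag),
    serum_abnormal_fraction = serum_abnormal_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_patients >= 1, cfg$baseline_level >= 0,
    cfg$clearance_halflife > 0,
    cfg$progression_fraction >= 0, cfg$progression_fraction <= 1,
    cfg$regrowth_rate > 1, cfg$detection_floor >= 0, cfg$assay_cv >= 0,
    cfg$n_timepoints >= 4
  )
  class(cfg) <- "plasma_sim_config"
  cfg
}

#' Month offsets for monitoring draws
#'
#' Every 3 months for the first two years, semiannually thereafter.
#'
#' @param n_timepoints number of draws including baseline.
#' @return numeric vector of months since treatment start.
#' @export
monitoring_months <- function(n_timepoints) {
  first <- seq(0, 21, by = 3)
  if (n_timepoints <= length(first)) return(first[seq_len(n_timepoints)])
  c(first, seq(27, by = 6, length.out = n_timepoints - length(first)))
}

#' Simulate longitudinal plasma methylated-marker trajectories
#'
#' @param config a [plasma_sim_config()].
#' @return long-format data.frame (class `plasma_cohort`): `patient_id`,
#'   `timepoint` (0-based draw index), `timepoint_month`, `level`
#'   (methylated-target/ACTB ratio), `cea_ng_ml`, `ca153_u_ml`,
#'   `progression` (planted truth, logical), `therapy`, `onset` (draw index
#'   of regrowth onset, `NA` for non-progressors).
#' @export
simulate_plasma_series <- function(config) {
  stopifnot(inherits(config, "plasma_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  tp <- config$n_timepoints
  months <- monitoring_months(tp)
  n_prog <- round(n * config$progression_fraction)
  progression <- rep(c(TRUE, FALSE), c(n_prog, n - n_prog))
  # onset late enough to fall after the clearance window, early enough that
  # at least one post-onset draw exists
  onset_lo <- 3L
  onset_hi <- max(onset_lo, tp - 2L)
  onset <- ifelse(progression,
                  sample(seq.int(onset_lo, onset_hi), n, replace = TRUE),
                  NA_integer_)
  sdlog <- sqrt(log(1 + config$assay_cv^2))
  reseed <- 2 * config$detection_floor
  rows <- vector("list", n)
  therapy <- rep(c("hormone_therapy", "other"),
                 c(round(n * config$hormone_fraction),
                   n - round(n * config$hormone_fraction)))
  for (i in seq_len(n)) {
    t_idx <- 0:(tp - 1)
    lev <- config$baseline_level * 2^(-t_idx / config$clearance_halflife)
    if (progression[i]) {
      grow <- ifelse(t_idx >= onset[i],
                     reseed * config$regrowth_rate^(t_idx - onset[i]), 0)
      lev <- lev + grow
    }
    if (config$assay_cv > 0) {
      lev <- lev * exp(stats::rnorm(tp, 0, sdlog))
    }
    lev[lev < config$detection_floor] <- 0
    cea <- config$cea_normal * exp(stats::rnorm(tp, 0, 0.25))
    ca153 <- config$ca153_normal * exp(stats::rnorm(tp, 0, 0.25))
    if (progression[i] && stats::runif(1) < config$serum_abnormal_fraction) {
      late <- t_idx >= onset[i] + config$serum_lag
      cea[late] <- cea[late] * 4      # pushes median past the 5 ng/mL bound
      ca153[late] <- ca153[late] * 2.5 # past the 25 U/mL bound
    }
    rows[[i]] <- data.frame(
      patient_id = sprintf("PL%03d", i),
      timepoint = t_idx,
      timepoint_month = months,
      level = lev,
      cea_ng_ml = cea,
      ca153_u_ml = ca153,
      progression = progression[i],
      therapy = therapy[i],
      onset = onset[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("plasma_cohort", "data.frame")
  out
}

#' Simulate survival records with a group-dependent hazard
#'
#' Exponential event times with the hazard multiplied by `hazard_ratio` in the
#' exposed (hypermethylated) group, administratively censored at
#' `censor_time`.
#'
#' @param n number of subjects.
#' @param hazard_ratio hazard multiplier for the exposed group (> 0).
#' @param group_fraction fraction of subjects exposed.
#' @param censor_time administrative censoring horizon (months).
#' @param baseline_median median survival of the unexposed group (months).
#' @param seed integer seed.
#' @return data.frame: `time` (months), `event` (1 = death), `group`
#'   (`"hypermethylated"` / `"hypomethylated"`), plus `age` covariate.
#' @export
simulate_survival <- function(n, hazard_ratio = 1, group_fraction = 0.5,
                              censor_time = 120, baseline_median = 60,
                              seed = 1L) {
  stopifnot(n >= 2, hazard_ratio > 0, censor_time >= 0,
            group_fraction >= 0, group_fraction <= 1)
  set.seed(as.integer(seed))
  n_exp <- round(n * group_fraction)
  exposed <- rep(c(TRUE, FALSE), c(n_exp, n - n_exp))
  rate0 <- log(2) / baseline_median
  t_event <- stats::rexp(n, rate0 * ifelse(exposed, hazard_ratio, 1))
  time <- pmin(t_event, censor_time)
  data.frame(
    time = time,
    event = as.integer(t_event <= censor_time),
    group = ifelse(exposed, "hypermethylated", "hypomethylated"),
    age = round(stats::rnorm(n, 58, 10)),
    stringsAsFactors = FALSE
  )
}
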