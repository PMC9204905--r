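# Generator properties: noiseless exactness, seed determinism, planted-effect
# recovery, and the qPCR/plasma/survival sub-generators.

test_that("noiseless cohort places planted tumor betas exactly at background + effect", {
  cfg <- cohort_config(n_pairs = 4, n_genes = 10, probes_per_gene = 2,
                       planted_genes = c("g0001", "g0002"),
                       delta_beta_effect = 0.5, background_beta = 0.1,
                       noise_sd = 0)
  co <- simulate_beta_cohort(cfg)
  planted <- co$probes$gene %in% c("g0001", "g0002")
  tumor <- co$samples$role == "tumor"
  expect_true(all(co$beta[planted, tumor] == 0.6))
  expect_true(all(co$beta[planted, !tumor] == 0.1))
  expect_true(all(co$beta[!planted, ] == 0.1))
})

test_that("identical config and seed reproduce bit-identical outputs", {
  cfg <- cohort_config(n_pairs = 5, n_genes = 50, seed = 42L)
  expect_identical(simulate_beta_cohort(cfg), simulate_beta_cohort(cfg))
  expect_identical(simulate_normal_panel(cfg, 4), simulate_normal_panel(cfg, 4))
  pcfg <- plasma_sim_config(n_patients = 10, seed = 7L)
  expect_identical(simulate_plasma_series(pcfg), simulate_plasma_series(pcfg))
})

test_that("all generated betas lie in [0,1] and planted effect overshoot warns", {
  cfg <- cohort_config(n_pairs = 5, n_genes = 40, noise_sd = 0.1,
                       background_beta = 0.1, delta_beta_effect = 0.8,
                       planted_genes = "g0001", seed = 3L)
  co <- simulate_beta_cohort(cfg)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  cfg2 <- cohort_config(n_pairs = 2, n_genes = 5, noise_sd = 0,
                        background_beta = 0.6, delta_beta_effect = 0.8,
                        planted_genes = "g0001")
  expect_warning(co2 <- simulate_beta_cohort(cfg2), "clipped")
  expect_true(all(co2$beta <= 1))
})

test_that("mean observed delta beta at planted genes concentrates near the effect", {
  cfg <- cohort_config(n_pairs = 20, n_genes = 1000, probes_per_gene = 2,
                       planted_genes = sprintf("g%04d", 1:20),
                       delta_beta_effect = 0.5, noise_sd = 0.05, seed = 11L)
  co <- simulate_beta_cohort(cfg)
  d <- delta_avg_beta_all(co)
  planted <- d$gene %in% cfg$planted_genes
  expect_lt(abs(mean(d$delta_avg_beta[planted]) - 0.5), 0.02)
  expect_lt(abs(mean(d$delta_avg_beta[!planted])), 0.01)
})

test_that("normal panel keeps every gene at the background level", {
  cfg <- cohort_config(n_pairs = 2, n_genes = 30, background_beta = 0.05,
                       noise_sd = 0, planted_genes = "g0001")
  panel <- simulate_normal_panel(cfg, n_tissues = 5)
  expect_true(all(panel$beta == 0.05))
  cfg2 <- cohort_config(n_pairs = 2, n_genes = 50, background_beta = 0.05,
                        noise_sd = 0.02, planted_genes = "g0001", seed = 5L)
  panel2 <- simulate_normal_panel(cfg2, n_tissues = 10,
                                  samples_per_tissue = 10)
  gm <- rowMeans(gene_beta_matrix(panel2))
  expect_true(all(abs(gm - 0.05) < 0.01))
})

test_that("expression coupling halves (or more) planted tumor expression", {
  cfg <- cohort_config(n_pairs = 6, n_genes = 20, expression_coupling = 2,
                       noise_sd = 0, planted_genes = c("g0001", "g0002"))
  co <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, co)
  tum <- ex$samples$role == "tumor"
  ratio <- rowMeans(ex$expression[, tum]) / rowMeans(ex$expression[, !tum])
  expect_equal(unname(ratio[c("g0001", "g0002")]), c(0.5, 0.5))
  expect_true(all(ratio[-(1:2)] == 1))

  # coupling = 1 is the identity
  cfg1 <- cohort_config(n_pairs = 6, n_genes = 20, expression_coupling = 1,
                        noise_sd = 0, planted_genes = "g0001")
  ex1 <- simulate_expression(cfg1, simulate_beta_cohort(cfg1))
  expect_true(all(ex1$expression == 100))
})

test_that("delta beta and expression log fold change are negatively correlated", {
  cfg <- cohort_config(n_pairs = 20, n_genes = 200, noise_sd = 0.05,
                       expression_coupling = 4, seed = 9L)
  co <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, co)
  d <- delta_avg_beta_all(co)
  tum <- ex$samples$role == "tumor"
  lfc <- log2(rowMeans(ex$expression[, tum]) /
                rowMeans(ex$expression[, !tum]))
  rho <- spearman_rho(d$delta_avg_beta, lfc)
  expect_lt(rho$rho, 0)
})

test_that("simulated qPCR encodes the planted ratio in the Cq difference", {
  m <- simulate_qpcr(0.25, cq_reference = 28, efficiency = 2, cq_sd = 0)
  expect_equal(unique(m$target_cq), 30)
  m1 <- simulate_qpcr(1, cq_reference = 28, cq_sd = 0)
  expect_equal(m1$target_cq, m1$reference_cq)
  m0 <- simulate_qpcr(0, cq_reference = 28, cq_sd = 0)
  expect_equal(unique(m0$target_cq), 50)
})

test_that("noisy qPCR recovers the planted ratio on average", {
  set.seed(123)
  est <- replicate(500, {
    m <- simulate_qpcr(0.1, replicates = 3, cq_sd = 0.1)
    relative_level(m)$level
  })
  expect_lt(abs(mean(est) - 0.1) / 0.1, 0.05)
})

test_that("noiseless plasma trajectories decay geometrically and censor at the floor", {
  cfg <- plasma_sim_config(n_patients = 1, baseline_level = 0.016,
                           clearance_halflife = 1, progression_fraction = 0,
                           assay_cv = 0, detection_floor = 0.002,
                           n_timepoints = 6)
  tr <- simulate_plasma_series(cfg)
  expect_equal(tr$level, c(0.016, 0.008, 0.004, 0.002, 0, 0))
  expect_false(any(tr$progression))
})

test_that("progression trajectories regrow after onset and labels follow the fraction", {
  cfg <- plasma_sim_config(n_patients = 20, progression_fraction = 0.5,
                           assay_cv = 0, seed = 2L)
  tr <- simulate_plasma_series(cfg)
  expect_equal(sum(tapply(tr$progression, tr$patient_id, unique)), 10)
  prog <- tr[tr$progression & tr$patient_id == tr$patient_id[1], ]
  post <- prog$level[prog$timepoint >= prog$onset[1]]
  expect_true(all(diff(post) > 0))
  expect_true(all(tr$onset[tr$progression] < cfg$n_timepoints))
})

test_that("survival generator censors administratively and recovers the hazard ratio", {
  s0 <- simulate_survival(10, censor_time = 0)
  expect_true(all(s0$time == 0) && all(s0$event == 0))
  s <- simulate_survival(500, hazard_ratio = 6, seed = 4L)
  fit <- cox_ph(transform(s, group = factor(
    group, levels = c("hypomethylated", "hypermethylated"))), "group")
  expect_lt(abs(fit$coef - log(6)) / log(6), 0.15)
})
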