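# The five-criterion funnel: threshold strictness, ranking and tie rules,
# all-tissue normal-panel rule, intersection algebra, and equivalence with a
# brute-force reimplementation on small instances.

test_that("hypermethylation criterion uses a strict cutoff", {
  probes <- data.frame(probe_id = c("cg1", "cg2"), gene = c("GA", "GB"),
                       region = "promoter", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("T1", "N1"), role = c("tumor", "adjacent_normal"),
    pair_id = "P1", response = "none", tissue = "breast",
    stringsAsFactors = FALSE
  )
  co <- beta_cohort(matrix(c(0.55, 0.10,   # GA: delta 0.45
                             0.50, 0.10),  # GB: delta 0.40 exactly
                           2, 2, byrow = TRUE), probes, samples)
  hits <- criterion_hypermethylation(co, cutoff = 0.4)
  expect_identical(as.character(hits), "GA")
})

test_that("planted cohort is fully recovered with a low false-inclusion rate", {
  cfg <- cohort_config(n_pairs = 20, n_genes = 1000, probes_per_gene = 2,
                       planted_genes = sprintf("g%04d", 1:20),
                       delta_beta_effect = 0.5, noise_sd = 0.05, seed = 21L)
  co <- simulate_beta_cohort(cfg)
  hits <- criterion_hypermethylation(co, cutoff = 0.4)
  expect_true(all(cfg$planted_genes %in% hits))
  false_in <- setdiff(hits, cfg$planted_genes)
  expect_lt(length(false_in) / (cfg$n_genes - 20), 0.01)
})

test_that("response top-k ranks by PD-CR mean difference with lexicographic ties", {
  pd <- matrix(c(0.6, 0.2, 0.5), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("pd1", "pd2")))
  cr <- matrix(c(0.1, 0.1, 0.2), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("cr1", "cr2")))
  top <- criterion_response_topk(pd, cr, k = 2)
  expect_equal(top$gene, c("g1", "g3"))
  expect_equal(top$diff, c(0.5, 0.3))

  tied_pd <- matrix(0.5, 3, 2, dimnames = list(c("gb", "ga", "gc"), NULL))
  tied_cr <- matrix(0.1, 3, 2, dimnames = list(c("gb", "ga", "gc"), NULL))
  expect_equal(criterion_response_topk(tied_pd, tied_cr, k = 3)$gene,
               c("ga", "gb", "gc"))
  expect_error(criterion_response_topk(pd, cr, k = 5), "exceeds")
})

test_that("a planted response gene lands in the top 20 among null genes", {
  hits <- 0L
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_pairs = 29, n_genes = 1000, probes_per_gene = 2,
                         planted_genes = "g0001", delta_beta_effect = 0,
                         response_delta_beta = 0.4,
                         responder_fraction = 21 / 29,
                         noise_sd = 0.05, seed = 1000L + s)
    co <- simulate_beta_cohort(cfg)
    tum <- co$samples$role == "tumor"
    gb <- gene_beta_matrix(co)
    top <- criterion_response_topk(
      gb[, tum & co$samples$response == "PD", drop = FALSE],
      gb[, tum & co$samples$response == "CR", drop = FALSE], k = 20
    )
    hits <- hits + ("g0001" %in% top$gene)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("normal-panel criterion requires every tissue below the bound", {
  probes <- data.frame(probe_id = c("cg1", "cg2"), gene = c("GA", "GB"),
                       region = "promoter", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("a1", "b1"), role = "normal_panel", pair_id = NA,
    response = "none", tissue = c("breast", "liver"), stringsAsFactors = FALSE
  )
  panel <- beta_cohort(matrix(c(0.05, 0.05,
                                0.05, 0.20), 2, 2, byrow = TRUE),
                       probes, samples)
  expect_identical(criterion_normal_low(panel, 0.1), "GA")

  cfg <- cohort_config(n_pairs = 2, n_genes = 500, background_beta = 0.05,
                       noise_sd = 0.02, planted_genes = "g0001", seed = 6L)
  big <- simulate_normal_panel(cfg, n_tissues = 10)
  passed <- criterion_normal_low(big, 0.1)
  expect_gte(length(passed) / 500, 0.99)
})

test_that("expression criterion is inclusive at the halving boundary", {
  mk <- function(ratios) {
    genes <- paste0("g", seq_along(ratios))
    expr <- cbind(tumor = 100 * ratios, normal = rep(100, length(ratios)))
    rownames(expr) <- genes
    list(expression = expr,
         samples = data.frame(sample_id = c("T", "N"),
                              role = c("tumor", "adjacent_normal"),
                              pair_id = "P1", response = "none",
                              tissue = "breast", stringsAsFactors = FALSE))
  }
  hits <- criterion_expression_halved(mk(c(0.5, 0.51, 0.2)))
  expect_setequal(as.character(hits), c("g1", "g3"))
  strict <- criterion_expression_halved(mk(c(0.5, 0.49)), inclusive = FALSE)
  expect_identical(as.character(strict), "g2")

  zero <- mk(c(0.4, 0.4))
  zero$expression[2, "normal"] <- 0
  z <- criterion_expression_halved(zero)
  expect_identical(as.character(z), "g1")
  expect_identical(attr(z, "flagged"), "g2")
})

test_that("run_funnel's final set is contained in every criterion set", {
  cfg <- cohort_config(n_pairs = 10, n_genes = 60, probes_per_gene = 2,
                       planted_genes = sprintf("g%04d", 1:5), seed = 31L)
  bundle <- simulate_bundle(cfg, plasma_sim_config(n_patients = 5, seed = 1L),
                            out_dir = withr::local_tempdir(),
                            survival_n = 20)
  rep <- run_funnel(funnel_config(top_k_response = 10), bundle$discovery,
                    bundle$replication, bundle$response, bundle$panel,
                    bundle$expression)
  for (s in rep$sets) expect_true(all(rep$final %in% s))
  expect_equal(unname(rep$counts), vapply(rep$sets, length, integer(1),
                                          USE.NAMES = FALSE))
  expect_setequal(rep$final, sprintf("g%04d", 1:5))
})

test_that("relaxing any cutoff never shrinks its criterion set", {
  cfg <- cohort_config(n_pairs = 8, n_genes = 100, noise_sd = 0.05, seed = 13L)
  co <- simulate_beta_cohort(cfg)
  panel <- simulate_normal_panel(cfg, 5)
  ex <- simulate_expression(cfg, co)
  for (cut in list(c(0.4, 0.3), c(0.2, 0.1))) {
    expect_true(all(
      criterion_hypermethylation(co, cut[1]) %in%
        criterion_hypermethylation(co, cut[2])
    ))
  }
  expect_true(all(
    criterion_normal_low(panel, 0.1) %in% criterion_normal_low(panel, 0.2)
  ))
  expect_true(all(
    criterion_expression_halved(ex, 0.5) %in%
      criterion_expression_halved(ex, 0.8)
  ))
})

test_that("permuting sample order changes no funnel output", {
  cfg <- cohort_config(n_pairs = 6, n_genes = 40, noise_sd = 0.05, seed = 17L)
  co <- simulate_beta_cohort(cfg)
  set.seed(1)
  perm <- sample(ncol(co$beta))
  co_p <- subset_samples(co, perm)
  expect_setequal(as.character(criterion_hypermethylation(co, 0.4)),
                  as.character(criterion_hypermethylation(co_p, 0.4)))
})

test_that("funnel matches a brute-force reimplementation on small instances", {
  # independent oracle: direct filtering with no shared package code
  oracle_funnel <- function(disc, repl, resp, panel, ex, k) {
    gene_means <- function(co) {
      genes <- unique(co$probes$gene)
      sapply(genes, function(g) {
        rows <- which(co$probes$gene == g)
        colMeans(co$beta[rows, , drop = FALSE], na.rm = TRUE)
      })
    }
    gd <- gene_means(disc)
    d1 <- colMeans(gd[disc$samples$role == "tumor", , drop = FALSE]) -
      colMeans(gd[disc$samples$role == "adjacent_normal", , drop = FALSE])
    gr <- gene_means(repl)
    d2 <- colMeans(gr[repl$samples$role == "tumor", , drop = FALSE]) -
      colMeans(gr[repl$samples$role == "adjacent_normal", , drop = FALSE])
    gresp <- gene_means(resp)
    pd <- resp$samples$role == "tumor" & resp$samples$response == "PD"
    cr <- resp$samples$role == "tumor" & resp$samples$response == "CR"
    diff <- colMeans(gresp[pd, , drop = FALSE]) -
      colMeans(gresp[cr, , drop = FALSE])
    top <- names(sort(diff, decreasing = TRUE))  # no ties in random data
    top <- top[seq_len(k)]
    gp <- gene_means(panel)
    ok4 <- sapply(colnames(gp), function(g) {
      all(tapply(gp[, g], panel$samples$tissue, mean) < 0.1)
    })
    tum <- ex$samples$role == "tumor"
    ratio <- rowMeans(ex$expression[, tum, drop = FALSE]) /
      rowMeans(ex$expression[, !tum, drop = FALSE])
    s5 <- names(ratio)[ratio <= 0.5]
    final <- names(d1)[d1 > 0.4]
    final <- final[final %in% names(d2)[d2 > 0.4]]
    final <- final[final %in% top]
    final <- final[final %in% names(ok4)[ok4]]
    final <- final[final %in% s5]
    final[order(match(final, top))]
  }

  for (s in 1:3) {
    cfg <- cohort_config(n_pairs = 8, n_genes = 40, probes_per_gene = 2,
                         planted_genes = sprintf("g%04d", 1:4),
                         noise_sd = 0.05, seed = 600L + s)
    b <- simulate_bundle(cfg, plasma_sim_config(n_patients = 5, seed = 1L),
                         out_dir = withr::local_tempdir(), survival_n = 20)
    fc <- funnel_config(top_k_response = 8)
    got <- run_funnel(fc, b$discovery, b$replication, b$response, b$panel,
                      b$expression)
    want <- oracle_funnel(b$discovery, b$replication, b$response, b$panel,
                          b$expression, k = 8)
    expect_identical(got$final, want)
  }
})

test_that("disjoint criterion sets give an empty final set but a full report", {
  cfg <- cohort_config(n_pairs = 4, n_genes = 20, noise_sd = 0,
                       delta_beta_effect = 0.5, planted_genes = "g0001",
                       background_beta = 0.3, seed = 2L)
  b <- simulate_bundle(cfg, plasma_sim_config(n_patients = 5, seed = 1L),
                       out_dir = withr::local_tempdir(), survival_n = 20,
                       panel_background_beta = 0.3)
  # panel background 0.3 fails the normal-low criterion for every gene
  rep <- run_funnel(funnel_config(top_k_response = 5), b$discovery,
                    b$replication, b$response, b$panel, b$expression)
  expect_length(rep$final, 0)
  expect_length(rep$counts, 5)
})
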