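test_that("interactome generation is deterministic and plants a dense module", {
  g1 <- generate_interactome(n_nodes = 200, n_seeds = 10, seed = 101)
  g2 <- generate_interactome(n_nodes = 200, n_seeds = 10, seed = 101)
  expect_identical(interactome_edges(g1$net), interactome_edges(g2$net))
  expect_identical(g1$truth, g2$truth)
  expect_true(all(g1$truth$seeds %in% g1$truth$planted_module))

  # module internal density clearly above background
  e <- interactome_edges(g1$net)
  mod <- g1$truth$planted_module
  in_mod <- e$from %in% mod & e$to %in% mod
  dens_mod <- sum(in_mod) / choose(length(mod), 2)
  dens_bg <- sum(!in_mod) / (choose(200, 2) - choose(length(mod), 2))
  expect_gt(dens_mod, dens_bg)

  # scale-free topology is heavy-tailed: hub degree far above the median
  deg <- interactome_degree(g1$net)
  expect_gt(max(deg), 5 * stats::median(deg))
})

test_that("degenerate generator parameters are rejected", {
  expect_error(generate_interactome(n_nodes = 30), "at least 50")
  expect_error(generate_interactome(n_seeds = 40, module_size = 30), "exceed")
  # p = 0 Erdos-Renyi yields an edgeless table the loader refuses
  expect_error(generate_interactome(topology = "erdos_renyi", er_p = 0, seed = 1))
})

test_that("expression generation is deterministic with exact mean-aggregated profiles", {
  genes <- sprintf("G%03d", 1:80)
  e1 <- generate_expression_data(genes, n_drugs = 10, n_reversers = 2,
                                 rho_targets = c(-0.5, -0.8), seed = 103)
  e2 <- generate_expression_data(genes, n_drugs = 10, n_reversers = 2,
                                 rho_targets = c(-0.5, -0.8), seed = 103)
  expect_identical(e1$signatures$values, e2$signatures$values)
  expect_identical(e1$tissue_table, e2$tissue_table)
  expect_error(generate_expression_data(genes, n_reversers = 1, rho_targets = -1),
               "< 1")

  # row-centred replicate noise: mean aggregation has zero replicate variance
  sig <- e1$signatures
  d <- signature_drugs(sig)[1]
  sel <- sig$col_meta$pert_iname == d
  expect_equal(ncol(sig$values[, sel]), 3)
  expect_gt(stats::sd(sig$values[1, sel]), 0)  # replicates do differ...
  prof <- aggregate_drug_signatures(sig, d)
  expect_equal(prof$z, rowMeans(sig$values[, sel]))  # ...but the mean is exact
})

test_that("a monotone-decreasing profile comes out of rho_target near -1 with no noise", {
  genes <- sprintf("G%02d", 1:40)
  e <- generate_expression_data(genes, n_drugs = 1, n_reversers = 1,
                                rho_targets = -0.999, sparsity = 0, noise_sd = 1e-9,
                                n_replicates = 1, replicate_noise_sd = 0, seed = 105)
  drug <- names(e$truth$reverser_drugs)
  prof <- aggregate_drug_signatures(e$signatures, drug)
  disease <- aggregate_disease_tissues(e$tissue_table)
  expect_lt(spearman_cor(prof$z[names(disease$z)], disease$z)$rho, -0.95)
})

test_that("tissue-model sparsity yields the planted coverage", {
  genes <- sprintf("G%03d", 1:323)
  e <- generate_expression_data(genes, n_drugs = 5, n_reversers = 0,
                                rho_targets = numeric(0), sparsity = 0.35, seed = 107)
  covered <- unique(e$tissue_table$gene)
  expect_setequal(covered, e$truth$covered_genes)
  # binomial band around the expected 65% coverage
  expect_gt(length(covered), 323 * 0.65 - 3 * sqrt(323 * 0.35 * 0.65))
  expect_lt(length(covered), 323 * 0.65 + 3 * sqrt(323 * 0.35 * 0.65))
  profile <- aggregate_disease_tissues(e$tissue_table)
  expect_length(profile$z, length(covered))
})

test_that("copula calibration: planted rho is recovered on average, nulls center at zero", {
  genes <- sprintf("G%02d", 1:60)
  rho_hat <- numeric(500)
  null_hat <- numeric(500)
  for (i in 1:500) {
    e <- generate_expression_data(genes, n_drugs = 2, n_reversers = 1,
                                  rho_targets = -0.5, sparsity = 0, n_tissues = 3,
                                  n_replicates = 1, seed = 5000 + i)
    disease <- aggregate_disease_tissues(e$tissue_table)
    rev_prof <- aggregate_drug_signatures(e$signatures, names(e$truth$reverser_drugs))
    null_prof <- aggregate_drug_signatures(e$signatures, e$truth$null_drugs[1])
    g <- names(disease$z)
    rho_hat[i] <- spearman_cor(rev_prof$z[g], disease$z[g])$rho
    null_hat[i] <- spearman_cor(null_prof$z[g], disease$z[g])$rho
  }
  expect_gt(mean(rho_hat), -0.58)
  expect_lt(mean(rho_hat), -0.42)
  expect_lt(abs(mean(null_hat)), 0.05)
})

test_that("generated LD matrices are PSD and single-variant models pass z through", {
  beta <- stats::setNames(c(0.5, -1, 2), c("GA", "GB", "GC"))
  tw <- generate_twas_inputs(beta, n_variants_per_gene = 4, seed = 109)
  for (g in names(tw$ld)) {
    expect_gte(min(eigen(tw$ld[[g]], symmetric = TRUE)$values), -1e-10)
    expect_equal(unname(diag(tw$ld[[g]])), rep(1, 4), tolerance = 1e-12)
  }
  tw1 <- generate_twas_inputs(beta, n_variants_per_gene = 1, seed = 111)
  res <- impute_all(tw1$models, tw1$gwas, tw1$ld)$table
  for (i in seq_len(nrow(res))) {
    m <- tw1$models[[i]]
    expect_equal(res$zscore[i],
                 sign(m$weights[[1]]) * tw1$gwas[[names(m$weights)]],
                 tolerance = 1e-12)
  }
})
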