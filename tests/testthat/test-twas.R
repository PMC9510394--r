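test_that("imputed z-score matches hand-evaluated forms of the statistic", {
  # single variant, unit variance: statistic reduces to the GWAS z itself
  expect_equal(
    impute_gene_zscore(c(v1 = 1), c(v1 = 2.5), matrix(1, dimnames = list("v1", "v1"))),
    2.5
  )
  # antisymmetric cancellation with identity LD
  g2 <- diag(2); dimnames(g2) <- list(c("a", "b"), c("a", "b"))
  expect_equal(impute_gene_zscore(c(a = 1, b = 1), c(a = 1, b = -1), g2), 0)
  # general case evaluated by hand:
  # num = 0.5*1*2 + 0.25*0.8*1 = 1.2 ; sigma_g^2 = w'Gw = 0.365
  gm <- matrix(c(1, 0.3, 0.3, 0.64), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(impute_gene_zscore(c(a = 0.5, b = 0.25), c(a = 2, b = 1), gm),
               1.2 / sqrt(0.365), tolerance = 1e-12)
})

test_that("identity LD with equal weights gives the sum / sqrt(n) closed form", {
  withr::with_seed(71, {
    for (n in c(3, 7, 15)) {
      vars <- sprintf("v%d", 1:n)
      g <- diag(n); dimnames(g) <- list(vars, vars)
      z <- stats::rnorm(n); names(z) <- vars
      w <- rep(0.4, n); names(w) <- vars
      expect_equal(impute_gene_zscore(w, z, g), sum(z) / sqrt(n), tolerance = 1e-12)
    }
  })
})

test_that("the statistic is invariant to positive rescaling of the weights", {
  withr::with_seed(73, {
    vars <- sprintf("v%d", 1:6)
    A <- matrix(stats::rnorm(72), 12, 6)
    g <- stats::cov2cor(crossprod(A) / 12); dimnames(g) <- list(vars, vars)
    w <- stats::setNames(stats::rnorm(6), vars)
    z <- stats::setNames(stats::rnorm(6), vars)
    base <- impute_gene_zscore(w, z, g)
    for (c0 in c(0.01, 3, 1e4)) {
      expect_equal(impute_gene_zscore(c0 * w, z, g), base, tolerance = 1e-9)
    }
  })
})

test_that("variants missing from the GWAS are dropped with the sub-matrix recomputed", {
  vars <- c("a", "b", "c")
  g <- matrix(c(1, .2, .1, .2, 1, .3, .1, .3, 1), 3, 3, dimnames = list(vars, vars))
  w <- c(a = 1, b = 2, c = 3)
  z_full <- c(a = 0.5, b = -1, c = 2)
  full <- impute_gene_zscore(w, z_full, g)
  partial <- NULL
  expect_warning(partial <- impute_gene_zscore(w, z_full[c("a", "b")], g), "dropped")
  # equals imputing with the sub-model directly
  direct <- impute_gene_zscore(w[c("a", "b")], z_full[c("a", "b")],
                               g[c("a", "b"), c("a", "b")])
  expect_equal(partial, direct)
  expect_false(isTRUE(all.equal(partial, full)))

  none <- suppressWarnings(impute_gene_zscore(w, c(zz = 1), g))
  expect_true(is.na(none))
  expect_match(attr(none, "reason"), "no model variant")
})

test_that("degenerate models (sigma_g = 0) are flagged, not computed", {
  vars <- c("a", "b")
  g <- matrix(1, 2, 2, dimnames = list(vars, vars))  # perfectly correlated pair
  res <- impute_gene_zscore(c(a = 1, b = -1), c(a = 1, b = 2), g)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "degenerate")
})

test_that("impute_all records per-model failures instead of raising them", {
  g_ok <- diag(2); dimnames(g_ok) <- list(c("x1", "x2"), c("x1", "x2"))
  g_bad <- matrix(1, 2, 2, dimnames = list(c("y1", "y2"), c("y1", "y2")))
  models <- list(
    list(gene = "GA", tissue = "t1", weights = c(x1 = 1, x2 = 1)),
    list(gene = "GA", tissue = "t2", weights = c(x1 = 2, x2 = 1)),
    list(gene = "GB", tissue = "t1", weights = c(y1 = 1, y2 = -1)),
    list(gene = "GB", tissue = "t2", weights = c(y1 = 1, y2 = -1))
  )
  gwas <- c(x1 = 1, x2 = 2, y1 = 0.5, y2 = 1)
  res <- suppressMessages(impute_all(models, gwas, list(GA = g_ok, GB = g_bad)))
  expect_equal(nrow(res$table), 2)
  expect_equal(unique(res$table$gene), "GA")
  expect_equal(nrow(res$skipped), 2)
  expect_match(res$skipped$reason[1], "degenerate")
})

test_that("planted expression effects are recovered across 200 genes", {
  withr::with_seed(77, {
    beta <- stats::setNames(stats::rnorm(200), sprintf("G%03d", 1:200))
    tw <- generate_twas_inputs(beta, seed = 770)
    res <- impute_all(tw$models, tw$gwas, tw$ld)
    z <- stats::setNames(res$table$zscore, res$table$gene)
    common <- intersect(names(z), names(beta))
    expect_gt(length(common), 190)
    expect_gt(stats::cor(beta[common], z[common], method = "spearman"), 0.8)
    expect_gt(mean(sign(beta[common]) == sign(z[common])), 0.9)
  })
})

test_that("twas text inputs round-trip through the readers", {
  d <- withr::local_tempdir()
  beta <- stats::setNames(c(1, -2), c("GA", "GB"))
  tw <- generate_twas_inputs(beta, n_variants_per_gene = 3, seed = 79)
  wt <- do.call(rbind, lapply(tw$models, function(m) {
    data.frame(gene = m$gene, tissue = m$tissue, variant_id = names(m$weights),
               weight = m$weights)
  }))
  write.table(wt, file.path(d, "w.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ldt <- do.call(rbind, lapply(names(tw$ld), function(g) {
    gm <- tw$ld[[g]]
    idx <- which(upper.tri(gm, diag = TRUE), arr.ind = TRUE)
    data.frame(gene = g, var_i = rownames(gm)[idx[, 1]],
               var_j = colnames(gm)[idx[, 2]], cov = gm[idx])
  }))
  write.table(ldt, file.path(d, "ld.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(variant_id = names(tw$gwas), zscore = tw$gwas),
              file.path(d, "g.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_twas_inputs(file.path(d, "w.tsv"), file.path(d, "ld.tsv"),
                           file.path(d, "g.tsv"))
  r1 <- impute_all(tw$models, tw$gwas, tw$ld)$table
  r2 <- impute_all(back$models, back$gwas, back$ld)$table
  r1 <- r1[order(r1$gene, r1$tissue), ]
  r2 <- r2[order(r2$gene, r2$tissue), ]
  expect_equal(r2$zscore, r1$zscore, tolerance = 1e-9)
})
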