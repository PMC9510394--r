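test_that("spearman matches hand-ranked values on the canonical examples", {
  # perfect anti-correlation
  x <- c(0.2, 1.1, 3, 4.5, 9)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # hand-ranked Pearson-of-ranks: rho = 0.6
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6, tolerance = 1e-12)
  # ties: mid-ranks x = (1.5, 1.5, 3), y = (1, 2, 3) give rho = 1.5/sqrt(1.5*2)
  expect_equal(spearman_cor(c(1, 1, 2), c(1, 2, 3))$rho, 1.5 / sqrt(3),
               tolerance = 1e-12)
})

test_that("spearman equals the explicit mid-rank oracle and cor.test on random data", {
  withr::with_seed(81, {
    for (rep in 1:40) {
      n <- sample(4:60, 1)
      x <- stats::rnorm(n)
      y <- stats::rnorm(n)
      if (rep %% 2 == 0) {  # inject ties
        x <- round(x, 1)
        y <- round(y, 1)
        if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) next
      }
      got <- spearman_cor(x, y)
      expect_equal(got$rho, spearman_oracle(x, y), tolerance = 1e-12)
      ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    }
  })
})

test_that("spearman is antisymmetric in y when y has no ties", {
  withr::with_seed(83, {
    for (rep in 1:10) {
      x <- stats::rnorm(20)
      y <- stats::rnorm(20)
      expect_equal(spearman_cor(x, -y)$rho, -spearman_cor(x, y)$rho, tolerance = 1e-12)
    }
  })
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  expect_error(spearman_cor(1:4, 1:3), "equal length")
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "zero rank variance")
  expect_error(spearman_cor(c(1, NA, 3), 1:3), "finite")
})

test_that("permutation p-values are reproducible, small for strong signal, uniform under the null", {
  x <- c(3, 1, 7, 2, 9, 4, 8, 5)
  p_strong <- permutation_p(x, -x, n_perm = 10000, seed = 85)
  expect_lte(p_strong, 0.001)
  expect_equal(permutation_p(x, -x, n_perm = 500, seed = 7),
               permutation_p(x, -x, n_perm = 500, seed = 7))
  expect_error(permutation_p(x, -x, n_perm = 50), "at least 100")

  withr::with_seed(87, {
    ps <- replicate(300, {
      permutation_p(stats::rnorm(20), stats::rnorm(20), n_perm = 199)
    })
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  })
})

test_that("a perfect planted reverser ranks first among noise drugs", {
  withr::with_seed(89, {
    genes <- sprintf("G%02d", 1:50)
    disease <- make_profile(stats::setNames(stats::rnorm(50), genes))
    profs <- c(
      list(make_profile(-disease$z, owner = "reverser")),
      lapply(sprintf("noise%02d", 1:20), function(d) {
        make_profile(stats::setNames(stats::rnorm(50), genes), owner = d)
      })
    )
    sc <- score_all_drugs(profs, disease, genes)
    expect_equal(sc$drug[1], "reverser")
    expect_equal(sc$rho[1], -1)
    expect_true(sc$candidate[1])
    expect_true(all(diff(sc$rho) >= 0))  # sorted ascending
  })
})

test_that("drugs sharing too few genes are skipped with a warning", {
  genes <- sprintf("G%d", 1:10)
  disease <- make_profile(stats::setNames(stats::rnorm(10), genes))
  small <- make_profile(c(G1 = 1, G2 = -1), owner = "tiny")
  ok <- make_profile(stats::setNames(stats::rnorm(10), genes), owner = "full")
  sc <- NULL
  expect_warning(sc <- score_all_drugs(list(small, ok), disease, genes), "tiny")
  expect_equal(sc$drug, "full")
  expect_error(suppressWarnings(score_all_drugs(list(small), disease, genes)),
               "no drug could be scored")
})

test_that("candidate, suggestive and risk flags follow the thresholds", {
  withr::with_seed(91, {
    genes <- sprintf("G%02d", 1:40)
    z <- stats::setNames(stats::rnorm(40), genes)
    disease <- make_profile(z)
    profs <- list(
      make_profile(-z, owner = "anti"),
      make_profile(z, owner = "mimic"),
      make_profile(stats::setNames(stats::rnorm(40), genes), owner = "null")
    )
    sc <- score_all_drugs(profs, disease, genes)
    sc <- sc[match(c("anti", "mimic", "null"), sc$drug), ]
    expect_true(sc$candidate[1] && !sc$flagged_risk[1])
    expect_true(sc$flagged_risk[2] && !sc$candidate[2])
    expect_true(all(sc$candidate == (sc$rho < 0 & sc$p_value < 0.05)))
    expect_true(all(sc$flagged_risk == (sc$rho > 0 & sc$p_value < 0.05)))
    expect_true(all(sc$p_value <= sc$bh_fdr + 1e-15))
    # candidates are a subset of suggestives
    expect_true(all(!sc$candidate | sc$suggestive))
  })
})

test_that("drug_targets scope restricts the correlated gene set per drug", {
  withr::with_seed(93, {
    genes <- sprintf("G%02d", 1:30)
    z <- stats::setNames(stats::rnorm(30), genes)
    disease <- make_profile(z)
    prof <- make_profile(stats::setNames(stats::rnorm(30), genes), owner = "d1")
    tmap <- structure(list(targets = list(d1 = genes[1:10]), genes_covered = genes[1:10]),
                      class = "drug_target_map")
    sc_all <- score_all_drugs(list(prof), disease, genes, targets = tmap)
    sc_tgt <- score_all_drugs(list(prof), disease, genes, gene_scope = "drug_targets",
                              targets = tmap)
    expect_equal(sc_all$n_genes, 30)
    expect_equal(sc_tgt$n_genes, 10)
    expect_equal(sc_tgt$rho, spearman_cor(prof$z[genes[1:10]], z[genes[1:10]])$rho)
    expect_error(score_all_drugs(list(prof), disease, genes, gene_scope = "drug_targets"),
                 "requires")
  })
})
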