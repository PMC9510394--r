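#' Generate a synthetic interactome with a planted disease module
#'
#' Draws a reduced-scale interactome emulating the heavy-tailed degree
#' structure of genome-scale PPI networks (preferential attachment by
#' default, Erdos-Renyi as an alternative), then plants a dense module —
#' extra edges among a designated gene set at `module_density` — and
#' chooses the disease seed genes inside that module. The generated graph
#' must keep at least 90% of nodes in its largest component.
#'
#' @param n_nodes number of genes (>= 50).
#' @param topology "scale_free" (preferential attachment, `pa_m` edges per
#'   new node) or "erdos_renyi" (edge probability `er_p`).
#' @param n_seeds number of seed genes (<= `module_size`).
#' @param module_size size of the planted dense module.
#' @param module_density internal edge probability of the module.
#' @param pa_m,er_p topology parameters.
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return list with `net` (an `interactome`) and `truth` (seed, module
#'   genes, seed genes).
#' @export
generate_interactome <- function(n_nodes = 500, topology = c("scale_free", "erdos_renyi"),
                                 n_seeds = 20, module_size = 30, module_density = 0.3,
                                 pa_m = 3, er_p = 0.02, seed = 1) {
  topology <- match.arg(topology)
  if (n_nodes < 50) stop("n_nodes must be at least 50", call. = FALSE)
  if (n_seeds > module_size) stop("n_seeds cannot exceed module_size", call. = FALSE)
  if (module_size > n_nodes) stop("module_size cannot exceed n_nodes", call. = FALSE)
  withr::with_seed(seed, {
    g <- switch(topology,
      scale_free = igraph::sample_pa(n_nodes, m = pa_m, directed = FALSE),
      erdos_renyi = igraph::sample_gnp(n_nodes, er_p)
    )
    syms <- sprintf("G%05d", seq_len(n_nodes))
    igraph::V(g)$name <- syms
    e <- igraph::as_data_frame(g, what = "edges")
    module <- sort(sample(syms, module_size))
    pairs <- utils::combn(module, 2)
    add <- stats::runif(ncol(pairs)) < module_density
    e <- rbind(e, data.frame(from = pairs[1, add], to = pairs[2, add],
                             stringsAsFactors = FALSE))
    net <- suppressMessages(load_interactome(e))
    comp <- igraph::components(net$graph)
    if (max(comp$csize) < 0.9 * n_nodes) {
      stop("infeasible parameters: largest component below 90% of nodes", call. = FALSE)
    }
    seeds <- sort(sample(module, n_seeds))
    list(net = net, truth = list(seed = seed, planted_module = module, seeds = seeds))
  })
}

#' Generate ground-truthed drug signatures and disease tissue z-scores
#'
#' Emulates (i) a Level-5-style drug signature matrix over the disease
#' network genes, with `n_reversers` planted reverser drugs, and (ii) a
#' sparse 13-tissue-style table of disease-association z-scores. The
#' disease has a per-gene true effect `beta ~ N(0,1)`; tissue z-scores are
#' `beta` plus Gaussian tissue noise, and a `sparsity` fraction of genes
#' lack a model in every tissue. Reverser profiles are built by a Gaussian
#' copula against the (mean-aggregated) disease profile so that the planted
#' quantity is exactly the population Spearman correlation `rho_target`
#' (the Pearson latent correlation used is `2 sin(pi rho / 6)`); replicate
#' columns add row-centred noise, so mean aggregation returns the planted
#' vector exactly. Null drugs are independent noise.
#'
#' @param network_genes character vector of disease-network genes.
#' @param n_drugs total drugs with signatures.
#' @param n_reversers number of planted reversers (<= n_drugs).
#' @param rho_targets vector of planted Spearman correlations, length
#'   `n_reversers`, each in (-1, 1).
#' @param n_tissues number of tissues.
#' @param noise_sd tissue-level noise standard deviation.
#' @param sparsity fraction of genes with no tissue model (default 0.35,
#'   approximating the ~64% imputation coverage seen on real brain-tissue
#'   panels).
#' @param tissue_presence per-tissue model probability for covered genes.
#' @param n_replicates signature columns per drug.
#' @param replicate_noise_sd replicate noise (row-centred).
#' @param seed integer RNG seed.
#' @return list with `signatures` (a `signature_matrix`), `tissue_table`
#'   (data.frame gene, tissue, zscore) and `truth` (disease_effect,
#'   reverser_drugs named by planted rho, null_drugs, covered_genes,
#'   covered_tissues, seed).
#' @export
generate_expression_data <- function(network_genes, n_drugs = 100, n_reversers = 4,
                                     rho_targets = rep(-0.5, n_reversers),
                                     n_tissues = 13, noise_sd = 0.5, sparsity = 0.35,
                                     tissue_presence = 0.7, n_replicates = 3,
                                     replicate_noise_sd = 0.3, seed = 1) {
  network_genes <- normalize_symbols(network_genes, context = "network genes")
  if (n_reversers > n_drugs) stop("n_reversers cannot exceed n_drugs", call. = FALSE)
  if (length(rho_targets) != n_reversers) {
    stop("rho_targets must have one value per reverser", call. = FALSE)
  }
  if (any(abs(rho_targets) >= 1)) stop("planted |rho| must be < 1", call. = FALSE)
  withr::with_seed(seed, {
    genes <- sort(unique(network_genes))
    n_genes <- length(genes)
    beta <- stats::setNames(stats::rnorm(n_genes), genes)

    covered <- genes[stats::runif(n_genes) >= sparsity]
    if (length(covered) < 3) {
      stop("infeasible parameters: fewer than 3 genes with a tissue model", call. = FALSE)
    }
    tissues <- sprintf("tissue%02d", seq_len(n_tissues))
    covered_tissues <- lapply(stats::setNames(covered, covered), function(g) {
      pres <- tissues[stats::runif(n_tissues) < tissue_presence]
      if (length(pres) == 0) pres <- sample(tissues, 1)
      pres
    })
    tissue_table <- do.call(rbind, lapply(covered, function(g) {
      tt <- covered_tissues[[g]]
      data.frame(gene = g, tissue = tt,
                 zscore = beta[[g]] + stats::rnorm(length(tt), sd = noise_sd),
                 stringsAsFactors = FALSE)
    }))
    rownames(tissue_table) <- NULL
    d <- tapply(tissue_table$zscore, tissue_table$gene, mean)[covered]

    drugs <- sprintf("drug%03d", seq_len(n_drugs))
    reversers <- sort(sample(drugs, n_reversers))
    rho_map <- stats::setNames(rho_targets, reversers)
    u <- stats::qnorm((rank(d) - 0.5) / length(d))
    profile_of <- function(drug) {
      z <- stats::rnorm(n_genes)
      names(z) <- genes
      if (drug %in% reversers) {
        r <- 2 * sin(pi * rho_map[[drug]] / 6)
        z[covered] <- r * u + sqrt(1 - r^2) * stats::rnorm(length(covered))
      }
      z
    }
    cols <- list()
    meta <- list()
    for (drug in drugs) {
      base <- profile_of(drug)
      eps <- matrix(stats::rnorm(n_genes * n_replicates, sd = replicate_noise_sd),
                    n_genes, n_replicates)
      eps <- eps - rowMeans(eps)  # mean aggregation recovers `base` exactly
      for (r in seq_len(n_replicates)) {
        id <- sprintf("%s_rep%d", drug, r)
        cols[[id]] <- base + eps[, r]
        meta[[id]] <- drug
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    sig <- signature_matrix(values, unlist(meta, use.names = FALSE))
    list(
      signatures = sig,
      tissue_table = tissue_table,
      truth = list(
        seed = seed,
        disease_effect = beta,
        reverser_drugs = rho_map,
        null_drugs = setdiff(drugs, reversers),
        covered_genes = covered,
        covered_tissues = covered_tissues
      )
    )
  })
}

#' Generate synthetic TWAS inputs with a planted expression effect
#'
#' Builds, per gene, a variant set with a random positive-semidefinite LD
#' correlation matrix (`cov2cor(A'A)`), per-tissue elastic-net-style
#' weights jittered around a shared base vector, and GWAS z-scores
#' constructed so that genes with large true effects `beta` receive large
#' imputed `Z_g` of matching sign in expectation:
#' `Z_l = effect_scale * beta_g * w_l + N(0, gwas_noise_sd)`.
#'
#' @param disease_effect named numeric vector of true per-gene effects.
#' @param covered_tissues named list gene -> tissue labels with a model;
#'   by default every gene gets a single "tissue01" model.
#' @param n_variants_per_gene variants per gene (>= 1).
#' @param effect_scale GWAS signal scale.
#' @param gwas_noise_sd GWAS noise standard deviation.
#' @param weight_jitter_sd tissue-level jitter around the base weights.
#' @param seed integer RNG seed.
#' @return list with `models`, `ld`, `gwas` (see [impute_all()]).
#' @export
generate_twas_inputs <- function(disease_effect, covered_tissues = NULL,
                                 n_variants_per_gene = 5, effect_scale = 3,
                                 gwas_noise_sd = 1, weight_jitter_sd = 0.3, seed = 1) {
  if (n_variants_per_gene < 1) stop("n_variants_per_gene must be >= 1", call. = FALSE)
  genes <- names(disease_effect)
  if (is.null(covered_tissues)) {
    covered_tissues <- lapply(stats::setNames(genes, genes), function(g) "tissue01")
  }
  withr::with_seed(seed, {
    models <- list()
    ld <- list()
    gwas <- numeric(0)
    m <- n_variants_per_gene
    for (g in genes) {
      vars <- sprintf("%s_v%d", g, seq_len(m))
      A <- matrix(stats::rnorm(2 * m * m), 2 * m, m)
      gamma <- stats::cov2cor(crossprod(A) / (2 * m))
      dimnames(gamma) <- list(vars, vars)
      ld[[g]] <- gamma
      w_base <- stats::rnorm(m)
      z <- effect_scale * disease_effect[[g]] * w_base +
        stats::rnorm(m, sd = gwas_noise_sd)
      gwas[vars] <- z
      for (tt in covered_tissues[[g]]) {
        w <- w_base + stats::rnorm(m, sd = weight_jitter_sd)
        models[[length(models) + 1L]] <- list(
          gene = g, tissue = tt,
          weights = stats::setNames(w, vars)
        )
      }
    }
    list(models = models, ld = ld, gwas = gwas)
  })
}
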