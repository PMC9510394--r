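#' Simulate a complete ground-truthed study on disk
#'
#' Generates every input the pipeline reads — interactome edge list, two
#' overlapping seed-gene source lists, a DGIdb-style drug interaction
#' table, a GCT signature matrix with planted reverser drugs, a sparse
#' tissue z-score table, TWAS weight/LD/GWAS tables — plus a truth manifest
#' and a ready-to-run `config.yaml`, all under `out_dir`. The default
#' scenario is a 500-node scale-free interactome with 20 seeds in a planted
#' module, 100 signature drugs of which 4 are reversers at Spearman
#' rho = -0.5, 13 tissues at 35% model sparsity. The disease network is
#' taken as the top 20% of non-seed diffusion ranks: on a 500-node graph
#' this yields a network whose absolute size (and hence correlation sample
#' size) matches the regime the method is used in at full scale, which the
#' paper-scale top-1% rule would not at this reduced node count.
#'
#' Extra drugs beyond the `n_drugs` signature drugs are planted to
#' exercise every filter: approved drugs targeting genes outside the
#' network, non-approved drugs, and approved network-targeting drugs
#' without a signature.
#'
#' @param out_dir output directory (created if needed).
#' @param n_nodes,topology,n_seeds,module_size,module_density,pa_m see
#'   [generate_interactome()].
#' @param diffusion_time,top_fraction network construction parameters.
#' @param n_drugs,n_reversers,rho_target,n_tissues,sparsity,noise_sd,n_replicates
#'   see [generate_expression_data()] (`rho_target` is recycled).
#' @param n_extra_drugs drugs added only to the interaction table.
#' @param alpha,alpha_suggestive significance thresholds for the config.
#' @param seed master integer seed; every sub-generator uses a seed derived
#'   from it, so two runs are byte-identical.
#' @return invisibly, a list with `config` (path), `truth`, and `paths`.
#' @export
simulate_study <- function(out_dir,
                           n_nodes = 500, topology = "scale_free", n_seeds = 20,
                           module_size = 30, module_density = 0.3, pa_m = 3,
                           diffusion_time = 0.1, top_fraction = 0.2,
                           n_drugs = 100, n_reversers = 4, rho_target = -0.5,
                           n_tissues = 13, sparsity = 0.35, noise_sd = 0.5,
                           n_replicates = 3, n_extra_drugs = 30,
                           alpha = 0.05, alpha_suggestive = 0.1, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  gi <- generate_interactome(n_nodes = n_nodes, topology = topology,
                             n_seeds = n_seeds, module_size = module_size,
                             module_density = module_density, pa_m = pa_m,
                             seed = seed)
  write_interactome(gi$net, p("interactome.tsv"))

  # two overlapping source lists, exercising merge + provenance
  seeds <- gi$truth$seeds
  k <- length(seeds)
  l1 <- seeds[seq_len(ceiling(0.65 * k))]
  l2 <- seeds[floor(0.45 * k):k]
  writeLines(c("# source list 1", l1), p("genes_gwas.txt"))
  writeLines(c("# source list 2", l2), p("genes_exome.txt"))

  diff <- suppressMessages(diffuse(gi$net, seeds, t = diffusion_time))
  dn <- select_top_fraction(diff, top_fraction)

  expr <- generate_expression_data(
    network_genes = dn$members, n_drugs = n_drugs, n_reversers = n_reversers,
    rho_targets = rep(rho_target, n_reversers), n_tissues = n_tissues,
    noise_sd = noise_sd, sparsity = sparsity, n_replicates = n_replicates,
    seed = seed + 1L
  )
  write_gct(expr$signatures, p("signatures.gct"))
  utils::write.table(expr$tissue_table, p("tissue_zscores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # drug-gene interaction table with planted filter cases
  drug_table <- withr::with_seed(seed + 2L, {
    sig_drugs <- signature_drugs(expr$signatures)
    rows <- lapply(sig_drugs, function(d) {
      data.frame(drug_name = d,
                 gene_name = sample(dn$members, sample(1:3, 1)),
                 approval_status = "approved", stringsAsFactors = FALSE)
    })
    outside <- setdiff(interactome_nodes(gi$net), dn$members)
    n3 <- max(1L, n_extra_drugs %/% 3L)
    extra <- list(
      data.frame(drug_name = sprintf("offnet%02d", seq_len(n3)),
                 gene_name = sample(outside, n3, replace = TRUE),
                 approval_status = "approved", stringsAsFactors = FALSE),
      data.frame(drug_name = sprintf("unapproved%02d", seq_len(n3)),
                 gene_name = sample(dn$members, n3, replace = TRUE),
                 approval_status = "investigational", stringsAsFactors = FALSE),
      data.frame(drug_name = sprintf("nosig%02d", seq_len(n3)),
                 gene_name = sample(dn$members, n3, replace = TRUE),
                 approval_status = "approved", stringsAsFactors = FALSE)
    )
    do.call(rbind, c(rows, extra))
  })
  utils::write.table(drug_table, p("drug_interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  twas <- generate_twas_inputs(expr$truth$disease_effect[expr$truth$covered_genes],
                               covered_tissues = expr$truth$covered_tissues,
                               seed = seed + 3L)
  wt <- do.call(rbind, lapply(twas$models, function(m) {
    data.frame(gene = m$gene, tissue = m$tissue, variant_id = names(m$weights),
               weight = m$weights, stringsAsFactors = FALSE)
  }))
  utils::write.table(wt, p("twas_weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ldt <- do.call(rbind, lapply(names(twas$ld), function(g) {
    gm <- twas$ld[[g]]
    idx <- which(upper.tri(gm, diag = TRUE), arr.ind = TRUE)
    data.frame(gene = g, var_i = rownames(gm)[idx[, 1]], var_j = colnames(gm)[idx[, 2]],
               cov = gm[idx], stringsAsFactors = FALSE)
  }))
  utils::write.table(ldt, p("twas_ld.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variant_id = names(twas$gwas), zscore = twas$gwas),
                     p("twas_gwas.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = seed,
    planted_module = gi$truth$planted_module,
    seeds = gi$truth$seeds,
    network_members = dn$members,
    reverser_drugs = as.list(expr$truth$reverser_drugs),
    null_drugs = expr$truth$null_drugs,
    covered_genes = expr$truth$covered_genes
  )
  yaml::write_yaml(truth, p("truth.yaml"))

  config <- list(
    seed = seed,
    out_dir = "results",
    inputs = list(
      interactome = "interactome.tsv",
      gene_lists = list(gwas = "genes_gwas.txt", exome = "genes_exome.txt"),
      drug_interactions = "drug_interactions.tsv",
      signatures = "signatures.gct",
      tissue_zscores = "tissue_zscores.tsv"
    ),
    params = list(
      diffusion_time = diffusion_time, laplacian = "combinatorial",
      top_fraction = top_fraction, drug_aggregation = "mean",
      tissue_aggregation = "mean", gene_scope = "network_all",
      alpha = alpha, alpha_suggestive = alpha_suggestive
    )
  )
  yaml::write_yaml(config, p("config.yaml"))

  invisible(list(config = p("config.yaml"), truth = truth,
                 paths = stats::setNames(
                   file.path(out_dir, c("interactome.tsv", "signatures.gct",
                                        "tissue_zscores.tsv", "drug_interactions.tsv")),
                   c("interactome", "signatures", "tissue_zscores", "drug_interactions"))))
}

validate_pipeline_config <- function(cfg) {
  pr <- cfg$params
  if (is.null(pr)) stop("config validation: missing 'params' block", call. = FALSE)
  f <- pr$top_fraction
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f <= 0 || f > 1) {
    stop("config validation: top_fraction must be in (0, 1]", call. = FALSE)
  }
  tt <- pr$diffusion_time
  if (!is.numeric(tt) || length(tt) != 1 || is.na(tt) || tt <= 0) {
    stop("config validation: diffusion_time must be positive", call. = FALSE)
  }
  for (a in c("alpha", "alpha_suggestive")) {
    v <- pr[[a]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(sprintf("config validation: %s must be in (0, 1)", a), call. = FALSE)
    }
  }
  if (!pr$gene_scope %in% c("network_all", "drug_targets")) {
    stop("config validation: gene_scope must be network_all or drug_targets", call. = FALSE)
  }
  if (is.null(cfg$inputs)) stop("config validation: missing 'inputs' block", call. = FALSE)
  invisible(cfg)
}

#' Run the full repurposing pipeline from a config
#'
#' Orchestrates seed merging, interactome loading, diffusion, disease
#' network selection, drug-target mapping, signature aggregation, disease
#' profile construction (from a tissue z-score table, or imputed from TWAS
#' inputs when a `twas` block is given instead), and the reversal screen.
#' Parameters are validated before anything is read; any stage error
#' aborts with the stage name. Writes the network node/edge/SIF tables,
#' the ranked drug table and a JSON run report of per-stage counts into
#' `out_dir`, and is fully deterministic for a fixed config.
#'
#' @param config a config list or path to a YAML config (see the config
#'   written by [simulate_study()] for the schema); relative input paths
#'   are resolved against the config file's directory.
#' @return invisibly, a list with `report` (stage counts), `scores` (the
#'   ranked drug data.frame) and `network` (the `disease_network`).
#' @export
run_pipeline <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  rel <- function(path) {
    if (is.null(path) || grepl("^/", path)) path else file.path(base, path)
  }
  ins <- config$inputs
  pr <- config$params
  out_dir <- rel(if (is.null(config$out_dir)) "results" else config$out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  seeds <- stage("gene_sets", {
    lists <- lapply(ins$gene_lists, function(f) read_gene_list(rel(f)))
    merge_gene_lists(lists)
  })
  net <- stage("interactome", load_interactome(rel(ins$interactome)))
  mapping <- stage("gene_sets", suppressWarnings(map_to_interactome(seeds, net)))
  diff <- stage("propagation", diffuse(net, mapping$mapped, t = pr$diffusion_time,
                                       laplacian = pr$laplacian))
  dn <- stage("disease_network", select_top_fraction(diff, pr$top_fraction))

  sig <- stage("signatures", {
    f <- rel(ins$signatures)
    if (grepl("\\.gct$", f)) read_gct(f) else read_signature_tsv(f, rel(ins$signature_col_meta))
  })
  dmap <- stage("drug_interactions",
                build_drug_target_map(rel(ins$drug_interactions), dn))
  dmap_sig <- stage("drug_interactions", restrict_to_signatures(dmap, sig))

  disease <- stage("signatures", {
    if (!is.null(ins$tissue_zscores)) {
      tab <- read_tissue_zscores(rel(ins$tissue_zscores))
    } else if (!is.null(ins$twas)) {
      tw <- read_twas_inputs(rel(ins$twas$weights), rel(ins$twas$ld), rel(ins$twas$gwas))
      tab <- impute_all(tw$models, tw$gwas, tw$ld)$table
    } else {
      stop("config needs either tissue_zscores or a twas input block", call. = FALSE)
    }
    aggregate_disease_tissues(tab, method = pr$tissue_aggregation)
  })

  scores <- stage("reversal", {
    profiles <- lapply(names(dmap_sig$targets), function(d) {
      aggregate_drug_signatures(sig, d, method = pr$drug_aggregation)
    })
    suppressWarnings(score_all_drugs(
      profiles, disease, dn, gene_scope = pr$gene_scope, targets = dmap_sig,
      alpha = pr$alpha, alpha_suggestive = pr$alpha_suggestive,
      drug_aggregation = pr$drug_aggregation
    ))
  })

  write_disease_network(dn, file.path(out_dir, "network"))
  write_diffusion(diff, file.path(out_dir, "diffusion.tsv"))
  write_reversal_table(scores, file.path(out_dir, "drugs_ranked.tsv"))

  report <- list(
    seed_genes_merged = length(seeds$merged),
    seed_genes_mapped = length(mapping$mapped$merged),
    seed_genes_unmapped = length(mapping$unmapped),
    network_size = length(dn$members),
    network_related_genes = sum(!dn$is_seed),
    approved_drugs_in_network = length(dmap$targets),
    network_genes_with_drug = length(dmap$genes_covered),
    drugs_with_signatures = length(dmap_sig$targets),
    disease_profile_genes = length(disease$z),
    drugs_scored = nrow(scores),
    candidates = sum(scores$candidate),
    suggestive = sum(scores$suggestive),
    flagged_risk = sum(scores$flagged_risk),
    params = pr
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf(
    "pipeline: %d/%d seeds mapped; network %d genes; %d drugs scored; %d candidate(s) at alpha = %g",
    report$seed_genes_mapped, report$seed_genes_merged, report$network_size,
    report$drugs_scored, report$candidates, pr$alpha
  ))
  invisible(list(report = report, scores = scores, network = dn))
}
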