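#' Spearman rank correlation with two-sided t p-value
#'
#' Pearson correlation of mid-ranks (ties get average ranks), with the
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' p-values are clamped into `(0, 1]` so perfect correlations do not return
#' an exact zero.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, neither
#'   constant.
#' @return list with `rho`, `p_value`, `n`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("zero rank variance: correlation undefined for constant input", call. = FALSE)
  }
  rho <- max(-1, min(1, stats::cor(rx, ry)))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(rho = rho, p_value = p, n = n)
}

#' Permutation p-value for the Spearman correlation
#'
#' Exact-style two-sided permutation test: `y` is permuted `n_perm` times
#' and `p = (1 + #{|rho*| >= |rho_obs|}) / (1 + n_perm)`. Useful as a
#' small-n alternative to the t approximation; reproducible given `seed`.
#'
#' @inheritParams spearman_cor
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed; the global RNG state is preserved.
#' @return permutation p-value.
#' @export
permutation_p <- function(x, y, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  obs <- abs(spearman_cor(x, y)$rho)
  rx <- rank(x)
  ry <- rank(y)
  run <- function() {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      r <- abs(stats::cor(rx, sample(ry)))
      if (r >= obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Score all drugs for transcriptional reversal of the disease profile
#'
#' For each drug, computes the Spearman correlation between its aggregated
#' perturbation profile and the disease profile over the disease-network
#' genes present in both. Negative correlations mean the drug's induced
#' expression changes oppose the disease-associated changes (down-regulates
#' what the disease up-regulates and vice versa) — the reversal hypothesis.
#' Significant positive correlations are flagged as potential risk drugs.
#'
#' @param drug_profiles list of `perturbation_profile` objects (one per
#'   drug), or a `signature_matrix` (aggregated per drug with
#'   `drug_aggregation`).
#' @param disease a `perturbation_profile` for the disease.
#' @param network a `disease_network` or character vector of member genes.
#' @param gene_scope "network_all" (default; correlate over all network
#'   genes shared by both profiles) or "drug_targets" (restrict further to
#'   the drug's own targets in the network; requires `targets`).
#' @param targets optional `drug_target_map`, required for
#'   `gene_scope = "drug_targets"` and used to report each drug's
#'   interaction partners.
#' @param alpha significance level for candidate/risk flags (default 0.05).
#' @param alpha_suggestive suggestive level (default 0.1).
#' @param drug_aggregation method passed to [aggregate_drug_signatures()]
#'   when `drug_profiles` is a `signature_matrix`.
#' @param min_genes minimum shared genes to score a drug (default 3);
#'   drugs below are skipped with a warning.
#' @return data.frame sorted by `rho` ascending (most reversing first) with
#'   columns drug, rho, p_value, bh_fdr, n_genes, targets_in_network,
#'   candidate (rho < 0 & p < alpha), suggestive (rho < 0 & p <
#'   alpha_suggestive), flagged_risk (rho > 0 & p < alpha).
#' @export
score_all_drugs <- function(drug_profiles, disease, network,
                            gene_scope = c("network_all", "drug_targets"),
                            targets = NULL, alpha = 0.05, alpha_suggestive = 0.1,
                            drug_aggregation = c("mean", "max_abs"), min_genes = 3) {
  gene_scope <- match.arg(gene_scope)
  drug_aggregation <- match.arg(drug_aggregation)
  stopifnot(inherits(disease, "perturbation_profile"))
  if (inherits(drug_profiles, "signature_matrix")) {
    mat <- drug_profiles
    drug_profiles <- lapply(signature_drugs(mat), function(d) {
      aggregate_drug_signatures(mat, d, method = drug_aggregation)
    })
  }
  members <- if (inherits(network, "disease_network")) network$members else {
    normalize_symbols(network, context = "network members")
  }
  if (gene_scope == "drug_targets" && is.null(targets)) {
    stop("gene_scope 'drug_targets' requires a drug_target_map", call. = FALSE)
  }
  rows <- list()
  for (prof in drug_profiles) {
    stopifnot(inherits(prof, "perturbation_profile"))
    drug <- prof$owner
    tg <- if (!is.null(targets)) targets$targets[[drug]] else NULL
    genes <- intersect(intersect(names(prof$z), names(disease$z)), members)
    if (gene_scope == "drug_targets") genes <- intersect(genes, tg)
    if (length(genes) < min_genes) {
      warning(sprintf("drug '%s' shares only %d gene(s) with the disease profile; skipped",
                      drug, length(genes)), call. = FALSE)
      next
    }
    sc <- spearman_cor(prof$z[genes], disease$z[genes])
    rows[[drug]] <- data.frame(
      drug = drug, rho = sc$rho, p_value = sc$p_value, n_genes = sc$n,
      targets_in_network = paste(tg, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) stop("no drug could be scored", call. = FALSE)
  out <- do.call(rbind, rows)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$candidate <- out$rho < 0 & out$p_value < alpha
  out$suggestive <- out$rho < 0 & out$p_value < alpha_suggestive
  out$flagged_risk <- out$rho > 0 & out$p_value < alpha
  out <- out[order(out$rho, out$drug), c("drug", "rho", "p_value", "bh_fdr", "n_genes",
                                         "targets_in_network", "candidate", "suggestive",
                                         "flagged_risk")]
  rownames(out) <- NULL
  out
}

#' Write the ranked drug reversal table
#'
#' @param scores data.frame from [score_all_drugs()].
#' @param path output TSV.
#' @export
write_reversal_table <- function(scores, path) {
  df <- scores
  for (col in c("rho", "p_value", "bh_fdr")) df[[col]] <- sprintf("%.12g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
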