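#' Summary-statistics TWAS z-score for one gene model
#'
#' The S-PrediXcan statistic: with elastic-net expression weights `w_l`,
#' per-variant GWAS z-scores `Z_l`, and an LD (genotype covariance) matrix
#' `Gamma`,
#' \deqn{Z_g = \sum_l w_l \, \sigma_l \, Z_l \; / \; \sigma_g,}
#' where \eqn{\sigma_l = \sqrt{\Gamma_{ll}}} and
#' \eqn{\sigma_g = \sqrt{w^\top \Gamma w}}. The statistic is invariant to
#' rescaling all weights by a positive constant. Variants missing from the
#' GWAS are dropped from both the weights and the LD sub-matrix (with a
#' warning) and \eqn{\sigma_g} recomputed. Allele harmonization is assumed
#' done upstream: z-scores must already be signed on a consistent effect
#' allele.
#'
#' @param weights named numeric vector of per-variant expression weights
#'   (at least one nonzero).
#' @param gwas named numeric vector of per-variant GWAS z-scores.
#' @param ld symmetric PSD covariance matrix with variant dimnames covering
#'   all model variants.
#' @return the imputed association z-score; `NA` with attribute `reason`
#'   when the gene is degenerate (`sigma_g = 0`) or no model variant has a
#'   GWAS z-score.
#' @export
impute_gene_zscore <- function(weights, gwas, ld) {
  if (is.null(names(weights)) || anyDuplicated(names(weights))) {
    stop("weights must be uniquely named by variant id", call. = FALSE)
  }
  if (all(weights == 0)) stop("model has no nonzero weight", call. = FALSE)
  ld <- as.matrix(ld)
  if (is.null(rownames(ld))) stop("ld matrix needs variant dimnames", call. = FALSE)
  if (max(abs(ld - t(ld))) > 1e-10) stop("ld matrix is not symmetric", call. = FALSE)
  miss_ld <- setdiff(names(weights), rownames(ld))
  if (length(miss_ld)) {
    stop(sprintf("variant '%s' missing from LD matrix", miss_ld[1]), call. = FALSE)
  }
  have <- names(weights) %in% names(gwas)
  if (!all(have)) {
    warning(sprintf("%d model variant(s) missing from GWAS; dropped", sum(!have)),
            call. = FALSE)
  }
  if (!any(have)) {
    return(structure(NA_real_, reason = "no model variant present in GWAS"))
  }
  v <- names(weights)[have]
  w <- weights[v]
  g <- ld[v, v, drop = FALSE]
  z <- gwas[v]
  if (!all(is.finite(z))) stop("GWAS z-scores must be finite", call. = FALSE)
  sigma_l <- sqrt(diag(g))
  sigma_g2 <- as.numeric(t(w) %*% g %*% w)
  if (sigma_g2 <= 0) {
    return(structure(NA_real_, reason = "degenerate model: sigma_g = 0"))
  }
  sum(w * sigma_l * z) / sqrt(sigma_g2)
}

#' Impute disease z-scores for a collection of gene-tissue models
#'
#' Applies [impute_gene_zscore()] to every model; per-gene failures are
#' recorded, never raised, so one degenerate model does not abort a
#' transcriptome-wide run.
#'
#' @param models list of models, each a list with `gene`, `tissue`, and
#'   `weights` (named numeric vector).
#' @param gwas named numeric vector of per-variant GWAS z-scores.
#' @param ld named list of per-gene LD covariance matrices (keyed by gene).
#' @return list with `table` (data.frame gene, tissue, zscore — the
#'   tissue expression table consumed by [aggregate_disease_tissues()]) and
#'   `skipped` (data.frame gene, tissue, reason).
#' @export
impute_all <- function(models, gwas, ld) {
  stopifnot(is.list(models))
  rows <- vector("list", length(models))
  skipped <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    res <- tryCatch({
      gm <- ld[[m$gene]]
      if (is.null(gm)) stop(sprintf("no LD matrix for gene '%s'", m$gene), call. = FALSE)
      suppressWarnings(impute_gene_zscore(m$weights, gwas, gm))
    }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
    if (is.na(res)) {
      skipped[[i]] <- data.frame(gene = m$gene, tissue = m$tissue,
                                 reason = attr(res, "reason"), stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(gene = m$gene, tissue = m$tissue,
                              zscore = as.numeric(res), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  skp <- do.call(rbind, skipped[!vapply(skipped, is.null, TRUE)])
  if (is.null(tab)) tab <- data.frame(gene = character(0), tissue = character(0),
                                      zscore = numeric(0))
  if (is.null(skp)) skp <- data.frame(gene = character(0), tissue = character(0),
                                      reason = character(0))
  if (nrow(skp)) {
    message(sprintf("twas: %d model(s) skipped (%d imputed)", nrow(skp), nrow(tab)))
  }
  list(table = tab, skipped = skp)
}

#' Read TWAS input files
#'
#' Readers for the three text inputs of the imputation stage: weight models
#' (TSV: gene, tissue, variant_id, weight), per-gene LD in long format
#' (TSV: gene, var_i, var_j, cov; symmetric entries may be given once), and
#' GWAS z-scores (TSV: variant_id, zscore).
#'
#' @param weights_path,ld_path,gwas_path file paths.
#' @return list with `models`, `ld`, `gwas` ready for [impute_all()].
#' @export
read_twas_inputs <- function(weights_path, ld_path, gwas_path) {
  wt <- utils::read.delim(weights_path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "tissue", "variant_id", "weight") %in% names(wt)))
  wt$gene <- normalize_symbols(wt$gene, context = "weights gene")
  key <- paste(wt$gene, wt$tissue, sep = "\r")
  models <- lapply(split(seq_len(nrow(wt)), key), function(idx) {
    list(gene = wt$gene[idx[1]], tissue = wt$tissue[idx[1]],
         weights = stats::setNames(wt$weight[idx], wt$variant_id[idx]))
  })
  names(models) <- NULL

  ldt <- utils::read.delim(ld_path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "var_i", "var_j", "cov") %in% names(ldt)))
  ldt$gene <- normalize_symbols(ldt$gene, context = "ld gene")
  ld <- lapply(split(ldt, ldt$gene), function(d) {
    vars <- sort(unique(c(d$var_i, d$var_j)))
    m <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
    m[cbind(d$var_i, d$var_j)] <- d$cov
    m[cbind(d$var_j, d$var_i)] <- d$cov
    m
  })

  gw <- utils::read.delim(gwas_path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "zscore") %in% names(gw)))
  gwas <- stats::setNames(as.numeric(gw$zscore), gw$variant_id)

  list(models = models, ld = ld, gwas = gwas)
}
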