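#' Construct a perturbation signature matrix
#'
#' Container for Level-5-style moderated z-score signatures: a genes x
#' signatures matrix plus per-column metadata. The `pert_iname` column of
#' the metadata identifies the perturbing drug and is what replicate
#' aggregation groups by.
#'
#' @param values numeric matrix, rownames = gene symbols, colnames =
#'   signature ids.
#' @param col_meta data.frame of per-column metadata with at least
#'   `pert_iname`; a character vector is taken as `pert_iname` directly.
#' @return object of class `signature_matrix` with `genes`, `values`,
#'   `col_meta` (includes `sig_id`).
#' @export
signature_matrix <- function(values, col_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(values))) stop("duplicate gene rows", call. = FALSE)
  if (!all(is.finite(values))) stop("signature values must be finite", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- sprintf("sig%04d", seq_len(ncol(values)))
  if (is.character(col_meta)) col_meta <- data.frame(pert_iname = col_meta,
                                                     stringsAsFactors = FALSE)
  if (nrow(col_meta) != ncol(values)) {
    stop("column metadata length must equal matrix width", call. = FALSE)
  }
  if (is.null(col_meta$pert_iname)) stop("col_meta needs a 'pert_iname' column", call. = FALSE)
  col_meta$sig_id <- colnames(values)
  rownames(values) <- normalize_symbols(rownames(values), context = "signature genes")
  structure(list(genes = rownames(values), values = values, col_meta = col_meta),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes x %d signatures (%d drug(s))\n",
              nrow(x$values), ncol(x$values), length(signature_drugs(x))))
  invisible(x)
}

#' Drugs present in a signature matrix
#' @param mat a `signature_matrix`.
#' @return unique lower-cased drug names.
#' @export
signature_drugs <- function(mat) {
  stopifnot(inherits(mat, "signature_matrix"))
  unique(tolower(trimws(mat$col_meta$pert_iname)))
}

#' Read a GCT v1.3 text file
#'
#' Parses the `#1.3` tab-delimited format used for CMAP/LINCS Level-5
#' exports: a dimensions line `nrow ncol nrhd nchd`, a header row of row-
#' metadata names and column ids, `nchd` column-metadata rows, then the
#' data rows. Column metadata become columns of `col_meta`.
#'
#' @param path GCT file path.
#' @return a `signature_matrix` (column metadata must include `pert_iname`
#'   for drug-level aggregation; other headers are carried through).
#' @export
read_gct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.3") {
    stop(sprintf("'%s' is not a GCT v1.3 file", path), call. = FALSE)
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "[ \t]+")[[1]])
  if (length(dims) != 4 || any(is.na(dims))) stop("malformed GCT dimensions line", call. = FALSE)
  nr <- dims[1]; nc <- dims[2]; nrhd <- dims[3]; nchd <- dims[4]
  hdr <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  cids <- hdr[(2 + nrhd):(1 + nrhd + nc)]
  col_meta <- data.frame(row.names = seq_len(nc))
  for (i in seq_len(nchd)) {
    f <- strsplit(lines[3 + i], "\t", fixed = TRUE)[[1]]
    col_meta[[f[1]]] <- f[(2 + nrhd):(1 + nrhd + nc)]
  }
  rows <- strsplit(lines[(4 + nchd):(3 + nchd + nr)], "\t", fixed = TRUE)
  rids <- vapply(rows, `[[`, "", 1)
  vals <- t(vapply(rows, function(f) as.numeric(f[(2 + nrhd):(1 + nrhd + nc)]),
                   numeric(nc)))
  if (nc == 1) vals <- matrix(vals, ncol = 1)
  dimnames(vals) <- list(rids, cids)
  if (nchd == 0) stop("GCT has no column metadata; a pert_iname header is required",
                      call. = FALSE)
  signature_matrix(vals, col_meta)
}

#' Write a signature matrix as GCT v1.3
#'
#' @param mat a `signature_matrix`.
#' @param path output path.
#' @export
write_gct <- function(mat, path) {
  stopifnot(inherits(mat, "signature_matrix"))
  v <- mat$values
  meta_cols <- setdiff(names(mat$col_meta), "sig_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(sprintf("%d\t%d\t%d\t%d", nrow(v), ncol(v), 0L, length(meta_cols)), con)
  writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
  for (m in meta_cols) {
    writeLines(paste(c(m, as.character(mat$col_meta[[m]])), collapse = "\t"), con)
  }
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.12g", v[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a plain TSV signature matrix
#'
#' Dialect alternative to GCT: a genes x signatures TSV whose first column
#' holds gene symbols. If `col_meta` is not given, column names are taken
#' as drug names (one signature per drug).
#'
#' @param path TSV of values.
#' @param col_meta optional path to a TSV with columns `sig_id`,
#'   `pert_iname`, ... matching the value columns.
#' @return a `signature_matrix`.
#' @export
read_signature_tsv <- function(path, col_meta = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  if (is.null(col_meta)) {
    cm <- data.frame(pert_iname = colnames(v), stringsAsFactors = FALSE)
  } else {
    cm <- utils::read.delim(col_meta, stringsAsFactors = FALSE, check.names = FALSE)
    cm <- cm[match(colnames(v), cm$sig_id), , drop = FALSE]
  }
  signature_matrix(v, cm)
}

#' Aggregate a drug's signatures into one perturbation profile
#'
#' Collapses all signature columns of one drug (cell lines, doses, times
#' pooled) into a single per-gene z-score vector. `mean` (default) is the
#' unweighted average; `max_abs` keeps, per gene, the signed value of
#' largest magnitude (first column wins ties).
#'
#' @param mat a `signature_matrix`.
#' @param drug drug name (matched after lower-casing/trimming).
#' @param method "mean" or "max_abs".
#' @return object of class `perturbation_profile`: `owner`, `z` (named
#'   per-gene vector), `n_source` (columns aggregated per gene).
#' @export
aggregate_drug_signatures <- function(mat, drug, method = c("mean", "max_abs")) {
  stopifnot(inherits(mat, "signature_matrix"))
  method <- match.arg(method)
  key <- tolower(trimws(drug))
  sel <- tolower(trimws(mat$col_meta$pert_iname)) == key
  if (!any(sel)) stop(sprintf("drug '%s' has no signature column", drug), call. = FALSE)
  v <- mat$values[, sel, drop = FALSE]
  z <- switch(method,
    mean = rowMeans(v),
    max_abs = v[cbind(seq_len(nrow(v)), max.col(abs(v), ties.method = "first"))]
  )
  names(z) <- rownames(v)
  structure(
    list(owner = key, z = z,
         n_source = stats::setNames(rep.int(ncol(v), nrow(v)), rownames(v))),
    class = "perturbation_profile"
  )
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf("perturbation_profile '%s': %d genes (max |z| = %.3g)\n",
              x$owner, length(x$z), max(abs(x$z))))
  invisible(x)
}

#' Read a long-format tissue z-score table
#'
#' @param path TSV with columns gene, tissue, zscore.
#' @return data.frame (gene, tissue, zscore) with normalized gene symbols.
#' @export
read_tissue_zscores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "tissue", "zscore")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("tissue table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df$gene <- normalize_symbols(df$gene, context = "tissue table gene")
  df$zscore <- as.numeric(df$zscore)
  df[, need]
}

#' Aggregate per-tissue disease z-scores into one disease profile
#'
#' Combines genetically imputed disease-association z-scores across tissues
#' into a single per-gene value. Genes with no model in any tissue are
#' simply absent from the profile. The combination rule is a deliberate,
#' configurable choice: unweighted `mean` by default, `max_abs`, or a
#' `single_tissue` pick.
#'
#' @param table data.frame (gene, tissue, zscore), sparse over tissues.
#' @param method "mean", "max_abs" or "single_tissue".
#' @param tissue tissue label, required for `single_tissue`.
#' @param label owner label for the resulting profile.
#' @return a `perturbation_profile`; `n_source` records tissues used per gene.
#' @export
aggregate_disease_tissues <- function(table, method = c("mean", "max_abs", "single_tissue"),
                                      tissue = NULL, label = "disease") {
  method <- match.arg(method)
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("tissue table is empty", call. = FALSE)
  }
  stopifnot(all(c("gene", "tissue", "zscore") %in% names(table)))
  if (!all(is.finite(table$zscore))) stop("tissue z-scores must be finite", call. = FALSE)
  if (method == "single_tissue") {
    if (is.null(tissue)) stop("method 'single_tissue' requires a tissue", call. = FALSE)
    table <- table[table$tissue == tissue, , drop = FALSE]
    if (nrow(table) == 0) stop(sprintf("no gene has a model in tissue '%s'", tissue),
                               call. = FALSE)
  }
  agg <- switch(method,
    mean = tapply(table$zscore, table$gene, mean),
    max_abs = tapply(table$zscore, table$gene, function(v) v[which.max(abs(v))]),
    single_tissue = tapply(table$zscore, table$gene, function(v) v[1])
  )
  n_source <- tapply(table$zscore, table$gene, length)
  genes <- sort(names(agg))
  structure(
    list(owner = label,
         z = stats::setNames(as.numeric(agg[genes]), genes),
         n_source = stats::setNames(as.integer(n_source[genes]), genes)),
    class = "perturbation_profile"
  )
}
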