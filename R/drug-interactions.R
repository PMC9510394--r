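#' Read a DGIdb-style drug-gene interaction table
#'
#' @param path TSV path with at least drug, gene and approval columns.
#' @param cols named list mapping roles to column names; defaults follow
#'   DGIdb exports: `drug = "drug_name"`, `gene = "gene_name"`,
#'   `approved = "approval_status"`.
#' @return data.frame with columns drug, gene, approved (as read).
#' @export
read_drug_interactions <- function(path,
                                   cols = list(drug = "drug_name",
                                               gene = "gene_name",
                                               approved = "approval_status")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(cols[c("drug", "gene", "approved")])
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("interaction table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  data.frame(drug = df[[cols$drug]], gene = df[[cols$gene]],
             approved = df[[cols$approved]], stringsAsFactors = FALSE)
}

approved_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("approved", "true", "t", "yes", "y", "1")
}

#' Build the drug -> target-gene map over a disease network
#'
#' Keeps only interactions of approved drugs with genes that are members of
#' the disease network, collapses duplicate rows, and returns the drug ->
#' target set map. Interaction type/direction is deliberately ignored: any
#' interaction row qualifies. Drug names are matched exactly after
#' lower-casing and trimming.
#'
#' @param interactions data.frame with columns drug, gene, approved (see
#'   [read_drug_interactions()]), or a path to such a TSV.
#' @param network a `disease_network` or character vector of member genes.
#' @param cols column mapping passed to [read_drug_interactions()] when
#'   `interactions` is a path.
#' @return object of class `drug_target_map`: `targets` (named list drug ->
#'   sorted gene vector), `genes_covered` (sorted union).
#' @export
build_drug_target_map <- function(interactions, network,
                                  cols = list(drug = "drug_name",
                                              gene = "gene_name",
                                              approved = "approval_status")) {
  if (is.character(interactions) && length(interactions) == 1) {
    interactions <- read_drug_interactions(interactions, cols)
  }
  if (!all(c("drug", "gene", "approved") %in% names(interactions))) {
    stop("interaction table needs columns drug, gene, approved", call. = FALSE)
  }
  if (nrow(interactions) == 0) stop("interaction table is empty", call. = FALSE)
  members <- if (inherits(network, "disease_network")) network$members else {
    normalize_symbols(network, context = "network members")
  }
  drug <- tolower(trimws(as.character(interactions$drug)))
  gene <- normalize_symbols(interactions$gene, context = "interaction gene")
  keep <- approved_flag(interactions$approved) & gene %in% members & nzchar(drug)
  if (!any(keep)) {
    warning("no approved drug-gene interactions map to the disease network", call. = FALSE)
    return(structure(list(targets = stats::setNames(list(), character(0)),
                          genes_covered = character(0)),
                     class = "drug_target_map"))
  }
  pairs <- unique(data.frame(drug = drug[keep], gene = gene[keep],
                             stringsAsFactors = FALSE))
  targets <- lapply(split(pairs$gene, pairs$drug), function(g) sort(unique(g)))
  targets <- targets[sort(names(targets))]
  covered <- sort(unique(pairs$gene))
  message(sprintf("drug-target map: %d approved drug(s) covering %d network gene(s)",
                  length(targets), length(covered)))
  structure(list(targets = targets, genes_covered = covered),
            class = "drug_target_map")
}

#' @export
print.drug_target_map <- function(x, ...) {
  cat(sprintf("drug_target_map: %d drug(s), %d gene(s) covered\n",
              length(x$targets), length(x$genes_covered)))
  invisible(x)
}

#' Restrict a drug-target map to drugs with perturbation signatures
#'
#' Drops drugs without a signature in the perturbation compendium and
#' recomputes the covered gene set. Idempotent; can only shrink the map.
#'
#' @param map a `drug_target_map`.
#' @param available character vector of drug names with signatures (matched
#'   after lower-casing/trimming), or a `signature_matrix`.
#' @return a `drug_target_map`.
#' @export
restrict_to_signatures <- function(map, available) {
  stopifnot(inherits(map, "drug_target_map"))
  if (inherits(available, "signature_matrix")) available <- signature_drugs(available)
  available <- tolower(trimws(as.character(available)))
  keep <- names(map$targets) %in% available
  if (!any(keep)) {
    stop("no drug in the map has a perturbation signature", call. = FALSE)
  }
  targets <- map$targets[keep]
  structure(list(targets = targets,
                 genes_covered = sort(unique(unlist(targets, use.names = FALSE)))),
            class = "drug_target_map")
}
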