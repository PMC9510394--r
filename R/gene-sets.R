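#' Normalize gene symbols
#'
#' Upper-cases and trims HGNC-style gene symbols. Matching throughout the
#' package is exact after this normalization; no alias or symbol-history
#' resolution is attempted.
#'
#' @param x character vector of gene symbols.
#' @param context label used in error messages.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x, context = "gene symbol") {
  x <- as.character(x)
  bad <- which(is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: missing value at position %d", context, bad[1]), call. = FALSE)
  }
  x <- toupper(trimws(x))
  bad <- which(!nzchar(x))
  if (length(bad)) {
    stop(sprintf("%s: empty symbol at position %d", context, bad[1]), call. = FALSE)
  }
  bad <- which(grepl("[[:space:]]", x))
  if (length(bad)) {
    stop(sprintf("%s: symbol '%s' contains whitespace", context, x[bad[1]]), call. = FALSE)
  }
  x
}

#' Merge disease seed-gene lists
#'
#' Unions several named source lists of gene symbols into one de-duplicated
#' seed set, keeping first-seen order and per-gene provenance. For two lists
#' the merged size obeys inclusion-exclusion exactly:
#' `|A union B| = |A| + |B| - |A intersect B|`.
#'
#' @param lists named list of character vectors (each non-empty), e.g. one
#'   vector of GWAS genes and one of exome-study genes.
#' @return an object of class `seed_gene_set` with elements `merged`
#'   (ordered unique symbols), `source_lists` (normalized inputs) and
#'   `provenance` (named list: gene -> source names).
#' @examples
#' s <- merge_gene_lists(list(gwas = c("SHANK3", "CHD8"), exome = c("CHD8", "SCN2A")))
#' s$merged
#' @export
merge_gene_lists <- function(lists) {
  if (!is.list(lists) || length(lists) == 0) {
    stop("'lists' must be a non-empty named list of gene vectors", call. = FALSE)
  }
  nm <- names(lists)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every source list must be named", call. = FALSE)
  }
  lists <- lapply(seq_along(lists), function(i) {
    v <- lists[[i]]
    if (length(v) == 0) stop(sprintf("source list '%s' is empty", nm[i]), call. = FALSE)
    unique(normalize_symbols(v, context = sprintf("list '%s'", nm[i])))
  })
  names(lists) <- nm
  merged <- character(0)
  provenance <- list()
  for (src in nm) {
    for (g in lists[[src]]) {
      if (is.null(provenance[[g]])) {
        merged <- c(merged, g)
        provenance[[g]] <- src
      } else {
        provenance[[g]] <- union(provenance[[g]], src)
      }
    }
  }
  structure(
    list(source_lists = lists, merged = merged, provenance = provenance),
    class = "seed_gene_set"
  )
}

#' @export
print.seed_gene_set <- function(x, ...) {
  cat(sprintf(
    "seed_gene_set: %d unique genes from %d source list(s) [%s]\n",
    length(x$merged), length(x$source_lists),
    paste(sprintf("%s: %d", names(x$source_lists), lengths(x$source_lists)), collapse = ", ")
  ))
  invisible(x)
}

#' Read a gene list from a text file
#'
#' Accepts one symbol per line (`#` comments and blank lines ignored) or a
#' two-column TSV of (symbol, source), in which case a named list split by
#' source is returned.
#'
#' @param path file path.
#' @return character vector, or a named list of character vectors when the
#'   file has a source column.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("no gene symbols in '%s'", path), call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2)) {
    sym <- vapply(parts, `[[`, "", 1)
    src <- vapply(parts, `[[`, "", 2)
    return(split(normalize_symbols(sym, context = path), src))
  }
  normalize_symbols(lines, context = path)
}

#' Map seed genes onto the interactome
#'
#' Restricts a seed set to the genes present as interactome nodes; genes
#' without a node are dropped with a warning (one per gene), mirroring the
#' usual silent attrition between curated gene lists and interactome
#' coverage.
#'
#' @param seeds a `seed_gene_set` or character vector.
#' @param net an `interactome`.
#' @return list with `mapped` (a `seed_gene_set` restricted to network
#'   genes) and `unmapped` (character vector).
#' @export
map_to_interactome <- function(seeds, net) {
  stopifnot(inherits(net, "interactome"))
  if (is.character(seeds)) seeds <- merge_gene_lists(list(seeds = seeds))
  stopifnot(inherits(seeds, "seed_gene_set"))
  nodes <- interactome_nodes(net)
  keep <- seeds$merged %in% nodes
  unmapped <- seeds$merged[!keep]
  for (g in unmapped) {
    warning(sprintf("seed gene '%s' is not in the interactome; dropped", g), call. = FALSE)
  }
  if (!any(keep)) {
    stop("none of the seed genes map to the interactome; propagation impossible", call. = FALSE)
  }
  mapped <- seeds
  mapped$merged <- seeds$merged[keep]
  mapped$provenance <- seeds$provenance[mapped$merged]
  mapped$source_lists <- lapply(seeds$source_lists, function(v) v[v %in% nodes])
  list(mapped = mapped, unmapped = unmapped)
}
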