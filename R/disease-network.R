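#' Size of the top fraction of a ranked pool
#'
#' Number of genes selected when taking the top `fraction` of a pool of
#' `n_pool` ranked non-seed genes: `ceiling(fraction * n_pool)`. Ceiling is
#' used so "top 1%" is read as at-least coverage; with a 17,706-node
#' interactome and 147 seeds this gives `ceiling(0.01 * 17559) = 176`
#' disease-related genes and a 323-gene disease network.
#'
#' @param n_pool number of candidate (non-seed) genes.
#' @param fraction fraction in (0, 1].
#' @return integer count.
#' @export
top_fraction_size <- function(n_pool, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  as.integer(ceiling(fraction * n_pool))
}

#' Select the disease network from a diffusion result
#'
#' The disease network is the mapped seed genes plus the top `fraction` of
#' *non-seed* nodes ranked by diffusion heat (seeds are excluded from the
#' ranked pool and retained unconditionally). Ties at the cutoff are broken
#' by lexicographic symbol order, making the selection deterministic.
#'
#' @param result a `diffusion_result`.
#' @param fraction fraction of non-seed nodes to include, in (0, 1];
#'   default 0.01 (top 1%).
#' @return object of class `disease_network`: `members` (seeds first, then
#'   selected genes by rank), `is_seed`, `heat` (named), `edges` (induced
#'   interactome edges), `fraction`.
#' @export
select_top_fraction <- function(result, fraction = 0.01) {
  stopifnot(inherits(result, "diffusion_result"))
  nodes <- names(result$heat)
  nonseed <- setdiff(nodes, result$seeds)
  if (length(nonseed) == 0) stop("no non-seed nodes to rank", call. = FALSE)
  k <- top_fraction_size(length(nonseed), fraction)
  ord <- order(-result$heat[nonseed], nonseed)
  selected <- nonseed[ord][seq_len(k)]
  members <- c(result$seeds, selected)
  structure(
    list(
      members = members,
      is_seed = stats::setNames(members %in% result$seeds, members),
      heat = result$heat[members],
      edges = network_induced_edges(result$net, members),
      fraction = fraction
    ),
    class = "disease_network"
  )
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("disease_network: %d members (%d seeds + %d related), %d induced edges\n",
              length(x$members), sum(x$is_seed), sum(!x$is_seed), nrow(x$edges)))
  invisible(x)
}

#' Induced subgraph edges
#'
#' Interactome edges with both endpoints in a member set.
#'
#' @param net an `interactome`.
#' @param members character vector of node symbols; every member must be a
#'   network node.
#' @return canonical sorted data.frame of edges (from, to).
#' @export
network_induced_edges <- function(net, members) {
  stopifnot(inherits(net, "interactome"))
  members <- normalize_symbols(members, context = "members")
  missing <- setdiff(members, interactome_nodes(net))
  if (length(missing)) {
    stop(sprintf("member '%s' is not an interactome node", missing[1]), call. = FALSE)
  }
  sub <- igraph::induced_subgraph(net$graph, members)
  e <- igraph::as_data_frame(sub, what = "edges")
  out <- data.frame(from = pmin(e$from, e$to), to = pmax(e$from, e$to),
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write disease network tables
#'
#' Writes a node table (symbol, heat, is_seed), an edge table, and a SIF
#' file for Cytoscape under the given prefix.
#'
#' @param dn a `disease_network`.
#' @param prefix path prefix; files `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>.sif` are written.
#' @return invisibly, the written paths.
#' @export
write_disease_network <- function(dn, prefix) {
  stopifnot(inherits(dn, "disease_network"))
  nodes <- data.frame(
    symbol = dn$members,
    heat = sprintf("%.12g", dn$heat),
    is_seed = unname(dn$is_seed),
    stringsAsFactors = FALSE
  )
  paths <- c(
    nodes = paste0(prefix, "_nodes.tsv"),
    edges = paste0(prefix, "_edges.tsv"),
    sif = paste0(prefix, ".sif")
  )
  utils::write.table(nodes, paths[["nodes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dn$edges, paths[["edges"]], sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(dn$edges$from, "pp", dn$edges$to, sep = "\t"), paths[["sif"]])
  invisible(paths)
}
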