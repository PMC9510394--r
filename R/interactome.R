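#' Load and validate a protein-protein interactome
#'
#' Builds an undirected simple graph from a two-column edge table of gene
#' symbols. Self-loops are removed and reversed/repeated edges collapsed
#' ((a,b) and (b,a) are the same undirected edge); counts of both are kept
#' on the returned object and reported. All symbols seen in the table,
#' including nodes left isolated by self-loop removal, are retained as
#' nodes; no largest-component restriction is applied (seeds in a small
#' component simply keep their heat there).
#'
#' @param x a data.frame/matrix with at least two columns, or a path to a
#'   TSV/CSV edge list (delimiter and an optional header are auto-detected).
#' @return an object of class `interactome` wrapping an igraph graph, with
#'   elements `graph`, `n_self_loops_removed`, `n_duplicates_removed`.
#' @examples
#' net <- load_interactome(data.frame(a = c("A", "B", "A"), b = c("B", "A", "C")))
#' interactome_edges(net)
#' @export
load_interactome <- function(x) {
  df <- if (is.character(x) && length(x) == 1) read_edge_table(x) else as.data.frame(x)
  if (nrow(df) == 0) stop("edge table is empty", call. = FALSE)
  if (ncol(df) < 2) stop("edge table needs two columns of gene symbols", call. = FALSE)
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  bad <- which(is.na(a) | is.na(b) | !nzchar(trimws(a)) | !nzchar(trimws(b)))
  if (length(bad)) {
    stop(sprintf("malformed edge row %d: missing or empty endpoint", bad[1]), call. = FALSE)
  }
  a <- normalize_symbols(a, context = "edge table column 1")
  b <- normalize_symbols(b, context = "edge table column 2")
  nodes <- sort(unique(c(a, b)))
  is_loop <- a == b
  n_self <- sum(is_loop)
  a2 <- a[!is_loop]
  b2 <- b[!is_loop]
  if (length(a2) == 0) {
    stop("no edges survive self-loop removal", call. = FALSE)
  }
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  n_dup <- sum(dup)
  edges <- data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  message(sprintf(
    "interactome: %d nodes, %d edges (%d self-loop(s) removed, %d duplicate edge(s) collapsed)",
    length(nodes), nrow(edges), n_self, n_dup
  ))
  structure(
    list(graph = g, n_self_loops_removed = n_self, n_duplicates_removed = n_dup),
    class = "interactome"
  )
}

read_edge_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  # header heuristic: column-name-like tokens rather than gene symbols
  header <- any(grepl("^(from|to|gene|node|protein|source|target|symbol)",
                      tolower(trimws(fields))))
  utils::read.table(path, sep = sep, header = header, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "", check.names = FALSE)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Interactome nodes
#' @param net an `interactome`.
#' @return character vector of node symbols (sorted).
#' @export
interactome_nodes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::V(net$graph)$name
}

#' Interactome edge table
#' @param net an `interactome`.
#' @return data.frame with columns `from`, `to`, canonically ordered
#'   (from < to, rows sorted).
#' @export
interactome_edges <- function(net) {
  stopifnot(inherits(net, "interactome"))
  e <- igraph::as_data_frame(net$graph, what = "edges")
  lo <- pmin(e$from, e$to)
  hi <- pmax(e$from, e$to)
  out <- data.frame(from = lo, to = hi, stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node degrees
#' @param net an `interactome`.
#' @return named integer vector of degrees.
#' @export
interactome_degree <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::degree(net$graph)
}

#' Connected components of the interactome
#'
#' @param net an `interactome`.
#' @return list of character vectors, one per component, covering all nodes;
#'   components ordered by decreasing size then first member.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "interactome"))
  comp <- igraph::components(net$graph)
  parts <- split(igraph::V(net$graph)$name, comp$membership)
  parts <- lapply(parts, sort)
  unname(parts[order(-lengths(parts), vapply(parts, `[[`, "", 1))])
}

#' Write an interactome or edge table to disk
#'
#' `tsv` writes the canonical sorted two-column edge list; `sif` writes
#' Cytoscape Simple Interaction Format with interaction type `pp`.
#'
#' @param net an `interactome`.
#' @param path output file.
#' @param format "tsv" or "sif".
#' @export
write_interactome <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- interactome_edges(net)
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(e$from, "pp", e$to, sep = "\t"), path)
  }
  invisible(path)
}
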