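#' Graph Laplacian of an interactome
#'
#' Combinatorial Laplacian `L = D - A` by default; the symmetric normalized
#' Laplacian `I - D^{-1/2} A D^{-1/2}` (isolated nodes get a zero row) is
#' available for sensitivity analysis. Heat conservation holds only for the
#' combinatorial form, whose columns sum to zero.
#'
#' @param net an `interactome`.
#' @param laplacian "combinatorial" or "normalized".
#' @return sparse symmetric matrix with node-name dimnames.
#' @export
graph_laplacian <- function(net, laplacian = c("combinatorial", "normalized")) {
  laplacian <- match.arg(laplacian)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  d <- Matrix::rowSums(A)
  if (laplacian == "combinatorial") {
    L <- Matrix::Diagonal(x = d) - A
  } else {
    inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
    S <- Matrix::Diagonal(x = inv_sqrt)
    L <- Matrix::Diagonal(x = as.numeric(d > 0)) - S %*% A %*% S
  }
  dimnames(L) <- dimnames(A)
  L
}

# exp(-t L) %*% v by uniformization: with c = max(diag(L)) and
# M = cI - L (entrywise non-negative), exp(-tL) = e^{-tc} exp(tM), and the
# Taylor series of exp(tM) v has non-negative terms, so heat can never go
# negative beyond rounding. Long times are split into steps with t*c <= 8
# per step to keep the series short and well-conditioned.
expm_multiply <- function(L, v, t, tol = 1e-14) {
  cmax <- max(Matrix::diag(L))
  if (cmax <= 0) return(v)  # edgeless graph: exp(0) = I
  nsteps <- max(1L, ceiling(t * cmax / 8))
  dt <- t / nsteps
  M <- Matrix::Diagonal(nrow(L), cmax) - L
  for (s in seq_len(nsteps)) {
    term <- v
    acc <- v
    k <- 0
    kmin <- dt * cmax
    repeat {
      k <- k + 1
      term <- as.numeric(M %*% term) * (dt / k)
      acc <- acc + term
      if (k >= kmin && sum(abs(term)) <= tol * max(sum(abs(acc)), 1e-300)) break
      if (k > 1e5) stop("matrix exponential series failed to converge", call. = FALSE)
    }
    v <- exp(-dt * cmax) * acc
  }
  v
}

#' Heat-kernel network propagation from seed genes
#'
#' Solves the graph heat equation `h(t) = exp(-t L) h0` with unit initial
#' heat on every mapped seed gene and zero elsewhere, as in the Cytoscape
#' Diffusion service. Higher final heat means stronger network relatedness
#' to the seeds. With the default combinatorial Laplacian total heat is
#' conserved (`sum h(t) = number of mapped seeds`) and every value is
#' non-negative.
#'
#' @param net an `interactome`.
#' @param seeds a `seed_gene_set` or character vector of seed symbols;
#'   seeds absent from the network are dropped with a warning.
#' @param t positive diffusion time. The default 0.1 is the Diffusion app's
#'   documented default.
#' @param laplacian "combinatorial" (default) or "normalized".
#' @return object of class `diffusion_result`: `heat` (named vector over
#'   all nodes), `seeds` (mapped seed symbols), `ranking` (all nodes by
#'   heat descending, ties broken by symbol), `t`, `laplacian`, `net`.
#' @export
diffuse <- function(net, seeds, t = 0.1, laplacian = c("combinatorial", "normalized")) {
  stopifnot(inherits(net, "interactome"))
  laplacian <- match.arg(laplacian)
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t <= 0) {
    stop("diffusion time t must be a positive number", call. = FALSE)
  }
  mapped <- map_to_interactome(seeds, net)$mapped$merged
  nodes <- interactome_nodes(net)
  h0 <- numeric(length(nodes))
  names(h0) <- nodes
  h0[mapped] <- 1
  L <- graph_laplacian(net, laplacian)
  h <- expm_multiply(L, unname(h0), t)
  h <- pmax(h, 0)  # clip rounding-level negatives
  names(h) <- nodes
  ranking <- nodes[order(-h, nodes)]
  structure(
    list(heat = h, seeds = mapped, t = t, laplacian = laplacian,
         ranking = ranking, net = net),
    class = "diffusion_result"
  )
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("diffusion_result: %d nodes, %d seeds, t = %g (%s Laplacian)\n",
              length(x$heat), length(x$seeds), x$t, x$laplacian))
  invisible(x)
}

#' Dense matrix-exponential diffusion oracle
#'
#' Independent brute-force computation of `exp(-tL) h0` by dense
#' eigendecomposition of the symmetric Laplacian. Intended for testing only
#' and refuses graphs above 200 nodes.
#'
#' @inheritParams diffuse
#' @return named heat vector.
#' @export
diffuse_oracle <- function(net, seeds, t, laplacian = c("combinatorial", "normalized")) {
  stopifnot(inherits(net, "interactome"))
  laplacian <- match.arg(laplacian)
  nodes <- interactome_nodes(net)
  if (length(nodes) > 200) stop("oracle restricted to graphs with <= 200 nodes", call. = FALSE)
  mapped <- map_to_interactome(seeds, net)$mapped$merged
  h0 <- numeric(length(nodes))
  names(h0) <- nodes
  h0[mapped] <- 1
  L <- as.matrix(graph_laplacian(net, laplacian))
  e <- eigen(L, symmetric = TRUE)
  h <- as.numeric(e$vectors %*% (exp(-t * e$values) * crossprod(e$vectors, h0)))
  names(h) <- nodes
  h
}

#' Write diffusion output as a node table
#'
#' @param result a `diffusion_result`.
#' @param path output TSV (node, heat, rank, is_seed).
#' @export
write_diffusion <- function(result, path) {
  stopifnot(inherits(result, "diffusion_result"))
  rk <- match(names(result$heat), result$ranking)
  df <- data.frame(
    node = names(result$heat),
    heat = sprintf("%.12g", result$heat),
    rank = rk,
    is_seed = names(result$heat) %in% result$seeds,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$rank), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
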