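# Independent brute-force oracles and small fixture builders. Everything
# here avoids the code paths it is used to check.

load_quiet <- function(x) suppressMessages(load_interactome(x))

# random simple graph as an edge data.frame (>= 1 edge guaranteed)
rand_edges <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
    e <- igraph::as_data_frame(g, what = "edges")
    if (nrow(e) == 0) e <- data.frame(from = "N001", to = "N002")
    e
  })
}

# union-find component count, independent of igraph
union_find_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$from[i]); rb <- find(edges$to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(nodes, find, "")))
}

# mid-rank computed from first principles
midrank_oracle <- function(v) {
  vapply(seq_along(v), function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2,
         numeric(1))
}

# Pearson of mid-ranks by explicit sums (no rank()/cor())
spearman_oracle <- function(x, y) {
  rx <- midrank_oracle(x)
  ry <- midrank_oracle(y)
  dx <- rx - sum(rx) / length(rx)
  dy <- ry - sum(ry) / length(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# brute-force undirected canonicalization of an edge table
canonical_pairs_oracle <- function(a, b) {
  loops <- 0L
  seen <- character(0)
  dups <- 0L
  for (i in seq_along(a)) {
    if (a[i] == b[i]) { loops <- loops + 1L; next }
    key <- paste(sort(c(a[i], b[i])), collapse = "|")
    if (key %in% seen) dups <- dups + 1L else seen <- c(seen, key)
  }
  list(n_loops = loops, n_dups = dups, n_edges = length(seen))
}

# tiny deterministic disease profile for reversal tests
make_profile <- function(z, owner = "disease") {
  structure(list(owner = owner, z = z,
                 n_source = stats::setNames(rep(1L, length(z)), names(z))),
            class = "perturbation_profile")
}
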