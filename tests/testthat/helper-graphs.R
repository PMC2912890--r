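# toy graphs and independent oracles for modularity / clustering tests

toy_graph <- function(edges, n = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  igraph::E(g)$weight <- 1
  igraph::E(g)$identity <- 1
  g
}

two_triangles <- function() toy_graph(cbind(c(1, 1, 2, 3, 4, 4, 5),
                                            c(2, 3, 3, 4, 5, 6, 6)))
path_graph <- function(n) toy_graph(cbind(seq_len(n - 1), 2:n))
complete_graph <- function(n) {
  el <- t(utils::combn(n, 2))
  toy_graph(el)
}
cycle_graph <- function(n) toy_graph(cbind(seq_len(n), c(2:n, 1)))

# random connected-ish test graph: G(n, p) with isolated vertices dropped,
# guaranteed >= 1 edge
random_test_graph <- function(n, p, seed) {
  g <- repeatgraph:::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::ecount(g) == 0)
    return(random_test_graph(n, min(1, p * 2), seed + 1000))
  igraph::E(g)$weight <- 1
  igraph::E(g)$identity <- 1
  g
}

# modularity oracle: the literal double sum over all ordered vertex pairs
modularity_double_sum <- function(g, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  k <- rowSums(A)
  m <- sum(A) / 2
  memb <- as.integer(factor(membership))
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  as.numeric(q / (2 * m))
}

# all set partitions of n elements as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (lab in seq_len(maxlab + 1))
      recurse(c(prefix, lab), max(maxlab, lab))
  }
  recurse(integer(0), 0L)
  out
}

# exhaustive maximum modularity over all partitions (small n only)
exhaustive_max_q <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  qs <- vapply(parts, function(p) compute_modularity(g, p), 0)
  list(q = max(qs), partition = parts[[which.max(qs)]])
}
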