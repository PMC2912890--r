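#' Expected edge term of the degree-matched random graph
#'
#' In a random graph with the same degree sequence, the expected number of
#' edges between vertices `i` and `j` is `k_i * k_j / (2m)`. This closed form
#' is the null model inside modularity; being an expectation, it can exceed 1.
#'
#' @param k_i,k_j vertex degrees.
#' @param m total number of edges (>= 1).
#' @return `k_i * k_j / (2 * m)`.
#' @export
edge_probability <- function(k_i, k_j, m) {
  if (any(m < 1)) stop("m must be >= 1")
  stopifnot(k_i >= 0, k_j >= 0)
  k_i * k_j / (2 * m)
}

partition_membership <- function(g, partition) {
  vn <- igraph::V(g)$name
  if (!is.null(names(partition))) {
    missing <- setdiff(vn, names(partition))
    if (length(missing)) stop("partition missing vertex: ", missing[1])
    partition <- partition[vn]
  } else if (length(partition) != length(vn)) {
    stop("partition must cover all ", length(vn), " vertices")
  }
  if (anyNA(partition)) stop("partition contains NA")
  as.integer(factor(partition))
}

#' Modularity of a graph partition
#'
#' `Q = (1/2m) * sum_ij [A_ij - k_i k_j / 2m] delta(c_i, c_j)`, the fraction
#' of edges inside communities minus its expectation in a degree-matched
#' random graph. Computed on the unweighted graph (`A_ij` in 0/1) via the
#' equivalent per-community form `Q = sum_c (l_c/m - (d_c/2m)^2)`. The
#' all-in-one-community partition gives exactly 0; values lie in [-1, 1).
#'
#' @param g a `similarity_graph` or igraph object with at least one edge.
#' @param partition community labels: either a vector named by vertex id or a
#'   vector in vertex order.
#' @return the modularity Q.
#' @export
compute_modularity <- function(g, partition) {
  g <- as_igraph(g)
  m <- igraph::ecount(g)
  if (m < 1) stop("modularity undefined for an edgeless graph")
  memb <- partition_membership(g, partition)
  nc <- max(memb)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  within <- memb[ends[, 1]] == memb[ends[, 2]]
  l_c <- tabulate(memb[ends[, 1]][within], nbins = nc)
  d_c <- tabulate(rep(memb[ends[, 1]], 1), nbins = nc) +
         tabulate(memb[ends[, 2]], nbins = nc)
  sum(l_c / m - (d_c / (2 * m))^2)
}

#' Greedy modularity agglomeration
#'
#' Starting from singleton communities, repeatedly merges the edge-connected
#' community pair with the largest modularity gain `dQ`, recording each merge,
#' until one community per connected component remains. Ties in `dQ` are
#' broken toward the merged community containing the smallest vertex id (then
#' the smaller partner id), so the merge sequence is deterministic.
#'
#' @param g a `similarity_graph` or igraph object with at least one edge.
#' @return a `merge_tree`: list with `merges` (data.frame `step`, `u`, `v`,
#'   `dq`, `q_after`; community ids number leaves `1..n` and merge `t` creates
#'   id `n + t`), `q0` (singleton-partition modularity), `n`, `vertex_names`,
#'   `n_components`.
#' @export
greedy_agglomeration <- function(g) {
  g <- as_igraph(g)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0L || m == 0L) stop("cannot agglomerate an empty or edgeless graph")
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  res <- .cnm_cpp(ends[, 1], ends[, 2], n)
  merges <- data.frame(step = seq_along(res$u), u = res$u, v = res$v,
                       dq = res$dq, q_after = res$q_after)
  structure(list(merges = merges, q0 = res$q0, n = n,
                 vertex_names = igraph::V(g)$name,
                 n_components = n - nrow(merges)),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("merge_tree:", x$n, "leaves,", nrow(x$merges), "merges,",
      x$n_components, "component(s); max Q =",
      format(max(c(x$q0, x$merges$q_after)), digits = 6), "\n")
  invisible(x)
}

#' Partition at a given agglomeration level
#'
#' Level 0 is the singleton partition; level `t` is the community structure
#' after the first `t` merges.
#'
#' @param tree a `merge_tree`.
#' @param level merge step, between 0 and `nrow(tree$merges)`.
#' @return named integer vector of community labels (contiguous from 1).
#' @export
partition_at_level <- function(tree, level) {
  stopifnot(inherits(tree, "merge_tree"),
            level >= 0, level <= nrow(tree$merges))
  n <- tree$n
  parent <- integer(n + level)
  if (level > 0) {
    for (t in seq_len(level)) {
      parent[tree$merges$u[t]] <- n + t
      parent[tree$merges$v[t]] <- n + t
    }
  }
  root <- seq_len(n + level)
  for (x in rev(seq_len(n + level))) {  # parents always have larger ids
    p <- parent[x]
    if (p > 0L) root[x] <- root[p]
  }
  comm <- root[seq_len(n)]
  setNames(as.integer(factor(comm)), tree$vertex_names)
}

#' Maximum-modularity cut of the merge tree
#'
#' Selects the agglomeration level with maximal modularity (the singleton
#' level counts as level 0). When several levels tie within 1e-12, the level
#' with fewer communities is chosen. Clusters are ordered by decreasing size
#' (ties by smallest member id) and named `CL1`, `CL2`, ...
#'
#' @param tree a `merge_tree`.
#' @return a `cluster_set`: list with `clusters` (named list of member id
#'   vectors), `membership` (named integer vector, cluster rank per vertex),
#'   `q_best` and `level`.
#' @export
best_cut <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  q_seq <- c(tree$q0, tree$merges$q_after)
  q_max <- max(q_seq)
  level <- max(which(q_seq >= q_max - 1e-12)) - 1L  # fewest communities
  memb <- partition_at_level(tree, level)
  sizes <- table(memb)
  first <- tapply(names(memb), memb, min)
  ord <- order(-as.integer(sizes), first)
  rank <- match(seq_along(sizes), ord)
  membership <- setNames(rank[memb], names(memb))
  clusters <- split(names(membership), membership)
  clusters <- clusters[order(as.integer(names(clusters)))]
  names(clusters) <- paste0("CL", seq_along(clusters))
  structure(list(clusters = clusters, membership = membership,
                 q_best = q_seq[level + 1L], level = level),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat("cluster_set:", length(x$clusters), "clusters, Q_best =",
      format(x$q_best, digits = 6), "\n")
  show <- head(sz, 10)
  cat("  sizes:", paste0(names(show), "=", show, collapse = " "),
      if (length(sz) > 10) "...\n" else "\n")
  invisible(x)
}

#' Compare connected components with the modularity clustering
#'
#' Components can either coincide with max-Q clusters or be broken into
#' several of them; clusters never span components (each cluster results from
#' merges along edges only). A violation of that refinement indicates an
#' internal inconsistency and raises an error.
#'
#' @param components component membership from [graph_components()].
#' @param clusters a `cluster_set` from [best_cut()].
#' @return a list with `table` (per component: size and number of clusters),
#'   `n_split` and `n_identical`.
#' @export
compare_partitions <- function(components, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  memb <- clusters$membership
  if (!setequal(names(components), names(memb)))
    stop("components and clusters cover different vertex sets")
  comp_of_cluster <- tapply(components[names(memb)], memb,
                            function(x) length(unique(x)))
  if (any(comp_of_cluster > 1L))
    stop("internal inconsistency: a cluster spans multiple components")
  per_comp <- tapply(memb, components[names(memb)],
                     function(x) length(unique(x)))
  sizes <- table(components)
  tab <- data.frame(component = as.integer(names(per_comp)),
                    size = as.integer(sizes[names(per_comp)]),
                    n_clusters = as.integer(per_comp))
  tab <- tab[order(tab$component), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       n_split = sum(tab$n_clusters > 1L),
       n_identical = sum(tab$n_clusters == 1L))
}

#' Export agglomeration results
#'
#' `write_merges_tsv()` writes the flat merge list, `write_q_curve_tsv()` the
#' modularity-vs-level curve, `write_membership_tsv()` cluster membership, and
#' `merge_tree_newick()` renders the dendrogram (one subtree per connected
#' component, joined at an artificial root) as a Newick string.
#'
#' @param tree a `merge_tree`.
#' @param path output file path.
#' @return the path invisibly; `merge_tree_newick()` returns the string.
#' @export
write_merges_tsv <- function(tree, path) write_tsv(tree$merges, path)

#' @rdname write_merges_tsv
#' @export
write_q_curve_tsv <- function(tree, path) {
  write_tsv(data.frame(level = 0:nrow(tree$merges),
                       n_communities = tree$n - (0:nrow(tree$merges)),
                       q = c(tree$q0, tree$merges$q_after)),
            path)
}

#' @rdname write_merges_tsv
#' @param clusters a `cluster_set`.
#' @export
write_membership_tsv <- function(clusters, path) {
  memb <- clusters$membership
  write_tsv(data.frame(read_id = names(memb),
                       cluster_id = paste0("CL", memb)), path)
}

#' @rdname write_merges_tsv
#' @export
merge_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  n <- tree$n
  total <- n + nrow(tree$merges)
  label <- c(gsub("[,();: ]", "_", tree$vertex_names),
             rep(NA_character_, nrow(tree$merges)))
  node_str <- as.list(label)
  merged <- logical(total)
  for (t in seq_len(nrow(tree$merges))) {
    u <- tree$merges$u[t]; v <- tree$merges$v[t]
    node_str[[n + t]] <- paste0("(", node_str[[u]], ",", node_str[[v]], ")")
    merged[u] <- TRUE; merged[v] <- TRUE
  }
  roots <- which(!merged)
  body <- if (length(roots) == 1L) node_str[[roots]]
          else paste0("(", paste(unlist(node_str[roots]), collapse = ","), ")")
  paste0(body, ";")
}
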