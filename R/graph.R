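#' Build the read-similarity graph
#'
#' Vertices are reads appearing in at least one admitted overlap; each
#' admitted pair contributes one undirected edge whose weight is the
#' alignment score. Reads with no admitted overlap form the singlet set
#' (presumed single- or low-copy sequences). Duplicate pairs collapse to one
#' edge keeping the maximal weight; orientation and identity are kept as edge
#' attributes but ignored by all graph algorithms.
#'
#' @param rs the deduplicated `read_set` the hits were computed from.
#' @param hits admitted hits from [filter_overlaps()].
#' @return a `similarity_graph`: list with `graph` (an igraph object, vertices
#'   in lexicographic id order), `singlets` (character vector of read ids) and
#'   `n_reads` (reads after deduplication).
#' @export
build_similarity_graph <- function(rs, hits) {
  stopifnot(inherits(rs, "read_set"), is.data.frame(hits))
  ids <- names(rs$seq)
  unknown <- setdiff(unique(c(hits$id_a, hits$id_b)), ids)
  if (length(unknown)) stop("hit references unknown read id: ", unknown[1])
  if (nrow(hits) > 0L && any(hits$id_a == hits$id_b))
    stop("self-hit in admitted overlaps")

  if (nrow(hits) > 0L) {
    a <- pmin(hits$id_a, hits$id_b)
    b <- pmax(hits$id_a, hits$id_b)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -hits$score)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  }
  vertices <- sort(unique(c(hits$id_a, hits$id_b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = hits$id_a, to = hits$id_b, weight = hits$score,
               identity = hits$identity, span = hits$span,
               orientation = hits$orientation, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = vertices))
  structure(list(graph = g, singlets = setdiff(ids, vertices),
                 n_reads = rs$n_retained),
            class = "similarity_graph")
}

as_igraph <- function(g) {
  if (inherits(g, "similarity_graph")) g$graph
  else if (inherits(g, "igraph")) g
  else stop("expected a similarity_graph or igraph object")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", igraph::vcount(x$graph), "vertices,",
      igraph::ecount(x$graph), "edges;", length(x$singlets), "singlets of",
      x$n_reads, "reads\n")
  invisible(x)
}

#' Connected components of the similarity graph
#'
#' Two reads share a component iff a path of admitted overlaps connects them.
#'
#' @param g a `similarity_graph` or igraph object.
#' @return named integer vector: component label (1-based, decreasing size)
#'   per vertex.
#' @export
graph_components <- function(g) {
  g <- as_igraph(g)
  comp <- igraph::components(g)
  # relabel by decreasing size, ties by smallest vertex name for determinism
  first <- tapply(igraph::V(g)$name, comp$membership, min)
  ord <- order(-comp$csize, first)
  relabel <- match(seq_along(comp$csize), ord)
  setNames(relabel[comp$membership], igraph::V(g)$name)
}

#' Graph statistics of a (sub)graph
#'
#' Diameter is the maximal shortest-path hop count (unweighted), density is
#' edges over all possible edges, and mean score / mean identity average the
#' induced edge attributes.
#'
#' @param g a `similarity_graph` or igraph object.
#' @param vertices optional vertex ids defining an induced subgraph (default:
#'   the whole graph). The induced subgraph must be connected.
#' @return a list of class `graph_stats`: `n_vertices`, `n_edges`,
#'   `max_degree`, `diameter`, `density`, `mean_score`, `mean_identity`.
#' @export
graph_stats <- function(g, vertices = NULL) {
  g <- as_igraph(g)
  if (!is.null(vertices)) {
    missing <- setdiff(vertices, igraph::V(g)$name)
    if (length(missing)) stop("unknown vertex: ", missing[1])
    g <- igraph::induced_subgraph(g, vertices)
  }
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty subgraph")
  if (n >= 2L && !igraph::is_connected(g))
    stop("diameter undefined: subgraph is disconnected")
  m <- igraph::ecount(g)
  density <- if (n < 2L) {
    warning("density undefined for a single vertex; reporting 0")
    0
  } else 2 * m / (n * (n - 1))
  diam <- if (n < 2L) 0L
          else as.integer(igraph::diameter(g, weights = NA))
  w <- igraph::E(g)$weight
  idy <- igraph::E(g)$identity
  structure(list(
    n_vertices = n, n_edges = m,
    max_degree = if (n > 0L) max(igraph::degree(g)) else 0L,
    diameter = diam, density = density,
    mean_score = if (m > 0L) mean(w) else NA_real_,
    mean_identity = if (m > 0L && !is.null(idy)) mean(idy) else NA_real_),
    class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(
    "graph_stats: n=%d m=%d max_degree=%d diameter=%d density=%.4f\n",
    x$n_vertices, x$n_edges, x$max_degree, x$diameter, x$density))
  if (!is.na(x$mean_score))
    cat(sprintf("  mean score %.2f, mean identity %.4f\n",
                x$mean_score, x$mean_identity))
  invisible(x)
}

#' Export the similarity graph
#'
#' `write_graphml()` writes GraphML (vertex ids plus edge weight, identity and
#' orientation attributes); `write_edges_tsv()` writes a flat edge list;
#' `write_components_tsv()` writes component membership and the singlet set.
#'
#' @param g a `similarity_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edges_tsv <- function(g, path) {
  ig <- as_igraph(g)
  el <- igraph::as_data_frame(ig, what = "edges")
  write_tsv(el, path)
}

#' @rdname write_graphml
#' @export
write_components_tsv <- function(g, path) {
  comp <- graph_components(g)
  df <- data.frame(read_id = names(comp), component = as.integer(comp))
  if (inherits(g, "similarity_graph") && length(g$singlets))
    df <- rbind(df, data.frame(read_id = g$singlets, component = NA_integer_))
  write_tsv(df, path)
}
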