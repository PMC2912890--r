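#' Deterministic 3D force-directed layout
#'
#' Computes Fruchterman-Reingold coordinates in 3D for a cluster subgraph.
#' Attraction along edges is proportional to the normalized edge weight
#' (weight / max weight in the subgraph), so that strongly similar reads are
#' pulled together; repulsion acts between all vertex pairs. Initial positions
#' and the annealing are driven by the R RNG, so identical
#' (graph, seed, iterations) give identical coordinates.
#'
#' @param g a `similarity_graph` or igraph object.
#' @param vertices optional vertex ids of an induced subgraph.
#' @param seed integer RNG seed.
#' @param iterations number of iterations (> 0).
#' @return numeric matrix (one row per vertex, columns `x`, `y`, `z`,
#'   rownames = read ids) with attributes `seed` and `iterations`; class
#'   `layout_coords`.
#' @export
layout_fr3d <- function(g, vertices = NULL, seed = 1L, iterations = 500L) {
  g <- as_igraph(g)
  if (!is.null(vertices)) {
    missing <- setdiff(vertices, igraph::V(g)$name)
    if (length(missing)) stop("unknown vertex: ", missing[1])
    g <- igraph::induced_subgraph(g, vertices)
  }
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty subgraph")
  if (iterations <= 0L) stop("iterations must be positive")
  if (n == 1L) {
    coords <- matrix(0, 1, 3, dimnames = list(igraph::V(g)$name,
                                              c("x", "y", "z")))
    return(structure(coords, seed = seed, iterations = iterations,
                     class = c("layout_coords", "matrix", "array")))
  }
  w <- igraph::E(g)$weight
  wn <- if (is.null(w) || length(w) == 0L) NULL else w / max(w)
  coords <- with_seed(seed, igraph::layout_with_fr(
    g, dim = 3, niter = iterations, weights = wn))
  dimnames(coords) <- list(igraph::V(g)$name, c("x", "y", "z"))
  structure(coords, seed = seed, iterations = iterations,
            class = c("layout_coords", "matrix", "array"))
}

#' Write layout coordinates as TSV
#'
#' @param coords a `layout_coords` matrix.
#' @param path output TSV path.
#' @param cluster_id optional cluster label(s) recycled across rows.
#' @return the path, invisibly.
#' @export
write_layout_tsv <- function(coords, path, cluster_id = NA_character_) {
  df <- data.frame(read_id = rownames(coords), x = coords[, 1],
                   y = coords[, 2], z = coords[, 3],
                   cluster_id = cluster_id)
  write_tsv(df, path)
}

#' Static 2D projection plot of a cluster layout
#'
#' Plots the (x, y) projection of a 3D layout, optionally colored by a label
#' per read (e.g. cluster or annotation). A non-interactive stand-in for
#' interactive graph browsers.
#'
#' @param coords a `layout_coords` matrix.
#' @param labels optional factor-like vector named by read id.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the coordinates.
#' @export
plot_layout <- function(coords, labels = NULL, ...) {
  col <- "grey30"
  if (!is.null(labels)) {
    f <- as.factor(labels[rownames(coords)])
    col <- grDevices::rainbow(nlevels(f))[as.integer(f)]
  }
  graphics::plot(coords[, 1], coords[, 2], col = col, pch = 19, cex = 0.5,
                 xlab = "x", ylab = "y", asp = 1, ...)
  invisible(coords)
}
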