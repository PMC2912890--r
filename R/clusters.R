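#' Shape-classification thresholds
#'
#' Heuristic thresholds for [classify_cluster_shape()]. They are tuning
#' parameters, not measured constants: the defaults separate well-known
#' exemplars (a short-monomer satellite graph with ~21% density and diameter
#' 6; a long-monomer satellite ring with ~1.7% density and diameter 19; a
#' dispersed LTR-element thread with diameter 62).
#'
#' @param min_size smallest cluster that is classified at all (reads).
#' @param satellite_density,satellite_diameter density/diameter cut for the
#'   dense star-like graphs of satellites with monomer shorter than the read.
#' @param circularity_min eccentricity-ratio threshold above which a graph is
#'   considered ring-like (see [shape_features()]).
#' @param conserved_identity mean edge identity above which a ring is called
#'   a conserved tandem unit (rDNA-like) rather than a diverged satellite.
#' @param linear_diameter absolute diameter above which a graph is called
#'   linear/dispersed even if `0.5 * sqrt(n)` is larger.
#' @return a list of class `shape_config`.
#' @export
shape_config <- function(min_size = 20L, satellite_density = 0.05,
                         satellite_diameter = 10L, circularity_min = 0.85,
                         conserved_identity = 0.96, linear_diameter = 20L) {
  structure(list(min_size = min_size, satellite_density = satellite_density,
                 satellite_diameter = satellite_diameter,
                 circularity_min = circularity_min,
                 conserved_identity = conserved_identity,
                 linear_diameter = linear_diameter),
            class = "shape_config")
}

#' Shape features of a cluster subgraph
#'
#' Computes the features used by [classify_cluster_shape()] beyond the plain
#' graph statistics. Circularity is the mean vertex eccentricity divided by
#' the diameter: every vertex of a cycle has eccentricity equal to the
#' diameter (ratio 1), while a path ranges from diameter/2 at the centre to
#' the diameter at the ends (mean ~0.75), so ring-like read graphs score high
#' and thread-like graphs low.
#'
#' @param g a `similarity_graph` or igraph object.
#' @param vertices optional vertex subset (must induce a connected subgraph).
#' @return list with `circularity` and `mean_identity`.
#' @export
shape_features <- function(g, vertices = NULL) {
  g <- as_igraph(g)
  if (!is.null(vertices)) g <- igraph::induced_subgraph(g, vertices)
  if (igraph::vcount(g) >= 2L && !igraph::is_connected(g))
    stop("shape features undefined: subgraph is disconnected")
  diam <- if (igraph::vcount(g) < 2L) 0 else
    as.numeric(igraph::diameter(g, weights = NA))
  circ <- if (diam > 0)
    mean(igraph::eccentricity(g, weights = NA)) / diam else 0
  idy <- igraph::E(g)$identity
  list(circularity = circ,
       mean_identity = if (length(idy)) mean(idy) else NA_real_)
}

#' Classify a cluster's repeat type from its graph topology
#'
#' Rule cascade on connected-cluster statistics: small clusters are left
#' unclassified; dense small-diameter graphs indicate satellites with monomer
#' shorter than the read (star-like); ring-like graphs (high circularity)
#' indicate tandem units longer than the read, split into conserved
#' (rDNA-like) and diverged satellites by mean edge identity; long-diameter
#' graphs indicate dispersed elements (LTR-retrotransposon-like threads).
#' All thresholds are heuristics exposed in [shape_config()].
#'
#' @param stats a `graph_stats` object for the cluster.
#' @param features output of [shape_features()] (list with `circularity` and
#'   `mean_identity`).
#' @param config a [shape_config()].
#' @return one of `"satellite-short"`, `"ring-tandem"`,
#'   `"circular-conserved"`, `"linear-dispersed"`, `"unclassified"`.
#' @export
classify_cluster_shape <- function(stats, features, config = shape_config()) {
  stopifnot(inherits(stats, "graph_stats"))
  n <- stats$n_vertices
  if (n < config$min_size) return("unclassified")
  if (stats$density >= config$satellite_density &&
      stats$diameter <= config$satellite_diameter)
    return("satellite-short")
  if (isTRUE(features$circularity >= config$circularity_min)) {
    if (isTRUE(features$mean_identity >= config$conserved_identity))
      return("circular-conserved")
    return("ring-tandem")
  }
  if (stats$diameter >= 0.5 * sqrt(n) ||
      stats$diameter >= config$linear_diameter)
    return("linear-dispersed")
  "unclassified"
}

#' Genome proportion of each cluster
#'
#' Under uniform random sampling, the number of reads in a cluster is
#' proportional to the genomic abundance of its repeat family, so cluster
#' size over total analyzed reads estimates the genome fraction.
#'
#' @param cs a `cluster_set`.
#' @param total_reads total reads analyzed (after deduplication; at least the
#'   sum of cluster sizes).
#' @return data.frame ordered by decreasing size: `cluster_id`, `size`,
#'   `genome_fraction`, `cumulative_fraction`.
#' @export
quantify_clusters <- function(cs, total_reads) {
  stopifnot(inherits(cs, "cluster_set"))
  if (total_reads <= 0) stop("total_reads must be positive")
  sizes <- lengths(cs$clusters)
  if (total_reads < sum(sizes))
    stop("total_reads smaller than the number of clustered reads")
  frac <- sizes / total_reads
  data.frame(cluster_id = names(cs$clusters), size = as.integer(sizes),
             genome_fraction = as.numeric(frac),
             cumulative_fraction = cumsum(as.numeric(frac)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Modularity of the best internal division of a cluster
#'
#' Re-runs greedy agglomeration on the induced subgraph of a cluster and
#' returns the modularity of its own best cut: near 0 when the cluster is
#' internally homogeneous, high when it contains separable sub-communities.
#'
#' @param g a `similarity_graph` or igraph object.
#' @param cluster vertex ids of the cluster.
#' @return the internal `Q_best`.
#' @export
internal_modularity <- function(g, cluster) {
  g <- as_igraph(g)
  sub <- igraph::induced_subgraph(g, cluster)
  if (igraph::ecount(sub) < 1L)
    stop("internal modularity undefined for an edgeless subgraph")
  best_cut(greedy_agglomeration(sub))$q_best
}

#' Fraction of reads in a designated graph branch
#'
#' Read-counting in graph branches quantifies structural variants of a repeat
#' family: e.g. reads spanning a deletion junction versus reads following the
#' full-length path over the same region. With an `alternative` branch the
#' denominator is `|subset| + |alternative|` (reads covering the same
#' region); without one it is the whole cluster.
#'
#' @param members cluster member read ids (or a `cluster_set` cluster
#'   element).
#' @param subset read ids of the branch of interest (must lie in `members`).
#' @param alternative optional read ids of the competing branch.
#' @return the fraction in [0, 1].
#' @export
subset_read_fraction <- function(members, subset, alternative = NULL) {
  if (length(setdiff(subset, members)))
    stop("subset contains reads outside the cluster")
  if (!is.null(alternative) && length(setdiff(alternative, members)))
    stop("alternative branch contains reads outside the cluster")
  if (length(subset) == 0L) return(0)
  denom <- if (is.null(alternative)) length(members)
           else length(subset) + length(alternative)
  length(subset) / denom
}

#' Read a repeat reference library
#'
#' FASTA of named reference repeats. The class label is taken from the header
#' after a `#` (RepeatMasker-style `name#class`); headers without `#` use the
#' whole id as class.
#'
#' @param path FASTA path.
#' @return data.frame with `name`, `class`, `seq`.
#' @export
read_repeat_library <- function(path) {
  rs <- load_reads(path, format = "fasta")
  ids <- names(rs$seq)
  has_class <- grepl("#", ids, fixed = TRUE)
  data.frame(name = sub("#.*$", "", ids),
             class = ifelse(has_class, sub("^[^#]*#", "", ids), ids),
             seq = unname(rs$seq), stringsAsFactors = FALSE)
}

#' Annotate clusters against a repeat library
#'
#' Aligns clustered reads against the library with the overlap aligner at
#' relaxed stringency (library sequences diverge from genomic copies), labels
#' each read with the class of its best qualifying hit, and labels each
#' cluster with the class hitting most of its reads. Coverage is measured on
#' the read (not the usually much longer library sequence).
#'
#' @param cs a `cluster_set`.
#' @param rs the `read_set`.
#' @param lib a repeat library from [read_repeat_library()] (or a data.frame
#'   with `name`, `class`, `seq`).
#' @param min_identity,min_cov per-read hit admission thresholds (defaults
#'   0.7 and 0.3).
#' @param word_size seed length for the library search (default 12; shorter
#'   than for read overlaps because more divergence is tolerated).
#' @return data.frame per cluster: `cluster_id`, `annotation` (class or
#'   `"NA"` when fewer than 10% of reads are labeled), `hit_fraction`.
#' @export
annotate_clusters <- function(cs, rs, lib, min_identity = 0.7,
                              min_cov = 0.3, word_size = 12L) {
  stopifnot(inherits(cs, "cluster_set"), inherits(rs, "read_set"))
  if (nrow(lib) == 0L) stop("empty repeat library")
  reads <- unlist(cs$clusters, use.names = FALSE)
  seqs <- unname(rs$seq[reads])
  params <- align_params(word_size = word_size, report_identity = min_identity)
  cand <- .seed_candidates_cpp(seqs, unname(lib$seq), params$word_size, FALSE)
  read_class <- rep(NA_character_, length(reads))
  if (nrow(cand) > 0L) {
    aln <- align_candidates(seqs, unname(lib$seq), cand, params)
    idy <- ifelse(aln$columns > 0, aln$matches / aln$columns, 0)
    cov <- (aln$a_end - aln$a_start + 1L) / nchar(seqs[aln$i])
    ok <- aln$score > 0 & idy >= min_identity & cov >= min_cov
    aln <- aln[ok, , drop = FALSE]
    if (nrow(aln) > 0L) {
      ord <- order(aln$i, -aln$score, aln$j)
      aln <- aln[ord, , drop = FALSE]
      aln <- aln[!duplicated(aln$i), , drop = FALSE]
      read_class[aln$i] <- lib$class[aln$j]
    }
  }
  names(read_class) <- reads
  res <- lapply(names(cs$clusters), function(cl) {
    cls <- read_class[cs$clusters[[cl]]]
    cls <- cls[!is.na(cls)]
    if (length(cls) == 0L)
      return(data.frame(cluster_id = cl, annotation = "NA", hit_fraction = 0))
    tab <- sort(table(cls), decreasing = TRUE)
    frac <- as.numeric(tab[1]) / length(cs$clusters[[cl]])
    data.frame(cluster_id = cl,
               annotation = if (frac < 0.1) "NA" else names(tab)[1],
               hit_fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-cluster characterization records
#'
#' Assembles, for every cluster of a clustering, the full record: graph
#' statistics, internal modularity, shape classification and genome fraction.
#'
#' @param sg the `similarity_graph`.
#' @param cs the `cluster_set`.
#' @param config a [shape_config()].
#' @return data.frame with one row per cluster (columns `cluster_id`, `size`,
#'   `n_edges`, `max_degree`, `diameter`, `density`, `internal_modularity`,
#'   `mean_score`, `mean_identity`, `circularity`, `shape`,
#'   `genome_fraction`, `cumulative_fraction`).
#' @export
cluster_records <- function(sg, cs, config = shape_config()) {
  stopifnot(inherits(sg, "similarity_graph"), inherits(cs, "cluster_set"))
  quant <- quantify_clusters(cs, sg$n_reads)
  g <- sg$graph
  rec <- lapply(names(cs$clusters), function(cl) {
    members <- cs$clusters[[cl]]
    st <- suppressWarnings(graph_stats(g, members))
    feats <- shape_features(g, members)
    qint <- if (st$n_edges >= 1L) internal_modularity(g, members) else NA_real_
    data.frame(cluster_id = cl, size = st$n_vertices, n_edges = st$n_edges,
               max_degree = st$max_degree, diameter = st$diameter,
               density = st$density, internal_modularity = qint,
               mean_score = st$mean_score, mean_identity = st$mean_identity,
               circularity = feats$circularity,
               shape = classify_cluster_shape(st, feats, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  merge(out, quant[, c("cluster_id", "genome_fraction",
                       "cumulative_fraction")],
        by = "cluster_id", sort = FALSE)
}

#' Write the cluster report TSV
#'
#' One row per cluster with the columns of [cluster_records()], optionally
#' merged with annotation results.
#'
#' @param records output of [cluster_records()].
#' @param path output TSV path.
#' @param annotation optional output of [annotate_clusters()].
#' @return the path, invisibly.
#' @export
write_cluster_report <- function(records, path, annotation = NULL) {
  if (!is.null(annotation))
    records <- merge(records, annotation, by = "cluster_id", sort = FALSE)
  write_tsv(records, path)
}

#' Cumulative cluster-size histogram
#'
#' Bar plot of cluster genome proportions against their cumulative share of
#' the reads: bar width and height both encode the cluster size, so the
#' "slope" summarizes how repeat-rich the genome is.
#'
#' @param quant output of [quantify_clusters()] (or [cluster_records()]).
#' @param ... passed to [graphics::rect()].
#' @return invisibly, `quant`.
#' @export
plot_cluster_sizes <- function(quant, ...) {
  x1 <- c(0, head(quant$cumulative_fraction, -1)) * 100
  x2 <- quant$cumulative_fraction * 100
  h <- quant$genome_fraction * 100
  graphics::plot(NULL, xlim = c(0, max(x2)), ylim = c(0, max(h)),
                 xlab = "cumulative % of reads", ylab = "cluster % of reads")
  graphics::rect(x1, 0, x2, h, col = "steelblue", border = "white", ...)
  invisible(quant)
}
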