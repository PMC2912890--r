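#' Cluster shotgun reads into repeat families
#'
#' The whole analysis in one call: exact-duplicate removal, all-to-all
#' overlap detection, edge admission (identity/coverage filter), similarity
#' graph construction, connected components, greedy modularity agglomeration
#' with the maximum-modularity cut, and per-cluster characterization.
#'
#' @param reads a `read_set` or a FASTA/FASTQ path.
#' @param params an [align_params()] object.
#' @param min_identity,min_coverage edge-admission thresholds (defaults 0.90
#'   and 0.55 of the longer read).
#' @param shape a [shape_config()].
#' @param library optional repeat library (see [read_repeat_library()]) for
#'   cluster annotation.
#' @param dedup remove exact duplicate reads first (default TRUE).
#' @param threads workers for the alignment stage (never changes results).
#' @param overlaps optional precomputed hit table (as from [find_overlaps()]
#'   or [read_overlaps()]); skips the alignment stage when supplied.
#' @return an object of class `repeat_clustering`: list with `reads` (the
#'   deduplicated `read_set`), `hits` (admitted overlaps), `graph` (a
#'   `similarity_graph`), `components`, `tree` (the `merge_tree`), `clusters`
#'   (the max-Q `cluster_set`), `records` (per-cluster characterization),
#'   `comparison` (components vs clusters), `annotation` (or NULL) and the
#'   parameters used.
#' @seealso [summary.repeat_clustering()], [plot.repeat_clustering()],
#'   [cluster_layout()]
#' @export
repeat_clustering <- function(reads, params = align_params(),
                              min_identity = 0.90, min_coverage = 0.55,
                              shape = shape_config(), library = NULL,
                              dedup = TRUE, threads = 1L, overlaps = NULL) {
  if (is.character(reads)) reads <- load_reads(reads)
  stopifnot(inherits(reads, "read_set"))
  if (dedup) reads <- dedup_reads(reads)
  all_hits <- if (is.null(overlaps))
    find_overlaps(reads, params, threads = threads) else overlaps
  hits <- filter_overlaps(all_hits, reads, min_identity, min_coverage)
  sg <- build_similarity_graph(reads, hits)

  if (igraph::ecount(sg$graph) >= 1L) {
    comp <- graph_components(sg)
    tree <- greedy_agglomeration(sg)
    cs <- best_cut(tree)
    records <- cluster_records(sg, cs, shape)
    comparison <- compare_partitions(comp, cs)
  } else {
    comp <- setNames(integer(0), character(0))
    tree <- NULL
    cs <- structure(list(clusters = list(),
                         membership = setNames(integer(0), character(0)),
                         q_best = NA_real_, level = 0L),
                    class = "cluster_set")
    records <- NULL
    comparison <- NULL
  }
  annotation <- if (!is.null(library) && length(cs$clusters))
    annotate_clusters(cs, reads, library) else NULL

  structure(list(reads = reads, hits = hits, graph = sg, components = comp,
                 tree = tree, clusters = cs, records = records,
                 comparison = comparison, annotation = annotation,
                 params = list(align = params, min_identity = min_identity,
                               min_coverage = min_coverage, shape = shape)),
            class = "repeat_clustering")
}

#' @export
print.repeat_clustering <- function(x, ...) {
  cat("repeat_clustering of", x$reads$n_retained, "reads\n")
  cat("  graph:", igraph::vcount(x$graph$graph), "vertices,",
      igraph::ecount(x$graph$graph), "edges;",
      length(x$graph$singlets), "singlets\n")
  if (!is.null(x$tree))
    cat("  ", length(unique(x$components)), " component(s) -> ",
        length(x$clusters$clusters), " clusters, Q_best = ",
        format(x$clusters$q_best, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Summarize a repeat clustering
#'
#' @param object a `repeat_clustering`.
#' @param n_top number of largest clusters to tabulate.
#' @param ... unused.
#' @return invisibly, the top-cluster table.
#' @export
summary.repeat_clustering <- function(object, n_top = 10L, ...) {
  print(object)
  if (is.null(object$records)) return(invisible(NULL))
  tab <- head(object$records, n_top)
  if (!is.null(object$annotation))
    tab <- merge(tab, object$annotation, by = "cluster_id", sort = FALSE)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  cat("\nTop clusters:\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' @export
#' @rdname plot_cluster_sizes
#' @param x a `repeat_clustering`.
plot.repeat_clustering <- function(x, ...) {
  if (is.null(x$records)) stop("nothing to plot: no clusters")
  plot_cluster_sizes(x$records, ...)
}

#' Layout of one cluster of a clustering
#'
#' Convenience wrapper around [layout_fr3d()] for a named cluster.
#'
#' @param x a `repeat_clustering`.
#' @param cluster_id cluster name (e.g. `"CL1"`).
#' @param seed,iterations see [layout_fr3d()].
#' @return a `layout_coords` matrix.
#' @export
cluster_layout <- function(x, cluster_id, seed = 1L, iterations = 500L) {
  stopifnot(inherits(x, "repeat_clustering"))
  members <- x$clusters$clusters[[cluster_id]]
  if (is.null(members)) stop("unknown cluster: ", cluster_id)
  layout_fr3d(x$graph, members, seed = seed, iterations = iterations)
}

#' Pipeline run configuration
#'
#' Validated bundle of all tunables plus input/output paths and stage
#' toggles. Defaults are the standard analysis settings: admission at 90%
#' identity over 55% of the longer read, word size 18, hits reported from 85%
#' identity.
#'
#' @param reads input FASTA/FASTQ path.
#' @param out_dir output directory.
#' @param min_identity,min_coverage edge admission thresholds.
#' @param word_size,report_identity aligner settings (see [align_params()]).
#' @param layout_seed,layout_iterations layout stage settings.
#' @param n_layout number of largest clusters to lay out (0 disables).
#' @param annotate_identity,annotate_coverage annotation stringency.
#' @param library optional repeat-library FASTA path.
#' @param shape a [shape_config()].
#' @param threads alignment workers.
#' @param reuse reuse an existing overlap TSV in `out_dir` on restart.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(reads, out_dir, min_identity = 0.90,
                       min_coverage = 0.55, word_size = 18L,
                       report_identity = 0.85, layout_seed = 1L,
                       layout_iterations = 500L, n_layout = 3L,
                       annotate_identity = 0.7, annotate_coverage = 0.3,
                       library = NULL, shape = shape_config(), threads = 1L,
                       reuse = FALSE) {
  for (nm in c("min_identity", "min_coverage", "report_identity",
               "annotate_identity", "annotate_coverage")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config error: ", nm, " must be in [0, 1], got ", v)
  }
  if (word_size < 8 || word_size > 32)
    stop("config error: word_size must be in [8, 32]")
  if (layout_iterations < 1) stop("config error: layout_iterations must be positive")
  structure(list(reads = reads, out_dir = out_dir,
                 min_identity = min_identity, min_coverage = min_coverage,
                 word_size = as.integer(word_size),
                 report_identity = report_identity,
                 layout_seed = as.integer(layout_seed),
                 layout_iterations = as.integer(layout_iterations),
                 n_layout = as.integer(n_layout),
                 annotate_identity = annotate_identity,
                 annotate_coverage = annotate_coverage,
                 library = library, shape = shape,
                 threads = as.integer(threads), reuse = isTRUE(reuse)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; unknown keys are an
#' error. Values given in `overrides` (e.g. from command-line flags) win.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("config error: unknown key ", bad[1])
  do.call(run_config, vals)
}

#' Run the full pipeline and write all artifacts
#'
#' Executes deduplication, overlap detection, edge admission, graph build,
#' components, agglomeration, best cut, cluster characterization, optional
#' annotation and layout, writing every stage artifact plus a machine-readable
#' `report.json` into `config$out_dir`. With `reuse = TRUE` an existing
#' `overlaps_all.tsv` in the output directory is loaded instead of
#' recomputing the alignment stage. Identical config + inputs give identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)

  reads <- dedup_reads(load_reads(config$reads))
  write_reads_fasta(reads, p("reads_retained.fasta"))
  write_dedup_report(reads, p("dedup_report.tsv"))

  params <- align_params(word_size = config$word_size,
                         report_identity = config$report_identity)
  hits_path <- p("overlaps_all.tsv")
  all_hits <- if (config$reuse && file.exists(hits_path)) read_overlaps(hits_path)
              else find_overlaps(reads, params, threads = config$threads)
  write_overlaps(all_hits, hits_path)
  hits <- filter_overlaps(all_hits, reads, config$min_identity,
                          config$min_coverage)
  write_overlaps(hits, p("overlaps_admitted.tsv"))

  library <- if (!is.null(config$library)) read_repeat_library(config$library)
  res <- repeat_clustering(reads, params, config$min_identity,
                           config$min_coverage, shape = config$shape,
                           library = library, dedup = FALSE,
                           overlaps = all_hits)
  sg <- res$graph
  write_edges_tsv(sg, p("edges.tsv"))
  write_graphml(sg, p("graph.graphml"))
  write_components_tsv(sg, p("components.tsv"))
  if (!is.null(res$tree)) {
    write_merges_tsv(res$tree, p("merges.tsv"))
    write_q_curve_tsv(res$tree, p("q_curve.tsv"))
    writeLines(merge_tree_newick(res$tree), p("dendrogram.newick"))
    write_membership_tsv(res$clusters, p("membership.tsv"))
    write_cluster_report(res$records, p("cluster_report.tsv"), res$annotation)
  }
  if (config$n_layout > 0L && length(res$clusters$clusters)) {
    top <- head(names(res$clusters$clusters), config$n_layout)
    for (cl in top) {
      coords <- cluster_layout(res, cl, seed = config$layout_seed,
                               iterations = config$layout_iterations)
      write_layout_tsv(coords, p(paste0("layout_", cl, ".tsv")),
                       cluster_id = cl)
    }
  }

  top_tab <- if (!is.null(res$records)) head(res$records, 10) else NULL
  report <- list(
    n_input = reads$n_input, n_retained = reads$n_retained,
    n_vertices = igraph::vcount(sg$graph), n_edges = igraph::ecount(sg$graph),
    n_singlets = length(sg$singlets),
    n_components = if (length(res$components)) max(res$components) else 0L,
    n_clusters = length(res$clusters$clusters),
    q_best = res$clusters$q_best,
    components_split = if (!is.null(res$comparison)) res$comparison$n_split
                       else 0L,
    top_clusters = top_tab,
    config = config[setdiff(names(config), c("shape"))])
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(res)
}
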