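fake_stats <- function(n, m = NULL, diameter, density, max_degree = 10L) {
  structure(list(n_vertices = n, n_edges = m %||% round(density * n * (n - 1) / 2),
                 max_degree = max_degree, diameter = diameter,
                 density = density, mean_score = 100, mean_identity = 0.95),
            class = "graph_stats")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cluster sizes quantify genome proportions with cumulative totals", {
  cs <- structure(list(clusters = list(CL1 = sprintf("r%03d", 1:300),
                                       CL2 = sprintf("s%03d", 1:200),
                                       CL3 = sprintf("t%03d", 1:100)),
                       membership = NULL, q_best = 0.5, level = 1L),
                  class = "cluster_set")
  q <- quantify_clusters(cs, 1000)
  expect_equal(q$genome_fraction, c(0.3, 0.2, 0.1))
  expect_equal(q$cumulative_fraction, c(0.3, 0.5, 0.6))

  one <- structure(list(clusters = list(CL1 = sprintf("r%03d", 1:250))),
                   class = c("cluster_set"))
  expect_equal(quantify_clusters(one, 5000)$genome_fraction, 0.05)
  expect_error(quantify_clusters(cs, 0), "positive")
  expect_error(quantify_clusters(cs, 10), "smaller")
})

test_that("shape classification reproduces the published exemplar rows", {
  # short-monomer satellite: very dense, tiny diameter, star-like
  sat <- fake_stats(1614, m = 269813, diameter = 6, density = 0.2073,
                    max_degree = 1166)
  expect_equal(classify_cluster_shape(sat, list(circularity = 0.9,
                                                mean_identity = 0.93)),
               "satellite-short")
  # long-monomer satellite: sparse ring
  ring <- fake_stats(737, m = 4536, diameter = 19, density = 0.0167,
                     max_degree = 81)
  expect_equal(classify_cluster_shape(ring, list(circularity = 0.95,
                                                 mean_identity = 0.93)),
               "ring-tandem")
  # dispersed LTR element: long thread
  ltr <- fake_stats(17701, m = 959759, diameter = 62, density = 0.0061,
                    max_degree = 434)
  expect_equal(classify_cluster_shape(ltr, list(circularity = 0.6,
                                                mean_identity = 0.93)),
               "linear-dispersed")
  # conserved tandem unit (rDNA-like): ring of near-identical reads
  rdna <- fake_stats(4209, m = 93866, diameter = 91, density = 0.0106,
                     max_degree = 85)
  expect_equal(classify_cluster_shape(rdna, list(circularity = 0.95,
                                                 mean_identity = 0.985)),
               "circular-conserved")
  # too small to classify
  expect_equal(classify_cluster_shape(fake_stats(10, diameter = 2,
                                                 density = 0.9),
                                      list(circularity = 0.5,
                                           mean_identity = 0.9)),
               "unclassified")
})

test_that("eccentricity-ratio circularity separates cycles from paths", {
  ring <- shape_features(cycle_graph(30))
  thread <- shape_features(path_graph(30))
  expect_gt(ring$circularity, 0.99)
  expect_lt(thread$circularity, 0.8)
  expect_error(shape_features(toy_graph(rbind(c(1, 2), c(3, 4)))),
               "disconnected")
})

test_that("internal modularity re-divides induced subgraphs", {
  tt <- two_triangles()
  expect_equal(internal_modularity(tt, sprintf("v%02d", 1:6)), 5 / 14)
  k4 <- complete_graph(4)
  expect_equal(internal_modularity(k4, sprintf("v%02d", 1:4)), 0,
               tolerance = 1e-12)
  p4 <- path_graph(4)
  expect_equal(internal_modularity(p4, sprintf("v%02d", 1:4)), 1 / 6)
  expect_error(internal_modularity(tt, c("v01")), "edgeless")
})

test_that("branch read fractions follow the two denominator modes", {
  members <- sprintf("r%03d", 1:200)
  expect_equal(subset_read_fraction(members, members[1:13], members[14:100]),
               0.13)
  expect_equal(subset_read_fraction(members, character(0)), 0)
  expect_equal(subset_read_fraction(members, members[1:20]), 0.1)
  expect_error(subset_read_fraction(members, "zzz"), "outside the cluster")
})

test_that("cluster records assemble stats, shapes and fractions coherently", {
  rsim <- small_sim_reads(seed = 41)
  res <- repeat_clustering(rsim$reads)
  rec <- res$records
  expect_true(all(rec$size == lengths(res$clusters$clusters)))
  expect_equal(rec$genome_fraction, rec$size / res$reads$n_retained)
  # cluster fractions plus singlet fraction account for every read
  expect_equal(sum(rec$genome_fraction) +
                 length(res$graph$singlets) / res$reads$n_retained,
               1, tolerance = 1e-9)
})

test_that("annotation labels clusters by majority library class", {
  fams <- list(repeat_family("satellite", "SATA", unit_length = 60,
                             copies = 100, divergence = 0.02))
  sim <- simulate_genome(fams, 3e4, seed = 51)
  rsim <- sample_reads(sim, coverage = 0.15, read_length = 100,
                       error_rate = 0.01, seed = 51)
  res <- repeat_clustering(rsim$reads)
  truth <- setNames(rsim$truth$family, rsim$truth$read_id)
  # library containing the (approximate) monomer, RepeatMasker-style header
  mono_start <- sim$features$start[1]
  monomer <- substr(sim$genome, mono_start, mono_start + 59)
  lib <- data.frame(name = "SATA_cons", class = "satellite",
                    seq = paste(rep(monomer, 3), collapse = ""))
  ann <- annotate_clusters(res$clusters, res$reads, lib)
  sat_cl <- names(res$clusters$clusters)[vapply(
    res$clusters$clusters,
    function(m) mean(truth[m] == "SATA") > 0.5, TRUE)][1]
  row <- ann[ann$cluster_id == sat_cl, ]
  expect_equal(row$annotation, "satellite")
  expect_gte(row$hit_fraction, 0.9)

  # unrelated library: no qualifying hits anywhere
  lib2 <- data.frame(name = "other", class = "Ty1/copia",
                     seq = rand_dna(2000, seed = 99))
  ann2 <- annotate_clusters(res$clusters, res$reads, lib2)
  expect_true(all(ann2$annotation == "NA"))
  expect_error(annotate_clusters(res$clusters, res$reads, lib[0, ]), "empty")
})

test_that("repeat libraries parse RepeatMasker-style class suffixes", {
  fa <- write_fasta_text(c(`ANGELA#Ty1/copia` = "ACGTACGTACGT",
                           PLAIN = "GGGGCCCC"),
                         withr::local_tempfile(fileext = ".fasta"))
  lib <- read_repeat_library(fa)
  expect_equal(lib$name, c("ANGELA", "PLAIN"))
  expect_equal(lib$class, c("Ty1/copia", "PLAIN"))
})
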