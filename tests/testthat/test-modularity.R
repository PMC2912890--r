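test_that("edge_probability evaluates the analytic null term", {
  expect_equal(edge_probability(2, 2, 3), 4 / 6)
  expect_equal(edge_probability(0, 5, 3), 0)
  expect_equal(edge_probability(3, 7, 7), 1.5)  # expectation, may exceed 1
  expect_error(edge_probability(1, 1, 0), "m must be")
})

test_that("modularity matches hand-derived values on worked graphs", {
  expect_identical(compute_modularity(complete_graph(3), rep(1, 3)), 0)
  expect_equal(compute_modularity(complete_graph(3), 1:3), -1 / 3)
  tt <- two_triangles()
  expect_equal(compute_modularity(tt, c(1, 1, 1, 2, 2, 2)), 5 / 14)
  expect_error(compute_modularity(tt, c(v01 = 1)), "missing|cover")
  expect_error(compute_modularity(toy_graph(matrix(0, 0, 2), n = 3), rep(1, 3)),
               "edgeless")
})

test_that("modularity equals the double-sum oracle and igraph on random graphs", {
  for (s in 1:25) {
    g <- random_test_graph(sample(5:20, 1), runif(1, 0.1, 0.5), seed = s)
    memb <- repeatgraph:::with_seed(
      s + 500, sample(1:3, igraph::vcount(g), replace = TRUE))
    q <- compute_modularity(g, memb)
    expect_equal(q, modularity_double_sum(g, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, as.integer(factor(memb))),
                 tolerance = 1e-12)
    expect_identical(compute_modularity(g, rep(1, igraph::vcount(g))), 0)
  }
})

test_that("greedy agglomeration recovers the optimal cut on worked graphs", {
  tt <- two_triangles()
  bc <- best_cut(greedy_agglomeration(tt))
  expect_equal(length(bc$clusters), 2L)
  expect_equal(sort(unname(lengths(bc$clusters))), c(3L, 3L))
  expect_equal(bc$q_best, 5 / 14)
  ex <- exhaustive_max_q(tt)
  expect_equal(bc$q_best, ex$q)
  expect_setequal(bc$clusters[[1]], c("v01", "v02", "v03"))

  p4 <- path_graph(4)
  bc4 <- best_cut(greedy_agglomeration(p4))
  expect_equal(bc4$q_best, 1 / 6)
  expect_equal(lengths(bc4$clusters), c(CL1 = 2L, CL2 = 2L))
  expect_equal(bc4$q_best, exhaustive_max_q(p4)$q)

  k3 <- complete_graph(3)
  bck3 <- best_cut(greedy_agglomeration(k3))
  expect_equal(length(bck3$clusters), 1L)  # tie at Q=0 resolved to coarser
  expect_equal(bck3$q_best, 0, tolerance = 1e-12)

  bck4 <- best_cut(greedy_agglomeration(complete_graph(4)))
  expect_equal(length(bck4$clusters), 1L)
  expect_equal(bck4$q_best, 0, tolerance = 1e-12)

  expect_error(greedy_agglomeration(toy_graph(matrix(0, 0, 2), n = 2)),
               "edgeless|empty")
})

test_that("greedy Q never exceeds the exhaustive maximum on small graphs", {
  for (s in 1:40) {
    g <- random_test_graph(sample(4:7, 1), runif(1, 0.3, 0.8), seed = s + 100)
    bc <- best_cut(greedy_agglomeration(g))
    expect_lte(bc$q_best, exhaustive_max_q(g)$q + 1e-12)
  }
})

test_that("incremental Q matches from-scratch recomputation after every merge", {
  for (s in 1:8) {
    g <- random_test_graph(sample(20:50, 1), runif(1, 0.05, 0.25),
                           seed = s + 300)
    tree <- greedy_agglomeration(g)
    expect_equal(tree$q0,
                 compute_modularity(g, partition_at_level(tree, 0)),
                 tolerance = 1e-10)
    for (lev in seq_len(nrow(tree$merges))) {
      expect_equal(tree$merges$q_after[lev],
                   compute_modularity(g, partition_at_level(tree, lev)),
                   tolerance = 1e-10)
    }
    # Q_after bookkeeping is internally additive
    expect_equal(tree$merges$q_after,
                 tree$q0 + cumsum(tree$merges$dq), tolerance = 1e-12)
  }
})

test_that("merges stay within components and count n - #components", {
  for (s in 1:10) {
    g <- random_test_graph(sample(8:25, 1), runif(1, 0.05, 0.3), seed = s + 700)
    tree <- greedy_agglomeration(g)
    ncomp <- igraph::count_components(g)
    expect_equal(nrow(tree$merges), igraph::vcount(g) - ncomp)
    bc <- best_cut(tree)
    comp <- graph_components(g)
    rep_cmp <- compare_partitions(comp, bc)
    expect_equal(sum(rep_cmp$table$n_clusters), length(bc$clusters))
    expect_equal(sum(lengths(bc$clusters)), igraph::vcount(g))
  }
})

test_that("partition comparison reports split and identical components", {
  tt <- two_triangles()
  rep1 <- compare_partitions(graph_components(tt),
                             best_cut(greedy_agglomeration(tt)))
  expect_equal(rep1$n_split, 1L)
  expect_equal(rep1$table$n_clusters, 2L)

  k4 <- complete_graph(4)
  rep2 <- compare_partitions(graph_components(k4),
                             best_cut(greedy_agglomeration(k4)))
  expect_equal(rep2$n_identical, 1L)

  # two disjoint K4s: each component equals its cluster
  el <- rbind(t(utils::combn(4, 2)), t(utils::combn(4, 2)) + 4L)
  g2 <- toy_graph(el)
  rep3 <- compare_partitions(graph_components(g2),
                             best_cut(greedy_agglomeration(g2)))
  expect_equal(rep3$n_identical, 2L)
  expect_equal(rep3$n_split, 0L)
})

test_that("best_cut picks the argmax level, preferring fewer communities", {
  tree <- structure(list(
    merges = data.frame(step = 1:3, u = c(1L, 3L, 5L), v = c(2L, 4L, 6L),
                        dq = c(0.3, 0.2, -0.05),
                        q_after = c(0.1, 0.3, 0.25)),
    q0 = -0.2, n = 4L, vertex_names = paste0("v", 1:4), n_components = 1L),
    class = "merge_tree")
  # synthetic Q sequence [-0.2, 0.1, 0.3, 0.25]: cut after step 2
  bc <- best_cut(tree)
  expect_equal(bc$level, 2L)
  expect_equal(bc$q_best, 0.3)
  expect_equal(lengths(bc$clusters), c(CL1 = 2L, CL2 = 2L))
  expect_setequal(bc$clusters$CL1, c("v1", "v2"))
})

test_that("the dendrogram exports to Newick readable by ape", {
  tt <- two_triangles()
  nwk <- merge_tree_newick(greedy_agglomeration(tt))
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines(nwk, tf)
  tr <- ape::read.tree(tf)
  expect_equal(sort(tr$tip.label), sprintf("v%02d", 1:6))
})
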