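test_that("genome and read simulation are deterministic in the seed", {
  fams <- default_repeat_families(2e5)
  g1 <- simulate_genome(fams, 2e5, seed = 9)
  g2 <- simulate_genome(fams, 2e5, seed = 9)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$features, g2$features)
  g3 <- simulate_genome(fams, 2e5, seed = 10)
  expect_false(identical(g1$genome, g3$genome))

  r1 <- sample_reads(g1, 0.05, 100, error_rate = 0.01, seed = 4)
  r2 <- sample_reads(g1, 0.05, 100, error_rate = 0.01, seed = 4)
  expect_identical(r1$reads$seq, r2$reads$seq)
  expect_identical(r1$truth, r2$truth)
})

test_that("family sizes, read counts and deletion counts follow the spec arithmetic", {
  fams <- list(repeat_family("satellite", "S", unit_length = 50,
                             copies = 1000, divergence = 0.02))
  sim <- simulate_genome(fams, 1e6, seed = 1)
  expect_equal(sim$family_table$true_fraction, 0.05)  # 50 kb of 1 Mb
  expect_equal(sim$family_table$total_length, 50000L)

  rsim <- sample_reads(sim, coverage = 0.05, read_length = 100, seed = 1)
  expect_equal(length(rsim$reads), 500L)  # round(0.05 * 1e6 / 100)

  del <- repeat_family("ltr_element", "L", unit_length = 5000, copies = 200,
                       divergence = 0.01, ltr_length = 600,
                       deletions = data.frame(start = 3000, length = 500,
                                              fraction = 0.13))
  gsim <- simulate_genome(list(del), 1.2e6, seed = 2)
  feats <- gsim$features[gsim$features$family == "L", ]
  expect_equal(sum(feats$variant == 1L), 26L)  # round(0.13 * 200)
  # deletion variants are 500 nt shorter
  expect_equal(unique(feats$end[feats$variant == 1L] -
                        feats$start[feats$variant == 1L] + 1L), 4500L)
  expect_equal(unique(feats$end[feats$variant == 0L] -
                        feats$start[feats$variant == 0L] + 1L), 5000L)
})

test_that("error-free reads are exact genome substrings on the right strand", {
  fams <- list(repeat_family("satellite", "S", unit_length = 50, copies = 400,
                             divergence = 0.02))
  sim <- simulate_genome(fams, 1e5, seed = 3)
  rsim <- sample_reads(sim, coverage = 0.05, read_length = 80,
                       error_rate = 0, seed = 3)
  tr <- rsim$truth
  for (k in head(seq_len(nrow(tr)), 20)) {
    sub <- substr(sim$genome, tr$start[k], tr$end[k])
    got <- rsim$reads$seq[[tr$read_id[k]]]
    expect_identical(got, if (tr$strand[k] == "+") sub else revcomp(sub))
  }
})

test_that("read counts per family follow genomic abundance binomially", {
  fams <- list(repeat_family("satellite", "S", unit_length = 100,
                             copies = 1000, divergence = 0.01))  # 10% of 1 Mb
  sim <- simulate_genome(fams, 1e6, seed = 5)
  rsim <- sample_reads(sim, coverage = 0.2, read_length = 100, seed = 5)
  n <- length(rsim$reads)
  frac <- mean(rsim$truth$family == "S")
  p <- sim$family_table$true_fraction
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("LTR copies carry identical terminal repeats within a copy", {
  fams <- list(repeat_family("ltr_element", "L", unit_length = 2000,
                             copies = 3, divergence = 0.05, ltr_length = 300))
  sim <- simulate_genome(fams, 1e4, seed = 6)
  feats <- sim$features[sim$features$family == "L", ]
  for (k in seq_len(nrow(feats))) {
    copy <- substr(sim$genome, feats$start[k], feats$end[k])
    expect_identical(substr(copy, 1, 300), substr(copy, 1701, 2000))
  }
})

test_that("satellite and dispersed-element clusters differ in topology as expected", {
  # short-monomer satellites give dense star graphs; elements much longer
  # than the read give sparse elongated graphs; long monomers give rings
  # with diameters between the two
  seeds <- 1:10
  ok_density <- ok_diam <- ok_ring <- logical(0)
  for (s in seeds) {
    sc <- run_default_scenario(s)
    sat50 <- cluster_stat_row(sc$res, family_cluster(sc$res, sc$truth, "SAT50"))
    sat510 <- cluster_stat_row(sc$res, family_cluster(sc$res, sc$truth, "SAT510"))
    ltr <- cluster_stat_row(sc$res, family_cluster(sc$res, sc$truth, "LTR5K"))
    if (nrow(sat50) == 0 || nrow(sat510) == 0 || nrow(ltr) == 0) next
    ok_density <- c(ok_density, sat50$density > ltr$density)
    ok_diam <- c(ok_diam, sat50$diameter < ltr$diameter)
    ok_ring <- c(ok_ring, sat510$diameter > sat50$diameter)
  }
  expect_gte(length(ok_density), 8)
  expect_true(all(ok_density))
  expect_true(all(ok_diam))
  expect_true(all(ok_ring))
})

test_that("simulation artifacts are written keyed by seed", {
  fams <- list(repeat_family("satellite", "S", unit_length = 60, copies = 50,
                             divergence = 0.02))
  sim <- simulate_genome(fams, 2e4, seed = 12)
  rsim <- sample_reads(sim, coverage = 0.1, read_length = 100, seed = 12)
  dir <- withr::local_tempdir()
  write_simulation(sim, rsim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fasta", "reads.fasta", "truth.tsv", "families.tsv")))))
  reads_back <- load_reads(file.path(dir, "reads.fasta"))
  expect_identical(reads_back$seq, rsim$reads$seq)
  expect_true(all(grepl("^sim12_", names(reads_back$seq))))
})
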