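# shared simulation scenarios for end-to-end tests

run_default_scenario <- function(seed, genome_length = 2e6, coverage = 0.1) {
  sim <- simulate_genome(default_repeat_families(genome_length),
                         genome_length, seed = seed)
  rsim <- sample_reads(sim, coverage = coverage, read_length = 100,
                       error_rate = 0.01, seed = seed)
  res <- repeat_clustering(rsim$reads)
  list(sim = sim, rsim = rsim, res = res,
       truth = setNames(rsim$truth$family, rsim$truth$read_id))
}

# largest cluster whose majority truth label is the given family
family_cluster <- function(res, truth, family) {
  hit <- vapply(res$clusters$clusters,
                function(m) mean(truth[m] == family) > 0.5, TRUE)
  ids <- names(res$clusters$clusters)[hit]
  if (!length(ids)) return(NULL)
  ids[which.max(lengths(res$clusters$clusters[ids]))]
}

cluster_stat_row <- function(res, cluster_id) {
  res$records[res$records$cluster_id == cluster_id, , drop = FALSE]
}

# ARI of the clustering against family truth, over clustered reads that
# originate from a simulated repeat family (background reads carry no family
# identity and are excluded from the recovery question)
family_recovery_ari <- function(res, truth, families) {
  memb <- res$clusters$membership
  keep <- names(memb)[truth[names(memb)] %in% families]
  mclust::adjustedRandIndex(memb[keep], truth[keep])
}
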