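# sequence fixtures and the independent full local-alignment oracle

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else repeatgraph:::with_seed(seed, draw())
}

write_fasta_text <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

write_fastq_text <- function(seqs, path) {
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      paste(rep("I", n), collapse = ""), "")),
             path)
  path
}

# does any exact w-mer occur in both reads (either strand of b)?
shares_kmer <- function(a, b, w = 18L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < w) return(character(0))
    unique(substring(s, 1:(n - w + 1), w:n))
  }
  ka <- kmers(a)
  any(ka %in% kmers(b)) || any(ka %in% kmers(repeatgraph::revcomp(b)))
}

# full Smith-Waterman oracle via Biostrings, same scoring scheme as the
# package aligner (match +1, mismatch -3, gap of length L costs 5 + 2L);
# tries both orientations and returns the better one
oracle_align <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                                     baseOnly = TRUE)
  one <- function(bb) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(bb), type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    list(score = Biostrings::score(aln),
         matches = Biostrings::nmatch(aln),
         columns = Biostrings::nchar(aln),
         fp_a = Biostrings::width(Biostrings::pattern(aln)),
         fp_b = Biostrings::width(Biostrings::subject(aln)))
  }
  fwd <- one(b)
  rev <- one(repeatgraph::revcomp(b))
  if (rev$score > fwd$score) c(rev, orientation = "reverse-complement")
  else c(fwd, orientation = "forward")
}

# admitted pair set according to the oracle, under the identity/coverage rule
oracle_admitted <- function(rs, min_identity = 0.90, min_cov = 0.55,
                            word_size = 18L) {
  ids <- names(rs$seq)
  out <- character(0)
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- rs$seq[[ids[j]]]; b <- rs$seq[[ids[i]]]
    if (!shares_kmer(a, b, word_size)) next
    o <- oracle_align(a, b)
    if (o$score <= 0) next
    identity <- o$matches / o$columns
    longer <- max(nchar(a), nchar(b))
    span <- if (nchar(a) > nchar(b)) o$fp_a
            else if (nchar(b) > nchar(a)) o$fp_b else max(o$fp_a, o$fp_b)
    if (identity >= min_identity && span / longer >= min_cov)
      out <- c(out, paste(ids[j], ids[i]))
  }
  sort(out)
}

# small simulated read set with genuine overlaps: one 60 bp satellite plus
# background in a 30 kb genome
small_sim_reads <- function(seed, n_target = 40) {
  fams <- list(repeat_family("satellite", "SATX", unit_length = 60,
                             copies = 80, divergence = 0.02))
  sim <- simulate_genome(fams, 3e4, seed = seed)
  rsim <- sample_reads(sim, coverage = n_target * 100 / 3e4,
                       read_length = 100, error_rate = 0.01, seed = seed)
  rsim
}
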