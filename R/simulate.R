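# Synthetic genome and low-pass read simulation with per-read truth labels.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute a Binomial(n, rate) number of positions with a different base
mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  n <- length(chars)
  k <- rbinom(1, n, rate)
  if (k == 0) return(chars)
  pos <- sample.int(n, k)
  bases <- c("A", "C", "G", "T")
  repl <- vapply(chars[pos],
                 function(b) sample(setdiff(bases, b), 1), "", USE.NAMES = FALSE)
  chars[pos] <- repl
  chars
}

#' Describe a repeat family for simulation
#'
#' @param kind `"satellite"` (tandem array of monomers), `"ltr_element"`
#'   (dispersed element with identical terminal repeats per copy) or
#'   `"rdna_like"` (tandem array of long, highly conserved units).
#' @param name family name used in truth labels.
#' @param unit_length monomer length (tandem kinds) or full element length
#'   including both LTRs (`ltr_element`), in nt.
#' @param copies number of genomic copies.
#' @param divergence per-base substitution probability applied independently
#'   to each copy (0 to 0.2).
#' @param ltr_length terminal-repeat length for `ltr_element` (nt).
#' @param deletions for `ltr_element`: data.frame with columns `start`,
#'   `length`, `fraction` describing internal deletion variants; each variant
#'   is carried by `round(fraction * copies)` copies.
#' @return a list of class `repeat_family`.
#' @export
repeat_family <- function(kind = c("satellite", "ltr_element", "rdna_like"),
                          name, unit_length, copies, divergence = 0.02,
                          ltr_length = NULL, deletions = NULL) {
  kind <- match.arg(kind)
  stopifnot(unit_length >= 1, copies >= 1, divergence >= 0, divergence <= 0.2)
  if (kind == "ltr_element") {
    if (is.null(ltr_length)) stop("ltr_element requires ltr_length")
    stopifnot(2 * ltr_length < unit_length)
  }
  if (!is.null(deletions)) {
    stopifnot(kind == "ltr_element",
              all(c("start", "length", "fraction") %in% names(deletions)),
              all(deletions$fraction >= 0), sum(deletions$fraction) <= 1,
              all(deletions$start > 1),
              all(deletions$start + deletions$length - 1 < unit_length))
  }
  structure(list(kind = kind, name = name,
                 unit_length = as.integer(unit_length),
                 copies = as.integer(copies), divergence = divergence,
                 ltr_length = if (is.null(ltr_length)) NULL
                              else as.integer(ltr_length),
                 deletions = deletions),
            class = "repeat_family")
}

# one copy of an LTR element: identical mutated LTR at both ends,
# independently mutated internal region, then optional deletion
ltr_copy <- function(ltr_cons, int_cons, divergence, deletion = NULL) {
  ltr <- mutate_seq(ltr_cons, divergence)
  int <- mutate_seq(int_cons, divergence)
  seq <- c(ltr, int, ltr)
  if (!is.null(deletion)) {
    drop <- seq(deletion$start, deletion$start + deletion$length - 1L)
    seq <- seq[-drop]
  }
  seq
}

#' Build a synthetic genome with known repeat structure
#'
#' Satellite and rDNA-like families are placed as single tandem arrays of
#' independently diverged unit copies; LTR-element copies are dispersed
#' individually; the remaining length is filled with i.i.d. uniform
#' single-copy background split randomly around the repeat blocks.
#' Deterministic for fixed `(families, genome_length, seed)`.
#'
#' @param families list of [repeat_family()] specifications.
#' @param genome_length total genome length in nt.
#' @param seed integer RNG seed.
#' @return a `genome_sim`: list with `genome` (one string), `features`
#'   (data.frame `family`, `copy`, `variant`, `start`, `end`), `family_table`
#'   (per-family copies and true genome fraction), `genome_length`, `seed`,
#'   `families`.
#' @export
simulate_genome <- function(families, genome_length, seed = 1L) {
  if (inherits(families, "repeat_family")) families <- list(families)
  stopifnot(length(families) > 0)
  with_seed(seed, {
    blocks <- list()  # each: list(family, copy, variant, chars)
    for (fam in families) {
      if (fam$kind %in% c("satellite", "rdna_like")) {
        cons <- strsplit(rand_seq(fam$unit_length), "")[[1]]
        arr <- lapply(seq_len(fam$copies), function(cp)
          list(family = fam$name, copy = cp, variant = 0L,
               chars = mutate_seq(cons, fam$divergence)))
        blocks <- c(blocks, list(arr))  # one tandem block of copies
      } else {
        ltr_cons <- strsplit(rand_seq(fam$ltr_length), "")[[1]]
        int_cons <- strsplit(
          rand_seq(fam$unit_length - 2L * fam$ltr_length), "")[[1]]
        variant_of <- rep(0L, fam$copies)
        if (!is.null(fam$deletions)) {
          pool <- sample.int(fam$copies)
          taken <- 0L
          for (d in seq_len(nrow(fam$deletions))) {
            nv <- round(fam$deletions$fraction[d] * fam$copies)
            if (nv > 0) {
              variant_of[pool[(taken + 1L):(taken + nv)]] <- d
              taken <- taken + nv
            }
          }
        }
        for (cp in seq_len(fam$copies)) {
          del <- if (variant_of[cp] > 0L)
            fam$deletions[variant_of[cp], ] else NULL
          blocks <- c(blocks, list(list(list(
            family = fam$name, copy = cp, variant = variant_of[cp],
            chars = ltr_copy(ltr_cons, int_cons, fam$divergence, del)))))
        }
      }
    }
    repeat_len <- sum(vapply(blocks, function(b)
      sum(vapply(b, function(x) length(x$chars), 0L)), 0))
    bg_len <- genome_length - repeat_len
    if (bg_len < 0) stop("families exceed the requested genome length")

    nb <- length(blocks)
    order_blocks <- sample.int(nb)
    # split background into nb + 1 random chunks
    cuts <- sort(sample.int(bg_len + 1L, nb, replace = TRUE) - 1L)
    chunk_len <- diff(c(0L, cuts, bg_len))

    pieces <- character(2L * nb + 1L)
    feats <- vector("list", nb)
    pos <- 0L
    for (k in seq_len(nb)) {
      pieces[2L * k - 1L] <- rand_seq(chunk_len[k])
      pos <- pos + chunk_len[k]
      blk <- blocks[[order_blocks[k]]]
      rows <- lapply(blk, function(x) {
        st <- pos + 1L
        pos <<- pos + length(x$chars)
        data.frame(family = x$family, copy = x$copy, variant = x$variant,
                   start = st, end = pos, stringsAsFactors = FALSE)
      })
      feats[[k]] <- do.call(rbind, rows)
      pieces[2L * k] <- paste(unlist(lapply(blk, `[[`, "chars")),
                              collapse = "")
    }
    pieces[2L * nb + 1L] <- rand_seq(chunk_len[nb + 1L])
    genome <- paste(pieces, collapse = "")
    features <- do.call(rbind, feats)
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL

    fam_len <- tapply(features$end - features$start + 1L, features$family, sum)
    family_table <- data.frame(
      family = names(fam_len),
      copies = as.integer(table(features$family)[names(fam_len)]),
      total_length = as.integer(fam_len),
      true_fraction = as.numeric(fam_len) / genome_length,
      stringsAsFactors = FALSE)
    structure(list(genome = genome, features = features,
                   family_table = family_table,
                   genome_length = as.integer(genome_length),
                   seed = as.integer(seed), families = families),
              class = "genome_sim")
  })
}

#' @export
print.genome_sim <- function(x, ...) {
  cat("genome_sim:", x$genome_length, "nt, seed", x$seed, "\n")
  print(x$family_table)
  invisible(x)
}

#' Sample low-pass shotgun reads from a simulated genome
#'
#' Reads are drawn uniformly over start positions and strands;
#' `round(coverage * genome_length / read_length)` reads of fixed length are
#' emitted, minus-strand reads reverse-complemented, and substitution errors
#' applied i.i.d. per base. Each read's truth record gives the repeat family
#' (or `"background"`) covering its midpoint, the copy and variant indices,
#' and genomic coordinates.
#'
#' @param sim a `genome_sim`.
#' @param coverage genome coverage (e.g. 0.1 for low-pass sampling).
#' @param read_length fixed read length in nt.
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return a `read_sim`: list with `reads` (a `read_set`) and `truth`
#'   (data.frame `read_id`, `family`, `copy`, `variant`, `start`, `end`,
#'   `strand`).
#' @export
sample_reads <- function(sim, coverage, read_length, error_rate = 0.01,
                         seed = 1L) {
  stopifnot(inherits(sim, "genome_sim"), coverage > 0,
            read_length <= sim$genome_length, error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    n_reads <- round(coverage * sim$genome_length / read_length)
    starts <- sample.int(sim$genome_length - read_length + 1L, n_reads,
                         replace = TRUE)
    ends <- starts + as.integer(read_length) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(sim$genome, starts, ends)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      k <- rbinom(n_reads, read_length, error_rate)
      idx <- which(k > 0)
      bases <- c("A", "C", "G", "T")
      for (i in idx) {
        chars <- strsplit(seqs[i], "")[[1]]
        pos <- sample.int(read_length, k[i])
        chars[pos] <- vapply(chars[pos],
                             function(b) sample(setdiff(bases, b), 1), "",
                             USE.NAMES = FALSE)
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    ids <- sprintf("sim%d_r%06d", sim$seed, seq_len(n_reads))
    names(seqs) <- ids

    # truth: repeat feature covering the read midpoint, else background
    mid <- starts + (as.integer(read_length) - 1L) %/% 2L
    fi <- findInterval(mid, sim$features$start)
    hit <- fi > 0 & mid <= sim$features$end[pmax(fi, 1L)]
    truth <- data.frame(
      read_id = ids,
      family = ifelse(hit, sim$features$family[pmax(fi, 1L)], "background"),
      copy = ifelse(hit, sim$features$copy[pmax(fi, 1L)], NA_integer_),
      variant = ifelse(hit, sim$features$variant[pmax(fi, 1L)], NA_integer_),
      start = starts, end = ends, strand = strand, stringsAsFactors = FALSE)
    structure(list(reads = read_set(seqs), truth = truth,
                   coverage = coverage, read_length = as.integer(read_length),
                   error_rate = error_rate, seed = as.integer(seed)),
              class = "read_sim")
  })
}

#' Reads spanning a deletion breakpoint
#'
#' For an LTR family simulated with deletion variants, returns the reads that
#' span the deletion junction in variant copies (`junction`) and the reads
#' that span the corresponding breakpoint position in full-length copies
#' (`full`), each requiring at least `flank` nt on both sides. Their relative
#' counts estimate the variant fraction via [subset_read_fraction()],
#' mirroring read-counting in the loops of a cluster graph.
#'
#' @param sim the `genome_sim`.
#' @param rsim the `read_sim` drawn from it.
#' @param family the LTR family name.
#' @param deletion which deletion variant (row of the family's `deletions`).
#' @param flank minimal anchoring on each side of the breakpoint (nt).
#' @return list with character vectors `junction` and `full`.
#' @export
breakpoint_reads <- function(sim, rsim, family, deletion = 1L, flank = 20L) {
  stopifnot(inherits(sim, "genome_sim"), inherits(rsim, "read_sim"))
  fam <- NULL
  for (f in sim$families) if (f$name == family) fam <- f
  if (is.null(fam) || is.null(fam$deletions))
    stop("family with deletion variants not found: ", family)
  del_start <- fam$deletions$start[deletion]

  feats <- sim$features[sim$features$family == family, , drop = FALSE]
  copy_start <- setNames(feats$start, feats$copy)
  tr <- rsim$truth[rsim$truth$family == family, , drop = FALSE]
  # genome position of the last base before the breakpoint, per copy
  bp <- copy_start[as.character(tr$copy)] + del_start - 1L
  spans <- tr$start <= bp - flank + 1L & tr$end >= bp + flank
  list(junction = tr$read_id[spans & tr$variant == deletion],
       full = tr$read_id[spans & tr$variant == 0L])
}

#' Reference simulation scenarios
#'
#' `default_repeat_families()` is the package's standard test genome: a
#' short-monomer satellite (50 bp, star-like graph expected), a long-monomer
#' satellite (510 bp, monomer much longer than a 100 nt read, ring-like graph
#' expected) and a dispersed 5 kb LTR-like element, at 8%, 6% and 4% of a
#' 2 Mb genome, with ~2% copy divergence (1% for the younger LTR family); the
#' rest is single-copy background. `deletion_variant_families()` is a
#' focused variant-quantification genome: one abundant 5 kb LTR family in
#' which 13% of copies carry a 500 nt internal deletion.
#'
#' @param genome_length genome length the copy numbers are scaled to.
#' @return list of [repeat_family()] objects.
#' @export
default_repeat_families <- function(genome_length = 2e6) {
  list(
    repeat_family("satellite", "SAT50", unit_length = 50,
                  copies = round(0.08 * genome_length / 50),
                  divergence = 0.02),
    repeat_family("satellite", "SAT510", unit_length = 510,
                  copies = round(0.06 * genome_length / 510),
                  divergence = 0.02),
    repeat_family("ltr_element", "LTR5K", unit_length = 5000,
                  copies = round(0.04 * genome_length / 5000),
                  divergence = 0.01, ltr_length = 600))
}

#' @rdname default_repeat_families
#' @param copies LTR-element copy number of the variant scenario; the default
#'   is sized so that roughly 700 reads span the breakpoint at 0.5x coverage,
#'   keeping the binomial standard error of the variant-fraction estimate
#'   near 0.012.
#' @export
deletion_variant_families <- function(copies = 2400L) {
  list(repeat_family("ltr_element", "LTRDEL", unit_length = 5000,
                     copies = copies, divergence = 0.01, ltr_length = 600,
                     deletions = data.frame(start = 3000, length = 500,
                                            fraction = 0.13)))
}

#' Write simulation artifacts
#'
#' Writes genome FASTA, reads FASTA, the truth TSV and the family table TSV,
#' all keyed by seed in the file headers/ids.
#'
#' @param sim a `genome_sim`.
#' @param rsim a `read_sim`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, rsim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gset <- Biostrings::DNAStringSet(setNames(sim$genome,
                                            paste0("genome_seed", sim$seed)))
  Biostrings::writeXStringSet(gset, file.path(dir, "genome.fasta"), width = 70L)
  write_reads_fasta(rsim$reads, file.path(dir, "reads.fasta"))
  write_tsv(rsim$truth, file.path(dir, "truth.tsv"))
  write_tsv(sim$family_table, file.path(dir, "families.tsv"))
  invisible(dir)
}
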