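#' Alignment parameters for overlap detection
#'
#' Scoring and seeding parameters for the all-to-all overlap search. The
#' defaults mirror a BLAST-style megablast search for highly similar reads:
#' word size 18, both strands, +1/-3 match/mismatch, affine gaps (a gap of
#' length L costs `|gap_open| + L * |gap_ext|`). Hits are reported when the
#' alignment identity reaches `report_identity` (0.85); the stricter
#' edge-admission rule is applied afterwards by [filter_overlaps()].
#'
#' @param word_size exact-match seed length in nt (>= 8).
#' @param match,mismatch per-column match/mismatch scores.
#' @param gap_open,gap_ext gap opening and extension penalties (negative).
#' @param report_identity minimum identity for a hit to be reported at all.
#' @return a list of class `align_params`.
#' @export
align_params <- function(word_size = 18L, match = 1, mismatch = -3,
                         gap_open = -5, gap_ext = -2,
                         report_identity = 0.85) {
  stopifnot(word_size >= 8, word_size <= 32, match > 0, mismatch < 0,
            gap_open <= 0, gap_ext <= 0,
            report_identity >= 0, report_identity <= 1)
  structure(list(word_size = as.integer(word_size), match = match,
                 mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext,
                 report_identity = report_identity),
            class = "align_params")
}

empty_hits <- function() {
  data.frame(id_a = character(), id_b = character(), identity = numeric(),
             span = integer(), score = numeric(), orientation = character(),
             stringsAsFactors = FALSE)
}

# Align candidate (i, j, strand) triples against the same sequence set and
# summarize each as one row of hit statistics.
align_candidates <- function(seqs_a, seqs_b, cand, params, threads = 1L) {
  if (nrow(cand) == 0L) return(NULL)
  align_chunk <- function(idx) {
    .align_pairs_cpp(seqs_a, seqs_b, cand$i[idx], cand$j[idx],
                     cand$strand[idx], params$match, params$mismatch,
                     abs(params$gap_open), abs(params$gap_ext))
  }
  if (threads > 1L && nrow(cand) > threads) {
    chunks <- split(seq_len(nrow(cand)),
                    cut(seq_len(nrow(cand)), threads, labels = FALSE))
    res <- parallel::mclapply(chunks, align_chunk, mc.cores = threads)
    do.call(rbind, res)  # chunk order fixed, so thread count cannot reorder
  } else {
    align_chunk(seq_len(nrow(cand)))
  }
}

#' All-to-all read overlap detection
#'
#' Finds candidate read pairs sharing at least one exact `word_size`-mer on
#' either strand, aligns each candidate pair with an affine-gap
#' Smith-Waterman, and reports the best-scoring alignment per unordered pair.
#' Identity is matches / alignment columns (gap columns count); span is the
#' alignment footprint on the longer read. `N` never seeds and mismatches
#' everything.
#'
#' @param rs a deduplicated `read_set`.
#' @param params an [align_params()] object.
#' @param threads number of worker processes for the alignment stage; the
#'   result is independent of thread count.
#' @return a data.frame of hits: `id_a`, `id_b` (lexicographically ordered
#'   within each pair), `identity`, `span`, `score`, `orientation`
#'   (`"forward"` or `"reverse-complement"`).
#' @export
find_overlaps <- function(rs, params = align_params(), threads = 1L) {
  stopifnot(inherits(rs, "read_set"))
  if (length(rs) == 0L) stop("empty read set")
  lens <- nchar(rs$seq)
  if (any(lens < params$word_size))
    warning(sum(lens < params$word_size), " read(s) shorter than the seed ",
            "word size can form no seeds")
  seqs <- unname(rs$seq)
  cand <- .seed_candidates_cpp(seqs, seqs, params$word_size, TRUE)
  aln <- align_candidates(seqs, seqs, cand, params, threads)
  if (is.null(aln)) return(empty_hits())

  aln <- aln[aln$score > 0, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty_hits())
  identity <- aln$matches / aln$columns
  len_i <- lens[aln$i]
  len_j <- lens[aln$j]
  fp_i <- aln$a_end - aln$a_start + 1L
  fp_j <- aln$b_end - aln$b_start + 1L
  span <- ifelse(len_i > len_j, fp_i, ifelse(len_j > len_i, fp_j,
                                             pmax(fp_i, fp_j)))
  keep <- identity >= params$report_identity
  if (!any(keep)) return(empty_hits())

  ids <- names(rs$seq)
  hit <- data.frame(
    id_a = pmin(ids[aln$i], ids[aln$j]),
    id_b = pmax(ids[aln$i], ids[aln$j]),
    identity = identity,
    span = as.integer(span),
    score = aln$score,
    orientation = ifelse(aln$strand == 1L, "reverse-complement", "forward"),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  # best-scoring orientation per unordered pair; deterministic tie-break
  ord <- order(hit$id_a, hit$id_b, -hit$score, hit$orientation)
  hit <- hit[ord, , drop = FALSE]
  hit <- hit[!duplicated(paste(hit$id_a, hit$id_b)), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Edge-admission filter for overlap hits
#'
#' Keeps hits with identity of at least `min_identity` *and* span covering at
#' least `min_cov` of the longer read's full length (both inclusive). These
#' are the pairs that become edges of the similarity graph.
#'
#' @param hits hit table from [find_overlaps()].
#' @param read_lengths named integer vector of read lengths (see
#'   [load_reads()]), or a `read_set`.
#' @param min_identity identity threshold (default 0.90).
#' @param min_cov coverage-of-longer-read threshold (default 0.55).
#' @return the admitted subset of `hits`.
#' @export
filter_overlaps <- function(hits, read_lengths, min_identity = 0.90,
                            min_cov = 0.55) {
  if (inherits(read_lengths, "read_set")) read_lengths <- read_lengths(read_lengths)
  stopifnot(min_identity >= 0, min_identity <= 1, min_cov >= 0, min_cov <= 1)
  if (nrow(hits) == 0L) return(hits)
  unknown <- setdiff(unique(c(hits$id_a, hits$id_b)), names(read_lengths))
  if (length(unknown)) stop("hit references unknown read id: ", unknown[1])
  longer <- pmax(read_lengths[hits$id_a], read_lengths[hits$id_b])
  keep <- hits$identity >= min_identity & hits$span / longer >= min_cov
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read overlap hits as TSV
#'
#' @param hits hit table.
#' @param path TSV file path.
#' @return the path (write) or the hit table (read).
#' @export
write_overlaps <- function(hits, path) write_tsv(hits, path)

#' @rdname write_overlaps
#' @export
read_overlaps <- function(path) {
  read_tsv(path, colClasses = c("character", "character", "numeric",
                                "integer", "numeric", "character"))
}
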