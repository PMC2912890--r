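#' Load shotgun reads from FASTA or FASTQ
#'
#' Reads a multi-FASTA or FASTQ file into a `read_set`. Sequences are
#' uppercased and any character outside `{A,C,G,T,N}` is converted to `N`.
#' FASTQ qualities are accepted and ignored. No duplicate removal is performed
#' here; see [dedup_reads()].
#'
#' @param path path to the sequence file.
#' @param format `"fasta"` or `"fastq"`; the default guesses from the file
#'   extension (`.fastq`/`.fq` means FASTQ).
#' @return a `read_set`: list with `seq` (named character vector of
#'   sequences), `n_input` and `n_retained` (equal until deduplication).
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(recs))
  # FASTA headers may carry descriptions; the id is the first token
  ids <- sub("\\s.*$", "", names(recs))
  if (anyNA(ids) || any(ids == ""))
    stop("record ", which(is.na(ids) | ids == "")[1], " has an empty id")
  empty <- which(nchar(seqs) == 0L)
  if (length(empty))
    stop("record ", empty[1], " (", ids[empty[1]], ") has an empty sequence")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate read id: ", dup[1])
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- ids
  new_read_set(seqs, n_input = length(seqs))
}

new_read_set <- function(seqs, n_input) {
  structure(list(seq = seqs, n_input = n_input, n_retained = length(seqs)),
            class = "read_set")
}

#' Construct a read set from sequences in memory
#'
#' @param seqs named character vector of nucleotide sequences.
#' @return a `read_set` (see [load_reads()]).
#' @export
read_set <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate read id")
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  new_read_set(toupper(seqs), n_input = length(seqs))
}

#' Remove exact duplicate reads
#'
#' Shotgun libraries from emulsion-PCR technologies contain artifactual clones:
#' multiple reads with byte-identical sequences. Exactly one representative
#' (the first in input order) is retained per distinct sequence string.
#' Reverse-complement copies are *not* treated as duplicates (clone artifacts
#' are same-strand). Idempotent.
#'
#' @param rs a `read_set`.
#' @return the deduplicated `read_set`; `n_input` is preserved and a
#'   `removed` attribute-like field records, per retained read, how many
#'   duplicates it absorbed.
#' @export
dedup_reads <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  keep <- !duplicated(rs$seq)
  removed <- as.integer(table(factor(match(rs$seq, rs$seq[keep]),
                                     levels = seq_len(sum(keep))))) - 1L
  out <- rs
  out$seq <- rs$seq[keep]
  out$n_retained <- length(out$seq)
  out$removed <- setNames(removed, names(out$seq))
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$n_retained, "reads")
  if (x$n_retained < x$n_input)
    cat(" (", x$n_input - x$n_retained, " duplicates removed of ",
        x$n_input, " input)", sep = "")
  cat("; length range", paste(range(nchar(x$seq)), collapse = "-"), "nt\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$seq)

read_lengths <- function(rs) setNames(nchar(rs$seq), names(rs$seq))

#' Write reads to FASTA
#'
#' @param rs a `read_set`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_reads_fasta <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(rs$seq), path, width = 70L)
  invisible(path)
}

#' Write a deduplication report
#'
#' TSV with one row per retained read: its id and the number of removed
#' duplicates it represents.
#'
#' @param rs a deduplicated `read_set` (output of [dedup_reads()]).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_dedup_report <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  removed <- if (is.null(rs$removed)) rep(0L, length(rs$seq)) else rs$removed
  write_tsv(data.frame(id = names(rs$seq),
                       removed_duplicate_count = as.integer(removed)),
            path)
}
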