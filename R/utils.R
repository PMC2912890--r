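# internal helpers

# Run code with a temporarily-seeded RNG, restoring caller state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Reverse-complement nucleotide sequences
#'
#' Vectorized reverse complement over `{A,C,G,T,N}`; any other character
#' becomes `N`.
#'
#' @param seqs character vector of sequences.
#' @return character vector of the same length (names preserved).
#' @export
revcomp <- function(seqs) {
  stopifnot(is.character(seqs))
  .revcomp_cpp(seqs)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = colClasses, comment.char = "")
}
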