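# small shared helpers (sequence handling, FASTA/TSV io)

#' Reverse-complement a nucleotide string
#'
#' Handles the full IUPAC alphabet via Biostrings.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split a sequence into codons
#'
#' @param seq single nucleotide string.
#' @param frame_offset 0, 1 or 2; bases skipped before the first codon.
#' @return character vector of 3-letter codons (trailing partial codon dropped).
#' @export
seq_codons <- function(seq, frame_offset = 0L) {
  stopifnot(length(seq) == 1L, frame_offset %in% 0:2)
  n <- nchar(seq)
  n_codons <- (n - frame_offset) %/% 3L
  if (n_codons < 1L) return(character(0))
  starts <- frame_offset + 3L * seq_len(n_codons) - 2L
  substring(seq, starts, starts + 2L)
}

# per-character matrix view of equal-length sequences (rows = sequences)
.seq_char_matrix <- function(seqs) {
  n <- nchar(seqs)
  stopifnot(length(unique(n)) == 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE,
         dimnames = list(names(seqs), NULL))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# deterministic evaluation under a local RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
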