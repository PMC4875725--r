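# translation, pseudoallele flagging, PBR site classification

#' PBR site mask
#'
#' Describes the reading frame of the amplified fragment and which codons
#' belong to the peptide-binding region (PBR).  Codon indices are 1-based
#' positions within the fragment's own reading frame.
#'
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @param pbr_codons integer vector of PBR codon positions.
#' @param fragment_length fragment length in nucleotides (default 159).
#' @return object of class `site_mask`.
#' @export
site_mask <- function(frame_offset = 0L, pbr_codons = integer(0),
                      fragment_length = 159L) {
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  n_codons <- (fragment_length - frame_offset) %/% 3L
  pbr_codons <- sort(unique(as.integer(pbr_codons)))
  if (length(pbr_codons) &&
      (min(pbr_codons) < 1L || max(pbr_codons) > n_codons))
    stop("pbr_codons out of range 1..", n_codons)
  structure(list(frame_offset = frame_offset, pbr_codons = pbr_codons,
                 fragment_length = as.integer(fragment_length),
                 n_codons = n_codons),
            class = "site_mask")
}

#' Default PBR mask for the 159-bp class II beta exon 2 fragment
#'
#' Loads the packaged mask (`inst/extdata/pbr_mask.yaml`): frame offset 0
#' (53 codons) with PBR codons inferred by homology to the human HLA-DR1
#' peptide-binding groove.  The exact register of the fragment against
#' HLA-DR1 is an assumption recorded in the mask file; users with locus-
#' specific information should supply their own mask via [read_mask()].
#'
#' @return a [site_mask()].
#' @export
default_pbr_mask <- function() {
  path <- system.file("extdata", "pbr_mask.yaml", package = "allelescope",
                      mustWork = TRUE)
  read_mask(path)
}

#' Read / write a site mask as YAML
#'
#' @param path YAML file with fields `frame_offset`, `pbr_codons`, and
#'   optionally `fragment_length`.
#' @return [site_mask()] (for `read_mask`); the path, invisibly (for
#'   `write_mask`).
#' @export
read_mask <- function(path) {
  y <- yaml::read_yaml(path)
  site_mask(frame_offset = y$frame_offset %||% 0L,
            pbr_codons = unlist(y$pbr_codons),
            fragment_length = y$fragment_length %||% 159L)
}

#' @rdname read_mask
#' @param mask a [site_mask()].
#' @export
write_mask <- function(mask, path) {
  yaml::write_yaml(list(frame_offset = mask$frame_offset,
                        pbr_codons = as.integer(mask$pbr_codons),
                        fragment_length = mask$fragment_length), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Translate a fragment under a site mask
#'
#' Standard genetic code, from the mask's frame offset; stops rendered `*`;
#' any trailing partial codon is dropped.
#'
#' @param seq character vector of nucleotide sequences (A/C/G/T only).
#' @param mask a [site_mask()] (only `frame_offset` is used).
#' @return character vector of amino-acid sequences.
#' @export
translate_fragment <- function(seq, mask = site_mask()) {
  code <- Biostrings::GENETIC_CODE
  vapply(seq, function(s) {
    s <- toupper(s)
    if (grepl("[^ACGT]", s)) stop("non-nucleotide character in sequence")
    if (nchar(s) < mask$frame_offset + 3L) stop("sequence shorter than one codon")
    paste(code[seq_codons(s, mask$frame_offset)], collapse = "")
  }, character(1), USE.NAMES = !is.null(names(seq)))
}

#' Classify fragment sites as PBR or non-PBR
#'
#' The codon-level partition follows the mask; the nucleotide-level
#' partition labels the three bases of every PBR codon as PBR and all other
#' positions (including any out-of-frame leading/trailing bases) as
#' non-PBR, so nucleotide and amino-acid partitions are congruent.
#'
#' @param mask a [site_mask()].
#' @return list with `codon` and `nucleotide` label vectors
#'   (values `"PBR"` / `"non-PBR"`).
#' @export
classify_sites <- function(mask) {
  stopifnot(inherits(mask, "site_mask"))
  codon <- rep("non-PBR", mask$n_codons)
  codon[mask$pbr_codons] <- "PBR"
  nt <- rep("non-PBR", mask$fragment_length)
  for (cd in mask$pbr_codons) {
    start <- mask$frame_offset + 3L * (cd - 1L) + 1L
    nt[start:(start + 2L)] <- "PBR"
  }
  list(codon = codon, nucleotide = nt)
}

# nucleotide site indices of a partition
.partition_sites <- function(mask, partition = c("all", "PBR", "non-PBR")) {
  partition <- match.arg(partition)
  if (partition == "all") return(seq_len(mask$fragment_length))
  which(classify_sites(mask)$nucleotide == partition)
}

.partition_codons <- function(mask, partition = c("all", "PBR", "non-PBR")) {
  partition <- match.arg(partition)
  if (partition == "all") return(seq_len(mask$n_codons))
  which(classify_sites(mask)$codon == partition)
}

#' Flag a pseudoallele
#'
#' A sequence is flagged as a pseudoallele if its translation contains an
#' in-frame stop codon, or (when a reference/consensus sequence is given)
#' if a global pairwise alignment against it implies an insertion/deletion
#' whose total length is not a multiple of 3 (a frameshift).  Alignment
#' scoring: match 1, mismatch -1, gap open -2, gap extend -1.
#'
#' @param seq single nucleotide sequence.
#' @param mask a [site_mask()].
#' @param consensus optional reference sequence for frameshift detection.
#' @return list with `flag` (logical) and `reason`
#'   (`"in-frame stop"`, `"frameshift-indel"` or `"none"`).
#' @export
flag_pseudoallele <- function(seq, mask = site_mask(), consensus = NULL) {
  if (!is.null(consensus)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq), Biostrings::DNAString(consensus),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 2, gapExtension = 1)
    ind <- Biostrings::nindel(al)
    gap_total <- sum(Biostrings::insertion(ind)[, "WidthSum"],
                     Biostrings::deletion(ind)[, "WidthSum"])
    if (gap_total %% 3L != 0L)
      return(list(flag = TRUE, reason = "frameshift-indel"))
  }
  aa <- tryCatch(translate_fragment(seq, mask), error = function(e) NA_character_)
  if (!is.na(aa) && grepl("*", aa, fixed = TRUE))
    return(list(flag = TRUE, reason = "in-frame stop"))
  list(flag = FALSE, reason = "none")
}

#' First-residue class of a peptide
#'
#' Class II beta exon 2 normally begins with glutamic acid (E) in this
#' fragment's register; sequences starting with aspartic acid (D) or
#' alanine (A) form a distinct ("Group B"-like) set that co-clusters with
#' pseudoalleles.
#'
#' @param aa_seq character vector of amino-acid sequences.
#' @return data.frame with `residue` (literal first residue), `class`
#'   (`"E"`, `"D"`, `"A"` or `"other"`) and `group_b_like` (TRUE for D/A).
#' @export
first_residue_class <- function(aa_seq) {
  stopifnot(all(nchar(aa_seq) > 0L))
  res <- substr(aa_seq, 1L, 1L)
  cls <- ifelse(res %in% c("E", "D", "A"), res, "other")
  data.frame(residue = res, class = cls,
             group_b_like = cls %in% c("D", "A"),
             stringsAsFactors = FALSE)
}

#' Annotate alleles: translation, pseudoallele flag, first residue
#'
#' @param seqs named character vector of allele nucleotide sequences.
#' @param mask a [site_mask()].
#' @param consensus optional reference for frameshift detection (see
#'   [flag_pseudoallele()]); by default only in-frame stops are flagged.
#' @return data.frame with columns `name`, `sequence`, `aa`, `pseudo`,
#'   `reason`, `first_residue`, `group_b_like`.
#' @export
annotate_orfs <- function(seqs, mask = default_pbr_mask(), consensus = NULL) {
  stopifnot(length(seqs) > 0L)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  flags <- lapply(seqs, flag_pseudoallele, mask = mask, consensus = consensus)
  aa <- vapply(seqs, function(s) {
    tryCatch(translate_fragment(s, mask), error = function(e) NA_character_)
  }, character(1))
  fr <- first_residue_class(ifelse(is.na(aa), "X", aa))
  data.frame(name = names(seqs), sequence = unname(seqs), aa = unname(aa),
             pseudo = vapply(flags, `[[`, logical(1), "flag"),
             reason = vapply(flags, `[[`, character(1), "reason"),
             first_residue = fr$residue, group_b_like = fr$group_b_like,
             row.names = NULL, stringsAsFactors = FALSE)
}
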