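# read processing and stepwise allele validation

#' Match degenerate primers and trim reads to the amplified template
#'
#' Searches each read for a complete (zero-mismatch) match of the forward
#' primer and of the reverse-complemented reverse primer, resolving IUPAC
#' degeneracies in the primers against the read's literal bases.  Both read
#' orientations are searched; a read found in reverse orientation is
#' reverse-complemented so the returned template is always in the forward
#' (primer 326 -> 325) orientation.  The first complete match wins.  The
#' template is the subsequence strictly between the two primer matches.
#'
#' @param reads character vector of read sequences.
#' @param fwd,rev primer strings in IUPAC notation (defaults:
#'   [mhc_primers()]).
#' @param mid_length number of bases immediately 5' of the forward primer
#'   reported as the multiplex identifier (MID) tag.
#' @return data.frame with one row per read: `template` (NA when either
#'   primer fails to match), `mid` (the `mid_length` bases preceding the
#'   forward primer, NA when unavailable) and `orientation`
#'   (`"fwd"`/`"rev"`/NA).
#' @export
match_and_trim <- function(reads, fwd = mhc_primers()$fwd,
                           rev = mhc_primers()$rev, mid_length = 10L) {
  stopifnot(length(reads) > 0L, all(nchar(reads) > 0L))
  reads <- toupper(reads)
  out <- data.frame(template = NA_character_, mid = NA_character_,
                    orientation = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, length(reads)), ]
  rownames(out) <- NULL
  scan <- function(seqs) .scan_primers(seqs, fwd, rev, mid_length)
  hit <- scan(reads)
  ok <- !is.na(hit$template)
  out[ok, ] <- hit[ok, ]
  out$orientation[ok] <- "fwd"
  if (any(!ok)) {
    hit2 <- scan(revcomp(reads[!ok]))
    ok2 <- !is.na(hit2$template)
    idx <- which(!ok)[ok2]
    out[idx, c("template", "mid")] <- hit2[ok2, c("template", "mid")]
    out$orientation[idx] <- "rev"
  }
  out
}

# forward-orientation primer scan: fwd ... template ... revcomp(rev)
.scan_primers <- function(seqs, fwd, rev, mid_length) {
  n <- length(seqs)
  subj <- Biostrings::DNAStringSet(seqs)
  f_hits <- Biostrings::vmatchPattern(Biostrings::DNAString(fwd), subj,
                                      fixed = "subject")
  r_hits <- Biostrings::vmatchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)), subj,
    fixed = "subject")
  fs <- Biostrings::startIndex(f_hits)
  fe <- Biostrings::endIndex(f_hits)
  rs <- Biostrings::startIndex(r_hits)
  f_start <- f_end <- r_start <- rep(NA_integer_, n)
  has_f <- lengths(fs) > 0L
  f_start[has_f] <- vapply(fs[has_f], `[`, integer(1), 1L)
  f_end[has_f] <- vapply(fe[has_f], `[`, integer(1), 1L)
  one_r <- which(lengths(rs) == 1L)
  r_start[one_r] <- unlist(rs[one_r], use.names = FALSE)
  for (i in which(lengths(rs) > 1L)) {   # rare: multiple reverse hits
    cand <- rs[[i]]
    if (!is.na(f_end[i])) cand <- cand[cand > f_end[i]]
    r_start[i] <- if (length(cand)) cand[1L] else NA_integer_
  }
  ok <- !is.na(f_end) & !is.na(r_start) & r_start > f_end
  template <- rep(NA_character_, n)
  template[ok] <- substr(seqs[ok], f_end[ok] + 1L, r_start[ok] - 1L)
  mid <- rep(NA_character_, n)
  has_mid <- ok & f_start > mid_length
  mid[has_mid] <- substr(seqs[has_mid], f_start[has_mid] - mid_length,
                         f_start[has_mid] - 1L)
  data.frame(template = template, mid = mid, stringsAsFactors = FALSE)
}

#' Assign trimmed reads to individuals via exact MID-tag match
#'
#' @param trimmed data.frame from [match_and_trim()], optionally carrying
#'   extra columns (`pcr`, `read_id`, ...), which are preserved.
#' @param mid_table data.frame with columns `individual` and `tag`
#'   (10-bp tags, pairwise distinct).
#' @return `trimmed` with an `individual` column (NA for unassigned reads);
#'   attribute `"n_unassigned"` counts reads with a template but no exact
#'   tag match.
#' @export
demultiplex <- function(trimmed, mid_table) {
  stopifnot(all(c("individual", "tag") %in% names(mid_table)))
  if (anyDuplicated(mid_table$tag)) stop("duplicate MID tags in table")
  if (any(nchar(mid_table$tag) != nchar(mid_table$tag[1])))
    stop("MID tags must share one length")
  trimmed$individual <-
    mid_table$individual[match(trimmed$mid, mid_table$tag)]
  attr(trimmed, "n_unassigned") <-
    sum(!is.na(trimmed$template) & is.na(trimmed$individual))
  trimmed
}

#' Tally sequence variants per individual and PCR replicate
#'
#' @param assigned data.frame with columns `individual`, `pcr` and
#'   `template` (reads lacking a template or an individual are dropped).
#' @return data.frame of per-(sequence, individual, pcr) read counts with
#'   columns `sequence`, `individual`, `pcr`, `count`.
#' @export
tally_variants <- function(assigned) {
  keep <- !is.na(assigned$template) & !is.na(assigned$individual)
  x <- assigned[keep, c("template", "individual", "pcr")]
  if (!nrow(x))
    return(data.frame(sequence = character(0), individual = character(0),
                      pcr = integer(0), count = integer(0)))
  agg <- stats::aggregate(list(count = rep(1L, nrow(x))),
                          by = list(sequence = x$template,
                                    individual = x$individual, pcr = x$pcr),
                          FUN = sum)
  agg <- agg[order(agg$sequence, agg$individual, agg$pcr), ]
  rownames(agg) <- NULL
  agg
}

#' Dataset-level replicate filter
#'
#' Retains a sequence variant iff its length equals `required_length` and
#' at least `min_pcrs` independent PCRs each contain at least
#' `min_reads_per_pcr` reads of it.  With `scope = "dataset"` (the default)
#' the qualifying PCRs may come from any individuals — each (individual,
#' replicate) combination is an independent PCR; with
#' `scope = "individual"` they must lie within one individual, and the
#' variant is retained only for individuals where the rule holds.
#'
#' @param variants data.frame from [tally_variants()].
#' @param required_length exact template length retained (default 159).
#' @param min_pcrs minimum number of qualifying PCRs (default 2).
#' @param min_reads_per_pcr minimum reads per qualifying PCR (default 3).
#' @param scope `"dataset"` or `"individual"`.
#' @return the retained rows of `variants`; attribute `"stage"` records
#'   variant counts in/out of the length and replication stages.
#' @export
dataset_filter <- function(variants, required_length = 159L, min_pcrs = 2L,
                           min_reads_per_pcr = 3L,
                           scope = c("dataset", "individual")) {
  scope <- match.arg(scope)
  if (required_length <= 0L) stop("required_length must be positive")
  n_var_in <- length(unique(variants$sequence))
  len_ok <- nchar(variants$sequence) == required_length
  v <- variants[len_ok, , drop = FALSE]
  n_var_len <- length(unique(v$sequence))
  strong <- v[v$count >= min_reads_per_pcr, , drop = FALSE]
  if (scope == "dataset") {
    pcr_key <- paste(strong$individual, strong$pcr, sep = "\r")
    n_pcrs <- tapply(pcr_key, strong$sequence,
                     function(k) length(unique(k)))
    keep_seq <- names(n_pcrs)[n_pcrs >= min_pcrs]
    out <- v[v$sequence %in% keep_seq, , drop = FALSE]
  } else {
    grp <- paste(strong$sequence, strong$individual, sep = "\r")
    n_pcrs <- tapply(strong$pcr, grp, function(p) length(unique(p)))
    keep_pair <- names(n_pcrs)[n_pcrs >= min_pcrs]
    out <- v[paste(v$sequence, v$individual, sep = "\r") %in% keep_pair,
             , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "stage") <- data.frame(
    stage = c("length", "replication"),
    variants_in = c(n_var_in, n_var_len),
    variants_out = c(n_var_len, length(unique(out$sequence))))
  out
}

#' Per-individual relative-coverage filter
#'
#' Within each individual, let M be the highest per-variant coverage
#' (summed over PCR replicates).  Variants with coverage strictly lower
#' than `relative_threshold * M` are discarded; exact ties at the
#' threshold are kept, and the maximal-coverage variant always survives.
#'
#' @param variants data.frame from [tally_variants()] (typically after
#'   [dataset_filter()]).
#' @param relative_threshold fraction of the per-individual maximum
#'   (default 0.10).
#' @return data.frame of retained alleles: `individual`, `sequence`,
#'   `coverage`.
#' @export
individual_filter <- function(variants, relative_threshold = 0.10) {
  if (!nrow(variants)) stop("individual_filter: empty variant table")
  stopifnot(.is_prob(relative_threshold) || relative_threshold >= 0)
  cov <- stats::aggregate(list(coverage = variants$count),
                          by = list(individual = variants$individual,
                                    sequence = variants$sequence),
                          FUN = sum)
  keep <- unlist(lapply(split(seq_len(nrow(cov)), cov$individual),
                        function(idx) {
    m <- max(cov$coverage[idx])
    # tolerance so integer ties at the threshold are kept despite
    # floating-point representation of the threshold
    idx[cov$coverage[idx] >= relative_threshold * m - 1e-9]
  }), use.names = FALSE)
  out <- cov[sort(keep), c("individual", "sequence", "coverage")]
  rownames(out) <- NULL
  out
}

#' Validate cloned Sanger sequences by PCR replication
#'
#' A cloned sequence is retained for an individual iff it occurs (at least
#' once) in at least two independent PCRs of that individual.  Individuals
#' represented by a single PCR cannot be validated; they are dropped with a
#' warning and listed in the `"unvalidatable"` attribute.
#'
#' @param clones data.frame with columns `individual`, `pcr`, `sequence`.
#' @param min_pcrs minimum number of PCRs a sequence must appear in
#'   (default 2).
#' @return data.frame of retained alleles: `individual`, `sequence`,
#'   `n_pcrs`.
#' @export
validate_clones <- function(clones, min_pcrs = 2L) {
  stopifnot(all(c("individual", "pcr", "sequence") %in% names(clones)))
  n_pcr_per_ind <- tapply(clones$pcr, clones$individual,
                          function(p) length(unique(p)))
  bad <- names(n_pcr_per_ind)[n_pcr_per_ind < min_pcrs]
  if (length(bad)) {
    warning("unvalidatable individuals (single PCR group): ",
            paste(bad, collapse = ", "))
    clones <- clones[!clones$individual %in% bad, , drop = FALSE]
  }
  u <- unique(clones[c("individual", "sequence", "pcr")])
  grp <- paste(u$individual, u$sequence, sep = "\r")
  n_pcrs <- tapply(u$pcr, grp, length)
  keys <- names(n_pcrs)[n_pcrs >= min_pcrs]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    individual = vapply(parts, `[`, character(1), 1L),
    sequence = vapply(parts, `[`, character(1), 2L),
    n_pcrs = as.integer(n_pcrs[keys]), stringsAsFactors = FALSE)
  out <- out[order(out$individual, out$sequence), ]
  rownames(out) <- NULL
  attr(out, "unvalidatable") <- bad
  out
}

#' Build a filtering report
#'
#' @param reads_in reads entering the filter chain (for pooled amplicon
#'   data, conventionally the reads with a complete primer match).
#' @param reads_retained reads belonging to validated alleles.
#' @param reads_matching_primers optional primer-stage count (defaults to
#'   `reads_in`).
#' @param stages optional data.frame of per-stage variant counts
#'   (`stage`, `variants_in`, `variants_out`).
#' @return object of class `filter_report`, with `retained_percent`
#'   rounded to the nearest integer for display and the exact fraction in
#'   `retained_fraction`.
#' @export
summarize_filtering <- function(reads_in, reads_retained,
                                reads_matching_primers = reads_in,
                                stages = NULL) {
  stopifnot(reads_in > 0, reads_retained >= 0, reads_retained <= reads_in)
  if (!is.null(stages))
    stopifnot(all(stages$variants_out <= stages$variants_in))
  rep <- list(reads_in = reads_in,
              reads_matching_primers = reads_matching_primers,
              reads_retained = reads_retained,
              retained_fraction = reads_retained / reads_in,
              retained_percent = as.integer(round(100 * reads_retained /
                                                    reads_in)),
              stages = stages)
  class(rep) <- "filter_report"
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Stepwise filtering report\n")
  cat(sprintf("  reads in: %d (complete primer match: %d)\n",
              x$reads_in, x$reads_matching_primers))
  cat(sprintf("  reads retained: %d (%d%% of reads in)\n",
              x$reads_retained, x$retained_percent))
  if (!is.null(x$stages)) {
    for (i in seq_len(nrow(x$stages)))
      cat(sprintf("  stage %-12s variants %d -> %d\n", x$stages$stage[i],
                  x$stages$variants_in[i], x$stages$variants_out[i]))
  }
  invisible(x)
}

#' Genotype pooled amplicon reads end to end
#'
#' Chains [match_and_trim()], [demultiplex()], [tally_variants()],
#' [dataset_filter()] and [individual_filter()] and assembles the
#' [summarize_filtering()] report.  Following standard practice for pooled
#' amplicon runs, the report's `reads_in` is the number of reads with a
#' complete primer match, so `retained_percent` expresses validated reads
#' as a share of primer-matched reads.
#'
#' @param reads data.frame with columns `read_id`, `pcr`, `sequence` (e.g.
#'   from [simulate_amplicon_reads()], whose truth columns are ignored).
#' @param mid_table data.frame (`individual`, `tag`).
#' @inheritParams match_and_trim
#' @inheritParams dataset_filter
#' @inheritParams individual_filter
#' @return list with `alleles` (validated alleles per individual:
#'   `individual`, `sequence`, `coverage`), `variants` (post replicate
#'   filter) and `report` (a `filter_report`).
#' @export
genotype_amplicons <- function(reads, mid_table,
                               fwd = mhc_primers()$fwd,
                               rev = mhc_primers()$rev,
                               required_length = 159L, min_pcrs = 2L,
                               min_reads_per_pcr = 3L,
                               relative_threshold = 0.10,
                               scope = c("dataset", "individual")) {
  scope <- match.arg(scope)
  stopifnot(all(c("pcr", "sequence") %in% names(reads)))
  trimmed <- match_and_trim(reads$sequence, fwd, rev)
  trimmed$pcr <- reads$pcr
  assigned <- demultiplex(trimmed, mid_table)
  variants <- tally_variants(assigned)
  kept <- dataset_filter(variants, required_length = required_length,
                         min_pcrs = min_pcrs,
                         min_reads_per_pcr = min_reads_per_pcr, scope = scope)
  alleles <- individual_filter(kept, relative_threshold = relative_threshold)
  retained_key <- paste(alleles$individual, alleles$sequence, sep = "\r")
  kept_key <- paste(kept$individual, kept$sequence, sep = "\r")
  reads_retained <- sum(kept$count[kept_key %in% retained_key])
  n_matched <- sum(!is.na(trimmed$template))
  stages <- rbind(
    attr(kept, "stage"),
    data.frame(stage = "coverage10pc",
               variants_in = length(unique(kept$sequence)),
               variants_out = length(unique(alleles$sequence))))
  report <- summarize_filtering(reads_in = n_matched,
                                reads_retained = reads_retained,
                                reads_matching_primers = n_matched,
                                stages = stages)
  report$reads_raw <- nrow(reads)
  report$n_unassigned <- attr(assigned, "n_unassigned")
  list(alleles = alleles, variants = kept, report = report)
}
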