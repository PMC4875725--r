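# Nei-Gojobori (1986) pathway counting of synonymous and non-synonymous
# sites and differences, with Jukes-Cantor correction

.codon_strings <- function() {
  names(Biostrings::GENETIC_CODE)
}

# permutations of 1..n for n <= 3
.perms <- list(list(1L),
               list(c(1L, 2L), c(2L, 1L)),
               list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' Synonymous and non-synonymous site counts of a codon
#'
#' Each codon position contributes the fraction of its three possible
#' single-base changes that are synonymous; changes producing a stop codon
#' count as non-synonymous, so `N + S = 3` for every sense codon.
#'
#' @param codon 3-letter sense codon.
#' @return named numeric vector `c(N, S)`.
#' @export
ng_site_counts <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L, !grepl("[^ACGT]", codon))
  if (code[[codon]] == "*") stop("stop codon has no site counts")
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.BASES, chars[p])) {
      alt <- chars; alt[p] <- b
      if (code[[paste(alt, collapse = "")]] == code[[codon]]) s <- s + 1 / 3
    }
  }
  c(N = 3 - s, S = s)
}

# pathway-averaged (Nd, Sd) for one codon pair; used to build the lookup
# tables.  Pathways passing through a stop codon are excluded; if every
# pathway does, all pathways are used with stop-crossing steps counted as
# non-synonymous (documented fallback).
.ng_pair_compute <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(codon_a, "", fixed = TRUE)[[1]]
  b <- strsplit(codon_b, "", fixed = TRUE)[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) return(c(Nd = 0, Sd = 0))
  walk <- function(order, allow_stops) {
    cur <- a; nd <- 0; sd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" && !identical(nxt, b) && !allow_stops)
        return(NULL)
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sd)
  }
  orders <- lapply(.perms[[d]], function(o) pos[o])
  paths <- Filter(Negate(is.null), lapply(orders, walk, allow_stops = FALSE))
  if (!length(paths))
    paths <- lapply(orders, walk, allow_stops = TRUE)
  m <- do.call(rbind, paths)
  c(Nd = mean(m[, 1]), Sd = mean(m[, 2]))
}

# cached lookup tables over all 64x64 codon pairs (NA where a stop codon
# is involved) and per-codon site counts
.ng_tables <- function() {
  if (!is.null(.als_cache$ng)) return(.als_cache$ng)
  code <- Biostrings::GENETIC_CODE
  codons <- .codon_strings()
  sense <- code != "*"
  NTab <- STab <- setNames(rep(NA_real_, 64L), codons)
  for (cd in codons[sense]) {
    ns <- ng_site_counts(cd)
    NTab[cd] <- ns["N"]; STab[cd] <- ns["S"]
  }
  NdTab <- SdTab <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  for (i in which(sense)) for (j in which(sense)) {
    if (j < i) next
    nd <- .ng_pair_compute(codons[i], codons[j])
    NdTab[i, j] <- NdTab[j, i] <- nd["Nd"]
    SdTab[i, j] <- SdTab[j, i] <- nd["Sd"]
  }
  .als_cache$ng <- list(N = NTab, S = STab, Nd = NdTab, Sd = SdTab)
  .als_cache$ng
}

#' Pathway-averaged synonymous/non-synonymous differences of a codon pair
#'
#' All minimal mutational pathways between the two codons are weighted
#' equally; pathways through stop codons are excluded (with a documented
#' fallback when no pathway avoids them).  `Nd + Sd` equals the number of
#' differing positions.
#'
#' @param codon_a,codon_b 3-letter sense codons.
#' @return named numeric vector `c(Nd, Sd)`.
#' @export
ng_pair <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (code[[codon_a]] == "*" || code[[codon_b]] == "*")
    stop("stop codons are not admitted to dN/dS counting")
  tb <- .ng_tables()
  c(Nd = tb$Nd[codon_a, codon_b], Sd = tb$Sd[codon_a, codon_b])
}

# per-pair, per-codon component matrices for a set of aligned sequences;
# codon pairs involving a stop or a non-ACGT base are masked out
.ng_components <- function(seqs, frame_offset = 0L) {
  tb <- .ng_tables()
  codons <- lapply(seqs, seq_codons, frame_offset = frame_offset)
  L <- length(codons[[1]])
  stopifnot(all(lengths(codons) == L))
  cm <- do.call(rbind, codons)            # n x L codon strings
  idx <- matrix(match(cm, .codon_strings()), nrow = nrow(cm))
  n <- length(seqs)
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  ia <- idx[pairs[, 2L], , drop = FALSE]
  ib <- idx[pairs[, 1L], , drop = FALSE]
  flat <- cbind(as.vector(ia), as.vector(ib))
  Nd <- matrix(tb$Nd[flat], nrow = nrow(ia))
  Sd <- matrix(tb$Sd[flat], nrow = nrow(ia))
  Nn <- matrix((tb$N[as.vector(ia)] + tb$N[as.vector(ib)]) / 2,
               nrow = nrow(ia))
  Ss <- matrix((tb$S[as.vector(ia)] + tb$S[as.vector(ib)]) / 2,
               nrow = nrow(ia))
  ok <- !is.na(Nd) & !is.na(Nn)
  Nd[!ok] <- 0; Sd[!ok] <- 0; Nn[!ok] <- 0; Ss[!ok] <- 0
  list(Nd = Nd, Sd = Sd, N = Nn, S = Ss, ok = ok, pairs = pairs,
       labels = names(seqs), n = n, L = L)
}

# Jukes-Cantor correction of a proportion of differences
.jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori dN or dS between two aligned coding sequences
#'
#' Proportions `pN = sum(Nd)/sum(N)` and `pS = sum(Sd)/sum(S)` are
#' accumulated over codons (site counts averaged between the two
#' sequences; codons containing a stop or a non-ACGT base are excluded
#' pairwise) and corrected with the Jukes-Cantor formula
#' `d = -3/4 log(1 - 4p/3)`.  Saturation (`p >= 3/4`) and comparisons
#' with zero synonymous sites return `NA`.
#'
#' @param seq_a,seq_b equal-length, in-frame nucleotide sequences.
#' @param kind `"dN"` or `"dS"`.
#' @param frame_offset bases skipped before the first codon.
#' @return the corrected distance (`NA` when undefined/saturated).
#' @export
ng_distance <- function(seq_a, seq_b, kind = c("dN", "dS"),
                        frame_offset = 0L) {
  kind <- match.arg(kind)
  cp <- .ng_components(setNames(c(seq_a, seq_b), c("a", "b")), frame_offset)
  nd <- sum(cp$Nd); sd_ <- sum(cp$Sd); nn <- sum(cp$N); ss <- sum(cp$S)
  if (kind == "dN") {
    if (nn <= 0) return(NA_real_)
    .jc_correct(nd / nn)
  } else {
    if (ss <= 0) return(NA_real_)
    .jc_correct(sd_ / ss)
  }
}

#' Pairwise dN or dS distance matrix
#'
#' @param seqs named character vector of aligned, in-frame coding
#'   sequences (pseudoalleles should be excluded: stop-containing codons
#'   are masked pairwise, which erodes the comparison).
#' @param kind `"dN"` or `"dS"`.
#' @param frame_offset bases skipped before the first codon.
#' @return symmetric matrix with attributes `model` and `partition`.
#' @export
ng_matrix <- function(seqs, kind = c("dN", "dS"), frame_offset = 0L) {
  kind <- match.arg(kind)
  cp <- .ng_components(seqs, frame_offset)
  num <- if (kind == "dN") rowSums(cp$Nd) else rowSums(cp$Sd)
  den <- if (kind == "dN") rowSums(cp$N) else rowSums(cp$S)
  d <- ifelse(den > 0, .jc_correct(num / den), NA_real_)
  m <- matrix(0, cp$n, cp$n)
  m[cbind(cp$pairs[, 1L], cp$pairs[, 2L])] <- d
  m[cbind(cp$pairs[, 2L], cp$pairs[, 1L])] <- d
  .distance_matrix(m, cp$labels, kind, "all")
}
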