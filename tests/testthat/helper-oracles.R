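# independent oracles used across tests

GENCODE <- Biostrings::GENETIC_CODE

# brute-force Nei-Gojobori pathway enumerator, written recursively and
# independently of the package's permutation-table implementation
oracle_ng_pair <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "", fixed = TRUE)[[1]]
  b <- strsplit(codon_b, "", fixed = TRUE)[[1]]
  paths_ok <- list()
  paths_all <- list()
  recurse <- function(cur, nd, sd, through_stop) {
    rem <- which(cur != b)
    if (!length(rem)) {
      rec <- c(nd, sd)
      paths_all[[length(paths_all) + 1L]] <<- rec
      if (!through_stop) paths_ok[[length(paths_ok) + 1L]] <<- rec
      return(invisible())
    }
    for (p in rem) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- GENCODE[[paste(cur, collapse = "")]]
      aa2 <- GENCODE[[paste(nxt, collapse = "")]]
      syn <- aa1 == aa2
      stop_here <- aa2 == "*" && !all(nxt == b)
      recurse(nxt, nd + !syn, sd + syn, through_stop || stop_here)
    }
  }
  recurse(a, 0L, 0L, FALSE)
  use <- if (length(paths_ok)) paths_ok else paths_all
  m <- do.call(rbind, use)
  c(Nd = mean(m[, 1]), Sd = mean(m[, 2]))
}

# brute-force site counts by enumerating the nine single-base changes
oracle_ng_sites <- function(codon) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  syn <- 0
  for (p in 1:3) for (base in setdiff(c("A", "C", "G", "T"), chars[p])) {
    alt <- chars
    alt[p] <- base
    if (GENCODE[[paste(alt, collapse = "")]] == GENCODE[[codon]])
      syn <- syn + 1 / 3
  }
  c(N = 3 - syn, S = syn)
}

# dN/dS of aligned sequences straight from the oracle pair counts
oracle_ng_distance <- function(seq_a, seq_b, kind) {
  ca <- seq_codons(seq_a)
  cb <- seq_codons(seq_b)
  nd <- sd_ <- nn <- ss <- 0
  for (k in seq_along(ca)) {
    pair <- oracle_ng_pair(ca[k], cb[k])
    sa <- oracle_ng_sites(ca[k])
    sb <- oracle_ng_sites(cb[k])
    nd <- nd + pair["Nd"]; sd_ <- sd_ + pair["Sd"]
    nn <- nn + (sa["N"] + sb["N"]) / 2
    ss <- ss + (sa["S"] + sb["S"]) / 2
  }
  p <- if (kind == "dN") nd / nn else sd_ / ss
  unname(-0.75 * log(1 - 4 * p / 3))
}

# random sense-codon coding sequence of n codons
random_cds <- function(n_codons, first = "GAG") {
  sense <- names(GENCODE)[GENCODE != "*"]
  paste(c(first, sample(sense, n_codons - 1L, replace = TRUE)), collapse = "")
}

# mean pairwise p-distance over a site subset, straight from the strings
oracle_mean_pdist <- function(seqs, sites) {
  pairs <- utils::combn(length(seqs), 2L)
  mean(apply(pairs, 2L, function(ij) {
    a <- strsplit(seqs[ij[1]], "")[[1]][sites]
    b <- strsplit(seqs[ij[2]], "")[[1]][sites]
    mean(a != b)
  }))
}
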