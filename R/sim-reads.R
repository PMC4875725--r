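# amplicon-read and clone-pick simulation: fusion-primer layout, coverage,
# substitution errors, PCR chimeras

#' Published degenerate primers for the 159-bp class II beta exon 2 fragment
#'
#' Forward primer "326" and reverse primer "325" in IUPAC notation, as used
#' in the fusion-primer design this simulator emulates.
#'
#' @return list with elements `fwd` and `rev` (named character strings).
#' @export
mhc_primers <- function() {
  list(fwd = c(p326 = "GAGTGYCAYTAYYTNAAYGGYAC"),
       rev = c(p325 = "GTAGTTGTGNCKGCAGTANSTGTCCAC"))
}

# 454 Titanium adapters used in the fusion-primer layout
.ADAPTER_A <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
.ADAPTER_B <- "CCTATCCCCTGTGTGCCTTGGCAGTCTCAG"

# n random realizations of a degenerate IUPAC primer
.realize_primer <- function(primer, n) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  cols <- lapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "", fixed = TRUE)[[1]]
    if (length(opts) == 1L) rep(opts, n) else sample(opts, n, replace = TRUE)
  })
  do.call(paste0, cols)
}

# substitution errors + single-breakpoint chimeras on template sequences
.apply_noise <- function(templates, owners, alleles_by_ind, error_rate,
                         chimera_rate, fragment_length) {
  n <- length(templates)
  is_chim <- logical(n)
  breakpoint <- rep(NA_integer_, n)
  if (chimera_rate > 0) {
    cand <- runif(n) < chimera_rate
    for (i in which(cand)) {
      others <- setdiff(alleles_by_ind[[owners[i]]], templates[i])
      if (!length(others)) next
      partner <- if (length(others) == 1L) others else sample(others, 1L)
      b <- sample.int(fragment_length - 1L, 1L)
      templates[i] <- paste0(substr(templates[i], 1L, b),
                             substr(partner, b + 1L, fragment_length))
      is_chim[i] <- TRUE
      breakpoint[i] <- b
    }
  }
  n_err <- if (error_rate > 0) rbinom(n, fragment_length, error_rate)
           else integer(n)
  for (i in which(n_err > 0L)) {
    chars <- strsplit(templates[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(fragment_length, n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
    templates[i] <- paste(chars, collapse = "")
  }
  list(sequence = templates, is_chimera = is_chim, breakpoint = breakpoint,
       n_errors = n_err)
}

#' Simulate pooled amplicon reads
#'
#' Every chromosome copy of every individual receives, in each PCR
#' replicate, a negative-binomial read count; each read is assembled as
#' adapter + 10-bp MID tag + a realization of the degenerate forward
#' primer + the 159-nt template (with substitution errors and, with
#' probability `chimera_rate`, a single-breakpoint two-parent recombinant
#' template) + the reverse-complemented reverse-primer realization.
#' Primer and tag bases are error-free: an error there would only drop
#' the read at the complete-match stage, which is equivalent to lowering
#' coverage.  All reads are emitted in forward orientation.
#'
#' @param genotypes output of [simulate_genotypes()].
#' @param pool output of [simulate_allele_pool()] (carried for provenance).
#' @param config the [sim_config()].
#' @param out_dir if non-NULL, reads are also written as one FASTA per
#'   (individual, PCR): `<individual>_<pcr>.fa`.
#' @return data.frame with `read_id`, `pcr`, `sequence` (the observable
#'   columns) plus simulation truth: `true_individual`, `true_allele_id`,
#'   `template`, `is_chimera`, `breakpoint`, `n_errors`.
#' @export
simulate_amplicon_reads <- function(genotypes, pool, config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(genotypes$allele_id %in% pool$allele_id))
    stop("genotype alleles missing from pool")
  .with_seed(config$seed + 4L, {
    R <- config$n_pcr_replicates
    floor_r <- floor(config$reads_floor / R)
    mu <- (config$reads_mean - config$reads_floor) / R
    size <- config$reads_dispersion
    per_ind <- split(unique(genotypes[c("individual", "sequence")])$sequence,
                     unique(genotypes[c("individual", "sequence")])$individual)
    parts <- list()
    for (r in seq_len(R)) {
      counts <- floor_r + rnbinom(nrow(genotypes), mu = mu, size = size)
      keep <- rep(seq_len(nrow(genotypes)), counts)
      parts[[r]] <- data.frame(
        pcr = r,
        true_individual = genotypes$individual[keep],
        true_allele_id = genotypes$allele_id[keep],
        template = genotypes$sequence[keep],
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, parts)
    noise <- .apply_noise(reads$template, reads$true_individual, per_ind,
                          config$per_base_error_rate, config$chimera_rate,
                          config$fragment_length)
    n <- nrow(reads)
    primers <- mhc_primers()
    fwd_real <- .realize_primer(primers$fwd, n)
    rev_real <- .realize_primer(primers$rev, n)
    mids <- setNames(config$mid_table$tag, config$mid_table$individual)
    reads$read_id <- sprintf("read%07d", seq_len(n))
    reads$sequence <- paste0(.ADAPTER_A, mids[reads$true_individual], fwd_real,
                             noise$sequence, revcomp(rev_real))
    reads$is_chimera <- noise$is_chimera
    reads$breakpoint <- noise$breakpoint
    reads$n_errors <- noise$n_errors
    reads$template_out <- noise$sequence
    reads <- reads[c("read_id", "pcr", "sequence", "true_individual",
                     "true_allele_id", "template", "template_out",
                     "is_chimera", "breakpoint", "n_errors")]
    rownames(reads) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (grp in split(reads,
                        paste(reads$true_individual, reads$pcr, sep = "_"))) {
        f <- file.path(out_dir, paste0(grp$true_individual[1], "_",
                                       grp$pcr[1], ".fa"))
        write_fasta(setNames(grp$sequence, grp$read_id), f)
      }
    }
    reads
  })
}

#' Simulate Sanger clone picks
#'
#' For each individual and each of its PCRs, `n_clones` inserts are drawn
#' uniformly with replacement from the individual's chromosome copies and
#' reported as undecorated template sequences subject to the same
#' substitution-error and chimera model as [simulate_amplicon_reads()].
#'
#' @inheritParams simulate_amplicon_reads
#' @return data.frame with `individual`, `pcr`, `clone_id`, `sequence`,
#'   plus truth columns `true_allele_id`, `template`, `is_chimera`,
#'   `n_errors`.
#' @export
simulate_clone_picks <- function(genotypes, pool, config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 5L, {
    per_ind <- split(unique(genotypes[c("individual", "sequence")])$sequence,
                     unique(genotypes[c("individual", "sequence")])$individual)
    parts <- list()
    for (ind in unique(genotypes$individual)) {
      g <- genotypes[genotypes$individual == ind, , drop = FALSE]
      for (r in seq_len(config$n_pcr_replicates)) {
        pick <- sample.int(nrow(g), config$n_clones, replace = TRUE)
        parts[[length(parts) + 1L]] <- data.frame(
          individual = ind, pcr = r,
          true_allele_id = g$allele_id[pick], template = g$sequence[pick],
          stringsAsFactors = FALSE)
      }
    }
    clones <- do.call(rbind, parts)
    noise <- .apply_noise(clones$template, clones$individual, per_ind,
                          config$per_base_error_rate, config$chimera_rate,
                          config$fragment_length)
    clones$sequence <- noise$sequence
    clones$is_chimera <- noise$is_chimera
    clones$n_errors <- noise$n_errors
    clones$clone_id <- sprintf("clone%05d", seq_len(nrow(clones)))
    clones <- clones[c("individual", "pcr", "clone_id", "sequence",
                       "true_allele_id", "template", "is_chimera", "n_errors")]
    rownames(clones) <- NULL
    clones
  })
}

#' Simulate a complete study
#'
#' Runs [simulate_allele_pool()], [simulate_genotypes()],
#' [simulate_amplicon_reads()] and [simulate_clone_picks()] under one
#' configuration.  When `out_dir` is given, writes the true-allele FASTA,
#' genotype TSV, per-(individual, PCR) read FASTAs, MID table and a JSON
#' manifest of the configuration.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `pool`, `genotypes`, `truth` ([true_allele_sets()]),
#'   `reads`, `clones`, `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  pool <- simulate_allele_pool(config)
  genotypes <- simulate_genotypes(pool, config)
  reads <- simulate_amplicon_reads(genotypes, pool, config, out_dir = out_dir)
  clones <- simulate_clone_picks(genotypes, pool, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- with(pool, sprintf("%s|%s|locus%d|%s", allele_id, species, locus,
                              ifelse(pseudo, "pseudo", "ok")))
    first <- !duplicated(pool$allele_id)
    write_fasta(setNames(pool$sequence[first], hdr[first]),
                file.path(out_dir, "true_alleles.fa"))
    .write_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    .write_tsv(config$mid_table, file.path(out_dir, "mids.tsv"))
    cfg <- config[c("seed", "loci_per_species", "alleles_per_locus",
                    "tsp_share_rate", "pseudoallele_rate",
                    "pbr_mutation_multiplier", "pool_mode",
                    "n_individuals_per_species", "n_pcr_replicates",
                    "reads_mean", "reads_dispersion", "per_base_error_rate",
                    "chimera_rate", "n_clones")]
    jsonlite::write_json(cfg, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(pool = pool, genotypes = genotypes, truth = true_allele_sets(genotypes),
       reads = reads, clones = clones, config = config)
}
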