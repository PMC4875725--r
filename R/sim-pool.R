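# allele-pool simulation: star genealogy with PBR-elevated substitution,
# trans-species sharing, pseudoalleles; alternative "tsp" and "convergent"
# regimes for the phylogenetic diagnostic

.genetic_code <- function() Biostrings::GENETIC_CODE

.sense_codons <- function() {
  code <- .genetic_code()
  names(code)[code != "*"]
}

.stop_codons <- function() c("TAA", "TAG", "TGA")

# random fragment of n_codons sense codons; first codon GAG (Glu) so the
# functional first-residue convention holds for non-pseudo alleles
.random_fragment <- function(n_codons) {
  cd <- sample(.sense_codons(), n_codons, replace = TRUE)
  cd[1] <- "GAG"
  unlist(strsplit(cd, "", fixed = TRUE), use.names = FALSE)
}

# per-nucleotide substitution probabilities with the PBR multiplier
.site_rates <- function(base_rate, mask, multiplier) {
  r <- rep(base_rate, mask$fragment_length)
  r[.partition_sites(mask, "PBR")] <- base_rate * multiplier
  pmin(r, 0.75)
}

# mutate a char vector under per-site probabilities
.mutate_chars <- function(chars, rates) {
  hit <- which(runif(length(chars)) < rates)
  for (i in hit) {
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  chars
}

# re-draw any codon that became a stop until the fragment is stop-free
.fix_stops <- function(chars, n_codons) {
  repeat {
    cods <- apply(matrix(chars[seq_len(3L * n_codons)], nrow = 3L), 2L, paste,
                  collapse = "")
    bad <- which(cods %in% .stop_codons())
    if (!length(bad)) return(chars)
    for (cd in bad) {
      pos <- 3L * (cd - 1L) + sample.int(3L, 1L)
      chars[pos] <- sample(setdiff(.BASES, chars[pos]), 1L)
    }
  }
}

# place a random stop codon (not the first codon)
.introduce_stop <- function(chars, n_codons) {
  cd <- sample(2:n_codons, 1L)
  stop_chars <- strsplit(sample(.stop_codons(), 1L), "", fixed = TRUE)[[1]]
  chars[(3L * (cd - 1L) + 1L):(3L * cd)] <- stop_chars
  chars
}

# random synonymous recoding of codons, with probability `rate` per codon;
# restricted to third-position changes within the codon's block (same first
# two bases), which leave Nei-Gojobori non-synonymous counts exactly
# unchanged (a single-position synonymous difference has Nd = 0, whereas
# synonymous codons from different blocks, e.g. serine TCT/AGT, force
# non-synonymous pathway steps)
.syn_shuffle <- function(codons, rate) {
  code <- .genetic_code()
  hit <- which(runif(length(codons)) < rate)
  for (i in hit) {
    block <- paste0(substr(codons[i], 1L, 2L), .BASES)
    alts <- setdiff(block[code[block] == code[[codons[i]]]], codons[i])
    if (length(alts))
      codons[i] <- if (length(alts) == 1L) alts else sample(alts, 1L)
  }
  codons
}

.chars_to_seq <- function(chars) paste(chars, collapse = "")

#' Simulate a multispecies allele pool
#'
#' Generates per-species sets of 159-nt class II beta exon 2 alleles with
#' the statistical structure the downstream analyses assume: substitution
#' rates elevated at PBR sites by `pbr_mutation_multiplier`, a fraction
#' `pseudoallele_rate` of alleles carrying an in-frame stop, and a fraction
#' roughly `tsp_share_rate` shared identically between confamilial species.
#'
#' Three genealogical regimes are available via `config$pool_mode`:
#' `"family"` (default) evolves alleles down a family > species > locus >
#' allele star genealogy; `"tsp"` draws each locus's alleles from deep
#' allelic lineages that predate the family split, the structure produced
#' by long-term trans-species polymorphism; `"convergent"` gives every
#' family a private synonymous background while PBR amino-acid motifs are
#' shared across families, the structure produced by convergent selection.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per (allele, species) occurrence:
#'   `allele_id`, `species`, `family`, `locus`, `sequence`, `pseudo`,
#'   `shared` (TRUE once the allele occurs in >= 2 species), `origin`
#'   (lineage/motif annotation where applicable).
#' @export
simulate_allele_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 2L, .simulate_pool_impl(config))
}

.simulate_pool_impl <- function(config) {
  st <- config$species_table
  mask <- config$mask
  nc <- config$n_codons
  mult <- config$pbr_mutation_multiplier
  br <- config$branch_rates
  root <- .random_fragment(nc)

  rows <- list()
  add_row <- function(id, sp, fam, locus, chars, pseudo, origin) {
    rows[[length(rows) + 1L]] <<- data.frame(
      allele_id = id, species = sp, family = fam, locus = locus,
      sequence = .chars_to_seq(chars), pseudo = pseudo, origin = origin,
      stringsAsFactors = FALSE)
  }

  if (config$pool_mode == "family") {
    fam_anc <- lapply(unique(st$family), function(f)
      .fix_stops(.mutate_chars(root, .site_rates(br$family, mask, mult)), nc))
    names(fam_anc) <- unique(st$family)
    for (i in seq_len(nrow(st))) {
      sp <- st$species[i]; fam <- st$family[i]
      sp_anc <- .fix_stops(
        .mutate_chars(fam_anc[[fam]], .site_rates(br$species, mask, mult)), nc)
      for (l in seq_len(config$loci_per_species[[sp]])) {
        loc_anc <- .fix_stops(
          .mutate_chars(sp_anc, .site_rates(br$locus, mask, mult)), nc)
        for (a in seq_len(config$alleles_per_locus)) {
          chars <- .fix_stops(
            .mutate_chars(loc_anc, .site_rates(br$allele, mask, mult)), nc)
          pseudo <- runif(1) < config$pseudoallele_rate
          if (pseudo) chars <- .introduce_stop(chars, nc)
          add_row(sprintf("%s.L%02d.A%02d", st$prefix[i], l, a),
                  sp, fam, l, chars, pseudo, NA_character_)
        }
      }
    }
  } else if (config$pool_mode == "tsp") {
    op <- config$tsp_opts
    lin <- lapply(seq_len(op$n_lineages), function(k)
      .fix_stops(.mutate_chars(root, .site_rates(op$lineage_rate, mask, mult)),
                 nc))
    for (i in seq_len(nrow(st))) {
      sp <- st$species[i]; fam <- st$family[i]
      for (l in seq_len(config$loci_per_species[[sp]])) {
        k <- sample.int(op$n_lineages, 1L)
        for (a in seq_len(config$alleles_per_locus)) {
          chars <- .fix_stops(
            .mutate_chars(lin[[k]], .site_rates(op$tip_rate, mask, mult)), nc)
          pseudo <- runif(1) < config$pseudoallele_rate
          if (pseudo) chars <- .introduce_stop(chars, nc)
          add_row(sprintf("%s.L%02d.A%02d", st$prefix[i], l, a),
                  sp, fam, l, chars, pseudo, sprintf("lineage%02d", k))
        }
      }
    }
  } else { # convergent
    op <- config$conv_opts
    root_codons <- apply(matrix(root, nrow = 3L), 2L, paste, collapse = "")
    fams <- unique(st$family)
    fam_codons <- lapply(fams, function(f)
      .syn_shuffle(root_codons, op$family_syn_rate))
    names(fam_codons) <- fams
    aa20 <- setdiff(unique(.genetic_code()), "*")
    pbr <- mask$pbr_codons
    code <- .genetic_code()
    syn_sets <- split(names(code), code)
    # each motif is a PBR amino-acid vector with one representative codon
    # per position; families encode it with third-position synonymous
    # variants only, so the shared motif is invisible to dS structure but
    # identical under dN across families
    motifs <- lapply(seq_len(op$n_motifs), function(m) {
      aas <- sample(aa20, length(pbr), replace = TRUE)
      vapply(aas, function(a) {
        s <- syn_sets[[a]]
        if (length(s) == 1L) s else sample(s, 1L)
      }, character(1))
    })
    fam_motif_codons <- lapply(fams, function(f)
      lapply(motifs, function(mo) .syn_shuffle(mo, 1)))
    names(fam_motif_codons) <- fams
    for (i in seq_len(nrow(st))) {
      sp <- st$species[i]; fam <- st$family[i]
      for (l in seq_len(config$loci_per_species[[sp]])) {
        for (a in seq_len(config$alleles_per_locus)) {
          m <- sample.int(op$n_motifs, 1L)
          cods <- .syn_shuffle(fam_codons[[fam]], op$allele_syn_rate)
          # independent non-synonymous noise at non-PBR codons so alleles
          # are never exactly tied under dN within a (family, motif) class
          non_pbr <- setdiff(seq_along(cods), pbr)
          hit <- non_pbr[runif(length(non_pbr)) < op$allele_nonsyn_rate]
          if (length(hit))
            cods[hit] <- sample(.sense_codons(), length(hit), replace = TRUE)
          cods[pbr] <- fam_motif_codons[[fam]][[m]]
          chars <- unlist(strsplit(cods, "", fixed = TRUE), use.names = FALSE)
          pseudo <- runif(1) < config$pseudoallele_rate
          if (pseudo) chars <- .introduce_stop(chars, nc)
          add_row(sprintf("%s.L%02d.A%02d", st$prefix[i], l, a),
                  sp, fam, l, chars, pseudo, sprintf("motif%02d", m))
        }
      }
    }
  }
  pool <- do.call(rbind, rows)

  # enforce distinct sequences across distinct allele ids
  for (iter in seq_len(200L)) {
    dup <- duplicated(pool$sequence) & !duplicated(pool$allele_id)
    if (!any(dup)) break
    for (j in which(dup)) {
      chars <- strsplit(pool$sequence[j], "", fixed = TRUE)[[1]]
      chars <- .fix_stops(.mutate_chars(chars, rep(0.01, length(chars))), nc)
      if (pool$pseudo[j]) chars <- .introduce_stop(chars, nc)
      pool$sequence[pool$allele_id == pool$allele_id[j]] <- .chars_to_seq(chars)
    }
  }

  # trans-species copies within families (identical-sequence sharing)
  if (config$tsp_share_rate > 0) {
    extra <- list()
    for (j in seq_len(nrow(pool))) {
      mates <- st$species[st$family == pool$family[j] &
                            st$species != pool$species[j]]
      if (!length(mates) || runif(1) >= config$tsp_share_rate) next
      recip <- if (length(mates) == 1L) mates else sample(mates, 1L)
      extra[[length(extra) + 1L]] <- data.frame(
        allele_id = pool$allele_id[j], species = recip,
        family = pool$family[j],
        locus = sample.int(config$loci_per_species[[recip]], 1L),
        sequence = pool$sequence[j], pseudo = pool$pseudo[j],
        origin = pool$origin[j], stringsAsFactors = FALSE)
    }
    if (length(extra)) pool <- rbind(pool, do.call(rbind, extra))
    pool <- pool[!duplicated(pool[c("species", "sequence")]), ]
  }
  shared_ids <- names(which(tapply(pool$species, pool$allele_id,
                                   function(s) length(unique(s))) > 1L))
  pool$shared <- pool$allele_id %in% shared_ids
  rownames(pool) <- NULL
  stopifnot(all(nchar(pool$sequence) == config$fragment_length))
  pool
}
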