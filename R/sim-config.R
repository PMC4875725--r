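# simulation configuration: study layout, rates, tags

#' Four-letter species code
#'
#' Builds the conventional allele-name prefix from a Latin binomial:
#' the first two letters of the genus and of the epithet, capitalised
#' as e.g. `"Climacteris picumnus"` -> `"Clpi"`.
#'
#' @param species character vector of binomials.
#' @return character vector of 4-letter codes.
#' @export
species_code <- function(species) {
  parts <- strsplit(species, "[ _]+")
  vapply(parts, function(p) {
    stopifnot(length(p) >= 2L)
    paste0(toupper(substr(p[1], 1, 1)), tolower(substr(p[1], 2, 2)),
           tolower(substr(p[2], 1, 2)))
  }, character(1))
}

#' Default species panel
#'
#' Seven Australian passerines from four basal families (Climacteridae,
#' Meliphagidae, Maluridae, Pardalotidae), the study design the simulator
#' emulates by default.
#'
#' @return data.frame with columns `species`, `genus`, `family`, `prefix`.
#' @export
default_species_table <- function() {
  species <- c("Climacteris picumnus",
               "Lichenostomus melanops",
               "Lichenostomus penicillatus",
               "Lichenostomus fuscus",
               "Malurus cyaneus",
               "Pardalotus punctatus",
               "Pardalotus striatus")
  family <- c("Climacteridae", "Meliphagidae", "Meliphagidae", "Meliphagidae",
              "Maluridae", "Pardalotidae", "Pardalotidae")
  data.frame(species = species,
             genus  = vapply(strsplit(species, " "), `[`, character(1), 1L),
             family = family,
             prefix = species_code(species),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  All randomness
#' downstream is derived from `seed`, so an identical configuration yields
#' byte-identical outputs.
#'
#' Defaults mirror the emulated study design: 7 species in 4 families, 5-9
#' class II beta loci per species, diploid genotypes, about 5 % pseudoalleles
#' and 8 % cross-species shared alleles, a 159-bp (53-codon) fragment with
#' substitution rates elevated at peptide-binding-region (PBR) sites, two
#' independent PCRs per individual, negative-binomial per-allele coverage
#' with mean 250 reads (summed over replicates, spanning roughly 100-600),
#' per-base substitution error 0.002 and PCR-chimera rate 0.01.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param species_table data.frame like [default_species_table()].
#' @param n_species use only the first `n_species` rows of `species_table`.
#' @param loci_per_species named integer vector (names = species); drawn
#'   uniformly from `loci_range` when `NULL`.
#' @param loci_range inclusive range loci counts are drawn from.
#' @param alleles_per_locus alleles segregating per locus in a species pool.
#' @param tsp_share_rate probability an allele is copied into a congeneric /
#'   confamilial species' pool (trans-species sharing).
#' @param pseudoallele_rate probability an allele carries an in-frame stop.
#' @param pbr_mutation_multiplier substitution-rate multiplier at PBR sites
#'   (must be >= 1).
#' @param pool_mode `"family"` (family-structured pools; default), `"tsp"`
#'   (deep allelic lineages predating the family split) or `"convergent"`
#'   (shared PBR amino-acid motifs on family-specific synonymous
#'   backgrounds).  The latter two are the contrasting regimes for the
#'   TSP-versus-convergence diagnostic.
#' @param branch_rates per-site substitution probabilities on the family /
#'   species / locus / allele branches of the star genealogy.
#' @param tsp_opts list: `n_lineages`, `lineage_rate`, `tip_rate` for
#'   `pool_mode = "tsp"`.
#' @param conv_opts list: `n_motifs`, `family_syn_rate`, `allele_syn_rate`,
#'   `allele_nonsyn_rate` for `pool_mode = "convergent"`.
#' @param n_individuals_per_species sampled individuals per species.
#' @param n_pcr_replicates independent PCRs per individual (>= 2).
#' @param reads_mean expected reads per allele copy per individual, summed
#'   over PCR replicates.
#' @param reads_floor guaranteed minimum reads per allele copy per
#'   individual (split evenly across replicates).  Real per-allele
#'   coverages in this kind of run span roughly 100-600 reads and never
#'   approach zero, so the negative-binomial spread rides on this floor;
#'   it also keeps every true allele above the relative-coverage filter.
#' @param reads_dispersion negative-binomial size parameter for the
#'   per-replicate coverage spread above the floor (smaller = more
#'   spread).
#' @param per_base_error_rate per-base substitution error probability.
#' @param chimera_rate probability a read is a two-parent single-breakpoint
#'   recombinant.
#' @param n_clones Sanger clones picked per individual per PCR.
#' @param mask PBR site mask, see [site_mask()].
#' @param mid_table data.frame (`individual`, `tag`) of 10-bp multiplex
#'   identifier tags; generated deterministically when `NULL`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species_table = default_species_table(),
                       n_species = nrow(species_table),
                       loci_per_species = NULL,
                       loci_range = c(5L, 9L),
                       alleles_per_locus = 3L,
                       tsp_share_rate = 0.08,
                       pseudoallele_rate = 0.05,
                       pbr_mutation_multiplier = 5,
                       pool_mode = c("family", "tsp", "convergent"),
                       branch_rates = list(family = 0.06, species = 0.02,
                                           locus = 0.03, allele = 0.02),
                       tsp_opts = list(n_lineages = 6L, lineage_rate = 0.12,
                                       tip_rate = 0.01),
                       conv_opts = list(n_motifs = 4L, family_syn_rate = 0.12,
                                        allele_syn_rate = 0.04,
                                        allele_nonsyn_rate = 0.06),
                       n_individuals_per_species = 2L,
                       n_pcr_replicates = 2L,
                       reads_mean = 250,
                       reads_floor = 100,
                       reads_dispersion = 5,
                       per_base_error_rate = 0.002,
                       chimera_rate = 0.01,
                       n_clones = 20L,
                       mask = default_pbr_mask(),
                       mid_table = NULL) {
  pool_mode <- match.arg(pool_mode)
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  seed <- as.integer(seed)
  stopifnot(n_species >= 1L, n_species <= nrow(species_table))
  species_table <- species_table[seq_len(n_species), , drop = FALSE]
  for (p in c(tsp_share_rate, pseudoallele_rate, per_base_error_rate,
              chimera_rate)) {
    if (!.is_prob(p)) stop("probability parameters must lie in [0, 1]")
  }
  if (!is.numeric(pbr_mutation_multiplier) || pbr_mutation_multiplier < 1)
    stop("pbr_mutation_multiplier must be >= 1")
  if (n_pcr_replicates < 2L)
    stop("n_pcr_replicates must be >= 2 (replicate validation needs two PCRs)")
  stopifnot(reads_mean > 0, reads_dispersion > 0, alleles_per_locus >= 1L,
            reads_floor >= 0, reads_floor < reads_mean)

  sp <- species_table$species
  if (is.null(loci_per_species)) {
    loci_per_species <- .with_seed(seed, {
      setNames(sample(seq.int(loci_range[1], loci_range[2]),
                      length(sp), replace = TRUE), sp)
    })
  } else {
    stopifnot(all(sp %in% names(loci_per_species)))
    loci_per_species <- loci_per_species[sp]
  }
  individuals <- data.frame(
    individual = unlist(lapply(seq_along(sp), function(i) {
      sprintf("%s_%02d", species_table$prefix[i],
              seq_len(n_individuals_per_species))
    }), use.names = FALSE),
    species = rep(sp, each = n_individuals_per_species),
    stringsAsFactors = FALSE)

  if (is.null(mid_table)) {
    mid_table <- .with_seed(seed + 1L, {
      tags <- character(0)
      while (length(tags) < nrow(individuals) * n_pcr_replicates) {
        cand <- paste(sample(.BASES, 10L, replace = TRUE), collapse = "")
        if (!cand %in% tags) tags <- c(tags, cand)
      }
      # one tag per individual; replicate identity comes from the read file
      data.frame(individual = individuals$individual,
                 tag = tags[seq_len(nrow(individuals))],
                 stringsAsFactors = FALSE)
    })
  }
  if (anyDuplicated(mid_table$tag)) stop("MID tags must be pairwise distinct")
  if (any(nchar(mid_table$tag) != 10L)) stop("MID tags must be 10 bp")

  cfg <- list(seed = seed, species_table = species_table,
              loci_per_species = loci_per_species,
              alleles_per_locus = as.integer(alleles_per_locus),
              tsp_share_rate = tsp_share_rate,
              pseudoallele_rate = pseudoallele_rate,
              pbr_mutation_multiplier = pbr_mutation_multiplier,
              pool_mode = pool_mode, branch_rates = branch_rates,
              tsp_opts = tsp_opts, conv_opts = conv_opts,
              n_individuals_per_species = as.integer(n_individuals_per_species),
              n_pcr_replicates = as.integer(n_pcr_replicates),
              reads_mean = reads_mean, reads_floor = reads_floor,
              reads_dispersion = reads_dispersion,
              per_base_error_rate = per_base_error_rate,
              chimera_rate = chimera_rate, n_clones = as.integer(n_clones),
              fragment_length = 159L, n_codons = 53L,
              mask = mask, individuals = individuals, mid_table = mid_table)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  species: ", nrow(x$species_table), " in ",
      length(unique(x$species_table$family)), " families; loci per species ",
      paste(range(x$loci_per_species), collapse = "-"), "\n", sep = "")
  cat("  pool mode: ", x$pool_mode,
      "; tsp_share_rate ", x$tsp_share_rate,
      "; pseudoallele_rate ", x$pseudoallele_rate,
      "; PBR multiplier ", x$pbr_mutation_multiplier, "\n", sep = "")
  cat("  individuals/species: ", x$n_individuals_per_species,
      "; PCR replicates: ", x$n_pcr_replicates,
      "; reads/allele mean ", x$reads_mean,
      "; error ", x$per_base_error_rate,
      "; chimera ", x$chimera_rate, "\n", sep = "")
  invisible(x)
}
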