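# small simulation configurations shared across tests

tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_species = 4L,
             loci_per_species = setNames(c(3L, 2L, 3L, 2L),
                                         default_species_table()$species[1:4]),
             alleles_per_locus = 2L, n_individuals_per_species = 1L,
             reads_mean = 60, reads_floor = 20, ...)
}

noise_free_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, per_base_error_rate = 0, chimera_rate = 0, ...)
}

# hand-built genotype table (one individual, one locus)
manual_genotype <- function(alleles, individual = "X_01",
                            species = "Climacteris picumnus") {
  data.frame(individual = individual, species = species, locus = 1L,
             copy = seq_along(alleles),
             allele_id = paste0("A", seq_along(alleles)),
             sequence = alleles, stringsAsFactors = FALSE)
}
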