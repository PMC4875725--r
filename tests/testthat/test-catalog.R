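test_that("the catalogue deduplicates sequences and tracks occurrence sets", {
  s1 <- random_cds(53); s2 <- random_cds(53)
  calls <- data.frame(
    individual = c("Clpi_01", "Clpi_02", "Lime_01"),
    species = c("Climacteris picumnus", "Climacteris picumnus",
                "Lichenostomus melanops"),
    sequence = c(s1, s1, s2))
  cat <- build_catalog(calls)
  expect_identical(nrow(cat), 2L)
  expect_identical(cat$name, c("Clpi01", "Lime01"))
  expect_identical(cat$n_individuals, c(2L, 1L))
  # one sequence in two species -> one entry with a two-species set
  calls2 <- rbind(calls, data.frame(individual = "Lime_02",
                                    species = "Lichenostomus melanops",
                                    sequence = s1))
  cat2 <- build_catalog(calls2)
  expect_identical(nrow(cat2), 2L)
  expect_identical(cat2$n_species[cat2$sequence == s1], 2L)
  expect_error(build_catalog(calls[, c("individual", "sequence")]),
               "species_map")
})

test_that("minimum-locus inference is the diploid ceiling bound", {
  expect_identical(infer_min_loci(17L), 9L)
  expect_identical(infer_min_loci(10L), 5L)
  expect_identical(infer_min_loci(2L), 1L)
  expect_error(infer_min_loci(0L))
  k <- 1:25
  expect_true(all(diff(infer_min_loci(k)) >= 0L))
  expect_identical(infer_min_loci(2L * k), infer_min_loci(2L * k - 1L))
  expect_identical(infer_min_loci(2L * k), k)
})

test_that("method overlap reproduces the cross-method allele accounting", {
  seqs <- replicate(177, random_cds(53))
  stopifnot(!anyDuplicated(seqs))
  a <- data.frame(sequence = seqs[1:81])
  b <- data.frame(sequence = seqs[44:177])
  ov <- method_overlap(a, b)
  expect_identical(ov$n_a, 81L)
  expect_identical(ov$n_b, 134L)
  expect_identical(ov$intersection, 38L)
  expect_identical(ov$union, 177L)
  # degenerate cases
  d <- method_overlap(data.frame(sequence = seqs[1:5]),
                      data.frame(sequence = seqs[6:10]))
  expect_identical(d$union, 10L)
  s <- method_overlap(data.frame(sequence = seqs[1:5]),
                      data.frame(sequence = seqs[1:10]))
  expect_identical(s$union, 10L)
})

test_that("within-species duplicate observations collapse to unique alleles", {
  # 98 observations of which 17 are second-species duplicates -> 81 entries
  sp <- default_species_table()$species
  useq <- replicate(81, random_cds(53))
  first_obs <- data.frame(individual = paste0("i", 1:81),
                          species = sample(sp, 81, TRUE), sequence = useq)
  dup_obs <- data.frame(individual = paste0("j", 1:17),
                        species = NA, sequence = useq[1:17])
  for (k in 1:17)  # a different species than the first observation
    dup_obs$species[k] <- sample(setdiff(sp, first_obs$species[k]), 1)
  calls <- rbind(first_obs, dup_obs)
  expect_identical(nrow(calls), 98L)
  cat <- build_catalog(calls, method = "cloning")
  expect_identical(nrow(cat), 81L)
})

test_that("shared alleles are classified by genus and family", {
  meta <- default_species_table()
  s <- replicate(3, random_cds(53))
  calls <- data.frame(
    individual = c("a", "b", "c", "d", "e", "f"),
    species = c("Pardalotus punctatus", "Pardalotus striatus",
                "Lichenostomus melanops", "Malurus cyaneus",
                "Climacteris picumnus", "Climacteris picumnus"),
    sequence = s[c(1, 1, 2, 2, 3, 3)])
  cat <- build_catalog(calls)
  sh <- shared_alleles(cat, meta)
  expect_identical(nrow(sh), 2L)
  expect_setequal(sh$classification, c("within-genus", "cross-family"))
  # a no-sharing simulation yields an empty table
  cfg <- tiny_config(seed = 31, tsp_share_rate = 0)
  pool <- simulate_allele_pool(cfg)
  cat0 <- build_catalog(data.frame(individual = pool$allele_id,
                                   species = pool$species,
                                   sequence = pool$sequence))
  expect_identical(nrow(shared_alleles(cat0, meta)), 0L)
})

test_that("sharing recorded in the catalogue matches the generator manifest", {
  cfg <- sim_config(seed = 32, tsp_share_rate = 0.3,
                    n_individuals_per_species = 1L)
  pool <- simulate_allele_pool(cfg)
  calls <- data.frame(individual = paste0(pool$species, "_x"),
                      species = pool$species, sequence = pool$sequence)
  cat <- build_catalog(calls)
  sh <- shared_alleles(cat, cfg$species_table)
  manifest_shared <- unique(pool$sequence[pool$shared])
  expect_setequal(cat$sequence[cat$n_species >= 2], manifest_shared)
  expect_identical(nrow(sh), length(manifest_shared))
  # the generator shares within families only
  expect_true(all(sh$classification %in% c("within-genus", "within-family")))
})

test_that("the per-species summary reports ranges, loci and pseudoalleles", {
  sp <- "Climacteris picumnus"
  seqs <- replicate(20, random_cds(53))
  calls <- data.frame(
    individual = rep(c("i1", "i2"), c(17, 8)),
    species = sp,
    sequence = c(seqs[1:17], seqs[c(1:5, 18:20)]))
  cat <- build_catalog(calls)
  ann <- annotate_orfs(setNames(cat$sequence, cat$name), mask = site_mask())
  smry <- summarize_catalog(cat, calls, ann)
  expect_identical(smry$n_alleles, 20L)
  expect_identical(smry$range, "8-17")
  expect_identical(smry$n_loci, 9L)
  expect_identical(smry$n_pseudo, sum(ann$pseudo))
  one <- summarize_catalog(cat, calls[calls$individual == "i2", ], ann)
  expect_identical(one$range, "8-8")
})

test_that("a catalogue round-trips through TSV + FASTA with an identical summary", {
  cfg <- tiny_config(seed = 33)
  sim <- simulate_study(cfg)
  g <- genotype_amplicons(sim$reads, cfg$mid_table)
  calls <- g$alleles
  calls$species <- cfg$individuals$species[
    match(calls$individual, cfg$individuals$individual)]
  cat <- build_catalog(calls)
  dir <- withr::local_tempdir()
  write_catalog(cat, dir)
  cat2 <- read_catalog(dir)
  expect_identical(as.data.frame(cat)[c("name", "sequence", "species")],
                   as.data.frame(cat2)[c("name", "sequence", "species")])
  expect_identical(summarize_catalog(cat, calls), summarize_catalog(cat2, calls))
  fa <- read_fasta(file.path(dir, "catalog.fa"))
  expect_identical(unname(fa), cat$sequence)
})

test_that("inferred minimum loci never exceed the simulated truth", {
  for (s in 1:3) {
    cfg <- tiny_config(seed = 40 + s)
    sim <- simulate_study(cfg)
    g <- genotype_amplicons(sim$reads, cfg$mid_table)
    calls <- g$alleles
    calls$species <- cfg$individuals$species[
      match(calls$individual, cfg$individuals$individual)]
    smry <- summarize_catalog(build_catalog(calls), calls)
    expect_true(all(smry$n_loci <= cfg$loci_per_species[smry$species]))
  }
})
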