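test_that("transition/transversion counting matches hand-classified cases", {
  expect_equal(count_PQ("ACGT", "ACGT"), c(P = 0, Q = 0, L = 4))
  # G<->T is a transversion
  expect_equal(count_PQ("AAGG", "AAGT"), c(P = 0, Q = 0.25, L = 4))
  # A<->G are all transitions
  expect_equal(count_PQ("AAAA", "GGGG"), c(P = 1, Q = 0, L = 4))
  # pairwise deletion of ambiguous sites
  expect_equal(count_PQ("AANA", "AAAG"), c(P = 1 / 3, Q = 0, L = 3))
  expect_error(count_PQ("NNN", "AAA"), "no comparable")
})

test_that("the K2P closed form and its small-distance behaviour hold", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0, 0.25),
               -0.5 * log(1 - 0.25) - 0.25 * log(1 - 0.5), tolerance = 1e-12)
  expect_equal(k2p_distance(0.125, 0.25),
               -0.5 * log(0.5) - 0.25 * log(0.5), tolerance = 1e-12)
  # first-order behaviour: d ~ P for small transition-only divergence
  expect_lt(abs(k2p_distance(0.01, 0) - 0.01), 2e-4)
  # saturation is flagged as NA
  expect_true(is.na(k2p_distance(0.6, 0)))
  expect_true(is.na(k2p_distance(0, 0.5)))
})

test_that("K2P correction never falls below the observed p-distance", {
  set.seed(5)
  for (i in 1:50) {
    P <- runif(1, 0, 0.35); Q <- runif(1, 0, 0.2)
    d <- k2p_distance(P, Q)
    if (!is.na(d)) expect_gte(d, P + Q - 1e-12)
  }
})

test_that("the Poisson amino-acid correction matches its closed form", {
  expect_equal(poisson_aa_distance("MKLV", "MKLV"), 0)
  expect_equal(poisson_aa_distance("MK", "MV"), log(2), tolerance = 1e-12)
  aa <- strrep("K", 53); bb <- paste0(strrep("K", 52), "R")
  expect_equal(poisson_aa_distance(aa, bb), -log(1 - 1 / 53),
               tolerance = 1e-12)
  expect_true(is.na(poisson_aa_distance("KK", "RR")))
  # stops and X are deleted pairwise
  expect_equal(poisson_aa_distance("K*K", "KRK"), 0)
})

test_that("mean pairwise distance equals the brute-force average", {
  set.seed(6)
  base <- random_cds(53)
  mutate_nt <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(159, k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- setNames(c(base, vapply(c(5L, 9L, 14L, 20L), mutate_nt, "",
                                  s = base)), paste0("s", 1:5))
  m <- k2p_matrix(seqs)
  brute <- mean(apply(utils::combn(5, 2), 2, function(ij) {
    pq <- count_PQ(seqs[ij[1]], seqs[ij[2]])
    k2p_distance(pq["P"], pq["Q"])
  }))
  expect_equal(mean_pairwise(m), brute, tolerance = 1e-12)
  expect_equal(mean_pairwise(matrix(0, 3, 3)), 0)
  two <- k2p_matrix(seqs[1:2])
  expect_equal(mean_pairwise(two), two[2, 1])
})

test_that("partitioned matrices respect the mask", {
  mask <- site_mask(pbr_codons = 1:10)
  a <- random_cds(53)
  b <- a
  substr(b, 3, 3) <- if (substr(a, 3, 3) == "G") "T" else "G"  # PBR codon 1
  seqs <- c(x = a, y = b)
  expect_gt(mean_pairwise(k2p_matrix(seqs, mask, "PBR")), 0)
  expect_equal(mean_pairwise(k2p_matrix(seqs, mask, "non-PBR")), 0)
})

test_that("bootstrap standard errors are deterministic and near the delta method", {
  # identical sequences -> SE exactly 0
  same <- c(a = strrep("ACG", 53), b = strrep("ACG", 53))
  expect_equal(as.numeric(bootstrap_se(same, site_mask(), reps = 50)), 0)
  # transition-only divergence at an exact fraction of sites:
  # d = -log(1 - 2P)/2, SE_delta = sqrt(P(1-P)/L) / (1 - 2P)
  L <- 500L
  P <- 0.2
  a <- strrep("A", L)
  b <- paste0(strrep("G", L * P), strrep("A", L * (1 - P)))
  mask <- site_mask(fragment_length = L)
  se <- bootstrap_se(c(a = a, b = b), mask, model = "K2P", reps = 1000,
                     seed = 3, unit = "nucleotide")
  se_delta <- sqrt(P * (1 - P) / L) / (1 - 2 * P)
  expect_lt(abs(as.numeric(se) - se_delta) / se_delta, 0.15)
  se2 <- bootstrap_se(c(a = a, b = b), mask, model = "K2P", reps = 1000,
                      seed = 3, unit = "nucleotide")
  expect_identical(as.numeric(se), as.numeric(se2))
})

test_that("the Poisson bootstrap SE matches the delta method on codon units", {
  # 200 codons, exactly 30% differing residues:
  # d = -log(1-p), SE_delta = sqrt(p(1-p)/L) / (1-p)
  n_cod <- 200L
  p <- 0.3
  a <- strrep("AAA", n_cod)                       # poly-K
  b <- paste0(strrep("AGA", n_cod * p), strrep("AAA", n_cod * (1 - p)))  # R
  mask <- site_mask(fragment_length = 3L * n_cod)
  se <- bootstrap_se(c(a = a, b = b), mask, model = "PoissonAA", reps = 1000,
                     seed = 4)
  se_delta <- sqrt(p * (1 - p) / n_cod) / (1 - p)
  expect_lt(abs(as.numeric(se) - se_delta) / se_delta, 0.15)
})

test_that("PBR diversity exceeds non-PBR diversity across simulated pools", {
  wins <- 0L
  for (s in 1:5) {
    cfg <- sim_config(seed = 60 + s, pbr_mutation_multiplier = 5,
                      n_individuals_per_species = 1L)
    pool <- simulate_allele_pool(cfg)
    sp <- pool[pool$species == pool$species[1] & !pool$pseudo, ]
    seqs <- setNames(sp$sequence, sp$allele_id)
    pbr <- suppressWarnings(mean_pairwise(k2p_matrix(seqs, cfg$mask, "PBR")))
    non <- suppressWarnings(mean_pairwise(k2p_matrix(seqs, cfg$mask,
                                                     "non-PBR")))
    wins <- wins + (pbr > non)
  }
  expect_gte(wins, 4L)
})

test_that("the diversity table has the expected layout and orderings", {
  cfg <- tiny_config(seed = 66)
  pool <- simulate_allele_pool(cfg)
  keep <- !pool$pseudo
  by_sp <- split(setNames(pool$sequence[keep], pool$allele_id[keep]),
                 pool$species[keep])
  tab <- suppressWarnings(diversity_table(by_sp, cfg$mask, reps = 100,
                                          seed = 2))
  expect_setequal(unique(tab$partition), c("all", "PBR", "non-PBR"))
  expect_setequal(unique(tab$level), c("nt", "aa"))
  expect_true(all(tab$mean >= 0) && all(tab$se >= 0))
  # all-sites mean lies between the two partition means
  for (sp in unique(tab$species)) for (lv in c("nt", "aa")) {
    sub <- tab[tab$species == sp & tab$level == lv, ]
    rng <- range(sub$mean[sub$partition != "all"])
    expect_gte(sub$mean[sub$partition == "all"], rng[1] - 5e-3)
    expect_lte(sub$mean[sub$partition == "all"], rng[2] + 5e-3)
  }
})
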