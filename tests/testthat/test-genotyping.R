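fwd <- mhc_primers()$fwd
rev <- mhc_primers()$rev

# one concrete realization of the degenerate primers (Y->C, N->A, K->G, S->C)
realize <- function(p) {
  chartr("YNKS", "CAGC", p)
}

make_read <- function(template, mid = "ACGTACGTAC",
                      fwd_r = realize(fwd), rev_r = realize(rev)) {
  paste0("GGGG", mid, fwd_r, template, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_r))))
}

test_that("primer matching trims a constructed read back to its template", {
  tpl <- random_cds(53)
  r <- make_read(tpl)
  hit <- match_and_trim(r)
  expect_identical(hit$template, tpl)
  expect_identical(hit$mid, "ACGTACGTAC")
  expect_identical(hit$orientation, "fwd")
  # reverse-orientation read gives the same canonical template
  hit_rev <- match_and_trim(revcomp(r))
  expect_identical(hit_rev$template, tpl)
  expect_identical(hit_rev$orientation, "rev")
})

test_that("a single mismatch at a non-degenerate primer position kills the match", {
  tpl <- random_cds(53)
  f <- realize(fwd)
  substr(f, 1, 1) <- "T"  # true first base is G, non-degenerate
  hit <- match_and_trim(make_read(tpl, fwd_r = f))
  expect_true(is.na(hit$template))
})

test_that("degenerate positions match exactly the IUPAC-compatible bases", {
  tpl <- random_cds(53)
  # position 6 of the forward primer is Y = {C, T}
  f_ok <- realize(fwd); substr(f_ok, 6, 6) <- "C"
  f_ok2 <- realize(fwd); substr(f_ok2, 6, 6) <- "T"
  f_bad <- realize(fwd); substr(f_bad, 6, 6) <- "G"
  expect_false(is.na(match_and_trim(make_read(tpl, fwd_r = f_ok))$template))
  expect_false(is.na(match_and_trim(make_read(tpl, fwd_r = f_ok2))$template))
  expect_true(is.na(match_and_trim(make_read(tpl, fwd_r = f_bad))$template))
})

test_that("demultiplexing is exact-match only", {
  tpl <- random_cds(53)
  mids <- data.frame(individual = c("A", "B"),
                     tag = c("ACGTACGTAC", "TTTTCCCCGG"))
  reads <- data.frame(
    template = tpl,
    mid = c("ACGTACGTAC", "ACGTACGTAA", "TTTTCCCCGG"),
    stringsAsFactors = FALSE)
  out <- demultiplex(reads, mids)
  expect_identical(out$individual, c("A", NA, "B"))
  expect_identical(attr(out, "n_unassigned"), 1L)
  expect_error(demultiplex(reads, data.frame(individual = c("A", "B"),
                                             tag = rep("ACGTACGTAC", 2))),
               "duplicate")
})

test_that("demultiplexed per-individual read counts match the generator", {
  cfg <- noise_free_config(seed = 21)
  sim <- simulate_study(cfg)
  trimmed <- match_and_trim(sim$reads$sequence)
  trimmed$pcr <- sim$reads$pcr
  out <- demultiplex(trimmed, cfg$mid_table)
  expect_identical(as.vector(table(out$individual)[
    sort(unique(sim$reads$true_individual))]),
    as.vector(table(sim$reads$true_individual)[
      sort(unique(sim$reads$true_individual))]))
})

test_that("the dataset filter applies the exact-length and 2-PCR/3-read rules", {
  v <- data.frame(
    sequence = c(rep(strrep("A", 159), 2), rep(strrep("C", 159), 2),
                 rep(strrep("G", 158), 2)),
    individual = "X",
    pcr = c(1L, 2L, 1L, 2L, 1L, 2L),
    count = c(3L, 3L, 10L, 2L, 50L, 50L))
  out <- dataset_filter(v)
  expect_identical(unique(out$sequence), strrep("A", 159))
  expect_error(dataset_filter(v, required_length = 0), "positive")
})

test_that("qualifying PCRs may come from different individuals at dataset scope", {
  s <- strrep("T", 159)
  v <- data.frame(sequence = s, individual = c("X", "Y"), pcr = 1L,
                  count = c(5L, 5L))
  expect_identical(nrow(dataset_filter(v, scope = "dataset")), 2L)
  expect_identical(nrow(dataset_filter(v, scope = "individual")), 0L)
})

test_that("raising the replicate thresholds never enlarges the retained set", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 40L
    v <- data.frame(
      sequence = strrep(sample(c("A", "C", "G", "T"), n, TRUE), 159),
      individual = sample(c("X", "Y"), n, TRUE),
      pcr = sample(1:3, n, TRUE),
      count = sample(1:6, n, TRUE))
    v <- v[!duplicated(v[c("sequence", "individual", "pcr")]), ]
    base <- unique(dataset_filter(v)$sequence)
    expect_true(all(unique(dataset_filter(v, min_reads_per_pcr = 4)$sequence)
                    %in% base))
    expect_true(all(unique(dataset_filter(v, min_pcrs = 3)$sequence)
                    %in% base))
  }
})

test_that("the relative-coverage filter keeps ties and drops strictly-lower variants", {
  v <- data.frame(sequence = c("s1", "s2", "s3"), individual = "X",
                  pcr = 1L, count = c(570L, 114L, 56L))
  out <- individual_filter(v)
  expect_setequal(out$sequence, c("s1", "s2"))   # 56 < 57 = 0.1 * 570
  # exact tie at the threshold is kept
  v2 <- data.frame(sequence = c("a", "b"), individual = "X", pcr = 1L,
                   count = c(100L, 10L))
  expect_identical(nrow(individual_filter(v2)), 2L)
  # a single variant is its own maximum
  v3 <- data.frame(sequence = "a", individual = "X", pcr = 1L, count = 4L)
  expect_identical(individual_filter(v3)$sequence, "a")
  expect_error(individual_filter(v3[0, ]), "empty")
})

test_that("the maximal-coverage variant survives any threshold up to one", {
  set.seed(7)
  for (rep in 1:5) {
    v <- data.frame(sequence = paste0("s", 1:6),
                    individual = rep(c("X", "Y"), each = 3),
                    pcr = 1L, count = sample(1:500, 6))
    for (thr in c(0.1, 0.5, 1)) {
      out <- individual_filter(v, thr)
      for (ind in c("X", "Y")) {
        vi <- v[v$individual == ind, ]
        expect_true(vi$sequence[which.max(vi$count)] %in%
                      out$sequence[out$individual == ind])
      }
    }
  }
})

test_that("clone validation needs presence in two independent PCRs", {
  cl <- data.frame(individual = c("X", "X", "X", "Y"),
                   pcr = c(1L, 2L, 1L, 1L),
                   sequence = c("aa", "aa", "bb", "cc"))
  expect_warning(out <- validate_clones(cl), "unvalidatable")
  expect_identical(out$sequence, "aa")
  expect_identical(attr(out, "unvalidatable"), "Y")
})

test_that("zero-noise clone fixtures validate back to the true genotypes", {
  cfg <- noise_free_config(seed = 23, n_clones = 60L)
  sim <- simulate_study(cfg)
  val <- validate_clones(sim$clones)
  rec <- recovery_stats(val, sim$truth)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})

test_that("the filtering report reproduces the printed retention arithmetic", {
  rep <- summarize_filtering(reads_in = 16257, reads_retained = 10783)
  expect_identical(rep$retained_percent, 66L)
  expect_identical(summarize_filtering(100, 100)$retained_percent, 100L)
  expect_identical(summarize_filtering(100, 0)$retained_percent, 0L)
  expect_error(summarize_filtering(0, 0))
  bad <- data.frame(stage = "s", variants_in = 1, variants_out = 2)
  expect_error(summarize_filtering(10, 5, stages = bad))
})

test_that("noise-free amplicon genotyping recovers the truth exactly", {
  cfg <- noise_free_config(seed = 25)
  sim <- simulate_study(cfg)
  g <- genotype_amplicons(sim$reads, cfg$mid_table)
  rec <- recovery_stats(g$alleles, sim$truth)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_true(all(diff(c(g$report$reads_in, g$report$reads_retained)) <= 0))
})

test_that("adding reads of a retained variant never removes it", {
  cfg <- noise_free_config(seed = 26)
  sim <- simulate_study(cfg)
  g <- genotype_amplicons(sim$reads, cfg$mid_table)
  # duplicate some reads of the first retained allele
  s <- g$alleles$sequence[1]
  extra <- sim$reads[sim$reads$template == s, ][1:10, ]
  g2 <- genotype_amplicons(rbind(sim$reads, extra), cfg$mid_table)
  expect_true(s %in% g2$alleles$sequence)
})
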