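# diploid genotype simulation over a species allele pool

#' Simulate diploid genotypes
#'
#' For every individual and every locus of its species, two allele copies
#' are drawn uniformly with replacement from that locus's alleles in the
#' species pool (so homozygotes arise naturally).  The per-individual
#' distinct-allele count is therefore bounded by twice the locus count.
#'
#' @param pool output of [simulate_allele_pool()].
#' @param config the [sim_config()] that generated the pool.
#' @return data.frame with one row per chromosome copy: `individual`,
#'   `species`, `locus`, `copy` (1 or 2), `allele_id`, `sequence`.
#' @export
simulate_genotypes <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"))
  missing_sp <- setdiff(config$individuals$species, pool$species)
  if (length(missing_sp))
    stop("species missing from pool: ", paste(missing_sp, collapse = ", "))
  .with_seed(config$seed + 3L, {
    rows <- list()
    for (i in seq_len(nrow(config$individuals))) {
      ind <- config$individuals$individual[i]
      sp <- config$individuals$species[i]
      sp_pool <- pool[pool$species == sp, , drop = FALSE]
      for (l in seq_len(config$loci_per_species[[sp]])) {
        loc <- sp_pool[sp_pool$locus == l, , drop = FALSE]
        if (!nrow(loc)) next
        pick <- sample.int(nrow(loc), 2L, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, species = sp, locus = l, copy = 1:2,
          allele_id = loc$allele_id[pick], sequence = loc$sequence[pick],
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' True allele sets per individual
#'
#' @param genotypes output of [simulate_genotypes()].
#' @return data.frame (`individual`, `sequence`) of distinct true alleles,
#'   the ground truth the validation filters are measured against.
#' @export
true_allele_sets <- function(genotypes) {
  out <- unique(genotypes[c("individual", "sequence")])
  rownames(out) <- NULL
  out
}

#' Precision and recall of called alleles against simulated truth
#'
#' Both sets are treated as (individual, sequence) pairs.
#'
#' @param called data.frame with columns `individual`, `sequence`.
#' @param truth data.frame with columns `individual`, `sequence`
#'   (e.g. [true_allele_sets()]).
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
recovery_stats <- function(called, truth) {
  key <- function(d) paste(d$individual, d$sequence, sep = "\r")
  ck <- unique(key(called)); tk <- unique(key(truth))
  tp <- length(intersect(ck, tk))
  list(precision = if (length(ck)) tp / length(ck) else NA_real_,
       recall = if (length(tk)) tp / length(tk) else NA_real_,
       tp = tp, fp = length(ck) - tp, fn = length(tk) - tp)
}
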