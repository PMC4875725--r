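# partitioned diversity: K2P nucleotide and Poisson-corrected amino-acid
# distances with site-bootstrap standard errors

#' Transition/transversion proportions between two aligned sequences
#'
#' Sites where either sequence has a non-ACGT character are excluded
#' (pairwise deletion).  `site_subset` may contain repeated indices, which
#' is how bootstrap resampling reuses this function.
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @param site_subset 1-based site indices to compare (default: all).
#' @return named numeric vector `c(P, Q, L)`: transition proportion,
#'   transversion proportion, number of compared sites.
#' @export
count_PQ <- function(seq_a, seq_b, site_subset = NULL) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (!is.null(site_subset)) {
    stopifnot(all(site_subset >= 1L), all(site_subset <= length(a)))
    a <- a[site_subset]; b <- b[site_subset]
  }
  valid <- a %in% .BASES & b %in% .BASES
  a <- a[valid]; b <- b[valid]
  L <- length(a)
  if (L == 0L) stop("no comparable sites (all excluded by pairwise deletion)")
  purine <- c("A", "G")
  diff <- a != b
  ts <- diff & ((a %in% purine) == (b %in% purine))
  c(P = sum(ts) / L, Q = sum(diff & !ts) / L, L = L)
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4`.  Pairs outside the model's
#' domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are saturated and return
#' `NA`, to be excluded from means.
#'
#' @param P,Q transition and transversion proportions (vectorised).
#' @return numeric distance(s), `NA` where saturated.
#' @export
k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ifelse(w1 > 0 & w2 > 0, -log(pmax(w1, 1e-300)) / 2 - log(pmax(w2, 1e-300)) / 4,
         NA_real_)
}

#' Poisson-corrected amino-acid distance
#'
#' `d = -log(1 - p)` with `p` the proportion of differing residues; sites
#' with `X`, `*`, `-` or `?` in either sequence are excluded (pairwise
#' deletion).  `p = 1` is saturated and returns `NA`.
#'
#' @param aa_a,aa_b equal-length amino-acid strings.
#' @param site_subset 1-based residue indices to compare (default: all).
#' @return the corrected distance, `NA` if saturated.
#' @export
poisson_aa_distance <- function(aa_a, aa_b, site_subset = NULL) {
  stopifnot(nchar(aa_a) == nchar(aa_b))
  a <- strsplit(toupper(aa_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aa_b), "", fixed = TRUE)[[1]]
  if (!is.null(site_subset)) {
    stopifnot(all(site_subset >= 1L), all(site_subset <= length(a)))
    a <- a[site_subset]; b <- b[site_subset]
  }
  bad <- c("X", "*", "-", "?")
  valid <- !(a %in% bad) & !(b %in% bad)
  a <- a[valid]; b <- b[valid]
  if (!length(a)) stop("no comparable residues")
  p <- mean(a != b)
  if (p >= 1) return(NA_real_)
  -log(1 - p)
}

# labelled symmetric matrix with model/partition tags
.distance_matrix <- function(m, labels, model, partition) {
  dimnames(m) <- list(labels, labels)
  attr(m, "model") <- model
  attr(m, "partition") <- partition
  m
}

#' Pairwise K2P distance matrix
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @param mask optional [site_mask()] used with `partition`.
#' @param partition `"all"`, `"PBR"` or `"non-PBR"` (nucleotide sites of
#'   the mask's PBR codons).
#' @return symmetric matrix with `NA` for saturated pairs; attributes
#'   `model` and `partition`.
#' @export
k2p_matrix <- function(seqs, mask = NULL, partition = "all") {
  sites <- if (is.null(mask)) NULL else .partition_sites(mask, partition)
  n <- length(seqs)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pq <- count_PQ(seqs[i], seqs[j], sites)
    m[i, j] <- m[j, i] <- k2p_distance(pq["P"], pq["Q"])
  }
  .distance_matrix(m, names(seqs), "K2P", partition)
}

#' Pairwise Poisson-corrected amino-acid distance matrix
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (translated internally).
#' @param mask a [site_mask()]; defines the frame and the PBR codons.
#' @param partition `"all"`, `"PBR"` or `"non-PBR"` (codon positions).
#' @return symmetric matrix, attributes `model` and `partition`.
#' @export
poisson_matrix <- function(seqs, mask = site_mask(), partition = "all") {
  aa <- translate_fragment(seqs, mask)
  codons <- .partition_codons(mask, partition)
  n <- length(seqs)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- poisson_aa_distance(aa[i], aa[j], codons)
  }
  .distance_matrix(m, names(seqs), "PoissonAA", partition)
}

#' Mean pairwise distance
#'
#' Arithmetic mean over the strictly-lower triangle of a symmetric
#' distance matrix; saturated (`NA`) pairs are excluded with a warning.
#'
#' @param m symmetric distance matrix.
#' @return the mean distance.
#' @export
mean_pairwise <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  d <- m[lower.tri(m)]
  if (anyNA(d)) {
    if (all(is.na(d))) stop("all pairs saturated")
    warning(sum(is.na(d)), " saturated pair(s) excluded from mean")
  }
  mean(d, na.rm = TRUE)
}

# per-pair site-wise status codes used by the bootstrap
# K2P: list(ts, tv, valid) logical matrices (pairs x sites)
.pair_site_status_nt <- function(seqs, sites) {
  cm <- .seq_char_matrix(seqs)[, sites, drop = FALSE]
  n <- nrow(cm)
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- cm[pairs[, 2L], , drop = FALSE]  # i < j: row=pair
  b <- cm[pairs[, 1L], , drop = FALSE]
  valid <- matrix(a %in% .BASES & b %in% .BASES, nrow = nrow(a))
  purine_a <- matrix(a %in% c("A", "G"), nrow = nrow(a))
  purine_b <- matrix(b %in% c("A", "G"), nrow = nrow(b))
  diff <- (a != b) & valid
  ts <- diff & (purine_a == purine_b)
  list(ts = ts, tv = diff & !ts, valid = valid)
}

.pair_site_status_aa <- function(aa, codons) {
  cm <- .seq_char_matrix(aa)[, codons, drop = FALSE]
  n <- nrow(cm)
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- cm[pairs[, 2L], , drop = FALSE]
  b <- cm[pairs[, 1L], , drop = FALSE]
  bad <- c("X", "*", "-", "?")
  valid <- matrix(!(a %in% bad) & !(b %in% bad), nrow = nrow(a))
  list(diff = (a != b) & valid, valid = valid)
}

#' Bootstrap standard error of a mean pairwise distance
#'
#' Resamples sites with replacement within the chosen partition
#' (nucleotide sites for the K2P model, codon positions for the Poisson
#' amino-acid model by default), recomputes the mean pairwise distance for
#' each replicate, and reports the standard deviation of the replicate
#' means.  Saturated pairs are dropped from each replicate's mean.
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @param mask a [site_mask()].
#' @param partition `"all"`, `"PBR"` or `"non-PBR"`.
#' @param model `"K2P"` or `"PoissonAA"`.
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @param unit resampling unit; default `"nucleotide"` for K2P and
#'   `"codon"` for PoissonAA.
#' @return the bootstrap standard error; attribute `"replicates"` holds
#'   the replicate means.
#' @export
bootstrap_se <- function(seqs, mask = site_mask(), partition = "all",
                         model = c("K2P", "PoissonAA"), reps = 1000L,
                         seed = 1L, unit = NULL) {
  model <- match.arg(model)
  stopifnot(reps >= 2L, length(seqs) >= 2L)
  if (is.null(unit)) unit <- if (model == "K2P") "nucleotide" else "codon"
  unit <- match.arg(unit, c("nucleotide", "codon"))

  if (model == "K2P") {
    sites <- .partition_sites(mask, partition)
    if (unit == "codon") {
      codons <- .partition_codons(mask, partition)
      groups <- lapply(codons, function(cd)
        mask$frame_offset + (3L * (cd - 1L) + 1L):(3L * cd))
      st <- .pair_site_status_nt(seqs, unlist(groups))
      unit_cols <- split(seq_along(unlist(groups)),
                         rep(seq_along(groups), lengths(groups)))
    } else {
      st <- .pair_site_status_nt(seqs, sites)
      unit_cols <- as.list(seq_along(sites))
    }
    num1 <- st$ts; num2 <- st$tv; den <- st$valid
    dist_fun <- function(P, Q) k2p_distance(P, Q)
  } else {
    aa <- translate_fragment(seqs, mask)
    codons <- .partition_codons(mask, partition)
    st <- .pair_site_status_aa(aa, codons)
    unit_cols <- as.list(seq_along(codons))
    num1 <- st$diff; num2 <- NULL; den <- st$valid
    dist_fun <- function(p, ignored) ifelse(p < 1, -log(1 - p), NA_real_)
  }
  n_units <- length(unit_cols)
  if (n_units < 2L) stop("degenerate partition: fewer than 2 resampling units")

  # aggregate per-site indicators to resampling units, then one matrix
  # multiply per indicator gives all replicates at once
  agg <- function(m) {
    if (all(lengths(unit_cols) == 1L)) m
    else do.call(cbind, lapply(unit_cols, function(cols)
      rowSums(m[, cols, drop = FALSE])))
  }
  A1 <- agg(num1 * 1); Aden <- agg(den * 1)
  A2 <- if (is.null(num2)) NULL else agg(num2 * 1)
  W <- .with_seed(seed, {
    vapply(seq_len(reps), function(r)
      tabulate(sample.int(n_units, n_units, replace = TRUE), n_units),
      numeric(n_units))
  })
  L <- Aden %*% W
  X1 <- (A1 %*% W) / L
  X2 <- if (is.null(A2)) NULL else (A2 %*% W) / L
  D <- dist_fun(X1, X2)
  D[L == 0] <- NA_real_
  rep_means <- colMeans(D, na.rm = TRUE)
  se <- sd(rep_means)
  attr(se, "replicates") <- rep_means
  se
}

#' Per-species diversity table (all sites / PBR / non-PBR)
#'
#' Computes, for each species, the mean pairwise K2P nucleotide distance
#' and Poisson-corrected amino-acid distance over all sites, PBR sites and
#' non-PBR sites, each with a site-bootstrap standard error — the standard
#' summary layout for partitioned MHC diversity.
#'
#' @param seqs_by_species named list: species -> named character vector of
#'   aligned 159-nt allele sequences (pseudoalleles should be excluded or
#'   included deliberately by the caller).
#' @param mask a [site_mask()].
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return data.frame with `species`, `level` (`nt`/`aa`), `partition`,
#'   `mean`, `se`, `n_alleles`.
#' @export
diversity_table <- function(seqs_by_species, mask = default_pbr_mask(),
                            reps = 1000L, seed = 1L) {
  rows <- list()
  for (sp in names(seqs_by_species)) {
    seqs <- seqs_by_species[[sp]]
    if (length(seqs) < 2L) next
    for (part in c("all", "PBR", "non-PBR")) {
      mk2p <- suppressWarnings(mean_pairwise(k2p_matrix(seqs, mask, part)))
      maa <- suppressWarnings(mean_pairwise(poisson_matrix(seqs, mask, part)))
      se_nt <- bootstrap_se(seqs, mask, part, "K2P", reps, seed)
      se_aa <- bootstrap_se(seqs, mask, part, "PoissonAA", reps, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, level = c("nt", "aa"), partition = part,
        mean = c(mk2p, maa), se = c(as.numeric(se_nt), as.numeric(se_aa)),
        n_alleles = length(seqs), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
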