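# neighbor-joining trees with codon-bootstrap support, cluster mixing,
# and the trans-species-polymorphism vs convergence diagnostic

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`); on an additive
#' matrix the induced tree metric reproduces the input distances exactly.
#' Negative branch lengths, which NJ can produce on non-additive input,
#' are clamped to zero with the deficit transferred to a sibling edge so
#' path lengths through the parent node are preserved where possible.
#'
#' @param m symmetric distance matrix with finite entries (labels as
#'   dimnames), e.g. from [ng_matrix()] or [k2p_matrix()].
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 3L)
  off <- m[row(m) != col(m)]
  if (any(!is.finite(off)))
    stop("non-finite entries in distance matrix (saturated pairs?)")
  tr <- ape::nj(stats::as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- setdiff(which(tr$edge[, 1L] == tr$edge[e, 1L]), e)
    if (length(sib))
      tr$edge.length[sib[1L]] <- max(0, tr$edge.length[sib[1L]] + deficit)
  }
  tr
}

# replace undefined/saturated distances so NJ stays runnable on bootstrap
# replicates: NA entries get 1.5x the largest finite distance
.patch_matrix <- function(m) {
  off <- m[row(m) != col(m)]
  if (!any(!is.finite(off))) return(m)
  mx <- max(off[is.finite(off)], 0)
  m[!is.finite(m)] <- 1.5 * mx
  diag(m) <- 0
  m
}

#' Codon-bootstrap support for a dN or dS neighbor-joining tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' resamples codon columns with replacement `reps` times, rebuilds the NJ
#' tree for each replicate, and scores every internal edge of the point
#' tree by the percentage of replicate trees containing the same
#' bipartition.  Supports are stored in `$node.label` (the root label is
#' empty).
#'
#' @param seqs named character vector of aligned, in-frame coding
#'   sequences (>= 4 for meaningful bipartitions).
#' @param kind `"dN"` or `"dS"`.
#' @param reps bootstrap replicates (default 5000; 200 is adequate for
#'   exploratory runs).
#' @param seed RNG seed for the resampling.
#' @param frame_offset bases skipped before the first codon.
#' @return the point-estimate `phylo` tree with numeric `node.label`
#'   supports in \[0, 100\].
#' @export
bootstrap_support <- function(seqs, kind = c("dN", "dS"), reps = 5000L,
                              seed = 1L, frame_offset = 0L) {
  kind <- match.arg(kind)
  stopifnot(reps >= 1L, length(seqs) >= 4L)
  cp <- .ng_components(seqs, frame_offset)
  num <- if (kind == "dN") cp$Nd else cp$Sd
  den <- if (kind == "dN") cp$N else cp$S
  point <- nj_tree(.patch_matrix(ng_matrix(seqs, kind, frame_offset)))
  W <- .with_seed(seed, {
    vapply(seq_len(reps), function(r)
      tabulate(sample.int(cp$L, cp$L, replace = TRUE), cp$L),
      numeric(cp$L))
  })
  NB <- num %*% W
  DB <- den %*% W
  P <- NB / DB
  D <- .jc_correct(P)
  D[!is.finite(D)] <- NA_real_
  trees <- vector("list", reps)
  m0 <- matrix(0, cp$n, cp$n, dimnames = list(cp$labels, cp$labels))
  ij <- cbind(cp$pairs[, 1L], cp$pairs[, 2L])
  ji <- cbind(cp$pairs[, 2L], cp$pairs[, 1L])
  for (r in seq_len(reps)) {
    m <- m0
    m[ij] <- D[, r]
    m[ji] <- D[, r]
    trees[[r]] <- nj_tree(.patch_matrix(m))
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / reps
  support[1L] <- NA_real_  # root split is trivial
  point$node.label <- support
  point
}

#' Supported-cluster family composition of a tree
#'
#' Clusters are the bipartitions of internal edges whose bootstrap support
#' meets `support_threshold`; each is scored by the number of distinct
#' families on its smaller side.  The mixed-cluster fraction is the share
#' of supported clusters containing two or more families.
#'
#' @param tree a `phylo` tree with numeric bootstrap supports in
#'   `$node.label` (e.g. from [bootstrap_support()]).
#' @param family_map named character vector: leaf label -> family.
#' @param support_threshold minimum support in \[0, 100\] (default 50).
#' @return list of class `mixing_report`: `clusters` (data.frame),
#'   `mixed_fraction`, `n_supported`.
#' @export
cluster_mixing <- function(tree, family_map, support_threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, names(family_map))
  if (length(missing))
    stop("leaves without family annotation: ", paste(missing, collapse = ", "))
  n_tip <- length(tree$tip.label)
  clades <- ape::prop.part(tree)  # one tip set per internal node, in order
  support <- suppressWarnings(as.numeric(tree$node.label))
  rows <- list()
  for (k in seq_along(clades)) {
    if (k == 1L) next                      # root: trivial bipartition
    if (is.na(support[k]) || support[k] < support_threshold) next
    tips <- tree$tip.label[clades[[k]]]
    side <- if (length(tips) <= n_tip / 2) tips
            else setdiff(tree$tip.label, tips)
    fams <- unique(unname(family_map[side]))
    rows[[length(rows) + 1L]] <- data.frame(
      node = n_tip + k, size = length(side),
      families = paste(sort(fams), collapse = ","),
      n_families = length(fams), mixed = length(fams) >= 2L,
      support = support[k], stringsAsFactors = FALSE)
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
              else data.frame(node = integer(0), size = integer(0),
                              families = character(0),
                              n_families = integer(0), mixed = logical(0),
                              support = numeric(0))
  out <- list(clusters = clusters,
              mixed_fraction = if (nrow(clusters)) mean(clusters$mixed)
                               else NA_real_,
              n_supported = nrow(clusters))
  class(out) <- "mixing_report"
  out
}

#' @export
print.mixing_report <- function(x, ...) {
  cat(sprintf("Mixing report: %d supported cluster(s), mixed fraction %s\n",
              x$n_supported,
              ifelse(is.na(x$mixed_fraction), "NA",
                     sprintf("%.2f", x$mixed_fraction))))
  invisible(x)
}

#' TSP-versus-convergence verdict from dN and dS cluster mixing
#'
#' Under trans-species polymorphism the dN- and dS-based phylogenies
#' should show the same (high) degree of cross-family allelic clustering;
#' under convergent selection only the dN tree mixes families while the
#' dS tree clusters by family.  Operationalised as: TSP-consistent when
#' both mixed fractions exceed `high_threshold` and differ by less than
#' `agreement_margin`; convergence-consistent when the dN fraction
#' exceeds `high_threshold` while the dS fraction is below
#' `low_threshold`; otherwise indeterminate.
#'
#' @param mixing_dn,mixing_ds `mixing_report` objects (or bare fractions)
#'   computed on the same leaf set.
#' @param agreement_margin maximum |dN - dS| fraction difference for the
#'   TSP call (default 0.2).
#' @param high_threshold,low_threshold fraction cutoffs (defaults 0.5 and
#'   0.2); all three thresholds are this package's operationalisation of
#'   a qualitative comparison and are configurable.
#' @return list with `verdict` (`"TSP-consistent"`,
#'   `"convergence-consistent"` or `"indeterminate"`), `dn_fraction`,
#'   `ds_fraction`.
#' @export
tsp_diagnostic <- function(mixing_dn, mixing_ds, agreement_margin = 0.2,
                           high_threshold = 0.5, low_threshold = 0.2) {
  f <- function(x) if (inherits(x, "mixing_report")) x$mixed_fraction
                   else as.numeric(x)
  dn <- f(mixing_dn); ds <- f(mixing_ds)
  verdict <- if (is.na(dn) || is.na(ds)) "indeterminate"
    else if (dn > high_threshold && ds > high_threshold &&
             abs(dn - ds) < agreement_margin) "TSP-consistent"
    else if (dn > high_threshold && ds < low_threshold)
      "convergence-consistent"
    else "indeterminate"
  list(verdict = verdict, dn_fraction = dn, ds_fraction = ds)
}

#' dN/dS tree comparison in one call
#'
#' Builds bootstrap-supported dN and dS neighbor-joining trees, scores
#' family mixing in both, and returns the [tsp_diagnostic()] verdict.
#'
#' @param seqs named character vector of aligned, in-frame coding
#'   sequences (exclude pseudoalleles).
#' @param family_map named character vector: leaf label -> family.
#' @param reps bootstrap replicates per tree.
#' @param seed RNG seed.
#' @param support_threshold cluster support cutoff (default 50).
#' @param ... passed to [tsp_diagnostic()].
#' @return list with `tree_dn`, `tree_ds`, `mixing_dn`, `mixing_ds`,
#'   `diagnostic`.
#' @export
tsp_analysis <- function(seqs, family_map, reps = 200L, seed = 1L,
                         support_threshold = 50, ...) {
  tree_dn <- bootstrap_support(seqs, "dN", reps = reps, seed = seed)
  tree_ds <- bootstrap_support(seqs, "dS", reps = reps, seed = seed + 1L)
  mixing_dn <- cluster_mixing(tree_dn, family_map, support_threshold)
  mixing_ds <- cluster_mixing(tree_ds, family_map, support_threshold)
  list(tree_dn = tree_dn, tree_ds = tree_ds,
       mixing_dn = mixing_dn, mixing_ds = mixing_ds,
       diagnostic = tsp_diagnostic(mixing_dn, mixing_ds, ...))
}
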