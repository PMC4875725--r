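# cross-species allele catalogue: naming, dedup, summaries

#' Build an allele catalogue
#'
#' Deduplicates validated allele sequences across individuals and species.
#' Each distinct sequence becomes one entry, named with the 4-letter code
#' of the species in which it was first observed plus a zero-padded index
#' in order of first observation (e.g. `Clpi01`).  Alleles later seen in
#' other species keep their first name; the full species set is recorded.
#'
#' @param calls data.frame of validated alleles with columns `individual`
#'   and `sequence` (e.g. the `alleles` element of [genotype_amplicons()]
#'   or the output of [validate_clones()]).
#' @param species_map data.frame mapping `individual` to `species`; may be
#'   omitted when `calls` already has a `species` column.
#' @param method detection-method label for these calls (`"454"` or
#'   `"cloning"`).
#' @param prefixes optional named character vector species -> 4-letter
#'   prefix; derived with [species_code()] when missing.
#' @return data.frame of class `allele_catalog`: `name`, `sequence`,
#'   `species` (comma-joined), `individuals` (comma-joined), `methods`,
#'   `n_species`, `n_individuals`.
#' @export
build_catalog <- function(calls, species_map = NULL, method = "454",
                          prefixes = NULL) {
  stopifnot(all(c("individual", "sequence") %in% names(calls)))
  if (!"species" %in% names(calls)) {
    if (is.null(species_map))
      stop("species_map required when calls lack a species column")
    m <- match(calls$individual, species_map$individual)
    if (anyNA(m))
      stop("individuals missing from species map: ",
           paste(unique(calls$individual[is.na(m)]), collapse = ", "))
    calls$species <- species_map$species[m]
  }
  if (is.null(prefixes)) {
    sp <- unique(calls$species)
    prefixes <- setNames(species_code(sp), sp)
  }
  first_idx <- which(!duplicated(calls$sequence))
  counters <- integer(0)
  entries <- lapply(first_idx, function(i) {
    s <- calls$sequence[i]
    rows <- calls[calls$sequence == s, , drop = FALSE]
    first_sp <- calls$species[i]
    counters[first_sp] <<- (if (is.na(counters[first_sp][1])) 0L
                            else counters[first_sp]) + 1L
    data.frame(
      name = sprintf("%s%02d", prefixes[[first_sp]], counters[[first_sp]]),
      sequence = s,
      species = paste(unique(rows$species), collapse = ","),
      individuals = paste(unique(rows$individual), collapse = ","),
      methods = method,
      n_species = length(unique(rows$species)),
      n_individuals = length(unique(rows$individual)),
      stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, entries)
  rownames(cat) <- NULL
  class(cat) <- c("allele_catalog", "data.frame")
  cat
}

#' Merge two catalogues built with different detection methods
#'
#' Entries with identical sequences are unified; species, individual and
#' method sets are merged.  Names from `a` take precedence.
#'
#' @param a,b `allele_catalog` objects.
#' @return merged `allele_catalog`.
#' @export
merge_catalogs <- function(a, b) {
  join <- function(x, y) paste(unique(c(strsplit(x, ",")[[1]],
                                        strsplit(y, ",")[[1]])), collapse = ",")
  next_name <- function(name, used) {
    if (!name %in% used) return(name)
    prefix <- sub("[0-9]+$", "", name)
    idx <- as.integer(sub(paste0("^", prefix), "",
                          grep(paste0("^", prefix, "[0-9]+$"), used,
                               value = TRUE)))
    sprintf("%s%02d", prefix, max(idx, 0L) + 1L)
  }
  out <- a
  for (j in seq_len(nrow(b))) {
    i <- match(b$sequence[j], out$sequence)
    if (is.na(i)) {
      row <- b[j, , drop = FALSE]
      row$name <- next_name(row$name, out$name)
      out <- rbind(out, row)
    } else {
      out$species[i] <- join(out$species[i], b$species[j])
      out$individuals[i] <- join(out$individuals[i], b$individuals[j])
      out$methods[i] <- join(out$methods[i], b$methods[j])
    }
  }
  out$n_species <- lengths(strsplit(out$species, ","))
  out$n_individuals <- lengths(strsplit(out$individuals, ","))
  rownames(out) <- NULL
  class(out) <- c("allele_catalog", "data.frame")
  out
}

#' Minimum number of loci implied by a per-individual allele count
#'
#' A diploid individual carries at most two alleles per locus, so
#' observing `k` distinct alleles in one individual implies at least
#' `ceiling(k / 2)` loci.
#'
#' @param max_alleles_per_individual integer vector of per-individual
#'   distinct-allele counts (>= 1).
#' @return integer vector of minimum locus counts.
#' @export
infer_min_loci <- function(max_alleles_per_individual) {
  if (any(max_alleles_per_individual < 1L))
    stop("allele counts must be >= 1")
  as.integer(ceiling(max_alleles_per_individual / 2))
}

#' Sequence-level overlap between two catalogues
#'
#' @param catalog_a,catalog_b `allele_catalog` objects (or data.frames
#'   with a `sequence` column).
#' @return list with `n_a`, `n_b`, `intersection`, `union`,
#'   `a_only`, `b_only` (counts of distinct sequences).
#' @export
method_overlap <- function(catalog_a, catalog_b) {
  a <- unique(catalog_a$sequence)
  b <- unique(catalog_b$sequence)
  i <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), intersection = i,
       union = length(a) + length(b) - i,
       a_only = length(a) - i, b_only = length(b) - i)
}

#' Alleles shared by two or more species
#'
#' @param catalog an `allele_catalog`.
#' @param meta species metadata with columns `species`, `genus`, `family`.
#' @return data.frame with `name`, `species` (comma-joined), `n_species`
#'   and `classification` (`"within-genus"`, `"within-family"` or
#'   `"cross-family"`).
#' @export
shared_alleles <- function(catalog, meta) {
  sh <- catalog[catalog$n_species >= 2L, , drop = FALSE]
  if (!nrow(sh))
    return(data.frame(name = character(0), species = character(0),
                      n_species = integer(0), classification = character(0)))
  cls <- vapply(strsplit(sh$species, ","), function(sp) {
    g <- unique(meta$genus[match(sp, meta$species)])
    f <- unique(meta$family[match(sp, meta$species)])
    if (length(g) == 1L) "within-genus"
    else if (length(f) == 1L) "within-family"
    else "cross-family"
  }, character(1))
  out <- data.frame(name = sh$name, species = sh$species,
                    n_species = sh$n_species, classification = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-species catalogue summary
#'
#' Reproduces the standard summary layout for multigene MHC surveys: total
#' alleles per species (N_A), the per-individual range of distinct-allele
#' counts, the implied minimum locus number (N_loci, via
#' [infer_min_loci()]) and the pseudoallele count (N_ps, when an
#' annotation from [annotate_orfs()] is supplied).
#'
#' @param catalog an `allele_catalog`.
#' @param calls the per-individual calls the catalogue was built from
#'   (columns `individual`, `species`, `sequence`).
#' @param annotation optional [annotate_orfs()] output matched to the
#'   catalogue by sequence.
#' @return data.frame with columns `species`, `n_alleles`, `range`,
#'   `min_alleles`, `max_alleles`, `n_loci`, `n_pseudo`.
#' @export
summarize_catalog <- function(catalog, calls, annotation = NULL) {
  stopifnot(all(c("individual", "species", "sequence") %in% names(calls)))
  pseudo_seqs <- if (is.null(annotation)) character(0)
                 else annotation$sequence[annotation$pseudo]
  species <- unique(calls$species)
  rows <- lapply(species, function(sp) {
    sub <- calls[calls$species == sp, , drop = FALSE]
    per_ind <- tapply(sub$sequence, sub$individual,
                      function(s) length(unique(s)))
    in_sp <- vapply(strsplit(catalog$species, ","), function(s) sp %in% s,
                    logical(1))
    data.frame(species = sp,
               n_alleles = length(unique(sub$sequence)),
               range = paste0(min(per_ind), "-", max(per_ind)),
               min_alleles = as.integer(min(per_ind)),
               max_alleles = as.integer(max(per_ind)),
               n_loci = infer_min_loci(max(per_ind)),
               n_pseudo = sum(catalog$sequence[in_sp] %in% pseudo_seqs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an allele catalogue
#'
#' The catalogue round-trips through a TSV table plus a FASTA whose
#' headers carry `name|species,...|methods|pseudo-or-ok`.
#'
#' @param catalog an `allele_catalog`.
#' @param dir output directory (files `catalog.tsv`, `catalog.fa`).
#' @param annotation optional [annotate_orfs()] output for pseudo flags in
#'   the FASTA headers.
#' @return the directory (write) or the reloaded catalogue (read).
#' @export
write_catalog <- function(catalog, dir, annotation = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(as.data.frame(catalog), file.path(dir, "catalog.tsv"))
  pseudo_seqs <- if (is.null(annotation)) character(0)
                 else annotation$sequence[annotation$pseudo]
  hdr <- sprintf("%s|%s|%s|%s", catalog$name, catalog$species,
                 catalog$methods,
                 ifelse(catalog$sequence %in% pseudo_seqs, "pseudo", "ok"))
  write_fasta(setNames(catalog$sequence, hdr), file.path(dir, "catalog.fa"))
  invisible(dir)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(dir) {
  cat <- .read_tsv(file.path(dir, "catalog.tsv"))
  class(cat) <- c("allele_catalog", "data.frame")
  cat
}
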