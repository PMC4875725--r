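---
title: "Validating and analysing MHC class II amplicon alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and analysing MHC class II amplicon alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelescope)
```

## The problem

Classical MHC class II β genes in passerine birds occur as families of
duplicated, highly polymorphic loci.  A single degenerate primer pair
amplifies a 159-bp fragment of exon 2 — the part encoding the
peptide-binding region (PBR) — from *all* loci at once, in every
individual of every species surveyed.  The observable is therefore a pool
of reads mixing (i) true alleles from an unknown number of loci, (ii) PCR
substitution errors, and (iii) PCR chimeras, and the analytical task has
four parts:

1. **Validation** — separate true alleles from artefacts using replicate
   structure and coverage, not sequence similarity.
2. **Cataloguing** — deduplicate alleles across individuals, species and
   detection methods, and bound the locus number from below.
3. **Diversity** — quantify polymorphism separately for PBR and non-PBR
   sites.
4. **Phylogenetics** — ask whether alleles shared or similar across
   species reflect trans-species polymorphism (TSP) or convergent
   selection, by contrasting trees built from non-synonymous (dN) and
   synonymous (dS) distances.

allelescope implements these four stages plus a simulator that generates
data with the same statistical structure, so every stage is testable
without any sequencing run.

## Validation model

Reads are first required to contain a *complete* (zero-mismatch) match to
both degenerate primers, with IUPAC codes in the primers resolved against
the read's literal bases; both orientations are searched and the template
between the primers is canonicalised to forward orientation.  Multiplex
identifier (MID) tags — the 10 bases preceding the forward primer — are
matched exactly, with no error correction: a tag with a single
substitution is left unassigned rather than risk misassignment.

Candidate variants (distinct trimmed templates; no clustering or
denoising) then pass two filters:

* **Dataset-level replicate filter.** A variant is retained iff its
  length is exactly 159 bp and at least two independent PCRs each contain
  at least three reads of it.  By default the qualifying PCRs may come
  from any individuals ("dataset" scope); a per-individual variant of the
  rule is available via `scope = "individual"`.  The rationale: errors
  and chimeras are largely private to a PCR, whereas true alleles
  replicate.
* **Individual-level coverage filter.** Within each individual, variants
  with coverage *strictly lower* than 10 % of that individual's
  highest-coverage variant are discarded.  "Lower than" is read
  literally, so an exact tie at the threshold is kept (the comparison
  uses a small numeric tolerance so integer ties survive floating-point
  representation of `0.10 * max`).  Coverage is summed across a given
  individual's PCR replicates; whether the original rule summed or took
  per-replicate coverage is not documented, and the summed reading is
  flagged here as the implemented choice.

Cloned Sanger sequences use the simpler rule: retained iff present in at
least two independent PCRs of the same individual; individuals with a
single PCR are reported as unvalidatable.

## Catalogue and locus inference

Validated alleles are deduplicated by exact full-length sequence
identity.  Entries are named with the four-letter code of the species of
first observation plus an index in order of first observation
(`Clpi01`, ...); an allele later found in another species keeps its first
name and accumulates its species set.  Because a diploid individual
carries at most two alleles per locus, the maximum per-individual
distinct-allele count `k` bounds the locus number from below by
`ceiling(k / 2)`; on simulations this is verified to never exceed the
true locus count.

Pseudoalleles are flagged by in-frame stop codons and, optionally, by
frameshifts: a global pairwise alignment against a supplied consensus
(match 1, mismatch −1, gap open −2, gap extend −1) whose total indel
length is not a multiple of three.  Both modes exist because exact-length
filtering removes frameshifted amplicon variants, while cloned reads of
unexpected length can still carry them.

## Site partition and diversity

The PBR/non-PBR partition is data, not code: a packaged YAML mask gives
the fragment's frame offset (0; the 159-bp fragment is read as 53 codons)
and the PBR codon positions, inferred by homology to the human HLA-DR1
peptide-binding groove under the assumption that the fragment begins at
β-chain position 11.  Neither the frame nor the register is derivable
from the fragment alone; both are recorded in the mask file and should be
checked against locus-specific information when available.  Nucleotide
sites of PBR codons form the nucleotide-level PBR partition, so
nucleotide and amino-acid partitions are congruent.

Diversity is the mean pairwise distance among a species' alleles:
Kimura 2-parameter for nucleotides
(`d = -log(1-2P-Q)/2 - log(1-2Q)/4`) and Poisson-corrected for amino
acids (`d = -log(1-p)`).  Ambiguous sites are deleted pairwise (the usual
default for pairwise distances); saturated pairs (outside the model
domain) are excluded from means with a warning rather than failing the
run, since real PBR data can saturate.  Standard errors come from
resampling sites with replacement within the partition — nucleotides for
the nucleotide model, codons for the amino-acid model — and taking the
standard deviation of replicate means (default 1000 replicates; the
bootstrap is validated against the delta-method SE on fixtures with
independent sites).

## Codon phylogenetics and the TSP diagnostic

dN and dS are computed by the Nei–Gojobori pathway method: per codon,
synonymous site counts are the fraction of the nine possible single-base
changes that preserve the amino acid (changes to stops count as
non-synonymous, so N + S = 3); per codon pair, differences are averaged
over all equally-weighted minimal mutational pathways, excluding pathways
through stop codons (if every pathway crosses a stop, all pathways are
used with stop-crossing steps counted as non-synonymous — a documented
fallback).  Proportions are Jukes–Cantor corrected
(`d = -3/4 log(1 - 4p/3)`); `p ≥ 3/4` is reported as saturated.
The implementation is table-driven (all 61 × 61 sense-codon pairs are
precomputed) and is checked in the tests against an independent recursive
pathway enumerator over the complete pair space.

Trees are neighbor-joining (via `ape::nj`) on the dN-only and dS-only
matrices, with codon-bootstrap supports: codon columns are resampled with
replacement, the tree is rebuilt per replicate, and each internal edge of
the point tree is scored by the percentage of replicates containing the
same bipartition.  Two conventions to note: negative NJ branch lengths
are clamped to zero with the deficit moved to a sibling edge, and ties in
the NJ criterion are resolved by `ape`'s internal rule.  Undefined or
saturated distances inside a bootstrap replicate are patched to 1.5× the
largest finite distance so the replicate stays usable.

The TSP-versus-convergence comparison is qualitative in origin; it is
operationalised here as the **mixed-cluster fraction**: among bipartitions
supported at ≥ 50 %, the share whose smaller side contains alleles from
two or more families.  The verdict is *TSP-consistent* when the dN and dS
fractions are both above 0.5 and agree within 0.2; *convergence-
consistent* when the dN fraction is above 0.5 while the dS fraction is
below 0.2; otherwise *indeterminate*.  All three thresholds are package
choices, configurable in `tsp_diagnostic()`.  Pseudoalleles are excluded
from dN/dS trees by default (stop codons erode the codon comparison);
`include_pseudoalleles = TRUE` overrides.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the emulated study: 7 species in 4
families, 5–9 loci per species, diploid genotypes, ~5 % pseudoalleles,
~8 % of alleles copied into a confamilial species (matching the observed
within-genus/within-family sharing), PBR substitution rates elevated
5-fold, 2 individuals per species, 2 PCRs each, and per-allele coverage
of 100 + negative-binomial spread with mean 250, spanning roughly
100–600 reads.  The explicit coverage floor reflects that real per-allele
coverages in such runs stay far from zero (the observed span was
114–570); it also makes the 10 % filter lossless in the absence of noise,
which is what lets the zero-noise round trip demand precision = recall
= 1 exactly.  Noise defaults are a per-base substitution rate of 0.002
and a PCR-chimera rate of 0.01 with a uniform single breakpoint.

Alleles evolve on a star genealogy (family → species → locus → allele)
rather than a coalescent: only the downstream statistics matter, not the
realism of the genealogy.  Two further regimes generate the contrasting
phylogenetic structures for the diagnostic:

* `pool_mode = "tsp"` draws each locus's alleles from deep allelic
  lineages generated *above* the family split.  Within-family allele
  copying alone cannot produce family-level cluster mixing, whereas
  lineages predating families — the signature of long-term TSP — mix
  families in both the dN and dS trees.
* `pool_mode = "convergent"` gives every family a private synonymous
  background while PBR amino-acid motifs are shared across families.
  Two numerical subtleties drove this design.  First, synonymous
  recoding is restricted to third-position changes within a codon block,
  because synonymous codons from different blocks (serine TCT/AGT)
  force non-synonymous steps in Nei–Gojobori pathways and would leak
  family signal into dN.  Second, the rates (family 0.12, allele 0.04
  per codon) keep cross-family synonymous divergence below Jukes–Cantor
  saturation — the fragment has only ~13 synonymous sites, so modest
  third-position divergence already saturates dS.  A small independent
  non-synonymous noise (0.06 per non-PBR codon) prevents exact dN ties
  between alleles; exact ties are resolved deterministically by NJ and
  would otherwise earn spurious 100 % bootstrap support.

The simulator does **not** model 454 homopolymer indels, quality scores,
read-length variation, primer-site polymorphism, allele-specific
amplification bias, or linkage between loci.  Passing tests therefore
show that the filters behave correctly under substitution errors and
chimeras at realistic coverage — not that they are robust to error modes
the simulator omits.

## Problem sizes and determinism

All randomness flows from a single integer seed; each generator stage
uses a fixed offset of it, so a configuration reproduces its outputs
byte-identically.  The shipped analyses use simulation sizes a desk
machine handles comfortably: default studies of 14 individuals
(~40–60 thousand reads), 100–200 bootstrap replicates for exploratory
trees (the conventional full analysis uses 1000 for distance SEs and
5000 for tree support, and both are plain arguments), and 20-seed
batteries for the recovery and diagnostic performance checks.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
report <- run_pipeline(cfg, out_dir = "run1")
report
```

The report chains every stage: the filtering report (reads in, reads
retained, per-stage variant counts), the merged catalogue with
per-species allele totals, ranges and minimum loci, the shared-allele
table, the partitioned diversity table, and the dN/dS mixing fractions
with the TSP verdict.

## Known limitations

* Exact-sequence variant identity means a systematic error shared by
  both PCRs of several individuals would pass the filters; the method
  relies on replicate independence.
* The locus bound is a lower bound only; it cannot detect loci whose
  alleles never co-occur heterozygously.
* The mixed-cluster fraction collapses tree structure to one number per
  tree; trees whose supported structure is sparse (few supported
  clusters) give noisy fractions, which the verdict reports as
  indeterminate rather than guessing.
* The PBR mask's register against HLA-DR1 is an assumption; diversity
  partitions shift if the fragment starts elsewhere in exon 2.
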