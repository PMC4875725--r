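# allelescope

Validation and evolutionary analysis of MHC class II β exon 2 amplicon
data from multigene families.

## The problem

Passerine birds carry many duplicated, highly polymorphic MHC class II β
loci.  A degenerate primer pair co-amplifies a 159-bp fragment of exon 2
(containing the peptide-binding region, PBR) from all loci of all
individuals in a pooled run, so the reads mix true alleles from an
unknown number of loci with PCR substitution errors and chimeras.
allelescope is for researchers genotyping such multilocus immune-gene
amplicons who need to (i) validate alleles from replicate structure and
coverage, (ii) catalogue them across individuals, species and detection
methods, (iii) quantify PBR-partitioned diversity, and (iv) distinguish
trans-species polymorphism (TSP) from convergent evolution.

## Methods at the core

* **Stepwise validation.** Reads must match both degenerate primers
  completely (IUPAC-aware, zero mismatches, both orientations); MID tags
  are matched exactly.  A variant is retained iff it is exactly 159 bp
  and occurs in ≥ 2 independent PCRs with ≥ 3 reads each; within each
  individual, variants with coverage < 10 % of that individual's maximum
  are discarded.  Cloned Sanger sequences are retained iff seen in ≥ 2
  independent PCRs.
* **Locus bound.** A diploid with *k* distinct alleles implies at least
  ⌈k/2⌉ loci.
* **Diversity.** Mean pairwise Kimura 2-parameter nucleotide distances,
  d = −½ln(1−2P−Q) − ¼ln(1−2Q), and Poisson-corrected amino-acid
  distances, d = −ln(1−p), over all / PBR / non-PBR sites, with
  site-bootstrap standard errors.
* **Codon phylogenetics.** Nei–Gojobori pathway counts of synonymous and
  non-synonymous sites and differences with Jukes–Cantor correction,
  d = −¾ln(1−4p/3); neighbor-joining trees on the dN-only and dS-only
  matrices with codon-bootstrap supports; the TSP diagnostic compares
  the fraction of supported clusters mixing ≥ 2 families between the two
  trees (similar and high → TSP; high dN only → convergence).
* **Simulator.** A seeded, coalescent-free generator produces
  multispecies multilocus genotypes, amplicon reads (fusion-primer
  layout, MID tags, substitution errors, single-breakpoint chimeras,
  negative-binomial coverage) and clone picks, so the whole pipeline is
  testable without sequencing data.

## Worked example

```r
library(allelescope)
cfg <- sim_config(seed = 1)          # 7 species / 4 families, 5-9 loci each
report <- run_pipeline(cfg, out_dir = "run1")
report
```

```
Pipeline report (seed 1)
Stepwise filtering report
  reads in: 46704 (complete primer match: 46704)
  reads retained: 33701 (72% of reads in)
  stage length       variants 11968 -> 11968
  stage replication  variants 11968 -> 112
  stage coverage10pc variants 112 -> 112
  catalogue: 113 alleles (41 via 454 only, 1 via cloning only, 71 both)
  454 recovery vs truth: precision 1.000, recall 1.000
  TSP diagnostic: indeterminate (dN mixing 0.00, dS mixing 0.00)
```

Reading the output: 46,704 simulated reads matched both primers; the
exact-length and 2-PCR/3-read replicate filters collapsed 11,968
distinct read variants (true alleles plus error and chimera variants) to
112 validated alleles, keeping 72 % of primer-matched reads, and the
10 % coverage rule removed none of them.  Merging the amplicon and
cloning catalogues gave 113 named alleles; every validated amplicon
allele matched a true simulated allele (precision and recall 1.0 at this
seed).  The default pool is family-structured, so the dN and dS trees
both cluster by family — mixing fractions near zero and no TSP signal,
as expected.  Rerunning with `sim_config(seed = 1, pool_mode = "tsp")`
or `"convergent"` produces the contrasting regimes and their verdicts.

Per-species summaries are in `report$catalog_summary` (allele totals,
per-individual ranges, minimum loci, pseudoallele counts) and the
partitioned diversity table in `report$diversity`; `run1/` holds the
catalogue FASTA/TSV, diversity table, Newick trees and a JSON summary.

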