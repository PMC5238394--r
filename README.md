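# allosnp

SNP genotyping-array design and diversity analysis for allotetraploid
genomes, with a fully synthetic, truth-labelled test bed.

## The problem

Cultivated groundnut (*Arachis hypogaea*) carries two diverged subgenomes (A
and B). When resequencing reads from tetraploid accessions are called
against the two progenitor references, every site where the subgenomes
differ masquerades as a SNP, and duplicated regions produce probe contexts
that hybridise in several places. An array built from an unfiltered
candidate list wastes most of its features. This package is for people who
design such arrays or analyse the genotype panels they produce. It
implements:

* a **candidate-SNP filtering cascade** — duplicate-record collapse,
  homeolog removal (a candidate is discarded when its 71-base probe context
  aligns to the other subgenome at ≥ 94% identity *and* the aligned base
  equals the alternate allele), a 10-kb gene-proximity window, probe-context
  uniqueness against both subgenomes (a qualifying placement has full-overlap
  identity ≥ 94% or a ≥ 60-base exact run; one homeologous counterpart is
  expected and discounted), and ambiguity/multiallelic removal — with a
  conservation-checked ledger: `input = passed + Σ discarded`;
* **probe design** — a documented deterministic conversion-score surrogate
  `p = clamp(0.95 − |GC − 0.45| − 0.25·min(dup,2) − 0.12·wobble −
  0.10·poly, 0, 1)`, the published recommendation rules kept verbatim
  (not-recommended if dup > 0 or poly > 0 or p < 0.4 or wobble distance < 21
  or wobbles ≥ 3; recommended if p > 0.6 with no wobbles and no
  homopolymer runs; else neutral), strand tiling, [A/T]/[C/G] exclusion, and
  genome-balanced manifest selection;
* a **codon-level effect classifier** (synonymous / missense / stop gained /
  stop lost / start lost / UTR / intron / intergenic / others) checked
  against a translate-and-compare oracle;
* **panel statistics** — call-rate QC (strict > 0.90), allele frequencies
  with heterozygotes as half an allele, observed heterozygosity, gene
  diversity `1 − Σpᵢ²`, Botstein's `PIC = 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ²`,
  polymorphism partitions by ploidy group, and density bookkeeping
  (Kb-per-SNP, SNPs-per-Mb, per-pseudomolecule means);
* **diversity and the subspecies scan** — allele-sharing distance
  `d(a,b) = mean |gₐ − g_b| / 2`, neighbor-joining clustering with a
  deterministic k-cluster tree cut, and a scan for alleles at > 80%
  frequency in exactly one cultivated subspecies and ≤ 20% in the other,
  with wild-shared SNPs reported separately and restricted to
  missense/nonsense effects;
* a **synthetic-data module** that generates diverged subgenome pairs, gene
  models with intact reading frames, candidate pools with planted homeolog,
  duplicated-flank and multiallelic artifacts, and structured genotype
  panels (wild + two cultivated subspecies, planted specific alleles,
  a hypogaea sub-lineage) — every artifact recoverable by construction, so
  the whole workflow is testable without any external data.

## Worked example

```r
library(allosnp)

cfg <- sim_config(
  n_pseudomolecules_per_subgenome = 4, pseudomolecule_length = 30000,
  n_genes = 24, n_true_snps = 200, n_homeolog_artifacts = 40,
  n_duplicated_flank_snps = 20, n_multiallelic = 10, n_trait_linked = 5,
  n_wild = 10, n_fastigiata = 12, n_hypogaea = 12,
  n_planted_specific = 15, n_sublineage_snps = 20, seed = 7)

out <- run_pipeline(cfg, run_config(log_level = "quiet"))
out$filter$ledger
#> Candidate-SNP filter ledger
#>   input                              270
#>   discarded_identical                0
#>   discarded_both_genomes             40
#>   discarded_both_strands             20
#>   discarded_far_from_gene            0
#>   discarded_flank_unevaluable        0
#>   discarded_self_match_failed        0
#>   discarded_ambiguous_multiallelic   10
#>   passed                             200
```

The 270 candidates resolve exactly into their planted classes: the 40
homeolog artifacts are discarded as present on both subgenomes, the 20
duplicated-flank SNPs as non-unique, the 10 multiallelic loci as ambiguous,
and all 200 true SNPs pass. Cutting the neighbor-joining tree of the
genotyped panel into four clusters recovers the planted structure — wild
accessions isolated, fastigiata together, and the hypogaea sub-lineages
apart:

```r
table(cluster = out$clusters,
      category = out$panel_truth$clusters[names(out$clusters)])
#>        category
#> cluster fastigiata hypogaea wild
#>       1          0        0   10
#>       2         12        0    0
#>       3          0        6    0
#>       4          0        6    0

unlist(out$scan$counts[c("total_specific", "fastigiata_specific",
                         "hypogaea_specific", "hypogaea_shared_with_wild")])
#>            total_specific       fastigiata_specific
#>                        30                        15
#>         hypogaea_specific hypogaea_shared_with_wild
#>                        15                         4
```

The scan finds exactly the 15 + 15 planted subspecies-specific SNPs (4 of
the hypogaea set also high-frequency in wild), with sensitivity and
specificity 1 against the planted truth.

## The analysis workflow

The numbered scripts under `analysis/` run the same study as a sequence of
inspectable steps, exchanging plain-text files under `results/`:

```sh
Rscript analysis/01_simulate.R        # genomes, gene models, candidates, truth
Rscript analysis/02_filter.R          # cascade + ledger vs truth
Rscript analysis/03_design.R          # scoring, tiling, manifest selection
Rscript analysis/04_annotate.R        # codon-level effects, category table
Rscript analysis/05_polymorphism.R    # panel QC, per-SNP stats, densities
Rscript analysis/06_diversity.R       # distances, NJ tree, cluster cut
Rscript analysis/07_subspecies_scan.R # category frequencies, >80% scan
```

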