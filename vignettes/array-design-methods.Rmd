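---
title: "Designing and evaluating a SNP array for an allotetraploid crop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a SNP array for an allotetraploid crop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosnp)
```

## The problem

Cultivated groundnut (*Arachis hypogaea*) is an allotetraploid: its nucleus
carries two diverged diploid-derived subgenomes (A, from an *A. duranensis*-like
ancestor, and B, from an *A. ipaensis*-like ancestor). When short reads from a
tetraploid accession are mapped against the two progenitor references, a read
from the A copy of a gene will often also map to the homeologous B copy.
Every site where the two subgenomes differ then looks like a heterozygous SNP,
although no accession in the panel actually varies there. A genotyping array
built from such a candidate list wastes features on markers that can never
segregate, so the design pipeline must separate three things that look
identical in a raw variant table: genuine inter-accession polymorphism,
fixed homeolog divergence, and repetitive or duplicated probe contexts that
would hybridise to several places at once.

`allosnp` implements that design pipeline and the downstream analyses a
germplasm panel genotyped on the resulting array supports: per-SNP
polymorphism statistics, diversity clustering, and a scan for alleles that
are near-fixed in one cultivated subspecies but not the other. Because the
sequencing data behind such arrays is typically not depositable at the scale
needed for testing, the package carries a first-class synthetic-data module
that generates every input with known truth labels; all tests and the
acceptance suite run against it.

## The filtering cascade

Candidates enter as biallelic records with 35-base flanks on each side of the
SNP, giving a 71-base probe context. The cascade applies five stages in
order; a conservation-checked ledger accounts for every record:

1. **Duplicate collapse.** Records identical in (subgenome, pseudomolecule,
   position, ref, alt) collapse to the first occurrence.
2. **Homeolog removal.** A candidate is homeologous when its context aligns
   to the *other* subgenome at ≥ 94% identity over the full overlap *and*
   the aligned base at the SNP column equals the alternate allele — the
   "polymorphism" is then exactly the fixed divergence between subgenomes.
   Candidates whose flanks are truncated by a pseudomolecule edge cannot be
   evaluated and are discarded with their own ledger category.
3. **Gene proximity.** Only candidates within 10 kb of an annotated gene
   span are kept ("within" read as ≤, distance 0 inside a gene,
   strand-agnostic).
4. **Uniqueness.** The context is searched against both subgenomes in both
   orientations. A placement *qualifies* when the ungapped full-overlap
   alignment has identity ≥ 94% **or** contains a contiguous exact-match run
   of ≥ 60 bases (the overlap itself must be ≥ 60 bases). The placement at
   the candidate's own locus is the required self-match; one qualifying
   placement on the other subgenome is the expected homeologous counterpart
   — in an allotetraploid nearly every locus has one, and the homeolog stage
   has already adjudicated whether it explains the allele — so it is
   discounted. Every further qualifying placement counts as a duplicate and
   the candidate is discarded as non-unique. Without the counterpart
   discount the uniqueness rule would be vacuous in an allotetraploid at any
   divergence where the homeolog filter itself still works.
5. **Ambiguity.** Loci observed with more than two alleles, records flagged
   multiallelic, and non-A/C/G/T symbols are removed.

The search behind stages 2 and 4 is exact-seed-and-verify: every forward
12-mer of both subgenomes is indexed once; a query context contributes
disjoint 12-mer seeds, and by pigeonhole any placement with at most 4
mismatches over 71 bases (the 94% threshold) and any placement containing a
60-base exact run must share a seed with the query. Seed hits are verified by
the full-overlap alignment. Reverse-strand placements are found by querying
the reverse-complemented context against the forward index. The thresholds
(identity 0.94, aligned length 60, window 10,000) are exposed as arguments
throughout.

Coordinates are 1-based inclusive everywhere — internal tables, VCF and GFF3
— matching the R/Bioconductor convention, so the file readers and writers
perform no offset arithmetic.

## Probe scoring, recommendation and tiling

Array vendors score each candidate probe with a proprietary random-forest
"p-convert" (probability that the SNP converts into clean genotype clusters)
built from probe sequence, binding energy and expected cross-hybridisation.
That model is not reproducible, so `score_probe()` substitutes a documented
deterministic surrogate over the same observable inputs:

p = clamp(0.95 − |GC − 0.45| − 0.25·min(dup, 2) − 0.12·wobble − 0.10·poly, 0, 1)

with GC the context GC fraction, `dup` the extra qualifying placements,
`wobble` the count of other known variants inside the context (an
interfering variant under the probe), and `poly` the number of homopolymer
runs ≥ 6 bases. The surrogate is monotonically non-increasing in every
penalty; its absolute values carry no meaning beyond ordering probes and
exercising the published decision thresholds, which are kept verbatim:

* **not recommended** if duplicate count > 0, or poly count > 0, or
  p-convert < 0.4, or a wobble lies within 21 bases of the SNP, or there are
  ≥ 3 wobbles — these exclusions take precedence;
* otherwise **recommended** if p-convert > 0.6 with no wobbles and no
  homopolymer runs;
* otherwise **neutral**.

Wobble distance is measured from the target SNP (the vendor definition does
not say; this is an explicit interpretation, as are the wobble and poly
definitions themselves). Each SNP is tiled on one strand: better
recommendation class first, then higher p-convert, then the forward strand as
a deterministic tie-break. Because every surrogate input is
reverse-complement symmetric, the pipeline's own probes always tie and tile
forward; the tiling logic is exercised directly in tests with asymmetric
inputs. SNPs whose alleles are {A,T} or {C,G} are excluded before selection —
on a two-colour array such complement-symmetric markers need twice the
features. `select_array()` then admits trait-linked SNPs unconditionally and
distributes the remaining quota over pseudomolecules proportionally to their
lengths (largest-remainder rounding, shortfall redistributed), ordering
within a pseudomolecule by class, descending p-convert, ascending position.

## Effect classification

`classify_effect()` re-implements a codon-level variant effect classifier
over single-transcript gene models. Inside a CDS the reference and alternate
codons are translated with the standard genetic code: same amino acid →
`synonymous_coding`; alternate stop → `stop_gained`; loss of the terminal
stop → `stop_lost`; any change in the initiator codon → `start_lost`;
amino-acid changes in the codon adjacent to the start or stop →
`non_synonymous_start` / `non_synonymous_stop` (a positional stand-in for
categories the array literature reports without defining); otherwise
`non_synonymous_coding`. UTR and intron positions map to their categories,
positions in no transcript are `intergenic`, and anything unclassifiable — a
CDS whose length is not a multiple of three, a reference mismatch — lands in
`others`. With overlapping transcripts the most severe category wins
(stop_gained > stop_lost > start_lost > non-synonymous variants >
synonymous > UTRs > intron > intergenic > others). The test suite checks the
classifier against an independent oracle that substitutes the allele into
the genome, re-extracts and fully translates the transcript, and compares
protein sequences.

## Panel statistics

Genotype calls are the diploidized codes an array reports (0/1/2 with −1
missing) and are taken at face value for tetraploids. Samples whose call
rate is not strictly above 0.90 are removed; DQC, an intensity-level metric
that cannot be derived from calls, is thresholded (> 0.75) only when
supplied as metadata. Allele frequencies count heterozygotes as half an
allele over non-missing calls. Per SNP the package reports observed
heterozygosity, gene diversity 1 − Σpᵢ², and Botstein's polymorphism
information content 1 − Σpᵢ² − Σᵢ<ⱼ2pᵢ²pⱼ²; both diversity statistics are
emitted because marker-software conventions differ on which one is printed
under the name "PIC" (for a biallelic locus PIC is bounded by 0.375, gene
diversity by 0.5). A SNP is polymorphic within a group when at least two
distinct non-missing codes occur there, so a heterozygote-only SNP counts
and a polymorphic SNP can print a two-decimal minor allele frequency of
0.00. Reported frequencies round to two decimals; density summaries round
Kb-per-SNP and per-pseudomolecule means half-up to integers and SNPs-per-Mb
to two decimals, the conventions under which the published bookkeeping
reproduces exactly.

## Distance, clustering and the subspecies scan

No distance metric or tree method is standard for array panels, so the
package uses the auditable pair: allele-sharing distance d(a,b) = mean over
SNPs non-missing in both samples of |gₐ − g_b|/2, and neighbor joining
(through `ape::nj`) behind `neighbor_joining()`. On additive matrices NJ
recovers the generating topology and branch lengths; the tests verify this
on random trees up to eight leaves. With missing calls the pairwise-complete
averaging can mildly violate the triangle inequality — a standard caveat of
such estimators; metricity is asserted only on complete matrices.
`assign_clusters()` cuts the tree into k leaf groups by removing internal
edges longest-first (postorder index as tie-break, terminal edges only after
all internal ones, cuts that would isolate a leafless subtree are skipped).

The subspecies scan computes per-category alternate-allele frequencies
(fastigiata, hypogaea, wild) and flags a SNP as category-specific when its
frequency is strictly above 0.80 in exactly one cultivated category and at
most 0.20 in the other — the "contrasting frequency" requirement made
operational; the threshold is a parameter. Specific SNPs whose wild
frequency also exceeds the threshold are additionally marked
shared-with-wild, and counts are reported both with and without that class
separated, since published totals can book wild-shared SNPs either way.
`scan_effect_filter()` finally restricts the specific SNPs to those with a
moderate (missense) or high (nonsense-like) predicted effect and lists the
genes hit.

## What the synthetic data emulates — and what it does not

`sim_config()` fixes the study conditions. Defaults: 10 pseudomolecules per
subgenome at a computationally tractable 100 kb each (chromosome-scale
pseudomolecules shrunk, not thinned: all length-dependent logic — flanks,
windows, quotas — operates unchanged); homeolog divergence 0.05; 120 gene
models with a minimal grammar (5′ UTR, two CDS exons with an intact reading
frame, one intron, 3′ UTR, one transcript per gene — enough to exercise
every effect category); a candidate pool of 2,000 true SNPs, 400 homeolog
artifacts, 100 duplicated-flank artifacts (half copied whole, half as
60-base cores, half reverse-complemented) and 50 multiallelic loci; and a
300-sample panel of 36 wild plus 132 + 132 cultivated accessions, mirroring
a reference germplasm set.

Construction guarantees make the truth labels exactly recoverable, and the
guarantees themselves are part of the documented design:

* subgenome B is subgenome A substituted at uniformly sampled sites, so the
  homeologous counterpart of any locus sits at identical coordinates;
  substitutions that would break a reading frame on B are reverted;
* homeolog artifacts are planted only at diverged sites whose 71-base
  context carries at most 4 total mismatches against the other subgenome, so
  the defining ≥ 94% cross-identity condition is satisfiable — and true SNPs
  never take the homeologous base as their alternate allele;
* duplicated-flank sources and their planted copies keep a full context
  length clear of genes and of every other candidate on both the
  pseudomolecule and its homeologous mirror, so a copy can neither destroy a
  neighbour's cross-subgenome match nor hand it a spurious extra placement;
* multiallelic loci sit at non-diverged sites so they can never satisfy the
  homeolog condition.

The panel draws background alternate-allele frequencies once per SNP from
Beta(0.5, 2.5) — the low-MAF spectrum of a predominantly selfing crop —
shared between the two cultivated categories; the wild category mixes that
background with an independent uniform draw (weight 0.5), which
simultaneously raises wild polymorphism (the panels behind such arrays show
several-fold higher wild diversity) and separates the wild cluster.
Genotypes are drawn under inbreeding F = 0.95, keeping observed
heterozygosity at the few-percent level typical of groundnut. Sixty planted
SNPs per cultivated category are near-fixed (frequency 0.92–1) in their
target category and rare (≤ 0.08) elsewhere; a quarter of the
hypogaea-specific set is also high-frequency in wild, so the wild-shared
class is exercised end-to-end. Half of the hypogaea samples form a planted
sub-lineage with contrasting frequencies at 60 further background SNPs —
real cultivated germplasm shows exactly this substructure (one subspecies
split over two clusters), and it makes a four-cluster tree cut well-posed:
wild, fastigiata, and the two hypogaea lineages.

The generator does **not** model reads, sequencing error, depth, linkage
disequilibrium, realistic haplotype structure, genome-size asymmetry between
subgenomes, or intensity-level artifacts (DQC is accepted as optional input,
never simulated). Passing tests therefore demonstrate that the decision
logic is implemented correctly and is recoverable under its own assumptions
— not that the thresholds would perform identically on real resequencing
data.

## Numerical and reproducibility choices

Every stochastic component derives its own sub-stream from the single run
seed (a fixed integer hash of seed and component label), so adding a
component does not perturb the draws of the others, and identical
configurations produce byte-identical outputs, including every file the
pipeline writes. Deterministic tie-breaks: forward strand on equal probes;
first occurrence on duplicate records; postorder edge index on equal tree
cuts; pseudomolecule name on equal selection remainders. Degenerate inputs
are defined, not special-cased: an empty candidate table yields an all-zero
ledger, a SNP with no non-missing calls reports call rate 0 with NA
statistics, a monomorphic SNP has PIC 0, and a sample pair with no shared
calls gets an NA distance (an error only if a tree is requested).

Problem sizes: unit tests run a 4 + 4 × 30 kb genome with a few hundred
candidates and a 34-sample panel; the acceptance suite additionally runs the
full default configuration (2,550 candidates, 300 samples) twice to verify
end-to-end determinism, which completes in well under a minute per run on a
single CPU.

## Known limitations

The p-convert surrogate ranks probes plausibly but is not the vendor model;
absolute recommendation proportions on real designs will differ. The
qualifying-hit contract (exact 12-mer seeds, ungapped verification) detects
the artifact classes the generator plants and any placement within its
mismatch budget, but unlike a gapped aligner it will not find indel-shifted
near-duplicates. Homeologous gene pairs sit at identical coordinates, which
real subgenomes do not; the filters never exploit that fact (all
cross-subgenome reasoning goes through sequence search), but it does make
the synthetic task geometrically cleaner than a real genome pair. The effect
classifier handles single-transcript models with intact frames; real
annotation pathologies (fuzzy phases, partial CDS) all fall into `others`
rather than being resolved.
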