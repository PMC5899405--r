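---
title: "Genotype-aware capture methylation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware capture methylation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmeth)
library(dplyr)
```

`capmeth` analyses dual-purpose targeted-capture experiments in
allopolyploids: one capture, split after elution, sequenced once untreated
(genotype) and once bisulphite-treated (methylome). This vignette is the
package's own account of the underlying models, the parameters that
matter, what the bundled simulator does and does not emulate, and the
design decisions taken where more than one reasonable construction
existed.

## The measurement model

Bisulphite treatment deaminates unmethylated cytosine to uracil, read as
T; 5-methylcytosine is protected. On the genomic top strand an
unmethylated C is therefore sequenced as T, and on the bottom strand the
reference-orientation signature is G read as A. A methylation *call* at a
cytosine site is the pair (methylated count, unmethylated count) over the
reads informative for that site's strand. Three confounders sit on top of
this signal:

1. **Genetic C→T / G→A variation.** A homozygous genomic C→T SNP in the
   sample produces T in every bisulphite read — the exact signature of a
   fully unmethylated cytosine. Without the untreated genotype data these
   sites are systematic false "unmethylated" calls.
2. **A/T→C/G variation.** The sample carries cytosines at positions where
   the reference has A or T; against the uncorrected reference these
   sites are simply never analysed.
3. **Sub-genome collapse.** The capture reference collapses homoeologous
   gene copies into one representative, so reads from the A, B and D
   sub-genomes stack on the same coordinates. Methylation differs between
   sub-genomes, so calls are only interpretable after each read is
   attributed to its sub-genome via diagnostic homoeologous alleles.

The package's pipeline addresses the three in order: polyploid SNP
calling from the untreated aliquot, reference correction/masking, and
homoeologous-allele read attribution.

## Polyploid SNP calling

Alignments are filtered (MAPQ ≥ 10; duplicates and non-unique mappings
removed), piled up per position, and a position is called when

* depth ≥ 5 (`min_cov`),
* column mean MAPQ > 15 (strict; arithmetic mean over contributing
  reads), and
* some non-reference base has frequency > 0.1 (strict), with frequencies
  computed over the post-filter column depth.

The 1/3 and 2/3 allele frequencies of homoeologous variants in a
hexaploid pass the 0.1 threshold comfortably, which is the point of the
frequency-based caller. Two unstated details were fixed here as package
decisions: the frequency denominator is the post-filter depth, and the
mean-MAPQ and frequency comparisons are strict inequalities (a column at
exactly mean MAPQ 15, or an allele at exactly 0.1, does not qualify).
These choices are pinned by boundary tests.

## Homoeologous SNP lists and read attribution

Two routes build the allele→sub-genome map:

* **Haplotype route** (`build_homoeolog_list_from_haplotypes()`): with
  coordinate-matched sub-genome sequences available, every position where
  the three copies disagree yields a record mapping each observed base to
  the set of sub-genomes carrying it. On simulated data this reproduces
  the generator's truth table exactly — there is no stochastic step.
* **Read route** (`build_homoeolog_list_from_reads()`): reads are first
  assigned to sub-genomes by exact full-length matching against each
  haplotype (either strand); only perfect hits to one or two genomes are
  kept — zero hits are noise, three hits carry no diagnostic
  information. SNPs are then called on the assigned reads and each
  allele is attributed to the union of the genome sets of the reads
  carrying it.

Methylation calls are attributed per read
(`assign_subgenome_methylation()`): a read participates when its MAPQ is
strictly above 20 and it covers at least one homoeologous SNP whose
observed allele identifies exactly one sub-genome; all cytosine calls on
that read are then credited to that sub-genome.

One subtlety is handled that a naive implementation gets wrong:
bisulphite conversion aliases alleles. On a top-strand read an observed T
at a C/T diagnostic SNP may be a converted unmethylated C, not the T
allele. The package therefore collapses the allele map per bisulphite
strand (C→T for top-strand reads, G→A for bottom-strand reads) before
matching, and discards SNP observations whose collapsed base no longer
identifies a single sub-genome. With this rule, error-free simulations
give 100 % correct attributions; without it, C/T diagnostic SNPs
systematically mis-assign unmethylated reads. By default only
singleton allele→genome sets assign reads (a `{B,D}` allele is skipped
rather than fractionally credited), and reads with conflicting
diagnostic alleles are discarded and tallied.

## Genotype correction

`classify_snps()` reduces each called position to its primary alternate
(highest frequency, alphabetical tie-break) and classifies it:
`CT_GA` (C→T or G→A — the bisulphite signature), `AT_CG` (new cytosine in
the sample), `CG_SWAP` (cytosine changes strand), `OTHER`.
`correct_reference()` applies edits whose alternate frequency is at least
0.9 — reference correction must encode homozygous states only, and in a
hexaploid a frequency near 1 across the collapsed column means the
variant is carried by all three sub-genome copies. Masked `CT_GA` sites
leave the cytosine analysis set; `AT_CG` substitutions add sites whose
context is recomputed from the corrected sequence; `CG_SWAP` (a class the
source design did not discuss) masks the lost strand and adds the gained
one. The corrected cytosine set satisfies, exactly,
`(original − masked) ∪ added` — verified by set algebra on simulations.

`correction_report()` computes the headline accounting: among cytosines
with depth ≥ 10, the percentage of calls that correction can eliminate is
`100 · n_CT_GA / n_analyzable` — an "up to" figure, since not every such
SNP position necessarily reaches analyzable depth. With the published
wheat-landrace tallies (672,949 C/G→T/A SNPs; 5,962,239 cytosines at
≥ 10×) this is 11.3 %. The analogous added-cytosine ratio
(779,185/5,962,239 ≈ 13.1 %) is reported as directly computed; the
package makes no attempt to reproduce the looser "about a fifth"
characterisation sometimes attached to that figure, whose basis is not
reconstructible from the printed counts.

## Conversion efficiency and differential methylation

Conversion efficiency is estimated on a genome assumed unmethylated (in
the wheat experiments, chloroplast carryover reads): efficiency
`= 100 · T/(C+T)` over cytosine observations on both strands. With zero
observations the estimate is reported as undefined rather than 0 or 100.

Differential methylation between two samples is tested per cytosine with
a two-sided Fisher exact test on the 2×2 methylated/unmethylated table,
at sites with depth ≥ 5 in both groups, significant at p < 0.01 **and**
an absolute methylation difference above a threshold in percentage
points. The difference threshold is deliberately an explicit argument
(default 25): both 25 and 50 are in legitimate circulation for this kind
of analysis, and the headline comparisons this package models used 25.
Sidedness is by minimum-likelihood summation — the p-value is the sum of
hypergeometric probabilities of all tables no more probable than the
observed one (relative tolerance 1e-7 against ties lost to floating
point), the convention of standard statistical practice, implemented
vectorised over tables grouped by shared margins so genome-wide per-base
testing is cheap. `stats::fisher.test` uses the same convention and
serves as an independent cross-check in the test suite, never as the
implementation. No multiple-testing correction is applied: the pairwise
per-base convention here is a raw p < 0.01, and a q-value layer is out
of scope. Records are strand-resolved and CpG sites are *not* merged
across strands — the assay profiles one strand of DNA per site.

Pairwise comparisons between samples are made per sub-genome (A–A, B–B,
D–D) on the attributed counts, not on pooled records: pooled counts mix
the haplotype-sampling ratio into the methylation signal at sites where
sub-genomes differ (in state or in base), which manufactures spurious
"differences" two aliquots of the same library do not actually have.

## The synthetic-data module

`build_genome()` + `simulate_reads()` + `bisulphite_convert()` generate
the study system every claim is tested on:

* a collapsed reference (default 3 contigs × 10 kb, GC 0.46) with three
  coordinate-matched haplotypes diverging at homoeologous positions
  (default rate 0.01/bp: at most positions one sub-genome carries a
  non-reference base, a minority have three distinct alleles);
* varietal SNPs (default 0.002/bp) at non-homoeologous positions, applied
  to **all three** haplotypes — an accession-wide difference from the
  reference variety, which is what lets untreated-read calls reach the
  homozygous-edit frequency, mirroring a landrace sequenced against the
  reference cultivar's assembly;
* binary per-site methylation states drawn per haplotype with
  context-specific rates (defaults CpG 0.8, CHG 0.6, CHH 0.1 — a heavily
  methylated plant genome with high symmetric-context and low asymmetric
  methylation; sites too close to a contig end for context classification
  are left unmethylated);
* single-end fragment reads of 125 bp (both pipelines process reads as
  fragments; paired-end emission is a non-goal) at a requested mean
  on-target depth (default 30×), with off-target reads split between an
  unmethylated 10 kb control genome and unmappable random background
  (on-target fraction default 0.5 — the enrichment actually achieved in
  capture experiments mixes mapping and enrichment effects and is a free
  parameter here);
* MAPQ drawn from a discrete distribution (default mass at 60 with small
  low-quality tails) so MAPQ filters are genuinely exercised;
  duplicate flagging and uniform substitution errors as options, both 0
  by default;
* bisulphite conversion applied on the fragment's genomic strand with a
  configurable efficiency (default 0.9873, the efficiency reported for
  the full-capture bisulphite sample in the study system this package
  models), non-directional by default (all four strand types emitted;
  the PCR-complement types differ only in alignment orientation, not in
  their reference-orientation base pattern).

One top-level seed drives named deterministic sub-streams per operation,
so identical configurations reproduce byte-identical FASTA/FASTQ/SAM
outputs, and truth tables (homoeologous and varietal SNPs, methylation
states) exactly describe the emitted haplotypes.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: alignment ambiguity and mapping error
(truth SAM coordinates are exact; MAPQ is simulated, not earned), indels
and structural variation (haplotypes are coordinate-matched by default;
CIGARs are matches-only and indel CIGARs are rejected), quality-score
structure, M-bias and end-repair artefacts, PCR duplicates that are
actual copies (duplicates are flagged, not duplicated), hemimethylation
dynamics and partial methylation (states are binary per site), and
capture chemistry (on/off-target is drawn, not hybridised). Conclusions
about filter thresholds, attribution logic, correction set algebra and
estimator calibration transfer; conclusions about aligner behaviour do
not.

## Numerical and interface choices

* Coordinates are 1-based in tibbles and SAM, 0-based half-open in BED,
  following each format's convention; probe offsets are 0-based.
* Selection and tie-breaking in probe design are deterministic
  (score, then contig, then offset), making the probe set a
  permutation-invariant function of the candidate set. The ranking
  weights the annotations equally by default — the source design names
  its ranking criteria but not their weights, so they are exposed as a
  length-4 weight vector; prior capture depth enters as closeness to the
  median depth (dead and runaway regions both rank low), with missing
  depth neutral at 0.5.
* "Above-average GC" boosting is strictly greater than the selected
  set's mean; with all-equal GC nothing is boosted regardless of
  capacity.
* Window-frequency normalisation is min–max over the whole track; a
  degenerate track (max = min) normalises to all zeros.
* Per-contig mean depth is averaged over covered positions by default
  (configurable to all positions) and "base-space mapped" counts
  positions with depth ≥ 1; percent-aligned counts individual read
  records against a supplied pre-filter total.
* Degenerate inputs are surfaced, not smoothed over: zero conversion
  observations → undefined estimate; zero analyzable cytosines →
  undefined percentages with a flag; empty bait list → flagged undefined
  profile; contradictory reference edits → error.

## Problem sizes used in the tests

The bundled suite runs everything at desk scale, chosen so each property
is measured with real statistical content: unit models of 2 contigs × 4–8
kb, and the end-to-end checks at the study conditions they model —
depth 30 simulations on 20–30 kb genomes (≈ 2,000+ attributed reads for
assignment accuracy, ≥ 100,000 control-genome cytosine observations for
conversion-efficiency recovery, ≈ 1,000+ sub-genome site pairs for the
split-design concordance analogue, 1,000 random pileup columns for the
caller/oracle comparison, and all 8,100 2×2 tables with margins ≤ 12 for
the Fisher/enumeration comparison). The diploid genotyping path of
capture experiments (likelihood-based homozygous calling) is deliberately
not implemented; this package's scope is the polyploid frequency-based
pipeline.

## Known limitations

* Exact-match read-to-genome assignment implements "perfect hits" only;
  assigning mismatched alignments is out of scope.
* Fractional attribution of multi-genome diagnostic alleles exists as an
  idea but not as a default; the package deliberately reports only
  unambiguous attributions.
* The simulator's uniform substitution errors do not model
  bisulphite-specific error modes (incomplete denaturation,
  over-conversion of methylated C).
* Placement of contigs onto chromosome pseudomolecules is consumed as
  precomputed coordinates by the windowed reporting; the package does not
  perform the placement.
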