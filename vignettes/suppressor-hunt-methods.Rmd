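---
title: "Mapping bacterial suppressor mutations by whole-genome resequencing: methods and design"
author: "suppressorSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bacterial suppressor mutations by whole-genome resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppressorSeq)
```

## The problem

When a bacterial strain carrying a defective or foreign essential gene
(here, the cell-division GTPase FtsZ) regains viability, the rescue is
usually caused by a single spontaneous suppressor mutation somewhere in the
genome. Whole-genome resequencing of a panel of independently derived
suppressor strains finds that mutation by elimination: every strain is
aligned to the public reference, single-nucleotide variants are called per
strain, and variants are then compared *across* strains.

* Variants shared by **all** strains are differences between the common lab
  parent and the public reference ("parental" mutations) — they cannot
  explain a strain-specific phenotype.
* A variant present in **exactly one** strain is that strain's suppressor
  candidate ("unique").
* Anything in between ("shared subset") is not predicted by the
  single-mutation model and is flagged for manual review rather than
  silently dropped.

suppressorSeq implements this entire workflow — including a short-read
simulator that provides ground truth — so that every stage is testable on a
desk-scale toy genome without any sequence download.

## The pipeline stages

### Read alignment: pigeonhole seeding with a two-mismatch budget

Reads are 36-nt single-end. A read is accepted at a reference position only
if its total Hamming distance there is at most 2; among accepted placements
the read is

* **aligned** when the minimum-mismatch placement is unique,
* **suppressed** when two or more placements tie at the minimum
  (multi-mapped reads, typically from repeated elements), and
* **orphan** when no placement is within budget.

The candidate placements are found by exact lookup of the read's three
disjoint 12-mers (offsets 0, 12 and 24) on both the read and its reverse
complement. This is the pigeonhole guarantee: any placement with at most
two substitutions leaves at least one of the three seeds exact, so the
candidate set provably contains the true origin. The test suite checks the
aligner read-by-read against an exhaustive all-positions-both-strands
Hamming scan.

Two readings of the acceptance rule were possible; we adopt *total*
mismatches ≤ 2 (the behaviour of classic short-read aligners in `-v 2`
mode) rather than "no more than two *consecutive* mismatches", because the
consecutive-only reading would accept reads with unboundedly many scattered
mismatches and defeat the purpose of a quality screen. Suppression is
decided among best-tier placements only: a unique 0-mismatch placement with
an additional 2-mismatch placement elsewhere is aligned, not suppressed —
standard best-hit semantics.

No quality trimming or filtering is applied anywhere; the acceptance rule
is the entire quality screen, and simulated qualities are constant.

### Consensus SNV calling

For every reference position the pileup tallies the base each aligned read
places there (reverse-strand reads contribute reverse-complemented bases).
A variant is called when

* aligned depth ≥ `minDepth` (default 10),
* the most frequent base differs from the reference, and
* that base is carried by at least `minFraction` (default 0.99) of the
  covering reads.

The 99% threshold transcribes the strict read-agreement criterion used for
visual mutation calling at high coverage. An important arithmetic
consequence: **at depths below 100, "at least 99%" is equivalent to
unanimity** — a single discordant read (for example one sequencing error at
the site) vetoes the call. The binomial consequences at desk-scale coverage
are analysed under *Known limitations* below.

Ties for the most frequent base are broken in lexicographic base order;
with `minFraction > 0.5` a tie can never reach the support threshold, so
the tie-break never creates a call. Support fractions are compared with a
`1e-12` epsilon so that exact decimal fractions (e.g. 99/100 against the
literal 0.99) are not lost to floating-point representation. Positions
whose consensus equals the reference are never reported, even at 100%
agreement.

The caller has no gapped logic whatsoever. A strain whose true private
variant is a deletion therefore yields **zero** unique calls: reads
spanning the deletion junction orphan out (or align with mismatches that
never reach 99% agreement). This indel blindness is deliberate — it
reproduces the situation where point-mutation analysis cannot resolve a
strain — and is exercised by the simulator's deletion strains.

### Cross-strain classification

Per-strain call sets are merged on exact `(position, ref, alt)` keys into a
variant-by-strain incidence matrix; near-position merging is not attempted
in this SNV-only setting. Classification is purely arithmetic: present in
all strains → parental; in exactly one → unique; otherwise shared_subset
(flagged). Two strains disagreeing on the reference allele at one position
would indicate an upstream bug and raise an error rather than a class.

### Effect annotation and amber-suppressor readthrough

Variants are localized against the feature table (CDS / tRNA / intergenic;
overlapping features are rejected as an annotation-model error). For CDS
variants the codon is read on the coding strand, translated with the
standard bacterial genetic code, and written in resequencing-table notation
rather than HGVS: `L36Q` (missense), `E38E` (synonymous), `W286Stop`
(premature stop). Stop gains are subtyped by the created codon: TAG =
amber, TAA = ochre, TGA = opal.

The tRNA logic models amber suppression. One tRNA in the toy genome
carries the anticodon CGA; the single-base change CGA→CTA lets that
serine-tRNA pair with the TAG amber stop codon, so every strain carrying
the change occasionally misincorporates serine at amber stops. Strain
suppressor status is derived once per strain from its full call set
(parental plus unique variants). When an amber stop gain lands in an
**essential** gene of a suppressor strain, the mutation is only viable
because of readthrough; such calls are annotated `Q11Amber(S)` — the `(S)`
marks serine misincorporation — and `readthrough_applied` is set. Ochre
and opal stop gains are never modified.

Notation for stop gains follows the convention of the tables this report
format mirrors: plain `Stop` in non-essential genes, `Amber` (plus the
`(S)` suffix in suppressor strains) for amber stops in essential genes,
where viability hinges on the readthrough.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which the analysis stages are validated.

What it emulates:

* a single circular-treated linear reference (configurable length; 50 kb in
  the standard scenario, standing in for a 4.62-Mb chromosome);
* non-overlapping CDS features (valid ORFs: ATG start, stop end, no
  internal stop, 100–300 codons) and tRNA features, with intergenic gaps of
  at least 120 bp; a subset of genes is flagged essential;
* exactly one tRNA with the CGA anticodon — the amber-suppressor locus;
* a set of shared variants implanted into *all* strain genomes plus at most
  one private variant per strain (SNV or 3-bp deletion), with every
  requested protein-level effect verified against the annotation module at
  construction time;
* 36-nt single-end reads drawn uniformly from either strand, with each base
  substituted independently at a configurable error rate (0.003 in the
  standard scenario) and constant FASTQ qualities.

What it does **not** emulate: paired ends, quality-dependent or
context-dependent errors, PCR duplicates, coverage bias, insertion
elements/repeats (beyond whatever repeats arise by chance), plasmids, and
structural variation other than the small private deletions. Passing tests
therefore demonstrate correctness of the algorithms under a clean
substitution-error model, not robustness to every artefact of real
sequencing data.

Numerical/design choices in the generator:

* **Variant spacing**: implanted sites are kept at least one read length
  apart, so no read spans two variants and the mismatch-budget analysis
  stays clean.
* **Deletion length 3**: any length is equally invisible to an SNV caller;
  3 bases avoid frameshift bookkeeping in the truth annotation.
* **Seeds**: all randomness flows from one integer seed; per-strain read
  simulation uses `seed + strain index`, and variant implantation uses
  `seed + nStrains + 1`, so no two stages share a stream.
* **Read count** is `round(meanDepth × L / readLength)`, making expected
  per-base depth equal `meanDepth` exactly.

## The standard scenario

`standardScenario()` fixes the configuration used by the acceptance script
and the end-to-end tests: 50-kb genome, 20 CDS + 1 tRNA, 13 strains,
17 shared SNVs (1 anticodon CGA→CTA, 1 synonymous, 2 stop gains,
10 missense, 3 intergenic), private variants = 11 SNVs (2 amber stop gains
in essential genes, 2 intergenic, 7 missense) + 2 strains with a 3-bp
deletion, 36-nt reads at 30X, error rate 0.003.

```{r scenario}
standardScenario(seed = 0)
```

## Known limitations

**Strict consensus at desk-scale depth is unanimity, and unanimity is
fragile.** At 30X, a call requires every covering read to carry the
variant base. Each covering read shows a different base with probability
equal to the per-base error rate ε, so a true variant site survives in one
strain with probability about `(1 − ε)^d` ≈ `exp(−εd)`; at ε = 0.003 and
d = 30 that is ≈ 0.914 per strain. A *shared* variant must survive in all
13 strains simultaneously (≈ 0.914¹³ ≈ 0.31 per site), so on a typical run
only a minority of the 17 shared variants are classified parental; most
drop to shared_subset because one or two strains lost the call. Unique
variants need only their own strain (≈ 0.91 each), so 10–11 of the 11
private SNVs are typically recovered. The `summary` element of a run
reports exactly what was recovered, and the flagged shared_subset keys make
the mechanism visible. The published workflow did not face this regime: at
107–254X, 99% agreement tolerates one or two discordant reads. Raising
`meanDepth` (≥ several hundred) or lowering `minFraction` restores full
parental recovery, but the standard scenario deliberately keeps the stated
parameters rather than tuning them.

Other limitations: no gapped alignment or indel calling (deletions are
detectable only as an *absence* of a unique call); no copy-number or
rearrangement detection; haploid/clonal model only (no genotype
likelihoods); the toy genome's base composition is uniform, so seed-level
repeat structure is rarer than in a real genome.

## Problem sizes used in the test suite

Unit tests run on micro-genomes (hundreds of bases to 12 kb, 2–4 genes,
3 strains at 25X noise-free — chosen so the depth floor is never the
binding constraint and recovery is exact by construction). The oracle
equivalence checks use 1.5–2-kb genomes with 80–120 reads per seed so the
exhaustive Hamming scan stays fast. The end-to-end checks and the
acceptance script run the full standard scenario (13 × ~41,667 reads),
which completes in well under a minute on one core.
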